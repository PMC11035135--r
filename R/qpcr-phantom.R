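# synthetic Ct tables with known fold changes

#' Specify a synthetic qRT-PCR experiment
#'
#' Defines target genes with true expression fold changes of the case group
#' (e.g. reporter-expressing cells) over the control group (e.g. GFP-only
#' cells), a housekeeping gene, biological sample counts, technical
#' replicates, and Gaussian replicate noise on Ct. Sample-to-sample loading
#' differences are modeled as a per-sample Ct shift applied equally to target
#' and housekeeping wells of that sample, which the delta-Ct normalization
#' must cancel.
#'
#' @param genes data frame with columns `gene` and `fold` (true case/control
#'   fold change, > 0).
#' @param housekeeping housekeeping gene name.
#' @param n_per_group biological samples per group.
#' @param replicates technical Ct replicates per well.
#' @param baseline_ct named numeric vector of control-group mean Ct per gene
#'   (targets and housekeeping); genes not named default to 25 cycles.
#' @param noise_sd replicate Ct noise standard deviation (cycles).
#' @param sample_shift_sd per-sample loading shift sd (cycles).
#' @param efficiency assumed amplification efficiency in percent (100 =
#'   perfect doubling; fold f shifts Ct by -log(f)/log(1 + eff/100)).
#' @param groups named character vector `c(case = ..., control = ...)`.
#' @param seed integer seed.
#' @return an object of class `ct_design_spec`.
#' @export
ct_design_spec <- function(genes, housekeeping = "GAPDH", n_per_group = 3L,
                           replicates = 3L, baseline_ct = c(GAPDH = 18),
                           noise_sd = 0.2, sample_shift_sd = 0.3,
                           efficiency = 100,
                           groups = c(case = "Aqp1", control = "GFP"),
                           seed = 1L) {
  stop_if(!is.data.frame(genes) || !all(c("gene", "fold") %in% names(genes)),
          "genes must be a data frame with columns gene, fold")
  stop_if(any(genes$fold <= 0), "fold changes must be positive")
  stop_if(housekeeping %in% genes$gene,
          "housekeeping gene cannot also be a target")
  stop_if(!is_count(replicates) || replicates < 1, "replicates must be >= 1")
  stop_if(!is_count(n_per_group) || n_per_group < 1, "n_per_group must be >= 1")
  stop_if(noise_sd < 0 || sample_shift_sd < 0, "noise sds must be >= 0")
  stop_if(efficiency <= 0, "efficiency must be positive")
  stop_if(!all(c("case", "control") %in% names(groups)),
          "groups must name a case and a control")
  structure(list(genes = genes, housekeeping = housekeeping,
                 n_per_group = as.integer(n_per_group),
                 replicates = as.integer(replicates),
                 baseline_ct = baseline_ct, noise_sd = noise_sd,
                 sample_shift_sd = sample_shift_sd, efficiency = efficiency,
                 groups = groups, seed = as.integer(seed)),
            class = "ct_design_spec")
}

#' Generate a Ct table with known ground-truth fold changes
#'
#' Ct values are drawn so that at the assumed amplification efficiency the
#' expected delta-delta-Ct of each target equals -log2(fold) (exactly
#' -log(fold)/log(1 + eff/100) in general): the case group's target Ct is
#' lowered by that amount, while housekeeping T and sample loading shifts are
#' common to both roles and cancel in delta-Ct.
#'
#' @param spec a [ct_design_spec()].
#' @return list with `table` (long-format `ct_table` data frame: sample,
#'   group, gene, role, replicate, ct) and `truth` (data frame: gene, fold,
#'   expected_ddct).
#' @examples
#' sp <- ct_design_spec(data.frame(gene = "BiP", fold = 2),
#'                      noise_sd = 0, sample_shift_sd = 0)
#' tab <- make_ct_table(sp)
#' relative_expression(tab$table, "BiP", "Aqp1", "GFP")$fold  # exactly 2
#' @export
make_ct_table <- function(spec) {
  stop_if(!inherits(spec, "ct_design_spec"), "spec must be a ct_design_spec")
  base_of <- function(g) {
    if (g %in% names(spec$baseline_ct)) spec$baseline_ct[[g]] else 25
  }
  ct_step <- log(spec$genes$fold) / log(1 + spec$efficiency / 100)
  names(ct_step) <- spec$genes$gene
  rows <- list()
  with_seed(spec$seed, {
    for (grp_role in c("case", "control")) {
      grp <- spec$groups[[grp_role]]
      for (s in seq_len(spec$n_per_group)) {
        sample_id <- sprintf("%s_%d", grp, s)
        shift <- if (spec$sample_shift_sd > 0)
          stats::rnorm(1, sd = spec$sample_shift_sd) else 0
        genes <- c(spec$genes$gene, spec$housekeeping)
        for (g in genes) {
          is_hk <- g == spec$housekeeping
          mu <- base_of(g) + shift -
            (if (!is_hk && grp_role == "case") ct_step[[g]] else 0)
          ct <- mu + if (spec$noise_sd > 0)
            stats::rnorm(spec$replicates, sd = spec$noise_sd) else
              rep(0, spec$replicates)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample_id, group = grp, gene = g,
            role = if (is_hk) "housekeeping" else "target",
            replicate = seq_len(spec$replicates), ct = ct)
        }
      }
    }
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("ct_table", class(tab))
  truth <- data.frame(gene = spec$genes$gene, fold = spec$genes$fold,
                      expected_ddct = -unname(ct_step))
  list(table = tab, truth = truth)
}
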
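#!/usr/bin/env Rscript
# qRT-PCR analysis on generated Ct tables: transgene and UPR-panel fold
# changes by 2^(-ddCt) with per-gene t-tests, primer-efficiency QC, and the
# one-sided ER-stress-induction comparison.

suppressMessages(library(aqpquant))
dir.create("results", showWarnings = FALSE)
seed <- 20260103L

# study design: n = 3 biological samples per group, triplicate wells,
# 0.2-cycle replicate noise; the transgene is strongly induced, the UPR
# panel quiet except a two-fold chaperone induction
genes <- data.frame(gene = c("Aqp1", "BiP", "CHOP", "XBP1s", "Grp94"),
                    fold = c(64, 1.1, 1.0, 1.1, 2.0))
gen <- make_ct_table(ct_design_spec(
  genes, housekeeping = "GAPDH", n_per_group = 3L, replicates = 3L,
  noise_sd = 0.2, sample_shift_sd = 0.3, seed = seed))

res <- do.call(rbind, lapply(genes$gene, function(g) {
  r <- relative_expression(gen$table, g, "Aqp1", "GFP")
  data.frame(gene = g, fold_true = genes$fold[genes$gene == g],
             fold = r$fold, se_ddct = r$se_ddct, p_two_sided = r$p_value)
}))
write.csv(format(res, digits = 6), "results/qpcr_fold_changes.csv",
          row.names = FALSE)
message("fold changes (Aqp1/GFP):")
for (i in seq_len(nrow(res)))
  message(sprintf("  %-6s true %5.1f  est %6.2f  p = %.3g", res$gene[i],
                  res$fold_true[i], res$fold[i], res$p_two_sided[i]))

# ER-stress induction (tunicamycin-style): direction known a priori, so the
# test is one-sided for up-regulation
stress <- make_ct_table(ct_design_spec(
  data.frame(gene = "BiP", fold = 4),
  groups = c(case = "tunicamycin", control = "vehicle"),
  n_per_group = 3L, noise_sd = 0.2, seed = seed + 1L))
p1 <- ddct_test(stress$table, "BiP", "tunicamycin", "vehicle",
                alternative = "less")
message(sprintf("BiP induction under ER stress: one-sided p = %.4g", p1))

# primer-efficiency QC on a perfect-doubling dilution series
dil <- make_assay_fixture("dilution_series", list(slope = -1 / log10(2)))
eff <- primer_efficiency(dil$data$dilution, dil$data$ct)
write.csv(data.frame(slope = eff$slope, efficiency_pct = eff$efficiency_pct,
                     bip_stress_p_one_sided = p1),
          "results/qpcr_efficiency.csv", row.names = FALSE)
message(sprintf("primer efficiency: %.2f%% (slope %.4f)",
                eff$efficiency_pct, eff$slope))
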
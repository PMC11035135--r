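# readers and writers: NIfTI + JSON sidecar for diffusion series and maps,
# multi-page TIFF + JSON for tomograms, CSV for tables, PNG for renders
#
# unit-bearing sidecar keys are spelled out (bvalues_ms_per_um2, voxel_mm,
# voxel_um) so files cannot silently drift units

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a diffusion series as NIfTI plus JSON sidecar
#'
#' The image stack is stored as a NIfTI file (double precision, so the round
#' trip is bit-exact) with the b-index as the last dimension; b-values, voxel
#' size and acquisition metadata go to a JSON sidecar next to it.
#'
#' @param series a [diffusion_series()].
#' @param path output `.nii` path; the sidecar is written alongside with a
#'   `.json` extension.
#' @return `write_diffusion_series()` returns `path` invisibly;
#'   `read_diffusion_series()` returns the [diffusion_series()].
#' @export
write_diffusion_series <- function(series, path) {
  stop_if(!inherits(series, "diffusion_series"), "series must be a diffusion_series")
  img <- RNifti::asNifti(series$data, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(
    list(bvalues_ms_per_um2 = series$bvalues, voxel_mm = series$voxel_mm,
         meta = series$meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_diffusion_series
#' @export
read_diffusion_series <- function(path) {
  stop_if(!file.exists(path), sprintf("no such file: %s", path))
  sc <- sidecar_path(path)
  stop_if(!file.exists(sc), sprintf("missing sidecar: %s", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  stop_if(is.null(meta$bvalues_ms_per_um2),
          "sidecar lacks field bvalues_ms_per_um2")
  stop_if(is.null(meta$voxel_mm), "sidecar lacks field voxel_mm")
  arr <- as.array(RNifti::readNifti(path))
  arr <- structure(as.vector(arr), dim = dim(arr))
  stop_if(dim(arr)[length(dim(arr))] != length(meta$bvalues_ms_per_um2),
          "sidecar field bvalues_ms_per_um2 does not match the stack depth")
  diffusion_series(arr, meta$bvalues_ms_per_um2, meta$voxel_mm,
                   if (is.null(meta$meta)) list() else meta$meta)
}

#' Write / read a refractive-index tomogram as multi-page TIFF plus JSON
#'
#' Each z-slice becomes one TIFF page. TIFF samples are 32-bit values scaled
#' to `[0, 1]`, so the index grid is stored as `n - offset` with
#' `offset = 1` recorded in the sidecar (refractive indices of aqueous
#' samples lie in (1, 2)); the quantization step is ~2.3e-10 refractive index
#' units, far below reconstruction noise. For a bit-exact round trip use
#' [write_diffusion_series()]'s NIfTI container instead.
#'
#' @param tom a [tomogram()].
#' @param path output `.tif` path; a `.json` sidecar with
#'   `voxel_um`, `n_surr` and `offset_ri` is written alongside.
#' @return `write_tomogram()` returns `path` invisibly; `read_tomogram()`
#'   the [tomogram()].
#' @export
write_tomogram <- function(tom, path) {
  stop_if(!inherits(tom, "tomogram"), "tom must be a tomogram")
  offset <- 1
  rng <- range(tom$n - offset)
  stop_if(rng[1] < 0 || rng[2] > 1,
          "refractive indices outside (1, 2) cannot be stored in this container")
  pages <- lapply(seq_len(dim(tom$n)[3]), function(k) tom$n[, , k] - offset)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(voxel_um = tom$voxel_um, n_surr = tom$n_surr, offset_ri = offset),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tomogram
#' @export
read_tomogram <- function(path) {
  stop_if(!file.exists(path), sprintf("no such file: %s", path))
  sc <- sidecar_path(path)
  stop_if(!file.exists(sc), sprintf("missing sidecar: %s", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  stop_if(is.null(meta$voxel_um), "sidecar lacks field voxel_um")
  stop_if(is.null(meta$n_surr), "sidecar lacks field n_surr")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  offset <- if (is.null(meta$offset_ri)) 0 else meta$offset_ri
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] + offset
  tomogram(arr, meta$voxel_um, meta$n_surr)
}

#' Write a diffusion map as NIfTI (invalid voxels stored as NaN)
#'
#' @param map a `diffusion_map` from [fit_adc_map()].
#' @param path output `.nii` path; sidecar records b-values and voxel size.
#' @return `path`, invisibly.
#' @export
write_diffusion_map <- function(map, path) {
  stop_if(!inherits(map, "diffusion_map"), "map must be a diffusion_map")
  RNifti::writeNifti(RNifti::asNifti(map$D, datatype = "double"), path,
                     datatype = "double")
  jsonlite::write_json(
    list(bvalues_ms_per_um2 = map$bvalues, voxel_mm = map$voxel_mm,
         units = "um^2/ms"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a rendered 8-bit diffusion map as PNG
#'
#' @param rendered a `rendered_map` from [render_diffusion_map()].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_rendered_png <- function(rendered, path) {
  stop_if(!inherits(rendered, "rendered_map"), "rendered must be a rendered_map")
  png::writePNG(rendered$pixels / 255, path)
  invisible(path)
}

#' Write / read a Ct table as CSV with one column per technical replicate
#'
#' The on-disk layout is wide — `sample, group, gene, role,
#' ct_rep1..ct_repN` — while the in-memory `ct_table` is long (one row per
#' replicate); the readers convert between the two.
#'
#' @param table a long-format `ct_table`.
#' @param path CSV path.
#' @return `write_ct_table()` returns `path` invisibly; `read_ct_table()`
#'   the long-format `ct_table`.
#' @export
write_ct_table <- function(table, path) {
  need <- c("sample", "group", "gene", "role", "replicate", "ct")
  stop_if(!all(need %in% names(table)), "not a long-format ct_table")
  wide <- stats::reshape(
    as.data.frame(table)[need], idvar = c("sample", "group", "gene", "role"),
    timevar = "replicate", direction = "wide", sep = "_rep")
  names(wide) <- sub("^ct_rep", "ct_rep", names(wide))
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  stop_if(!file.exists(path), sprintf("no such file: %s", path))
  wide <- utils::read.csv(path, check.names = FALSE)
  repcols <- grep("^ct_rep", names(wide), value = TRUE)
  stop_if(length(repcols) == 0L, "no ct_rep* columns found")
  long <- stats::reshape(wide, varying = repcols, v.names = "ct",
                         timevar = "replicate",
                         times = as.integer(sub("^ct_rep", "", repcols)),
                         direction = "long")
  long <- long[order(long$sample, long$gene, long$replicate),
               c("sample", "group", "gene", "role", "replicate", "ct")]
  rownames(long) <- NULL
  long <- long[!is.na(long$ct), , drop = FALSE]
  class(long) <- c("ct_table", class(long))
  long
}
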
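# shared validation and unit helpers

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 0

#' Convert diffusivity between micrometer^2/ms and mm^2/s
#'
#' The native unit of this package is um^2/ms (so that b in ms/um^2 makes b*D
#' dimensionless); the clinical literature often uses mm^2/s. The conversion
#' is exact: 1 um^2/ms = 1e-3 mm^2/s.
#'
#' @param D diffusivity in um^2/ms.
#' @param D_mm2s diffusivity in mm^2/s.
#' @return the converted value.
#' @examples
#' mm2s_to_um2ms(um2ms_to_mm2s(1.23)) == 1.23
#' @export
um2ms_to_mm2s <- function(D) D * 1e-3

#' @rdname um2ms_to_mm2s
#' @export
mm2s_to_um2ms <- function(D_mm2s) D_mm2s * 1e3

# standard error of the mean, sample sd (n - 1 denominator)
sem <- function(x) stats::sd(x) / sqrt(length(x))

# seeded evaluation without touching the caller's RNG state
with_seed <- function(seed, code) {
  stop_if(!is_count(seed + 0), "seed must be a single non-negative integer")
  withr::with_seed(as.integer(seed), code)
}
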
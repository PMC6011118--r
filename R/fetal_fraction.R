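#' Fragment-size ratio of short to long cfDNA fragments
#'
#' Fetal cfDNA runs shorter than maternal cfDNA, so the ratio of short-
#' to long-fragment counts rises with the fetal fraction and serves as a
#' sequencing-only proxy for it. Both windows are inclusive of their
#' endpoints; the defaults (short 100-150 bp, long 163-169 bp) bracket
#' the fetal mode below and the maternal 166 bp mode above.
#'
#' @param lengths integer vector of fragment lengths in bp (nonempty).
#' @param short_window,long_window inclusive `c(lo, hi)` windows in bp;
#'   must be disjoint.
#' @param gate gate cut-off carried into `passes_gate` (strict `>`).
#' @return An object of class `size_ratio_result`: list with
#'   `size_ratio`, `n_short`, `n_long`, `passes_gate`.
#'   When no fragment falls in the long window the ratio is undefined
#'   and an error of class `niptscreen_non_evaluable` is raised — a
#'   distinct condition from failing the gate.
#' @export
size_ratio <- function(lengths, short_window = c(100, 150),
                       long_window = c(163, 169), gate = 0.84) {
  stopifnot(length(lengths) > 0, length(short_window) == 2,
            length(long_window) == 2,
            short_window[1] <= short_window[2],
            long_window[1] <= long_window[2])
  if (short_window[2] >= long_window[1] && long_window[2] >= short_window[1]) {
    stop("short and long windows must be disjoint")
  }
  n_short <- sum(lengths >= short_window[1] & lengths <= short_window[2])
  n_long <- sum(lengths >= long_window[1] & lengths <= long_window[2])
  if (n_long == 0) {
    stop(structure(class = c("niptscreen_non_evaluable", "error",
                             "condition"),
                   list(message = "no fragments in the long window; size ratio undefined",
                        call = sys.call(-1))))
  }
  ratio <- n_short / n_long
  structure(list(size_ratio = ratio, n_short = n_short, n_long = n_long,
                 passes_gate = size_gate(ratio, gate)),
            class = "size_ratio_result")
}

#' @export
print.size_ratio_result <- function(x, ...) {
  cat(sprintf("size ratio %.4f (%d short / %d long) - gate %s\n",
              x$size_ratio, x$n_short, x$n_long,
              if (x$passes_gate) "passed" else "FAILED"))
  invisible(x)
}

#' Fetal-fraction gate on the size ratio
#'
#' Strict comparison: a ratio exactly at the cut-off fails. The default
#' 0.84 is the minimum considered to carry enough fetal signal for
#' aneuploidy scoring.
#'
#' @param ratio size ratio (or a [size_ratio()] result).
#' @param cutoff gate value, default 0.84.
#' @return `TRUE` iff `ratio > cutoff`.
#' @export
size_gate <- function(ratio, cutoff = 0.84) {
  if (inherits(ratio, "size_ratio_result")) ratio <- ratio$size_ratio
  ratio > cutoff
}

#' Calibrate size ratio against known fetal fraction
#'
#' Ordinary least-squares line mapping size ratio to fetal fraction.
#' The relationship is positively linear over the gestational range of
#' interest; the fit's slope is required to be positive.
#'
#' @param ratios numeric vector of size ratios.
#' @param ff numeric vector of known fetal fractions (same length,
#'   >= 3 pairs, non-degenerate ratios).
#' @return An object of class `size_calibration`: `slope`, `intercept`,
#'   `r` (Pearson correlation), `n`.
#' @export
fit_size_calibration <- function(ratios, ff) {
  stopifnot(length(ratios) == length(ff), length(ratios) >= 3)
  if (stats::sd(ratios) == 0) stop("degenerate design: constant ratios")
  fit <- stats::lm(ff ~ ratios)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope is not positive; ratio does not track fetal fraction in these data")
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(ratios, ff), n = length(ratios)),
            class = "size_calibration")
}

#' @export
print.size_calibration <- function(x, ...) {
  cat(sprintf("size_calibration: ff = %.4f x ratio %+.4f (r = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' Estimate fetal fraction from a size ratio
#'
#' @param calibration a [fit_size_calibration()] result.
#' @param ratio size ratio (vectorized).
#' @return Estimated fetal fraction, clamped to `[0, 1]`.
#' @export
apply_size_calibration <- function(calibration, ratio) {
  stopifnot(inherits(calibration, "size_calibration"))
  pmin(pmax(calibration$intercept + calibration$slope * ratio, 0), 1)
}
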
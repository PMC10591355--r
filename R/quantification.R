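# Scalar assay quantifications: RNAscope H-score and qPCR standard-curve
# absolute quantification (vector copy number, circular arRNA copies).

#' RNAscope H-score
#'
#' The RNAscope signal is binned into five dot-density groups per cell; the
#' H-score weights the percentage of cells in each bin by the bin index:
#' `0*p0 + 1*p1 + 2*p2 + 3*p3 + 4*p4`, ranging 0-400.
#'
#' @param bins Numeric vector of length 5: percentage of cells in bins
#'   0..4. Must sum to 100 (tolerance 1e-6).
#' @return The H-score (numeric scalar in \[0, 400\]).
#' @examples
#' h_score(c(0, 0, 0, 0, 100))    # 400
#' h_score(c(20, 20, 20, 20, 20)) # 200
#' @export
h_score <- function(bins) {
  bins <- as.numeric(bins)
  if (length(bins) != 5L || any(is.na(bins)))
    stop("bins must be 5 numeric percentages (bins 0..4)", call. = FALSE)
  if (any(bins < 0) || any(bins > 100))
    stop("bin percentages must lie in [0, 100]", call. = FALSE)
  if (abs(sum(bins) - 100) > 1e-6)
    stop("bin percentages must sum to 100 (got ", sum(bins), ")",
         call. = FALSE)
  sum(bins * 0:4)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(copies). A perfect doubling per
#' cycle gives slope -1/log10(2) = -3.3219 and amplification efficiency
#' `10^(-1/slope) - 1 = 1` (i.e. 100%).
#'
#' @param copies Known input copy numbers of the standards (> 0).
#' @param cq Measured quantification cycles, same length.
#' @return Object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency` (fraction; 1 = 100%), and the Cq range of the
#'   standards (used to flag extrapolation).
#' @export
fit_standard_curve <- function(copies, cq) {
  copies <- as.numeric(copies); cq <- as.numeric(cq)
  if (length(copies) != length(cq))
    stop("copies and cq must have equal length", call. = FALSE)
  if (length(copies) < 3L)
    stop("need at least 3 standard points", call. = FALSE)
  if (any(copies <= 0)) stop("copies must be positive", call. = FALSE)
  if (length(unique(copies)) < 2L)
    stop("standards have zero variance in copy number", call. = FALSE)
  fit <- lm(cq ~ log10(copies))
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope >= 0)
    warning("non-negative slope: Cq should decrease with input copies")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((cq - mean(cq))^2)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 efficiency = 10^(-1 / slope) - 1,
                 cq_range = range(cq)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve: Cq = %.4f %+.4f * log10(copies); R^2 = %.4f; efficiency = %.1f%%\n",
    x$intercept, x$slope, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Absolute quantification from a standard curve
#'
#' Inverts the standard curve at a sample's Cq:
#' `copies = 10^((Cq - intercept) / slope)`. Technical replicates (e.g.
#' triplicate Cq measurements) are averaged before inversion and their SD is
#' reported. Cq values outside the range spanned by the standards are
#' flagged as extrapolated, not rejected.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param cq Numeric vector of replicate Cq measurements for one sample.
#' @return List: `copies`, `cq_mean`, `cq_sd` (NA for a single
#'   measurement), `extrapolated`.
#' @examples
#' curve <- fit_standard_curve(10^(0:5), 40 - 3.3219 * (0:5))
#' absolute_quantify(curve, 36.6781)$copies  # ~10
#' @export
absolute_quantify <- function(curve, cq) {
  stopifnot(is(curve, "standard_curve"))
  cq <- as.numeric(cq)
  if (!length(cq) || any(is.na(cq))) stop("invalid Cq values", call. = FALSE)
  m <- mean(cq)
  list(copies = 10^((m - curve$intercept) / curve$slope),
       cq_mean = m,
       cq_sd = if (length(cq) > 1L) sd(cq) else NA_real_,
       extrapolated = m < curve$cq_range[1] || m > curve$cq_range[2])
}
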
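#' Logit and inverse-logit transforms
#'
#' All adjustment and regression stages of the pipeline operate on the
#' logit of lifetime prevalence, which respects the (0, 1) bound of a
#' proportion. `logit()` requires its argument strictly inside (0, 1);
#' boundary observations must first be offset (see
#' [squeeze_boundary()]).
#'
#' @param p proportion(s) in (0, 1).
#' @param x real number(s).
#' @return `logit` returns log(p / (1 - p)); `expit` returns
#'   1 / (1 + exp(-x)).
#' @examples
#' logit(0.5)          # 0
#' expit(logit(0.2))   # 0.2
#' @export
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("logit() requires values strictly inside (0, 1)", call. = FALSE)
  }
  log(p / (1 - p))
}

#' @rdname logit
#' @export
expit <- function(x) {
  1 / (1 + exp(-x))
}

#' Delta-method standard error on the logit scale
#'
#' For a prevalence estimate `mean` with natural-scale standard error
#' `se`, the first-order (delta-method) standard error of
#' `logit(mean)` is `se / (mean * (1 - mean))`.
#'
#' @param mean prevalence in (0, 1).
#' @param se natural-scale standard error, > 0.
#' @return logit-scale standard error, strictly positive and finite.
#' @export
se_logit <- function(mean, se) {
  stopifnot(all(mean > 0 & mean < 1), all(se > 0))
  se / (mean * (1 - mean))
}

#' Offset boundary prevalences away from 0 and 1
#'
#' Observed proportions of exactly 0 or 1 have infinite logit. They are
#' offset to `0.5 / n` and `1 - 0.5 / n` respectively, where `n` is the
#' observation's sample size (taken as 100 when absent) — the minimal
#' distortion that keeps the logit finite.
#'
#' @param p observed proportion(s) in \[0, 1\].
#' @param n sample size(s); `NA` entries fall back to 100.
#' @return proportions strictly inside (0, 1).
#' @export
squeeze_boundary <- function(p, n = NA_real_) {
  stopifnot(all(p >= 0 & p <= 1))
  n <- rep_len(ifelse(is.na(n), 100, n), length(p))
  p <- ifelse(p == 0, 0.5 / n, p)
  ifelse(p == 1, 1 - 0.5 / n, p)
}
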
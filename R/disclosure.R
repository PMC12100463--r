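#' Fit the survey-mode disclosure model
#'
#' Face-to-face interviews under-elicit disclosure of sexual violence
#' relative to confidential self-reports. From studies observing the
#' same population under both modes, the confidential logit prevalence
#' is regressed (ordinary least squares) on the face-to-face logit
#' prevalence; the fitted line is later used to linearly transform
#' face-to-face observations onto the confidential scale.
#'
#' @param pairs data frame with columns `logit_ftf` and `logit_conf`,
#'   one row per paired-mode study.
#' @param min_pairs minimum studies required (default 5); with fewer,
#'   the fallback transform `fallback` is returned (flagged).
#' @param fallback list(intercept, slope, residual_sd) used when too
#'   few pairs are available; default is the identity with zero
#'   residual variance.
#' @return object of class `"svac_disclosure"` with `intercept`,
#'   `slope`, `residual_sd`, `n_pairs`, `estimated`.
#' @export
fit_disclosure <- function(pairs, min_pairs = 5,
                           fallback = list(intercept = 0, slope = 1,
                                           residual_sd = 0)) {
  if (nrow(pairs) < min_pairs) {
    warning("fewer than ", min_pairs,
            " paired-mode studies; using fallback transform")
    return(structure(list(intercept = fallback$intercept,
                          slope = fallback$slope,
                          residual_sd = fallback$residual_sd,
                          n_pairs = nrow(pairs), estimated = FALSE),
                     class = "svac_disclosure"))
  }
  fit <- stats::lm(logit_conf ~ logit_ftf, data = pairs)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 residual_sd = summary(fit)$sigma,
                 n_pairs = nrow(pairs), estimated = TRUE),
            class = "svac_disclosure")
}

#' @export
print.svac_disclosure <- function(x, ...) {
  cat(sprintf(paste0("Disclosure transform: logit(conf) = %.4f + %.4f",
                     " * logit(ftf)  [resid SD %.4f, n = %d]\n"),
              x$intercept, x$slope, x$residual_sd, x$n_pairs))
  invisible(x)
}

#' @export
coef.svac_disclosure <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.svac_disclosure <- function(object, logit_ftf, ...) {
  object$intercept + object$slope * logit_ftf
}

#' Apply the disclosure correction
#'
#' Face-to-face observations are mapped onto the confidential scale,
#' `logit(mean_adj) = intercept + slope * logit(mean)`, their logit
#' variance increased by the model's residual variance, and retagged
#' `mode = "confidential"`. Confidential observations are the reference
#' and pass through unchanged.
#'
#' @param obs observation table.
#' @param model a `svac_disclosure`.
#' @return observation table with all rows on the confidential mode;
#'   adjusted rows carry `disclosure_adjusted = TRUE`.
#' @export
apply_disclosure <- function(obs, model) {
  obs$disclosure_adjusted <- FALSE
  ftf <- which(obs$mode == "face_to_face")
  for (i in ftf) {
    lg <- model$intercept + model$slope * logit(obs$mean[i])
    v <- se_logit(obs$mean[i], obs$se[i])^2 + model$residual_sd^2
    m <- expit(lg)
    obs$mean[i] <- m
    obs$se[i] <- sqrt(v) * m * (1 - m)
    obs$mode[i] <- "confidential"
    obs$disclosure_adjusted[i] <- TRUE
  }
  obs
}
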
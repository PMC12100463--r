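#' Within-study definition pairs
#'
#' Finds observation pairs that share (source_id, location, year, sex,
#' age span) and differ only in case definition, one side being the
#' reference. Each pair yields the logit difference `d =
#' logit(mean_alt) - logit(mean_ref)` with the delta-method combined
#' standard error — the raw material of the crosswalk meta-regression.
#'
#' @param obs observation table.
#' @return data frame with one row per pair: `tag`, `d`, `se`, and the
#'   shared cell keys. Empty (zero rows) when no cell is reported under
#'   both the reference and an alternative definition.
#' @export
pair_within_study <- function(obs) {
  key <- interaction(obs$source_id, obs$location_id, obs$year, obs$sex,
                     obs$age_start, obs$age_end, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    grp <- obs[key == k, , drop = FALSE]
    ref <- grp[grp$definition == "reference", , drop = FALSE]
    alt <- grp[grp$definition != "reference", , drop = FALSE]
    if (nrow(ref) == 0 || nrow(alt) == 0) next
    r <- ref[1, ]
    for (j in seq_len(nrow(alt))) {
      a <- alt[j, ]
      out[[length(out) + 1]] <- data.frame(
        source_id = a$source_id, location_id = a$location_id,
        year = a$year, sex = a$sex, age_start = a$age_start,
        tag = a$definition,
        d = logit(a$mean) - logit(r$mean),
        se = sqrt(se_logit(a$mean, a$se)^2 + se_logit(r$mean, r$se)^2),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(source_id = character(), location_id = numeric(),
                      year = numeric(), sex = character(),
                      age_start = numeric(), tag = character(),
                      d = numeric(), se = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# inverse-variance weighted mean with iterative trimming: refit after
# dropping the largest |standardised residual| until trim_fraction of
# pairs is removed
trimmed_ivw <- function(d, se, trim_fraction) {
  n <- length(d)
  n_trim <- floor(trim_fraction * n)
  keep <- rep(TRUE, n)
  for (i in seq_len(n_trim)) {
    w <- 1 / se[keep]^2
    b <- sum(w * d[keep]) / sum(w)
    z <- abs(d - b) / se
    z[!keep] <- -Inf
    keep[which.max(z)] <- FALSE
  }
  w <- 1 / se[keep]^2
  beta <- sum(w * d[keep]) / sum(w)
  list(beta = beta, beta_se = sqrt(1 / sum(w)), n_used = sum(keep))
}

#' Fit the case-definition crosswalk
#'
#' Trimmed inverse-variance-weighted meta-regression of within-study
#' logit differences: per alternative-definition tag, the weighted mean
#' of `d` after iteratively removing the `trim_fraction` largest
#' standardised residuals (fit, drop the worst pair, refit). Tags with
#' fewer than `min_pairs` pairs are left unestimated and fall back to
#' the `prior_offsets` when the model is applied.
#'
#' @param pairs from [pair_within_study()] (or any data frame with
#'   columns `tag`, `d`, `se`).
#' @param trim_fraction fraction of pairs discarded per tag
#'   (default 0.1).
#' @param min_pairs minimum pairs required to estimate a tag
#'   (default 5).
#' @param prior_offsets named fallback logit offsets for unestimated
#'   tags (optional).
#' @return object of class `"svac_crosswalk"`: per-tag `beta`,
#'   `beta_se`, `n_pairs_used`, `estimated` flag. The reference
#'   definition has `beta = 0` by construction.
#' @export
fit_crosswalk <- function(pairs, trim_fraction = 0.1, min_pairs = 5,
                          prior_offsets = NULL) {
  tags <- setdiff(.obs_definitions, "reference")
  beta <- stats::setNames(rep(NA_real_, length(tags)), tags)
  beta_se <- beta
  n_used <- stats::setNames(integer(length(tags)), tags)
  estimated <- stats::setNames(rep(FALSE, length(tags)), tags)
  for (tag in tags) {
    p <- pairs[pairs$tag == tag, , drop = FALSE]
    if (nrow(p) < min_pairs) {
      if (!is.null(prior_offsets) && tag %in% names(prior_offsets)) {
        beta[tag] <- prior_offsets[[tag]]
        beta_se[tag] <- 0
      }
      next
    }
    fit <- trimmed_ivw(p$d, p$se, trim_fraction)
    beta[tag] <- fit$beta
    beta_se[tag] <- fit$beta_se
    n_used[tag] <- fit$n_used
    estimated[tag] <- TRUE
  }
  structure(list(beta = beta, beta_se = beta_se, n_pairs_used = n_used,
                 estimated = estimated, trim_fraction = trim_fraction),
            class = "svac_crosswalk")
}

#' @export
print.svac_crosswalk <- function(x, ...) {
  cat("Case-definition crosswalk (trimmed IVW, trim =",
      x$trim_fraction, ")\n")
  print(data.frame(beta = round(x$beta, 4), se = round(x$beta_se, 4),
                   pairs = x$n_pairs_used, estimated = x$estimated))
  invisible(x)
}

#' @export
coef.svac_crosswalk <- function(object, ...) object$beta

#' Apply the crosswalk to observations
#'
#' Alternative-definition observations are moved onto the reference
#' definition on the logit scale: `logit(mean_adj) = logit(mean) -
#' beta[tag]`. A positive beta (the definition captures more cases than
#' the reference) therefore adjusts downwards; negative betas adjust
#' upwards. Adjustment uncertainty is propagated additively on the
#' logit-variance scale (`var_adj = var + beta_se^2`), so adjusted
#' uncertainty never shrinks. Reference observations pass through
#' unchanged.
#'
#' @param obs observation table.
#' @param model a `svac_crosswalk`.
#' @return observation table with all rows on the reference definition;
#'   adjusted rows are retagged `definition = "reference"` and carry
#'   `crosswalked = TRUE`.
#' @export
apply_crosswalk <- function(obs, model) {
  obs$crosswalked <- FALSE
  for (i in seq_len(nrow(obs))) {
    tag <- obs$definition[i]
    if (tag == "reference") next
    b <- model$beta[[tag]]
    if (is.na(b)) {
      stop("definition '", tag, "' is unestimated and no prior offset ",
           "was configured", call. = FALSE)
    }
    lg <- logit(obs$mean[i]) - b
    v <- se_logit(obs$mean[i], obs$se[i])^2 + model$beta_se[[tag]]^2
    m <- expit(lg)
    obs$mean[i] <- m
    obs$se[i] <- sqrt(v) * m * (1 - m)   # back to natural scale
    obs$definition[i] <- "reference"
    obs$crosswalked[i] <- TRUE
  }
  obs
}
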
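#' ST-GPR configuration
#'
#' Hyperparameters of the three-stage spatiotemporal Gaussian process
#' regression. None of these smoothing constants is dictated by the
#' estimation problem itself; the defaults are conventional values and
#' all are exposed here.
#'
#' @param zeta spatial weight in (0,1): an observation contributes
#'   `zeta` to cells in its own country, `zeta*(1-zeta)` to its region,
#'   `zeta*(1-zeta)^2` to its super-region, 0 elsewhere.
#' @param lam time-weight exponent (lambda > 0) in
#'   `w_time = (1 - (|dt|/(1+max_dt))^lambda)^3`.
#' @param omega age-weight decay: `w_age = exp(-omega * |d_index|)`
#'   over canonical age-group indices.
#' @param gpr_scale Matern length-scale in years.
#' @param amplitude_mad_mult multiplier on the MAD-based GP amplitude.
#' @param amplitude_floor lower bound for the GP amplitude (logit
#'   scale).
#' @param n_draws posterior draws per cell (>= 100; default 1000).
#' @return config list.
#' @export
stgpr_config <- function(zeta = 0.9, lam = 0.5, omega = 0.5,
                         gpr_scale = 10, amplitude_mad_mult = 1.0,
                         amplitude_floor = 0.05, n_draws = 1000) {
  stopifnot(zeta > 0, zeta < 1, lam > 0, omega >= 0, gpr_scale > 0,
            n_draws >= 100)
  as.list(environment())
}

# effect lookup with 0 for levels unseen at fit time
.effect <- function(table, key) {
  v <- table[as.character(key)]
  v[is.na(v)] <- 0
  unname(v)
}

#' Stage 1: pooled linear prior
#'
#' A weighted linear model on the logit scale fitted to both sexes at
#' once — fixed effects for sex, canonical age group, and a linear
#' calendar-year trend, with nested region / super-region random
#' intercepts (shrunk via [lme4::lmer]) so the global sex ratio and
#' data-rich neighbours inform data-sparse countries. Every grid cell
#' is predicted, including countries with no data, which inherit their
#' region / super-region effects.
#'
#' Degenerate designs fall back gracefully: if the mixed model cannot
#' be fitted (too few observations or grouping levels) a weighted fixed
#' -effects model is used, dropping rank-deficient terms; a single
#' observation yields a constant surface at its logit mean.
#'
#' @param obs observation table, single canonical age groups, both
#'   sexes.
#' @param hierarchy a `svac_hierarchy`.
#' @param grid data frame of cells to predict (`location_id`, `year`,
#'   `age_start`, `sex`).
#' @param config from [stgpr_config()].
#' @return the grid with a `value` column (logit scale), classed
#'   `"svac_surface"`, attribute `stage = "stage1"`; the fitted sex
#'   coefficient and effect tables are attached as attributes.
#' @export
stage1_fit <- function(obs, hierarchy, grid, config = stgpr_config()) {
  stopifnot(nrow(obs) >= 1)
  cn <- countries(hierarchy)
  df <- data.frame(
    y = logit(obs$mean),
    w = 1 / obs_logit_variance(obs),
    sex = obs$sex,
    age_f = factor(obs$age_start),
    year_c = obs$year - mean(grid$year),
    region = factor(cn$region_id[match(obs$location_id, cn$location_id)]),
    super = factor(cn$super_region_id[match(obs$location_id, cn$location_id)]))

  int <- stats::weighted.mean(df$y, df$w)
  sex_eff <- c(female = 0, male = 0)
  age_eff <- numeric(0); year_slope <- 0
  region_eff <- numeric(0); super_eff <- numeric(0)

  fill_fixed <- function(cf) {
    if ("sexmale" %in% names(cf)) sex_eff["male"] <<- cf[["sexmale"]]
    a <- grep("^age_f", names(cf), value = TRUE)
    age_eff <<- stats::setNames(unname(cf[a]), sub("^age_f", "", a))
    if ("year_c" %in% names(cf)) year_slope <<- cf[["year_c"]]
    int <<- cf[["(Intercept)"]]
  }

  fitted_ok <- FALSE
  if (nrow(df) >= 10 && nlevels(droplevels(df$region)) >= 2) {
    fit <- tryCatch(
      lme4::lmer(y ~ sex + age_f + year_c + (1 | super) + (1 | region),
                 data = df, weights = w,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- lme4::fixef(fit)
      cf[is.na(cf)] <- 0
      fill_fixed(cf)
      re <- lme4::ranef(fit)
      region_eff <- stats::setNames(re$region[[1]], rownames(re$region))
      super_eff <- stats::setNames(re$super[[1]], rownames(re$super))
      fitted_ok <- TRUE
    }
  }
  if (!fitted_ok && nrow(df) >= 3) {
    keep <- c(if (length(unique(df$sex)) > 1) "sex",
              if (nlevels(droplevels(df$age_f)) > 1) "age_f",
              if (length(unique(df$year_c)) > 1) "year_c")
    form <- stats::reformulate(if (length(keep)) keep else "1", response = "y")
    fit <- stats::lm(form, data = df, weights = w)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      warning("rank-deficient stage-1 design; dropping aliased terms")
      cf[is.na(cf)] <- 0
    }
    fill_fixed(cf)
    fitted_ok <- TRUE
  }
  # (fewer than 3 rows: constant surface at the weighted logit mean)

  g_age <- .effect(age_eff, grid$age_start)
  g_sex <- ifelse(grid$sex == "male", sex_eff[["male"]], 0)
  g_region <- .effect(region_eff,
                      cn$region_id[match(grid$location_id, cn$location_id)])
  g_super <- .effect(super_eff,
                     cn$super_region_id[match(grid$location_id, cn$location_id)])
  surface <- grid
  surface$value <- int + g_sex + g_age + year_slope * (grid$year - mean(grid$year)) +
    g_region + g_super
  structure(surface,
            class = c("svac_surface", "data.frame"),
            stage = "stage1",
            sex_coef = sex_eff[["male"]],
            effects = list(intercept = int, age = age_eff,
                           year_slope = year_slope, region = region_eff,
                           super = super_eff))
}

# predict a surface at observation cells
surface_at <- function(surface, obs) {
  key_s <- paste(surface$location_id, surface$year, surface$age_start,
                 surface$sex)
  key_o <- paste(obs$location_id, obs$year, obs$age_start, obs$sex)
  i <- match(key_o, key_s)
  if (anyNA(i)) {
    stop("observation cell outside the model grid: ",
         key_o[which(is.na(i))[1]], call. = FALSE)
  }
  surface$value[i]
}

#' Stage 2: spatiotemporal residual smoothing
#'
#' Adds to the stage-1 prior, in every grid cell, a weighted mean of
#' the observation residuals. Weights factorise as `w_space * w_age *
#' w_time`: space discounts by hierarchy distance (own country,
#' region, super-region), age decays exponentially in age-group index
#' distance, and time uses the cubic-root-distance kernel
#' `(1 - (|dt|/(1+max_dt))^lambda)^3` with `max_dt` the span of the
#' estimation window. Sexes are smoothed separately. Cells whose total
#' weight is zero keep the stage-1 value.
#'
#' @param surface stage-1 `svac_surface`.
#' @param obs observation table (single canonical groups).
#' @param hierarchy a `svac_hierarchy`.
#' @param config from [stgpr_config()].
#' @return a `svac_surface` with `stage = "stage2"`.
#' @export
stage2_smooth <- function(surface, obs, hierarchy, config = stgpr_config()) {
  cn <- countries(hierarchy)
  groups <- canonical_age_groups(min(surface$age_start), max(surface$age_start))
  max_dt <- diff(range(surface$year))
  resid <- logit(obs$mean) - surface_at(surface, obs)
  o_loc <- obs$location_id
  o_reg <- cn$region_id[match(o_loc, cn$location_id)]
  o_sup <- cn$super_region_id[match(o_loc, cn$location_id)]
  o_idx <- age_group_index(obs$age_start, groups)
  o_year <- obs$year
  g_reg <- cn$region_id[match(surface$location_id, cn$location_id)]
  g_sup <- cn$super_region_id[match(surface$location_id, cn$location_id)]
  g_idx <- age_group_index(surface$age_start, groups)
  z <- config$zeta
  out <- surface$value
  for (i in seq_len(nrow(surface))) {
    same_sex <- obs$sex == surface$sex[i]
    if (!any(same_sex)) next
    w_space <- ifelse(o_loc == surface$location_id[i], z,
                      ifelse(o_reg == g_reg[i], z * (1 - z),
                             ifelse(o_sup == g_sup[i], z * (1 - z)^2, 0)))
    w_space[!same_sex] <- 0
    if (all(w_space == 0)) next
    dt <- abs(o_year - surface$year[i])
    w_time <- (1 - (dt / (1 + max_dt))^config$lam)^3
    w_age <- exp(-config$omega * abs(o_idx - g_idx[i]))
    w <- w_space * w_time * w_age
    sw <- sum(w)
    if (sw > 0) out[i] <- surface$value[i] + sum(w * resid) / sw
  }
  # leave-one-source-out residuals at the observation cells: each
  # observation's residual against the smoothed value computed without
  # any row of its own source (the row itself, its extrapolated copies,
  # split siblings and within-study twins share noise or provenance),
  # so the GP amplitude below is not deflated by in-sample shrinkage
  loo <- numeric(nrow(obs))
  loco <- numeric(nrow(obs))
  for (j in seq_len(nrow(obs))) {
    w_space <- ifelse(o_loc == obs$location_id[j], z,
                      ifelse(o_reg == o_reg[j], z * (1 - z),
                             ifelse(o_sup == o_sup[j], z * (1 - z)^2, 0)))
    dt <- abs(o_year - obs$year[j])
    w_time <- (1 - (dt / (1 + max_dt))^config$lam)^3
    w_age <- exp(-config$omega * abs(o_idx - o_idx[j]))
    w <- w_space * w_time * w_age
    w[obs$sex != obs$sex[j]] <- 0
    s1j <- surface_at(surface, obs[j, , drop = FALSE])
    wj <- w
    wj[obs$source_id == obs$source_id[j]] <- 0
    loo[j] <- logit(obs$mean[j]) -
      (if (sum(wj) > 0) s1j + sum(wj * resid) / sum(wj) else s1j)
    # leave-one-country-out: the error geometry of predicting a country
    # that contributed no data at all
    wc <- w
    wc[o_loc == obs$location_id[j]] <- 0
    loco[j] <- logit(obs$mean[j]) -
      (if (sum(wc) > 0) s1j + sum(wc * resid) / sum(wc) else s1j)
  }
  res <- surface
  res$value <- out
  attr(res, "stage") <- "stage2"
  attr(res, "loo_resid") <- loo
  attr(res, "loco_resid") <- loco
  res
}

# Matern nu = 3/2 correlation at scaled distance r
matern32 <- function(r) {
  s <- sqrt(3) * r
  (1 + s) * exp(-s)
}

# exact GP posterior over `years` for one series; prior mean m(t),
# covariance amp^2 * matern32(|dt|/scale); observations (t_i, y_i) with
# heteroscedastic noise variance v_i. Jitter escalates 1e-8 -> 1e-4
# before failing.
gp_posterior <- function(years, prior_mean, obs_years, obs_y, obs_var,
                         amp, scale) {
  K <- amp^2 * matern32(abs(outer(years, years, "-")) / scale)
  if (length(obs_years) == 0) {
    return(list(mean = prior_mean, cov = K))
  }
  Ko <- amp^2 * matern32(abs(outer(obs_years, obs_years, "-")) / scale) +
    diag(obs_var, length(obs_years))
  Kx <- amp^2 * matern32(abs(outer(years, obs_years, "-")) / scale)
  m_obs <- prior_mean[match(obs_years, years)]
  sol <- NULL
  for (jit in c(0, 1e-8, 1e-6, 1e-4)) {
    sol <- tryCatch(solve(Ko + diag(jit, nrow(Ko))),
                    error = function(e) NULL)
    if (!is.null(sol)) break
  }
  if (is.null(sol)) stop("GP observation covariance not invertible",
                         call. = FALSE)
  list(mean = as.numeric(prior_mean + Kx %*% sol %*% (obs_y - m_obs)),
       cov = K - Kx %*% sol %*% t(Kx))
}

# lower-triangular factor with escalating jitter
chol_jitter <- function(S) {
  for (jit in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    L <- tryCatch(t(chol(S + diag(jit, nrow(S)))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("posterior covariance not positive definite", call. = FALSE)
}

#' Stage 3: Gaussian process regression with posterior draws
#'
#' Per (country, age group, sex) series over time: a GP with prior
#' mean equal to the stage-2 surface and a Matern nu = 3/2 kernel is
#' conditioned exactly on that series' observations, whose noise
#' variance is the delta-method logit variance times the squared
#' extrapolation inflation — inflated (extrapolated) points are thereby
#' down-weighted. The prior amplitude is `amplitude_mad_mult * 1.4826 *
#' MAD(stage-2 residuals)` pooled over all observations, floored at
#' `amplitude_floor`; the residuals are leave-one-out (each observation
#' against the stage-2 value computed without it), since in-sample
#' residuals are shrunk toward zero by the smoothing itself and would
#' understate the prior uncertainty. `n_draws` joint posterior draws per series are
#' generated by Cholesky factorisation, each series using a dedicated
#' seed substream ordered by (location, age, sex), and mapped through
#' the inverse logit.
#'
#' @param surface stage-2 `svac_surface`.
#' @param obs observation table.
#' @param config from [stgpr_config()].
#' @param seed integer root seed.
#' @return object of class `"svac_draws"`: `grid` (location_id, year,
#'   age_start, sex), `draws` (cells x n_draws matrix, prevalence
#'   scale), `post_mean` (logit scale), `amplitude`.
#' @export
gpr_fit <- function(surface, obs, config = stgpr_config(), seed = 1) {
  amp_resid <- attr(surface, "loo_resid")
  if (is.null(amp_resid)) amp_resid <- logit(obs$mean) - surface_at(surface, obs)
  amp <- max(config$amplitude_floor,
             config$amplitude_mad_mult * 1.4826 *
               stats::mad(amp_resid, constant = 1))
  # series in countries that contributed no same-sex data face the
  # additional between-country error, estimated by leave-one-country-out
  loco <- attr(surface, "loco_resid")
  amp_sparse <- if (is.null(loco)) amp else {
    max(amp, config$amplitude_mad_mult * 1.4826 *
          stats::mad(loco, constant = 1))
  }
  has_data <- unique(paste(obs$location_id, obs$sex))
  years <- sort(unique(surface$year))
  series <- unique(surface[, c("location_id", "age_start", "sex")])
  series <- series[order(series$location_id, series$age_start, series$sex), ,
                   drop = FALSE]
  key_s <- paste(surface$location_id, surface$age_start, surface$sex)
  key_o <- paste(obs$location_id, obs$age_start, obs$sex)
  obs_var <- obs_logit_variance(obs)
  n_cells <- nrow(surface)
  draws <- matrix(NA_real_, n_cells, config$n_draws)
  post_mean <- numeric(n_cells)
  for (s in seq_len(nrow(series))) {
    sk <- paste(series$location_id[s], series$age_start[s], series$sex[s])
    gi <- which(key_s == sk)
    gi <- gi[order(surface$year[gi])]
    oi <- which(key_o == sk)
    amp_s <- if (paste(series$location_id[s], series$sex[s]) %in% has_data)
      amp else amp_sparse
    post <- gp_posterior(years, surface$value[gi],
                         obs$year[oi], logit(obs$mean[oi]), obs_var[oi],
                         amp_s, config$gpr_scale)
    L <- chol_jitter(post$cov)
    set.seed((seed + 7919 * s) %% .Machine$integer.max)
    Z <- matrix(stats::rnorm(length(years) * config$n_draws),
                length(years), config$n_draws)
    draws[gi, ] <- expit(post$mean + L %*% Z)
    post_mean[gi] <- post$mean
  }
  structure(list(grid = surface[, c("location_id", "year", "age_start", "sex")],
                 draws = draws, post_mean = post_mean, amplitude = amp,
                 amplitude_sparse = amp_sparse, n_draws = config$n_draws),
            class = "svac_draws")
}

#' @export
print.svac_draws <- function(x, ...) {
  cat("Prevalence draw surface:", nrow(x$grid), "cells x", x$n_draws,
      "draws (GP amplitude", round(x$amplitude, 3), ")\n")
  invisible(x)
}
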
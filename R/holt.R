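#' Flag data-sparse series
#'
#' A (location, sex) series is flagged when its count of directly
#' observed (non-extrapolated) datapoints falls below `threshold`. The
#' default threshold of 1 flags only truly data-free series, where the
#' GP reverts to its prior and time trends can be implausible for a
#' lifetime quantity.
#'
#' @param obs processed observation table.
#' @param hierarchy a `svac_hierarchy` (supplies the complete country
#'   list, so countries with zero observations are enumerable).
#' @param threshold minimum direct observations to escape flagging.
#' @return data frame of flagged (`location_id`, `sex`) combinations.
#' @export
flag_sparse <- function(obs, hierarchy, threshold = 1) {
  cn <- countries(hierarchy)
  combos <- expand.grid(location_id = cn$location_id,
                        sex = c("female", "male"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  direct <- obs[!obs$extrapolated, , drop = FALSE]
  cnt <- vapply(seq_len(nrow(combos)), function(i) {
    sum(direct$location_id == combos$location_id[i] &
          direct$sex == combos$sex[i])
  }, numeric(1))
  combos[cnt < threshold, , drop = FALSE]
}

# forward damped-trend filter; init level = y[1], trend = y[2] - y[1]
holt_filter <- function(y, alpha, beta, phi) {
  n <- length(y)
  level <- numeric(n); trend <- numeric(n)
  level[1] <- y[1]
  trend[1] <- y[2] - y[1]
  for (t in 2:n) {
    level[t] <- alpha * y[t] + (1 - alpha) * (level[t - 1] + phi * trend[t - 1])
    trend[t] <- beta * (level[t] - level[t - 1]) + (1 - beta) * phi * trend[t - 1]
  }
  list(level = level, trend = trend)
}

#' Damped-trend forecast from final states
#'
#' The h-step-ahead forecast is `level + (phi + phi^2 + ... + phi^h) *
#' trend`; with `phi < 1` forecasts converge to `level + phi / (1 -
#' phi) * trend` as h grows, with `phi = 1` the trend is undamped.
#'
#' @param level,trend smoothing states.
#' @param phi damping parameter in (0, 1\].
#' @param h forecast horizon(s), positive integers (vectorised).
#' @return forecast value(s).
#' @export
holt_forecast <- function(level, trend, phi, h) {
  vapply(h, function(hh) {
    damp <- if (phi == 1) hh else phi * (1 - phi^hh) / (1 - phi)
    level + damp * trend
  }, numeric(1))
}

#' Holt damped linear-trend smoothing
#'
#' Applies the standard damped-trend exponential smoothing recursions
#' `level_t = alpha*y_t + (1-alpha)*(level_{t-1} + phi*trend_{t-1})`,
#' `trend_t = beta*(level_t - level_{t-1}) + (1-beta)*phi*trend_{t-1}`
#' forward and (on the reversed series) backward; the smoothed series
#' is the average of the two level sequences, which damps oscillations
#' symmetrically. Optionally the series is extended by damped
#' forecasts (`h_ahead`) and backcasts (`h_back`). With `anchor > 0`
#' the first/last `anchor` smoothed values are linearly blended back
#' into the original values so the smoothed interior joins the
#' trusted ends without a discontinuity.
#'
#' @param y numeric series (length >= 3).
#' @param alpha level smoothing parameter in (0, 1).
#' @param beta trend smoothing parameter in (0, 1).
#' @param phi damping parameter in (0, 1\].
#' @param h_ahead,h_back number of forecast / backcast steps appended.
#' @param anchor blending window length at each end (in steps).
#' @return list with `smoothed` (length `h_back + length(y) +
#'   h_ahead`), `level`, `trend` (forward states), and the index range
#'   `core` of the original series within `smoothed`.
#' @export
holt_damped <- function(y, alpha = 0.3, beta = 0.1, phi = 0.9,
                        h_ahead = 0, h_back = 0, anchor = 0) {
  if (length(y) < 3) stop("series must have length >= 3", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1 ||
      phi <= 0 || phi > 1) {
    stop("require 0 < alpha, beta < 1 and 0 < phi <= 1", call. = FALSE)
  }
  fwd <- holt_filter(y, alpha, beta, phi)
  bwd <- holt_filter(rev(y), alpha, beta, phi)
  sm <- (fwd$level + rev(bwd$level)) / 2
  if (anchor > 0) {
    n <- length(y)
    a <- min(anchor, n)
    wt <- rep(0, n)                       # weight on the original values
    wt[seq_len(a)] <- pmax(wt[seq_len(a)], rev(seq_len(a)) / a)
    wt[n - seq_len(a) + 1] <- pmax(wt[n - seq_len(a) + 1], rev(seq_len(a)) / a)
    sm <- wt * y + (1 - wt) * sm
  }
  ahead <- if (h_ahead > 0) {
    holt_forecast(fwd$level[length(y)], fwd$trend[length(y)], phi,
                  seq_len(h_ahead))
  } else numeric(0)
  back <- if (h_back > 0) {
    rev(holt_forecast(bwd$level[length(y)], bwd$trend[length(y)], phi,
                      seq_len(h_back)))
  } else numeric(0)
  list(smoothed = c(back, sm, ahead), level = fwd$level, trend = fwd$trend,
       core = h_back + seq_along(y))
}

#' Smooth draw trajectories of flagged series
#'
#' For every flagged (location, sex) — all its age groups — each draw's
#' time trajectory is replaced by its Holt damped-trend smoothed
#' version on the logit scale. Unflagged series are untouched; grid and
#' draw count are preserved exactly.
#'
#' @param draws a `svac_draws`.
#' @param flags data frame from [flag_sparse()].
#' @param alpha,beta,phi smoothing parameters, see [holt_damped()].
#' @param anchor blending window, see [holt_damped()].
#' @return a `svac_draws` of identical shape.
#' @export
smooth_draws <- function(draws, flags, alpha = 0.3, beta = 0.1, phi = 0.9,
                         anchor = 0) {
  if (nrow(flags) == 0) return(draws)
  g <- draws$grid
  flag_key <- paste(flags$location_id, flags$sex)
  series <- unique(g[, c("location_id", "age_start", "sex")])
  for (s in seq_len(nrow(series))) {
    if (!(paste(series$location_id[s], series$sex[s]) %in% flag_key)) next
    gi <- which(g$location_id == series$location_id[s] &
                  g$age_start == series$age_start[s] &
                  g$sex == series$sex[s])
    gi <- gi[order(g$year[gi])]
    Y <- logit(draws$draws[gi, , drop = FALSE])   # years x draws
    fwd <- holt_filter_mat(Y, alpha, beta, phi)
    bwd <- holt_filter_mat(Y[rev(seq_len(nrow(Y))), , drop = FALSE],
                           alpha, beta, phi)
    sm <- (fwd + bwd[rev(seq_len(nrow(bwd))), , drop = FALSE]) / 2
    if (anchor > 0) {
      n <- nrow(Y)
      a <- min(anchor, n)
      wt <- rep(0, n)
      wt[seq_len(a)] <- pmax(wt[seq_len(a)], rev(seq_len(a)) / a)
      wt[n - seq_len(a) + 1] <- pmax(wt[n - seq_len(a) + 1],
                                     rev(seq_len(a)) / a)
      sm <- wt * Y + (1 - wt) * sm
    }
    draws$draws[gi, ] <- expit(sm)
  }
  draws
}

# matrix variant of the forward filter (rows = time, columns = draws);
# returns the level sequence
holt_filter_mat <- function(Y, alpha, beta, phi) {
  n <- nrow(Y)
  level <- Y[1, ]
  trend <- Y[2, ] - Y[1, ]
  out <- matrix(NA_real_, n, ncol(Y))
  out[1, ] <- level
  for (t in 2:n) {
    prev <- level
    level <- alpha * Y[t, ] + (1 - alpha) * (level + phi * trend)
    trend <- beta * (level - prev) + (1 - beta) * phi * trend
    out[t, ] <- level
  }
  out
}
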
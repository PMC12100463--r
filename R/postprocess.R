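#' Direct age-standardisation of draws
#'
#' Per draw and per (location, year, sex), the weighted sum of
#' age-specific prevalence over age groups 20 and older, using
#' standard-population weights renormalised over the age groups present
#' in the draw surface. Groups below 20 are never included (the
#' childhood exposure window is incomplete there).
#'
#' @param draws a `svac_draws` with age-specific cells.
#' @param standard a `svac_stdpop`.
#' @return a `svac_draws` whose grid has `age_start = NA` and
#'   `age_label = "age_standardised_20plus"`, one cell per (location,
#'   year, sex).
#' @export
age_standardise <- function(draws, standard = read_standard_population()) {
  g <- draws$grid
  ages <- sort(unique(g$age_start[g$age_start >= 20]))
  if (!length(ages)) stop("no age groups >= 20 in draw surface", call. = FALSE)
  w <- standard$weight[match(ages, standard$age_start)]
  if (anyNA(w)) {
    stop("standard population lacks age group ", ages[which(is.na(w))[1]],
         call. = FALSE)
  }
  w <- w / sum(w)
  cells <- unique(g[, c("location_id", "year", "sex")])
  out <- matrix(NA_real_, nrow(cells), ncol(draws$draws))
  for (i in seq_len(nrow(cells))) {
    acc <- 0
    for (a in seq_along(ages)) {
      j <- which(g$location_id == cells$location_id[i] &
                   g$year == cells$year[i] & g$sex == cells$sex[i] &
                   g$age_start == ages[a])
      if (length(j) != 1) {
        stop("missing age group ", ages[a], " for cell (",
             cells$location_id[i], ", ", cells$year[i], ", ",
             cells$sex[i], ")", call. = FALSE)
      }
      acc <- acc + w[a] * draws$draws[j, ]
    }
    out[i, ] <- acc
  }
  cells$age_start <- NA_real_
  cells$age_label <- "age_standardised_20plus"
  structure(list(grid = cells, draws = out, n_draws = ncol(out)),
            class = "svac_draws")
}

#' Aggregate country draws up the location hierarchy
#'
#' Parent draws are the population-weighted mean of their children's
#' draws, draw-index aligned so between-draw correlation is preserved;
#' applied country -> region -> super-region -> global. For
#' age-standardised surfaces the weight is the location's population
#' aged 20+, for age-specific surfaces the cell's own age-group
#' population.
#'
#' @param draws a `svac_draws` over countries.
#' @param hierarchy a `svac_hierarchy`.
#' @param population a `svac_population` (country level).
#' @return a `svac_draws` containing the original country cells plus
#'   region, super-region and global cells.
#' @export
aggregate_locations <- function(draws, hierarchy, population) {
  g <- draws$grid
  standardised <- all(is.na(g$age_start))
  pop_for <- function(location_id, year, sex, age_start) {
    i <- population$location_id == location_id & population$year == year &
      population$sex == sex
    if (standardised) i <- i & population$age_start >= 20
    else i <- i & population$age_start == age_start
    if (!any(i)) {
      stop("missing population for location ", location_id, call. = FALSE)
    }
    sum(population$population[i])
  }
  agg_level <- function(child_draws, child_map) {
    cg <- child_draws$grid
    parents <- unique(child_map[match(cg$location_id, names(child_map))])
    out_g <- list(); out_m <- list()
    for (p in parents) {
      kids <- names(child_map)[child_map == p]
      cells <- unique(cg[cg$location_id %in% kids,
                         setdiff(names(cg), "location_id"), drop = FALSE])
      for (i in seq_len(nrow(cells))) {
        j <- which(cg$location_id %in% kids &
                     cg$year == cells$year[i] & cg$sex == cells$sex[i] &
                     (standardised | cg$age_start == cells$age_start[i]))
        if (length(j) != length(kids)) {
          stop("missing child draws under parent ", p, call. = FALSE)
        }
        w <- vapply(cg$location_id[j], function(l) {
          pop_for(l, cells$year[i], cells$sex[i], cells$age_start[i])
        }, numeric(1))
        row <- cells[i, , drop = FALSE]
        row$location_id <- as.numeric(p)
        out_g[[length(out_g) + 1]] <- row
        out_m[[length(out_m) + 1]] <-
          colSums(child_draws$draws[j, , drop = FALSE] * w) / sum(w)
      }
    }
    gg <- do.call(rbind, out_g)
    gg <- gg[, names(cg), drop = FALSE]
    list(grid = gg, draws = do.call(rbind, out_m))
  }
  cn <- countries(hierarchy)
  # parent populations: sum of children (kept consistent by construction)
  pop_parent <- function(map) {
    pp <- population
    pp$location_id <- as.numeric(map[as.character(pp$location_id)])
    stats::aggregate(population ~ location_id + year + sex + age_start,
                     data = pp, FUN = sum)
  }
  map_cr <- stats::setNames(cn$region_id, cn$location_id)
  reg <- agg_level(draws, map_cr)
  rn <- hierarchy[hierarchy$level == "region", ]
  map_rs <- stats::setNames(rn$parent_id, rn$location_id)
  population <- population_table(pop_parent(map_cr))
  sup <- agg_level(reg, map_rs)
  sn <- hierarchy[hierarchy$level == "super_region", ]
  map_sg <- stats::setNames(sn$parent_id, sn$location_id)
  population <- population_table(pop_parent(map_rs))
  glob <- agg_level(sup, map_sg)
  grid <- rbind(g, reg$grid, sup$grid, glob$grid)
  rownames(grid) <- NULL
  structure(list(grid = grid,
                 draws = rbind(draws$draws, reg$draws, sup$draws, glob$draws),
                 n_draws = ncol(draws$draws)),
            class = "svac_draws")
}

#' Summarise draws into point estimate and 95% uncertainty interval
#'
#' Mean and the empirical 2.5th / 97.5th percentiles of the draw
#' distribution per cell. Percentiles use the linear-interpolation
#' quantile definition (type 7, the R default), fixed here for
#' reproducibility.
#'
#' @param draws a `svac_draws` (or a bare numeric matrix, cells in
#'   rows).
#' @return data frame: the grid columns plus `mean`, `lower`, `upper`
#'   (with `lower <= mean <= upper` up to draw noise).
#' @export
summarise_draws <- function(draws) {
  m <- if (inherits(draws, "svac_draws")) draws$draws else as.matrix(draws)
  q <- t(apply(m, 1, stats::quantile, probs = c(0.025, 0.975),
               type = 7, names = FALSE))
  res <- data.frame(mean = rowMeans(m), lower = q[, 1], upper = q[, 2])
  if (inherits(draws, "svac_draws")) res <- cbind(draws$grid, res)
  rownames(res) <- NULL
  res
}

#' @export
summary.svac_draws <- function(object, ...) summarise_draws(object)

#' Change in prevalence between two years
#'
#' The per-draw difference (year_b minus year_a) for one age group,
#' summarised after differencing so that between-year draw correlation
#' is preserved.
#'
#' @param draws a `svac_draws`.
#' @param year_a,year_b comparison years.
#' @param age_start age group (default 20, i.e. ages 20-24, the
#'   youngest group past the childhood window).
#' @return data frame per (location, sex): mean difference and 95%
#'   interval.
#' @export
change_over_time <- function(draws, year_a, year_b, age_start = 20) {
  g <- draws$grid
  sel <- function(yr) {
    i <- which(g$year == yr &
                 (if (all(is.na(g$age_start))) TRUE else g$age_start == age_start))
    if (!length(i)) stop("year ", yr, " not present in draw surface",
                         call. = FALSE)
    i
  }
  ia <- sel(year_a); ib <- sel(year_b)
  ka <- paste(g$location_id[ia], g$sex[ia])
  kb <- paste(g$location_id[ib], g$sex[ib])
  ib <- ib[match(ka, kb)]
  diff <- draws$draws[ib, , drop = FALSE] - draws$draws[ia, , drop = FALSE]
  out <- summarise_draws(diff)
  cbind(g[ia, c("location_id", "sex")], year_a = year_a, year_b = year_b, out)
}
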
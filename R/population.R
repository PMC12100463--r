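#' Population table
#'
#' Counts by (location_id, year, sex, canonical age group), complete
#' over the modelled grid. Used for age-split weights and for
#' population-weighted aggregation up the location hierarchy.
#'
#' @param df data frame with columns `location_id`, `year`, `sex`,
#'   `age_start`, `population`.
#' @return validated data frame classed `"svac_population"`.
#' @export
population_table <- function(df) {
  req <- c("location_id", "year", "sex", "age_start", "population")
  if (!all(req %in% names(df))) {
    stop("population table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$population < 0)) stop("negative population", call. = FALSE)
  structure(df, class = c("svac_population", "data.frame"))
}

#' @rdname population_table
#' @param path CSV file path.
#' @export
read_population <- function(path) {
  population_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

pop_lookup <- function(pop, location_id, year, sex, age_start) {
  i <- pop$location_id == location_id & pop$year == year &
    pop$sex == sex & pop$age_start == age_start
  if (!any(i)) {
    stop("missing population for cell (", location_id, ", ", year, ", ",
         sex, ", age ", age_start, ")", call. = FALSE)
  }
  sum(pop$population[i])
}

#' Standard-population age weights
#'
#' Weights per canonical age group used for direct age-standardisation,
#' restricted to ages 20 and older (the youngest groups have not yet
#' completed the childhood exposure window). Weights must sum to 1 over
#' the included groups. The packaged default
#' (`inst/extdata/standard_population_synthetic.csv`) is a synthetic stand-in
#' roughly following a world-population age structure; users may supply
#' their preferred standard.
#'
#' @param df data frame with columns `age_start`, `weight`.
#' @return validated data frame classed `"svac_stdpop"`.
#' @export
standard_population <- function(df) {
  req <- c("age_start", "weight")
  if (!all(req %in% names(df))) {
    stop("standard population needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$age_start < 20)) {
    stop("standard population must be restricted to age groups >= 20",
         call. = FALSE)
  }
  if (any(df$weight < 0)) stop("negative weight", call. = FALSE)
  df$weight <- df$weight / sum(df$weight)
  structure(df, class = c("svac_stdpop", "data.frame"))
}

#' @rdname standard_population
#' @param path CSV file path; default is the packaged synthetic
#'   stand-in weights.
#' @export
read_standard_population <- function(path = system.file("extdata",
                                                        "standard_population_synthetic.csv",
                                                        package = "svacprev")) {
  standard_population(utils::read.csv(path, stringsAsFactors = FALSE))
}
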
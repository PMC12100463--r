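#' Canonical five-year age groups
#'
#' The model grid uses half-open integer-year intervals \[start, end):
#' \[15,20), \[20,25), ..., \[90,95) and a terminal open-ended group
#' coded \[95,125) for population arithmetic. "20-24 years" is \[20,25).
#'
#' @param min_start first age-group start (default 15).
#' @param max_start last age-group start (default 95, the terminal
#'   group).
#' @return data frame with columns `age_start`, `age_end`, `age_label`.
#' @export
canonical_age_groups <- function(min_start = 15, max_start = 95) {
  stopifnot(min_start %% 5 == 0, max_start %% 5 == 0, max_start >= min_start)
  starts <- seq(min_start, max_start, by = 5)
  ends <- starts + 5
  labels <- paste0(starts, "-", ends - 1)
  if (max_start == 95) {
    ends[length(ends)] <- 125
    labels[length(labels)] <- "95 plus"
  }
  data.frame(age_start = starts, age_end = ends, age_label = labels,
             stringsAsFactors = FALSE)
}

#' Canonical groups covered by an age span
#'
#' @param age_start,age_end half-open span \[age_start, age_end).
#' @param groups canonical group table from [canonical_age_groups()].
#' @return the rows of `groups` whose interval intersects the span.
#' @export
covered_age_groups <- function(age_start, age_end, groups = canonical_age_groups()) {
  stopifnot(age_end > age_start)
  groups[groups$age_end > age_start & groups$age_start < age_end, , drop = FALSE]
}

# index of a canonical group (1-based by start age); used for the
# age-distance weight in stage-2 smoothing
age_group_index <- function(age_start, groups = canonical_age_groups()) {
  match(age_start, groups$age_start)
}
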
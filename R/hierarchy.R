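#' Location hierarchy
#'
#' A four-level hierarchy global > super-region > region > country, as
#' used for borrowing strength across locations and for aggregating
#' country draws upward. Stored as a plain data frame with one row per
#' node.
#'
#' @param nodes data frame with columns `location_id`, `name`, `level`
#'   (one of `"global"`, `"super_region"`, `"region"`, `"country"`) and
#'   `parent_id` (`NA` for the global root).
#' @return the validated data frame, classed `"svac_hierarchy"`, with
#'   ancestor columns `region_id` and `super_region_id` filled in for
#'   country rows.
#' @export
location_hierarchy <- function(nodes) {
  req <- c("location_id", "name", "level", "parent_id")
  if (!all(req %in% names(nodes))) {
    stop("hierarchy needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(nodes$location_id)) {
    stop("duplicate location_id in hierarchy", call. = FALSE)
  }
  bad <- setdiff(nodes$level, c("global", "super_region", "region", "country"))
  if (length(bad)) stop("unknown hierarchy level: ", bad[1], call. = FALSE)
  if (sum(nodes$level == "global") != 1) {
    stop("hierarchy must have exactly one global root", call. = FALSE)
  }
  parent_of <- stats::setNames(nodes$parent_id, nodes$location_id)
  level_of <- stats::setNames(nodes$level, nodes$location_id)
  ancestor <- function(id, lev) {
    while (!is.na(id) && level_of[[as.character(id)]] != lev) {
      id <- parent_of[[as.character(id)]]
    }
    id
  }
  nodes$region_id <- NA
  nodes$super_region_id <- NA
  for (i in which(nodes$level == "country")) {
    r <- ancestor(nodes$parent_id[i], "region")
    s <- ancestor(nodes$parent_id[i], "super_region")
    if (is.na(r) || is.na(s)) {
      stop("country ", nodes$location_id[i],
           " lacks a region or super-region ancestor", call. = FALSE)
    }
    nodes$region_id[i] <- r
    nodes$super_region_id[i] <- s
  }
  nodes$region_id[nodes$level == "region"] <- nodes$location_id[nodes$level == "region"]
  structure(nodes, class = c("svac_hierarchy", "data.frame"))
}

#' @export
print.svac_hierarchy <- function(x, ...) {
  tab <- table(x$level)
  cat("Location hierarchy:",
      tab[["country"]], "countries in",
      tab[["region"]], "regions /",
      tab[["super_region"]], "super-regions\n")
  invisible(x)
}

#' Read a location hierarchy from CSV
#'
#' Expects columns `location_id,name,level,parent_id` (UTF-8, '.'
#' decimal separator).
#'
#' @param path CSV file path.
#' @return a `svac_hierarchy`, see [location_hierarchy()].
#' @export
read_hierarchy <- function(path) {
  location_hierarchy(utils::read.csv(path, stringsAsFactors = FALSE))
}

countries <- function(hierarchy) {
  hierarchy[hierarchy$level == "country", , drop = FALSE]
}
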
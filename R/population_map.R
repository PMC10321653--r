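#' Sample-to-group population map
#'
#' @param assignment named character vector: names are sample ids, values are
#'   group labels (e.g. CULAPO, CULSEX, WILDAPO, WILDSEX1, WILDSEX2, OUTGROUP).
#' @param outgroup the label used for the outgroup (default `"OUTGROUP"`).
#' @return object of class `population_map` with fields `assignment`, `groups`
#'   (non-outgroup labels, in order of first appearance) and `outgroup`.
#' @export
population_map <- function(assignment, outgroup = "OUTGROUP") {
  stopifnot(is.character(assignment), !is.null(names(assignment)))
  if (anyDuplicated(names(assignment))) stop("duplicated sample ids in map")
  labs <- unique(unname(assignment))
  obj <- list(assignment = assignment,
              groups = setdiff(labs, outgroup),
              outgroup = outgroup)
  class(obj) <- "population_map"
  obj
}

#' @export
print.population_map <- function(x, ...) {
  tab <- table(x$assignment)
  cat("population_map:", length(x$assignment), "samples in",
      length(tab), "groups\n")
  print(tab)
  invisible(x)
}

#' Samples belonging to a group
#' @param pm a [population_map()].
#' @param group group label (the outgroup label is allowed).
#' @param universe optional sample set to intersect with (e.g. the samples of
#'   a genotype matrix); order follows `universe`.
#' @return character vector of sample ids.
#' @export
group_samples <- function(pm, group, universe = NULL) {
  s <- names(pm$assignment)[pm$assignment == group]
  if (!is.null(universe)) s <- universe[universe %in% s]
  s
}

#' Read a sample-map TSV (sample<TAB>group)
#' @param path file with two columns and no header.
#' @param outgroup outgroup label.
#' @return a [population_map()].
#' @export
read_population_map <- function(path, outgroup = "OUTGROUP") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "group"),
                          colClasses = "character")
  population_map(stats::setNames(df$group, df$sample), outgroup = outgroup)
}

#' Write a sample-map TSV
#' @param pm a [population_map()].
#' @param path output path.
#' @export
write_population_map <- function(pm, path) {
  utils::write.table(data.frame(names(pm$assignment), unname(pm$assignment)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
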
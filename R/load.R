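#' Classify annotated sites as deleterious or tolerated
#'
#' A numeric deleteriousness score classifies a substitution as deleterious
#' when `score <= cutoff` (default 0.05) and tolerated otherwise; tables with
#' explicit labels pass through unchanged.
#'
#' @param ann data frame with `chrom`, `pos` and either `score` (in \[0, 1\])
#'   or `label` (`deleterious`/`tolerated`), as from [read_annotations()].
#' @param cutoff score cutoff, inclusive on the deleterious side.
#' @return data frame `chrom`, `pos`, `class`.
#' @export
classify_sites <- function(ann, cutoff = 0.05) {
  if (!is.null(ann$score)) {
    if (any(ann$score < 0 | ann$score > 1, na.rm = TRUE))
      stop("deleteriousness scores must lie in [0, 1]")
    cls <- ifelse(ann$score <= cutoff, "deleterious", "tolerated")
  } else if (!is.null(ann$label)) {
    bad <- setdiff(unique(ann$label), c("deleterious", "tolerated", "none"))
    if (length(bad)) stop("unknown annotation labels: ", paste(bad, collapse = ", "))
    cls <- ann$label
  } else stop("annotation table needs a 'score' or 'label' column")
  data.frame(chrom = ann$chrom, pos = ann$pos, class = cls,
             stringsAsFactors = FALSE)
}

#' Derived deleterious-allele load per individual
#'
#' Counts, over polarized deleterious sites, each sample's heterozygous-
#' derived and homozygous-derived site numbers. The total derived deleterious
#' allele count per individual is `n_het + 2 * n_hom` (segregating sites plus
#' twice the fixed-derived sites carried by that individual). Sites with an
#' unknown ancestral state are excluded and their number reported.
#'
#' @param gm polarized [geno_matrix()] with the `annotation` field set (see
#'   [annotate_sites()]).
#' @param pm a [population_map()]; used for per-group summaries.
#' @return object of class `load_report`: a list with `per_sample` (data frame
#'   `sample`, `group`, `n_het_del`, `n_hom_del`, `n_del_total`), `n_sites`
#'   (deleterious polarizable sites used) and `n_unpolarized` (excluded).
#' @export
count_load <- function(gm, pm) {
  del <- gm$annotation == "deleterious"
  if (!any(del)) stop("no deleterious sites in the matrix")
  d <- derived_dosage(gm)
  usable <- del & !(is.na(gm$anc) | gm$anc == "unknown")
  if (!any(usable)) stop("no polarizable deleterious sites")
  dd <- d[, usable, drop = FALSE]
  n_het <- rowSums(dd == 1L, na.rm = TRUE)
  n_hom <- rowSums(dd == 2L, na.rm = TRUE)
  per <- data.frame(sample = gm$samples,
                    group = unname(pm$assignment[gm$samples]),
                    n_het_del = n_het, n_hom_del = n_hom,
                    n_del_total = n_het + 2L * n_hom,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(per_sample = per, n_sites = sum(usable),
              n_unpolarized = sum(del) - sum(usable))
  class(out) <- "load_report"
  out
}

#' @export
print.load_report <- function(x, ...) {
  cat("load_report over", x$n_sites, "polarized deleterious sites (",
      x$n_unpolarized, "excluded, ancestral state unknown )\n")
  agg <- stats::aggregate(cbind(n_het_del, n_hom_del, n_del_total) ~ group,
                          x$per_sample, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Write a per-sample load report TSV
#' @param report a `load_report` from [count_load()].
#' @param path output path.
#' @export
write_load_report <- function(report, path) {
  utils::write.table(report$per_sample, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
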
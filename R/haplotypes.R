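# Windowed haplotype divergence and mean-standardized distances, used to
# trace outcrossing during leaky sexual reproduction in apomicts: a
# within-sample haplotype pair that is as divergent as a cross-population
# pair points to a haplotype acquired by outcrossing.

hap_alleles <- function(gm, sample, which) {
  i <- match(sample, gm$samples)
  if (is.na(i)) stop("unknown sample: ", sample)
  if (which == 1) gm$hap1[i, ] else gm$hap2[i, ]
}

pdist_windows <- function(gm, a, b, window_bp, pair) {
  diff <- as.integer(a != b)
  diff[is.na(a) | is.na(b)] <- NA_integer_
  win <- site_windows(gm, window_bp)
  ns <- vapply(win$idx, function(i) sum(!is.na(diff[i])), 0L)
  val <- vapply(win$idx, function(i) mean(diff[i], na.rm = TRUE), 0)
  val[ns == 0] <- NA_real_
  out <- window_frame(win, ns, val)
  out$pair <- pair
  out
}

#' Windowed p-distance between two haplotypes
#'
#' Proportion of differing sites among jointly non-missing sites per window
#' (25-kb windows by default). Symmetric in its two arguments.
#'
#' @param gm phased [geno_matrix()].
#' @param hapA,hapB haplotype references: `list(sample, which)` or a
#'   2-element vector `c(sample, which)` with `which` in `{1, 2}`.
#' @param window_bp window length in bp.
#' @return a `window_stat` data frame with columns `chrom`, `start`, `end`,
#'   `n_sites` (compared sites), `value` (raw p-distance) and `pair`.
#' @export
hap_pdist <- function(gm, hapA, hapB, window_bp = 25000) {
  a <- hap_alleles(gm, hapA[[1]], as.integer(hapA[[2]]))
  b <- hap_alleles(gm, hapB[[1]], as.integer(hapB[[2]]))
  pdist_windows(gm, a, b, window_bp,
                paste0(hapA[[1]], ".", hapA[[2]], "-", hapB[[1]], ".", hapB[[2]]))
}

#' Per-window mean pairwise haplotype distance across a cohort
#'
#' The standardization background: for every pair of haplotypes among
#' `samples`, the windowed p-distance is computed and averaged per window.
#'
#' @param gm phased [geno_matrix()].
#' @param window_bp window length in bp.
#' @param samples cohort samples (default all).
#' @return a `window_stat` data frame whose `value` is the mean over all
#'   haplotype pairs (pairs without data in a window are skipped).
#' @export
hap_window_means <- function(gm, window_bp = 25000, samples = gm$samples) {
  haps <- expand.grid(sample = samples, which = 1:2, stringsAsFactors = FALSE)
  n <- nrow(haps)
  win <- site_windows(gm, window_bp)
  acc <- matrix(0, nrow(win), 2)  # sum of p-distances, count of pairs
  for (i in seq_len(n - 1)) {
    ai <- hap_alleles(gm, haps$sample[i], haps$which[i])
    for (j in (i + 1):n) {
      bj <- hap_alleles(gm, haps$sample[j], haps$which[j])
      d <- pdist_windows(gm, ai, bj, window_bp, "")
      ok <- !is.na(d$value)
      acc[ok, 1] <- acc[ok, 1] + d$value[ok]
      acc[ok, 2] <- acc[ok, 2] + 1
    }
  }
  val <- ifelse(acc[, 2] > 0, acc[, 1] / acc[, 2], NA_real_)
  window_frame(win, as.integer(acc[, 2]), val)
}

#' Standardize windowed distances by the cohort window mean
#'
#' `std_d = raw_d / mean(raw_d over all cohort haplotype pairs in that
#' window)`; windows whose mean is zero or absent are `NA`. Standardization
#' makes values comparable across windows with different mutation density and
#' is scale-free.
#'
#' @param dists a `window_stat` from [hap_pdist()] or [hap_vs_group()].
#' @param means a `window_stat` from [hap_window_means()] on the same window
#'   grid.
#' @return `dists` with an added `std_d` column.
#' @export
standardize <- function(dists, means) {
  key <- function(d) paste(d$chrom, d$start)
  m <- means$value[match(key(dists), key(means))]
  dists$std_d <- ifelse(!is.na(m) & m > 0, dists$value / m, NA_real_)
  dists
}

#' Windowed mean distance from one haplotype to a group's haplotypes
#'
#' Per window, the mean p-distance from `hap` to every haplotype of every
#' sample in `group` (pairs without comparable sites are skipped).
#'
#' @param gm phased [geno_matrix()].
#' @param hap haplotype reference `c(sample, which)`.
#' @param group group label.
#' @param pm a [population_map()].
#' @param window_bp window length in bp.
#' @return a `window_stat` data frame with a `pair` column
#'   `"<sample>.<which>-<group>"`.
#' @export
hap_vs_group <- function(gm, hap, group, pm, window_bp = 25000) {
  gs <- group_samples(pm, group, gm$samples)
  gs <- setdiff(gs, hap[[1]])
  if (length(gs) == 0) stop("group '", group, "' has no (other) samples")
  a <- hap_alleles(gm, hap[[1]], as.integer(hap[[2]]))
  win <- site_windows(gm, window_bp)
  acc <- matrix(0, nrow(win), 2)
  for (s in gs) for (w in 1:2) {
    d <- pdist_windows(gm, a, hap_alleles(gm, s, w), window_bp, "")
    ok <- !is.na(d$value)
    acc[ok, 1] <- acc[ok, 1] + d$value[ok]
    acc[ok, 2] <- acc[ok, 2] + 1
  }
  val <- ifelse(acc[, 2] > 0, acc[, 1] / acc[, 2], NA_real_)
  out <- window_frame(win, as.integer(acc[, 2]), val)
  out$pair <- paste0(hap[[1]], ".", hap[[2]], "-", group)
  out
}

#' Fraction of windows where one pair's standardized distance exceeds another
#'
#' Share of windows (both values present) where `pairA`'s `std_d` is
#' strictly greater than `pairB`'s; ties count as not exceeding.
#'
#' @param pairA,pairB `window_stat` data frames carrying `std_d` (see
#'   [standardize()]) on the same window grid.
#' @return a proportion in `[0, 1]`.
#' @export
fraction_exceeding <- function(pairA, pairB) {
  key <- function(d) paste(d$chrom, d$start)
  b <- pairB$std_d[match(key(pairA), key(pairB))]
  ok <- !is.na(pairA$std_d) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  mean(pairA$std_d[ok] > b[ok])
}

#' Designate the outlier haplotype ("Hap2") of a sample
#'
#' Picks the haplotype with the larger genome-wide mean p-distance to a
#' reference group's haplotypes. This auto rule substitutes for tree-based
#' haplotype clustering; callers may instead designate Hap2 explicitly.
#'
#' @param gm phased [geno_matrix()].
#' @param sample sample id.
#' @param ref_group reference group label.
#' @param pm a [population_map()].
#' @return integer 1 or 2: the haplotype index designated Hap2.
#' @export
designate_hap2 <- function(gm, sample, ref_group, pm) {
  span <- max(gm$pos)
  d1 <- hap_vs_group(gm, list(sample, 1), ref_group, pm, window_bp = span + 1)
  d2 <- hap_vs_group(gm, list(sample, 2), ref_group, pm, window_bp = span + 1)
  m1 <- stats::weighted.mean(d1$value, d1$n_sites, na.rm = TRUE)
  m2 <- stats::weighted.mean(d2$value, d2$n_sites, na.rm = TRUE)
  if (isTRUE(m2 >= m1)) 2L else 1L
}
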
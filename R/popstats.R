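# Windowed diversity / differentiation statistics.
#
# All windows are 0-based half-open [start, end) on the bp axis; a site at
# 1-based position p falls in the window containing p - 1. Ratio statistics
# (pi, Dxy, Fst) are ratio-of-sums over the window's sites, so adjacent
# windows recombine exactly by summing numerators and denominators.

site_windows <- function(gm, window_bp, sites = seq_along(gm$pos)) {
  if (length(sites) == 0)
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  w0 <- (gm$pos[sites] - 1) %/% window_bp
  key <- paste(gm$chrom[sites], w0)
  split_idx <- split(sites, factor(key, levels = unique(key)))
  first <- vapply(split_idx, `[`, 0L, 1L)
  data.frame(chrom = gm$chrom[first],
             start = ((gm$pos[first] - 1) %/% window_bp) * window_bp,
             end = ((gm$pos[first] - 1) %/% window_bp + 1) * window_bp,
             idx = I(unname(split_idx)))
}

window_frame <- function(win, n_sites, value) {
  out <- data.frame(chrom = win$chrom, start = win$start, end = win$end,
                    n_sites = n_sites, value = value,
                    stringsAsFactors = FALSE)
  class(out) <- c("window_stat", "data.frame")
  out
}

# per-site alt-allele count k and allele number n for a set of samples
site_counts <- function(gm, samples) {
  sub <- gm$geno[match(samples, gm$samples), , drop = FALSE]
  n <- 2L * colSums(!is.na(sub))
  k <- colSums(sub, na.rm = TRUE)
  list(k = k, n = n)
}

# per-site unbiased heterozygosity 2pq * n/(n-1); NA where n < 2
pi_site <- function(k, n) {
  out <- rep(NA_real_, length(k))
  ok <- n >= 2
  p <- k[ok] / n[ok]
  out[ok] <- 2 * p * (1 - p) * n[ok] / (n[ok] - 1)
  out
}

#' Windowed nucleotide diversity (pi)
#'
#' Mean pairwise difference per bp within a group, computed from unphased
#' allele counts: per site `2 p q n/(n-1)`, summed over the window's usable
#' sites and divided by the window length in bp (25-kb windows by default).
#'
#' @param gm a [geno_matrix()].
#' @param pm a [population_map()].
#' @param group group label.
#' @param window_bp window length in bp.
#' @param min_sites minimum usable sites for a window value (else `NA`).
#' @return a `window_stat` data frame (`chrom`, `start`, `end`, `n_sites`,
#'   `value`).
#' @export
window_pi <- function(gm, pm, group, window_bp = 25000, min_sites = 10) {
  sc <- site_counts(gm, group_samples(pm, group, gm$samples))
  ps <- pi_site(sc$k, sc$n)
  win <- site_windows(gm, window_bp)
  ns <- vapply(win$idx, function(i) sum(!is.na(ps[i])), 0L)
  val <- vapply(win$idx, function(i) sum(ps[i], na.rm = TRUE), 0)
  val <- ifelse(ns >= min_sites, val / (win$end - win$start), NA_real_)
  window_frame(win, ns, val)
}

#' Windowed absolute divergence (Dxy)
#'
#' Mean between-group pairwise difference per bp:
#' `sum over sites of (pA qB + qA pB) / window bp`.
#'
#' @inheritParams window_pi
#' @param groupA,groupB the two group labels.
#' @return a `window_stat` data frame.
#' @export
window_dxy <- function(gm, pm, groupA, groupB, window_bp = 25000,
                       min_sites = 10) {
  sa <- site_counts(gm, group_samples(pm, groupA, gm$samples))
  sb <- site_counts(gm, group_samples(pm, groupB, gm$samples))
  ok <- sa$n >= 1 & sb$n >= 1
  pa <- ifelse(ok, sa$k / sa$n, NA_real_)
  pb <- ifelse(ok, sb$k / sb$n, NA_real_)
  ds <- pa * (1 - pb) + pb * (1 - pa)
  win <- site_windows(gm, window_bp)
  ns <- vapply(win$idx, function(i) sum(!is.na(ds[i])), 0L)
  val <- vapply(win$idx, function(i) sum(ds[i], na.rm = TRUE), 0)
  val <- ifelse(ns >= min_sites, val / (win$end - win$start), NA_real_)
  window_frame(win, ns, val)
}

#' Windowed Hudson-type Fst (ratio of sums)
#'
#' `Fst = 1 - sum(pi_within) / sum(dxy)` over the window's sites, where
#' `pi_within` averages the two groups' per-site unbiased heterozygosities.
#' Windows with zero between-group divergence are `NA`.
#'
#' @inheritParams window_dxy
#' @return a `window_stat` data frame.
#' @export
window_fst <- function(gm, pm, groupA, groupB, window_bp = 25000,
                       min_sites = 10) {
  parts <- fst_parts(gm, pm, groupA, groupB)
  win <- site_windows(gm, window_bp)
  ns <- vapply(win$idx, function(i) sum(!is.na(parts$within[i]) &
                                          !is.na(parts$between[i])), 0L)
  val <- vapply(win$idx, function(i) {
    ok <- !is.na(parts$within[i]) & !is.na(parts$between[i])
    bw <- sum(parts$between[i][ok])
    if (sum(ok) == 0 || bw == 0) return(NA_real_)
    1 - sum(parts$within[i][ok]) / bw
  }, 0)
  val[ns < min_sites] <- NA_real_
  window_frame(win, ns, val)
}

fst_parts <- function(gm, pm, groupA, groupB) {
  sa <- site_counts(gm, group_samples(pm, groupA, gm$samples))
  sb <- site_counts(gm, group_samples(pm, groupB, gm$samples))
  pia <- pi_site(sa$k, sa$n); pib <- pi_site(sb$k, sb$n)
  ok <- sa$n >= 1 & sb$n >= 1
  pa <- ifelse(ok, sa$k / sa$n, NA_real_)
  pb <- ifelse(ok, sb$k / sb$n, NA_real_)
  list(within = (pia + pib) / 2, between = pa * (1 - pb) + pb * (1 - pa))
}

#' Genome-wide Hudson Fst
#'
#' Ratio-of-sums over every usable site in the matrix; the windowed version
#' is [window_fst()].
#'
#' @inheritParams window_dxy
#' @return a single numeric Fst value.
#' @export
global_fst <- function(gm, pm, groupA, groupB) {
  parts <- fst_parts(gm, pm, groupA, groupB)
  ok <- !is.na(parts$within) & !is.na(parts$between)
  if (sum(parts$between[ok]) == 0) return(NA_real_)
  1 - sum(parts$within[ok]) / sum(parts$between[ok])
}

#' Windowed Tajima's D
#'
#' Standard normalized difference between mean pairwise diversity and
#' Watterson's estimator from `S` segregating sites, using the usual
#' `a1, a2, b1, b2, c1, c2, e1, e2` constants (100-kb windows by default).
#' Windows with `S = 0` are `NA`, not 0.
#'
#' @inheritParams window_pi
#' @param window_bp window length in bp (default 100 kb).
#' @return a `window_stat` data frame.
#' @export
tajimas_d <- function(gm, pm, group, window_bp = 100000, min_sites = 1) {
  sc <- site_counts(gm, group_samples(pm, group, gm$samples))
  win <- site_windows(gm, window_bp)
  ns <- integer(nrow(win)); val <- rep(NA_real_, nrow(win))
  for (w in seq_len(nrow(win))) {
    i <- win$idx[[w]]
    seg <- sc$k[i] > 0 & sc$k[i] < sc$n[i] & sc$n[i] >= 2
    S <- sum(seg); ns[w] <- S
    if (S == 0 || S < min_sites) next
    n <- stats::median(sc$n[i][seg])
    if (n < 4) next
    pi_sum <- sum(pi_site(sc$k[i][seg], sc$n[i][seg]))
    val[w] <- tajima_d_value(n, S, pi_sum)
  }
  window_frame(win, ns, val)
}

tajima_d_value <- function(n, S, pi_sum) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Observed heterozygosity of one sample
#'
#' @param gm a [geno_matrix()].
#' @param sample sample id.
#' @return proportion of heterozygous calls among non-missing calls.
#' @export
heterozygosity <- function(gm, sample) {
  g <- gm$geno[match(sample, gm$samples), ]
  mean(g == 1L, na.rm = TRUE)
}

#' Windowed heterozygous-site density of one sample
#'
#' Counts heterozygous calls in non-overlapping windows (100 kb by default);
#' `value` is the count per bp and `n_sites` the non-missing calls, so window
#' counts sum to the sample's global heterozygous-call count.
#'
#' @inheritParams heterozygosity
#' @param window_bp window length in bp.
#' @return a `window_stat` data frame with an extra `n_het` column.
#' @export
window_het <- function(gm, sample, window_bp = 100000) {
  g <- gm$geno[match(sample, gm$samples), ]
  win <- site_windows(gm, window_bp)
  nh <- vapply(win$idx, function(i) sum(g[i] == 1L, na.rm = TRUE), 0L)
  ns <- vapply(win$idx, function(i) sum(!is.na(g[i])), 0L)
  out <- window_frame(win, ns, nh / (win$end - win$start))
  out$n_het <- nh
  out
}

#' Unfolded site frequency spectrum in ten clusters
#'
#' Derived-allele frequencies in `(0, 1]` within a group are binned into ten
#' equal-width half-open clusters `(k/10, (k+1)/10]`; sites with an unknown
#' ancestral state, no data, or derived frequency 0 are excluded. Bin
#' proportions sum to 1.
#'
#' @inheritParams window_pi
#' @param sites optional logical/integer site filter (e.g. deleterious sites).
#' @return data frame with `bin`, `lower`, `upper`, `count`, `proportion`.
#' @export
usfs <- function(gm, pm, group, sites = NULL) {
  d <- derived_dosage(gm)[match(group_samples(pm, group, gm$samples),
                                gm$samples), , drop = FALSE]
  keep <- rep(TRUE, n_sites(gm))
  if (!is.null(sites)) {
    keep <- rep(FALSE, n_sites(gm)); keep[sites] <- TRUE
  }
  n <- 2L * colSums(!is.na(d))
  f <- ifelse(n > 0, colSums(d, na.rm = TRUE) / n, NA_real_)
  f <- f[keep & !is.na(f) & f > 0]
  if (length(f) == 0) stop("no qualifying sites for the uSFS")
  bin <- pmin(ceiling(f * 10), 10L)
  cnt <- tabulate(bin, nbins = 10L)
  data.frame(bin = 1:10, lower = 0:9 / 10, upper = 1:10 / 10,
             count = cnt, proportion = cnt / sum(cnt))
}

#' Write a windowed statistic as BED-like TSV
#' @param ws a `window_stat` data frame.
#' @param path output path.
#' @export
write_windows <- function(ws, path) {
  utils::write.table(ws, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
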
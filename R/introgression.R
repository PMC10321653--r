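# Site-pattern gene-flow statistics (ABBA-BABA family) and diagnostic-marker
# introgression dosage. All statistics work on derived-allele frequencies
# polarized by the outgroup; sites with an unknown ancestral state are
# excluded throughout.

#' Derived-allele frequency table for a four-taxon test
#'
#' @param gm polarized [geno_matrix()].
#' @param pm a [population_map()].
#' @param p1,p2,p3 group labels for the (P1, P2; P3, O) topology.
#' @param outgroup outgroup label (default the map's outgroup).
#' @return object of class `freq_table` with `chrom`, `pos` and per-site
#'   frequencies `p1..p4`; sites lacking data in any taxon are dropped.
#' @export
freq_table <- function(gm, pm, p1, p2, p3, outgroup = pm$outgroup) {
  gf <- group_freqs(gm, pm, groups = c(p1, p2, p3, outgroup))
  ok <- colSums(is.na(gf$freq)) == 0
  out <- list(chrom = gm$chrom[ok], pos = gm$pos[ok],
              p1 = gf$freq[p1, ok], p2 = gf$freq[p2, ok],
              p3 = gf$freq[p3, ok], p4 = gf$freq[outgroup, ok],
              groups = c(p1, p2, p3, outgroup))
  class(out) <- "freq_table"
  out
}

abba_baba <- function(p1, p2, p3, p4) {
  list(abba = (1 - p1) * p2 * p3 * (1 - p4),
       baba = p1 * (1 - p2) * p3 * (1 - p4))
}

genome_blocks <- function(chrom, pos, block_bp) {
  b <- paste(chrom, (pos - 1) %/% block_bp)
  match(b, unique(b))
}

# delete-one-block jackknife of a ratio-of-sums statistic
jackknife_ratio <- function(num, den, block) {
  B <- max(block)
  tot_n <- sum(num); tot_d <- sum(den)
  if (B < 2) stop("need at least 2 jackknife blocks")
  loo <- vapply(seq_len(B), function(i) {
    in_i <- block == i
    (tot_n - sum(num[in_i])) / (tot_d - sum(den[in_i]))
  }, 0)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  list(se = se, n_blocks = B, loo = loo)
}

#' Patterson's D (ABBA-BABA) with block jackknife
#'
#' Per site `ABBA = (1-p1) p2 p3 (1-p4)` and `BABA = p1 (1-p2) p3 (1-p4)`;
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)`. The Z score comes from a
#' delete-one jackknife over contiguous genomic blocks (5 Mb by default).
#'
#' @param ft a [freq_table()].
#' @param block_bp jackknife block length in bp.
#' @return object of class `d_stat`: `D`, `Z`, `se`, `n_blocks`, `abba_sum`,
#'   `baba_sum`, `n_sites`, `groups`.
#' @export
d_statistic <- function(ft, block_bp = 5e6) {
  ab <- abba_baba(ft$p1, ft$p2, ft$p3, ft$p4)
  num <- ab$abba - ab$baba; den <- ab$abba + ab$baba
  if (sum(den) == 0) stop("D statistic undefined: sum(ABBA + BABA) is zero")
  D <- sum(num) / sum(den)
  jk <- jackknife_ratio(num, den, genome_blocks(ft$chrom, ft$pos, block_bp))
  out <- list(D = D, Z = if (jk$se > 0) D / jk$se else NA_real_, se = jk$se,
              n_blocks = jk$n_blocks, abba_sum = sum(ab$abba),
              baba_sum = sum(ab$baba), n_sites = length(num),
              groups = ft$groups)
  class(out) <- "d_stat"
  out
}

#' @export
print.d_stat <- function(x, ...) {
  cat(sprintf("Patterson's D  (P1=%s, P2=%s; P3=%s, O=%s)\n",
              x$groups[1], x$groups[2], x$groups[3], x$groups[4]))
  cat(sprintf("  D = %.4f  Z = %.2f  (jackknife SE %.4g over %d blocks, %d sites)\n",
              x$D, x$Z, x$se, x$n_blocks, x$n_sites))
  invisible(x)
}

#' Windowed f_d admixture-fraction estimator
#'
#' `f_d = sum(ABBA - BABA) / sum(ABBA_D - BABA_D)` per window, where the
#' donor frequency replaces both P2 and P3 by whichever of the two has the
#' higher derived frequency at each site. Windows whose D is negative (the
#' statistic is defined for the positive-D direction) or whose denominator is
#' zero are `NA`.
#'
#' @param ft a [freq_table()].
#' @param window_bp window length in bp (default 25 kb).
#' @param min_sites minimum informative sites per window.
#' @return a `window_stat` data frame.
#' @export
fd_windows <- function(ft, window_bp = 25000, min_sites = 1) {
  ab <- abba_baba(ft$p1, ft$p2, ft$p3, ft$p4)
  pd <- pmax(ft$p2, ft$p3)
  abd <- abba_baba(ft$p1, pd, pd, ft$p4)
  num <- ab$abba - ab$baba
  den <- abd$abba - abd$baba
  win <- site_windows(ft, window_bp)
  ns <- vapply(win$idx, length, 0L)
  val <- vapply(win$idx, function(i) {
    s_num <- sum(num[i]); s_den <- sum(den[i])
    if (s_den == 0 || s_num < 0) return(NA_real_)
    s_num / s_den
  }, 0)
  val[ns < min_sites] <- NA_real_
  window_frame(win, ns, val)
}

#' Identify species-specific markers (SSMs)
#'
#' A site is an SSM when (a) every non-missing call in the cultivated
#' defining group is homozygous for one allele, (b) every non-missing call in
#' the wild reference group is homozygous for the other allele, (c) each
#' defining group's missingness is at most `miss_tol`, and (d) the outgroup
#' is fully genotyped and monomorphic (the incomplete-lineage-sorting
#' control). The cultivated-diagnostic allele and its polarity relative to
#' the ancestral state are recorded.
#'
#' @param gm a [geno_matrix()] (polarized matrices record SSM polarity).
#' @param pm a [population_map()].
#' @param group_cul cultivated defining group label(s); several labels are
#'   pooled (e.g. `c("CULAPO", "CULSEX")`).
#' @param group_wild wild reference group label (e.g. `"WILDSEX1"`).
#' @param miss_tol maximum missing-call fraction per defining group.
#' @return object of class `ssm_set`: data frame `chrom`, `pos`, `site`,
#'   `diag_allele` (`"ref"`/`"alt"`), `polarity`
#'   (`"derived"`/`"ancestral"`/`"unknown"`).
#' @export
identify_ssms <- function(gm, pm, group_cul, group_wild, miss_tol = 0) {
  cul <- unique(unlist(lapply(group_cul, group_samples, pm = pm,
                              universe = gm$samples)))
  wld <- group_samples(pm, group_wild, gm$samples)
  if (length(intersect(cul, wld))) stop("defining groups overlap")
  if (length(cul) < 2 || length(wld) < 2)
    stop("both defining groups need at least 2 samples")
  og <- group_samples(pm, pm$outgroup, gm$samples)
  if (length(og) == 0) stop("outgroup samples required for the ILS filter")
  fixed_allele <- function(samples) {
    sub <- gm$geno[match(samples, gm$samples), , drop = FALSE]
    n <- colSums(!is.na(sub))
    miss_ok <- (1 - n / length(samples)) <= miss_tol & n > 0
    a0 <- colSums(sub == 0L, na.rm = TRUE) == n
    a2 <- colSums(sub == 2L, na.rm = TRUE) == n
    ifelse(miss_ok & a0, 0L, ifelse(miss_ok & a2, 2L, NA_integer_))
  }
  fc <- fixed_allele(cul); fw <- fixed_allele(wld)
  osub <- gm$geno[match(og, gm$samples), , drop = FALSE]
  o_ok <- colSums(is.na(osub)) == 0 &
    (colSums(osub == 0L) == length(og) | colSums(osub == 2L) == length(og))
  is_ssm <- !is.na(fc) & !is.na(fw) & fc != fw & o_ok
  site <- which(is_ssm)
  diag_allele <- ifelse(fc[site] == 2L, "alt", "ref")
  anc <- gm$anc[site]
  polarity <- rep("unknown", length(site))
  known <- !is.na(anc) & anc != "unknown"
  polarity[known] <- ifelse(diag_allele[known] == anc[known],
                            "ancestral", "derived")
  out <- data.frame(chrom = gm$chrom[site], pos = gm$pos[site], site = site,
                    diag_allele = diag_allele, polarity = polarity,
                    stringsAsFactors = FALSE)
  class(out) <- c("ssm_set", "data.frame")
  out
}

#' Per-individual introgression dosage at diagnostic markers
#'
#' For each target sample, the proportion of cultivated-origin alleles is the
#' summed diagnostic-allele dosage over its genotyped SSMs divided by twice
#' the number of genotyped SSMs; heterozygous and homozygous diagnostic site
#' counts are reported alongside.
#'
#' @param gm a [geno_matrix()].
#' @param ssm an `ssm_set` from [identify_ssms()].
#' @param samples target sample ids (default: all samples in `gm`).
#' @return data frame (`sample`, `proportion`, `n_het_sites`, `n_hom_sites`,
#'   `n_genotyped`); samples without any genotyped SSM are skipped with a
#'   warning.
#' @export
introgression_dosage <- function(gm, ssm, samples = gm$samples) {
  if (nrow(ssm) == 0) stop("empty SSM set")
  g <- gm$geno[match(samples, gm$samples), ssm$site, drop = FALSE]
  alt_diag <- ssm$diag_allele == "alt"
  dos <- g
  dos[, !alt_diag] <- 2L - dos[, !alt_diag, drop = FALSE]
  ng <- rowSums(!is.na(dos))
  if (any(ng == 0)) {
    warning("samples without genotyped SSMs skipped: ",
            paste(samples[ng == 0], collapse = ", "))
    keep <- ng > 0
    samples <- samples[keep]; dos <- dos[keep, , drop = FALSE]; ng <- ng[keep]
  }
  data.frame(sample = samples,
             proportion = rowSums(dos, na.rm = TRUE) / (2 * ng),
             n_het_sites = rowSums(dos == 1L, na.rm = TRUE),
             n_hom_sites = rowSums(dos == 2L, na.rm = TRUE),
             n_genotyped = ng, row.names = NULL, stringsAsFactors = FALSE)
}
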
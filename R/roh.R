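#' Detect runs of homozygosity (PLINK-style sliding scan)
#'
#' Slides a 50-SNP window along each chromosome; a window is called
#' homozygous when it contains at most `max_het` heterozygous calls. A SNP is
#' ROH-eligible when the fraction of overlapping homozygous windows reaches
#' `hit_threshold`. Maximal runs of eligible SNPs are split wherever the gap
#' between successive SNPs reaches `max_gap_bp`, then kept only if they have
#' at least `min_snps` SNPs, a length strictly greater than `min_length_bp`,
#' and a density of at least `min_density` SNPs per 100 kb.
#'
#' Defaults mirror the usual scanning rules: 50-SNP windows with at most 3
#' heterozygous calls, a minimum of 50 SNPs and >500 kb per run, successive
#' SNPs closer than 100 kb, and at least 10 SNPs per 100 kb.
#'
#' @param gm a [geno_matrix()] whose sites are position-sorted per chromosome.
#' @param sample sample id to scan.
#' @param window_snps scanning window size in SNPs.
#' @param max_het maximum heterozygous calls for a homozygous window.
#' @param hit_threshold minimum fraction of overlapping homozygous windows
#'   for a SNP to be eligible (scanning-tool default 0.05).
#' @param min_snps,min_length_bp,max_gap_bp,min_density run filters.
#' @return data frame (`sample`, `chrom`, `start`, `end`, `n_snps`,
#'   `length_bp`), non-overlapping and sorted; zero rows when nothing passes.
#' @export
detect_roh <- function(gm, sample, window_snps = 50, max_het = 3,
                       hit_threshold = 0.05, min_snps = 50,
                       min_length_bp = 5e5, max_gap_bp = 1e5,
                       min_density = 10) {
  g <- gm$geno[match(sample, gm$samples), ]
  out <- list()
  for (ch in unique(gm$chrom)) {
    i <- which(gm$chrom == ch)
    pos <- gm$pos[i]
    if (is.unsorted(pos, strictly = FALSE)) stop("positions unsorted on ", ch)
    het <- as.integer(!is.na(g[i]) & g[i] == 1L)
    m <- length(i)
    if (m < window_snps) next
    # window w covers SNPs w .. w+window_snps-1; hom iff <= max_het hets
    csum <- cumsum(c(0L, het))
    nw <- m - window_snps + 1L
    hom <- (csum[(1:nw) + window_snps] - csum[1:nw]) <= max_het
    # per-SNP fraction of overlapping homozygous windows
    lo <- pmax(1L, seq_len(m) - window_snps + 1L)
    hi <- pmin(nw, seq_len(m))
    hcs <- cumsum(c(0L, as.integer(hom)))
    frac <- (hcs[hi + 1L] - hcs[lo]) / (hi - lo + 1L)
    elig <- frac >= hit_threshold
    # maximal runs of eligible SNPs, split at large gaps
    brk <- c(FALSE, diff(pos) >= max_gap_bp)
    run_id <- cumsum(!elig | brk)
    for (r in split(which(elig), run_id[elig])) {
      n <- length(r)
      len <- pos[r[n]] - pos[r[1]] + 1L
      if (n >= min_snps && len > min_length_bp &&
          n / len * 1e5 >= min_density)
        out[[length(out) + 1L]] <- data.frame(
          sample = sample, chrom = ch, start = pos[r[1]], end = pos[r[n]],
          n_snps = n, length_bp = len, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), length_bp = integer(0)))
  do.call(rbind, out)
}

#' Total ROH length per sample
#' @param gm a [geno_matrix()].
#' @param samples sample ids (default all).
#' @param ... passed to [detect_roh()].
#' @return data frame (`sample`, `n_roh`, `total_bp`).
#' @export
roh_summary <- function(gm, samples = gm$samples, ...) {
  rows <- lapply(samples, function(s) {
    r <- detect_roh(gm, s, ...)
    data.frame(sample = s, n_roh = nrow(r), total_bp = sum(r$length_bp))
  })
  do.call(rbind, rows)
}
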
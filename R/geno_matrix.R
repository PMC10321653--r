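#' Diploid genotype matrix over biallelic sites
#'
#' The central in-memory container of the package: an ordered set of biallelic
#' SNP sites with per-sample diploid calls coded as the count of ALT alleles
#' (0, 1, 2 or `NA` for missing), optional phased haplotypes, per-site quality
#' annotations and, after [polarize()], the inferred ancestral allele.
#'
#' Coordinates are 1-based at the VCF boundary (`pos`); all windowed
#' operations use 0-based half-open windows internally, so a site at `pos`
#' falls in the window `[start, end)` iff `start <= pos - 1 < end`.
#'
#' @param geno integer matrix, samples in rows, sites in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param chrom,pos,ref,alt per-site chromosome, 1-based position, reference
#'   and alternate alleles.
#' @param samples sample identifiers (defaults to the rownames of `geno`).
#' @param qd,qual,mq optional per-site quality fields (QD, QUAL, MQ).
#' @param anc per-site ancestral-allele code in `{"ref","alt","unknown"}`, or
#'   `NA` while unpolarized.
#' @param annotation per-site class in `{"deleterious","tolerated","none"}`.
#' @param hap1,hap2 optional integer matrices of phased haplotype alleles
#'   (0/1/`NA`), same dimensions as `geno`.
#' @param phased logical matrix marking calls whose haplotype order is known.
#' @param dp optional numeric matrix of per-call read depths.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, chrom, pos, ref, alt, samples = rownames(geno),
                        qd = NULL, qual = NULL, mq = NULL,
                        anc = NULL, annotation = NULL,
                        hap1 = NULL, hap2 = NULL, phased = NULL, dp = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  ns <- nrow(geno); nl <- ncol(geno)
  if (is.null(samples)) samples <- paste0("S", seq_len(ns))
  stopifnot(length(samples) == ns, length(chrom) == nl, length(pos) == nl,
            length(ref) == nl, length(alt) == nl)
  if (nl > 0 && any(pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  fill <- function(x, default) if (is.null(x)) rep(default, nl) else x
  if (is.null(phased)) phased <- matrix(FALSE, ns, nl)
  if (is.null(hap1)) hap1 <- matrix(NA_integer_, ns, nl)
  if (is.null(hap2)) hap2 <- matrix(NA_integer_, ns, nl)
  storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
  ok <- !is.na(hap1) & !is.na(hap2) & !is.na(geno)
  if (any(ok) && any((hap1 + hap2)[ok] != geno[ok]))
    stop("haplotype pair must sum to the genotype code at non-missing calls")
  rownames(geno) <- samples
  obj <- list(
    samples = as.character(samples),
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    qd = as.numeric(fill(qd, NA_real_)), qual = as.numeric(fill(qual, NA_real_)),
    mq = as.numeric(fill(mq, NA_real_)),
    anc = as.character(fill(anc, NA_character_)),
    annotation = as.character(fill(annotation, "none")),
    geno = geno, hap1 = hap1, hap2 = hap2, phased = phased, dp = dp
  )
  class(obj) <- "geno_matrix"
  obj
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$samples), "samples x", n_sites(x), "sites\n")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  pol <- sum(!is.na(x$anc) & x$anc != "unknown")
  cat("  polarized sites:", pol, "| phased calls:", sum(x$phased), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Number of sites in a genotype matrix
#' @param gm a [geno_matrix()].
#' @return integer site count.
#' @export
n_sites <- function(gm) length(gm$pos)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param x a [geno_matrix()].
#' @param samples integer/logical/character index over samples.
#' @param sites integer/logical index over sites.
#' @param ... unused.
#' @return a `geno_matrix` with the selected rows/columns; order preserved.
#' @export
`[.geno_matrix` <- function(x, samples = NULL, sites = NULL, ...) {
  if (is.null(samples)) samples <- seq_along(x$samples)
  if (is.character(samples)) samples <- match(samples, x$samples)
  if (is.null(sites)) sites <- seq_along(x$pos)
  geno_matrix(x$geno[samples, sites, drop = FALSE],
              x$chrom[sites], x$pos[sites], x$ref[sites], x$alt[sites],
              samples = x$samples[samples],
              qd = x$qd[sites], qual = x$qual[sites], mq = x$mq[sites],
              anc = x$anc[sites], annotation = x$annotation[sites],
              hap1 = x$hap1[samples, sites, drop = FALSE],
              hap2 = x$hap2[samples, sites, drop = FALSE],
              phased = x$phased[samples, sites, drop = FALSE],
              dp = if (!is.null(x$dp)) x$dp[samples, sites, drop = FALSE])
}

#' Derived-allele dosage view of a polarized matrix
#'
#' Maps genotype codes onto counts of the *derived* allele: equal to the code
#' where the ancestral allele is REF, `2 - code` where it is ALT, and `NA`
#' where the ancestral state is unknown or the call is missing.
#'
#' @param gm a polarized [geno_matrix()] (see [polarize()]).
#' @return integer matrix, samples x sites, with `NA` columns at
#'   unknown-ancestral sites.
#' @export
derived_dosage <- function(gm) {
  if (all(is.na(gm$anc))) stop("matrix is not polarized; run polarize() first")
  d <- gm$geno
  flip <- which(gm$anc == "alt")
  if (length(flip)) d[, flip] <- 2L - d[, flip, drop = FALSE]
  unk <- which(is.na(gm$anc) | gm$anc == "unknown")
  if (length(unk)) d[, unk] <- NA_integer_
  d
}

#' Per-group derived-allele frequencies
#'
#' @param gm polarized [geno_matrix()].
#' @param pm a [population_map()].
#' @param groups group labels to tabulate (default: all non-outgroup groups
#'   plus the outgroup).
#' @return list with `freq` (groups x sites derived-allele frequency, `NA`
#'   where no data or ancestral state unknown) and `n_chr` (non-missing
#'   chromosome counts).
#' @export
group_freqs <- function(gm, pm, groups = NULL) {
  if (is.null(groups)) groups <- pm$groups
  d <- derived_dosage(gm)
  freq <- matrix(NA_real_, length(groups), n_sites(gm),
                 dimnames = list(groups, NULL))
  nchr <- matrix(0L, length(groups), n_sites(gm), dimnames = list(groups, NULL))
  for (gi in seq_along(groups)) {
    idx <- match(group_samples(pm, groups[gi], gm$samples), gm$samples)
    sub <- d[idx, , drop = FALSE]
    n <- 2L * colSums(!is.na(sub))
    s <- colSums(sub, na.rm = TRUE)
    freq[gi, ] <- ifelse(n > 0, s / n, NA_real_)
    nchr[gi, ] <- n
  }
  list(freq = freq, n_chr = nchr)
}
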
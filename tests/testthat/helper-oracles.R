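# Independent brute-force oracles. These re-derive each statistic from its
# definition by explicit loops over haplotype/sample pairs and sites, and
# stay deliberately separate from the package's vectorized implementations.

# per-site heterozygosity sum via explicit pair counting: k alt alleles of n
oracle_pi_sum <- function(k, n) {
  tot <- 0
  for (i in seq_along(k)) {
    if (n[i] < 2) next
    diffs <- 0; pairs <- 0
    alleles <- c(rep(1, k[i]), rep(0, n[i] - k[i]))
    for (a in seq_len(n[i] - 1)) for (b in (a + 1):n[i]) {
      pairs <- pairs + 1
      if (alleles[a] != alleles[b]) diffs <- diffs + 1
    }
    tot <- tot + diffs / pairs
  }
  tot
}

oracle_dxy_sum <- function(kA, nA, kB, nB) {
  tot <- 0
  for (i in seq_along(kA)) {
    if (nA[i] < 1 || nB[i] < 1) next
    a <- c(rep(1, kA[i]), rep(0, nA[i] - kA[i]))
    b <- c(rep(1, kB[i]), rep(0, nB[i] - kB[i]))
    diffs <- 0
    for (x in a) for (y in b) if (x != y) diffs <- diffs + 1
    tot <- tot + diffs / (nA[i] * nB[i])
  }
  tot
}

oracle_fst <- function(kA, nA, kB, nB) {
  piw <- (oracle_pi_sum(kA, nA) + oracle_pi_sum(kB, nB)) / 2
  dxy <- oracle_dxy_sum(kA, nA, kB, nB)
  1 - piw / dxy
}

# Tajima (1989) D coded independently from the constants up
oracle_tajima <- function(n, S, pi_sum) {
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracle_d_stat <- function(p1, p2, p3, p4) {
  abba <- 0; baba <- 0
  for (i in seq_along(p1)) {
    abba <- abba + (1 - p1[i]) * p2[i] * p3[i] * (1 - p4[i])
    baba <- baba + p1[i] * (1 - p2[i]) * p3[i] * (1 - p4[i])
  }
  (abba - baba) / (abba + baba)
}

# naive leave-one-block-out jackknife SE of a ratio of sums
oracle_jackknife_se <- function(num, den, block) {
  blocks <- sort(unique(block))
  B <- length(blocks)
  loo <- numeric(B)
  for (i in seq_len(B)) {
    keep <- block != blocks[i]
    loo[i] <- sum(num[keep]) / sum(den[keep])
  }
  sqrt((B - 1) / B * sum((loo - mean(loo))^2))
}

oracle_pdist <- function(a, b) {
  diffs <- 0; comp <- 0
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) next
    comp <- comp + 1
    if (a[i] != b[i]) diffs <- diffs + 1
  }
  if (comp == 0) NA_real_ else diffs / comp
}

# minimal single-locus Hudson coalescent with infinite-sites mutation:
# returns the list of carrier tip sets (one per mutation) for one locus
coalescent_locus <- function(n, theta) {
  active <- as.list(seq_len(n))     # descendant tip sets of active lineages
  t_now <- 0
  birth <- rep(0, n)                # per-lineage start times
  muts <- list()
  while (length(active) > 1) {
    k <- length(active)
    t_now <- t_now + stats::rexp(1, rate = k * (k - 1) / 2)
    pick <- sample(k, 2)
    merged <- c(active[[pick[1]]], active[[pick[2]]])
    for (p in pick) {
      nmut <- stats::rpois(1, theta / 2 * (t_now - birth[p]))
      if (nmut > 0)
        muts <- c(muts, rep(active[p], nmut))
    }
    active <- active[-pick]
    birth <- birth[-pick]
    active[[length(active) + 1]] <- merged
    birth <- c(birth, t_now)
  }
  muts
}

# many independent loci; returns haplotype matrix n x S plus locus index.
# small theta keeps sites on (mostly) independent genealogies.
coalescent_sites <- function(n, n_loci, theta) {
  carriers <- list()
  locus <- integer(0)
  for (l in seq_len(n_loci)) {
    m <- coalescent_locus(n, theta)
    if (length(m)) {
      carriers <- c(carriers, m)
      locus <- c(locus, rep(l, length(m)))
    }
  }
  S <- length(carriers)
  haps <- matrix(0L, n, S)
  for (j in seq_len(S)) haps[carriers[[j]], j] <- 1L
  list(haps = haps, locus = locus)
}

# wrap a haplotype matrix (n_hap x S, derived = 1) into a polarized
# geno_matrix of n_hap/2 diploids, one locus per `locus_bp` window
coalescent_gm <- function(cs, locus_bp = 1e5) {
  haps <- cs$haps
  n_hap <- nrow(haps)
  stopifnot(n_hap %% 2 == 0)
  S <- ncol(haps)
  pos <- integer(S)
  for (l in unique(cs$locus)) {
    idx <- which(cs$locus == l)
    pos[idx] <- (l - 1) * locus_bp + sort(sample.int(locus_bp - 1, length(idx)))
  }
  o <- order(pos)
  haps <- haps[, o, drop = FALSE]; pos <- pos[o]
  h1 <- haps[seq(1, n_hap, 2), , drop = FALSE]
  h2 <- haps[seq(2, n_hap, 2), , drop = FALSE]
  samples <- paste0("S", seq_len(n_hap / 2))
  rownames(h1) <- rownames(h2) <- samples
  gm <- geno_matrix(h1 + h2, chrom = rep("chr1", S), pos = pos,
                    ref = rep("A", S), alt = rep("T", S), samples = samples,
                    anc = rep("ref", S), hap1 = h1, hap2 = h2,
                    phased = matrix(TRUE, n_hap / 2, S))
  pm <- population_map(c(stats::setNames(rep("POP", n_hap / 2), samples),
                         OUT = "OUTGROUP"))
  list(gm = gm, pm = pm)
}
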
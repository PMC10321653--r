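# Synthetic cohorts with a known truth channel.
#
# Population structure follows a Balding-Nichols model: each group's
# derived-allele frequency at a site is Beta(p(1-F)/F, (1-p)(1-F)/F) around
# an ancestral frequency p drawn from a neutral-like (density proportional
# to 1/p) spectrum. Apomictic groups draw their two haplotypes from two
# diverged source pools, producing the elevated heterozygosity that clonal
# lineages accumulate. Introgression is planted by copying contiguous
# donor-derived tracts into target haplotypes, so per-sample introgressed
# allele fractions are exact to tract-length granularity.

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the five-group kumquat study design: cultivated apomicts
#' and sexuals, wild apomicts and two wild sexual subpopulations, plus a
#' diverged outgroup used for polarization. The two wild sexual groups'
#' drift coefficients default to 0.1332 each, so their expected pairwise
#' Hudson Fst equals the headline differentiation of the system being
#' emulated (under this generator E\[Fst\] is the mean of the two F values).
#'
#' @param groups named integer vector of group sizes.
#' @param n_outgroup outgroup sample count.
#' @param drift named per-group Balding-Nichols F values (0 = no drift).
#' @param n_sites total biallelic SNP count.
#' @param chrom_len named chromosome lengths in bp.
#' @param n_diag number of planted diagnostic sites (fixed derived in the
#'   cultivated groups, fixed ancestral in wild groups and outgroup).
#' @param deleterious_frac fraction of non-diagnostic sites annotated
#'   deleterious (an equal number receive tolerated scores).
#' @param cultivated_groups labels treated as cultivated for diagnostic
#'   sites.
#' @param apomict_groups labels whose samples draw haplotypes from two
#'   diverged pools.
#' @param apomict_divergence drift F separating an apomictic group's two
#'   haplotype pools.
#' @param outgroup_fixed_frac fraction of sites at which the outgroup is
#'   fixed for the ancestral allele (diagnostic sites always are); remaining
#'   sites get a polymorphic outgroup and polarize to "unknown".
#' @param anc_ref_prob probability that the ancestral allele is REF.
#' @param freq_range truncation range of the ancestral frequency spectrum.
#' @param introgression `NULL`, or a data frame with columns `sample`,
#'   `donor`, `fraction`, `tract_bp` describing planted cultivated-origin
#'   tracts per target sample.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(groups = c(CULAPO = 6, CULSEX = 6, WILDAPO = 6,
                                     WILDSEX1 = 8, WILDSEX2 = 6),
                          n_outgroup = 4,
                          drift = c(CULAPO = 0.08, CULSEX = 0.08,
                                    WILDAPO = 0.06, WILDSEX1 = 0.1332,
                                    WILDSEX2 = 0.1332),
                          n_sites = 4000,
                          chrom_len = c(chr1 = 25e6, chr2 = 25e6),
                          n_diag = min(400, n_sites %/% 2),
                          deleterious_frac = 0.05,
                          cultivated_groups = c("CULAPO", "CULSEX"),
                          apomict_groups = c("CULAPO", "WILDAPO"),
                          apomict_divergence = 0.15,
                          outgroup_fixed_frac = 0.95,
                          anc_ref_prob = 0.7,
                          freq_range = c(0.05, 0.95),
                          introgression = NULL) {
  stopifnot(all(groups >= 1), n_outgroup >= 1, n_sites > 0,
            all(chrom_len > 0), n_diag >= 0, n_diag <= n_sites)
  if (is.null(names(drift)) || !all(names(groups) %in% names(drift)))
    stop("drift must name every group")
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

bn_freq <- function(p, F) {
  if (F <= 0) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate a structured cohort with planted truth
#'
#' Deterministic under `(cfg, seed)`. See [cohort_config()] for the model.
#'
#' @param cfg a [cohort_config()].
#' @param seed integer RNG seed.
#' @return list with `gm` (phased [geno_matrix()]), `pm`
#'   ([population_map()]), `truth` (planted ground truth: per-sample
#'   introgression fractions and tract map, diagnostic and deleterious site
#'   indices, true ancestral alleles, per-sample heterozygous/homozygous
#'   deleterious site counts) and `annotations` (chrom/pos/score table).
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = 1) {
  set.seed(seed)
  genome <- sum(cfg$chrom_len)
  # --- sites ---------------------------------------------------------------
  n_per <- round(cfg$n_sites * cfg$chrom_len / genome)
  n_per[length(n_per)] <- cfg$n_sites - sum(n_per[-length(n_per)])
  chrom <- rep(names(cfg$chrom_len), n_per)
  pos <- unlist(lapply(seq_along(cfg$chrom_len), function(i)
    sort(sample.int(cfg$chrom_len[i], n_per[i]))), use.names = FALSE)
  n <- cfg$n_sites
  anc_is_ref <- stats::runif(n) < cfg$anc_ref_prob
  ref <- ifelse(anc_is_ref, "A", "T"); alt <- ifelse(anc_is_ref, "T", "A")
  a <- cfg$freq_range[1]; b <- cfg$freq_range[2]
  p0 <- a * (b / a)^stats::runif(n)       # density ~ 1/p on [a, b]
  diag_sites <- sort(sample.int(n, cfg$n_diag))
  pool <- setdiff(seq_len(n), diag_sites)
  n_del <- round(cfg$deleterious_frac * length(pool))
  picked <- sample(pool, 2 * n_del)
  del_sites <- sort(picked[seq_len(n_del)])
  tol_sites <- sort(picked[-seq_len(n_del)])

  # --- group frequencies ---------------------------------------------------
  glabs <- names(cfg$groups)
  freq <- sapply(glabs, function(g) bn_freq(p0, cfg$drift[[g]]))
  is_cul <- glabs %in% cfg$cultivated_groups
  freq[diag_sites, is_cul] <- 1; freq[diag_sites, !is_cul] <- 0
  pools <- list()
  for (g in intersect(cfg$apomict_groups, glabs)) {
    pa <- bn_freq(freq[, g], cfg$apomict_divergence)
    pb <- bn_freq(freq[, g], cfg$apomict_divergence)
    pa[diag_sites] <- freq[diag_sites, g]; pb[diag_sites] <- freq[diag_sites, g]
    pools[[g]] <- cbind(pa, pb)
  }

  # --- haplotypes ----------------------------------------------------------
  samples <- unlist(lapply(glabs, function(g)
    paste0(g, "_", seq_len(cfg$groups[[g]]))), use.names = FALSE)
  og_samples <- paste0("OUTGROUP_", seq_len(cfg$n_outgroup))
  assign <- c(stats::setNames(rep(glabs, cfg$groups), samples),
              stats::setNames(rep("OUTGROUP", cfg$n_outgroup), og_samples))
  all_samples <- c(samples, og_samples)
  ns <- length(all_samples)
  h1 <- h2 <- matrix(0L, ns, n, dimnames = list(all_samples, NULL))
  for (s in samples) {
    g <- assign[[s]]
    if (!is.null(pools[[g]])) {
      h1[s, ] <- stats::rbinom(n, 1L, pools[[g]][, 1])
      h2[s, ] <- stats::rbinom(n, 1L, pools[[g]][, 2])
    } else {
      h1[s, ] <- stats::rbinom(n, 1L, freq[, g])
      h2[s, ] <- stats::rbinom(n, 1L, freq[, g])
    }
  }
  og_fixed <- stats::runif(n) < cfg$outgroup_fixed_frac
  og_fixed[diag_sites] <- TRUE
  for (s in og_samples) {
    h1[s, !og_fixed] <- stats::rbinom(sum(!og_fixed), 1L, 0.5)
    h2[s, !og_fixed] <- stats::rbinom(sum(!og_fixed), 1L, 0.5)
  }

  # --- planted introgression tracts ---------------------------------------
  intro <- cfg$introgression
  tract_map <- list()
  intro_frac <- stats::setNames(rep(0, length(samples)), samples)
  if (!is.null(intro) && nrow(intro) > 0) {
    for (r in seq_len(nrow(intro))) {
      smp <- intro$sample[r]; donor <- intro$donor[r]
      frac <- intro$fraction[r]; tract <- intro$tract_bp[r]
      stopifnot(smp %in% samples, donor %in% glabs, frac >= 0, frac <= 1)
      target_bp <- frac * 2 * genome
      n_full <- floor(target_bp / tract)
      rem <- target_bp - n_full * tract
      slots <- do.call(rbind, lapply(names(cfg$chrom_len), function(ch) {
        k <- floor(cfg$chrom_len[[ch]] / tract)
        if (k == 0) return(NULL)
        data.frame(chrom = ch, start = (seq_len(k) - 1) * tract)
      }))
      units <- rbind(cbind(slots, hap = 1L), cbind(slots, hap = 2L))
      need <- n_full + (rem > 0)
      if (need > nrow(units))
        stop("requested introgression fraction unreachable with tract_bp = ",
             tract)
      take <- units[sample.int(nrow(units), need), , drop = FALSE]
      take$len <- c(rep(tract, n_full), if (rem > 0) rem)
      dfreq <- if (!is.null(pools[[donor]]))
        rowMeans(pools[[donor]]) else freq[, donor]
      for (u in seq_len(nrow(take))) {
        sel <- chrom == take$chrom[u] & pos > take$start[u] &
          pos <= take$start[u] + take$len[u]
        if (any(sel)) {
          drawn <- stats::rbinom(sum(sel), 1L, dfreq[sel])
          if (take$hap[u] == 1L) h1[smp, sel] <- drawn else h2[smp, sel] <- drawn
        }
      }
      tract_map[[smp]] <- rbind(tract_map[[smp]], data.frame(
        chrom = take$chrom, start = take$start, end = take$start + take$len,
        hap = take$hap, donor = donor))
      intro_frac[smp] <- intro_frac[smp] + frac
    }
  }

  # --- encode as REF/ALT ---------------------------------------------------
  flip <- which(!anc_is_ref)        # there, derived allele is REF
  a1 <- h1; a2 <- h2
  if (length(flip)) {
    a1[, flip] <- 1L - a1[, flip, drop = FALSE]
    a2[, flip] <- 1L - a2[, flip, drop = FALSE]
  }
  geno <- a1 + a2
  annotation <- rep("none", n)
  annotation[del_sites] <- "deleterious"; annotation[tol_sites] <- "tolerated"
  gm <- geno_matrix(geno, chrom = chrom, pos = pos, ref = ref, alt = alt,
                    samples = all_samples,
                    qd = rep(30, n), qual = rep(100, n), mq = rep(60, n),
                    annotation = annotation,
                    hap1 = a1, hap2 = a2,
                    phased = matrix(TRUE, ns, n))
  pm <- population_map(assign)

  # --- truth channel -------------------------------------------------------
  ddos <- h1 + h2                   # derived dosage by construction
  het_del <- rowSums(ddos[, del_sites, drop = FALSE] == 1L)
  hom_del <- rowSums(ddos[, del_sites, drop = FALSE] == 2L)
  score <- rep(NA_real_, n)
  score[del_sites] <- stats::runif(n_del, 0, 0.05)
  score[tol_sites] <- stats::runif(length(tol_sites), 0.06, 1)
  ann_df <- data.frame(chrom = chrom[!is.na(score)], pos = pos[!is.na(score)],
                       score = score[!is.na(score)])
  truth <- list(group_of = assign,
                introgression_fraction = intro_frac,
                tract_map = tract_map,
                diag_sites = diag_sites,
                deleterious_sites = del_sites,
                true_anc = ifelse(anc_is_ref, "ref", "alt"),
                het_del = het_del, hom_del = hom_del,
                seed = seed)
  list(gm = gm, pm = pm, truth = truth, annotations = ann_df)
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf.gz`, `samples.tsv`, `annotations.tsv` and `truth.json`
#' under `dir`.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$gm, file.path(dir, "cohort.vcf.gz"))
  write_population_map(sim$pm, file.path(dir, "samples.tsv"))
  utils::write.table(sim$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  truth <- sim$truth
  truth$tract_map <- lapply(truth$tract_map, function(d) as.list(d))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

# constants calibrating the default occurrence clouds: a two-block bioclim
# correlation structure (a 10-variable temperature-like block, a 6-variable
# precipitation-like block, 3 independent variables) and a cultivated-mean
# shift along the first block. rho1/rho2 set the population PC1/PC2 shares
# of the pooled standardized PCA to 47.5%/20.6%, and the shift's Mahalanobis
# norm solves P(chisq_19(ncp) <= chisq_19(0.95)) = 0.58, the directional
# 95%-niche-region overlap of two equal-covariance Gaussian niches.
.occ_rho1 <- 0.7010038
.occ_rho2 <- 0.5828
.occ_shift <- 8.626417

occ_correlation <- function() {
  R <- diag(19)
  R[1:10, 1:10] <- .occ_rho1
  R[11:16, 11:16] <- .occ_rho2
  diag(R) <- 1
  R
}

#' Simulate a labeled bioclimatic occurrence table
#'
#' Two 19-dimensional Gaussian clouds ("wild" and "cultivated") with a
#' block-correlated bioclim-like covariance; the default mean shift and
#' correlation blocks are calibrated so that, at the population level, the
#' pooled standardized PCA explains 47.5%/20.6% on PC1/PC2 and the
#' directional 95% niche-region overlap is 58%. Deterministic under `seed`.
#'
#' @param n_wild,n_cult record counts (default 244 and 152).
#' @param mean_shift scalar multiplying the calibrated shift vector (0 gives
#'   identical distributions; large values give disjoint clouds).
#' @param cov_scale positive scalar multiplying the covariance.
#' @param seed integer RNG seed.
#' @return data frame with a `label` column (`wild`/`cultivated`) and 19
#'   standardized variables `bio1..bio19`; no missing values.
#' @export
simulate_occurrences <- function(n_wild = 244, n_cult = 152, mean_shift = 1,
                                 cov_scale = 1, seed = 1) {
  stopifnot(n_wild >= 2, n_cult >= 2)
  if (cov_scale <= 0) stop("cov_scale must be positive")
  set.seed(seed)
  R <- occ_correlation() * cov_scale
  L <- chol(R)
  draw <- function(k, mu) {
    z <- matrix(stats::rnorm(k * 19), k, 19) %*% L
    sweep(z, 2, mu, `+`)
  }
  mu_w <- rep(0, 19)
  mu_c <- c(rep(mean_shift * .occ_shift / sqrt(10), 10), rep(0, 9))
  x <- rbind(draw(n_wild, mu_w), draw(n_cult, mu_c))
  colnames(x) <- paste0("bio", 1:19)
  data.frame(label = rep(c("wild", "cultivated"), c(n_wild, n_cult)),
             x, stringsAsFactors = FALSE)
}
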
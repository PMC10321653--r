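# Site-pattern statistics on hand-built frequency tables plus truth-channel
# recovery of planted gene flow.

ft_manual <- function(p1, p2, p3, p4, pos = NULL, chrom = NULL) {
  n <- length(p1)
  if (is.null(pos)) pos <- seq_len(n) * 1e6
  if (is.null(chrom)) chrom <- rep("chr1", n)
  structure(list(chrom = chrom, pos = pos, p1 = p1, p2 = p2, p3 = p3,
                 p4 = p4, groups = c("P1", "P2", "P3", "O")),
            class = "freq_table")
}

test_that("D statistic reproduces hand-computed ABBA/BABA sums", {
  # pure ABBA site
  ft1 <- ft_manual(0, 1, 1, 0, pos = c(1e6), chrom = "chr1")
  ft1$pos <- c(1e6, 9e6); ft1$chrom <- rep("chr1", 2)
  ft1$p1 <- c(0, 0); ft1$p2 <- c(1, 1); ft1$p3 <- c(1, 1); ft1$p4 <- c(0, 0)
  expect_equal(d_statistic(ft1)$D, 1)

  # hand case: sum(ABBA) = 1.5, sum(BABA) = 1, D = 0.2
  ft2 <- ft_manual(c(0, 1, 0), c(1, 0, 0.5), c(1, 1, 1), c(0, 0, 0))
  d <- d_statistic(ft2, block_bp = 1e6)
  expect_equal(d$abba_sum, 1.5)
  expect_equal(d$baba_sum, 1)
  expect_equal(d$D, 0.2)

  # sign convention: swapping P1 and P2 negates D
  ft3 <- ft_manual(ft2$p2, ft2$p1, ft2$p3, ft2$p4)
  expect_equal(d_statistic(ft3, block_bp = 1e6)$D, -0.2)

  # undefined when no informative sites
  ft0 <- ft_manual(c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  expect_error(d_statistic(ft0), "undefined")
})

test_that("D and its jackknife SE match the brute-force oracle", {
  set.seed(21)
  n <- 50
  ft <- ft_manual(runif(n), runif(n), runif(n), runif(n, 0, 0.1),
                  pos = sort(sample.int(40e6, n)))
  d <- d_statistic(ft, block_bp = 5e6)
  expect_equal(d$D, oracle_d_stat(ft$p1, ft$p2, ft$p3, ft$p4),
               tolerance = 1e-10)
  ab <- cwrpop:::abba_baba(ft$p1, ft$p2, ft$p3, ft$p4)
  blk <- cwrpop:::genome_blocks(ft$chrom, ft$pos, 5e6)
  expect_equal(d$se, oracle_jackknife_se(ab$abba - ab$baba,
                                         ab$abba + ab$baba, blk),
               tolerance = 1e-10)
})

test_that("f_d is 1 under complete replacement and NA in negative-D windows", {
  set.seed(22)
  p1 <- runif(40, 0, 0.2); p3 <- runif(40, 0.3, 1); p4 <- rep(0, 40)
  ft <- ft_manual(p1, p3, p3, p4, pos = sort(sample.int(1e6, 40)))
  fd <- fd_windows(ft, window_bp = 25000)
  expect_true(all(abs(fd$value[!is.na(fd$value)] - 1) < 1e-12))

  ft_neg <- ft_manual(c(1, 1), c(0, 0), c(1, 1), c(0, 0),
                      pos = c(100, 200))
  expect_true(all(is.na(fd_windows(ft_neg, window_bp = 25000)$value)))
})

test_that("SSM identification follows the fixed-difference definition", {
  g <- rbind(c1 = c(2L, 2L, 2L, 2L), c2 = c(2L, 1L, 2L, 2L),
             w1 = c(0L, 0L, 0L, 0L), w2 = c(0L, 0L, 0L, 0L),
             o1 = c(0L, 0L, 1L, 0L), o2 = c(0L, 0L, 0L, NA))
  pm <- make_pm(c1 = "CUL", c2 = "CUL", w1 = "WILD", w2 = "WILD",
                o1 = "OUTGROUP", o2 = "OUTGROUP")
  gm <- polarize(make_gm(g), pm)
  ssm <- identify_ssms(gm, pm, "CUL", "WILD")
  # site 1 qualifies; site 2 has a het cultivated call; site 3 het outgroup;
  # site 4 outgroup missing
  expect_equal(ssm$site, 1L)
  expect_equal(ssm$diag_allele, "alt")
  expect_equal(ssm$polarity, "derived")
  expect_error(identify_ssms(gm, pm, "CUL", "CUL"), "overlap")
})

test_that("dosage counts diagnostic alleles per the direct-count formula", {
  # 20 SSMs, sample het at 10 of them: 10 / 40 alleles = 0.25
  ssm <- data.frame(chrom = "chr1", pos = 1:20 * 1000, site = 1:20,
                    diag_allele = "alt", polarity = "derived")
  class(ssm) <- c("ssm_set", "data.frame")
  g <- matrix(0L, 2, 20, dimnames = list(c("t", "cul"), NULL))
  g["t", 1:10] <- 1L
  g["cul", ] <- 2L
  gm <- make_gm(g)
  dos <- introgression_dosage(gm, ssm)
  expect_equal(dos$proportion, c(0.25, 1))
  expect_equal(dos$n_het_sites, c(10L, 0L))
  expect_equal(dos$n_hom_sites, c(0L, 20L))
  # identity: n_het + 2 n_hom equals the dosage numerator
  expect_equal(dos$n_het_sites + 2 * dos$n_hom_sites,
               dos$proportion * 2 * dos$n_genotyped)
  # all-missing sample is skipped with a warning
  g2 <- rbind(g, miss = rep(NA_integer_, 20))
  expect_warning(d2 <- introgression_dosage(make_gm(g2), ssm), "skipped")
  expect_equal(nrow(d2), 2L)
})

test_that("SSMs recover planted diagnostic sites (Jaccard >= 0.95)", {
  sim <- simulate_cohort(cohort_config(n_sites = 2000), seed = 31)
  gm <- polarize(sim$gm, sim$pm)
  ssm <- identify_ssms(gm, sim$pm, c("CULAPO", "CULSEX"), "WILDSEX1")
  jac <- length(intersect(ssm$site, sim$truth$diag_sites)) /
    length(union(ssm$site, sim$truth$diag_sites))
  expect_gte(jac, 0.95)
})

test_that("f-branch flags planted donor flow and respects its masks", {
  tree <- "((WILDSEX1,WILDSEX2),(CULAPO,CULSEX));"
  intro <- data.frame(sample = paste0("WILDSEX2_", 1:6), donor = "CULAPO",
                      fraction = 0.2, tract_bp = 1e6)
  sim <- simulate_cohort(cohort_config(n_sites = 3000, introgression = intro),
                         seed = 32)
  gm <- polarize(sim$gm, sim$pm)
  fb <- f_branch(gm, sim$pm, tree, block_bp = 5e6)
  # donors descending from a branch are masked
  expect_true(is.na(fb$fb["WILDSEX2", "WILDSEX2"]))
  # planted CULAPO -> WILDSEX2 cell exceeds its sister's cell
  expect_gt(fb$fb["WILDSEX2", "CULAPO"], 0.1)
  expect_lt(fb$fb["WILDSEX1", "CULAPO"], 0.05)
  expect_true(fb$significant["WILDSEX2", "CULAPO"])
})

test_that("f-hat equals 1 when the recipient equals the donor", {
  sim <- simulate_cohort(cohort_config(n_sites = 1000), seed = 33)
  gm <- polarize(sim$gm, sim$pm)
  # duplicate the donor group under a second label: B := C data rows
  pm <- sim$pm
  ft <- freq_table(gm, pm, "WILDSEX1", "CULAPO", "CULAPO")
  ab <- cwrpop:::abba_baba(ft$p1, ft$p2, ft$p3, ft$p4)
  abd <- cwrpop:::abba_baba(ft$p1, ft$p3, ft$p3, ft$p4)
  fhat <- sum(ab$abba - ab$baba) / sum(abd$abba - abd$baba)
  expect_equal(fhat, 1, tolerance = 1e-12)
})

test_that("no-flow f-branch cells stay near zero and non-significant", {
  tree <- "((WILDSEX1,WILDSEX2),(CULAPO,CULSEX));"
  vals <- c(); nsig <- 0
  for (s in 1:5) {
    sim <- simulate_cohort(cohort_config(n_sites = 2000), seed = 40 + s)
    gm <- polarize(sim$gm, sim$pm)
    fb <- f_branch(gm, sim$pm, tree, block_bp = 5e6)
    vals <- c(vals, fb$fb[!is.na(fb$fb)])
    nsig <- nsig + sum(fb$significant & fb$fb > 0, na.rm = TRUE)
  }
  expect_lt(mean(vals), 0.02)
  expect_equal(nsig, 0)
})
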
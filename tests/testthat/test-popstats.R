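pm2 <- make_pm(a1 = "A", a2 = "A", b1 = "B", b2 = "B", o = "OUTGROUP")

test_that("window_pi matches its definition and the all-pairs oracle", {
  # 2 haplotypes (1 diploid het call) differing at 1 site in a 100-bp window
  gm <- make_gm(matrix(1L, 1, 1), pos = 50, samples = "a1")
  pm1 <- make_pm(a1 = "A", o = "OUTGROUP")
  pi1 <- window_pi(gm, pm1, "A", window_bp = 100, min_sites = 1)
  expect_equal(pi1$value, 0.01)

  # monomorphic window
  gm0 <- make_gm(matrix(0L, 2, 5), samples = c("a1", "a2"))
  expect_equal(window_pi(gm0, pm2, "A", 1e5, min_sites = 1)$value, 0)

  # 4 haplotypes, derived counts (1, 2): brute-force all-pairs equality
  gm2 <- make_gm(rbind(a1 = c(1L, 0L), a2 = c(0L, 2L)), pos = c(10, 20))
  got <- window_pi(gm2, pm2, "A", window_bp = 100, min_sites = 1)$value
  expect_equal(got, oracle_pi_sum(c(1, 2), c(4, 4)) / 100, tolerance = 1e-12)
})

test_that("window_dxy matches definition and between-pairs oracle", {
  # groups fixed for different alleles at 1 site / 100 bp
  gm <- make_gm(rbind(a1 = 0L, a2 = 0L, b1 = 2L, b2 = 2L), pos = 50)
  expect_equal(window_dxy(gm, pm2, "A", "B", 100, min_sites = 1)$value, 0.01)

  set.seed(2)
  g <- matrix(sample(0:2, 40, replace = TRUE), 4, 10,
              dimnames = list(c("a1", "a2", "b1", "b2"), NULL))
  gm2 <- make_gm(g, pos = 1:10 * 10)
  kA <- colSums(g[1:2, ]); kB <- colSums(g[3:4, ])
  want <- oracle_dxy_sum(kA, rep(4, 10), kB, rep(4, 10)) / 1000
  got <- window_dxy(gm2, pm2, "A", "B", 1000, min_sites = 1)$value
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("Hudson Fst is 1 for fixed differences and ~0 for panmixia", {
  gm <- make_gm(rbind(a1 = 0L, a2 = 0L, b1 = 2L, b2 = 2L), pos = 50)
  expect_equal(window_fst(gm, pm2, "A", "B", 100, min_sites = 1)$value, 1)

  # identical panmictic groups: mean Fst near zero across seeds
  vals <- sapply(1:50, function(s) {
    set.seed(s)
    p <- runif(200, 0.1, 0.9)
    g <- matrix(rbinom(4 * 200, 2, rep(p, each = 4)), 4, 200, byrow = FALSE,
                dimnames = list(c("a1", "a2", "b1", "b2"), NULL))
    gm <- make_gm(g, pos = seq_len(200))
    global_fst(gm, pm2, "A", "B")
  })
  expect_lt(abs(mean(vals)), 0.01)
})

test_that("Balding-Nichols cohort recovers its drift F as genome-wide Fst", {
  # both groups at F = 0.1 around shared ancestral frequencies: the Hudson
  # ratio-of-sums expectation is F (within-het 2pq(1-F) vs between-het 2pq)
  drift <- c(CULAPO = 0.1, CULSEX = 0.1, WILDAPO = 0.1, WILDSEX1 = 0.1,
             WILDSEX2 = 0.1)
  fst <- sapply(1:3, function(s) {
    sim <- simulate_cohort(cohort_config(n_sites = 4000, n_diag = 0,
                                         drift = drift), seed = 500 + s)
    global_fst(sim$gm, sim$pm, "WILDSEX1", "WILDSEX2")
  })
  expect_equal(mean(fst), 0.1, tolerance = 0.02)
})

test_that("Tajima's D handles undefined windows and matches the oracle", {
  gm0 <- make_gm(matrix(0L, 4, 3), samples = c("a1", "a2", "b1", "b2"))
  td <- tajimas_d(gm0, pm2, "A", 1e5)
  expect_true(all(is.na(td$value)))   # S = 0 is missing, not 0

  # hand case: n = 4 haplotypes, S = 2 segregating sites
  gm <- make_gm(rbind(a1 = c(1L, 0L), a2 = c(0L, 2L)), pos = c(10, 20))
  got <- tajimas_d(gm, pm2, "A", 1e5)$value
  want <- oracle_tajima(4, 2, oracle_pi_sum(c(1, 2), c(4, 4)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("Tajima's D is near zero under equilibrium neutrality", {
  set.seed(77)
  cs <- coalescent_sites(20, 100, theta = 6)
  cg <- coalescent_gm(cs)
  td <- tajimas_d(cg$gm, cg$pm, "POP", window_bp = 1e5)
  expect_gt(sum(!is.na(td$value)), 80)
  expect_lt(abs(mean(td$value, na.rm = TRUE)), 0.2)
})

test_that("heterozygosity and window_het conserve the global count", {
  g <- rbind(s1 = c(0L, 1L, 1L, 2L, NA), s2 = c(0L, 0L, 0L, 0L, 0L))
  gm <- make_gm(g, pos = c(10, 20, 150010, 150020, 150030))
  expect_equal(heterozygosity(gm, "s1"), 2 / 4)
  expect_equal(heterozygosity(gm, "s2"), 0)
  wh <- window_het(gm, "s1", window_bp = 1e5)
  expect_equal(sum(wh$n_het), 2L)
  sim <- simulate_cohort(cohort_config(n_sites = 500), seed = 9)
  s <- "WILDAPO_1"
  expect_equal(sum(window_het(sim$gm, s, 1e6)$n_het),
               sum(sim$gm$geno[s, ] == 1L))
})

test_that("windowed ratio statistics recombine exactly across windows", {
  set.seed(14)
  g <- matrix(sample(0:2, 4 * 60, replace = TRUE), 4, 60,
              dimnames = list(c("a1", "a2", "b1", "b2"), NULL))
  gm <- make_gm(g, pos = sort(sample.int(2000, 60)))
  small_pi <- window_pi(gm, pm2, "A", 1000, min_sites = 1)
  big_pi <- window_pi(gm, pm2, "A", 2000, min_sites = 1)
  expect_equal(sum(small_pi$value * 1000), sum(big_pi$value * 2000),
               tolerance = 1e-12)
  # Fst: ratio of summed parts, not mean of ratios
  parts <- cwrpop:::fst_parts(gm, pm2, "A", "B")
  expect_equal(global_fst(gm, pm2, "A", "B"),
               1 - sum(parts$within) / sum(parts$between), tolerance = 1e-12)
})

test_that("uSFS bins half-open clusters and sums to one", {
  # 10 diploids: derived freqs 1.0 and exactly 0.1
  g <- cbind(rep(2L, 10), c(1L, rep(0L, 9)))
  rownames(g) <- paste0("s", 1:10)
  gm <- make_gm(g, anc = c("ref", "ref"))
  pm <- population_map(c(stats::setNames(rep("P", 10), paste0("s", 1:10)),
                         o = "OUTGROUP"))
  sp <- usfs(gm, pm, "P")
  expect_equal(sum(sp$proportion), 1)
  expect_equal(sp$count[10], 1L)  # fixed derived in final bin
  expect_equal(sp$count[1], 1L)   # 0.1 falls in bin (0, 0.1]
  # all sites fixed derived
  gmf <- make_gm(matrix(2L, 10, 4, dimnames = list(paste0("s", 1:10), NULL)),
                 anc = rep("ref", 4))
  expect_equal(usfs(gmf, pm, "P")$proportion[10], 1)
  # no qualifying sites
  gm0 <- make_gm(matrix(0L, 10, 2, dimnames = list(paste0("s", 1:10), NULL)),
                 anc = rep("ref", 2))
  expect_error(usfs(gm0, pm, "P"), "qualifying")
})

test_that("neutral uSFS follows the 1/i expectation (chi-square GOF)", {
  set.seed(101)
  i <- 1:19
  p_i <- (1 / i) / sum(1 / i)
  expected <- as.numeric(tapply(p_i, pmin(ceiling(i / 2), 10),
                                sum)[as.character(1:10)])
  pvals <- sapply(1:3, function(r) {
    cs <- coalescent_sites(20, 2500, theta = 0.3)
    cg <- coalescent_gm(cs)
    sp <- usfs(cg$gm, cg$pm, "POP")
    stat <- sum((sp$count - sum(sp$count) * expected)^2 /
                  (sum(sp$count) * expected))
    stats::pchisq(stat, df = 9, lower.tail = FALSE)
  })
  expect_gt(stats::median(pvals), 0.01)
})
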
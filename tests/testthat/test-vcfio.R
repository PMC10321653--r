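test_that("read_vcf encodes biallelic SNPs, phase and missingness", {
  p <- write_vcf_text(c(
    vcf_header(c("S1", "S2", "S3")),
    "chr1\t100\t.\tA\tT\t60\tPASS\tQD=25;MQ=55\tGT\t0/1\t1|1\t./.",
    "chr1\t200\t.\tG\tC\t60\tPASS\tQD=25;MQ=55\tGT\t0/0\t0|1\t1/1"))
  gm <- read_vcf(p)
  expect_equal(dim(gm), c(3L, 2L))
  expect_equal(unname(gm$geno[, 1]), c(1L, 2L, NA))
  expect_equal(unname(gm$geno[, 2]), c(0L, 1L, 2L))
  expect_true(gm$phased[2, 1])   # 1|1 keeps its pipe
  expect_false(gm$phased[1, 1])  # 0/1 unphased
  expect_equal(gm$hap1[2, 2], 0L)
  expect_equal(gm$hap2[2, 2], 1L)
  expect_equal(gm$qual, c(60, 60))
  expect_equal(gm$qd, c(25, 25))
})

test_that("multiallelic records and half-missing calls are excluded", {
  p <- write_vcf_text(c(
    vcf_header("S1"),
    "chr1\t100\t.\tA\tT,G\t60\tPASS\t.\tGT\t1/2"))
  expect_warning(gm <- read_vcf(p), "no biallelic")
  expect_equal(n_sites(gm), 0L)

  p2 <- write_vcf_text(c(
    vcf_header("S1"),
    "chr1\t100\t.\tA\tT\t60\tPASS\t.\tGT\t./1"))
  gm2 <- read_vcf(p2)
  expect_true(is.na(gm2$geno[1, 1]))
})

test_that("write/read round-trips a synthetic matrix", {
  set.seed(5)
  geno <- matrix(sample(c(0:2, NA), 100, replace = TRUE), 5, 20)
  gm <- make_gm(geno, samples = paste0("S", 1:5))
  path <- tempfile(fileext = ".vcf.gz")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_equal(unname(back$geno), unname(gm$geno))
  expect_equal(back$pos, gm$pos)
  expect_equal(back$ref, gm$ref)
  expect_equal(back$samples, gm$samples)
})

test_that("site filters use strict inequalities", {
  # QUAL exactly at the 40 threshold is dropped; just above is kept
  gm <- make_gm(matrix(c(0L, 1L), 2, 3), qual = c(40, 40.01, 100),
                qd = c(10, 10, 10), mq = c(50, 50, 50),
                samples = c("a", "b"))
  out <- filter_sites(gm)
  expect_equal(out$qual, c(40.01, 100))

  # exactly 20% missing is dropped (strict < 20%)
  g <- matrix(0L, 10, 2)
  g[1:2, 1] <- NA
  g[1, 2] <- NA
  out2 <- filter_sites(make_gm(g, samples = paste0("s", 1:10)))
  expect_equal(n_sites(out2), 1L)
  expect_equal(out2$pos, 2000L)
})

test_that("depth bounds blank calls and the filter is idempotent", {
  g <- matrix(1L, 4, 2)
  dp <- matrix(c(2, 50, 100, 30, 10, 10, 10, 10), 4, 2)
  gm <- make_gm(g, samples = paste0("s", 1:4), dp = dp)
  out <- filter_sites(gm, list(max_missing = 0.9))
  expect_true(is.na(out$geno[1, 1]))   # depth 2 fails "> 2"
  expect_true(is.na(out$geno[3, 1]))   # depth 100 fails "< 100"
  expect_equal(unname(out$geno[2, 1]), 1L)
  out2 <- filter_sites(out, list(max_missing = 0.9))
  expect_equal(out2$geno, out$geno)
  expect_equal(out2$pos, out$pos)

  gm_pass <- make_gm(matrix(0L, 2, 4), samples = c("x", "y"))
  expect_equal(filter_sites(gm_pass)$pos, gm_pass$pos)
  expect_error(filter_sites(gm_pass, list(qual = "high")), "numeric")
})

test_that("polarize infers ancestral alleles from fixed outgroup calls", {
  pm <- make_pm(a = "G1", b = "G1", o1 = "OUTGROUP", o2 = "OUTGROUP")
  # site 1: outgroup fixed ref; site 2: fixed alt; site 3: het outgroup;
  # site 4: outgroup fully missing
  g <- rbind(a = c(1L, 1L, 1L, 1L),
             b = c(2L, 0L, 2L, 0L),
             o1 = c(0L, 2L, 0L, NA),
             o2 = c(0L, 2L, 1L, NA))
  gm <- polarize(make_gm(g), pm)
  expect_equal(gm$anc, c("ref", "alt", "unknown", "unknown"))
  d <- derived_dosage(gm)
  expect_equal(unname(d[, 1]), c(1L, 2L, 0L, 0L))
  expect_equal(unname(d[, 2]), c(1L, 2L, 0L, 0L))  # flipped at anc=alt
  expect_true(all(is.na(d[, 3:4])))
  expect_error(polarize(make_gm(g), make_pm(a = "G1", b = "G1")),
               "outgroup")
})

test_that("polarized derived counts match a per-site recount on 100 sites", {
  set.seed(11)
  n <- 100
  g <- matrix(sample(c(0:2, NA), 6 * n, replace = TRUE, prob = c(.3, .3, .3, .1)),
              6, n)
  g[5:6, ] <- matrix(sample(c(0L, 0L, 2L, NA), 2 * n, replace = TRUE), 2, n)
  gm <- make_gm(g, samples = c(paste0("s", 1:4), "o1", "o2"))
  pm <- make_pm(s1 = "A", s2 = "A", s3 = "B", s4 = "B",
                o1 = "OUTGROUP", o2 = "OUTGROUP")
  gm <- polarize(gm, pm)
  d <- derived_dosage(gm)
  for (j in seq_len(n)) {
    og <- g[5:6, j]
    og <- og[!is.na(og)]
    if (length(og) == 0 || length(unique(og)) > 1 || any(og == 1L)) {
      expect_true(all(is.na(d[, j])))
    } else if (og[1] == 0L) {
      expect_equal(unname(d[1:4, j]), unname(g[1:4, j]))
    } else {
      expect_equal(unname(d[1:4, j]), unname(2L - g[1:4, j]))
    }
  }
  # polarize never alters genotype codes
  expect_equal(gm$geno, make_gm(g, samples = gm$samples)$geno)
})

test_that("annotation tables classify scores with an inclusive 0.05 cutoff", {
  ann <- data.frame(chrom = "chr1", pos = c(1000, 2000, 3000),
                    score = c(0.05, 0.051, 0.9))
  cls <- classify_sites(ann)
  expect_equal(cls$class, c("deleterious", "tolerated", "tolerated"))
  expect_error(classify_sites(data.frame(chrom = "c", pos = 1, score = -1)),
               "0, 1")
  lab <- data.frame(chrom = "chr1", pos = 1:2,
                    label = c("deleterious", "tolerated"))
  expect_equal(classify_sites(lab)$class, c("deleterious", "tolerated"))

  gm <- make_gm(matrix(0L, 1, 3), samples = "s")
  gm <- annotate_sites(gm, ann)
  expect_equal(gm$annotation, c("deleterious", "tolerated", "tolerated"))
})

test_that("config and map TSV readers parse their formats", {
  cfgp <- tempfile()
  writeLines(c("qd=2.0", "qual=40  # comment", "label=hudson"), cfgp)
  cfg <- read_config(cfgp)
  expect_equal(cfg$qd, 2)
  expect_equal(cfg$qual, 40)
  expect_equal(cfg$label, "hudson")

  mp <- tempfile()
  writeLines(c("s1\tCULAPO", "s2\tOUTGROUP"), mp)
  pm <- read_population_map(mp)
  expect_equal(unname(pm$assignment["s2"]), "OUTGROUP")
  expect_equal(pm$groups, "CULAPO")
})
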
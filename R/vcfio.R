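#' Read a multi-sample VCF into a genotype matrix
#'
#' Retains biallelic SNPs only (multiallelic records and indels are skipped),
#' preserves missing calls and phased pipes, and carries QUAL plus the INFO
#' fields QD and MQ and per-call DP when present. Half-missing diploid calls
#' (`./1`) are treated as missing.
#'
#' @param path path to a VCF 4.x file (optionally gzipped).
#' @param region optional `"chrom"` or `"chrom:start-end"` restriction
#'   (1-based inclusive).
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) {
    warning("VCF contains no records; returning empty matrix")
    return(empty_gm(character(0)))
  }
  keep <- !grepl(",", fix[, "ALT"]) & !is.na(fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
    keep <- keep & fix[, "CHROM"] == m[2]
    if (m[3] != "")
      keep <- keep & as.integer(fix[, "POS"]) >= as.integer(m[4]) &
        as.integer(fix[, "POS"]) <= as.integer(m[5])
  }
  samples <- colnames(v@gt)[-1]
  if (anyDuplicated(samples)) stop("duplicate sample ids in VCF")
  if (!any(keep)) {
    warning("no biallelic SNPs after reading ", path)
    return(empty_gm(samples))
  }
  v <- v[keep, ]
  fix <- v@fix
  gt <- vcfR::extract.gt(v, element = "GT")
  dm <- dim(gt)
  mz <- function(x) matrix(x, dm[1], dm[2])   # substr/as.integer drop dims
  a1 <- mz(suppressWarnings(as.integer(substr(gt, 1, 1))))
  sep <- mz(substr(gt, 2, 2))
  a2 <- mz(suppressWarnings(as.integer(substr(gt, 3, 3))))
  geno <- t(a1 + a2)                       # samples x sites; NA if any allele missing
  phased <- t(sep == "|" & !is.na(a1) & !is.na(a2))
  phased[is.na(phased)] <- FALSE
  hap1 <- t(mz(ifelse(sep == "|", a1, NA_integer_)))
  hap2 <- t(mz(ifelse(sep == "|", a2, NA_integer_)))
  # unphased homozygous calls still have a determined haplotype pair
  hom <- !phased & !is.na(geno) & geno != 1L
  hap1[hom] <- geno[hom] %/% 2L; hap2[hom] <- geno[hom] %/% 2L
  dp <- NULL
  if (any(grepl("(^|:)DP(:|$)", v@gt[, 1])))
    dp <- t(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (all(is.na(x))) rep(NA_real_, nrow(fix)) else suppressWarnings(as.numeric(x))
  }
  geno_matrix(geno, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
              ref = fix[, "REF"], alt = fix[, "ALT"], samples = samples,
              qd = info_num("QD"), qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
              mq = info_num("MQ"),
              hap1 = hap1, hap2 = hap2, phased = phased, dp = dp)
}

empty_gm <- function(samples) {
  geno_matrix(matrix(integer(0), length(samples), 0),
              chrom = character(0), pos = integer(0),
              ref = character(0), alt = character(0), samples = samples)
}

#' Write a genotype matrix to VCF
#'
#' Emits a minimal VCF 4.2 with GT (phased pipes where the call is phased and
#' heterozygous-informative), QUAL, and QD/MQ in INFO when present. Output is
#' gzip-compressed (standard for VCF tooling); [read_vcf()] round-trips it.
#'
#' @param gm a [geno_matrix()].
#' @param path output path (conventionally `*.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  nl <- n_sites(gm)
  info <- rep(".", nl)
  has_qd <- !all(is.na(gm$qd)); has_mq <- !all(is.na(gm$mq))
  if (has_qd || has_mq) {
    parts <- cbind(if (has_qd) paste0("QD=", gm$qd),
                   if (has_mq) paste0("MQ=", gm$mq))
    info <- apply(parts, 1, paste, collapse = ";")
  }
  fix <- cbind(CHROM = gm$chrom, POS = as.character(gm$pos),
               ID = rep(".", nl), REF = gm$ref, ALT = gm$alt,
               QUAL = ifelse(is.na(gm$qual), ".", as.character(gm$qual)),
               FILTER = rep("PASS", nl), INFO = info)
  code <- function(g, h1, h2, ph) {
    out <- rep("./.", length(g))
    ph[is.na(ph)] <- FALSE
    use_ph <- ph & !is.na(h1) & !is.na(h2)
    out[use_ph] <- paste0(h1[use_ph], "|", h2[use_ph])
    un <- !use_ph & !is.na(g)
    out[un] <- c("0/0", "0/1", "1/1")[g[un] + 1L]
    out
  }
  gt <- matrix("", nl, length(gm$samples) + 1L)
  colnames(gt) <- c("FORMAT", gm$samples)
  gt[, 1] <- "GT"
  for (i in seq_along(gm$samples))
    gt[, i + 1L] <- code(gm$geno[i, ], gm$hap1[i, ], gm$hap2[i, ], gm$phased[i, ])
  meta <- c("##fileformat=VCFv4.2",
            "##source=cwrpop",
            "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
            "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  v <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Site and call quality filtering
#'
#' Applies the variation-map filter: keep sites with QD > 2, QUAL > 40 and
#' MQ > 30 (strict inequalities; absent fields pass), set calls with depth
#' <= 2 or >= 100 to missing, then drop sites with 20% or more missing
#' genotypes. Site order is preserved and the filter is idempotent.
#'
#' @param gm a [geno_matrix()].
#' @param thresholds named list overriding `qd` (2), `qual` (40), `mq` (30),
#'   `min_dp` (2, exclusive), `max_dp` (100, exclusive) and `max_missing`
#'   (0.2, exclusive upper bound on the missing fraction kept).
#' @return the filtered `geno_matrix`.
#' @export
filter_sites <- function(gm, thresholds = list()) {
  th <- utils::modifyList(list(qd = 2, qual = 40, mq = 30, min_dp = 2,
                               max_dp = 100, max_missing = 0.2), thresholds)
  if (!all(vapply(th, is.numeric, TRUE))) stop("filter thresholds must be numeric")
  if (!is.null(gm$dp)) {
    bad <- !is.na(gm$dp) & (gm$dp <= th$min_dp | gm$dp >= th$max_dp)
    if (any(bad)) {
      gm$geno[bad] <- NA_integer_
      gm$hap1[bad] <- NA_integer_; gm$hap2[bad] <- NA_integer_
      gm$phased[bad] <- FALSE
    }
  }
  pass_num <- function(x, cut) is.na(x) | x > cut   # absent field passes
  keep <- pass_num(gm$qd, th$qd) & pass_num(gm$qual, th$qual) &
    pass_num(gm$mq, th$mq)
  miss <- colMeans(is.na(gm$geno))
  keep <- keep & miss < th$max_missing
  gm[, sites = which(keep)]
}

#' Polarize sites with outgroup genotypes
#'
#' Sets the ancestral allele per site to the allele for which all non-missing
#' outgroup calls are homozygous (at least one call required); sites with a
#' polymorphic (any heterozygous or discordant call) or entirely missing
#' outgroup get `anc = "unknown"`. Genotype codes are never altered; the
#' derived-allele view is available via [derived_dosage()].
#'
#' @param gm a [geno_matrix()].
#' @param pm a [population_map()] whose outgroup samples are present in `gm`.
#' @return `gm` with the `anc` field set.
#' @export
polarize <- function(gm, pm) {
  og <- group_samples(pm, pm$outgroup, gm$samples)
  if (length(og) == 0) stop("no outgroup samples available for polarization")
  sub <- gm$geno[match(og, gm$samples), , drop = FALSE]
  n <- colSums(!is.na(sub))
  all0 <- colSums(sub == 0L, na.rm = TRUE) == n
  all2 <- colSums(sub == 2L, na.rm = TRUE) == n
  anc <- rep("unknown", n_sites(gm))
  anc[n > 0 & all0] <- "ref"
  anc[n > 0 & all2] <- "alt"
  gm$anc <- anc
  gm
}

#' Classify sites from a deleteriousness annotation table
#'
#' Scores follow the usual substitution-tolerance convention: a site is
#' deleterious when its score is at most 0.05 and tolerated above 0.05;
#' tables may instead carry explicit `deleterious`/`tolerated` labels, which
#' pass through. Unannotated sites keep class `none`.
#'
#' @param gm a [geno_matrix()].
#' @param ann data frame with columns `chrom`, `pos` and either `score` or
#'   `label` (see [read_annotations()]).
#' @param cutoff deleteriousness score cutoff (default 0.05, inclusive).
#' @return `gm` with the `annotation` field set.
#' @export
annotate_sites <- function(gm, ann, cutoff = 0.05) {
  cls <- classify_sites(ann, cutoff = cutoff)
  key <- paste(gm$chrom, gm$pos)
  hit <- match(key, paste(cls$chrom, cls$pos))
  out <- rep("none", n_sites(gm))
  out[!is.na(hit)] <- cls$class[hit[!is.na(hit)]]
  gm$annotation <- out
  gm
}

#' Read an annotation TSV (chrom, pos, score-or-label)
#' @param path three-column TSV without header.
#' @return data frame with `chrom`, `pos`, and `score` or `label`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "character"))
  names(df) <- c("chrom", "pos", "value")
  num <- suppressWarnings(as.numeric(df$value))
  if (all(!is.na(num))) data.frame(chrom = df$chrom, pos = df$pos, score = num)
  else data.frame(chrom = df$chrom, pos = df$pos, label = df$value)
}

#' Read a key=value filter/config file
#' @param path plain-text file with one `key=value` per line; `#` comments.
#' @return named list with numeric values where parseable.
#' @export
read_config <- function(path) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1], collapse = "="))
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  stats::setNames(vals, trimws(vapply(kv, `[`, "", 1)))
}
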
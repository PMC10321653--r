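# Small fixture builders used across the suite.

# compact geno_matrix constructor: geno is samples x sites
make_gm <- function(geno, pos = seq_len(ncol(geno)) * 1000,
                    chrom = rep("chr1", ncol(geno)), anc = NULL, ...) {
  n <- ncol(geno)
  geno_matrix(geno, chrom = chrom, pos = pos,
              ref = rep("A", n), alt = rep("T", n), anc = anc, ...)
}

make_pm <- function(...) {
  population_map(c(...))
}

# write a small hand-crafted VCF text file; returns path
write_vcf_text <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"mq\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# default small introgression design used in recovery tests
intro_one <- function(fraction = 0.25, sample = "WILDSEX2_1",
                      donor = "CULAPO", tract_bp = 1e6) {
  data.frame(sample = sample, donor = donor, fraction = fraction,
             tract_bp = tract_bp, stringsAsFactors = FALSE)
}
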
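# Writers for tiny caller-dialect VCF fixtures, built in code at test time.

vcf_file <- function(lines, name = "fixture.vcf") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

vcf_header <- function(samples, format_defs) {
  c("##fileformat=VCFv4.2",
    format_defs,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# MuTect-style: per-sample AD = "ref,alt"
mutect_vcf_lines <- function(records, samples = c("BRAIN", "BLOOD")) {
  c(vcf_header(samples,
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depth">'),
    vapply(records, function(r) {
      paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", r$filter %||% "PASS",
            ".", "AD",
            sprintf("%d,%d", r$brain_ref, r$brain_alt),
            sprintf("%d,%d", r$blood_ref, r$blood_alt), sep = "\t")
    }, character(1)))
}

# Varscan-style: RD (ref depth) and AD (alt depth), NORMAL first
varscan_vcf_lines <- function(records) {
  c(vcf_header(c("NORMAL", "TUMOR"), c(
      '##FORMAT=<ID=RD,Number=1,Type=Integer,Description="Ref depth">',
      '##FORMAT=<ID=AD,Number=1,Type=Integer,Description="Alt depth">')),
    vapply(records, function(r) {
      paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", r$filter %||% "PASS",
            ".", "RD:AD",
            sprintf("%d:%d", r$blood_ref, r$blood_alt),
            sprintf("%d:%d", r$brain_ref, r$brain_alt), sep = "\t")
    }, character(1)))
}

# Strelka-style: per-base tier1,tier2 counts
strelka_vcf_lines <- function(records, samples = c("TUMOR", "NORMAL")) {
  base_field <- function(ref, alt, ref_n, alt_n) {
    counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    counts[ref] <- ref_n
    counts[alt] <- alt_n
    paste(sprintf("%d,%d", counts, counts + 1L), collapse = ":")
  }
  c(vcf_header(samples, c(
      '##FORMAT=<ID=AU,Number=2,Type=Integer,Description="A tier counts">',
      '##FORMAT=<ID=CU,Number=2,Type=Integer,Description="C tier counts">',
      '##FORMAT=<ID=GU,Number=2,Type=Integer,Description="G tier counts">',
      '##FORMAT=<ID=TU,Number=2,Type=Integer,Description="T tier counts">')),
    vapply(records, function(r) {
      paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", r$filter %||% "PASS",
            ".", "AU:CU:GU:TU",
            base_field(r$ref, r$alt, r$brain_ref, r$brain_alt),
            base_field(r$ref, r$alt, r$blood_ref, r$blood_alt), sep = "\t")
    }, character(1)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A canonical two-record fixture: one SNV with the validated-site counts
# and one indel that must be skipped.
two_record_mutect2 <- function() {
  list(
    list(chrom = "chr1", pos = 207461994, ref = "C", alt = "T",
         brain_ref = 997, brain_alt = 10, blood_ref = 1472, blood_alt = 0),
    list(chrom = "chr1", pos = 300, ref = "A", alt = "AT",
         brain_ref = 500, brain_alt = 9, blood_ref = 500, blood_alt = 0))
}
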
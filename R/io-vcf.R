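#' Read a single sample's variant calls from a VCF file
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) and returns one row per
#' alternate allele per site for the requested sample: multiallelic sites
#' are decomposed into biallelic records, and ref/alt strings are trimmed
#' (common suffix, then common prefix) so that the same indel is always
#' represented identically regardless of its original padding.
#'
#' Strand support for the alternate allele is taken from the per-sample
#' FORMAT fields `ADF`/`ADR` when present, otherwise from the INFO `DP4`
#' field (SAMtools dialect: alt-forward is the third entry, alt-reverse the
#' fourth). When neither is present the counts are recorded as `NA` and
#' downstream strand filtering treats the record as passing.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param sample sample identifier; must be present in the VCF header.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `genotype`
#'   (`"hom_ref"`, `"het"` or `"hom_alt"`), `qual`, `mq`, `fwd_reads`,
#'   `rev_reads` and `sample_id`. Sites with a missing genotype call for
#'   the sample are dropped.
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "denovoherd")
#' read_vcf(vcf, "PROBAND")
#' @export
read_vcf <- function(path, sample) {
  stopifnot(is.character(path), length(path) == 1L)
  .validate_vcf_lines(path)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  empty <- tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), genotype = character(), qual = double(),
    mq = double(), fwd_reads = integer(), rev_reads = integer(),
    sample_id = character()
  )
  if (nrow(vcf@fix) == 0L) {
    samples <- colnames(vcf@gt)[-1]
    if (!is.null(samples) && length(samples) && !sample %in% samples) {
      abort(paste0("sample '", sample, "' not found in VCF header"))
    }
    return(empty)
  }
  samples <- colnames(vcf@gt)[-1]
  if (!sample %in% samples) {
    abort(paste0("sample '", sample, "' not found in VCF header (has: ",
                 paste(samples, collapse = ", "), ")"))
  }
  fix <- vcf@fix
  fmt <- vcf@gt[, "FORMAT"]
  gt_raw <- vcf@gt[, sample]
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "MQ")))
  dp4 <- vcfR::extract.info(vcf, "DP4")

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    alts <- alts[!is.na(alts) & alts != "." & alts != ""]
    if (!length(alts)) next
    parts <- strsplit(gt_raw[i], ":", fixed = TRUE)[[1]]
    keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
    gt <- parts[match("GT", keys)]
    if (is.na(gt) || grepl("\\.", gt)) next
    alleles <- as.integer(strsplit(gt, "[/|]")[[1]])
    adf <- .parse_ad_field(parts, keys, "ADF")
    adr <- .parse_ad_field(parts, keys, "ADR")
    for (k in seq_along(alts)) {
      n_alt <- sum(alleles == k)
      geno <- c("hom_ref", "het", "hom_alt")[n_alt + 1L]
      if (!is.null(adf)) {
        fwd <- adf[k + 1L]; rev <- adr[k + 1L]
      } else if (!is.na(dp4[i]) && dp4[i] != ".") {
        d <- suppressWarnings(as.integer(strsplit(dp4[i], ",", fixed = TRUE)[[1]]))
        fwd <- d[3L]; rev <- d[4L]
      } else {
        fwd <- NA_integer_; rev <- NA_integer_
      }
      norm <- .trim_alleles(as.integer(fix[i, "POS"]), fix[i, "REF"], alts[k])
      rows[[i]] <- rbind(rows[[i]], data.frame(
        chrom = fix[i, "CHROM"], pos = norm$pos, ref = norm$ref,
        alt = norm$alt, genotype = geno,
        qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
        mq = mq[i], fwd_reads = fwd, rev_reads = rev,
        sample_id = sample, stringsAsFactors = FALSE
      ))
    }
  }
  out <- bind_rows(rows)
  if (!nrow(out)) return(empty)
  as_tibble(out)
}

.validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf < 8L) {
      abort(paste0("malformed VCF record at line ", i, ": expected >= 8 ",
                   "tab-separated fields, found ", nf))
    }
  }
  invisible(TRUE)
}

.parse_ad_field <- function(parts, keys, key) {
  j <- match(key, keys)
  if (is.na(j) || j > length(parts)) return(NULL)
  v <- suppressWarnings(as.integer(strsplit(parts[j], ",", fixed = TRUE)[[1]]))
  if (all(is.na(v))) NULL else v
}

# trim shared suffix then shared prefix, keeping at least one base of each
# allele; pos advances by the number of prefix bases removed
.trim_alleles <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Write a variant tibble to a single-sample VCF file
#'
#' Writes the fixed dialect read back by [read_vcf()]: one (already
#' biallelic) record per row, `MQ` in INFO, genotype plus `ADF`/`ADR`
#' strand counts in FORMAT. Reference-allele strand counts are not part of
#' the in-memory representation and are written as 0.
#'
#' @param variants tibble as returned by [read_vcf()].
#' @param path output path.
#' @param sample sample name for the header; defaults to the tibble's
#'   `sample_id`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample = NULL) {
  sample <- sample %||% (if (nrow(variants)) variants$sample_id[[1]] else "SAMPLE")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Forward-strand allelic depths\">",
    "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Reverse-strand allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  body <- character(0)
  if (nrow(variants)) {
    variants <- arrange(variants, .data$chrom, .data$pos, .data$alt)
    body <- vapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      info <- if (is.na(v$mq)) "." else paste0("MQ=", format(v$mq, trim = TRUE))
      if (is.na(v$fwd_reads) || is.na(v$rev_reads)) {
        fmt <- "GT"; smp <- gt_code[[v$genotype]]
      } else {
        fmt <- "GT:ADF:ADR"
        smp <- paste(gt_code[[v$genotype]],
                     paste0("0,", v$fwd_reads), paste0("0,", v$rev_reads),
                     sep = ":")
      }
      paste(v$chrom, v$pos, ".", v$ref, v$alt,
            if (is.na(v$qual)) "." else format(v$qual, trim = TRUE),
            "PASS", info, fmt, smp, sep = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
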
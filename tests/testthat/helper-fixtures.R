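# Shared fixtures and independent oracles, all built in code.

vcf_header <- function(samples = "PROBAND") {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"strand depths\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"fwd\">",
    "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"rev\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

write_vcf_fixture <- function(body, samples = "PROBAND") {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(vcf_header(samples), body), path)
  path
}

# a variant tibble row for building screens by hand
vrow <- function(chrom = "1", pos = 1000L, ref = "A", alt = "T",
                 genotype = "het", qual = 50, mq = 50,
                 fwd = 5L, rev = 5L, sample_id = "S") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 genotype = genotype, qual = qual, mq = mq,
                 fwd_reads = as.integer(fwd), rev_reads = as.integer(rev),
                 sample_id = sample_id)
}

ann_row <- function(v, consequence, sift = NA_character_) {
  tibble::tibble(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                 consequence = consequence, sift_class = sift)
}

# small hand-built phased panel: allele strings per individual
panel_from_strings <- function(p_haps, m_haps, chrom = "1",
                               spacing = 50000L, labels = NULL) {
  stopifnot(identical(names(p_haps), names(m_haps)))
  n_mark <- nchar(p_haps[[1]])
  map <- tibble::tibble(marker_id = sprintf("m%03d", seq_len(n_mark)),
                        chrom = chrom, pos = spacing * seq_len(n_mark))
  haps <- tibble::tibble(
    id = rep(names(p_haps), each = 2),
    hap = rep(c("P", "M"), length(p_haps)),
    alleles = as.vector(rbind(unlist(p_haps), unlist(m_haps))))
  phased_panel(map, haps, labels = labels)
}

# independent two-sided Fisher oracle: exhaustive enumeration of all
# tables with the observed margins, point probabilities via lchoose
fisher_oracle <- function(a, m, b, n) {
  K <- a + b
  k <- max(0L, K - n):min(K, m)
  logp <- lchoose(m, k) + lchoose(n, K - k) - lchoose(m + n, K)
  pr <- exp(logp)
  obs <- pr[k == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# brute-force founder contribution: sum over explicit descent paths
contribution_oracle <- function(ped, founder, id) {
  sire <- stats::setNames(ped$sire, ped$id)
  dam <- stats::setNames(ped$dam, ped$id)
  walk <- function(x, len) {
    if (identical(x, founder)) return(0.5^len)
    tot <- 0
    for (p in c(sire[[x]], dam[[x]])) {
      if (!is.na(p)) tot <- tot + walk(p, len + 1L)
    }
    tot
  }
  if (identical(id, founder)) 1 else walk(id, 0L)
}

# brute-force per-marker shared-homozygosity intersection
shared_ibd_oracle <- function(panel, individuals, min_markers = 20L,
                              max_het = 1L, require_same_allele = FALSE) {
  runs <- dplyr::bind_rows(lapply(individuals, function(id) {
    detect_roh(panel, id, min_markers = min_markers,
               max_het_markers = max_het)
  }))
  out <- list()
  for (ch in unique(panel$map$chrom)) {
    cols <- which(panel$map$chrom == ch)
    shared <- rep(TRUE, length(cols))
    for (j in seq_along(cols)) {
      allele_seen <- character(0)
      for (id in individuals) {
        r <- runs[runs$individual == id & runs$chrom == ch &
                  runs$start_marker <= j & runs$end_marker >= j, ]
        if (!nrow(r)) { shared[j] <- FALSE; break }
        a <- panel$hap[paste0(id, "|P"), cols[j]]
        b <- panel$hap[paste0(id, "|M"), cols[j]]
        if (a == b) allele_seen <- c(allele_seen, a)
      }
      if (shared[j] && require_same_allele &&
          length(unique(allele_seen)) > 1L) {
        shared[j] <- FALSE
      }
    }
    r <- rle(shared)
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
    for (seg in which(r$values)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch, start_marker = lo[seg], end_marker = hi[seg])
    }
  }
  dplyr::bind_rows(out)
}
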
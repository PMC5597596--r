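#' Detect runs of homozygosity for one individual
#'
#' Finds, per chromosome, the maximal stretches of consecutive markers at
#' which the individual's two haplotypes carry the same allele, tolerating
#' up to `max_het_markers` heterozygous markers inside a run (a
#' genotyping-error allowance). Runs are trimmed so that they start and
#' end on homozygous markers, and only runs of at least `min_markers`
#' markers are reported.
#'
#' @param panel a [phased_panel()].
#' @param individual individual id.
#' @param min_markers minimum run length in markers (default 20).
#' @param max_het_markers heterozygous markers tolerated per run
#'   (default 1).
#' @return Tibble of runs: `individual`, `chrom`, `start_marker`,
#'   `end_marker` (indices within the chromosome), `start_bp`, `end_bp`,
#'   `marker_count`, `n_het`, `allele` (the run's allele string, taken
#'   from the paternal haplotype; at tolerated heterozygous markers the
#'   two haplotypes differ).
#' @export
detect_roh <- function(panel, individual, min_markers = 20L,
                       max_het_markers = 1L) {
  if (!individual %in% .panel_ids(panel)) {
    abort(paste0("individual '", individual, "' not in panel"))
  }
  out <- list()
  for (ch in unique(panel$map$chrom)) {
    cols <- which(panel$map$chrom == ch)
    hp <- panel$hap[paste0(individual, "|P"), cols]
    hm <- panel$hap[paste0(individual, "|M"), cols]
    het <- hp != hm
    runs <- .max_runs_with_k_mismatches(het, max_het_markers)
    pos <- panel$map$pos[cols]
    for (r in runs) {
      lo <- r[1]; hi <- r[2]
      while (lo <= hi && het[lo]) lo <- lo + 1L
      while (hi >= lo && het[hi]) hi <- hi - 1L
      if (hi - lo + 1L < min_markers) next
      out[[length(out) + 1L]] <- tibble(
        individual = individual, chrom = ch,
        start_marker = lo, end_marker = hi,
        start_bp = pos[lo], end_bp = pos[hi],
        marker_count = hi - lo + 1L,
        n_het = sum(het[lo:hi]),
        allele = paste(hp[lo:hi], collapse = ""))
    }
  }
  if (!length(out)) {
    return(tibble(individual = character(), chrom = character(),
                  start_marker = integer(), end_marker = integer(),
                  start_bp = integer(), end_bp = integer(),
                  marker_count = integer(), n_het = integer(),
                  allele = character()))
  }
  distinct(bind_rows(out))
}

# all maximal intervals [l, r] containing at most k TRUE entries,
# by the two-pointer sweep; returns list of c(l, r)
.max_runs_with_k_mismatches <- function(mismatch, k) {
  n <- length(mismatch)
  if (!n) return(list())
  res <- list()
  r <- 0L; bad <- 0L; prev_r <- 0L
  for (l in seq_len(n)) {
    if (r < l - 1L) { r <- l - 1L; bad <- 0L }
    while (r < n && bad + mismatch[r + 1L] <= k) {
      r <- r + 1L; bad <- bad + mismatch[r]
    }
    if (r > prev_r) {
      res[[length(res) + 1L]] <- c(l, r)
      prev_r <- r
    }
    bad <- bad - mismatch[l]
  }
  res
}

#' Intersect runs of homozygosity across affected individuals
#'
#' Computes the genomic intervals where every individual (or at least a
#' fraction `min_fraction` of them) lies inside one of its runs of
#' homozygosity — the candidate shared identity-by-descent segments of a
#' recessive defect. With `require_same_allele`, markers at which two
#' homozygous individuals carry different alleles additionally break the
#' segment, demanding a single shared haplotype.
#'
#' @param runs tibble of runs from [detect_roh()], covering at least two
#'   individuals.
#' @param panel the [phased_panel()] the runs were computed from.
#' @param require_same_allele demand an identical homozygous allele
#'   string across individuals over the segment.
#' @param min_fraction minimum fraction of individuals whose runs must
#'   cover a marker (default 1 = all).
#' @param min_markers minimum reported segment length in markers.
#' @param individuals the individuals the intersection is over; defaults
#'   to those appearing in `runs`, but must be given explicitly when an
#'   individual might contribute no run at all (it then breaks every
#'   full-sharing segment, which the default could not see).
#' @return Tibble of shared segments: `chrom`, `start_marker`,
#'   `end_marker`, `start_bp`, `end_bp`, `marker_count`, `n_individuals`.
#' @export
shared_ibd_segment <- function(runs, panel, require_same_allele = FALSE,
                               min_fraction = 1, min_markers = 1L,
                               individuals = NULL) {
  inds <- individuals %||% unique(runs$individual)
  if (length(inds) < 2L) abort("need runs from at least two individuals")
  extra <- setdiff(unique(runs$individual), inds)
  if (length(extra)) {
    abort(paste0("runs include individual(s) outside `individuals`: ",
                 paste(extra, collapse = ", ")))
  }
  out <- list()
  for (ch in unique(panel$map$chrom)) {
    cols <- which(panel$map$chrom == ch)
    m <- length(cols)
    cov <- matrix(FALSE, length(inds), m)
    rch <- runs[runs$chrom == ch, ]
    for (i in seq_len(nrow(rch))) {
      cov[match(rch$individual[i], inds),
          rch$start_marker[i]:rch$end_marker[i]] <- TRUE
    }
    shared <- colMeans(cov) >= min_fraction
    if (require_same_allele && any(shared)) {
      H <- panel$hap[, cols, drop = FALSE]
      for (j in which(shared)) {
        alleles <- character(0)
        for (i in seq_along(inds)) {
          if (!cov[i, j]) next
          a <- H[paste0(inds[i], "|P"), j]
          b <- H[paste0(inds[i], "|M"), j]
          if (a == b) alleles <- c(alleles, a)  # tolerated het sites skipped
        }
        if (length(unique(alleles)) > 1L) shared[j] <- FALSE
      }
    }
    if (!any(shared)) next
    r <- rle(shared)
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
    pos <- panel$map$pos[cols]
    for (seg in which(r$values)) {
      if (r$lengths[seg] < min_markers) next
      out[[length(out) + 1L]] <- tibble(
        chrom = ch, start_marker = lo[seg], end_marker = hi[seg],
        start_bp = pos[lo[seg]], end_bp = pos[hi[seg]],
        marker_count = hi[seg] - lo[seg] + 1L,
        n_individuals = length(inds))
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start_marker = integer(),
                  end_marker = integer(), start_bp = integer(),
                  end_bp = integer(), marker_count = integer(),
                  n_individuals = integer()))
  }
  bind_rows(out)
}
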
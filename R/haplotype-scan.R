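#' Two-sided Fisher's exact test on a 2x2 carrier table
#'
#' Exact two-sided p-value for the table
#' `[[a, n_case - a], [b, n_control - b]]`, computed by summing the
#' hypergeometric point probabilities that do not exceed the observed
#' table's probability (the standard two-sided rule, with the usual
#' `1 + 1e-7` relative tolerance for ties). Vectorised over `a` and `b`.
#'
#' @param count_case_carrier carriers among cases (`a`).
#' @param n_case number of cases (> 0).
#' @param count_control_carrier carriers among controls (`b`).
#' @param n_control number of controls (> 0).
#' @return Two-sided exact p-value(s) in (0, 1].
#' @examples
#' fisher_window_test(12, 49, 2, 89)  # the 24.5% vs 2.2% carrier table
#' @export
fisher_window_test <- function(count_case_carrier, n_case,
                               count_control_carrier, n_control) {
  if (n_case <= 0 || n_control <= 0) abort("group sizes must be positive")
  a <- as.integer(count_case_carrier)
  b <- as.integer(count_control_carrier)
  if (any(a < 0 | a > n_case | b < 0 | b > n_control)) {
    abort("carrier counts must lie within their group sizes")
  }
  P <- .fisher_p_table(as.integer(n_case), as.integer(n_control))
  unname(P[cbind(a + 1L, b + 1L)])
}

# lookup table P[a+1, b+1] of two-sided Fisher p for fixed group sizes,
# memoised package-wide (the permutation scans index it millions of times)
.fisher_p_table <- function(m, n) {
  key <- paste(m, n, sep = ":")
  hit <- .denovoherd_cache[[key]]
  if (!is.null(hit)) return(hit)
  P <- matrix(NA_real_, m + 1L, n + 1L)
  for (K in 0:(m + n)) {
    k <- max(0L, K - n):min(K, m)
    pr <- dhyper(k, m, n, K)
    pv <- vapply(pr, function(p0) sum(pr[pr <= p0 * (1 + 1e-7)]), 0.0)
    P[cbind(k + 1L, K - k + 1L)] <- pmin(pv, 1)
  }
  .denovoherd_cache[[key]] <- P
  P
}

#' Map a dominant mutation by exhaustive shared-haplotype search
#'
#' Scans sliding windows for a haplotype allele carried by 100% of the
#' case haplotypes and rare (frequency at most `max_control_freq`) among
#' control haplotypes, then merges runs of consecutive qualifying windows
#' into candidate intervals. Each case contributes exactly one haplotype —
#' the one assumed to carry the causative mutation — and each control the
#' haplotype assumed to carry the wild-type allele.
#'
#' @param panel a [phased_panel()] with `case`/`control` labels (or the
#'   labels named in `case_label`/`control_label`).
#' @param window_size,step sliding-window geometry (defaults 10 and 1).
#' @param case_label,control_label phenotype labels defining the groups.
#' @param case_hap,control_hap which haplotype each individual
#'   contributes: a single `"P"`/`"M"`, or a vector named by individual id.
#' @param max_control_freq maximum frequency of the case-shared allele
#'   among control haplotypes (default 0.05).
#' @param chroms chromosomes to scan (default: all in the map).
#' @return Tibble of candidate intervals: `chrom`, `start_marker`,
#'   `end_marker` (indices within the chromosome), `start_bp`, `end_bp`,
#'   `n_windows`. Zero rows when no window qualifies.
#' @export
dominant_scan <- function(panel, window_size = 10L, step = 1L,
                          case_label = "case", control_label = "control",
                          case_hap = "P", control_hap = "P",
                          max_control_freq = 0.05, chroms = NULL) {
  lab <- panel$individuals
  cases <- lab$id[lab$label == case_label]
  controls <- lab$id[lab$label == control_label]
  if (!length(cases)) abort(paste0("no individuals labelled '", case_label, "'"))
  if (!length(controls)) abort(paste0("no individuals labelled '", control_label, "'"))
  hap_of <- function(ids, which_hap) {
    w <- if (length(which_hap) == 1L) setNames(rep(which_hap, length(ids)), ids)
         else which_hap[ids]
    paste(ids, w, sep = "|")
  }
  case_rows <- hap_of(cases, case_hap)
  control_rows <- hap_of(controls, control_hap)
  chroms <- chroms %||% unique(panel$map$chrom)
  out <- list()
  for (ch in chroms) {
    cols <- which(panel$map$chrom == ch)
    if (length(cols) < window_size) next
    cm <- panel$hap[case_rows, cols, drop = FALSE]
    km <- panel$hap[control_rows, cols, drop = FALSE]
    pos <- panel$map$pos[cols]
    starts <- .window_starts(length(cols), window_size, step)
    qual <- logical(length(starts))
    for (wi in seq_along(starts)) {
      idx <- starts[wi]:(starts[wi] + window_size - 1L)
      cs <- do.call(paste0, lapply(idx, function(j) cm[, j]))
      if (length(unique(cs)) != 1L) next
      ks <- do.call(paste0, lapply(idx, function(j) km[, j]))
      qual[wi] <- mean(ks == cs[[1]]) <= max_control_freq
    }
    if (!any(qual)) next
    r <- rle(qual)
    ends_at <- cumsum(r$lengths)
    begins <- ends_at - r$lengths + 1L
    for (seg in which(r$values)) {
      w0 <- begins[seg]; w1 <- ends_at[seg]
      sm <- starts[w0]; em <- starts[w1] + window_size - 1L
      out[[length(out) + 1L]] <- tibble(
        chrom = ch, start_marker = sm, end_marker = em,
        start_bp = pos[sm], end_bp = pos[em], n_windows = w1 - w0 + 1L)
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start_marker = integer(),
                  end_marker = integer(), start_bp = integer(),
                  end_bp = integer(), n_windows = integer()))
  }
  bind_rows(out)
}

#' Sliding-window haplotype association scan for modifier loci
#'
#' Compares carrier frequencies of every window haplotype between two
#' phenotype groups (by default mildly affected versus unaffected
#' half-sibs) with a two-sided Fisher exact test. Carrier coding (at
#' least one copy) is the default; `dosage = TRUE` tests allele counts
#' instead. On chromosomes named in `maternal_only_chroms` — typically
#' the chromosome carrying the causal mutation itself, where the shared
#' paternal haplotype would swamp the signal — carrier status is computed
#' from maternal haplotypes only. The per-window statistic is the minimum
#' Fisher p across that window's alleles after a minimum-carrier filter.
#'
#' @param panel a labelled [phased_panel()].
#' @param window_size,step sliding-window geometry (defaults 10 and 1).
#' @param case_label,control_label phenotype labels of the two groups.
#' @param maternal_only_chroms chromosomes restricted to maternal
#'   haplotypes.
#' @param min_carriers minimum total carriers (both groups) for an allele
#'   to be tested (default 3).
#' @param dosage test allele dosage instead of carrier status.
#' @param chroms chromosomes to scan (default: all).
#' @return A tibble of class `window_scan`, one row per (window, allele):
#'   group carrier counts and sizes, `fisher_p`, the per-window `window_p`
#'   (minimum over its alleles), and unset empirical p columns to be
#'   filled by [permutation_empirical_p()].
#' @examples
#' sim <- simulate_halfsib_panel(seed = 1)
#' scan <- modifier_scan(sim$panel,
#'                       maternal_only_chroms = sim$truth$causal_chrom)
#' glance(scan)
#' @export
modifier_scan <- function(panel, window_size = 10L, step = 1L,
                          case_label = "mildly_affected",
                          control_label = "unaffected",
                          maternal_only_chroms = character(),
                          min_carriers = 3L, dosage = FALSE, chroms = NULL) {
  lab <- panel$individuals
  cases <- lab$id[lab$label == case_label]
  controls <- lab$id[lab$label == control_label]
  if (!length(cases) || !length(controls)) {
    abort("both phenotype groups must be non-empty")
  }
  ids <- c(cases, controls)
  is_case <- c(rep(TRUE, length(cases)), rep(FALSE, length(controls)))
  chroms <- chroms %||% unique(panel$map$chrom)
  index <- list()
  rows <- list()
  for (ch in chroms) {
    hap_use <- if (ch %in% maternal_only_chroms) "maternal" else "both"
    ix <- .window_index(panel, ch, ids, window_size, step, hap_use)
    X <- if (dosage) ix$D else ix$C
    copies <- if (dosage && hap_use == "both") 2L else 1L
    m <- length(cases) * copies
    n <- length(controls) * copies
    a <- as.integer(X[, is_case, drop = FALSE] %*% rep(1L, sum(is_case)))
    b <- as.integer(X[, !is_case, drop = FALSE] %*% rep(1L, sum(!is_case)))
    keep <- (a + b) >= min_carriers
    if (!any(keep)) next
    p <- fisher_window_test(a[keep], m, b[keep], n)
    tb <- ix$windows[ix$col_window[keep], ]
    tb$chrom <- ch
    tb$allele <- ix$col_allele[keep]
    tb$count_case_carrier <- a[keep]
    tb$n_case <- m
    tb$count_control_carrier <- b[keep]
    tb$n_control <- n
    tb$fisher_p <- p
    tb <- tb %>% group_by(.data$window) %>%
      mutate(window_p = min(.data$fisher_p)) %>% ungroup()
    rows[[ch]] <- tb
    index[[ch]] <- list(X = X[keep, , drop = FALSE], m = m, n = n,
                        copies = copies, hap_use = hap_use)
  }
  out <- bind_rows(rows) %>%
    select("chrom", "window", "start_marker", "end_marker", "start_bp",
           "end_bp", "allele", "count_case_carrier", "n_case",
           "count_control_carrier", "n_control", "fisher_p", "window_p") %>%
    mutate(empirical_p_chromwide = NA_real_, empirical_p_genomewide = NA_real_)
  structure(out,
            index = index, is_case = is_case, ids = ids,
            params = list(window_size = window_size, step = step,
                          min_carriers = min_carriers, dosage = dosage,
                          case_label = case_label,
                          control_label = control_label,
                          maternal_only_chroms = maternal_only_chroms),
            class = c("window_scan", class(out)))
}

#' Permutation empirical p-values for a window scan
#'
#' Reassigns the case/control labels uniformly at random (preserving
#' group sizes), recomputes the scan's minimum Fisher p within each scope
#' — per chromosome and genome-wide — for every permutation, and converts
#' each window's observed p into an empirical p with the add-one rule
#' `(1 + #[permutation minima <= observed]) / (n_perm + 1)`. Ties count as
#' smaller-or-equal (conservative). Fully reproducible given `seed`.
#'
#' @param scan a `window_scan` from [modifier_scan()].
#' @param n_perm number of permutations (default 10,000).
#' @param seed RNG seed.
#' @param scope `"both"` (default), `"chromosome"` or `"genome"`.
#' @param permute_within optional factor (named by individual id) whose
#'   levels constrain the permutation: labels are shuffled within each
#'   stratum, preserving family structure.
#' @param block permutations processed per matrix block (memory knob).
#' @return The scan with `empirical_p_chromwide` and/or
#'   `empirical_p_genomewide` filled.
#' @export
permutation_empirical_p <- function(scan, n_perm = 10000L, seed = NULL,
                                    scope = c("both", "chromosome", "genome"),
                                    permute_within = NULL, block = 2000L) {
  stopifnot(inherits(scan, "window_scan"), n_perm >= 1L)
  scope <- match.arg(scope)
  if (!is.null(seed)) set.seed(seed)
  index <- attr(scan, "index")
  is_case <- attr(scan, "is_case")
  ids <- attr(scan, "ids")
  N <- length(is_case)
  strata <- if (is.null(permute_within)) rep(1L, N)
            else as.integer(factor(permute_within[ids]))
  chrom_min <- matrix(Inf, n_perm, length(index),
                      dimnames = list(NULL, names(index)))
  done <- 0L
  while (done < n_perm) {
    B <- min(block, n_perm - done)
    Z <- matrix(0, N, B)
    for (j in seq_len(B)) {
      # shuffle labels within strata (one stratum = free permutation);
      # individual perm[i] receives the label of individual i
      perm <- unlist(lapply(split(seq_len(N), strata),
                            function(s) if (length(s) > 1L) sample(s) else s),
                     use.names = FALSE)
      ord <- unlist(split(seq_len(N), strata), use.names = FALSE)
      Z[perm, j] <- as.numeric(is_case[ord])
    }
    for (ch in names(index)) {
      ix <- index[[ch]]
      A <- ix$X %*% Z                      # alleles x B case-carrier counts
      tot <- as.vector(ix$X %*% rep(1, N))
      Bm <- tot - A
      P <- .fisher_p_table(ix$m, ix$n)
      pmat <- matrix(P[cbind(as.vector(A) + 1, as.vector(Bm) + 1)],
                     nrow(A), B)
      chrom_min[done + seq_len(B), ch] <- apply(pmat, 2, min)
    }
    done <- done + B
  }
  genome_min <- apply(chrom_min, 1, min)
  tol <- 1 + 1e-9
  if (scope %in% c("both", "chromosome")) {
    scan$empirical_p_chromwide <- map_dbl(seq_len(nrow(scan)), function(i) {
      (1 + sum(chrom_min[, scan$chrom[i]] <= scan$fisher_p[i] * tol)) /
        (n_perm + 1)
    })
  }
  if (scope %in% c("both", "genome")) {
    scan$empirical_p_genomewide <- vapply(scan$fisher_p, function(p) {
      (1 + sum(genome_min <= p * tol)) / (n_perm + 1)
    }, 0.0)
  }
  attr(scan, "n_perm") <- n_perm
  attr(scan, "seed") <- seed
  scan
}

#' Search a panel for carriers of an ancestral haplotype
#'
#' Matches a target haplotype allele string, defined over a span of
#' consecutive markers, against both haplotypes of every individual.
#' Individuals carrying the haplotype but not the causative mutation are
#' ancestral-haplotype carriers: their existence shows the disease
#' haplotype predates the mutation and supports its de novo origin.
#'
#' @param panel a [phased_panel()].
#' @param chrom chromosome of the span.
#' @param start_marker,end_marker 1-based marker indices within the
#'   chromosome delimiting the span (inclusive).
#' @param target_haplotype allele string of length
#'   `end_marker - start_marker + 1`.
#' @param mutation_carriers optional character vector of ids known to
#'   carry the causative mutation; matching individuals not in it are
#'   flagged `ancestral`.
#' @param reference optional full-length chromosome haplotype string used
#'   to measure how far each match extends identically beyond the span;
#'   when `NULL` the extension equals the span itself.
#' @return Tibble with one row per matching haplotype: `id`, `hap`,
#'   `ext_start_marker`, `ext_end_marker`, `ext_markers`, `ext_bp`,
#'   `mutation_carrier`, `ancestral`.
#' @export
ancestral_carrier_search <- function(panel, chrom, start_marker, end_marker,
                                     target_haplotype,
                                     mutation_carriers = NULL,
                                     reference = NULL) {
  cols <- which(panel$map$chrom == chrom)
  if (!length(cols)) abort(paste0("no markers on chromosome ", chrom))
  m <- length(cols)
  if (start_marker < 1L || end_marker > m || start_marker > end_marker) {
    abort("span outside the chromosome's marker map")
  }
  target <- strsplit(target_haplotype, "", fixed = TRUE)[[1]]
  if (length(target) != end_marker - start_marker + 1L) {
    abort("target haplotype length does not match the span")
  }
  H <- panel$hap[, cols, drop = FALSE]
  span <- start_marker:end_marker
  hit <- which(apply(H[, span, drop = FALSE], 1,
                     function(x) all(x == target)))
  if (!length(hit)) {
    return(tibble(id = character(), hap = character(),
                  ext_start_marker = integer(), ext_end_marker = integer(),
                  ext_markers = integer(), ext_bp = integer(),
                  mutation_carrier = logical(), ancestral = logical()))
  }
  ref <- if (!is.null(reference)) strsplit(reference, "", fixed = TRUE)[[1]]
  if (!is.null(ref) && length(ref) != m) {
    abort("reference haplotype length does not match the chromosome")
  }
  pos <- panel$map$pos[cols]
  rows <- map(hit, function(r) {
    lo <- start_marker; hi <- end_marker
    if (!is.null(ref)) {
      while (lo > 1L && H[r, lo - 1L] == ref[lo - 1L]) lo <- lo - 1L
      while (hi < m && H[r, hi + 1L] == ref[hi + 1L]) hi <- hi + 1L
    }
    rn <- rownames(H)[r]
    id <- sub("\\|[PM]$", "", rn)
    carrier <- if (is.null(mutation_carriers)) NA else id %in% mutation_carriers
    tibble(id = id, hap = sub("^.*\\|", "", rn),
           ext_start_marker = lo, ext_end_marker = hi,
           ext_markers = hi - lo + 1L, ext_bp = pos[hi] - pos[lo] + 1L,
           mutation_carrier = carrier,
           ancestral = if (is.na(carrier)) NA else !carrier)
  })
  bind_rows(rows)
}

#' @export
print.window_scan <- function(x, ...) {
  p <- attr(x, "params")
  cat("<window_scan> ", nrow(x), " window-allele tests, window_size = ",
      p$window_size, ", min_carriers = ", p$min_carriers, "\n", sep = "")
  NextMethod()
}

#' @rdname modifier_scan
#' @param x,object a `window_scan`.
#' @param ... unused.
#' @method tidy window_scan
#' @export
tidy.window_scan <- function(x, ...) {
  out <- x
  attributes(out)[c("index", "is_case", "ids", "params")] <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @rdname modifier_scan
#' @method glance window_scan
#' @export
glance.window_scan <- function(x, ...) {
  best <- x[which.min(x$fisher_p), ]
  tibble(n_tests = nrow(x), n_windows = n_distinct(x[c("chrom", "window")]),
         min_fisher_p = best$fisher_p, best_chrom = best$chrom,
         best_window = best$window,
         best_empirical_p_chromwide = best$empirical_p_chromwide,
         best_empirical_p_genomewide = best$empirical_p_genomewide,
         n_perm = attr(x, "n_perm") %||% NA_integer_)
}

#' @rdname modifier_scan
#' @method autoplot window_scan
#' @export
autoplot.window_scan <- function(object, ...) {
  df <- tidy(object) %>%
    group_by(.data$chrom, .data$window) %>%
    summarise(mid_bp = (first(.data$start_bp) + first(.data$end_bp)) / 2,
              window_p = first(.data$window_p), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_bp / 1e6,
                                   y = -log10(.data$window_p))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)),
                  title = "sliding-window haplotype association") +
    ggplot2::theme_minimal()
}
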
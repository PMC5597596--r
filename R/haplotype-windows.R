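# Internal window/haplotype indexing shared by the scans.
#
# For one chromosome, builds every sliding window of `window_size`
# consecutive markers (step `step`, trimmed at the chromosome end), the
# distinct haplotype allele strings observed in each window, and
# per-individual dosage/carrier matrices over those window-alleles.

.panel_ids <- function(panel) panel$individuals$id

.chrom_hap_matrix <- function(panel, chrom, ids, hap_use = c("both", "maternal", "paternal")) {
  hap_use <- match.arg(hap_use)
  cols <- which(panel$map$chrom == chrom)
  if (!length(cols)) abort(paste0("no markers on chromosome ", chrom))
  suffix <- switch(hap_use, both = c("P", "M"), maternal = "M", paternal = "P")
  rows <- as.vector(t(outer(ids, suffix, paste, sep = "|")))
  list(mat = panel$hap[rows, cols, drop = FALSE],
       ind = rep(seq_along(ids), each = length(suffix)),
       cols = cols)
}

.window_starts <- function(m, window_size, step) {
  if (m < window_size) return(integer(0))
  seq.int(1L, m - window_size + 1L, by = step)
}

# returns list(windows = tibble, col_window, col_allele, C = carrier, D = dosage)
.window_index <- function(panel, chrom, ids, window_size = 10L, step = 1L,
                          hap_use = "both") {
  stopifnot(window_size >= 1L, step >= 1L)
  h <- .chrom_hap_matrix(panel, chrom, ids, hap_use)
  m <- ncol(h$mat)
  starts <- .window_starts(m, window_size, step)
  pos <- panel$map$pos[h$cols]
  windows <- tibble(
    window = seq_along(starts),
    start_marker = starts, end_marker = starts + window_size - 1L,
    start_bp = pos[starts], end_bp = pos[starts + window_size - 1L]
  )
  col_window <- integer(0); col_allele <- character(0)
  D_list <- vector("list", length(starts))
  for (wi in seq_along(starts)) {
    idx <- starts[wi]:(starts[wi] + window_size - 1L)
    strs <- do.call(paste0, lapply(idx, function(j) h$mat[, j]))
    f <- factor(strs)
    D <- t(unclass(table(factor(h$ind, levels = seq_along(ids)), f)))
    # rows = alleles, cols = individuals
    D_list[[wi]] <- D
    col_window <- c(col_window, rep(wi, nlevels(f)))
    col_allele <- c(col_allele, levels(f))
  }
  D <- do.call(rbind, D_list)           # (total alleles) x individuals
  storage.mode(D) <- "integer"
  colnames(D) <- ids
  list(chrom = chrom, windows = windows, col_window = col_window,
       col_allele = col_allele, D = D, C = D > 0L, ids = ids,
       hap_use = hap_use)
}

#' Enumerate sliding-window haplotypes on a chromosome
#'
#' Forms haplotypes from windows of `window_size` consecutive markers
#' sliding along the chromosome (default 10 markers, moving one marker at
#' a time), and tabulates every distinct allele string observed in the
#' panel together with per-individual carrier status and dosage.
#'
#' @param panel a [phased_panel()].
#' @param chrom chromosome to scan.
#' @param window_size number of consecutive markers per window.
#' @param step marker offset between consecutive windows.
#' @param hap_use which haplotypes contribute: `"both"`, `"maternal"` or
#'   `"paternal"`.
#' @return A tibble with one row per (window, allele): `window`,
#'   `start_marker`, `end_marker`, `start_bp`, `end_bp`, `allele`,
#'   `n_carrier`, and a list-column `dosage` holding a named 0/1/2 vector
#'   over individuals.
#' @export
enumerate_window_haplotypes <- function(panel, chrom, window_size = 10L,
                                        step = 1L, hap_use = "both") {
  ids <- .panel_ids(panel)
  ix <- .window_index(panel, chrom, ids, window_size, step, hap_use)
  out <- ix$windows[ix$col_window, ]
  out$allele <- ix$col_allele
  out$n_carrier <- as.integer(rowSums(ix$C))
  out$dosage <- lapply(seq_len(nrow(ix$D)), function(i) {
    setNames(as.integer(ix$D[i, ]), ids)
  })
  as_tibble(out)
}
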
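#' Configuration for the de novo discovery filter cascade
#'
#' Thresholds of the whole-genome screen for dominant de novo deleterious
#' mutations: variant and mapping quality cut-offs, the consequence classes
#' regarded as deleterious to protein function, and the private-variant
#' density rule used when screening healthy AI sires (a candidate sitting
#' on a rare ancestral haplotype is betrayed by an excess of co-located
#' private variants).
#'
#' @param qual_min minimum Phred-scaled variant quality (default 30).
#' @param mq_min minimum mapping quality (default 30).
#' @param relaxed_qual_min variant-quality threshold used in relaxed mode,
#'   for low-coverage genomes (default 15).
#' @param deleterious_classes consequence classes retained as deleterious.
#'   `"missense_deleterious"` means a missense call whose `sift_class`
#'   annotation is `"deleterious"`; tolerated missense is dropped.
#' @param density_window_bp half-width of the interval scanned around each
#'   candidate for co-located private variants (default 2,500,000 bp,
#'   i.e. +/- 2.5 Mb, boundary inclusive).
#' @param density_max_private maximum number of private variants in that
#'   interval (candidate included) for the candidate to be classified as a
#'   likely recent mutation (default 10).
#' @param autosomes_only drop records on `X`, `Y` and `MT` (default TRUE).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(qual_min = 30, mq_min = 30, relaxed_qual_min = 15,
                          deleterious_classes = c(
                            "frameshift", "inframe_insertion",
                            "inframe_deletion", "stop_gained", "stop_lost",
                            "splice_donor", "splice_acceptor",
                            "missense_deleterious"),
                          density_window_bp = 2500000L,
                          density_max_private = 10L,
                          autosomes_only = TRUE) {
  stopifnot(qual_min >= 0, mq_min >= 0, relaxed_qual_min >= 0,
            density_window_bp >= 0, density_max_private >= 0,
            length(deleterious_classes) > 0)
  structure(list(qual_min = qual_min, mq_min = mq_min,
                 relaxed_qual_min = relaxed_qual_min,
                 deleterious_classes = deleterious_classes,
                 density_window_bp = as.integer(density_window_bp),
                 density_max_private = as.integer(density_max_private),
                 autosomes_only = autosomes_only),
            class = "filter_config")
}

#' Quality filter
#'
#' Retains records with `qual >= qual_min` and `mq >= mq_min` (boundary
#' inclusive). In relaxed mode the quality threshold drops to
#' `relaxed_qual_min`, the setting used for low-coverage genomes.
#'
#' @param variants variant tibble (see [read_vcf()]).
#' @param config a [filter_config()].
#' @param relaxed use the relaxed quality threshold.
#' @return Filtered variant tibble.
#' @export
filter_quality <- function(variants, config = filter_config(), relaxed = FALSE) {
  qmin <- if (relaxed) config$relaxed_qual_min else config$qual_min
  filter(variants, .data$qual >= qmin, .data$mq >= config$mq_min)
}

#' Retain heterozygous variants absent from the control panel
#'
#' The dominant de novo model: the causative mutation is carried
#' heterozygously by the affected animal and is private, i.e. absent from
#' every control genome in the panel.
#'
#' @inheritParams filter_quality
#' @param panel a [control_panel()].
#' @return Filtered variant tibble.
#' @export
select_het_private <- function(variants, panel) {
  variants[variants$genotype == "het" & !in_control_panel(panel, variants), ]
}

#' Remove variants supported by a single read on each strand
#'
#' Calls with exactly one forward and one reverse supporting read are the
#' signature of a sequencing error read twice on a short fragment and are
#' removed. Records with unknown strand counts pass through.
#'
#' @inheritParams filter_quality
#' @return Filtered variant tibble.
#' @export
strand_filter <- function(variants) {
  drop <- !is.na(variants$fwd_reads) & !is.na(variants$rev_reads) &
    variants$fwd_reads == 1L & variants$rev_reads == 1L
  variants[!drop, ]
}

#' Retain variants with a deleterious predicted consequence
#'
#' Joins the annotation table on (`chrom`, `pos`, `ref`, `alt`) and keeps
#' frameshifts, in-frame indels, stop gain/loss, splice donor/acceptor
#' variants and missense calls flagged deleterious. Unannotated records
#' are treated as non-coding; unknown consequence strings raise a warning
#' and are not retained.
#'
#' @inheritParams filter_quality
#' @param annotations annotation tibble (see [read_annotations()]).
#' @return Filtered variant tibble with a `consequence` column attached.
#' @export
consequence_filter <- function(variants, annotations, config = filter_config()) {
  known <- c("frameshift", "inframe_insertion", "inframe_deletion",
             "stop_gained", "stop_lost", "splice_donor", "splice_acceptor",
             "missense", "synonymous", "intergenic", "intron", "utr",
             "non_coding", "upstream", "downstream")
  ann <- annotations %>%
    mutate(effective_class = ifelse(
      .data$consequence == "missense",
      paste0("missense_", ifelse(is.na(.data$sift_class), "unknown", .data$sift_class)),
      .data$consequence)) %>%
    select("chrom", "pos", "ref", "alt", "consequence", "effective_class")
  joined <- left_join(variants, ann, by = c("chrom", "pos", "ref", "alt"))
  unknown <- setdiff(unique(joined$consequence),
                     c(known, NA_character_))
  if (length(unknown)) {
    warn(paste0("unknown consequence class(es) treated as non-retained: ",
                paste(unknown, collapse = ", ")))
  }
  joined %>%
    filter(.data$effective_class %in% config$deleterious_classes) %>%
    select(-"effective_class")
}

#' Subtract variants called in either parent
#'
#' Trio refinement of the screen: a candidate is de novo only if its
#' (`chrom`, `pos`, `ref`, `alt`) key is carried by neither parent.
#' Parental `hom_ref` records (sites called but without the alternate
#' allele) do not count as carrying the variant.
#'
#' @param proband_variants,sire_variants,dam_variants variant tibbles,
#'   decomposed and normalised identically (as [read_vcf()] guarantees).
#' @return Proband records absent from both parents.
#' @export
trio_subtract <- function(proband_variants, sire_variants, dam_variants) {
  carried <- function(v) variant_key(v[v$genotype != "hom_ref", ])
  parental <- c(carried(sire_variants), carried(dam_variants))
  proband_variants[!variant_key(proband_variants) %in% parental, ]
}

#' Count private variants around each candidate
#'
#' For each candidate, counts private variants on the same chromosome
#' within `density_window_bp` base pairs (inclusive at exactly the window
#' half-width); the candidate counts itself, so the minimum is 1 when the
#' candidate is part of `all_private`.
#'
#' @param candidates candidate variant tibble.
#' @param all_private the genome's full private-variant set (not only
#'   deleterious ones).
#' @param config a [filter_config()].
#' @return `candidates` with a `private_density` integer column.
#' @export
private_density <- function(candidates, all_private, config = filter_config()) {
  w <- config$density_window_bp
  priv <- lapply(split(all_private$pos, all_private$chrom), sort)
  dens <- map_int(seq_len(nrow(candidates)), function(i) {
    p <- priv[[candidates$chrom[i]]]
    if (is.null(p)) return(0L)
    hi <- findInterval(candidates$pos[i] + w, p)
    lo <- findInterval(candidates$pos[i] - w - 1L, p)
    hi - lo
  })
  mutate(candidates, private_density = dens)
}

#' Classify candidates as likely recent mutations
#'
#' A private deleterious variant surrounded by at most
#' `density_max_private` private variants (itself included) in the +/-
#' window sits on a non-rare haplotype and is classified as a likely
#' recent (de novo) mutation; denser clusters indicate a rare ancestral
#' haplotype carried by a single animal in the dataset.
#'
#' @param candidates tibble with a `private_density` column (see
#'   [private_density()]).
#' @param config a [filter_config()].
#' @return `candidates` with a logical `classified_recent` column.
#' @export
classify_recent <- function(candidates, config = filter_config()) {
  mutate(candidates,
         classified_recent = .data$private_density <= config$density_max_private)
}

#' Run the full de novo discovery cascade on one genome
#'
#' Applies, in order: quality filter, heterozygous + control-panel-private
#' selection, one-read-per-strand removal, deleterious-consequence
#' retention, then mode-specific refinement — `"trio"` subtracts variants
#' carried by either parent; `"sire_screen"` computes the private-variant
#' density around each candidate and keeps only those classified as likely
#' recent mutations. Each stage's input and output counts are recorded in
#' a filter trail.
#'
#' @param variants proband variant tibble (see [read_vcf()]).
#' @param panel a [control_panel()].
#' @param annotations annotation tibble.
#' @param config a [filter_config()].
#' @param mode `"dominant_case"`, `"trio"` or `"sire_screen"`.
#' @param sire_variants,dam_variants parental variant tibbles (trio mode).
#' @param relaxed use the relaxed quality threshold.
#' @param interval optional `list(chrom =, start =, end =)` restriction
#'   applied to the final candidates (1-based inclusive).
#' @return An object of class `denovo_screen`: the candidate tibble, with
#'   the per-stage filter trail in `attr(, "trail")`. `tidy()` returns the
#'   candidates, `glance()` a one-row summary.
#' @examples
#' sim <- simulate_denovo_genome(seed = 1)
#' scr <- screen_genome(sim$proband, sim$panel, sim$annotations)
#' tidy(scr)
#' @export
screen_genome <- function(variants, panel, annotations,
                          config = filter_config(),
                          mode = c("dominant_case", "trio", "sire_screen"),
                          sire_variants = NULL, dam_variants = NULL,
                          relaxed = FALSE, interval = NULL) {
  mode <- match.arg(mode)
  if (mode == "trio" && (is.null(sire_variants) || is.null(dam_variants))) {
    abort("trio mode requires sire_variants and dam_variants")
  }
  trail <- list()
  step <- function(name, out, n_in) {
    trail[[length(trail) + 1L]] <<- tibble(stage = name, n_in = n_in,
                                           n_out = nrow(out))
    out
  }
  cur <- variants
  if (config$autosomes_only) {
    cur <- step("autosomes", filter(cur, !.data$chrom %in% c("X", "Y", "MT")),
                nrow(variants))
  }
  cur <- step("quality", filter_quality(cur, config, relaxed), nrow(cur))
  cur <- step("het_private", select_het_private(cur, panel), nrow(cur))
  all_private <- cur  # full private set, before consequence filtering
  cur <- step("strand", strand_filter(cur), nrow(cur))
  cur <- step("consequence", consequence_filter(cur, annotations, config),
              nrow(cur))
  if (mode == "trio") {
    cur <- step("trio_subtract",
                trio_subtract(cur, sire_variants, dam_variants), nrow(cur))
  }
  cur <- private_density(cur, all_private, config)
  cur <- classify_recent(cur, config)
  if (mode == "sire_screen") {
    cur <- step("recent_density", filter(cur, .data$classified_recent),
                nrow(cur))
  }
  if (!is.null(interval)) {
    cur <- step("interval",
                restrict_to_interval(cur, interval$chrom, interval$start,
                                     interval$end), nrow(cur))
  }
  structure(cur,
            trail = bind_rows(trail),
            mode = mode, config = config, relaxed = relaxed,
            class = c("denovo_screen", class(cur)))
}

#' Restrict candidates to a genomic interval
#'
#' @param candidates candidate tibble.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return Candidates with matching chromosome and
#'   `start <= pos <= end`.
#' @export
restrict_to_interval <- function(candidates, chrom, start, end) {
  stopifnot(start <= end)
  filter(candidates, .data$chrom == !!chrom,
         .data$pos >= start, .data$pos <= end)
}

#' @export
print.denovo_screen <- function(x, ...) {
  cat("<denovo_screen> mode =", attr(x, "mode"), "\n")
  print(attr(x, "trail"))
  cat("candidates:\n")
  print(as_tibble(x))
  invisible(x)
}

#' @rdname screen_genome
#' @param x a `denovo_screen` object.
#' @param ... unused.
#' @method tidy denovo_screen
#' @export
tidy.denovo_screen <- function(x, ...) {
  as_tibble(x)
}

#' @rdname screen_genome
#' @method glance denovo_screen
#' @export
glance.denovo_screen <- function(x, ...) {
  tr <- attr(x, "trail")
  cfg <- attr(x, "config")
  tibble(mode = attr(x, "mode"), n_input = tr$n_in[[1]],
         n_candidates = nrow(x), n_stages = nrow(tr),
         qual_min = if (attr(x, "relaxed")) cfg$relaxed_qual_min else cfg$qual_min,
         mq_min = cfg$mq_min)
}

#' @rdname screen_genome
#' @param object a `denovo_screen` object.
#' @method autoplot denovo_screen
#' @export
autoplot.denovo_screen <- function(object, ...) {
  tr <- attr(object, "trail")
  tr$stage <- factor(tr$stage, levels = tr$stage)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "variants retained (log scale)",
                  title = "de novo filter cascade") +
    ggplot2::theme_minimal()
}
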
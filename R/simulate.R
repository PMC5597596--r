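#' Simulate a genome for the de novo discovery screen
#'
#' Generates, with planted ground truth, everything the filter cascade
#' consumes: a proband variant set over a background of control-panel
#' variants and private inherited variants, parental variant sets, a
#' consequence annotation table and a control panel. Exactly one
#' heterozygous de novo deleterious variant is planted (absent from both
#' parents and from the panel), in a region kept free of other private
#' variants so its private-variant density is 1 by construction. An
#' optional rare-ancestral-haplotype confound plants a cluster of
#' `confound_size` co-located private variants — one of them deleterious —
#' within the +/- 2.5 Mb density window, so that the density rule must
#' reject it. A handful of fixed decoy variants exercise each filter
#' (low quality, one-read-per-strand, panel-shared, homozygous,
#' tolerated missense).
#'
#' @param seed RNG seed; identical seeds give identical output.
#' @param n_chromosomes autosomes simulated (default 2).
#' @param chrom_length_bp chromosome length (default 2e7).
#' @param n_panel_sites panel variant sites per chromosome (default 200).
#' @param panel_genomes control genomes behind the panel (default 1230).
#' @param background_carry_prob probability the proband carries a panel
#'   site (default 0.4).
#' @param private_rate Poisson mean of private inherited variants per
#'   genome (default 30).
#' @param confound_size cluster size of the rare-haplotype confound;
#'   0 (default) disables it.
#' @param n_inherited_deleterious private deleterious variants inherited
#'   from a parent (default 0); used to exercise trio subtraction.
#' @param out_dir optional directory: writes `proband.vcf`, `sire.vcf`,
#'   `dam.vcf`, `annotations.tsv`, `panel.txt`, `truth.json`.
#' @return List of class `denovo_sim`: `proband`, `sire`, `dam` (variant
#'   tibbles), `panel` (a [control_panel()]), `annotations`, `truth`
#'   (planted variant key, confound keys, inherited deleterious keys).
#' @export
simulate_denovo_genome <- function(seed = NULL, n_chromosomes = 2L,
                                   chrom_length_bp = 2e7,
                                   n_panel_sites = 200L,
                                   panel_genomes = 1230L,
                                   background_carry_prob = 0.4,
                                   private_rate = 30,
                                   confound_size = 0L,
                                   n_inherited_deleterious = 0L,
                                   out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- as.character(seq_len(n_chromosomes))
  bases <- c("A", "C", "G", "T")
  rand_alleles <- function(n) {
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "x")
    list(ref = ref, alt = unname(alt))
  }
  plant_chrom <- "1"
  plant_pos <- as.integer(chrom_length_bp / 2)
  confound_chrom <- chroms[length(chroms)]
  confound_pos <- as.integer(chrom_length_bp / 2)
  guard <- 2500000L + 100000L   # keep background out of the density window

  # control panel sites
  panel_rows <- map(chroms, function(ch) {
    pos <- sort(sample.int(chrom_length_bp, n_panel_sites))
    al <- rand_alleles(n_panel_sites)
    tibble(chrom = ch, pos = pos, ref = al$ref, alt = al$alt)
  }) %>% bind_rows()
  panel <- control_panel(panel_rows, panel_genomes)

  mk_variant <- function(chrom, pos, ref, alt, genotype = "het",
                         qual = NULL, mq = NULL, fwd = NULL, rev = NULL,
                         sample_id = "PROBAND") {
    n <- length(pos)
    tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
           genotype = genotype,
           qual = qual %||% round(runif(n, 35, 90), 1),
           mq = mq %||% round(runif(n, 40, 60), 1),
           fwd_reads = as.integer(fwd %||% (2L + rpois(n, 4))),
           rev_reads = as.integer(rev %||% (2L + rpois(n, 4))),
           sample_id = sample_id)
  }

  # background: panel sites carried by the proband, inherited from a parent
  carried <- panel_rows[runif(nrow(panel_rows)) < background_carry_prob, ]
  geno <- sample(c("het", "hom_alt"), nrow(carried), replace = TRUE,
                 prob = c(0.7, 0.3))
  background <- mk_variant(carried$chrom, carried$pos, carried$ref,
                           carried$alt, genotype = geno)
  from_sire <- runif(nrow(background)) < 0.5

  # private inherited variants, placed outside the guarded regions
  free_pos <- function(ch, n) {
    out <- integer(0)
    while (length(out) < n) {
      p <- sample.int(chrom_length_bp, n)
      bad <- (ch == plant_chrom & abs(p - plant_pos) <= guard) |
             (ch == confound_chrom & abs(p - confound_pos) <= guard)
      out <- unique(c(out, p[!bad]))
    }
    sort(out[seq_len(n)])
  }
  n_priv <- rpois(1, private_rate)
  priv_chrom <- sample(chroms, n_priv, replace = TRUE)
  private <- map(chroms, function(ch) {
    k <- sum(priv_chrom == ch)
    if (!k) return(NULL)
    al <- rand_alleles(k)
    mk_variant(ch, free_pos(ch, k), al$ref, al$alt)
  }) %>% bind_rows()
  priv_from_sire <- if (nrow(private)) runif(nrow(private)) < 0.5 else logical(0)

  # the planted de novo deleterious variant
  planted <- mk_variant(plant_chrom, plant_pos, "C", "CT",
                        qual = 72.0, mq = 55.0, fwd = 6L, rev = 8L)

  # rare-ancestral-haplotype confound: a tight cluster of private variants
  confound <- NULL
  if (confound_size > 0L) {
    off <- sort(sample(seq(-2000000L, 2000000L), confound_size - 1L))
    al <- rand_alleles(confound_size - 1L)
    confound_del <- mk_variant(confound_chrom, confound_pos, "G", "GA",
                               qual = 65.0, mq = 54.0, fwd = 5L, rev = 6L)
    confound_rest <- mk_variant(confound_chrom, confound_pos + off,
                                al$ref, al$alt)
    confound <- bind_rows(confound_del, confound_rest)
  }

  # inherited private deleterious variants (survive the cascade, removed
  # only by trio subtraction)
  inherited_del <- NULL
  if (n_inherited_deleterious > 0L) {
    ch <- chroms[min(2L, length(chroms))]
    base <- as.integer(chrom_length_bp * 0.1)
    inherited_del <- mk_variant(ch, base + seq_len(n_inherited_deleterious) * 400000L,
                                "T", "TG")
  }

  # fixed decoys, one per upstream filter
  decoy_ch <- chroms[min(2L, length(chroms))]
  dbase <- as.integer(chrom_length_bp * 0.75)
  decoys <- bind_rows(
    mk_variant(decoy_ch, dbase + 10000L, "A", "G", qual = 20.0),   # low QUAL
    mk_variant(decoy_ch, dbase + 20000L, "C", "A", fwd = 1L, rev = 1L),
    mk_variant(decoy_ch, dbase + 30000L, "G", "T", genotype = "hom_alt"),
    mk_variant(decoy_ch, dbase + 40000L, "T", "C")                 # tolerated
  )
  panel_decoy <- mk_variant(panel_rows$chrom[[1]], panel_rows$pos[[1]],
                            panel_rows$ref[[1]], panel_rows$alt[[1]])

  proband <- bind_rows(background, private, planted, confound,
                       inherited_del, decoys) %>%
    arrange(.data$chrom, .data$pos, .data$alt)

  resample_quality <- function(v, sample_id) {
    mutate(v, sample_id = sample_id,
           qual = round(runif(n(), 35, 90), 1),
           mq = round(runif(n(), 40, 60), 1),
           fwd_reads = 2L + rpois(n(), 4), rev_reads = 2L + rpois(n(), 4))
  }
  sire <- bind_rows(background[from_sire, ], private[priv_from_sire, ],
                    inherited_del) %>%
    resample_quality("SIRE") %>% arrange(.data$chrom, .data$pos, .data$alt)
  dam <- bind_rows(background[!from_sire, ], private[!priv_from_sire, ]) %>%
    resample_quality("DAM") %>% arrange(.data$chrom, .data$pos, .data$alt)

  annotate <- function(v, consequence, sift = NA_character_) {
    tibble(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
           consequence = consequence, sift_class = sift)
  }
  annotations <- bind_rows(
    annotate(background, sample(c("intergenic", "intron", "synonymous"),
                                nrow(background), replace = TRUE)),
    if (nrow(private)) {
      annotate(private, sample(c("intergenic", "intron", "synonymous"),
                               nrow(private), replace = TRUE))
    },
    annotate(planted, "frameshift"),
    if (!is.null(confound)) bind_rows(
      annotate(confound[1, ], "stop_gained"),
      annotate(confound[-1, ], "intergenic")),
    if (!is.null(inherited_del)) annotate(inherited_del, "stop_gained"),
    annotate(decoys[1, ], "splice_donor"),
    annotate(decoys[2, ], "stop_lost"),
    annotate(decoys[3, ], "splice_acceptor"),
    annotate(decoys[4, ], "missense", "tolerated"),
    annotate(panel_decoy, "frameshift")
  ) %>% distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                 .keep_all = TRUE)

  truth <- list(
    planted = planted[, c("chrom", "pos", "ref", "alt")],
    planted_key = variant_key(planted),
    confound_keys = if (!is.null(confound)) variant_key(confound) else character(0),
    confound_deleterious_key = if (!is.null(confound)) variant_key(confound[1, ]) else character(0),
    inherited_deleterious_keys = if (!is.null(inherited_del)) variant_key(inherited_del) else character(0)
  )
  out <- structure(list(proband = proband, sire = sire, dam = dam,
                        panel = panel, annotations = annotations,
                        truth = truth),
                   class = "denovo_sim")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(proband, file.path(out_dir, "proband.vcf"), "PROBAND")
    write_vcf(sire, file.path(out_dir, "sire.vcf"), "SIRE")
    write_vcf(dam, file.path(out_dir, "dam.vcf"), "DAM")
    readr::write_tsv(annotations, file.path(out_dir, "annotations.tsv"))
    write_control_panel(panel, file.path(out_dir, "panel.txt"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# single-crossover meiosis: transmitted haplotype and its origin track.
# h1/h2 are lists with $alleles and $origin vectors of equal length.
.meiosis <- function(h1, h2) {
  m <- length(h1$alleles)
  b <- sample(0:m, 1L)               # markers 1..b from the first phase
  first <- sample(c(TRUE, FALSE), 1L)
  a <- if (first) h1 else h2
  z <- if (first) h2 else h1
  pick <- c(rep(TRUE, b), rep(FALSE, m - b))
  list(alleles = ifelse(pick, a$alleles, z$alleles),
       origin = ifelse(pick, a$origin, z$origin))
}

.pool_haplotype <- function(freq_b, origin_id) {
  list(alleles = ifelse(runif(length(freq_b)) < freq_b, "B", "A"),
       origin = rep(origin_id, length(freq_b)))
}

#' Simulate a phased half-sib panel with planted causal and modifier loci
#'
#' Emulates the mapping design of a large paternal half-sib family: one
#' sire heterozygous for a causal haplotype, many dams from a homogeneous
#' population, affected offspring defined by paternal transmission of the
#' causal segment. A modifier haplotype on another chromosome is planted
#' maternally in a configured number of mildly affected and unaffected
#' carriers (default 12 of 49 versus 2 of 89, the ten-fold carrier
#' enrichment of the study design). Meioses use a single uniform
#' crossover per chromosome. The planted segments carry derived marker
#' alleles absent from the founder haplotype pool at regularly spaced
#' "distinguishing" markers, so no pool haplotype can match them over any
#' scan window — emulating haplotypes unique to the mutant lineage.
#'
#' @param seed RNG seed.
#' @param n_chromosomes,n_markers,spacing_bp map geometry (defaults 3
#'   chromosomes x 120 markers at 50 kb, so a 10-marker window spans
#'   ~500 kb).
#' @param n_case,n_control group sizes (defaults 49 and 89).
#' @param pool_size founder haplotypes per chromosome in the dam
#'   population (default 16).
#' @param plant_causal,causal_chrom,causal_span plant a causal haplotype
#'   of `causal_span` markers centred on `causal_chrom`.
#' @param plant_modifier,modifier_chrom,modifier_span,modifier_carriers_case,modifier_carriers_control
#'   plant a modifier haplotype with exactly these carrier counts per
#'   group (maternally).
#' @param distinguisher_every spacing of the derived-allele markers
#'   inside planted segments (default 5).
#' @param plant_ancestral also give one unaffected individual a maternal
#'   copy of the causal haplotype without the mutation (an ancestral
#'   carrier, default FALSE).
#' @param out_dir optional directory: writes `map.tsv`,
#'   `haplotypes.tsv`, `labels.tsv`, `truth.json`.
#' @return List of class `halfsib_sim`: `panel` (a [phased_panel()] with
#'   labels `mildly_affected` / `unaffected`) and `truth` (planted spans,
#'   carrier ids, the sire's haplotypes, and the chromosome that must be
#'   scanned maternally).
#' @export
simulate_halfsib_panel <- function(seed = NULL, n_chromosomes = 3L,
                                   n_markers = 120L, spacing_bp = 50000L,
                                   n_case = 49L, n_control = 89L,
                                   pool_size = 16L,
                                   plant_causal = TRUE, causal_chrom = "2",
                                   causal_span = 40L,
                                   plant_modifier = TRUE,
                                   modifier_chrom = "3",
                                   modifier_span = 16L,
                                   modifier_carriers_case = 12L,
                                   modifier_carriers_control = 2L,
                                   distinguisher_every = 5L,
                                   plant_ancestral = FALSE,
                                   out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- as.character(seq_len(n_chromosomes))
  stopifnot(causal_chrom %in% chroms, modifier_chrom %in% chroms,
            causal_chrom != modifier_chrom,
            modifier_carriers_case <= n_case,
            modifier_carriers_control <= n_control)
  map <- bind_rows(lapply(chroms, function(ch) {
    tibble(marker_id = sprintf("c%s_m%03d", ch, seq_len(n_markers)),
           chrom = ch, pos = spacing_bp * seq_len(n_markers))
  }))
  span_of <- function(len) {
    s <- as.integer((n_markers - len) / 2) + 1L
    c(s, s + len - 1L)
  }
  causal_sp <- span_of(causal_span)
  modifier_sp <- span_of(modifier_span)

  freq <- lapply(setNames(chroms, chroms),
                 function(ch) runif(n_markers, 0.15, 0.85))
  # derived-allele markers: the pool is fixed to "A" there
  dist_markers <- list()
  dist_markers[[causal_chrom]] <- seq(causal_sp[1], causal_sp[2],
                                      by = distinguisher_every)
  dist_markers[[modifier_chrom]] <- seq(modifier_sp[1], modifier_sp[2],
                                        by = distinguisher_every)
  pool <- lapply(setNames(chroms, chroms), function(ch) {
    h <- lapply(seq_len(pool_size), function(i) .pool_haplotype(freq[[ch]], i))
    d <- dist_markers[[ch]]
    if (!is.null(d)) h <- lapply(h, function(x) {
      x$alleles[d] <- "A"; x
    })
    h
  })
  pattern_over <- function(ch, sp) {
    pat <- ifelse(runif(sp[2] - sp[1] + 1L) < freq[[ch]][sp[1]:sp[2]], "B", "A")
    d <- dist_markers[[ch]] - sp[1] + 1L
    pat[d] <- "B"
    pat
  }
  causal_pattern <- pattern_over(causal_chrom, causal_sp)
  modifier_pattern <- pattern_over(modifier_chrom, modifier_sp)

  draw_pool <- function(ch) pool[[ch]][[sample.int(pool_size, 1L)]]
  # sire: haplotype 1 carries the causal segment (when planted)
  sire <- lapply(setNames(chroms, chroms), function(ch) {
    h1 <- draw_pool(ch); h2 <- draw_pool(ch)
    h1$origin <- rep(-1L, n_markers); h2$origin <- rep(-2L, n_markers)
    if (plant_causal && ch == causal_chrom) {
      h1$alleles[causal_sp[1]:causal_sp[2]] <- causal_pattern
    }
    list(h1 = h1, h2 = h2)
  })

  dam_meiosis <- function(ch) .meiosis(draw_pool(ch), draw_pool(ch))
  paternal_meiosis <- function(ch, want_causal) {
    s <- sire[[ch]]
    if (ch != causal_chrom || !plant_causal) return(.meiosis(s$h1, s$h2))
    span_idx <- causal_sp[1]:causal_sp[2]
    for (try in 1:100) {
      g <- .meiosis(s$h1, s$h2)
      ok <- if (want_causal) all(g$origin[span_idx] == -1L)
            else g$origin[span_idx[as.integer(length(span_idx) / 2)]] == -2L
      if (ok) return(g)
    }
    if (want_causal) s$h1 else s$h2
  }

  ids <- c(sprintf("case%03d", seq_len(n_case)),
           sprintf("ctrl%03d", seq_len(n_control)))
  is_case <- c(rep(TRUE, n_case), rep(FALSE, n_control))
  hap <- matrix(NA_character_, 2L * length(ids), n_markers * n_chromosomes,
                dimnames = list(paste(rep(ids, each = 2), c("P", "M"),
                                      sep = "|"), NULL))
  for (i in seq_along(ids)) {
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      off <- (ci - 1L) * n_markers
      pat <- paternal_meiosis(ch, is_case[i])
      mat <- dam_meiosis(ch)
      hap[2L * i - 1L, off + seq_len(n_markers)] <- pat$alleles
      hap[2L * i, off + seq_len(n_markers)] <- mat$alleles
    }
  }
  # columns must follow the validated map order (sorted by chrom, pos)
  colnames(hap) <- map$marker_id

  modifier_ids <- character(0)
  if (plant_modifier) {
    modifier_ids <- c(sample(ids[is_case], modifier_carriers_case),
                      sample(ids[!is_case], modifier_carriers_control))
    ci <- match(modifier_chrom, chroms)
    cols <- (ci - 1L) * n_markers + (modifier_sp[1]:modifier_sp[2])
    for (id in modifier_ids) {
      hap[paste0(id, "|M"), cols] <- modifier_pattern
    }
  }
  ancestral_id <- character(0)
  if (plant_ancestral) {
    ancestral_id <- sample(setdiff(ids[!is_case], modifier_ids), 1L)
    ci <- match(causal_chrom, chroms)
    cols <- (ci - 1L) * n_markers + (causal_sp[1]:causal_sp[2])
    hap[paste0(ancestral_id, "|M"), cols] <- causal_pattern
  }

  labels <- tibble(id = ids,
                   label = ifelse(is_case, "mildly_affected", "unaffected"))
  panel <- phased_panel(map, hap, labels = labels)
  truth <- list(
    causal_chrom = causal_chrom,
    causal_span_markers = causal_sp,
    causal_center_marker = as.integer(mean(causal_sp)),
    causal_center_bp = spacing_bp * as.integer(mean(causal_sp)),
    causal_pattern = paste(causal_pattern, collapse = ""),
    modifier_chrom = modifier_chrom,
    modifier_span_markers = modifier_sp,
    modifier_pattern = paste(modifier_pattern, collapse = ""),
    modifier_carrier_ids = modifier_ids,
    ancestral_carrier_id = ancestral_id,
    case_ids = ids[is_case],
    maternal_only_chroms = causal_chrom,
    sire_hap1 = vapply(chroms, function(ch) {
      h <- sire[[ch]]$h1$alleles
      if (plant_causal && ch == causal_chrom) {
        h[causal_sp[1]:causal_sp[2]] <- causal_pattern
      }
      paste(h, collapse = "")
    }, "x")
  )
  out <- structure(list(panel = panel, truth = truth), class = "halfsib_sim")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_phased_panel(panel, file.path(out_dir, "map.tsv"),
                       file.path(out_dir, "haplotypes.tsv"),
                       file.path(out_dir, "labels.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Simulate a multi-generation pedigree descending from a mutant founder
#'
#' Emulates the emergence of a recessive defect after a de novo mutation
#' in a popular sire: the founder carries one mutant haplotype; later
#' generations mate either with unrelated animals or, with probability
#' `consanguinity`, with another descendant, creating inbreeding loops.
#' Whole marker haplotypes are gene-dropped (single crossover per
#' meiosis), so affected individuals — homozygous for the founder's
#' mutant haplotype at the mutation marker — are autozygous around the
#' mutation locus. When `n_affected` is positive (and `consanguinity`
#' non-zero), additional carrier x carrier half-sib matings are appended
#' until that many affected exist, emulating the ascertainment of cases
#' in the field.
#'
#' @param seed RNG seed.
#' @param n_chromosomes,n_markers,spacing_bp map geometry (defaults 2
#'   chromosomes x 400 markers at 50 kb, i.e. 20 Mb chromosomes: dense
#'   enough that a 20-marker run is a small fraction of the chromosome,
#'   as on a genome-wide 50k array).
#' @param mutation_chrom,mutation_marker locus of the founder mutation
#'   (default: middle of chromosome 1).
#' @param n_gen1 founder offspring in the first generation (default 12).
#' @param n_matings_per_gen,n_children_per_mating later-generation mating
#'   plan (defaults 14 and 3).
#' @param n_generations generations after the first (default 2).
#' @param consanguinity probability a mating is between two descendants
#'   (default 0.5).
#' @param n_affected affected individuals guaranteed by appended
#'   carrier x carrier matings (default 7; 0 disables).
#' @param protected_radius markers on each side of the mutation locus
#'   kept free of crossovers in gametes transmitting the mutant allele
#'   (default 30, ~1.5 Mb), so affected individuals carry the intact
#'   founder haplotype around the mutation — the generator's autozygosity
#'   contract.
#' @param out_dir optional directory: writes `pedigree.tsv`, `map.tsv`,
#'   `haplotypes.tsv`, `labels.tsv`, `truth.json`.
#' @return List of class `founder_sim`: `pedigree`, `genotypes` (tibble
#'   `id`, `n_mutant_alleles`, `affected`), `panel` (phased panel of the
#'   affected individuals), `map`, and `truth` (founder id, mutation
#'   locus, affected ids).
#' @export
simulate_founder_pedigree <- function(seed = NULL, n_chromosomes = 2L,
                                      n_markers = 400L, spacing_bp = 50000L,
                                      mutation_chrom = "1",
                                      mutation_marker = NULL,
                                      n_gen1 = 12L,
                                      n_matings_per_gen = 14L,
                                      n_children_per_mating = 3L,
                                      n_generations = 2L,
                                      consanguinity = 0.5,
                                      n_affected = 7L,
                                      protected_radius = 30L,
                                      out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- as.character(seq_len(n_chromosomes))
  mutation_marker <- mutation_marker %||% as.integer(n_markers / 2)
  map <- bind_rows(lapply(chroms, function(ch) {
    tibble(marker_id = sprintf("c%s_m%03d", ch, seq_len(n_markers)),
           chrom = ch, pos = spacing_bp * seq_len(n_markers))
  }))
  freq <- lapply(setNames(chroms, chroms),
                 function(ch) runif(n_markers, 0.15, 0.85))

  origin_counter <- 0L
  new_founder_genome <- function() {
    lapply(setNames(chroms, chroms), function(ch) {
      h1 <- .pool_haplotype(freq[[ch]], origin_counter + 1L)
      h2 <- .pool_haplotype(freq[[ch]], origin_counter + 2L)
      origin_counter <<- origin_counter + 2L
      list(h1, h2)
    })
  }
  genomes <- list()
  ped_rows <- list()
  add_individual <- function(id, sire, dam, sex, birth_year, genome) {
    genomes[[id]] <<- genome
    ped_rows[[length(ped_rows) + 1L]] <<-
      tibble(id = id, sire = sire, dam = dam, sex = sex,
             birth_year = as.integer(birth_year))
    id
  }
  # a gamete that transmits the mutant-origin allele keeps an intact
  # founder-haplotype context of `protected_radius` markers around the
  # locus (resampling the crossover), so affected individuals are
  # autozygous around the mutation, as ascertained field cases are
  zone <- max(1L, mutation_marker - protected_radius):
          min(n_markers, mutation_marker + protected_radius)
  protected_meiosis <- function(h1, h2, mutant_id) {
    for (try in 1:100) {
      g <- .meiosis(h1, h2)
      if (g$origin[mutation_marker] != mutant_id ||
          all(g$origin[zone] == mutant_id)) {
        return(g)
      }
    }
    if (h1$origin[mutation_marker] == mutant_id) h1 else h2
  }
  mate <- function(sire_id, dam_id) {
    lapply(setNames(chroms, chroms), function(ch) {
      gam <- function(par) {
        h1 <- genomes[[par]][[ch]][[1]]; h2 <- genomes[[par]][[ch]][[2]]
        if (ch == mutation_chrom) {
          protected_meiosis(h1, h2, mutant_origin)
        } else {
          .meiosis(h1, h2)
        }
      }
      list(gam(sire_id), gam(dam_id))
    })
  }
  founder <- add_individual("FOUNDER", NA, NA, "M", 2000, new_founder_genome())
  mutant_origin <- genomes$FOUNDER[[mutation_chrom]][[1]]$origin[[1]]
  n_mutant <- function(id) {
    g <- genomes[[id]][[mutation_chrom]]
    sum(g[[1]]$origin[mutation_marker] == mutant_origin,
        g[[2]]$origin[mutation_marker] == mutant_origin)
  }
  new_mate <- function(sex, birth_year) {
    id <- sprintf("EXT%03d", length(ped_rows))
    add_individual(id, NA, NA, sex, birth_year, new_founder_genome())
  }

  gen1 <- character(n_gen1)
  sex_of <- character(0)
  for (i in seq_len(n_gen1)) {
    dam <- new_mate("F", 2000)
    id <- sprintf("G1_%03d", i)
    sx <- if (i %% 2L) "M" else "F"
    add_individual(id, founder, dam, sx, 2003, mate(founder, dam))
    sex_of[id] <- sx
    gen1[i] <- id
  }
  all_desc <- gen1
  year <- 2003L
  for (g in seq_len(n_generations)) {
    year <- year + 3L
    born <- character(0)
    males <- all_desc[sex_of[all_desc] == "M"]
    females <- all_desc[sex_of[all_desc] == "F"]
    for (mi in seq_len(n_matings_per_gen)) {
      consang <- runif(1) < consanguinity && length(males) && length(females)
      if (consang) {
        s <- sample(males, 1L); d <- sample(females, 1L)
      } else if (runif(1) < 0.5 && length(males)) {
        s <- sample(males, 1L); d <- new_mate("F", year - 3L)
      } else {
        s <- new_mate("M", year - 3L); d <- sample(females, 1L)
      }
      for (k in seq_len(n_children_per_mating)) {
        id <- sprintf("G%d_%03d_%d", g + 1L, mi, k)
        sx <- sample(c("M", "F"), 1L)
        add_individual(id, s, d, sx, year, mate(s, d))
        sex_of[id] <- sx
        born <- c(born, id)
      }
    }
    all_desc <- c(all_desc, born)
  }

  ids_now <- vapply(ped_rows, function(r) r$id, "x")
  affected_ids <- ids_now[vapply(ids_now, n_mutant, 0L) == 2L]
  if (n_affected > 0L && consanguinity > 0) {
    carriers <- function(pool) pool[vapply(pool, n_mutant, 0L) >= 1L]
    # prefer first-generation carriers (short descent paths, as in the
    # ascertained field cases); widen to all descendants if a sex has none
    cm <- carriers(gen1[sex_of[gen1] == "M"])
    cf <- carriers(gen1[sex_of[gen1] == "F"])
    if (!length(cm)) cm <- carriers(all_desc[sex_of[all_desc] == "M"])
    if (!length(cf)) cf <- carriers(all_desc[sex_of[all_desc] == "F"])
    by_id <- function(id) ped_rows[[match(id, vapply(ped_rows, `[[`, "x", "id"))]]
    k <- 0L
    while (length(affected_ids) < n_affected && length(cm) && length(cf) &&
           k < 10000L) {
      k <- k + 1L
      s <- sample(cm, 1L); d <- sample(cf, 1L)
      id <- sprintf("ASC_%04d", k)
      yr <- max(by_id(s)$birth_year, by_id(d)$birth_year) + 3L
      add_individual(id, s, d, sample(c("M", "F"), 1L), yr, mate(s, d))
      if (n_mutant(id) == 2L) affected_ids <- c(affected_ids, id)
    }
  }

  pedigree <- as_pedigree(bind_rows(ped_rows))
  genotypes <- tibble(id = pedigree$id,
                      n_mutant_alleles = vapply(pedigree$id, n_mutant, 0L)) %>%
    mutate(affected = .data$n_mutant_alleles == 2L)

  panel <- NULL
  if (length(affected_ids) >= 1L) {
    hap <- do.call(rbind, lapply(affected_ids, function(id) {
      g <- genomes[[id]]
      rbind(unlist(lapply(chroms, function(ch) g[[ch]][[1]]$alleles)),
            unlist(lapply(chroms, function(ch) g[[ch]][[2]]$alleles)))
    }))
    rownames(hap) <- paste(rep(affected_ids, each = 2), c("P", "M"), sep = "|")
    colnames(hap) <- map$marker_id
    panel <- phased_panel(map, hap,
                          labels = tibble(id = affected_ids, label = "case"))
  }
  truth <- list(founder = "FOUNDER",
                mutation_chrom = mutation_chrom,
                mutation_marker = mutation_marker,
                mutation_bp = spacing_bp * mutation_marker,
                affected_ids = affected_ids)
  out <- structure(list(pedigree = pedigree, genotypes = genotypes,
                        panel = panel, map = map, truth = truth),
                   class = "founder_sim")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pedigree(pedigree, file.path(out_dir, "pedigree.tsv"))
    if (!is.null(panel)) {
      write_phased_panel(panel, file.path(out_dir, "map.tsv"),
                         file.path(out_dir, "haplotypes.tsv"),
                         file.path(out_dir, "labels.tsv"))
    }
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
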
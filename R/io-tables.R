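#' Read and validate a pedigree file
#'
#' The pedigree is a tab-separated file with header
#' `id  sire  dam  sex  birth_year`; `"0"` or `"."` denote an unknown
#' parent. Validation checks that ids are unique, every named parent is
#' itself a row, no individual is its own ancestor, and every individual is
#' born after its known parents.
#'
#' @param path path to the pedigree TSV.
#' @return A tibble with columns `id`, `sire`, `dam` (both `NA` when
#'   unknown), `sex` and `birth_year`, in validated topological order
#'   (parents before offspring).
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), sire = readr::col_character(),
    dam = readr::col_character(), sex = readr::col_character(),
    birth_year = readr::col_integer()
  ))
  ped <- mutate(ped, across(c("sire", "dam"), ~ ifelse(.x %in% c("0", "."), NA, .x)))
  as_pedigree(ped)
}

#' Validate an in-memory pedigree tibble
#'
#' @param ped tibble with columns `id`, `sire`, `dam`, `sex`, `birth_year`
#'   (`NA` = unknown parent).
#' @return The pedigree, reordered topologically (parents first).
#' @export
as_pedigree <- function(ped) {
  need <- c("id", "sire", "dam", "sex", "birth_year")
  if (!all(need %in% names(ped))) {
    abort(paste0("pedigree must have columns ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(ped$id)) {
    abort(paste0("duplicate individual id(s): ",
                 paste(unique(ped$id[duplicated(ped$id)]), collapse = ", ")))
  }
  parents <- c(ped$sire, ped$dam)
  dangling <- setdiff(parents[!is.na(parents)], ped$id)
  if (length(dangling)) {
    abort(paste0("parent id(s) not present as individuals: ",
                 paste(dangling, collapse = ", ")))
  }
  ord <- .pedigree_topo_order(ped)
  ped <- ped[ord, ]
  bad <- !is.na(ped$birth_year) & (
    (!is.na(ped$sire) & ped$birth_year <= ped$birth_year[match(ped$sire, ped$id)]) |
    (!is.na(ped$dam) & ped$birth_year <= ped$birth_year[match(ped$dam, ped$id)]))
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    abort(paste0("individual(s) born no later than a parent: ",
                 paste(ped$id[bad], collapse = ", ")))
  }
  ped
}

# Kahn topological sort; on failure reconstructs one cycle for the message
.pedigree_topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  sire_i <- idx[ped$sire]; dam_i <- idx[ped$dam]
  placed <- logical(n)
  order_out <- integer(0)
  repeat {
    ready <- which(!placed &
                   (is.na(sire_i) | placed[replace(sire_i, is.na(sire_i), 1L)]) &
                   (is.na(dam_i) | placed[replace(dam_i, is.na(dam_i), 1L)]))
    if (!length(ready)) break
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
  }
  if (length(order_out) < n) {
    start <- which(!placed)[1]
    path <- ped$id[start]; cur <- start
    repeat {
      nxt <- if (!is.na(sire_i[cur]) && !placed[sire_i[cur]]) sire_i[cur] else dam_i[cur]
      if (ped$id[nxt] %in% path) {
        path <- c(path, ped$id[nxt])
        break
      }
      path <- c(path, ped$id[nxt]); cur <- nxt
    }
    abort(paste0("pedigree contains a cycle: ", paste(rev(path), collapse = " -> ")))
  }
  order_out
}

#' Write a pedigree tibble
#'
#' Unknown parents are written as `"0"`.
#' @param ped pedigree tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- mutate(ped, across(c("sire", "dam"), ~ ifelse(is.na(.x), "0", .x)))
  readr::write_tsv(out[, c("id", "sire", "dam", "sex", "birth_year")], path)
  invisible(path)
}

#' Read a SNP marker map
#'
#' @param path TSV with columns `marker_id`, `chrom`, `pos` (1-based bp).
#' @return Tibble sorted by (`chrom`, `pos`), validated: unique marker ids,
#'   strictly increasing positions within each chromosome.
#' @export
read_marker_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer()
  ))
  validate_marker_map(map)
}

#' @rdname read_marker_map
#' @param map in-memory marker-map tibble.
#' @export
validate_marker_map <- function(map) {
  if (anyDuplicated(map$marker_id)) {
    abort(paste0("duplicate marker id(s): ",
                 paste(unique(map$marker_id[duplicated(map$marker_id)]), collapse = ", ")))
  }
  if (any(map$pos < 1L)) abort("marker positions must be >= 1")
  map <- arrange(map, .data$chrom, .data$pos)
  dup <- map %>% group_by(.data$chrom) %>%
    summarise(bad = anyDuplicated(.data$pos) > 0L, .groups = "drop")
  if (any(dup$bad)) {
    abort(paste0("duplicate positions within chromosome(s): ",
                 paste(dup$chrom[dup$bad], collapse = ", ")))
  }
  map
}

#' Construct a phased SNP panel
#'
#' A phased panel couples a marker map with exactly two haplotype allele
#' strings per individual (paternal `"P"` and maternal `"M"`) and a
#' phenotype label per individual.
#'
#' @param map marker-map tibble (`marker_id`, `chrom`, `pos`).
#' @param haplotypes character matrix of single-character alleles, one row
#'   per haplotype, rownames `"<id>|P"` / `"<id>|M"`, one column per marker
#'   in map order; or a tibble with columns `id`, `hap` (`"P"`/`"M"`),
#'   `alleles` (string).
#' @param labels optional tibble (`id`, `label`) with labels in
#'   `c("case", "control", "mildly_affected", "unaffected", "unknown")`;
#'   defaults to `"unknown"`.
#' @param alphabet allowed allele symbols.
#' @return An object of class `phased_panel`.
#' @export
phased_panel <- function(map, haplotypes, labels = NULL,
                         alphabet = c("A", "B")) {
  map <- validate_marker_map(map)
  if (is.data.frame(haplotypes)) {
    n <- nchar(haplotypes$alleles)
    bad <- haplotypes$id[n != nrow(map)]
    if (length(bad)) {
      abort(paste0("haplotype length != number of markers (", nrow(map),
                   ") for individual(s): ", paste(unique(bad), collapse = ", ")))
    }
    mat <- do.call(rbind, strsplit(haplotypes$alleles, "", fixed = TRUE))
    rownames(mat) <- paste(haplotypes$id, haplotypes$hap, sep = "|")
    haplotypes <- mat
  }
  ids <- sub("\\|[PM]$", "", rownames(haplotypes))
  hap <- sub("^.*\\|", "", rownames(haplotypes))
  tab <- table(ids, hap)
  ok <- nrow(tab) > 0 && all(tab == 1L) && all(c("P", "M") %in% colnames(tab))
  if (!ok) {
    bad <- rownames(tab)[rowSums(tab) != 2L | apply(tab, 1, max) > 1L]
    abort(paste0("each individual needs exactly one P and one M haplotype",
                 if (length(bad)) paste0("; offending: ", paste(bad, collapse = ", "))))
  }
  if (ncol(haplotypes) != nrow(map)) {
    abort("haplotype matrix has a different number of markers than the map")
  }
  if (!is.null(colnames(haplotypes))) {
    if (!setequal(colnames(haplotypes), map$marker_id)) {
      abort("haplotype column names do not match the marker map")
    }
    haplotypes <- haplotypes[, map$marker_id, drop = FALSE]
  }
  if (!all(haplotypes %in% alphabet)) {
    abort(paste0("allele symbols outside declared alphabet {",
                 paste(alphabet, collapse = ","), "}"))
  }
  colnames(haplotypes) <- map$marker_id
  uids <- unique(ids)
  if (is.null(labels)) labels <- tibble(id = uids, label = "unknown")
  labels <- left_join(tibble(id = uids), labels, by = "id") %>%
    mutate(label = ifelse(is.na(.data$label), "unknown", .data$label))
  # fixed row order: P then M per individual
  haplotypes <- haplotypes[paste(rep(uids, each = 2), c("P", "M"), sep = "|"), ,
                           drop = FALSE]
  structure(list(map = map, hap = haplotypes, individuals = labels,
                 alphabet = alphabet),
            class = "phased_panel")
}

#' @export
print.phased_panel <- function(x, ...) {
  cat("<phased_panel> ", nrow(x$individuals), " individuals, ",
      nrow(x$map), " markers on ", length(unique(x$map$chrom)),
      " chromosome(s)\n", sep = "")
  print(count(x$individuals, .data$label))
  invisible(x)
}

#' Read a phased panel from its marker-map and haplotype files
#'
#' The haplotype file is a TSV with columns `id`, `hap` (`P` or `M`) and
#' `alleles` (one symbol per marker, concatenated), two rows per
#' individual.
#'
#' @param map_path marker-map TSV path.
#' @param hap_path haplotype TSV path.
#' @param labels optional tibble (`id`, `label`), or the path of a labels
#'   TSV with those columns.
#' @inheritParams phased_panel
#' @return A `phased_panel`.
#' @export
read_phased_panel <- function(map_path, hap_path, labels = NULL,
                              alphabet = c("A", "B")) {
  if (is.character(labels)) {
    labels <- readr::read_tsv(labels, col_types = readr::cols(
      id = readr::col_character(), label = readr::col_character()
    ))
  }
  map <- read_marker_map(map_path)
  haps <- readr::read_tsv(hap_path, col_types = readr::cols(
    id = readr::col_character(), hap = readr::col_character(),
    alleles = readr::col_character()
  ))
  phased_panel(map, haps, labels = labels, alphabet = alphabet)
}

#' Write a phased panel to marker-map and haplotype TSV files
#'
#' @param panel a `phased_panel`.
#' @param map_path,hap_path output paths.
#' @param labels_path optional path for the phenotype-label TSV.
#' @return `hap_path`, invisibly.
#' @export
write_phased_panel <- function(panel, map_path, hap_path, labels_path = NULL) {
  readr::write_tsv(panel$map, map_path)
  rn <- rownames(panel$hap)
  haps <- tibble(
    id = sub("\\|[PM]$", "", rn),
    hap = sub("^.*\\|", "", rn),
    alleles = apply(panel$hap, 1, paste, collapse = "")
  )
  readr::write_tsv(haps, hap_path)
  if (!is.null(labels_path)) readr::write_tsv(panel$individuals, labels_path)
  invisible(hap_path)
}

#' Read a variant consequence annotation table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`,
#'   `consequence`, `sift_class`.
#' @return A tibble.
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    consequence = readr::col_character(), sift_class = readr::col_character()
  ))
}

#' Build a control-genome variant panel
#'
#' A queryable index of every variant observed across a set of control
#' genomes; membership is keyed on (`chrom`, `pos`, `ref`, `alt`).
#'
#' @param variants tibble with columns `chrom`, `pos`, `ref`, `alt` (extra
#'   columns ignored), or a character vector of `chrom:pos:ref:alt` keys.
#' @param n_genomes number of control genomes behind the panel (> 0).
#' @return An object of class `control_panel`.
#' @export
control_panel <- function(variants, n_genomes) {
  stopifnot(n_genomes > 0)
  keys <- if (is.character(variants)) variants else variant_key(variants)
  structure(list(keys = unique(keys), n_genomes = as.integer(n_genomes)),
            class = "control_panel")
}

#' @export
print.control_panel <- function(x, ...) {
  cat("<control_panel> ", length(x$keys), " variant keys from ",
      x$n_genomes, " genomes\n", sep = "")
  invisible(x)
}

#' @rdname control_panel
#' @param panel a `control_panel`.
#' @return For `in_control_panel`, a logical vector aligned with the rows
#'   of `variants`.
#' @export
in_control_panel <- function(panel, variants) {
  stopifnot(inherits(panel, "control_panel"))
  variant_key(variants) %in% panel$keys
}

#' @rdname control_panel
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Write / read a control panel as a plain-text key file
#'
#' @param panel a `control_panel`.
#' @param path output path; first line holds the genome count.
#' @return `path` (write) or a `control_panel` (read).
#' @export
write_control_panel <- function(panel, path) {
  writeLines(c(paste0("#n_genomes=", panel$n_genomes), sort(panel$keys)), path)
  invisible(path)
}

#' @rdname write_control_panel
#' @export
read_control_panel <- function(path) {
  lines <- readLines(path)
  n <- as.integer(sub("^#n_genomes=", "", lines[[1]]))
  control_panel(lines[-1], n)
}
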
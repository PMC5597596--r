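#' Filter trail of a de novo screen
#'
#' The per-stage bookkeeping of the discovery cascade: each filter's
#' input and output counts, mirroring the count columns of a
#' whole-genome-screen results table.
#'
#' @param screen a `denovo_screen` from [screen_genome()].
#' @return Tibble (`stage`, `n_in`, `n_out`).
#' @export
filter_trail <- function(screen) {
  stopifnot(inherits(screen, "denovo_screen"))
  attr(screen, "trail")
}

#' Render an analysis result to a report file
#'
#' Serialises a pipeline result — a `denovo_screen`, a `window_scan`, or
#' any tibble — deterministically, embedding a provenance block (package
#' version, parameters, seed and permutation count where applicable).
#'
#' @param x result object.
#' @param path output file path.
#' @param format `"tsv"`, `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(x, path, format = c("tsv", "json", "markdown")) {
  if (!is.character(format) ||
      !all(format %in% c("tsv", "json", "markdown"))) {
    abort("unknown report format; use 'tsv', 'json' or 'markdown'")
  }
  format <- match.arg(format)
  meta <- .report_meta(x)
  data <- .report_data(x)
  if (format == "tsv") {
    hdr <- paste0("# ", names(meta), ": ", unlist(meta))
    writeLines(hdr, path)
    suppressWarnings(readr::write_tsv(data, path, append = TRUE,
                                      col_names = TRUE))
  } else if (format == "json") {
    jsonlite::write_json(list(meta = meta, data = data), path,
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  } else {
    lines <- c(
      paste0("# ", class(x)[[1]], " report"), "",
      paste0("- ", names(meta), ": ", unlist(meta)), "",
      knitr_free_md_table(data)
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname render_report
#' @return For `read_report_json`, a list with elements `meta` and
#'   `data` (a tibble), round-tripping [render_report()]'s json output.
#' @export
read_report_json <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  r$data <- as_tibble(r$data)
  r
}

.report_meta <- function(x) {
  meta <- list(package = "denovoherd",
               version = as.character(utils::packageVersion("denovoherd")))
  if (inherits(x, "denovo_screen")) {
    cfg <- attr(x, "config")
    meta <- c(meta, list(
      mode = attr(x, "mode"),
      qual_min = if (isTRUE(attr(x, "relaxed"))) cfg$relaxed_qual_min else cfg$qual_min,
      mq_min = cfg$mq_min,
      density_window_bp = cfg$density_window_bp,
      density_max_private = cfg$density_max_private))
  } else if (inherits(x, "window_scan")) {
    p <- attr(x, "params")
    meta <- c(meta, list(
      window_size = p$window_size, step = p$step,
      min_carriers = p$min_carriers,
      n_perm = attr(x, "n_perm") %||% NA,
      seed = attr(x, "seed") %||% NA))
  }
  meta$config_hash <- rlang::hash(meta)
  meta
}

.report_data <- function(x) {
  if (inherits(x, "denovo_screen")) {
    cand <- tidy(x)
    cand$dosage <- NULL
    return(cand)
  }
  if (inherits(x, "window_scan")) return(tidy(x))
  as_tibble(x)
}

# minimal pipe-table rendering (avoids a knitr dependency)
knitr_free_md_table <- function(df) {
  if (!nrow(df)) return("(no rows)")
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
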
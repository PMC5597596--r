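#' Genetic contribution of a founder to every individual
#'
#' The contribution of a founder to an individual's gene pool: 1 for the
#' founder itself, and the parental average
#' `c(i) = (c(sire) + c(dam)) / 2` down the pedigree, with unknown
#' parents contributing 0. For a mutation that arose de novo in the
#' founder, `c(i)` is the probability that individual `i` carries the
#' founder's mutant allele under single-path transmission.
#'
#' @param pedigree validated pedigree tibble (see [read_pedigree()] /
#'   [as_pedigree()]).
#' @param founder founder id; must be present in the pedigree.
#' @return Tibble (`id`, `contribution`) for every individual.
#' @export
founder_contribution <- function(pedigree, founder) {
  ped <- as_pedigree(pedigree)
  if (!founder %in% ped$id) {
    abort(paste0("founder '", founder, "' not in pedigree"))
  }
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  cc <- numeric(nrow(ped))
  cc[idx[[founder]]] <- 1
  for (i in seq_len(nrow(ped))) {   # topological order: parents first
    if (ped$id[i] == founder) next
    cs <- if (is.na(ped$sire[i])) 0 else cc[idx[[ped$sire[i]]]]
    cd <- if (is.na(ped$dam[i])) 0 else cc[idx[[ped$dam[i]]]]
    cc[i] <- (cs + cd) / 2
  }
  tibble(id = ped$id, contribution = cc)
}

#' Risk of at-risk matings producing a homozygous mutant calf
#'
#' For each calf, the probability of being homozygous for a mutation
#' that arose de novo (heterozygously) in the founder is scored as
#' `c_sire * c_dam / 4`, the product of the parents' founder
#' contributions over four. Calves with zero risk — at least one parental
#' line not descending from the founder — are omitted.
#'
#' @inheritParams founder_contribution
#' @param calves ids to score (default: every individual with at least
#'   one known parent).
#' @return Tibble (`id`, `birth_year`, `c_sire`, `c_dam`, `risk`) sorted
#'   by decreasing risk.
#' @export
mating_risk <- function(pedigree, founder, calves = NULL) {
  ped <- as_pedigree(pedigree)
  contrib <- founder_contribution(ped, founder)
  cc <- setNames(contrib$contribution, contrib$id)
  calves <- calves %||% ped$id[!is.na(ped$sire) | !is.na(ped$dam)]
  ped %>%
    filter(.data$id %in% calves) %>%
    mutate(c_sire = ifelse(is.na(.data$sire), 0, cc[.data$sire]),
           c_dam = ifelse(is.na(.data$dam), 0, cc[.data$dam]),
           risk = .data$c_sire * .data$c_dam / 4) %>%
    filter(.data$risk > 0) %>%
    select("id", "birth_year", "c_sire", "c_dam", "risk") %>%
    arrange(desc(.data$risk), .data$id)
}

#' Expected number of affected homozygotes per birth year
#'
#' Sums the per-calf risks over a birth cohort: the expected count of
#' homozygous mutant calves born that year, with the cohort size and mean
#' risk alongside.
#'
#' @param mating_risks tibble from [mating_risk()].
#' @param year optional birth year; when `NULL`, one row per year.
#' @return Tibble (`birth_year`, `n_calves`, `mean_risk`,
#'   `expected_affected`).
#' @export
expected_affected <- function(mating_risks, year = NULL) {
  out <- mating_risks %>%
    group_by(birth_year = .data$birth_year) %>%
    summarise(n_calves = n(), mean_risk = mean(.data$risk),
              expected_affected = sum(.data$risk), .groups = "drop")
  if (!is.null(year)) {
    out <- filter(out, .data$birth_year == year)
    if (!nrow(out)) {
      out <- tibble(birth_year = as.integer(year), n_calves = 0L,
                    mean_risk = 0, expected_affected = 0)
    }
  }
  out
}

#' Wright's coefficient of inbreeding
#'
#' `F(i)` is the probability that an individual's two alleles at a locus
#' are identical by descent, computed by the tabular (recursive kinship)
#' method: `F(i) = kinship(sire_i, dam_i)`, with
#' `kinship(x, x) = (1 + F(x)) / 2` and unknown parents taken as
#' unrelated and non-inbred.
#'
#' @inheritParams founder_contribution
#' @param individuals ids to report (default: all).
#' @return Tibble (`id`, `F`).
#' @export
inbreeding_coefficient <- function(pedigree, individuals = NULL) {
  ped <- as_pedigree(pedigree)
  individuals <- individuals %||% ped$id
  missing <- setdiff(individuals, ped$id)
  if (length(missing)) {
    abort(paste0("individual(s) not in pedigree: ",
                 paste(missing, collapse = ", ")))
  }
  rank <- setNames(seq_len(nrow(ped)), ped$id)
  sire <- setNames(ped$sire, ped$id)
  dam <- setNames(ped$dam, ped$id)
  memo <- new.env(parent = emptyenv())
  phi <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    if (rank[[x]] < rank[[y]]) { tmp <- x; x <- y; y <- tmp }
    key <- paste(x, y)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (x == y) {
      (1 + phi(sire[[x]], dam[[x]])) / 2
    } else {
      # x has the higher topological rank, so x is not an ancestor of y
      (phi(sire[[x]], y) + phi(dam[[x]], y)) / 2
    }
    memo[[key]] <- val
    val
  }
  tibble(id = individuals,
         F = vapply(individuals, function(i) phi(sire[[i]], dam[[i]]), 0.0,
                    USE.NAMES = FALSE))
}

#' Gene-dropping simulation of a founder mutation
#'
#' Drops one heterozygous mutant allele from the founder down the
#' pedigree `n_drops` times, each meiosis transmitting either parental
#' allele with probability 1/2, and reports per-individual Monte-Carlo
#' carrier and homozygote probabilities. This is the exact counterpart of
#' the `c_sire * c_dam / 4` risk formula, which assumes a single
#' transmission path per parent; on pedigrees with inbreeding loops the
#' two can differ, and the simulation quantifies the gap.
#'
#' @inheritParams founder_contribution
#' @param n_drops number of replicate drops (default 10,000).
#' @param seed RNG seed.
#' @return Tibble (`id`, `p_carrier`, `p_hom`) of Monte-Carlo frequencies.
#' @export
gene_drop <- function(pedigree, founder, n_drops = 10000L, seed = NULL) {
  ped <- as_pedigree(pedigree)
  if (!founder %in% ped$id) {
    abort(paste0("founder '", founder, "' not in pedigree"))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  # allele slot 1 = from sire line, slot 2 = from dam line
  A1 <- matrix(FALSE, n, n_drops)
  A2 <- matrix(FALSE, n, n_drops)
  fi <- idx[[founder]]
  A1[fi, ] <- TRUE                     # the founder's single mutant allele
  transmit <- function(p) {
    pick <- runif(n_drops) < 0.5
    ifelse(pick, A1[p, ], A2[p, ])
  }
  for (i in seq_len(n)) {
    if (i == fi) next
    if (!is.na(ped$sire[i])) A1[i, ] <- transmit(idx[[ped$sire[i]]])
    if (!is.na(ped$dam[i])) A2[i, ] <- transmit(idx[[ped$dam[i]]])
  }
  tibble(id = ped$id,
         p_carrier = rowMeans(A1 | A2),
         p_hom = rowMeans(A1 & A2))
}
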
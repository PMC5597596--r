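# founder F mated to two unrelated dams: son S and daughter D are
# paternal half-sibs, and C is their offspring
trio_ped <- function() {
  tibble::tibble(
    id = c("F", "D0", "D1", "S", "D", "C"),
    sire = c(NA, NA, NA, "F", "F", "S"),
    dam = c(NA, NA, NA, "D0", "D1", "D"),
    sex = c("M", "F", "F", "M", "F", "M"),
    birth_year = c(2000L, 2000L, 2000L, 2003L, 2003L, 2006L))
}

test_that("founder contribution follows the parental-average recursion", {
  ped <- trio_ped()
  cc <- founder_contribution(ped, "F")
  get <- function(id) cc$contribution[cc$id == id]
  expect_equal(get("F"), 1)
  expect_equal(get("S"), 0.5)      # child of founder x unrelated dam
  expect_equal(get("C"), 0.5)      # both parents carry 0.5
  expect_equal(get("D0"), 0)
  expect_error(founder_contribution(ped, "NOBODY"), "NOBODY")

  # great-grandchild through a single line: (1/2)^3
  line <- tibble::tibble(
    id = c("F", "A", "B", "G"),
    sire = c(NA, "F", "A", "B"),
    dam = c(NA, NA, NA, NA),
    sex = "M", birth_year = c(2000L, 2003L, 2006L, 2009L))
  cc2 <- founder_contribution(line, "F")
  expect_equal(cc2$contribution[cc2$id == "G"], 0.125)
  expect_equal(cc2$contribution[cc2$id == "G"],
               contribution_oracle(line, "F", "G"))
})

test_that("contribution equals the path-counting oracle on simulated pedigrees", {
  for (s in c(3L, 5L)) {
    sim <- simulate_founder_pedigree(seed = s, n_generations = 2L,
                                     n_affected = 3L)
    cc <- founder_contribution(sim$pedigree, "FOUNDER")
    pick <- sample(nrow(cc), 25)
    for (i in pick) {
      expect_equal(cc$contribution[i],
                   contribution_oracle(sim$pedigree, "FOUNDER", cc$id[i]))
    }
  }
})

test_that("adding a generation never increases the contribution", {
  sim <- simulate_founder_pedigree(seed = 11, n_generations = 2L,
                                   n_affected = 0L)
  cc <- founder_contribution(sim$pedigree, "FOUNDER")
  ped <- sim$pedigree
  kids <- ped[!is.na(ped$sire) & !is.na(ped$dam), ]
  for (i in seq_len(min(20, nrow(kids)))) {
    c_child <- cc$contribution[cc$id == kids$id[i]]
    c_par <- max(cc$contribution[cc$id == kids$sire[i]],
                 cc$contribution[cc$id == kids$dam[i]])
    expect_lte(c_child, c_par)
  }
})

test_that("mating risk scores c_sire * c_dam / 4 and omits zero-risk calves", {
  ped <- trio_ped()
  mr <- mating_risk(ped, "F")
  # son(0.5) x daughter(0.5) -> 1/16
  expect_identical(mr$id, "C")
  expect_equal(mr$risk, 1 / 16)

  # sire = founder, dam unrelated -> omitted
  ped2 <- tibble::tibble(
    id = c("F", "D0", "K"), sire = c(NA, NA, "F"), dam = c(NA, NA, "D0"),
    sex = c("M", "F", "M"), birth_year = c(2000L, 2000L, 2003L))
  expect_identical(nrow(mating_risk(ped2, "F")), 0L)
})

test_that("the 1/16 formula agrees with gene dropping within 3 binomial SE", {
  ped <- trio_ped()
  n <- 100000L
  gd <- gene_drop(ped, "F", n_drops = n, seed = 12L)
  p_hat <- gd$p_hom[gd$id == "C"]
  se <- sqrt((1 / 16) * (15 / 16) / n)
  expect_lt(abs(p_hat - 1 / 16), 3 * se)
  # carrier probability of a founder child is 1/2
  p_c <- gd$p_carrier[gd$id == "S"]
  expect_lt(abs(p_c - 0.5), 3 * sqrt(0.25 / n))
})

test_that("expected affected counts are cohort sums of risks", {
  # 16 calves each at risk 1/16 -> expectation 1.0
  risks <- tibble::tibble(id = sprintf("c%02d", 1:16), birth_year = 2013L,
                          c_sire = 0.5, c_dam = 0.5, risk = 1 / 16)
  ea <- expected_affected(risks, 2013L)
  expect_equal(ea$expected_affected, 1.0)
  expect_identical(ea$n_calves, 16L)
  # a year with no at-risk calves
  ea0 <- expected_affected(risks, 1999L)
  expect_equal(ea0$expected_affected, 0)
  expect_identical(ea0$n_calves, 0L)
})

test_that("expected counts match gene-dropping on a simulated pedigree", {
  sim <- simulate_founder_pedigree(seed = 37, n_affected = 0L)
  mr <- mating_risk(sim$pedigree, "FOUNDER")
  ea <- expected_affected(mr)
  n <- 1000L
  gd <- gene_drop(sim$pedigree, "FOUNDER", n_drops = n, seed = 8L)
  joined <- dplyr::inner_join(
    dplyr::select(sim$pedigree, "id", "birth_year"), gd, by = "id")
  for (yr in ea$birth_year) {
    ids <- mr$id[mr$birth_year == yr]
    sim_mean <- sum(joined$p_hom[joined$id %in% ids])
    expected <- ea$expected_affected[ea$birth_year == yr]
    # binomial SE of a sum of independent indicators, bounded by sqrt(E)
    se <- sqrt(sum(joined$p_hom[joined$id %in% ids] *
                   (1 - joined$p_hom[joined$id %in% ids]) / n))
    expect_lt(abs(sim_mean - expected), 3 * se + 1e-9)
  }
})

test_that("inbreeding coefficients reproduce textbook closed forms", {
  # outbred trio
  ped <- tibble::tibble(
    id = c("S", "D", "C"), sire = c(NA, NA, "S"), dam = c(NA, NA, "D"),
    sex = c("M", "F", "M"), birth_year = c(2000L, 2000L, 2003L))
  expect_equal(inbreeding_coefficient(ped, "C")$F, 0)

  # full-sib mating offspring: F = 1/4
  fs <- tibble::tibble(
    id = c("S", "D", "A", "B", "X"),
    sire = c(NA, NA, "S", "S", "A"),
    dam = c(NA, NA, "D", "D", "B"),
    sex = c("M", "F", "M", "F", "M"),
    birth_year = c(2000L, 2000L, 2003L, 2003L, 2006L))
  expect_equal(inbreeding_coefficient(fs, "X")$F, 0.25)

  # half-sib mating offspring: F = 1/8
  hs <- trio_ped()
  expect_equal(inbreeding_coefficient(hs, "C")$F, 0.125)

  # F equals total autozygosity summed over the four founder alleles;
  # each gene_drop tracks one allele of one founder, and by symmetry the
  # untracked allele of the same founder contributes the same amount:
  # F = 2 * p_hom(S allele) + 2 * p_hom(D allele)
  gd <- gene_drop(fs, "S", n_drops = 50000L, seed = 3L)
  gd2 <- gene_drop(fs, "D", n_drops = 50000L, seed = 4L)
  f_hat <- 2 * gd$p_hom[gd$id == "X"] + 2 * gd2$p_hom[gd2$id == "X"]
  expect_lt(abs(f_hat - 0.25), 0.02)
})

test_that("unknown individuals are rejected", {
  expect_error(inbreeding_coefficient(trio_ped(), "GHOST"), "GHOST")
})
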
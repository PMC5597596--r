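test_that("window enumeration has the right geometry and carrier logic", {
  haps <- setNames(rep(list(strrep("A", 12)), 2), c("x", "y"))
  panel <- panel_from_strings(haps, haps)
  # 12 markers, window 10, step 1 -> 3 windows
  w <- enumerate_window_haplotypes(panel, "1")
  expect_identical(unique(w$window), 1:3)
  # identical haplotypes -> one allele per window carried by all
  expect_identical(nrow(w), 3L)
  expect_true(all(w$n_carrier == 2L))
  expect_identical(w$dosage[[1]], c(x = 2L, y = 2L))

  # 10 markers, window 10 -> exactly one window
  haps10 <- lapply(haps, substr, 1, 10)
  panel10 <- panel_from_strings(haps10, haps10)
  expect_identical(unique(enumerate_window_haplotypes(panel10, "1")$window), 1L)

  # dosage distinguishes het from hom carriers
  p2 <- panel_from_strings(list(a = strrep("B", 10), b = strrep("B", 10)),
                           list(a = strrep("A", 10), b = strrep("B", 10)))
  w2 <- enumerate_window_haplotypes(p2, "1")
  bb <- w2[w2$allele == strrep("B", 10), ]
  expect_identical(bb$dosage[[1]], c(a = 1L, b = 2L))
})

test_that("Fisher test equals enumeration and fisher.test on key tables", {
  # the printed carrier table
  expect_equal(fisher_window_test(12, 49, 2, 89),
               fisher_oracle(12, 49, 2, 89), tolerance = 1e-12)
  expect_equal(fisher_window_test(12, 49, 2, 89),
               stats::fisher.test(matrix(c(12, 37, 2, 87), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-9)
  # degenerate tables
  expect_equal(fisher_window_test(5, 10, 5, 10), 1)
  expect_equal(fisher_window_test(0, 10, 0, 10), 1)
  # zero-size group errors
  expect_error(fisher_window_test(0, 0, 1, 10), "positive")

  # random spot-check against stats::fisher.test
  set.seed(1)
  for (i in 1:50) {
    m <- sample(2:40, 1); n <- sample(2:40, 1)
    a <- sample(0:m, 1); b <- sample(0:n, 1)
    expect_equal(fisher_window_test(a, m, b, n),
                 stats::fisher.test(matrix(c(a, m - a, b, n - b), 2,
                                           byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("dominant scan finds the planted segment and honours the control cap", {
  sim <- simulate_halfsib_panel(seed = 13)
  ds <- dominant_scan(sim$panel, case_label = "mildly_affected",
                      control_label = "unaffected")
  expect_gt(nrow(ds), 0L)
  hit <- ds[ds$chrom == sim$truth$causal_chrom &
            ds$start_bp <= sim$truth$causal_center_bp &
            ds$end_bp >= sim$truth$causal_center_bp, ]
  expect_identical(nrow(hit), 1L)

  # all cases identical to all controls -> empty under any cap < 1
  same <- strrep("AB", 10)
  p_eq <- panel_from_strings(
    list(c1 = same, c2 = same, k1 = same, k2 = same),
    list(c1 = same, c2 = same, k1 = same, k2 = same),
    labels = tibble::tibble(id = c("c1", "c2", "k1", "k2"),
                            label = c("case", "case", "control", "control")))
  expect_identical(nrow(dominant_scan(p_eq, max_control_freq = 0.5)), 0L)

  # max_control_freq = 0 with one carrier control -> empty
  shared <- strrep("B", 20); other <- strrep("A", 20)
  p_one <- panel_from_strings(
    list(c1 = shared, c2 = shared, k1 = shared, k2 = other),
    list(c1 = other, c2 = other, k1 = other, k2 = other),
    labels = tibble::tibble(id = c("c1", "c2", "k1", "k2"),
                            label = c("case", "case", "control", "control")))
  expect_identical(nrow(dominant_scan(p_one, max_control_freq = 0)), 0L)
  expect_gt(nrow(dominant_scan(p_one, max_control_freq = 0.5)), 0L)
})

test_that("modifier scan reports the planted carrier counts and percentages", {
  sim <- simulate_halfsib_panel(seed = 29)
  tr <- sim$truth
  scan <- modifier_scan(sim$panel,
                        maternal_only_chroms = tr$maternal_only_chroms)
  # the genome-wide best window overlaps the planted span
  best <- scan[which.min(scan$fisher_p), ]
  expect_identical(best$chrom, tr$modifier_chrom)
  expect_lte(best$start_marker, tr$modifier_span_markers[2])
  expect_gte(best$end_marker, tr$modifier_span_markers[1])
  # the window at the span start carries the planted allele at exactly
  # the configured 12/49 vs 2/89 design
  planted <- scan[scan$chrom == tr$modifier_chrom &
                  scan$start_marker == tr$modifier_span_markers[1] &
                  scan$allele == substr(tr$modifier_pattern, 1, 10), ]
  expect_identical(nrow(planted), 1L)
  expect_identical(planted$count_case_carrier, 12L)
  expect_identical(planted$count_control_carrier, 2L)
  # carrier percentages as reported: 24.5% and 2.2%
  expect_equal(round(100 * planted$count_case_carrier / planted$n_case, 1),
               24.5)
  expect_equal(round(100 * planted$count_control_carrier / planted$n_control,
                     1), 2.2)
})

test_that("single-window single-allele panel yields one scan row", {
  same <- strrep("A", 10)
  p <- panel_from_strings(
    list(a = same, b = same), list(a = same, b = same),
    labels = tibble::tibble(id = c("a", "b"),
                            label = c("mildly_affected", "unaffected")))
  scan <- modifier_scan(p, min_carriers = 1L)
  expect_identical(nrow(scan), 1L)
  expect_equal(scan$fisher_p, 1)
})

test_that("permutation empirical p follows the add-one rule and is seeded", {
  sim <- simulate_halfsib_panel(seed = 57, n_chromosomes = 2L,
                                n_markers = 60L, n_case = 20L,
                                n_control = 30L, causal_chrom = "1",
                                modifier_chrom = "2",
                                modifier_carriers_case = 10L,
                                modifier_carriers_control = 0L)
  scan <- modifier_scan(sim$panel,
                        maternal_only_chroms = sim$truth$maternal_only_chroms)
  res <- permutation_empirical_p(scan, n_perm = 200L, seed = 5L)
  # empirical p bounded below by 1/(n_perm+1), above by 1
  expect_true(all(res$empirical_p_genomewide >= 1 / 201))
  expect_true(all(res$empirical_p_genomewide <= 1))
  # a window whose observed p is 1 can never beat a permutation minimum
  expect_true(all(res$empirical_p_genomewide[res$fisher_p == 1] == 1))
  # chromosome-wide p <= genome-wide p at the best window (fewer minima
  # can undercut the observed p within one chromosome)
  best <- res[which.min(res$fisher_p), ]
  expect_lte(best$empirical_p_chromwide, best$empirical_p_genomewide)

  # identical seed reproduces; different seed stays within Monte Carlo noise
  res2 <- permutation_empirical_p(scan, n_perm = 200L, seed = 5L)
  expect_identical(res$empirical_p_genomewide, res2$empirical_p_genomewide)
  res3 <- permutation_empirical_p(scan, n_perm = 200L, seed = 6L)
  p1 <- res$empirical_p_genomewide
  p3 <- res3$empirical_p_genomewide
  # both estimates carry Monte-Carlo noise: pooled two-sample tolerance
  pbar <- (p1 + p3) / 2
  tol <- 3 * sqrt(2 * pmax(pbar * (1 - pbar), 0.25 / 201) / 200)
  expect_gte(mean(abs(p1 - p3) <= tol + 1e-12), 0.99)
})

test_that("permutation can preserve family strata", {
  sim <- simulate_halfsib_panel(seed = 58, n_chromosomes = 2L,
                                n_markers = 40L, n_case = 12L,
                                n_control = 12L, causal_chrom = "1",
                                modifier_chrom = "2", causal_span = 20L,
                                modifier_span = 12L,
                                modifier_carriers_case = 4L,
                                modifier_carriers_control = 1L)
  scan <- modifier_scan(sim$panel, min_carriers = 2L,
                        maternal_only_chroms = sim$truth$maternal_only_chroms)
  ids <- attr(scan, "ids")
  strata <- setNames(rep(c(1, 2), length.out = length(ids)), ids)
  res <- permutation_empirical_p(scan, n_perm = 50L, seed = 9L,
                                 permute_within = strata)
  expect_true(all(res$empirical_p_genomewide >= 1 / 51))
})

test_that("ancestral carrier search separates mutation carriers from ancestors", {
  sim <- simulate_halfsib_panel(seed = 71, plant_ancestral = TRUE)
  tr <- sim$truth
  span <- tr$causal_span_markers
  hits <- ancestral_carrier_search(
    sim$panel, tr$causal_chrom, span[1], span[2], tr$causal_pattern,
    mutation_carriers = tr$case_ids,
    reference = tr$sire_hap1[[tr$causal_chrom]])
  # every case matches on its paternal haplotype; the planted ancestral
  # carrier matches maternally without the mutation
  anc <- hits[hits$ancestral, ]
  expect_identical(anc$id, tr$ancestral_carrier_id)
  expect_identical(anc$hap, "M")
  expect_true(all(tr$case_ids %in% hits$id[hits$mutation_carrier]))
  # matches extend at least over the span itself
  expect_true(all(hits$ext_start_marker <= span[1]))
  expect_true(all(hits$ext_end_marker >= span[2]))

  # no individual matches an impossible haplotype
  none <- ancestral_carrier_search(
    sim$panel, tr$causal_chrom, span[1], span[1] + 1L, "ZZ")
  expect_identical(nrow(none), 0L)

  # span validation
  expect_error(
    ancestral_carrier_search(sim$panel, tr$causal_chrom, 1L, 9999L, "A"),
    "span")
})
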
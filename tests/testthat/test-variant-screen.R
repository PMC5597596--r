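test_that("quality filter respects inclusive boundaries and relaxed mode", {
  v <- dplyr::bind_rows(
    vrow(pos = 1L, qual = 30, mq = 30),
    vrow(pos = 2L, qual = 29.9, mq = 50),
    vrow(pos = 3L, qual = 50, mq = 29.9),
    vrow(pos = 4L, qual = 15, mq = 30),
    vrow(pos = 5L, qual = 14.9, mq = 30))
  expect_identical(filter_quality(v)$pos, 1L)
  # relaxed mode only lowers the QUAL threshold; MQ stays at 30
  expect_identical(filter_quality(v, relaxed = TRUE)$pos, c(1L, 2L, 4L))
})

test_that("het + panel-private selection applies both rules", {
  # 10 variants: 7 in the panel, one of the remaining 3 homozygous -> 2
  v <- vrow(pos = as.integer(1:10 * 100))
  v$genotype[9] <- "hom_alt"
  panel <- control_panel(v[1:7, ], n_genomes = 1230)
  kept <- select_het_private(v, panel)
  expect_identical(kept$pos, c(800L, 1000L))

  # het variant present in the panel is removed
  expect_identical(nrow(select_het_private(v[1, ], panel)), 0L)
})

test_that("strand filter removes exactly the one-read-per-strand records", {
  v <- dplyr::bind_rows(
    vrow(pos = 1L, fwd = 1L, rev = 1L),
    vrow(pos = 2L, fwd = 2L, rev = 1L),
    vrow(pos = 3L, fwd = 1L, rev = 2L),
    vrow(pos = 4L, fwd = NA, rev = NA))
  expect_identical(strand_filter(v)$pos, c(2L, 3L, 4L))
})

test_that("consequence filter keeps the deleterious classes only", {
  v <- vrow(pos = as.integer(1:5 * 100))
  ann <- dplyr::bind_rows(
    ann_row(v[1, ], "synonymous"),
    ann_row(v[2, ], "frameshift"),
    ann_row(v[3, ], "missense", "tolerated"),
    ann_row(v[4, ], "missense", "deleterious"))
  # v[5, ] unannotated -> treated as non-coding
  kept <- consequence_filter(v, ann)
  expect_identical(kept$pos, c(200L, 400L))
  expect_identical(kept$consequence, c("frameshift", "missense"))

  annx <- ann_row(v[1, ], "mystery_class")
  expect_warning(out <- consequence_filter(v[1, ], annx), "mystery_class")
  expect_identical(nrow(out), 0L)
})

test_that("trio subtraction removes variants carried by either parent", {
  prob <- vrow(pos = as.integer(1:9 * 1000), sample_id = "P")
  sire <- prob[1:5, ]
  dam <- prob[6:8, ]
  expect_identical(trio_subtract(prob, sire, dam)$pos, 9000L)

  # hom_ref parental records do not carry the allele
  sire_ref <- dplyr::mutate(sire, genotype = "hom_ref")
  expect_identical(nrow(trio_subtract(prob, sire_ref, dam)), 6L)
})

test_that("private density matches a brute-force scan, inclusive at 2.5 Mb", {
  cand <- vrow(pos = 10000000L)
  # no other private variant on the chromosome -> counts itself
  expect_identical(private_density(cand, cand)$private_density, 1L)

  # a variant at exactly 2,500,000 bp is counted
  at_edge <- dplyr::bind_rows(cand, vrow(pos = 12500000L),
                              vrow(pos = 12500001L))
  expect_identical(private_density(cand, at_edge)$private_density, 2L)

  # 13 private variants scattered over +/- 4 Mb vs an O(n) oracle
  set.seed(7)
  offs <- as.integer(sample(-4000000:4000000, 13))
  priv <- dplyr::bind_rows(cand, vrow(pos = cand$pos + offs))
  oracle <- sum(abs(priv$pos - cand$pos) <= 2500000L)
  expect_identical(private_density(cand, priv)$private_density, oracle)

  # other chromosomes never contribute
  far <- dplyr::bind_rows(cand, vrow(chrom = "2", pos = cand$pos + 1000L))
  expect_identical(private_density(cand, far)$private_density, 1L)
})

test_that("recent-mutation classification uses the <= 10 boundary", {
  cand <- vrow(pos = 1000L)
  d <- function(n) classify_recent(dplyr::mutate(cand, private_density = n))
  expect_true(d(10L)$classified_recent)
  expect_false(d(11L)$classified_recent)
  expect_true(d(1L)$classified_recent)
})

test_that("interval restriction is 1-based inclusive", {
  cand <- dplyr::bind_rows(
    vrow(pos = 100L), vrow(pos = 200L), vrow(pos = 300L),
    vrow(chrom = "2", pos = 200L))
  kept <- restrict_to_interval(cand, "1", 100L, 200L)
  expect_identical(kept$pos, c(100L, 200L))
  expect_true(all(kept$chrom == "1"))
  expect_error(restrict_to_interval(cand, "1", 300L, 100L))
})

test_that("cascade stages are monotone and per-record filters commute", {
  sim <- simulate_denovo_genome(seed = 21, confound_size = 25L)
  scr <- screen_genome(sim$proband, sim$panel, sim$annotations,
                       mode = "sire_screen")
  trail <- filter_trail(scr)
  expect_true(all(trail$n_out <= trail$n_in))
  expect_true(all(diff(trail$n_out) <= trail$n_in[-1] - trail$n_out[-1] + 0))

  # the three pure per-record filters give the same set in any order
  v <- sim$proband
  cfg <- filter_config()
  ann <- sim$annotations
  a <- consequence_filter(strand_filter(filter_quality(v, cfg)), ann, cfg)
  b <- strand_filter(consequence_filter(filter_quality(v, cfg), ann, cfg))
  c <- filter_quality(consequence_filter(strand_filter(v), ann, cfg), cfg)
  expect_setequal(variant_key(a), variant_key(b))
  expect_setequal(variant_key(a), variant_key(c))
})

test_that("screen recovers exactly the planted variant on a clean background", {
  for (s in c(101L, 102L, 103L)) {
    sim <- simulate_denovo_genome(seed = s)
    scr <- screen_genome(sim$proband, sim$panel, sim$annotations)
    expect_identical(variant_key(scr), sim$truth$planted_key)
  }
  # empty input
  sim <- simulate_denovo_genome(seed = 101L)
  empty <- sim$proband[0, ]
  scr <- screen_genome(empty, sim$panel, sim$annotations)
  expect_identical(nrow(tidy(scr)), 0L)
})

test_that("sire screen rejects the planted rare-haplotype confound", {
  sim <- simulate_denovo_genome(seed = 31, confound_size = 25L)
  scr <- screen_genome(sim$proband, sim$panel, sim$annotations,
                       mode = "sire_screen")
  expect_identical(variant_key(scr), sim$truth$planted_key)
  # the confound's deleterious member passed every per-record filter but
  # fails the density rule
  pre <- screen_genome(sim$proband, sim$panel, sim$annotations,
                       mode = "dominant_case")
  expect_true(sim$truth$confound_deleterious_key %in% variant_key(pre))
  dens <- private_density(
    pre[variant_key(pre) == sim$truth$confound_deleterious_key, ],
    select_het_private(filter_quality(sim$proband), sim$panel))
  expect_gte(dens$private_density, 25L)
})

test_that("trio mode leaves only the de novo variant", {
  sim <- simulate_denovo_genome(seed = 41, n_inherited_deleterious = 8L)
  pre <- screen_genome(sim$proband, sim$panel, sim$annotations)
  expect_identical(nrow(tidy(pre)), 9L)  # planted + 8 inherited
  scr <- screen_genome(sim$proband, sim$panel, sim$annotations,
                       mode = "trio", sire_variants = sim$sire,
                       dam_variants = sim$dam)
  expect_identical(variant_key(scr), sim$truth$planted_key)
})
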
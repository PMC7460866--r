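test_that("gaps are the maximal uncovered intervals including chromosome ends", {
  tads <- tibble::tibble(chrom = "1", start = c(100, 500), end = c(300, 800),
                         name = "TAD")
  g <- complement_gaps(tads, c("1" = 1000))
  expect_equal(g$start, c(0, 300, 800))
  expect_equal(g$end, c(100, 500, 1000))
  expect_true(all(g$name == "gap"))

  # full coverage -> no gaps; no TADs -> one whole-chromosome gap
  full <- tibble::tibble(chrom = "1", start = 0, end = 1000, name = "TAD")
  expect_equal(nrow(complement_gaps(full, c("1" = 1000))), 0L)
  g2 <- complement_gaps(tads[0, ], c("1" = 1000))
  expect_equal(list(g2$start, g2$end), list(0, 1000))

  # TAD beyond the chromosome end is clipped with a warning
  over <- tibble::tibble(chrom = "1", start = 900, end = 1200, name = "TAD")
  expect_warning(g3 <- complement_gaps(over, c("1" = 1000)), "clipped")
  expect_equal(list(g3$start, g3$end), list(0, 900))

  # overlapping TADs are merged before complementing
  ov <- tibble::tibble(chrom = "1", start = c(100, 200), end = c(400, 600),
                       name = "TAD")
  expect_warning(g4 <- complement_gaps(ov, c("1" = 1000)), "merged")
  expect_equal(list(g4$start, g4$end), list(c(0, 600), c(100, 1000)))
})

test_that("bin assignment follows the proportional-floor rule with closed boundaries", {
  # interval [100, 300): VCF pos 101 is the first base, pos 300 the last
  expect_equal(bin_counts(101, 100, 300)[1], 1L)
  expect_equal(bin_counts(300, 100, 300)[10], 1L)
  expect_equal(sum(bin_counts(c(100, 301), 100, 300)), 0L)  # outside
  # translation invariance
  withr::with_seed(3, {
    pos <- sample(1001:2000, 200)
    expect_equal(bin_counts(pos, 1000, 2000),
                 bin_counts(pos + 55000, 56000, 57000))
  })
  # interval shorter than the bin count falls back to a single bin
  expect_warning(b <- bin_counts(c(3, 5), 0, 8), "single-bin")
  expect_equal(b, c(2L, rep(0L, 9)))
})

test_that("uniform variants fill bins evenly (multinomial flatness)", {
  withr::with_seed(4, {
    n <- 10000
    pos <- sample.int(5e5, n)
    counts <- bin_counts(pos, 0, 5e5)
    expect_gt(stats::chisq.test(counts)$p.value, 0.001)
    expect_true(all(abs(counts - n / 10) < 3 * sqrt(n * 0.1 * 0.9)))
  })
})

test_that("TADs and gaps partition the chromosome and conserve variant totals", {
  fx <- sim_fixture()
  v <- fx$vars$treated[[1]]
  prof <- tad_bin_profile(v, fx$ref$tads, fx$ref$chrom_lengths)
  per_chrom <- dplyr::count(v, chrom)
  tot <- dplyr::summarise(dplyr::group_by(prof, chrom), n = sum(count),
                          .groups = "drop")
  expect_equal(dplyr::arrange(tot, chrom)$n,
               dplyr::arrange(per_chrom, chrom)$n)
  # domains cover each chromosome exactly
  cov <- prof |>
    dplyr::distinct(chrom, domain_id, start, end) |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(covered = sum(end - start), .groups = "drop")
  expect_equal(cov$covered,
               unname(as.numeric(fx$ref$chrom_lengths[cov$chrom])))
  # aggregation is invariant to domain processing order
  shuf <- prof[sample.int(nrow(prof)), ]
  expect_equal(dplyr::arrange(bin_aggregate(shuf), chrom, location, bin),
               dplyr::arrange(bin_aggregate(prof), chrom, location, bin))
})

test_that("inside:outside ratios report raw and length-normalized values", {
  prof <- tibble::tibble(
    chrom = "1",
    domain_id = rep(c("1.inside.1", "1.outside.1"), each = 10),
    location = rep(c("inside", "outside"), each = 10),
    start = rep(c(0, 500), each = 10), end = rep(c(500, 1500), each = 10),
    bin = rep(1:10, 2),
    count = c(rep(20, 10), rep(10, 10)))
  r <- inside_outside_ratio(prof)
  expect_equal(r$raw_ratio, 2.0)           # 200 vs 100
  expect_equal(r$norm_ratio, 4.0)          # density 0.4 vs 0.1
  # equal densities (counts proportional to covered length) normalize to 1
  prof$count <- c(rep(10, 10), rep(20, 10))
  r <- inside_outside_ratio(prof)
  expect_equal(r$norm_ratio, 1.0)
  # no outside events: ratios reported absent
  prof$count <- c(rep(10, 10), rep(0, 10))
  expect_true(all(is.na(inside_outside_ratio(prof)[c("raw_ratio", "norm_ratio")])))
})

test_that("a 2x inside-density fixture recovers a normalized ratio of about 2", {
  cfg <- small_sim_config(seed = 77, shared_fraction = 0,
                          error_variant_rate = 0,
                          n_treated_variants = 8000L,
                          per_chromosome_weights = c(1, 1, 1),
                          tad_boundary_weight = 1)
  ref <- sim_reference(cfg)
  vars <- suppressWarnings(sim_variants(cfg, ref))
  snvs <- dplyr::filter(classify_indel(vars$treated[[1]]),
                        variant_type == "SNV")
  prof <- tad_bin_profile(snvs, ref$tads, ref$chrom_lengths)
  io <- inside_outside_ratio(prof)
  pooled <- (sum(io$count_inside) / sum(io$length_inside)) /
    (sum(io$count_outside) / sum(io$length_outside))
  se <- 2 * sqrt(1 / sum(io$count_inside) + 1 / sum(io$count_outside))
  expect_lt(abs(pooled - cfg$tad_inside_weight), 3 * se)
})

test_that("boundary enrichment scores edge bins against the interior", {
  prof <- tibble::tibble(
    chrom = "1", domain_id = "1.inside.1", location = "inside",
    start = 0, end = 1000, bin = 1:10,
    count = c(20L, rep(10L, 8), 20L))
  be <- boundary_enrichment(prof)
  expect_equal(be$score, 2.0)
  # all mass in the edge bins: interior mean 0 -> score absent
  prof$count <- c(50L, rep(0L, 8), 50L)
  expect_true(is.na(boundary_enrichment(prof)$score))
  # uniform counts give a score near 1 on simulated uniform placement
  withr::with_seed(6, {
    pos <- sample.int(5e5, 10000)
    prof_u <- tibble::tibble(
      chrom = "1", domain_id = "1.inside.1", location = "inside",
      start = 0, end = 5e5, bin = 1:10,
      count = bin_counts(pos, 0, 5e5))
    sc <- boundary_enrichment(prof_u)$score
    expect_lt(abs(sc - 1), 0.15)
  })
})

test_that("a 2x boundary-weighted generator recovers an enrichment score of about 2", {
  cfg <- small_sim_config(seed = 78, shared_fraction = 0,
                          error_variant_rate = 0,
                          n_treated_variants = 8000L,
                          per_chromosome_weights = c(1, 1, 1),
                          tad_inside_weight = 1, tad_boundary_weight = 2)
  ref <- sim_reference(cfg)
  vars <- suppressWarnings(sim_variants(cfg, ref))
  snvs <- dplyr::filter(classify_indel(vars$treated[[1]]),
                        variant_type == "SNV")
  prof <- tad_bin_profile(snvs, ref$tads, ref$chrom_lengths)
  agg <- dplyr::filter(bin_aggregate(prof), location == "inside")
  tot <- dplyr::summarise(dplyr::group_by(agg, bin), n = sum(count),
                          .groups = "drop")
  edge <- mean(tot$n[tot$bin %in% c(1, 10)])
  interior <- mean(tot$n[!tot$bin %in% c(1, 10)])
  score <- edge / interior
  se <- score * sqrt(1 / sum(tot$n[tot$bin %in% c(1, 10)]) +
                       1 / sum(tot$n[!tot$bin %in% c(1, 10)]))
  expect_lt(abs(score - cfg$tad_boundary_weight), 3 * se)
})
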
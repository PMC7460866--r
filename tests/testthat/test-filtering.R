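test_that("sample filter removes exact control-pool matches only", {
  treated <- make_variants("1", 100, "A", "G")
  expect_equal(nrow(sample_filter(treated, make_variants("1", 100, "A", "G"))), 0L)
  expect_equal(nrow(sample_filter(treated, make_variants("1", 100, "A", "T"))), 1L)
  expect_equal(nrow(sample_filter(treated, make_variants("2", 100, "A", "G"))), 1L)
  expect_warning(out <- sample_filter(treated, treated[0, ]), "empty")
  expect_equal(nrow(out), 1L)
})

test_that("coverage thresholds are inclusive minima and NA is retained flagged", {
  v <- make_variants("1", 1:5, "A", "G",
                     dp = c(3L, 2L, 60L, 60L, NA),
                     gq = c(20L, 99L, 19L, 99L, NA))
  out <- suppressWarnings(coverage_filter(v))
  expect_equal(out$pos, c(1L, 4L, 5L))      # dp=3/gq=20 kept; NA kept flagged
  expect_warning(coverage_filter(v), "lack DP")
})

test_that("binomial filter matches the exact tail and its decision boundary", {
  # dp=30, alt=2: tail ~ 4.27e-4 < 0.001 -> retained (frozen oracle value)
  expect_equal(binomial_error_p(2, 30), 0.0004269616479, tolerance = 1e-9)
  # dp=30, alt=1: tail = 1 - 0.999^30 ~ 0.0296 -> removed
  expect_equal(binomial_error_p(1, 30), 0.02956903274, tolerance = 1e-9)
  v <- make_variants("1", 1:4, "A", "G", dp = c(30L, 30L, 60L, 50L),
                     alt_count = c(2L, 1L, 30L, 0L))
  out <- binomial_filter(v)
  expect_equal(out$pos, c(1L, 3L))   # strong het signal retained, alt=0 removed
  expect_error(binomial_filter(make_variants("1", 1, "A", "G", dp = 10L,
                                             alt_count = 11L)),
               "alt_count")
  # missing AD skips the stage with a warning
  vna <- make_variants("1", 1, "A", "G", dp = 30L)
  vna$alt_count <- NA_integer_
  expect_warning(out <- binomial_filter(vna), "skipped")
  expect_equal(nrow(out), 1L)
})

test_that("exact binomial tail equals brute-force summation across the dp grid", {
  set.seed(11)
  dp <- sample.int(200L, 400L, replace = TRUE)
  alt <- vapply(dp, function(d) sample.int(d, 1L), integer(1))
  got <- binomial_error_p(alt, dp, 0.001)
  want <- mapply(oracle_binom_tail, alt, dp, MoreArgs = list(p = 0.001))
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("filter chain tallies reconcile and the retained set is order-invariant", {
  fx <- sim_fixture()
  treated <- fx$vars$treated[[1]]
  pool <- fx$vars$control
  res <- run_filter_chain(treated, pool)
  rep <- res$report

  # conservation: before = after + per-stage removals, per variant type
  expect_true(all(rep$counts$before ==
                    rep$counts$after + rep$counts$removed_sample +
                    rep$counts$removed_coverage + rep$counts$removed_binomial))
  expect_equal(sum(rep$counts$before), nrow(treated))
  expect_equal(sum(rep$counts$after), nrow(res$variants))

  # idempotence: filtering the retained set again changes nothing
  res2 <- run_filter_chain(res$variants, pool)
  expect_identical(as.data.frame(res2$variants), as.data.frame(res$variants))

  # order invariance: the retained set is the intersection of the stage
  # predicates, so any composition order gives the same keys
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt)
  composed <- list(
    treated |> sample_filter(pool) |> coverage_filter() |> binomial_filter(),
    treated |> binomial_filter() |> coverage_filter() |> sample_filter(pool),
    treated |> coverage_filter() |> sample_filter(pool) |> binomial_filter()
  )
  for (out in composed) expect_setequal(key(out), key(res$variants))

  # glance/tidy reshape the same tallies
  g <- glance(rep)
  expect_equal(g$n_before, nrow(treated))
  expect_equal(sum(tidy(rep)$removed), g$n_before - g$n_after)
})

test_that("retained fraction on generator defaults is about 2 percent", {
  fx <- sim_fixture()
  res <- run_filter_chain(fx$vars$treated[[1]], fx$vars$control)
  frac <- nrow(res$variants) / nrow(fx$vars$treated[[1]])
  n <- nrow(fx$vars$treated[[1]])
  expect_lt(abs(frac - 0.0199), 3 * sqrt(0.02 * 0.98 / n) + 2 / n)
  # what survives is overwhelmingly the IR-specific injection
  expect_true(mean(res$variants$origin == "ir") > 0.99)
})

test_that("filters are monotone in their thresholds", {
  fx <- sim_fixture()
  treated <- fx$vars$treated[[1]]
  loose <- suppressWarnings(coverage_filter(treated, dp_min = 3, gq_min = 20))
  tight <- suppressWarnings(coverage_filter(treated, dp_min = 10, gq_min = 60))
  expect_true(nrow(tight) <= nrow(loose))
  expect_true(all(paste(tight$chrom, tight$pos) %in% paste(loose$chrom, loose$pos)))

  small_a <- binomial_filter(treated, alpha = 1e-6)
  big_a <- binomial_filter(treated, alpha = 1e-2)
  expect_true(nrow(small_a) <= nrow(big_a))
  expect_true(all(paste(small_a$chrom, small_a$pos) %in%
                    paste(big_a$chrom, big_a$pos)))
})

test_that("keep_all mode labels each variant with its first failing stage", {
  fx <- sim_fixture()
  res <- run_filter_chain(fx$vars$treated[[1]], fx$vars$control,
                          keep_all = TRUE)
  expect_equal(nrow(res$variants), nrow(fx$vars$treated[[1]]))
  expect_setequal(setdiff(unique(res$variants$filter), "PASS"),
                  c("sample_filter", "binomial_filter"))
  expect_equal(sum(res$variants$filter == "PASS"),
               sum(res$report$counts$after))
})
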
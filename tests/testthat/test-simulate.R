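test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(shared_fraction = 1.2), "fraction")
  expect_error(sim_config(per_chromosome_weights = c(1, 2)), "length")
  expect_error(sim_config(per_chromosome_weights = c(-1, rep(1, 7))),
               "positive")
  expect_error(sim_config(context_mix = c(rep = 0.5, mh = 0.3, none = 0.3)),
               "sum to 1")
  expect_error(sim_config(chrom_lengths = c(chr1 = 5000L, chr2 = 20000L),
                          per_chromosome_weights = c(1, 1)),
               "10 kb")
  expect_error(
    sim_translocations(sim_config(chrom_lengths = c(chr1 = 50000L),
                                  per_chromosome_weights = 1)),
    "2 chromosomes")
})

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- small_sim_config()
  r1 <- sim_reference(cfg)
  r2 <- sim_reference(cfg)
  expect_identical(r1, r2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  x1 <- suppressWarnings(simulate_dataset(cfg, d1))
  x2 <- suppressWarnings(simulate_dataset(cfg, d2))
  expect_identical(readLines(x1$paths$reference), readLines(x2$paths$reference))
  expect_identical(readLines(x1$paths$control_vcf),
                   readLines(x2$paths$control_vcf))
  expect_identical(readLines(x1$paths$control_translocations),
                   readLines(x2$paths$control_translocations))
  # a different seed changes the sequence
  r3 <- sim_reference(small_sim_config(seed = 43))
  expect_false(identical(r1$sequences, r3$sequences))
})

test_that("bands partition each chromosome and TADs stay in bounds", {
  fx <- sim_fixture()
  ref <- fx$ref
  for (cn in names(ref$chrom_lengths)) {
    b <- ref$bands[ref$bands$chrom == cn, ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], unname(ref$chrom_lengths[[cn]]))
    expect_equal(b$start[-1], b$end[-nrow(b)])  # contiguous partition
    t <- ref$tads[ref$tads$chrom == cn, ]
    expect_true(all(t$start >= 0 & t$end <= ref$chrom_lengths[[cn]]))
    expect_true(all(t$start < t$end))
    cov <- sum(t$end - t$start) / ref$chrom_lengths[[cn]]
    expect_gt(cov, 0.6)
    expect_lt(cov, 0.8)
  }
  # nucleotide content is plain A/C/G/T
  expect_true(all(strsplit(substr(ref$sequences[1], 1, 5000), "")[[1]] %in%
                    c("A", "C", "G", "T")))
})

test_that("treated samples realize the configured composition", {
  fx <- sim_fixture()
  cfg <- fx$cfg
  tr <- fx$vars$treated[[1]]
  n <- nrow(tr)
  comp <- table(tr$origin)

  # shared fraction by construction (up to key collisions removed in dedup)
  expect_equal(unname(comp["shared"]) / n, cfg$shared_fraction,
               tolerance = 0.01)
  # every shared variant is present in the control pool
  shared <- tr[tr$origin == "shared", ]
  pool_keys <- paste(fx$vars$control$chrom, fx$vars$control$pos,
                     fx$vars$control$ref, fx$vars$control$alt)
  expect_true(all(paste(shared$chrom, shared$pos, shared$ref, shared$alt)
                  %in% pool_keys))

  # IR-specific Ti fraction ~ ir_titv / (1 + ir_titv) = 0.592
  ir <- classify_indel(tr[tr$origin == "ir", ])
  snv <- ir[ir$variant_type == "SNV", ]
  is_ti <- paste0(snv$ref, ">", snv$alt) %in%
    c("A>G", "G>A", "C>T", "T>C")
  p0 <- cfg$ir_titv / (1 + cfg$ir_titv)
  expect_lt(abs(mean(is_ti) - p0), 3 * sqrt(p0 * (1 - p0) / nrow(snv)))

  # SNV:InDel ratio of the IR-specific injection
  expect_equal(sum(ir$variant_type == "SNV") /
                 sum(ir$variant_type %in% c("ins", "del")),
               cfg$ir_snv_indel_ratio, tolerance = 0.35)

  # artifact alternate support is binomial at the error rate: almost all < 3
  art <- tr[tr$origin == "artifact", ]
  expect_true(mean(art$alt_count < 3) > 0.95)
})

test_that("generated deletion context labels agree with the classifier", {
  fx <- ir_fixture()
  ir <- classify_indel(fx$vars$treated[[1]])
  dels <- ir[ir$origin == "ir" & ir$variant_type == "del", ]
  expect_gt(nrow(dels), 200)
  ctx <- indel_context(dels, fx$ref$sequences)
  expect_equal(ctx$context_class, dels$context_true)

  # deleting an implanted tandem unit is a repeat context by construction
  reg <- utils::head(fx$ref$repeats[fx$ref$repeats$unit_len == 3, ], 5)
  v <- tibble::tibble(
    sample = "x", chrom = reg$chrom, pos = reg$pos - 1L,
    ref = substring(fx$ref$sequences[reg$chrom], reg$pos - 1L, reg$pos + 2L),
    alt = substring(fx$ref$sequences[reg$chrom], reg$pos - 1L, reg$pos - 1L),
    gt = "0/1", dp = 60L, gq = 99L, alt_count = 30L)
  expect_true(all(indel_context(v, fx$ref$sequences)$context_class == "rep"))
})

test_that("context mix and length decay are recovered within sampling error", {
  fx <- ir_fixture()
  cfg <- fx$cfg
  ir <- classify_indel(fx$vars$treated[[1]])
  dels <- ir[ir$origin == "ir" & ir$variant_type == "del", ]
  nd <- nrow(dels)
  for (cl in c("rep", "mh", "none")) {
    p0 <- cfg$context_mix[[cl]]
    expect_lt(abs(mean(dels$context_true == cl) - p0),
              3 * sqrt(p0 * (1 - p0) / nd) + 0.02)
  }
  # mono/dinucleotide dominance from the geometric decay
  lens <- ir$indel_length[ir$origin == "ir" &
                            ir$variant_type %in% c("ins", "del")]
  expect_gt(mean(lens <= 2), 0.6)
})

test_that("translocation tables embed removable control copies and threshold straddlers", {
  fx <- sim_fixture()
  tl <- fx$tl
  tr <- tl$treated[[1]]
  shared <- tr[tr$origin == "control_shared", ]
  novel <- tr[tr$origin == "novel", ]
  # every shared event is windowed-equal to some control event; no novel is
  match_any <- function(row) {
    any(vapply(seq_len(nrow(tl$control)), function(i) {
      windowed_equal(row, tl$control[i, ])
    }, logical(1)))
  }
  expect_true(all(vapply(seq_len(nrow(shared)),
                         function(i) match_any(shared[i, ]), logical(1))))
  expect_false(any(vapply(seq_len(nrow(novel)),
                          function(i) match_any(novel[i, ]), logical(1))))
  # support/confidence straddle the 20-read and 80-score thresholds
  expect_true(any(tr$supporting_reads < 20) && any(tr$supporting_reads >= 20))
  expect_true(any(tr$confidence <= 80) && any(tr$confidence > 80))
  expect_true(all(tr$chrom_a < tr$chrom_b))
})
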
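test_that("InDels classify by allele-length difference", {
  v <- make_variants("1", 1:4, c("ATTT", "A", "A", "AG"),
                     c("A", "ACG", "G", "CT"))
  out <- classify_indel(v)
  expect_equal(out$variant_type, c("del", "ins", "SNV", "MNV"))
  expect_equal(out$indel_length, c(3L, 2L, 0L, 0L))
})

test_that("context classification follows the rep > mh > none precedence", {
  # a full downstream copy of the deleted sequence is a repeat context
  expect_equal(classify_context("ACG", "TTTT", "ACGTTT")$context_class, "rep")
  # partial prefix homology downstream: microhomology with bimh = 3
  cc <- classify_context("TAGC", "CCCC", "TAGGGG")
  expect_equal(cc$context_class, "mh")
  expect_equal(cc$bimh, 3L)
  # length-1 deletion flanked by different bases: none (mh impossible)
  cc <- classify_context("T", "AAAA", "GGGG")
  expect_equal(cc$context_class, "none")
  expect_true(is.na(cc$bimh))
  # length-1 deletion adjacent to the same base: mononucleotide run = rep
  expect_equal(classify_context("T", "AAAA", "TGGG")$context_class, "rep")
  expect_equal(classify_context("T", "AAAT", "GGGG")$context_class, "rep")
  # upstream suffix homology also counts toward bimh
  cc <- classify_context("TTAC", "GGAC", "GGGG")
  expect_equal(cc$context_class, "mh")
  expect_equal(cc$bimh, 2L)
})

test_that("classifier agrees with the character-scanning oracle on random loci", {
  withr::with_seed(21, {
    for (case in seq_len(400)) {
      L <- sample(1:5, 1)
      ref_len <- L + sample(2:14, 1)
      refseq <- paste(sample(c("A", "C", "G", "T"), ref_len, replace = TRUE),
                      collapse = "")
      i <- sample.int(ref_len - L + 1, 1)
      s <- substr(refseq, i, i + L - 1)
      up <- substr(refseq, 1, i - 1)
      dn <- substr(refseq, i + L, ref_len)
      want <- oracle_context(s, up, dn)
      got <- classify_context(s, up, dn)
      expect_equal(got$context_class, want$class)
      expect_equal(got$bimh, want$bimh)
    }
  })
})

test_that("the variant-level path (anchor stripping, flank windows) matches the oracle", {
  withr::with_seed(22, {
    chrom_seq <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                       collapse = "")
    reference <- c(z = chrom_seq)
    n <- 300
    L <- sample(1:5, n, replace = TRUE)
    s0 <- sample(100:4800, n)  # first deleted base
    v <- tibble::tibble(
      sample = "x", chrom = "z", pos = s0 - 1L,
      ref = substring(chrom_seq, s0 - 1L, s0 + L - 1L),
      alt = substring(chrom_seq, s0 - 1L, s0 - 1L),
      gt = "0/1", dp = 60L, gq = 99L, alt_count = 30L)
    got <- indel_context(v, reference)
    for (i in seq_len(n)) {
      want <- oracle_context(substring(chrom_seq, s0[i], s0[i] + L[i] - 1L),
                             substring(chrom_seq, 1, s0[i] - 1L),
                             substring(chrom_seq, s0[i] + L[i], 5000))
      expect_equal(got$context_class[i], want$class)
      expect_equal(got$bimh[i], want$bimh)
    }
    # partition property: each event gets exactly one class
    expect_true(all(got$context_class %in% c("rep", "mh", "none")))
  })
})

test_that("context class is invariant under reverse complementation", {
  withr::with_seed(23, {
    rc <- function(x) irmutscan:::revcomp(x)
    for (case in seq_len(300)) {
      L <- sample(1:5, 1)
      s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
      up <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                  collapse = "")
      dn <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                  collapse = "")
      fwd <- classify_context(s, up, dn)
      rev <- classify_context(rc(s), rc(dn), rc(up))
      expect_equal(fwd$context_class, rev$context_class)
      expect_equal(fwd$bimh, rev$bimh)
    }
  })
})

test_that("unresolvable loci are reported, not guessed", {
  reference <- c(z = strrep("ACGT", 100))
  # deletion whose stated sequence disagrees with the reference
  v <- make_variants("z", 10, "AAAAA", "A")
  expect_equal(indel_context(v, reference)$context_class, "unresolved")
  # chromosome absent from the reference
  v2 <- make_variants("y", 10, "AC", "A")
  expect_equal(indel_context(v2, reference)$context_class, "unresolved")
})

test_that("category labels encode type, context and bucketed sub-length", {
  expect_equal(signature_category("del", "mh", 2L), "del.mh.bimh.2")
  expect_equal(signature_category("ins", "rep", 3L), "ins.rep.len.3")
  expect_equal(signature_category("del", "none", 7L), "del.none.len.5+")
  expect_equal(signature_category("del", "none", 5L), "del.none.len.5+")
  p <- parse_signature_category(c("del.mh.bimh.2", "ins.none.len.5+"))
  expect_equal(p$indel_type, c("del", "ins"))
  expect_equal(p$context_class, c("mh", "none"))
  expect_equal(p$sub_length, c("2", "5+"))
})

test_that("spectra cover the canonical grid and tally MNV/unresolved apart", {
  reference <- c(z = strrep("ACGT", 1000))
  empty <- indel_spectrum(make_variants("z", integer(), "A", "G"), reference)
  expect_true(all(empty$n == 0L))
  expect_equal(nrow(empty), 30L)  # 2 types x 3 contexts x 5 buckets
  expect_equal(attr(empty, "total"), 0L)

  fx <- ir_fixture()
  ir <- fx$vars$treated[[1]]
  spec <- indel_spectrum(ir, fx$ref$sequences)
  cls <- classify_indel(ir)
  expect_equal(attr(spec, "total") + attr(spec, "n_unresolved"),
               sum(cls$variant_type %in% c("ins", "del")))
  expect_equal(attr(spec, "n_mnv"), sum(cls$variant_type == "MNV"))
  # deletions come before insertions, rep before mh before none
  expect_equal(spec$indel_type, rep(c("del", "ins"), each = 15))
  expect_equal(spec$context_class[1:15], rep(c("rep", "mh", "none"), each = 5))
})

test_that("configured deletion context proportions are recovered in the spectrum", {
  fx <- ir_fixture()
  spec <- indel_spectrum(fx$vars$treated[[1]], fx$ref$sequences)
  dels <- spec[spec$indel_type == "del", ]
  nd <- sum(dels$n)
  for (cl in c("rep", "mh", "none")) {
    p0 <- fx$cfg$context_mix[[cl]]
    got <- sum(dels$n[dels$context_class == cl]) / nd
    expect_lt(abs(got - p0), 3 * sqrt(p0 * (1 - p0) / nd) + 0.02)
  }
})

test_that("fold changes use log10 with pseudocounts only for zero cells", {
  mk <- function(categories, n) tibble::tibble(category = categories, n = n)
  cats <- c("del.rep.len.1", "del.mh.bimh.1", "ins.none.len.2")
  # identity
  fc <- fold_change(mk(cats, c(10, 20, 30)), mk(cats, c(10, 20, 30)))
  expect_equal(fc$log10_fc, rep(0, 3))
  # one category 100 -> 1 is -2
  fc <- fold_change(mk("del.rep.len.1", 1), mk("del.rep.len.1", 100))
  expect_equal(fc$log10_fc, -2)
  # zero cell takes the pseudocount; the non-zero side is untouched
  fc <- fold_change(mk("del.rep.len.1", 0), mk("del.rep.len.1", 100),
                    pseudocount = 0.5)
  expect_equal(fc$log10_fc, log10(0.5 / 100))
  # category absent from both spectra is omitted
  fc <- fold_change(mk(cats, c(5, 0, 0)), mk(cats, c(50, 10, 0)))
  expect_equal(nrow(fc), 2L)
  # per-type averages
  av <- fold_change_averages(fc)
  expect_setequal(av$indel_type, c("del"))
})

test_that("uniform retention makes every fold change log10 of the retained fraction", {
  cats <- signature_levels()
  unf <- tibble::tibble(category = cats, n = 1000L)
  fil <- tibble::tibble(category = cats, n = 20L)
  fc <- fold_change(fil, unf)
  expect_equal(fc$log10_fc, rep(log10(0.02), length(cats)))
  av <- fold_change_averages(fc)
  expect_equal(av$mean_log10_fc, rep(log10(0.02), 2))
})
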
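# shared fixtures, generated once per test run

.fixture_env <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 42, ...) {
  defaults <- list(
    seed = seed,
    chrom_lengths = setNames(c(300000L, 250000L, 200000L), paste0("chr", 1:3)),
    per_chromosome_weights = c(5, 2, 1),
    n_control_variants = 6000L,
    n_treated_variants = 4000L,
    doses = 2,
    repair_intervals = "16h",
    n_translocations = 10L,
    n_control_translocations = 8L
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

sim_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    cfg <- small_sim_config()
    ref <- sim_reference(cfg)
    vars <- suppressWarnings(sim_variants(cfg, ref))
    tl <- sim_translocations(cfg)
    .fixture_env$fx <- list(cfg = cfg, ref = ref, vars = vars, tl = tl)
  }
  .fixture_env$fx
}

# all-IR fixture: no shared pool, no artifacts -> every variant is an
# IR-specific injection, giving enough InDels for context recovery checks
ir_fixture <- function() {
  if (is.null(.fixture_env$ir)) {
    cfg <- small_sim_config(seed = 43, shared_fraction = 0,
                            error_variant_rate = 0,
                            n_treated_variants = 3000L)
    ref <- sim_reference(cfg)
    vars <- suppressWarnings(sim_variants(cfg, ref))
    .fixture_env$ir <- list(cfg = cfg, ref = ref, vars = vars)
  }
  .fixture_env$ir
}

# bare-bones variant tibble for constructed examples
make_variants <- function(chrom, pos, ref, alt, dp = 60L, gq = 99L,
                          alt_count = NULL, sample = "s1") {
  n <- length(pos)
  if (is.null(alt_count)) alt_count <- pmax(1L, as.integer(round(dp / 2)))
  tibble::tibble(
    sample = rep_len(sample, n), chrom = rep_len(chrom, n),
    pos = as.integer(pos), ref = rep_len(ref, n), alt = rep_len(alt, n),
    gt = "0/1", dp = rep_len(as.integer(dp), n),
    gq = rep_len(as.integer(gq), n),
    alt_count = rep_len(as.integer(alt_count), n)
  )
}

vcf_text <- function(records, sample = "s1") {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="GQ">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"),
    records)
}
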
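# Deterministic synthetic-data generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# large control (pre-IR) variant pool; treated samples that share 98% of
# their variants with the pool plus treatment-specific variants with their
# own Ti/Tv (1.45 vs 2.1), SNV:InDel ratio (2.1 vs 5.2), heterogeneous
# per-chromosome loading (10x spread for IR-specific variants, ~2x for the
# pre-IR pool), TAD-weighted placement, geometric InDel length decay with
# controlled deletion contexts (rep/mh/none), low-support artifact variants,
# SnpEff-style annotations, and translocation tables containing jittered
# control-shared events with support/confidence values straddling the
# filter thresholds. Everything is reproducible bit-for-bit from the seed.

#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic-data generator.
#' Defaults encode the experimental structure the analysis expects: treated
#' samples sharing 98% of their variants with the untreated pool, Ti/Tv of
#' 2.1 (pre-IR) vs 1.45 (IR-specific), SNV:InDel ratios of 5.2 vs 2.1, a
#' 10-fold per-chromosome loading spread for IR-specific variants, a TAD
#' inside:outside density ratio of 2 with accumulation at domain borders,
#' and a dose (0.5/2/10 Gy) by repair-interval (16 h / 7 d) sample grid in
#' which dose is metadata only (no dose-response is simulated).
#'
#' @param seed Integer seed; reproducibly determines all generator output.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param per_chromosome_weights Relative per-Mb variant loading of
#'   IR-specific variants; same length as `chrom_lengths`.
#' @param n_bands_per_chrom,n_tads_per_chrom Bands partition each
#'   chromosome; TADs cover `tad_coverage` of it with gaps between them.
#' @param tad_coverage Fraction of each chromosome covered by TADs.
#' @param doses,repair_intervals Sample grid labels (metadata only).
#' @param n_control_variants Size of the control (pre-IR) variant pool.
#' @param n_treated_variants Variants per treated sample.
#' @param shared_fraction Fraction of treated-sample variants drawn from the
#'   control pool.
#' @param pre_titv,ir_titv Ti/Tv of shared / treatment-specific SNVs.
#' @param pre_snv_indel_ratio,ir_snv_indel_ratio SNV:InDel ratios.
#' @param ins_fraction Fraction of InDels that are insertions.
#' @param indel_length_decay Geometric parameter: lengths are
#'   `1 + Geometric(p)`, truncated at `max_indel_length`.
#' @param max_indel_length Truncation for generated InDel lengths.
#' @param context_mix Proportions of rep/mh/none deletion contexts
#'   (named vector summing to 1); applies to IR-specific deletions.
#' @param triplet_none_boost Multiplier on the joint probability of
#'   length-3 deletions in `"none"` context.
#' @param tad_inside_weight Relative placement density of IR-specific SNVs
#'   inside TADs vs gaps.
#' @param tad_boundary_weight Relative density of the first/last bin of each
#'   TAD vs its interior bins.
#' @param n_translocations,n_control_translocations Events per treated
#'   sample / in the control table.
#' @param control_translocation_fraction Fraction of treated events
#'   duplicated from control events with breakend jitter < 200 nt.
#' @param dp_mean Mean sequencing depth (Poisson).
#' @param gq_mean,gq_sd Genotype-quality distribution (truncated normal,
#'   capped at 99).
#' @param af_alt Alternate-allele fraction of heterozygous calls.
#' @param error_variant_rate Fraction of treated variants injected as
#'   sequencing artifacts with `alt_count ~ Binomial(DP, error_rate)`.
#' @param error_rate Per-read error probability of artifact support.
#' @param impact_mix Named proportions of HIGH/MODERATE/LOW/MODIFIER primary
#'   annotations.
#' @param refseq_known_rate Probability that a secondary transcript
#'   annotation carries a "known" RefSeq accession.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = NULL,
                       per_chromosome_weights = NULL,
                       n_bands_per_chrom = 5L,
                       n_tads_per_chrom = 4L,
                       tad_coverage = 0.7,
                       doses = c(0.5, 2, 10),
                       repair_intervals = c("16h", "7d"),
                       n_control_variants = 30000L,
                       n_treated_variants = 20000L,
                       shared_fraction = 0.98,
                       pre_titv = 2.1,
                       ir_titv = 1.45,
                       pre_snv_indel_ratio = 5.2,
                       ir_snv_indel_ratio = 2.1,
                       ins_fraction = 0.5,
                       indel_length_decay = 0.55,
                       max_indel_length = 10L,
                       context_mix = c(rep = 0.4, mh = 0.3, none = 0.3),
                       triplet_none_boost = 1,
                       tad_inside_weight = 2,
                       tad_boundary_weight = 2,
                       n_translocations = 40L,
                       n_control_translocations = 30L,
                       control_translocation_fraction = 0.5,
                       dp_mean = 60,
                       gq_mean = 80,
                       gq_sd = 12,
                       af_alt = 0.5,
                       error_variant_rate = 0.005,
                       error_rate = 0.001,
                       impact_mix = c(HIGH = 0.001, MODERATE = 0.006,
                                      LOW = 0.1, MODIFIER = 0.893),
                       refseq_known_rate = 0.85) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- setNames(
      as.integer(c(1.2e6, 1.0e6, 9e5, 8e5, 7e5, 6e5, 5e5, 4e5)),
      paste0("chr", 1:8))
  }
  if (is.null(per_chromosome_weights)) {
    per_chromosome_weights <- c(10, 6, 4, 3, 2.5, 2, 1.5, 1)[
      seq_along(chrom_lengths)]
  }
  cfg <- list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths,
    per_chromosome_weights = per_chromosome_weights,
    n_bands_per_chrom = n_bands_per_chrom,
    n_tads_per_chrom = n_tads_per_chrom, tad_coverage = tad_coverage,
    doses = doses, repair_intervals = repair_intervals,
    n_control_variants = n_control_variants,
    n_treated_variants = n_treated_variants,
    shared_fraction = shared_fraction,
    pre_titv = pre_titv, ir_titv = ir_titv,
    pre_snv_indel_ratio = pre_snv_indel_ratio,
    ir_snv_indel_ratio = ir_snv_indel_ratio,
    ins_fraction = ins_fraction,
    indel_length_decay = indel_length_decay,
    max_indel_length = as.integer(max_indel_length),
    context_mix = context_mix, triplet_none_boost = triplet_none_boost,
    tad_inside_weight = tad_inside_weight,
    tad_boundary_weight = tad_boundary_weight,
    n_translocations = n_translocations,
    n_control_translocations = n_control_translocations,
    control_translocation_fraction = control_translocation_fraction,
    dp_mean = dp_mean, gq_mean = gq_mean, gq_sd = gq_sd, af_alt = af_alt,
    error_variant_rate = error_variant_rate, error_rate = error_rate,
    impact_mix = impact_mix, refseq_known_rate = refseq_known_rate
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$shared_fraction, cfg$tad_coverage, cfg$ins_fraction,
          cfg$indel_length_decay, cfg$control_translocation_fraction,
          cfg$error_variant_rate, cfg$af_alt, cfg$refseq_known_rate,
          cfg$context_mix, cfg$impact_mix)
  if (any(fr < 0 | fr > 1)) abort("all fractions must lie in [0, 1]")
  if (length(cfg$per_chromosome_weights) != length(cfg$chrom_lengths)) {
    abort("per_chromosome_weights must match chrom_lengths in length")
  }
  if (any(cfg$per_chromosome_weights <= 0)) abort("weights must be positive")
  if (abs(sum(cfg$context_mix) - 1) > 1e-8) abort("context_mix must sum to 1")
  if (!all(c("rep", "mh", "none") %in% names(cfg$context_mix))) {
    abort("context_mix needs rep/mh/none entries")
  }
  # 10 bins per TAD/band and flanking windows need room to exist
  if (min(cfg$chrom_lengths) < 10 * 1000) {
    abort("chromosomes must be at least 10 kb (10x the bin granularity)")
  }
  invisible(cfg)
}

# arm-style band names: p<k> descending, then q<k> ascending
band_names <- function(n) {
  np <- ceiling(n / 2)
  c(paste0("p", rev(seq_len(np))), paste0("q", seq_len(n - np)))
}

#' Generate the synthetic reference: sequence, bands, TADs, gene density
#'
#' Produces i.i.d.-uniform A/C/G/T chromosome sequences with implanted
#' tandem-duplication tracts (unit lengths 1-6, registered in `repeats`) so
#' repeat deletion contexts exist; a cytogenetic-band partition of each
#' chromosome; TADs covering `tad_coverage` of each chromosome with gaps
#' between them; and a per-chromosome gene-density table whose noise level
#' makes the expected correlation with the IR loading weights about 0.55.
#'
#' @param config A [sim_config()].
#' @return List with `sequences` (named character), `chrom_lengths`,
#'   `bands`, `tads`, `repeats`, `gene_density`.
#' @export
sim_reference <- function(config) {
  withr::with_seed(config$seed + 101L, {
    chroms <- normalize_chrom(names(config$chrom_lengths))
    lens <- as.integer(config$chrom_lengths)
    names(lens) <- chroms
    seqs <- character(length(chroms))
    names(seqs) <- chroms
    repeats <- vector("list", length(chroms))
    bands <- vector("list", length(chroms))
    tads <- vector("list", length(chroms))

    for (i in seq_along(chroms)) {
      len <- lens[i]
      chars <- sample(DNA_BASES, len, replace = TRUE)

      # implant non-overlapping tandem duplications (unit lengths 1..6)
      grid <- sample(seq(200L, len - 200L, by = 50L))
      gi <- 0L
      reg <- list()
      for (L in 1:6) {
        n_imp <- min(40L, length(grid) - gi)
        if (n_imp <= 0) break
        p <- grid[gi + seq_len(n_imp)]
        gi <- gi + n_imp
        for (pp in p) chars[(pp + L):(pp + 2L * L - 1L)] <- chars[pp:(pp + L - 1L)]
        reg[[L]] <- tibble(chrom = chroms[i], pos = p, unit_len = L)
      }
      repeats[[i]] <- bind_rows(reg)
      seqs[i] <- paste(chars, collapse = "")

      # bands partition the chromosome
      nb <- config$n_bands_per_chrom
      bw <- runif(nb, 0.6, 1.4)
      brk <- round(cumsum(bw) / sum(bw) * len)
      bands[[i]] <- tibble(chrom = chroms[i],
                           start = c(0, brk[-nb]), end = brk,
                           name = band_names(nb))

      # alternating gap/TAD layout covering ~tad_coverage of the chromosome
      nt <- config$n_tads_per_chrom
      tw <- runif(nt, 0.6, 1.4)
      tw <- tw / sum(tw) * config$tad_coverage * len
      gw <- runif(nt + 1, 0.6, 1.4)
      gw <- gw / sum(gw) * (1 - config$tad_coverage) * len
      widths <- as.vector(rbind(gw, c(tw, NA)))
      widths <- widths[!is.na(widths)]
      bounds <- round(cumsum(widths))
      starts <- c(0, bounds[-length(bounds)])
      is_tad <- seq_along(widths) %% 2 == 0
      tads[[i]] <- tibble(chrom = chroms[i],
                          start = starts[is_tad], end = bounds[is_tad],
                          name = "TAD")
    }

    w <- config$per_chromosome_weights
    # noise scaled so the expected Pearson r with the weights is ~0.55
    sigma <- stats::sd(w) * sqrt(1 / 0.55^2 - 1)
    gene_density <- tibble(
      chrom = chroms,
      genes_per_mb = pmax(0.5, 15 + w + rnorm(length(w), 0, sigma))
    )

    list(sequences = seqs, chrom_lengths = lens,
         bands = bind_rows(bands), tads = bind_rows(tads),
         repeats = bind_rows(repeats), gene_density = gene_density)
  })
}

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                              C = c("A", "G"), T = c("A", "G"))

TERM_POOLS <- list(
  HIGH = c("stop_gained", "frameshift_variant",
           "splice_acceptor_variant&intron_variant",
           "splice_donor_variant&intron_variant",
           "stop_gained&splice_region_variant"),
  MODERATE = c("missense_variant", "missense_variant&splice_region_variant",
               "inframe_deletion"),
  LOW = c("synonymous_variant", "splice_region_variant&synonymous_variant",
          "splice_region_variant&intron_variant", "stop_retained_variant"),
  MODIFIER = c("intron_variant", "intergenic_region",
               "downstream_gene_variant", "upstream_gene_variant",
               "3_prime_UTR_variant",
               "5_prime_UTR_premature_start_codon_gain_variant",
               "non_coding_transcript_exon_variant")
)

# SnpEff-style annotation list-column. The primary annotation always sits on
# a "known" RefSeq transcript so configured impact proportions are
# recoverable after the RefSeq restriction; secondary transcripts carry the
# same or a lower-severity term.
make_annotations <- function(n, cfg) {
  if (!n) return(list())
  sample_terms <- function(impacts) {
    out <- character(length(impacts))
    for (im in unique(impacts)) {
      idx <- which(impacts == im)
      out[idx] <- sample(TERM_POOLS[[im]], length(idx), replace = TRUE)
    }
    out
  }
  primary_impact <- sample(IMPACT_LEVELS, n, replace = TRUE,
                           prob = cfg$impact_mix[IMPACT_LEVELS])
  primary_term <- sample_terms(primary_impact)
  gene <- sprintf("GENE%04d", sample.int(3000L, n, replace = TRUE))
  n_extra <- stats::rbinom(n, 2L, 0.2)
  tid <- sprintf("NM_%06d.1", sample.int(999999L, n, replace = TRUE))

  # secondary transcripts: same term, or a term of equal/lower severity
  m <- sum(n_extra)
  if (m > 0) {
    owner <- rep.int(seq_len(n), n_extra)
    dup <- runif(m) < 0.5
    sev_lo <- match(primary_impact[owner], IMPACT_LEVELS)
    extra_impact <- IMPACT_LEVELS[sev_lo +
      floor(runif(m) * (4L - sev_lo + 1L))]
    extra_impact[dup] <- primary_impact[owner][dup]
    extra_term <- sample_terms(extra_impact)
    extra_term[dup] <- primary_term[owner][dup]
    known <- runif(m) < cfg$refseq_known_rate
    extra_id <- ifelse(known,
                       sprintf("NM_%06d.2", sample.int(999999L, m, replace = TRUE)),
                       sprintf("ENST%011d", sample.int(99999999L, m, replace = TRUE)))
  } else {
    owner <- integer(0)
    extra_impact <- extra_term <- extra_id <- character(0)
  }

  long_owner <- c(seq_len(n), owner)
  ord <- order(long_owner)
  so <- c(primary_term, extra_term)[ord]
  im <- c(primary_impact, extra_impact)[ord]
  ids <- c(tid, extra_id)[ord]
  gn <- gene[long_owner][ord]
  known_flag <- grepl("^N[MR]_", ids)
  idx_split <- unname(split(seq_along(ord), long_owner[ord]))
  lapply(idx_split, function(ix) {
    tibble::new_tibble(list(so_term = so[ix], impact = im[ix],
                            gene = gn[ix], transcript_id = ids[ix],
                            is_refseq_known = known_flag[ix]),
                       nrow = length(ix))
  })
}

draw_depths <- function(n, cfg) {
  dp <- pmax(1L, stats::rpois(n, cfg$dp_mean))
  gq <- pmin(99L, pmax(0L, as.integer(round(rnorm(n, cfg$gq_mean, cfg$gq_sd)))))
  gt <- sample(c("0/1", "1/1"), n, replace = TRUE, prob = c(0.7, 0.3))
  af <- ifelse(gt == "1/1", 0.98, cfg$af_alt)
  alt_count <- pmin(dp, pmax(1L, stats::rbinom(n, dp, af)))
  tibble(gt = gt, dp = dp, gq = gq, alt_count = alt_count)
}

# allocate n variants to chromosomes with probability ~ weight * length
alloc_chroms <- function(n, chroms, lens, weights) {
  sample(chroms, n, replace = TRUE, prob = weights * lens / sum(weights * lens))
}

# uniform unique positions per chromosome, away from the ends
uniform_positions <- function(chrom, lens, margin = 30L) {
  out <- integer(length(chrom))
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    out[idx] <- sample.int(lens[[cn]] - 2L * margin, length(idx)) + margin
  }
  out
}

snv_alleles <- function(seqs, chrom, pos, titv) {
  if (!length(pos)) return(tibble(ref = character(), alt = character()))
  ref <- unname(substring(seqs[chrom], pos, pos))
  is_ti <- runif(length(pos)) < titv / (1 + titv)
  tv_pick <- runif(length(pos)) < 0.5
  alt <- ifelse(is_ti, TRANSITION_PARTNER[ref],
                ifelse(tv_pick,
                       vapply(TRANSVERSION_PARTNERS[ref], `[`, character(1), 1L),
                       vapply(TRANSVERSION_PARTNERS[ref], `[`, character(1), 2L)))
  tibble(ref = ref, alt = unname(alt))
}

random_strings <- function(lens) {
  vapply(lens, function(l) paste(sample(DNA_BASES, l, replace = TRUE),
                                 collapse = ""), character(1))
}

# per-domain-bin placement weights implementing the TAD inside:outside and
# boundary density model for IR-specific SNVs
build_bin_weights <- function(reference, cfg, n_bins = 10L) {
  merged <- merge_tads(reference$tads, reference$chrom_lengths)
  gp <- suppressWarnings(complement_gaps(merged, reference$chrom_lengths))
  domains <- bind_rows(mutate(merged, location = "inside"),
                       mutate(gp, location = "outside"))
  rows <- vector("list", nrow(domains))
  for (i in seq_len(nrow(domains))) {
    d <- domains[i, ]
    wd <- d$end - d$start
    lo <- floor((seq_len(n_bins) - 1) * wd / n_bins)
    hi <- floor(seq_len(n_bins) * wd / n_bins) - 1
    w <- (hi - lo + 1) *
      (if (d$location == "inside") cfg$tad_inside_weight else 1)
    if (d$location == "inside") {
      # boundary shape, normalized so the mean density inside a TAD stays
      # tad_inside_weight (the realized inside:outside density ratio)
      shape <- rep(1, n_bins)
      shape[c(1L, n_bins)] <- cfg$tad_boundary_weight
      w <- w * shape / mean(shape)
    }
    rows[[i]] <- tibble(chrom = d$chrom, start = d$start, lo = lo, hi = hi,
                        weight = w)
  }
  bind_rows(rows)
}

place_weighted_positions <- function(n_per_chrom, bin_weights, lens,
                                     margin = 30L) {
  out <- vector("list", length(n_per_chrom))
  for (j in seq_along(n_per_chrom)) {
    cn <- names(n_per_chrom)[j]
    k <- n_per_chrom[[j]]
    if (!k) next
    bw <- bin_weights[bin_weights$chrom == cn, ]
    cells <- tabulate(sample.int(nrow(bw), k, replace = TRUE,
                                 prob = bw$weight), nbins = nrow(bw))
    pos <- integer(0)
    for (ci in which(cells > 0)) {
      width <- bw$hi[ci] - bw$lo[ci] + 1
      off <- sample.int(width, min(cells[ci], width)) - 1L
      pos <- c(pos, bw$start[ci] + bw$lo[ci] + off + 1L)
    }
    pos <- pmin(pmax(pos, margin + 1L), lens[[cn]] - margin)
    out[[j]] <- tibble(chrom = cn, pos = as.integer(pos))
  }
  bind_rows(out)
}

# joint (context class, length) distribution for IR-specific deletions
del_context_grid <- function(cfg, boost = cfg$triplet_none_boost) {
  L <- seq_len(cfg$max_indel_length)
  pL <- stats::dgeom(L - 1, cfg$indel_length_decay)
  pL <- pL / sum(pL)
  grid <- crossing(context = c("rep", "mh", "none"), len = L) |>
    mutate(p = cfg$context_mix[.data$context] * pL[.data$len])
  # microhomology needs len >= 2; renormalize the mh column over len >= 2
  mh1 <- grid$context == "mh" & grid$len == 1
  mh_mass <- sum(grid$p[grid$context == "mh"])
  grid$p[mh1] <- 0
  grid$p[grid$context == "mh"] <-
    grid$p[grid$context == "mh"] / sum(grid$p[grid$context == "mh"]) * mh_mass
  boost_cell <- grid$context == "none" & grid$len == 3
  grid$p[boost_cell] <- grid$p[boost_cell] * boost
  grid$p <- grid$p / sum(grid$p)
  grid
}

# place IR-specific deletions realizing the requested context classes,
# validated with the package's own classifier; falls back to the implanted
# repeat registry for rare long repeat contexts, then to natural contexts
# (with a warning) if a request is unplaceable
place_context_deletions <- function(n_del, cfg, reference, weights,
                                    boost = cfg$triplet_none_boost) {
  if (!n_del) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), context_true = character(),
                  del_len = integer()))
  }
  grid <- del_context_grid(cfg, boost)
  cell <- sample.int(nrow(grid), n_del, replace = TRUE, prob = grid$p)
  want <- tibble(context = grid$context[cell], len = grid$len[cell])
  chroms <- names(reference$chrom_lengths)
  lens <- reference$chrom_lengths
  want$chrom <- alloc_chroms(n_del, chroms, lens, weights)
  seqs <- reference$sequences

  out <- vector("list", 0)
  unplaced <- 0L
  for (grp in split(seq_len(n_del),
                    paste(want$chrom, want$len, sep = "."))) {
    cn <- want$chrom[grp[1]]
    L <- want$len[grp[1]]
    need <- table(factor(want$context[grp], c("rep", "mh", "none")))
    len_c <- lens[[cn]]

    n_cand <- min(len_c - 100L, sum(need) * 40L + 200L)
    s_cand <- sample.int(len_c - 2L * 40L - L, n_cand) + 40L
    S <- substring(seqs[cn], s_cand, s_cand + L - 1L)
    flank <- max(12L, 2L * L)
    U <- substring(seqs[cn], s_cand - flank, s_cand - 1L)
    D <- substring(seqs[cn], s_cand + L, s_cand + L + flank - 1L)
    cls <- classify_context(S, U, D)$context_class

    picked_pos <- integer(0)
    picked_cls <- character(0)
    for (ctx in c("rep", "mh", "none")) {
      k <- need[[ctx]]
      if (!k) next
      avail <- s_cand[cls == ctx]
      take <- utils::head(avail, k)
      short <- k - length(take)
      if (short > 0 && ctx == "rep" && L <= 6L) {
        # fall back to implanted tandem-duplication sites
        reg <- reference$repeats
        reg <- reg[reg$chrom == cn & reg$unit_len == L, ]
        extra <- utils::head(setdiff(reg$pos, take), short)
        take <- c(take, extra)
        short <- k - length(take)
      }
      if (short > 0) {
        # unplaceable: accept natural contexts from unused candidates
        unplaced <- unplaced + short
        spare <- utils::head(setdiff(s_cand, c(take, picked_pos)), short)
        picked_pos <- c(picked_pos, spare)
        picked_cls <- c(picked_cls, rep(NA_character_, length(spare)))
      }
      picked_pos <- c(picked_pos, take)
      picked_cls <- c(picked_cls, rep(ctx, length(take)))
    }
    s <- picked_pos
    ref <- unname(substring(seqs[cn], s - 1L, s + L - 1L))
    alt <- unname(substring(seqs[cn], s - 1L, s - 1L))
    # fill in natural classes of fallback picks
    if (anyNA(picked_cls)) {
      na_i <- which(is.na(picked_cls))
      flank <- max(12L, 2L * L)
      cc <- classify_context(
        substring(seqs[cn], s[na_i], s[na_i] + L - 1L),
        substring(seqs[cn], s[na_i] - flank, s[na_i] - 1L),
        substring(seqs[cn], s[na_i] + L, s[na_i] + L + flank - 1L))
      picked_cls[na_i] <- cc$context_class
    }
    out[[length(out) + 1L]] <- tibble(
      chrom = cn, pos = as.integer(s - 1L), ref = ref, alt = alt,
      context_true = picked_cls, del_len = L)
  }
  if (unplaced > 0) {
    warn(sprintf("%d deletion context request(s) unplaceable; natural contexts used",
                 unplaced))
  }
  bind_rows(out)
}

gen_variant_block <- function(n, cfg, reference, titv, snv_indel_ratio,
                              weights, tad_weighted = FALSE,
                              bin_weights = NULL, context_boost = 1) {
  chroms <- names(reference$chrom_lengths)
  lens <- reference$chrom_lengths
  seqs <- reference$sequences
  n_snv <- round(n * snv_indel_ratio / (1 + snv_indel_ratio))
  n_ind <- n - n_snv
  n_ins <- round(n_ind * cfg$ins_fraction)
  n_del <- n_ind - n_ins

  # SNVs
  if (tad_weighted) {
    cv <- alloc_chroms(n_snv, chroms, lens, weights)
    per <- table(factor(cv, chroms))
    snv_pos <- place_weighted_positions(setNames(as.integer(per), chroms),
                                        bin_weights, lens)
  } else {
    cv <- alloc_chroms(n_snv, chroms, lens, weights)
    snv_pos <- tibble(chrom = cv, pos = uniform_positions(cv, lens))
  }
  snvs <- bind_cols(snv_pos,
                    snv_alleles(seqs, snv_pos$chrom, snv_pos$pos, titv)) |>
    mutate(origin_type = "SNV", context_true = NA_character_,
           del_len = NA_integer_)

  # insertions: inserted strings drawn uniformly, positions uniform
  ci <- alloc_chroms(n_ins, chroms, lens, weights)
  ipos <- uniform_positions(ci, lens)
  ilen <- pmin(1L + stats::rgeom(n_ins, cfg$indel_length_decay),
               cfg$max_indel_length)
  iref <- unname(substring(seqs[ci], ipos, ipos))
  ins <- tibble(chrom = ci, pos = ipos, ref = iref,
                alt = paste0(iref, random_strings(ilen)),
                origin_type = "ins", context_true = NA_character_,
                del_len = NA_integer_)

  # deletions: context-controlled placement for every pool, so filtering
  # leaves the signature distribution patterns unchanged; the triplet boost
  # applies only where requested (IR-specific deletions)
  dels <- place_context_deletions(n_del, cfg, reference, weights,
                                  boost = context_boost) |>
    mutate(origin_type = "del")
  bind_rows(snvs, ins, dels)
}

#' Generate the control pool and treated variant sets
#'
#' Treated samples contain `shared_fraction` variants drawn from the control
#' pool (with freshly drawn per-sample depth/quality), treatment-specific
#' variants with the IR Ti/Tv, SNV:InDel ratio, per-chromosome weights,
#' TAD-weighted SNV placement and context-controlled deletions, and a small
#' fraction of artifact variants whose alternate support is drawn from
#' `Binomial(DP, error_rate)`. Deletion context placement is validated with
#' the package's own classifier.
#'
#' @param config A [sim_config()].
#' @param reference Output of [sim_reference()].
#' @return List with `control` (variant tibble), `treated` (named list of
#'   variant tibbles with an `origin` column: shared / ir / artifact), and
#'   `truth` (per-sample origin counts).
#' @export
sim_variants <- function(config, reference) {
  withr::with_seed(config$seed + 202L, {
    cfg <- config
    chroms <- names(reference$chrom_lengths)
    lens <- reference$chrom_lengths
    ctrl_w <- cfg$per_chromosome_weights^0.3  # ~2x pre-IR spread

    control <- gen_variant_block(cfg$n_control_variants, cfg, reference,
                                 titv = cfg$pre_titv,
                                 snv_indel_ratio = cfg$pre_snv_indel_ratio,
                                 weights = ctrl_w) |>
      distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
               .keep_all = TRUE) |>
      arrange(.data$chrom, .data$pos)
    control <- bind_cols(control, draw_depths(nrow(control), cfg))
    control$ann <- make_annotations(nrow(control), cfg)
    control$sample <- "control"
    control$origin <- "control"
    control <- select(control, "sample", "chrom", "pos", "ref", "alt",
                      "gt", "dp", "gq", "alt_count", "ann", "origin",
                      "context_true", "del_len")

    bin_w <- build_bin_weights(reference, cfg)
    labels <- as.vector(outer(cfg$doses, cfg$repair_intervals,
                              function(d, r) paste0(d, "Gy_", r)))

    treated <- vector("list", length(labels))
    names(treated) <- labels
    truth <- vector("list", length(labels))
    names(truth) <- labels
    for (lab in labels) {
      n_tot <- cfg$n_treated_variants
      n_art <- round(n_tot * cfg$error_variant_rate)
      n_rest <- n_tot - n_art
      n_shared <- round(n_rest * cfg$shared_fraction)
      n_spec <- n_rest - n_shared

      shared <- control[sample.int(nrow(control), n_shared), ] |>
        select("chrom", "pos", "ref", "alt", "ann", "context_true",
               "del_len")
      shared <- bind_cols(shared, draw_depths(n_shared, cfg))
      shared$origin <- "shared"

      spec <- gen_variant_block(n_spec, cfg, reference,
                                titv = cfg$ir_titv,
                                snv_indel_ratio = cfg$ir_snv_indel_ratio,
                                weights = cfg$per_chromosome_weights,
                                tad_weighted = TRUE, bin_weights = bin_w,
                                context_boost = cfg$triplet_none_boost)
      spec <- bind_cols(spec, draw_depths(nrow(spec), cfg))
      spec$ann <- make_annotations(nrow(spec), cfg)
      spec$origin <- "ir"
      spec$origin_type <- NULL

      ca <- sample(chroms, n_art, replace = TRUE,
                   prob = lens / sum(lens))
      art <- tibble(chrom = ca, pos = uniform_positions(ca, lens))
      art <- bind_cols(art, snv_alleles(reference$sequences, art$chrom,
                                        art$pos, cfg$pre_titv))
      art_dp <- pmax(1L, stats::rpois(n_art, cfg$dp_mean))
      art <- art |>
        mutate(gt = "0/1", dp = art_dp,
               gq = pmin(99L, pmax(0L, as.integer(
                 round(rnorm(n_art, cfg$gq_mean, cfg$gq_sd))))),
               alt_count = stats::rbinom(n_art, art_dp, cfg$error_rate),
               origin = "artifact", context_true = NA_character_,
               del_len = NA_integer_)
      art$ann <- make_annotations(n_art, cfg)

      smp <- bind_rows(shared, spec, art) |>
        distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                 .keep_all = TRUE) |>
        arrange(.data$chrom, .data$pos)
      smp$sample <- lab
      smp <- select(smp, "sample", "chrom", "pos", "ref", "alt", "gt",
                    "dp", "gq", "alt_count", "ann", "origin",
                    "context_true", "del_len")
      treated[[lab]] <- smp
      truth[[lab]] <- count(smp, .data$origin, name = "n")
    }
    list(control = control, treated = treated, truth = truth)
  })
}

#' Generate control and treated translocation tables
#'
#' A configured fraction of each treated sample's events are duplicated from
#' control events with both breakends jittered by less than 200 nt (so a
#' 200-nt window removes them); the remainder are novel events placed at
#' least 5 kb from every other event. Supporting reads are drawn from 10-40
#' and confidence from 60-99, straddling the 20-read and 80-score
#' thresholds.
#'
#' @param config A [sim_config()].
#' @return List with `control` (call tibble), `treated` (named list of call
#'   tibbles carrying `origin` and `passes_quality` ground-truth columns)
#'   and `truth` (per-sample expected retained counts).
#' @export
sim_translocations <- function(config) {
  if (length(config$chrom_lengths) < 2) {
    abort("translocation simulation needs at least 2 chromosomes")
  }
  withr::with_seed(config$seed + 303L, {
    cfg <- config
    chroms <- normalize_chrom(names(cfg$chrom_lengths))
    lens <- as.integer(cfg$chrom_lengths)
    names(lens) <- chroms

    # breakend grid with 5 kb spacing keeps all distinct events well apart
    grids <- lapply(chroms, function(cn)
      sample(seq(10000L, lens[[cn]] - 10000L, by = 5000L)))
    names(grids) <- chroms
    cursor <- setNames(rep(1L, length(chroms)), chroms)
    take_point <- function(cn) {
      p <- grids[[cn]][cursor[[cn]]]
      cursor[[cn]] <<- cursor[[cn]] + 1L
      p
    }

    draw_events <- function(n) {
      ca <- character(n); cb <- character(n)
      pa <- integer(n); pb <- integer(n)
      for (i in seq_len(n)) {
        pr <- sort(sample(chroms, 2L))
        ca[i] <- pr[1]; cb[i] <- pr[2]
        pa[i] <- take_point(pr[1]); pb[i] <- take_point(pr[2])
      }
      tibble(chrom_a = ca, pos_a = pa, chrom_b = cb, pos_b = pb,
             supporting_reads = sample(10:40, n, replace = TRUE),
             confidence = as.numeric(sample(60:99, n, replace = TRUE)))
    }

    control <- draw_events(cfg$n_control_translocations)

    labels <- as.vector(outer(cfg$doses, cfg$repair_intervals,
                              function(d, r) paste0(d, "Gy_", r)))
    treated <- vector("list", length(labels))
    names(treated) <- labels
    truth <- vector("list", length(labels))
    names(truth) <- labels
    for (lab in labels) {
      n_sh <- round(cfg$n_translocations * cfg$control_translocation_fraction)
      n_nov <- cfg$n_translocations - n_sh
      sh_idx <- sample.int(nrow(control), n_sh,
                           replace = n_sh > nrow(control))
      sh <- control[sh_idx, ]
      sh$pos_a <- sh$pos_a + sample(-199:199, n_sh, replace = TRUE)
      sh$pos_b <- sh$pos_b + sample(-199:199, n_sh, replace = TRUE)
      sh$supporting_reads <- sample(10:40, n_sh, replace = TRUE)
      sh$confidence <- as.numeric(sample(60:99, n_sh, replace = TRUE))
      sh$origin <- "control_shared"
      nov <- draw_events(n_nov)
      nov$origin <- "novel"
      smp <- bind_rows(sh, nov) |>
        mutate(passes_quality = .data$supporting_reads >= 20 &
                 .data$confidence > 80)
      smp <- smp[sample.int(nrow(smp)), ]
      treated[[lab]] <- smp
      truth[[lab]] <- tibble(
        sample = lab, n_events = nrow(smp), n_control_shared = n_sh,
        n_expected_retained = sum(smp$origin == "novel" & smp$passes_quality))
    }
    list(control = control, treated = treated, truth = bind_rows(truth))
  })
}

#' Generate and write a complete synthetic input set
#'
#' Runs [sim_reference()], [sim_variants()] and [sim_translocations()] and
#' writes every external format the pipeline consumes: reference FASTA,
#' cytogenetic band table, TAD BED, gene-density TSV, control and
#' per-sample VCFs (with ANN annotations), BreakDancer-style translocation
#' tables and a JSON manifest of ground-truth parameters for recovery
#' tests. Output is bit-identical for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return (Invisibly) a list with `paths`, `config`, `reference`,
#'   `variants`, `translocations`.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- sim_reference(config)
  vars <- sim_variants(config, ref)
  tl <- sim_translocations(config)

  paths <- list(
    reference = file.path(dir, "reference.fa"),
    cytobands = file.path(dir, "cytobands.txt"),
    tads = file.path(dir, "tads.bed"),
    gene_density = file.path(dir, "gene_density.tsv"),
    control_vcf = file.path(dir, "control.vcf"),
    control_translocations = file.path(dir, "translocations_control.txt"),
    manifest = file.path(dir, "manifest.json")
  )

  dna <- Biostrings::DNAStringSet(ref$sequences)
  names(dna) <- add_chr_prefix(names(ref$sequences))
  Biostrings::writeXStringSet(dna, paths$reference, width = 70L)

  write_intervals(ref$bands, paths$cytobands,
                  extra = rep("gneg", nrow(ref$bands)))
  write_intervals(ref$tads, paths$tads)
  readr::write_tsv(ref$gene_density |>
                     mutate(chrom = add_chr_prefix(.data$chrom)),
                   paths$gene_density, progress = FALSE)

  write_vcf(vars$control, paths$control_vcf,
            contig_lengths = ref$chrom_lengths)
  for (lab in names(vars$treated)) {
    p <- file.path(dir, paste0(lab, ".vcf"))
    paths[[paste0("vcf_", lab)]] <- p
    write_vcf(vars$treated[[lab]], p, contig_lengths = ref$chrom_lengths)
  }

  write_translocation_table(tl$control, paths$control_translocations)
  for (lab in names(tl$treated)) {
    p <- file.path(dir, paste0("translocations_", lab, ".txt"))
    paths[[paste0("tl_", lab)]] <- p
    write_translocation_table(tl$treated[[lab]], p)
  }

  manifest <- list(
    seed = config$seed,
    chrom_lengths = as.list(config$chrom_lengths),
    parameters = config[c("shared_fraction", "pre_titv", "ir_titv",
                          "pre_snv_indel_ratio", "ir_snv_indel_ratio",
                          "ins_fraction", "indel_length_decay",
                          "context_mix", "triplet_none_boost",
                          "tad_inside_weight", "tad_boundary_weight",
                          "error_variant_rate", "error_rate")],
    variant_truth = lapply(vars$truth, function(x) as.list(setNames(x$n, x$origin))),
    translocation_truth = tl$truth
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(paths = paths, config = config, reference = ref,
                 variants = vars, translocations = tl))
}
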
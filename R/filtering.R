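# Three-stage filter chain isolating IR-induced variants:
#   1. sample filter    — remove variants present in the untreated control
#                         pool (matching on chrom, pos, ref, alt);
#   2. coverage filter  — require DP >= 3 and GQ >= 20 (inclusive minima);
#   3. binomial filter  — remove variants whose alternate-read support is
#                         consistent with a sequencing error rate of 0.001
#                         (exact one-sided binomial tail test).
# The three predicates are independent, so the retained set does not depend
# on stage order; per-stage removal tallies do.

#' Remove control-pool variants from a treated sample
#'
#' Retains exactly those treated variants with no control-pool entry matching
#' on (chrom, pos, ref, alt). Genotype is ignored: matching operates on
#' variant pools, not genotypes.
#'
#' @param treated Variant tibble for a treated sample.
#' @param control_pool Variant tibble; the union over all control samples.
#' @return Treated variants absent from the control pool.
#' @export
sample_filter <- function(treated, control_pool) {
  if (!nrow(control_pool)) {
    warn("control pool is empty; all treated variants retained")
    return(treated)
  }
  pool <- distinct(control_pool[, c("chrom", "pos", "ref", "alt")])
  anti_join(treated, pool, by = c("chrom", "pos", "ref", "alt"))
}

#' Depth / genotype-quality coverage filter
#'
#' Retains variants with `dp >= dp_min` and `gq >= gq_min` (both inclusive).
#' Variants lacking DP or GQ are retained with a warning and counted
#' separately in the chain report.
#'
#' @param variants Variant tibble.
#' @param dp_min Minimum sequencing depth (default 3).
#' @param gq_min Minimum genotype quality (default 20).
#' @return Filtered variant tibble.
#' @export
coverage_filter <- function(variants, dp_min = 3, gq_min = 20) {
  flagged <- is.na(variants$dp) | is.na(variants$gq)
  if (any(flagged)) {
    warn(sprintf("%d variant(s) lack DP and/or GQ; retained unfiltered",
                 sum(flagged)))
  }
  variants[flagged | (variants$dp >= dp_min & variants$gq >= gq_min), ]
}

#' Exact binomial tail probability of the alternate-read support
#'
#' One-sided tail `P(X >= alt_count)` with `X ~ Binomial(dp, error_rate)`:
#' the probability of seeing at least the observed alternate support from
#' sequencing error alone.
#'
#' @param alt_count Alternate-supporting read counts.
#' @param dp Sequencing depths.
#' @param error_rate Per-read sequencing error probability (default 0.001).
#' @return Numeric vector of tail probabilities.
#' @export
binomial_error_p <- function(alt_count, dp, error_rate = 0.001) {
  stats::pbinom(alt_count - 1, dp, error_rate, lower.tail = FALSE)
}

#' Binomial sequencing-error filter
#'
#' Retains a variant iff its alternate support is inconsistent with
#' sequencing error alone: `P(X >= alt_count) < alpha` with
#' `X ~ Binomial(dp, error_rate)`. A variant with `alt_count = 0` has tail
#' probability 1 and is removed. Variants lacking `alt_count` or `dp` skip
#' this filter (retained with a warning).
#'
#' @inheritParams binomial_error_p
#' @param variants Variant tibble with `alt_count` and `dp` columns.
#' @param alpha Significance level for retention (default 0.001).
#' @return Filtered variant tibble.
#' @export
binomial_filter <- function(variants, error_rate = 0.001, alpha = 0.001) {
  skip <- is.na(variants$alt_count) | is.na(variants$dp)
  if (any(skip)) {
    warn(sprintf("%d variant(s) lack AD/DP; binomial filter skipped for them",
                 sum(skip)))
  }
  bad <- !skip & variants$alt_count > variants$dp
  if (any(bad)) abort("alt_count exceeds dp; corrupt allelic depths")
  p <- binomial_error_p(variants$alt_count, variants$dp, error_rate)
  variants[skip | (p < alpha), ]
}

#' Run the full three-stage filter chain
#'
#' Applies the sample, coverage and binomial filters in order and reconciles
#' per-stage removal tallies in a `filter_report`. The retained set is the
#' intersection of the three stage predicates and therefore independent of
#' stage order; the chain is idempotent.
#'
#' @inheritParams coverage_filter
#' @inheritParams binomial_filter
#' @param treated Variant tibble for one treated sample.
#' @param control_pool Union of control-sample variant tibbles.
#' @param keep_all Return all input variants with a `filter` column naming
#'   the first failing stage (`"PASS"` otherwise) instead of dropping them.
#' @param quiet Suppress per-stage record-count messages.
#' @return A list with `variants` (the retained tibble, or the annotated full
#'   tibble when `keep_all = TRUE`) and `report` (a `filter_report`; see
#'   [tidy.filter_report()]).
#' @export
run_filter_chain <- function(treated, control_pool,
                             dp_min = 3, gq_min = 20,
                             error_rate = 0.001, alpha = 0.001,
                             keep_all = FALSE, quiet = TRUE) {
  v <- classify_indel(treated)
  v$.type <- ifelse(v$variant_type %in% c("ins", "del"), "InDel", v$variant_type)

  pool_keys <- if (nrow(control_pool)) {
    unique(variant_key(control_pool))
  } else {
    character()
  }
  if (!nrow(control_pool)) warn("control pool is empty; sample filter is a no-op")
  pass_sample <- !(variant_key(v) %in% pool_keys)

  flagged_cov <- is.na(v$dp) | is.na(v$gq)
  pass_cov <- flagged_cov | (v$dp >= dp_min & v$gq >= gq_min)

  flagged_bin <- is.na(v$alt_count) | is.na(v$dp)
  if (any(!flagged_bin & v$alt_count > v$dp)) {
    abort("alt_count exceeds dp; corrupt allelic depths")
  }
  p <- binomial_error_p(v$alt_count, v$dp, error_rate)
  pass_bin <- flagged_bin | (!is.na(p) & p < alpha)

  stage <- dplyr::case_when(
    !pass_sample ~ "sample_filter",
    !pass_cov ~ "coverage_filter",
    !pass_bin ~ "binomial_filter",
    TRUE ~ "PASS"
  )
  retained <- pass_sample & pass_cov & pass_bin

  counts <- tibble(type = v$.type, stage = stage, dp = v$dp,
                   retained = retained) |>
    group_by(.data$type) |>
    summarise(
      before = dplyr::n(),
      removed_sample = sum(.data$stage == "sample_filter"),
      removed_coverage = sum(.data$stage == "coverage_filter"),
      removed_binomial = sum(.data$stage == "binomial_filter"),
      after = sum(.data$retained),
      dp_before = sum(.data$dp, na.rm = TRUE),
      dp_after = sum(.data$dp[.data$retained], na.rm = TRUE),
      .groups = "drop"
    )

  report <- structure(
    list(
      counts = counts,
      n_flagged_coverage = sum(flagged_cov),
      n_flagged_binomial = sum(flagged_bin),
      params = list(dp_min = dp_min, gq_min = gq_min,
                    error_rate = error_rate, alpha = alpha)
    ),
    class = "filter_report"
  )

  if (!quiet) {
    inform(sprintf(
      "filter chain: %d in; sample -%d; coverage -%d; binomial -%d; %d retained",
      nrow(v), sum(!pass_sample), sum(pass_sample & !pass_cov),
      sum(pass_sample & pass_cov & !pass_bin), sum(retained)))
  }

  v$variant_type <- NULL
  v$indel_length <- NULL
  v$.type <- NULL
  if (keep_all) {
    v$filter <- stage
    list(variants = v, report = report)
  } else {
    list(variants = v[retained, ], report = report)
  }
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Three-stage variant filter report\n")
  cat(sprintf("  thresholds: DP >= %s, GQ >= %s; error rate %g, alpha %g\n",
              x$params$dp_min, x$params$gq_min,
              x$params$error_rate, x$params$alpha))
  print(x$counts)
  if (x$n_flagged_coverage) {
    cat(sprintf("  %d variant(s) lacked DP/GQ (retained, counted separately)\n",
                x$n_flagged_coverage))
  }
  invisible(x)
}

#' Tidy a filter report
#'
#' @param x A `filter_report` from [run_filter_chain()].
#' @param ... Unused.
#' @return Long tibble with one row per (variant type, stage) removal tally.
#' @export
tidy.filter_report <- function(x, ...) {
  x$counts |>
    pivot_longer(c("removed_sample", "removed_coverage", "removed_binomial"),
                 names_to = "stage", values_to = "removed") |>
    mutate(stage = sub("^removed_", "", .data$stage)) |>
    select("type", "stage", "removed", "before", "after")
}

#' Glance at a filter report
#'
#' @param x A `filter_report` from [run_filter_chain()].
#' @param ... Unused.
#' @return One-row tibble with totals and the retained fraction.
#' @export
glance.filter_report <- function(x, ...) {
  tibble(
    n_before = sum(x$counts$before),
    n_after = sum(x$counts$after),
    retained_fraction = sum(x$counts$after) / sum(x$counts$before),
    removed_sample = sum(x$counts$removed_sample),
    removed_coverage = sum(x$counts$removed_coverage),
    removed_binomial = sum(x$counts$removed_binomial)
  )
}
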
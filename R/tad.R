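# Variant accumulation inside and outside topologically associating domains
# (TADs). Each TAD and each gap (the region outside TADs, including the
# chromosome ends) is binned into `n_bins` equally long portions; a variant
# at VCF position p falls in bin floor((p - 1 - start) * n_bins / width).
# Bins therefore differ by at most 1 bp in width when the length is not
# divisible by n_bins.

#' Complement of a TAD set: the gaps
#'
#' Computes the maximal intervals of `[0, chromosome_length)` not covered by
#' any TAD, including the chromosome ends. Overlapping TADs are merged first
#' (with a warning) and TADs extending beyond the chromosome end are clipped
#' (with a warning), so TADs and gaps always partition the chromosome.
#'
#' @param tads Interval tibble (`chrom`, 0-based `start`, exclusive `end`).
#' @param chrom_lengths Named vector of chromosome lengths (bp). Gaps are
#'   computed for every named chromosome, even those without TADs.
#' @return Tibble of gap intervals with `name = "gap"`.
#' @export
complement_gaps <- function(tads, chrom_lengths) {
  names(chrom_lengths) <- normalize_chrom(names(chrom_lengths))
  tads <- mutate(tads, chrom = normalize_chrom(.data$chrom))
  out <- vector("list", length(chrom_lengths))
  for (i in seq_along(chrom_lengths)) {
    cn <- names(chrom_lengths)[i]
    len <- as.numeric(chrom_lengths[[i]])
    t_i <- filter(tads, .data$chrom == cn)
    if (!nrow(t_i)) {
      out[[i]] <- tibble(chrom = cn, start = 0, end = len, name = "gap")
      next
    }
    if (any(t_i$end > len)) {
      warn(sprintf("TAD(s) beyond end of chromosome %s clipped", cn))
      t_i$end <- pmin(t_i$end, len)
      t_i <- filter(t_i, .data$start < .data$end)
    }
    ir <- IRanges::IRanges(t_i$start + 1, t_i$end)
    merged <- IRanges::reduce(ir)
    if (length(merged) < length(ir)) {
      warn(sprintf("overlapping/adjacent TADs on chromosome %s merged", cn))
    }
    gp <- IRanges::gaps(merged, start = 1, end = len)
    out[[i]] <- tibble(chrom = cn,
                       start = IRanges::start(gp) - 1,
                       end = as.numeric(IRanges::end(gp)),
                       name = "gap")
  }
  bind_rows(out)
}

# merged TADs as a tibble (used so that TADs + gaps form a partition)
merge_tads <- function(tads, chrom_lengths) {
  names(chrom_lengths) <- normalize_chrom(names(chrom_lengths))
  tads <- mutate(tads, chrom = normalize_chrom(.data$chrom))
  tads |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      len <- chrom_lengths[[key$chrom]]
      if (!is.null(len) && any(d$end > len)) {
        d$end <- pmin(d$end, len)
        d <- filter(d, .data$start < .data$end)
      }
      m <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
      tibble(start = IRanges::start(m) - 1, end = as.numeric(IRanges::end(m)))
    }) |>
    ungroup() |>
    mutate(name = "TAD")
}

#' Bin variant positions within one interval
#'
#' Assigns each VCF position `p` inside `[start, end)` to bin
#' `floor((p - 1 - start) * n_bins / (end - start))` (clamped to the last
#' bin) and returns the per-bin counts. Positions outside the interval are
#' ignored. An interval shorter than `n_bins` falls back to a single bin
#' (all counts in bin 1) with a warning.
#'
#' @param pos Integer vector of 1-based VCF positions.
#' @param start,end Interval bounds (0-based half-open).
#' @param n_bins Number of equally long portions (default 10).
#' @return Integer vector of `n_bins` counts.
#' @export
bin_counts <- function(pos, start, end, n_bins = 10) {
  width <- end - start
  inside <- pos - 1 >= start & pos - 1 < end
  pos <- pos[inside]
  if (width < n_bins) {
    warn("interval shorter than n_bins; single-bin fallback")
    return(c(length(pos), rep(0L, n_bins - 1L)))
  }
  b <- floor((pos - 1 - start) * n_bins / width)
  b <- pmin(pmax(b, 0), n_bins - 1)
  tabulate(b + 1L, nbins = n_bins)
}

#' Binned variant profile across TADs and gaps
#'
#' Merges the input TADs (with a warning if overlapping), computes the gap
#' complement, and bins the variants of every domain into `n_bins` equally
#' long portions. TADs and gaps partition each chromosome, so the summed bin
#' counts equal the per-chromosome variant totals.
#'
#' @param variants Variant tibble.
#' @param tads TAD interval tibble.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param n_bins Bins per domain (default 10).
#' @return Tibble with `chrom`, `domain_id`, `location` (`"inside"` /
#'   `"outside"`), `start`, `end`, `bin` (1-based), `count`; `n_bins` rows
#'   per domain.
#' @export
tad_bin_profile <- function(variants, tads, chrom_lengths, n_bins = 10) {
  merged <- merge_tads(tads, chrom_lengths)
  gaps_tbl <- suppressWarnings(complement_gaps(merged, chrom_lengths))
  domains <- bind_rows(
    mutate(merged, location = "inside"),
    mutate(gaps_tbl, location = "outside")
  ) |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(domain_id = paste0(.data$chrom, ".", .data$location, ".",
                              cumulate_location(.data$location))) |>
    ungroup()

  variants <- mutate(variants, chrom = normalize_chrom(.data$chrom))
  rows <- vector("list", nrow(domains))
  for (i in seq_len(nrow(domains))) {
    d <- domains[i, ]
    pos <- variants$pos[variants$chrom == d$chrom]
    counts <- suppressWarnings(bin_counts(pos, d$start, d$end, n_bins))
    rows[[i]] <- tibble(chrom = d$chrom, domain_id = d$domain_id,
                        location = d$location, start = d$start, end = d$end,
                        bin = seq_len(n_bins), count = counts)
  }
  bind_rows(rows)
}

# running index per location value ("inside.1", "inside.2", ... style ids)
cumulate_location <- function(location) {
  stats::ave(seq_along(location), location, FUN = seq_along)
}

#' Inside:outside TAD variant ratios
#'
#' @param profile A binned profile from [tad_bin_profile()].
#' @return Per-chromosome tibble with inside/outside counts and covered
#'   lengths, the raw count ratio and the length-normalized density ratio
#'   (`(inside per Mb) / (outside per Mb)`); ratios are `NA` when the
#'   denominator is 0.
#' @export
inside_outside_ratio <- function(profile) {
  by_loc <- profile |>
    group_by(.data$chrom, .data$location) |>
    summarise(
      count = sum(.data$count),
      length = sum((.data$end - .data$start)[!duplicated(.data$domain_id)]),
      .groups = "drop"
    ) |>
    pivot_wider(names_from = "location", values_from = c("count", "length"),
                values_fill = 0)
  for (col in c("count_inside", "count_outside", "length_inside", "length_outside")) {
    if (!col %in% names(by_loc)) by_loc[[col]] <- 0
  }
  by_loc |>
    mutate(
      raw_ratio = ifelse(.data$count_outside == 0, NA_real_,
                         .data$count_inside / .data$count_outside),
      norm_ratio = ifelse(.data$count_outside == 0 | .data$length_inside == 0 |
                            .data$length_outside == 0, NA_real_,
                          (.data$count_inside / .data$length_inside) /
                            (.data$count_outside / .data$length_outside))
    )
}

#' Aggregate bin counts across domains
#'
#' Element-wise sum of the bin vectors of all domains, per chromosome and
#' location; order of domain processing does not matter.
#'
#' @param profile A binned profile from [tad_bin_profile()].
#' @return Tibble with `chrom`, `location`, `bin`, `count`.
#' @export
bin_aggregate <- function(profile) {
  profile |>
    group_by(.data$chrom, .data$location, .data$bin) |>
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Boundary enrichment score
#'
#' Operationalizes "accumulation at domain borders": per chromosome and
#' location, the aggregated first and last bins are compared against the
#' interior bins; `score = mean(edge bins) / mean(interior bins)`, `NA` when
#' the interior mean is 0.
#'
#' @param profile A binned profile from [tad_bin_profile()].
#' @return Tibble with `chrom`, `location`, `edge_mean`, `interior_mean`,
#'   `score`.
#' @export
boundary_enrichment <- function(profile) {
  n_bins <- max(profile$bin)
  bin_aggregate(profile) |>
    group_by(.data$chrom, .data$location) |>
    summarise(
      edge_mean = mean(.data$count[.data$bin %in% c(1L, n_bins)]),
      interior_mean = mean(.data$count[!.data$bin %in% c(1L, n_bins)]),
      .groups = "drop"
    ) |>
    mutate(score = ifelse(.data$interior_mean == 0, NA_real_,
                          .data$edge_mean / .data$interior_mean))
}
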
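# Inter-chromosomal translocation post-processing: windowed control
# subtraction, support/confidence filtering and per-chromosome-pair counts.
#
# Two calls are "equal" when their chromosome pairs match and both breakends
# lie within the same 200-nucleotide window (strict <, configurable). Reads
# are thresholded inclusively ("at least 20"), confidence strictly
# ("greater than 80").

#' Windowed equality of two translocation calls
#'
#' @param a,b One-row tibbles (or lists) with `chrom_a`, `pos_a`, `chrom_b`,
#'   `pos_b`, canonically ordered.
#' @param window Window size in bp (default 200); both breakend offsets must
#'   be strictly smaller.
#' @return `TRUE` iff the chromosome pairs match and both breakends fall
#'   within the window.
#' @export
windowed_equal <- function(a, b, window = 200) {
  a$chrom_a == b$chrom_a && a$chrom_b == b$chrom_b &&
    abs(a$pos_a - b$pos_a) < window && abs(a$pos_b - b$pos_b) < window
}

# for each row of x, is any row of y windowed-equal?
has_windowed_match <- function(x, y, window = 200) {
  if (!nrow(x)) return(logical())
  if (!nrow(y)) return(rep(FALSE, nrow(x)))
  x$.row <- seq_len(nrow(x))
  m <- inner_join(x, y, by = c("chrom_a", "chrom_b"),
                  suffix = c("", ".y"), relationship = "many-to-many") |>
    filter(abs(.data$pos_a - .data$pos_a.y) < window,
           abs(.data$pos_b - .data$pos_b.y) < window)
  seq_len(nrow(x)) %in% m$.row
}

#' Remove translocations shared with control samples
#'
#' Retains the treated calls with no windowed-equal control call, keeping
#' only rearrangements induced after irradiation.
#'
#' @param treated_calls,control_calls Translocation tibbles (see
#'   [read_translocation_table()]).
#' @param window Window size in bp (default 200).
#' @return The treated calls without control-shared events.
#' @export
subtract_controls <- function(treated_calls, control_calls, window = 200) {
  treated_calls[!has_windowed_match(treated_calls, control_calls, window), ]
}

#' Support/confidence filter for translocation calls
#'
#' Retains calls with `supporting_reads >= min_reads` (inclusive) and
#' `confidence > min_confidence` (strict).
#'
#' @param calls Translocation tibble.
#' @param min_reads Minimum supporting reads (default 20, inclusive).
#' @param min_confidence Confidence threshold (default 80, exclusive).
#' @return Filtered tibble.
#' @export
quality_filter <- function(calls, min_reads = 20, min_confidence = 80) {
  calls[calls$supporting_reads >= min_reads &
          calls$confidence > min_confidence, ]
}

#' Deduplicate windowed-equal calls within one sample
#'
#' Greedily keeps the highest-confidence call of every windowed-equal group.
#'
#' @inheritParams quality_filter
#' @param window Window size in bp (default 200).
#' @return Deduplicated tibble.
#' @export
dedup_translocations <- function(calls, window = 200) {
  if (nrow(calls) < 2) return(calls)
  ord <- order(-calls$confidence, -calls$supporting_reads)
  calls <- calls[ord, ]
  kept <- calls[0, ]
  for (i in seq_len(nrow(calls))) {
    if (!any(has_windowed_match(calls[i, ], kept, window))) {
      kept <- bind_rows(kept, calls[i, ])
    }
  }
  kept
}

#' Per-chromosome-pair translocation counts
#'
#' Counts calls per unordered chromosome pair (direction is ignored; calls
#' are canonically ordered, so the pair map is symmetric by construction).
#'
#' @param calls Inter-chromosomal translocation tibble.
#' @return Tibble with `chrom_a`, `chrom_b`, `n`, sorted by pair; the total
#'   call count is attached as attribute `"total"`.
#' @export
pair_matrix <- function(calls) {
  out <- calls |>
    count(.data$chrom_a, .data$chrom_b, name = "n") |>
    arrange(.data$chrom_a, .data$chrom_b)
  structure(out, total = sum(out$n))
}

#' Full translocation post-processing pipeline
#'
#' Control subtraction, optional within-sample deduplication (highest
#' confidence kept), then the support/confidence filter — the
#' post-processing applied to each treated sample's call table.
#'
#' @inheritParams subtract_controls
#' @inheritParams quality_filter
#' @param dedup Merge windowed-equal treated calls before counting (default
#'   `TRUE`).
#' @return List with `calls` (retained tibble) and `matrix`
#'   ([pair_matrix()] of the retained calls).
#' @export
translocation_pipeline <- function(treated_calls, control_calls,
                                   window = 200, min_reads = 20,
                                   min_confidence = 80, dedup = TRUE) {
  kept <- subtract_controls(treated_calls, control_calls, window)
  if (dedup) kept <- dedup_translocations(kept, window)
  kept <- quality_filter(kept, min_reads, min_confidence)
  list(calls = kept, matrix = pair_matrix(kept))
}
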
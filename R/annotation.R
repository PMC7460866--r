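# Functional-impact summaries of SnpEff-annotated variants.
#
# Counting rules: annotations are restricted to "known" RefSeq
# protein-coding transcripts (NM_/NR_ accessions); per chromosomal location
# (chrom, pos, ref, alt) each distinct combined SO term contributes once
# regardless of how many transcripts carry it; the impact of a location is
# the highest-severity impact among its retained annotations
# (HIGH > MODERATE > LOW > MODIFIER).

SO_TERM_MAP <- c(
  "splice_region_variant&intron_variant" = "splice_region",
  "splice_region_variant" = "splice_region",
  "splice_region_variant&synonymous_variant" = "splice_region",
  "splice_region_variant&non_coding_exon_variant" = "splice_region",
  "splice_acceptor_variant&intron_variant" = "splice_site",
  "splice_donor_variant&intron_variant" = "splice_site",
  "splice_acceptor_variant&splice_donor_variant&intron_variant" = "splice_site",
  "missense_variant&splice_region_variant" = "missense_variant",
  "stop_retained_variant" = "synonymous_variant",
  "stop_gained&splice_region_variant" = "stop_gained",
  "5_prime_UTR_premature_start_codon_gain_variant" = "5_prime_UTR_variant"
)

#' Combine sequence-ontology terms into less specific ones
#'
#' Maps compound or overly specific SnpEff SO terms to the combined terms
#' used for reporting (e.g. `"splice_acceptor_variant&intron_variant"` ->
#' `"splice_site"`, `"stop_retained_variant"` -> `"synonymous_variant"`).
#' Unmapped terms pass through unchanged.
#'
#' @param so_term Character vector of SO term strings.
#' @return Character vector of combined terms.
#' @export
#' @examples
#' combine_so_terms(c("splice_region_variant&intron_variant",
#'                    "synonymous_variant"))
combine_so_terms <- function(so_term) {
  mapped <- unname(SO_TERM_MAP[so_term])
  dplyr::coalesce(mapped, so_term)
}

#' Tally predicted functional impact of annotated variants
#'
#' Summarizes the `ann` list-column of a variant tibble into per-impact and
#' per-combined-term counts. Annotations are filtered to RefSeq-known
#' transcripts (unless `refseq_only = FALSE`); each (location, combined
#' term) pair counts once; each location contributes one impact, the most
#' severe among its retained annotations. Variants with no retained
#' annotation are counted under a configurable fallback.
#'
#' @param variants Variant tibble with an `ann` list-column.
#' @param by Grouping for the tallies: `"genome"`, `"chromosome"` or
#'   `"band"` (requires `bands`).
#' @param bands Interval tibble of cytogenetic bands (needed for
#'   `by = "band"`); a variant's band is the interval containing `pos - 1`.
#' @param refseq_only Restrict to annotations with `is_refseq_known`.
#' @param unannotated_impact,unannotated_term Fallback impact/term for
#'   locations with no retained annotation.
#' @return List of class `impact_tally` with `impacts` (tibble `group`,
#'   `impact`, `n`; zero-filled over the four SnpEff classes) and `terms`
#'   (tibble `group`, `term`, `n`).
#' @export
impact_tally <- function(variants, by = c("genome", "chromosome", "band"),
                         bands = NULL, refseq_only = TRUE,
                         unannotated_impact = "MODIFIER",
                         unannotated_term = "unannotated") {
  by <- match.arg(by)
  v <- variants
  v$.loc <- variant_key(v)
  v$group <- switch(by,
    genome = "genome",
    chromosome = v$chrom,
    band = assign_band(v, bands)
  )

  ann_long <- v |>
    select(".loc", "group", "ann") |>
    mutate(ann = map(.data$ann, ~ .x %||% empty_ann())) |>
    unnest("ann", keep_empty = FALSE)
  if (!"impact" %in% names(ann_long)) {
    ann_long <- bind_cols(ann_long[, c(".loc", "group")], empty_ann())
  }
  if (refseq_only) {
    ann_long <- filter(ann_long, .data$is_refseq_known)
  }
  ann_long <- filter(ann_long, .data$impact %in% IMPACT_LEVELS)
  ann_long$term <- combine_so_terms(ann_long$so_term)

  locs <- distinct(v, .data$.loc, .data$group)
  annotated <- distinct(ann_long, .data$.loc)

  # one impact per location: the most severe retained annotation
  impact_per_loc <- if (nrow(ann_long)) {
    ann_long |>
      mutate(sev = match(.data$impact, IMPACT_LEVELS)) |>
      group_by(.data$.loc, .data$group) |>
      summarise(impact = IMPACT_LEVELS[min(.data$sev)], .groups = "drop")
  } else {
    tibble(.loc = character(), group = character(), impact = character())
  }
  unann <- locs |>
    anti_join(annotated, by = ".loc") |>
    mutate(impact = unannotated_impact)
  impacts <- bind_rows(impact_per_loc, unann) |>
    count(.data$group, .data$impact, name = "n") |>
    mutate(impact = factor(.data$impact, levels = IMPACT_LEVELS)) |>
    tidyr::complete(group = unique(locs$group),
                    impact = factor(IMPACT_LEVELS, levels = IMPACT_LEVELS),
                    fill = list(n = 0L)) |>
    arrange(.data$group, .data$impact) |>
    mutate(impact = as.character(.data$impact), n = as.integer(.data$n))

  # each distinct (location, combined term) once
  terms <- bind_rows(
    distinct(ann_long, .data$.loc, .data$group, .data$term),
    mutate(unann[c(".loc", "group")], term = unannotated_term)
  ) |>
    count(.data$group, .data$term, name = "n") |>
    arrange(.data$group, .data$term)

  structure(list(impacts = impacts, terms = terms, by = by),
            class = "impact_tally")
}

assign_band <- function(variants, bands) {
  if (is.null(bands)) abort("`bands` is required for by = \"band\"")
  out <- rep("unassigned", nrow(variants))
  for (cn in unique(bands$chrom)) {
    idx <- which(variants$chrom == cn)
    if (!length(idx)) next
    b <- bands[bands$chrom == cn, ]
    subj <- IRanges::IRanges(b$start + 1, b$end)
    hit <- IRanges::findOverlaps(IRanges::IRanges(variants$pos[idx],
                                                  variants$pos[idx]),
                                 subj, select = "first")
    out[idx[!is.na(hit)]] <- b$name[hit[!is.na(hit)]]
  }
  out
}

#' @export
print.impact_tally <- function(x, ...) {
  cat(sprintf("Functional impact tally (grouping: %s)\n", x$by))
  print(pivot_wider(x$impacts, names_from = "impact", values_from = "n"))
  invisible(x)
}

#' Tidy an impact tally
#'
#' @param x An `impact_tally` from [impact_tally()].
#' @param ... Unused.
#' @return Long tibble of per-group impact counts.
#' @export
tidy.impact_tally <- function(x, ...) x$impacts
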
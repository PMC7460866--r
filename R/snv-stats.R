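# Accumulation and substitution statistics.
#
# Band-normalized accumulation:  V/Mb = 1e6 * count / (end - start).
# Ti/Tv: transitions are the purine-purine (A<->G) and pyrimidine-pyrimidine
# (C<->T) substitutions; everything else is a transversion.

TI_PAIRS <- c("A>G", "G>A", "C>T", "T>C")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Variant accumulation per genomic interval
#'
#' Counts variants per interval and normalizes to variants per megabase.
#' A variant at VCF position `p` is assigned to the unique interval
#' `[start, end)` with `start <= p - 1 < end`. Variants outside every
#' interval of their chromosome are tallied in an `"unassigned"` row.
#'
#' @param variants Variant tibble.
#' @param intervals Interval tibble (`chrom`, 0-based `start`, exclusive
#'   `end`, `name`), non-overlapping within chromosome (a warning is emitted
#'   otherwise and the first containing interval wins).
#' @param variant_type Restrict to `"SNV"` or `"InDel"`, or count `"both"`.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `count`, `per_mb`
#'   (`per_mb = 1e6 * count / (end - start)`), plus one `"unassigned"` row
#'   per chromosome that has stray variants.
#' @export
accumulate <- function(variants, intervals,
                       variant_type = c("both", "SNV", "InDel")) {
  variant_type <- match.arg(variant_type)
  if (variant_type != "both") {
    v <- classify_indel(variants)
    keep <- if (variant_type == "SNV") v$variant_type == "SNV"
            else v$variant_type %in% c("ins", "del")
    variants <- variants[keep, ]
  }
  if (any(intervals$end <= intervals$start)) {
    abort("zero- or negative-length interval in `intervals`")
  }
  intervals <- arrange(intervals, .data$chrom, .data$start, .data$end)
  warn_if_overlapping(intervals, "intervals")

  counts <- integer(nrow(intervals))
  unassigned <- tibble(chrom = character(), count = integer())
  for (cn in unique(intervals$chrom)) {
    iv_idx <- which(intervals$chrom == cn)
    pos <- variants$pos[variants$chrom == cn]
    if (!length(pos)) next
    # containment: s <= p - 1 < e  <=>  p in [s + 1, e] (1-based closed)
    subj <- IRanges::IRanges(intervals$start[iv_idx] + 1, intervals$end[iv_idx])
    qry <- IRanges::IRanges(pos, pos)
    hits <- IRanges::findOverlaps(qry, subj, select = "first")
    tab <- tabulate(hits[!is.na(hits)], nbins = length(iv_idx))
    counts[iv_idx] <- tab
    n_out <- sum(is.na(hits))
    if (n_out) {
      unassigned <- bind_rows(unassigned, tibble(chrom = cn, count = n_out))
    }
  }
  # variants on chromosomes with no intervals at all
  stray <- setdiff(unique(variants$chrom), unique(intervals$chrom))
  for (cn in stray) {
    unassigned <- bind_rows(
      unassigned, tibble(chrom = cn, count = sum(variants$chrom == cn)))
  }

  out <- intervals |>
    mutate(count = counts,
           per_mb = 1e6 * counts / (.data$end - .data$start))
  if (nrow(unassigned)) {
    out <- bind_rows(out, mutate(unassigned, start = NA_real_, end = NA_real_,
                                 name = "unassigned", per_mb = NA_real_))
  }
  out
}

#' Whole-chromosome accumulation profile
#'
#' Convenience wrapper around [accumulate()] with one interval per
#' chromosome, yielding per-chromosome counts and variants/Mb.
#'
#' @param variants Variant tibble.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @inheritParams accumulate
#' @return Tibble with `chrom`, `count`, `per_mb`.
#' @export
chromosome_profile <- function(variants, chrom_lengths,
                               variant_type = c("both", "SNV", "InDel")) {
  iv <- tibble(chrom = normalize_chrom(names(chrom_lengths)),
               start = 0, end = as.numeric(chrom_lengths),
               name = "chromosome")
  accumulate(variants, iv, variant_type = match.arg(variant_type)) |>
    filter(.data$name != "unassigned") |>
    select("chrom", "count", "per_mb")
}

#' Transition/transversion summary
#'
#' Counts transitions (A<->G, C<->T) and transversions among the single-base
#' substitutions of `variants` and reports the ratio `nTi/nTv`, plus the six
#' substitution classes collapsed to a pyrimidine reference (C>T, C>A, C>G,
#' T>A, T>C, T>G). Non-SNVs are excluded and tallied in `n_excluded`. The
#' ratio is `NA` when there are no transversions.
#'
#' @param variants Variant tibble.
#' @param by Grouping: `"genome"` (one row), `"chromosome"` or `"sample"`.
#' @return Tibble with `group`, the six class counts, `ti`, `tv`, `titv`,
#'   `n_excluded`.
#' @export
titv <- function(variants, by = c("genome", "chromosome", "sample")) {
  by <- match.arg(by)
  v <- variants
  v$group <- switch(by,
    genome = "genome",
    chromosome = v$chrom,
    sample = v$sample
  )
  is_snv <- nchar(v$ref) == 1 & nchar(v$alt) == 1 &
    v$ref %in% DNA_BASES & v$alt %in% DNA_BASES & v$ref != v$alt
  excl <- v |>
    group_by(.data$group) |>
    summarise(n_excluded = sum(!is_snv[dplyr::cur_group_rows()]),
              .groups = "drop")
  s <- v[is_snv, ]
  # collapse to pyrimidine reference
  flip <- s$ref %in% c("A", "G")
  ref2 <- ifelse(flip, COMPLEMENT[s$ref], s$ref)
  alt2 <- ifelse(flip, COMPLEMENT[s$alt], s$alt)
  s$class <- paste0(ref2, ">", alt2)
  s$is_ti <- paste0(s$ref, ">", s$alt) %in% TI_PAIRS
  classes <- c("C>T", "C>A", "C>G", "T>A", "T>C", "T>G")
  wide <- s |>
    count(.data$group, .data$class) |>
    mutate(class = factor(.data$class, levels = classes)) |>
    complete(.data$group, class = factor(classes, levels = classes),
             fill = list(n = 0L)) |>
    pivot_wider(names_from = "class", values_from = "n")
  summ <- s |>
    group_by(.data$group) |>
    summarise(ti = sum(.data$is_ti), tv = sum(!.data$is_ti), .groups = "drop") |>
    mutate(titv = ifelse(.data$tv == 0, NA_real_, .data$ti / .data$tv))
  wide |>
    left_join(summ, by = "group") |>
    left_join(excl, by = "group") |>
    mutate(n_excluded = as.integer(replace_na(.data$n_excluded, 0L)))
}

#' SNV:InDel ratio
#'
#' @param variants Variant tibble.
#' @return One-row tibble with `n_snv`, `n_indel`, `ratio` (`NA` when there
#'   are no InDels). MNVs count toward neither class.
#' @export
snv_indel_ratio <- function(variants) {
  v <- classify_indel(variants)
  n_snv <- sum(v$variant_type == "SNV")
  n_indel <- sum(v$variant_type %in% c("ins", "del"))
  tibble(n_snv = n_snv, n_indel = n_indel,
         ratio = ifelse(n_indel == 0, NA_real_, n_snv / n_indel))
}

#' Correlation between variant density and gene density
#'
#' Pearson (or Spearman) correlation of per-chromosome variants/Mb against
#' genes/Mb.
#'
#' @param profile Per-chromosome profile with `chrom` and `per_mb` columns
#'   (e.g. from [chromosome_profile()]).
#' @param density Gene-density tibble with `chrom` and `genes_per_mb`
#'   columns (see [read_gene_density()]).
#' @param method `"pearson"` (default; the relationship examined is linear)
#'   or `"spearman"`.
#' @return One-row tibble with `method`, `estimate`, `n`. `estimate` is `NA`
#'   (with a warning) when either vector is constant or fewer than 3
#'   chromosomes overlap.
#' @export
gene_density_correlation <- function(profile, density,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  joined <- inner_join(
    profile |> mutate(chrom = normalize_chrom(.data$chrom)),
    density |> mutate(chrom = normalize_chrom(.data$chrom)),
    by = "chrom"
  )
  est <- NA_real_
  if (nrow(joined) < 3) {
    warn("fewer than 3 chromosomes in common; correlation not computed")
  } else if (stats::sd(joined$per_mb) == 0 || stats::sd(joined$genes_per_mb) == 0) {
    warn("constant vector; correlation undefined")
  } else {
    est <- stats::cor(joined$per_mb, joined$genes_per_mb, method = method)
  }
  tibble(method = method, estimate = est, n = nrow(joined))
}
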
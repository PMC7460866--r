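# InDel signature classification.
#
# Every insertion/deletion is assigned a context class from its flanking
# reference sequence:
#   rep  — at least one full additional copy of the event sequence lies
#          immediately adjacent on either flank (a flanking mononucleotide
#          run for length-1 events);
#   mh   — not rep, and the event sequence shares a partial prefix with the
#          downstream flank or a partial suffix with the upstream flank;
#          bimh ("biggest InDel microhomology") is the longest such match;
#   none — neither.
# Precedence is rep > mh > none: a full copy is stronger evidence than
# partial homology. The definition is symmetric in the two flanks, so the
# class is invariant under reverse complementation of the locus.

#' Classify variants as SNV / insertion / deletion / MNV
#'
#' Adds `variant_type` (`"SNV"`, `"ins"`, `"del"` or `"MNV"`) and
#' `indel_length` (`|nchar(alt) - nchar(ref)|`; 0 for substitutions) columns.
#' A deletion is called when the reference allele is longer than the
#' alternate, an insertion when it is shorter; equal lengths give an SNV
#' (length 1) or an MNV (longer), the latter being tallied but excluded from
#' signature analysis.
#'
#' @param variants Variant tibble with `ref` and `alt` columns.
#' @return The input with `variant_type` and `indel_length` columns added.
#' @export
classify_indel <- function(variants) {
  mutate(variants,
         variant_type = variant_class(.data$ref, .data$alt),
         indel_length = abs(nchar(.data$alt) - nchar(.data$ref)))
}

variant_class <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  dplyr::case_when(
    nr > na ~ "del",
    nr < na ~ "ins",
    nr == 1L ~ "SNV",
    TRUE ~ "MNV"
  )
}

#' Classify InDel flanking context (repeat / microhomology / none)
#'
#' Core classifier operating on the event sequence and its two reference
#' flanks. Vectorized over all three arguments. `seq` is the inserted or
#' deleted sequence (anchor base removed), `upstream` the reference
#' immediately 5' of the event locus, `downstream` immediately 3' of it.
#'
#' A full adjacent copy of `seq` on either flank gives class `"rep"`.
#' Otherwise the longest `m` with `1 <= m < nchar(seq)` such that the first
#' `m` bases of `seq` equal the first `m` bases of `downstream`, or the last
#' `m` bases of `seq` equal the last `m` bases of `upstream`, gives class
#' `"mh"` with `bimh = m`. If no such `m` exists the class is `"none"`.
#'
#' @param seq,upstream,downstream Character vectors of equal length (or
#'   length 1, recycled).
#' @return Tibble with `context_class` and `bimh` (`NA` unless `"mh"`).
#' @export
#' @examples
#' classify_context("ACG", upstream = "TTTT", downstream = "ACGT")  # rep
#' classify_context("TAGC", upstream = "CCCC", downstream = "TAGG") # mh, bimh 3
classify_context <- function(seq, upstream, downstream) {
  n <- max(length(seq), length(upstream), length(downstream))
  seq <- rep_len(seq, n); upstream <- rep_len(upstream, n)
  downstream <- rep_len(downstream, n)
  len <- nchar(seq)
  if (any(len < 1L)) abort("event sequences must be non-empty")
  up_n <- nchar(upstream)
  dn_n <- nchar(downstream)

  is_rep <- (dn_n >= len & startsWith(downstream, seq)) |
    (up_n >= len & endsWith(upstream, seq))

  best <- integer(n)
  max_m <- max(c(0L, len - 1L))
  m <- 1L
  while (m <= max_m) {
    idx <- which(!is_rep & len > m)
    if (length(idx)) {
      pre <- dn_n[idx] >= m &
        substr(seq[idx], 1L, m) == substr(downstream[idx], 1L, m)
      suf <- up_n[idx] >= m &
        substr(seq[idx], len[idx] - m + 1L, len[idx]) ==
          substr(upstream[idx], up_n[idx] - m + 1L, up_n[idx])
      best[idx[pre | suf]] <- m
    }
    m <- m + 1L
  }

  cls <- rep("none", n)
  cls[is_rep] <- "rep"
  is_mh <- !is_rep & best >= 1L
  cls[is_mh] <- "mh"
  tibble(context_class = cls,
         bimh = ifelse(is_mh, best, NA_integer_))
}

#' Assign repeat/microhomology context signatures to InDels
#'
#' For each insertion or deletion, extracts the event sequence and its
#' reference flanks (stripping the left-anchor base of the VCF
#' representation; the event locus is the position immediately after the
#' anchor) and classifies the flanking context with [classify_context()].
#' Deletions whose stated sequence disagrees with the reference at the locus,
#' or whose chromosome is absent from `reference`, are classed
#' `"unresolved"`. SNVs and MNVs get `NA` context columns.
#'
#' @param variants Variant tibble.
#' @param reference Named character vector or `DNAStringSet` of chromosome
#'   sequences covering the loci.
#' @param window Minimum flank width (bp) examined on each side; at least
#'   twice the event length is always used.
#' @param max_bucket Sub-length value at which category labels overflow into
#'   a terminal `"<max_bucket>+"` bucket.
#' @return The input with `variant_type`, `indel_length`, `context_class`,
#'   `bimh`, `sub_length` and `category` columns added. Category labels
#'   follow the `del.mh.bimh.2` / `ins.rep.len.3` convention (sub-length is
#'   the InDel length for rep/none and the biggest microhomology length for
#'   mh).
#' @export
indel_context <- function(variants, reference, window = 50, max_bucket = 5) {
  seqs <- reference_as_strings(reference)
  v <- classify_indel(variants)
  n <- nrow(v)
  context_class <- rep(NA_character_, n)
  bimh <- rep(NA_integer_, n)
  sub_length <- rep(NA_integer_, n)

  idx <- which(v$variant_type %in% c("ins", "del"))
  if (length(idx)) {
    chrom <- v$chrom[idx]
    pos <- v$pos[idx]
    ref <- v$ref[idx]
    alt <- v$alt[idx]
    is_del <- v$variant_type[idx] == "del"
    L <- v$indel_length[idx]

    # left-anchored representation: the shorter allele must prefix the longer
    anchored <- ifelse(is_del, startsWith(ref, alt), startsWith(alt, ref))
    known <- chrom %in% names(seqs)
    chrom_len <- rep(NA_real_, length(idx))
    chrom_len[known] <- nchar(seqs[chrom[known]])

    s <- ifelse(is_del, substring(ref, nchar(alt) + 1L), substring(alt, nchar(ref) + 1L))
    locus <- pos + ifelse(is_del, nchar(alt), nchar(ref))  # first deleted base / first base 3' of insertion point
    flank <- pmax(window, 2L * L)

    ok <- anchored & known & locus >= 1 & !is.na(chrom_len) &
      (ifelse(is_del, locus + L - 1, locus - 1) <= chrom_len)
    res_cls <- rep("unresolved", length(idx))
    res_bimh <- rep(NA_integer_, length(idx))

    if (any(ok)) {
      cid <- chrom[ok]
      seq_full <- seqs[cid]
      up_start <- pmax(1, locus[ok] - flank[ok])
      up <- substring(seq_full, up_start, locus[ok] - 1)
      dn_start <- ifelse(is_del[ok], locus[ok] + L[ok], locus[ok])
      dn_end <- pmin(chrom_len[ok], dn_start + flank[ok] - 1)
      dn <- ifelse(dn_start > chrom_len[ok], "",
                   substring(seq_full, dn_start, dn_end))
      # deletions must match the reference at the locus
      consistent <- !is_del[ok] |
        substring(seq_full, locus[ok], locus[ok] + L[ok] - 1) == s[ok]
      cc <- classify_context(s[ok], up, dn)
      res_cls[ok] <- ifelse(consistent, cc$context_class, "unresolved")
      res_bimh[ok] <- ifelse(consistent, cc$bimh, NA_integer_)
    }

    context_class[idx] <- res_cls
    bimh[idx] <- res_bimh
    sub_length[idx] <- ifelse(res_cls == "mh", res_bimh,
                              ifelse(res_cls == "unresolved", NA_integer_, L))
  }

  v$context_class <- context_class
  v$bimh <- bimh
  v$sub_length <- sub_length
  v$category <- signature_category(v$variant_type, v$context_class,
                                   v$sub_length, max_bucket)
  v
}

#' Build a canonical signature category label
#'
#' @param indel_type `"ins"` or `"del"`.
#' @param context_class `"rep"`, `"mh"` or `"none"`.
#' @param sub_length InDel length (rep/none) or biggest microhomology length
#'   (mh).
#' @param max_bucket Lengths `>= max_bucket` collapse into a terminal
#'   `"<max_bucket>+"` bucket.
#' @return Character vector of labels such as `"del.mh.bimh.2"`,
#'   `"ins.rep.len.3"`, `"del.none.len.5+"`; `NA` where inputs are `NA` or
#'   unresolved.
#' @export
signature_category <- function(indel_type, context_class, sub_length,
                               max_bucket = 5) {
  bucket <- ifelse(sub_length >= max_bucket, paste0(max_bucket, "+"),
                   as.character(sub_length))
  mid <- ifelse(context_class == "mh", "mh.bimh", paste0(context_class, ".len"))
  out <- paste(indel_type, mid, bucket, sep = ".")
  out[is.na(indel_type) | is.na(context_class) | is.na(sub_length) |
        !(indel_type %in% c("ins", "del")) |
        !(context_class %in% c("rep", "mh", "none"))] <- NA_character_
  out
}

#' Parse a signature category label back into its fields
#'
#' Inverse of [signature_category()].
#'
#' @param label Character vector of category labels.
#' @return Tibble with `indel_type`, `context_class`, `sub_length`
#'   (character; may be an overflow bucket such as `"5+"`).
#' @export
parse_signature_category <- function(label) {
  parts <- str_split(label, stringr::fixed("."))
  tibble(
    indel_type = map_chr(parts, 1),
    context_class = map_chr(parts, 2),
    sub_length = map_chr(parts, ~ .x[length(.x)])
  )
}

#' Canonical ordering of signature categories
#'
#' Deletions before insertions; rep, mh, none; ascending sub-length with a
#' terminal overflow bucket. Used for plot-stable spectrum output.
#'
#' @param max_bucket Overflow bucket threshold (see [signature_category()]).
#' @return Character vector of category labels in canonical order.
#' @export
signature_levels <- function(max_bucket = 5) {
  buckets <- c(as.character(seq_len(max_bucket - 1)), paste0(max_bucket, "+"))
  unlist(lapply(c("del", "ins"), function(ty) {
    unlist(lapply(c("rep", "mh", "none"), function(cl) {
      mid <- if (cl == "mh") "mh.bimh" else paste0(cl, ".len")
      paste(ty, mid, buckets, sep = ".")
    }))
  }))
}

#' Count InDel signature categories
#'
#' Classifies all insertions/deletions in `variants` with [indel_context()]
#' and tallies them per category. Categories are zero-filled over the
#' canonical grid and ordered canonically (deletions before insertions; rep,
#' mh, none; ascending sub-length) so plot output is stable. MNVs and
#' unresolved events are reported in attributes, not in the spectrum.
#'
#' @inheritParams indel_context
#' @return Tibble of class `irmut_spectrum` with `category`, `indel_type`,
#'   `context_class`, `sub_length`, `n`. Attributes: `total` (sum of `n`),
#'   `n_mnv`, `n_unresolved`.
#' @export
indel_spectrum <- function(variants, reference, window = 50, max_bucket = 5) {
  ctx <- indel_context(variants, reference, window = window,
                       max_bucket = max_bucket)
  lv <- signature_levels(max_bucket)
  counted <- ctx |>
    filter(!is.na(.data$category)) |>
    count(.data$category, name = "n")
  out <- tibble(category = lv) |>
    left_join(counted, by = "category") |>
    mutate(n = as.integer(replace_na(.data$n, 0L)))
  out <- bind_cols(out["category"], parse_signature_category(out$category),
                   out["n"])
  structure(
    out,
    class = c("irmut_spectrum", class(out)),
    total = sum(out$n),
    n_mnv = sum(ctx$variant_type == "MNV"),
    n_unresolved = sum(ctx$context_class == "unresolved", na.rm = TRUE)
  )
}

#' Log10 fold change between filtered and unfiltered signature spectra
#'
#' Per category, computes `log10(n_filtered / n_unfiltered)` with a
#' configurable pseudocount substituted for zero cells only. Categories
#' absent from both spectra are omitted. Per-type averages (mean over
#' deletion categories, mean over insertion categories) are attached as the
#' `"averages"` attribute.
#'
#' @param filtered,unfiltered Spectra from [indel_spectrum()] (or any tibble
#'   with `category` and `n` columns) computed from the same sample.
#' @param pseudocount Value substituted for zero cells (default 0.5).
#' @return Tibble with `category`, `indel_type`, `context_class`,
#'   `sub_length`, `n_filtered`, `n_unfiltered`, `log10_fc`; attribute
#'   `averages` is a tibble with `indel_type` and `mean_log10_fc`.
#' @export
fold_change <- function(filtered, unfiltered, pseudocount = 0.5) {
  f <- tibble(category = filtered$category, n_filtered = filtered$n)
  u <- tibble(category = unfiltered$category, n_unfiltered = unfiltered$n)
  out <- full_join(f, u, by = "category") |>
    mutate(n_filtered = replace_na(.data$n_filtered, 0),
           n_unfiltered = replace_na(.data$n_unfiltered, 0)) |>
    filter(.data$n_filtered > 0 | .data$n_unfiltered > 0)
  nf <- ifelse(out$n_filtered == 0, pseudocount, out$n_filtered)
  nu <- ifelse(out$n_unfiltered == 0, pseudocount, out$n_unfiltered)
  out$log10_fc <- log10(nf / nu)
  out <- bind_cols(out["category"], parse_signature_category(out$category),
                   out[c("n_filtered", "n_unfiltered", "log10_fc")])
  averages <- out |>
    group_by(.data$indel_type) |>
    summarise(mean_log10_fc = mean(.data$log10_fc), .groups = "drop")
  structure(out, averages = averages)
}

#' @export
#' @rdname fold_change
#' @param fc A fold-change tibble from [fold_change()].
fold_change_averages <- function(fc) attr(fc, "averages")
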
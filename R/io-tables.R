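# Tab-delimited interval / translocation / gene-density tables.
#
# Interval coordinates follow the BED convention throughout: 0-based,
# half-open [start, end). A variant at VCF position p lies within [s, e)
# iff s <= p - 1 < e.

#' Read genomic intervals (cytogenetic bands, TADs, generic BED)
#'
#' @param path Tab-delimited file; `#`-prefixed lines are skipped. The
#'   cytoband dialect needs >= 4 columns (chrom, start, end, name); TAD/BED
#'   dialects need >= 3.
#' @param kind One of `"bed"`, `"cytoband"`, `"tad"`; controls the required
#'   column count and the default interval name.
#' @return Tibble with `chrom`, `start` (0-based), `end` (exclusive), `name`,
#'   sorted within chromosome. Records with `start >= end` are rejected with
#'   a warning; overlapping intervals are kept as-is with a warning.
#' @export
read_intervals <- function(path, kind = c("bed", "cytoband", "tad")) {
  kind <- match.arg(kind)
  df <- suppressWarnings(readr::read_tsv(
    path, col_names = FALSE, comment = "#",
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  ))
  if (!nrow(df)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character()))
  }
  need <- if (kind == "cytoband") 4L else 3L
  if (ncol(df) < need) {
    abort(sprintf("'%s' has %d column(s); %s format needs at least %d",
                  path, ncol(df), kind, need))
  }
  name <- if (ncol(df) >= 4) df[[4]] else rep(toupper(kind), nrow(df))
  out <- tibble(
    chrom = normalize_chrom(df[[1]]),
    start = as.numeric(df[[2]]),
    end = as.numeric(df[[3]]),
    name = name
  )
  bad <- !is.finite(out$start) | !is.finite(out$end) | out$start >= out$end
  if (any(bad)) {
    warn(sprintf("%d interval(s) with start >= end rejected from '%s'",
                 sum(bad), path))
    out <- out[!bad, ]
  }
  out <- arrange(out, .data$chrom, .data$start, .data$end)
  warn_if_overlapping(out, path)
  out
}

warn_if_overlapping <- function(intervals, label = "input") {
  ov <- intervals |>
    group_by(.data$chrom) |>
    summarise(ov = any(.data$start[-1] < cummax(.data$end)[-dplyr::n()]),
              .groups = "drop")
  if (any(ov$ov)) warn(sprintf("overlapping intervals in '%s' kept as-is", label))
  invisible(any(ov$ov))
}

write_intervals <- function(intervals, path, extra = NULL, chr_prefix = TRUE) {
  chroms <- if (chr_prefix) add_chr_prefix(intervals$chrom) else intervals$chrom
  df <- data.frame(chroms, as.integer(intervals$start), as.integer(intervals$end),
                   intervals$name)
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BreakDancer-style translocation table
#'
#' Consumes the tab-delimited `breakdancer-max` output dialect (columns:
#' chr1, pos1, orientation1, chr2, pos2, orientation2, type, size, score,
#' num_reads, ...). Only inter-chromosomal calls (type `"CTX"`) are kept, and
#' breakends are stored in canonical order (`chrom_a < chrom_b` after
#' normalization). Orientation strings are not used for call equality.
#'
#' @param path Tab-delimited file with `#`-prefixed header lines.
#' @return Tibble with `chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#'   `supporting_reads`, `confidence`.
#' @export
read_translocation_table <- function(path) {
  df <- suppressWarnings(readr::read_tsv(
    path, col_names = FALSE, comment = "#",
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  ))
  if (!nrow(df)) {
    return(tibble(chrom_a = character(), pos_a = integer(),
                  chrom_b = character(), pos_b = integer(),
                  supporting_reads = integer(), confidence = numeric()))
  }
  if (ncol(df) < 10) {
    abort(sprintf("'%s' has %d column(s); BreakDancer output needs at least 10",
                  path, ncol(df)))
  }
  out <- tibble(
    chrom_a = normalize_chrom(df[[1]]),
    pos_a = as.integer(df[[2]]),
    chrom_b = normalize_chrom(df[[4]]),
    pos_b = as.integer(df[[5]]),
    type = df[[7]],
    confidence = as.numeric(df[[9]]),
    supporting_reads = as.integer(df[[10]])
  )
  out <- filter(out, .data$type == "CTX", .data$chrom_a != .data$chrom_b)
  out$type <- NULL
  canonicalize_translocations(out)
}

# natural chromosome order: numeric names numerically, then others
# alphabetically (so 2 < 16 < X)
chrom_swap_needed <- function(a, b) {
  na_ <- suppressWarnings(as.numeric(a))
  nb <- suppressWarnings(as.numeric(b))
  ifelse(!is.na(na_) & !is.na(nb), na_ > nb,
         ifelse(is.na(na_) & is.na(nb), a > b, is.na(na_)))
}

# enforce canonical breakend order (chrom_a before chrom_b)
canonicalize_translocations <- function(calls) {
  if (!nrow(calls)) return(calls)
  swap <- chrom_swap_needed(calls$chrom_a, calls$chrom_b)
  if (any(swap)) {
    tmp_c <- calls$chrom_a[swap]; tmp_p <- calls$pos_a[swap]
    calls$chrom_a[swap] <- calls$chrom_b[swap]
    calls$pos_a[swap] <- calls$pos_b[swap]
    calls$chrom_b[swap] <- tmp_c
    calls$pos_b[swap] <- tmp_p
  }
  calls
}

write_translocation_table <- function(calls, path, chr_prefix = TRUE) {
  header <- paste("#Chr1", "Pos1", "Orientation1", "Chr2", "Pos2",
                  "Orientation2", "Type", "Size", "Score", "num_Reads",
                  sep = "\t")
  if (nrow(calls)) {
    ca <- if (chr_prefix) add_chr_prefix(calls$chrom_a) else calls$chrom_a
    cb <- if (chr_prefix) add_chr_prefix(calls$chrom_b) else calls$chrom_b
    type <- if ("type" %in% names(calls)) calls$type else rep("CTX", nrow(calls))
    body <- paste(ca, calls$pos_a, "2+2-", cb, calls$pos_b, "0+2-",
                  type, -1, calls$confidence, calls$supporting_reads,
                  sep = "\t")
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a per-chromosome gene-density table
#'
#' @param path Tab-delimited file with a header and columns `chrom`,
#'   `genes_per_mb`.
#' @return Tibble with normalized chromosome names.
#' @export
read_gene_density <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("chrom", "genes_per_mb") %in% names(df))) {
    abort(sprintf("'%s' must have columns 'chrom' and 'genes_per_mb'", path))
  }
  tibble(chrom = normalize_chrom(df$chrom),
         genes_per_mb = as.numeric(df$genes_per_mb))
}
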
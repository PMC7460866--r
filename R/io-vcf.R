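# VCF input/output
#
# Variants are represented as one tibble row per (record, alternate allele):
# sample, chrom, pos (1-based), ref, alt, gt, dp, gq, alt_count, ann.
# `ann` is a list-column; each element is a tibble of SnpEff-style
# annotations (so_term, impact, gene, transcript_id, is_refseq_known).
# Missing DP/GQ/AD are carried as NA (a flag, never a zero).

#' Read a VCF file into a variant tibble
#'
#' Reads a VCF v4.x file and returns one row per record and alternate allele
#' (multi-allelic records are decomposed before any filtering). DP, GQ and AD
#' are taken from the first sample's FORMAT fields; `alt_count` is the
#' allele-matched entry of AD. SnpEff `ANN` INFO entries, when present, are
#' parsed into the `ann` list-column. Records lacking DP or GQ are retained
#' with `NA` markers rather than dropped.
#'
#' @param path Path to a VCF file.
#' @param sample_label Label stored in the `sample` column; defaults to the
#'   VCF sample name (or the file name when the VCF has no sample column).
#' @return A tibble of variants (zero rows for a header-only VCF).
#' @export
read_vcf <- function(path, sample_label = NULL) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  if (length(body)) {
    nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
    bad <- body[nf < 8]
    if (length(bad)) {
      abort(sprintf("malformed VCF record at line %d of '%s' (fewer than 8 fields)",
                    bad[1], path))
    }
  }
  if (!length(body)) return(empty_variants())

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)

  has_sample <- ncol(v@gt) >= 2
  if (has_sample) {
    gt <- unname(vcfR::extract.gt(v, element = "GT")[, 1])
    dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1]))
    gq <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "GQ")[, 1]))
    ad <- vcfR::extract.gt(v, element = "AD")[, 1]
    if (is.null(sample_label)) sample_label <- colnames(v@gt)[2]
  } else {
    gt <- rep(NA_character_, n)
    dp <- gq <- rep(NA_integer_, n)
    ad <- rep(NA_character_, n)
    if (is.null(sample_label)) sample_label <- basename(path)
  }
  if (anyNA(dp) || anyNA(gq)) {
    inform(sprintf("%d record(s) in '%s' lack DP and/or GQ; flagged as NA",
                   sum(is.na(dp) | is.na(gq)), basename(path)))
  }

  ann_raw <- tryCatch(vcfR::extract.info(v, element = "ANN"),
                      error = function(e) rep(NA_character_, n))
  if (is.null(ann_raw)) ann_raw <- rep(NA_character_, n)

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep.int(seq_len(n), n_alt)
  alt_rank <- sequence(n_alt)

  ad_fields <- strsplit(ad, ",", fixed = TRUE)
  alt_count <- vapply(seq_along(idx), function(i) {
    f <- ad_fields[[idx[i]]]
    k <- alt_rank[i] + 1L
    if (length(f) >= k) suppressWarnings(as.integer(f[k])) else NA_integer_
  }, integer(1))

  out <- tibble(
    sample = sample_label,
    chrom = normalize_chrom(unname(fix[, "CHROM"])[idx]),
    pos = as.integer(unname(fix[, "POS"]))[idx],
    ref = unname(fix[, "REF"])[idx],
    alt = unlist(alts, use.names = FALSE),
    gt = gt[idx],
    dp = dp[idx],
    gq = gq[idx],
    alt_count = alt_count
  )
  out$ann <- parse_ann_column(ann_raw[idx], out$alt)
  out
}

# parse SnpEff ANN INFO values into annotation tibbles, keeping entries whose
# allele field matches the decomposed alt (all entries when none match, e.g.
# symbolic alleles)
parse_ann_column <- function(ann_raw, alt) {
  n <- length(ann_raw)
  out <- rep(list(empty_ann()), n)
  has <- !is.na(ann_raw) & nzchar(ann_raw)
  if (!any(has)) return(out)
  entries <- strsplit(ann_raw[has], ",", fixed = TRUE)
  owner <- rep.int(which(has), lengths(entries))
  f <- stringr::str_split(unlist(entries, use.names = FALSE),
                          stringr::fixed("|"), simplify = TRUE)
  if (ncol(f) < 7) f <- cbind(f, matrix("", nrow(f), 7 - ncol(f)))
  allele_match <- f[, 1] == alt[owner]
  matched <- unique(owner[allele_match])
  keep <- allele_match | !(owner %in% matched)
  owner <- owner[keep]
  f <- f[keep, , drop = FALSE]
  known <- grepl("^N[MR]_", f[, 7])
  sp <- split(seq_along(owner), owner)
  for (k in seq_along(sp)) {
    ix <- sp[[k]]
    out[[owner[ix[1]]]] <- tibble::new_tibble(list(
      so_term = f[ix, 2], impact = f[ix, 3], gene = f[ix, 4],
      transcript_id = f[ix, 7], is_refseq_known = known[ix]),
      nrow = length(ix))
  }
  out
}

format_ann_info <- function(ann, alt) {
  if (is.null(ann) || !nrow(ann)) return(".")
  entries <- sprintf(
    "%s|%s|%s|%s|%s|transcript|%s|protein_coding|||||||||",
    alt, ann$so_term, ann$impact, ann$gene, ann$gene, ann$transcript_id
  )
  paste0("ANN=", paste(entries, collapse = ","))
}

#' Write a variant tibble to a VCF file
#'
#' Emits a minimal VCF v4.2 with FORMAT `GT:DP:GQ:AD` for a single sample and
#' SnpEff-style `ANN` INFO entries rebuilt from the `ann` list-column.
#' Re-reading the file with [read_vcf()] restores the original field values.
#'
#' @param variants Variant tibble (see [read_vcf()] for the columns).
#' @param path Output path.
#' @param contig_lengths Optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @param chr_prefix Add a `"chr"` prefix to chromosome names on output.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contig_lengths = NULL, chr_prefix = TRUE) {
  sample_name <- if (nrow(variants) && !is.null(variants$sample)) variants$sample[1] else "sample"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=irmutscan",
    '##INFO=<ID=ANN,Number=.,Type=String,Description="Functional annotations: Allele|Annotation|Annotation_Impact|Gene_Name|Gene_ID|Feature_Type|Feature_ID|Transcript_BioType|Rank|HGVS.c|HGVS.p|cDNA.pos|CDS.pos|AA.pos|Distance|Errors">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">'
  )
  if (!is.null(contig_lengths)) {
    nm <- if (chr_prefix) add_chr_prefix(names(contig_lengths)) else normalize_chrom(names(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", nm, as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_name, sep = "\t"))
  if (nrow(variants)) {
    chroms <- if (chr_prefix) add_chr_prefix(variants$chrom) else normalize_chrom(variants$chrom)
    gt <- if ("gt" %in% names(variants)) replace_na_chr(variants$gt, "0/1") else rep("0/1", nrow(variants))
    dp <- variants$dp
    gq <- variants$gq
    ac <- variants$alt_count
    ad <- ifelse(is.na(dp) | is.na(ac), ".", paste(dp - ac, ac, sep = ","))
    fmt <- paste(gt,
                 ifelse(is.na(dp), ".", dp),
                 ifelse(is.na(gq), ".", gq),
                 ad, sep = ":")
    ann_list <- if ("ann" %in% names(variants)) variants$ann else vector("list", nrow(variants))
    info <- vapply(seq_len(nrow(variants)),
                   function(i) format_ann_info(ann_list[[i]], variants$alt[i]),
                   character(1))
    filt <- if ("filter" %in% names(variants)) variants$filter else rep(".", nrow(variants))
    body <- paste(chroms, variants$pos, ".", variants$ref, variants$alt, ".",
                  filt, info, "GT:DP:GQ:AD", fmt, sep = "\t")
  } else {
    body <- character()
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

replace_na_chr <- function(x, value) {
  x[is.na(x)] <- value
  x
}
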
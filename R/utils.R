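# shared internal helpers

# SnpEff impact classes, most severe first
IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

DNA_BASES <- c("A", "C", "G", "T")

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix so that UCSC-style (`chr19`) and
#' Ensembl-style (`19`) names compare equal. All readers apply this on input;
#' writers re-add the prefix when `chr_prefix = TRUE`.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector without the `"chr"` prefix.
#' @export
#' @examples
#' normalize_chrom(c("chr1", "1", "chrX"))
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

add_chr_prefix <- function(x) paste0("chr", normalize_chrom(x))

# unique variant identity used by the sample filter and location-wise tallies
variant_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

empty_ann <- function() {
  tibble(
    so_term = character(), impact = character(), gene = character(),
    transcript_id = character(), is_refseq_known = logical()
  )
}

empty_variants <- function() {
  tibble(
    sample = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gt = character(),
    dp = integer(), gq = integer(), alt_count = integer(),
    ann = list()
  )
}

# coerce a DNAStringSet / named character vector of chromosome sequences to a
# named character vector with normalized names
reference_as_strings <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
  } else if (is.character(reference)) {
    seqs <- reference
  } else {
    abort("`reference` must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(seqs))) abort("reference sequences must be named by chromosome")
  names(seqs) <- normalize_chrom(names(seqs))
  seqs
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
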
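#' Reference sequence accessors
#'
#' Variant normalization needs read access to the reference sequence so that
#' indels can be left-aligned across caller representations. An accessor is a
#' function `f(chrom, start, end)` returning the reference bases on `chrom`
#' between 1-based positions `start` and `end` inclusive, as an uppercase
#' string.
#'
#' @param fasta Path to a FASTA file, or a named character vector of contig
#'   sequences, or a [Biostrings::DNAStringSet].
#' @return A function `(chrom, start, end) -> character(1)`.
#' @export
ref_accessor <- function(fasta) {
  seqs <- if (inherits(fasta, "DNAStringSet")) {
    fasta
  } else if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    Biostrings::readDNAStringSet(fasta)
  } else if (is.character(fasta) && !is.null(names(fasta))) {
    Biostrings::DNAStringSet(toupper(fasta))
  } else {
    abort("`fasta` must be a FASTA path, a named character vector, or a DNAStringSet")
  }
  # FASTA headers may carry descriptions after whitespace
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  function(chrom, start, end) {
    if (!chrom %in% names(seqs)) abort(sprintf("contig '%s' not in reference", chrom))
    n <- length(seqs[[chrom]])
    if (start < 1 || end > n) abort(sprintf("positions %d-%d outside contig '%s' (length %d)", start, end, chrom, n))
    as.character(Biostrings::subseq(seqs[[chrom]], start, end))
  }
}

valid_allele <- function(x) nchar(x) > 0 & !grepl("[^ACGT]", x)

#' Normalize a variant to its parsimonious, left-aligned representation
#'
#' Callers disagree on how they write the same indel (anchored at different
#' positions, padded with extra reference bases). Cross-caller matching
#' therefore keys variants on a canonical form: trailing shared bases are
#' trimmed (extending leftwards through the reference when an allele would
#' empty out), then leading shared bases are trimmed while both alleles keep
#' at least one base. SNVs pass through unchanged. The result is the unique
#' minimal left-most representation, so every representation of the same
#' event maps to the same key.
#'
#' @param chrom Contig name.
#' @param pos 1-based position of the (possibly padded) allele.
#' @param ref,alt Reference and alternate allele strings (A/C/G/T).
#' @param get_ref A reference accessor from [ref_accessor()].
#' @return A one-row tibble with columns `chrom`, `pos`, `ref`, `alt`, or
#'   `NULL` (with a warning) when the stated reference allele does not match
#'   the reference sequence.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, get_ref) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!valid_allele(ref) || !valid_allele(alt)) {
    abort("alleles must be non-empty strings over A/C/G/T")
  }
  if (identical(ref, alt)) abort("degenerate variant: ref == alt")
  observed <- get_ref(chrom, pos, pos + nchar(ref) - 1L)
  if (!identical(observed, ref)) {
    warn(sprintf("reference mismatch at %s:%d (record %s, reference %s); record rejected",
                 chrom, pos, ref, observed))
    return(NULL)
  }
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 && substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 1L) abort(sprintf("cannot left-extend past start of contig '%s'", chrom))
        b <- get_ref(chrom, pos - 1L, pos - 1L)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
        pos <- pos - 1L
      }
    } else break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)
}

#' Normalize every variant in a table
#'
#' Applies [normalize_variant()] row-wise. Records whose stated reference
#' allele mismatches the reference sequence are dropped with one summary
#' warning.
#'
#' @param df A data frame with columns `chrom`, `pos`, `ref`, `alt` (other
#'   columns are carried along).
#' @param get_ref A reference accessor from [ref_accessor()].
#' @return A tibble like `df` with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variants <- function(df, get_ref) {
  df <- as_tibble(df)
  if (nrow(df) == 0) return(df)
  norm <- purrr::pmap(list(df$chrom, df$pos, df$ref, df$alt), function(c_, p_, r_, a_) {
    tryCatch(suppressWarnings(normalize_variant(c_, p_, r_, a_, get_ref)),
             error = function(e) NULL)
  })
  ok <- !vapply(norm, is.null, logical(1))
  if (any(!ok)) {
    warn(sprintf("%d record(s) rejected during normalization (reference mismatch or invalid alleles)",
                 sum(!ok)))
  }
  keep <- df[ok, , drop = FALSE]
  nk <- bind_rows(norm[ok])
  keep$pos <- nk$pos; keep$ref <- nk$ref; keep$alt <- nk$alt
  keep
}
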
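# VCF-style left normalization of variants. Aligners place gaps arbitrarily
# inside repeats; keying candidates requires one canonical form.

#' Left-normalize a variant against the reference
#'
#' Standard VCF normalization: trailing bases shared by REF and ALT are
#' trimmed (extending to the left with reference bases when one allele would
#' empty), then shared leading bases beyond the anchor are trimmed. Applying
#' it twice changes nothing.
#'
#' @param chrom contig name.
#' @param pos 1-based position of the first REF base.
#' @param ref,alt allele strings over A/C/G/T (non-empty unless the event
#'   abuts the anchor, in which case the anchor base is added here).
#' @param reference named character vector of contigs or FASTA path.
#' @return list(chrom, pos, ref, alt).
#' @export
normalize_variant <- function(chrom, pos, ref, alt, reference) {
  rb <- .ref_bytes(reference)[[chrom]]
  r <- strsplit(toupper(ref), "")[[1L]]
  a <- strsplit(toupper(alt), "")[[1L]]
  repeat {
    nr <- length(r); na <- length(a)
    if (nr > 0L && na > 0L && r[nr] == a[na] && !(nr == 1L && na == 1L)) {
      r <- r[-nr]; a <- a[-na]
    } else if (nr == 0L || na == 0L) {
      if (pos <= 1L) stop("cannot left-extend variant at contig start")
      pos <- pos - 1L
      b <- rawToChar(rb[pos])
      r <- c(b, r); a <- c(b, a)
    } else break
  }
  # trim shared leading bases beyond the anchor
  while (length(r) >= 2L && length(a) >= 2L && r[1L] == a[1L]) {
    r <- r[-1L]; a <- a[-1L]; pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}
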
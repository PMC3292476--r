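# Reference sequences are held as a named character vector (one element per
# contig). Pileup code works on raw byte vectors for speed; `.ref_bytes`
# builds that view once per pass.

#' Read a FASTA reference into a named character vector
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector, one element per contig, upper-cased.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1L]) stop("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  names_ <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  out <- toupper(unname(seqs))
  names(out) <- names_
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param reference named character vector of contig sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reference, path, width = 70L) {
  stopifnot(is.character(reference), !is.null(names(reference)))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(reference)) {
    writeLines(paste0(">", nm), con)
    s <- reference[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# resolve a reference argument: named character vector, or a FASTA path
.as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference)) {
    return(read_fasta(reference))
  }
  if (!is.character(reference) || is.null(names(reference))) {
    stop("reference must be a named character vector of contig sequences ",
         "or a path to a FASTA file")
  }
  reference
}

.ref_bytes <- function(reference) {
  lapply(.as_reference(reference), charToRaw)
}

#' Fetch one reference base
#'
#' @param reference named character vector (or FASTA path).
#' @param chrom contig name.
#' @param pos 1-based position.
#' @return single-character base.
#' @export
ref_base <- function(reference, chrom, pos) {
  reference <- .as_reference(reference)
  if (!chrom %in% names(reference)) stop("unknown contig: ", chrom)
  if (pos < 1L || pos > nchar(reference[[chrom]])) {
    stop("position ", pos, " outside contig ", chrom)
  }
  substr(reference[[chrom]], pos, pos)
}

#' Generate a random reference sequence
#'
#' Bases are drawn i.i.d. uniform over A/C/G/T using the current RNG state.
#'
#' @param length contig length in bp.
#' @param name contig name.
#' @return named character vector of length 1.
#' @export
random_reference <- function(length, name = "seq1") {
  stopifnot(length >= 1L)
  out <- paste(sample(.BASES, length, replace = TRUE), collapse = "")
  names(out) <- name
  out
}
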
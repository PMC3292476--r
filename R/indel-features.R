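# INDEL candidate discovery from CIGARs and the INDEL model covariates.
#
# Candidates are keyed by their left-normalized VCF representation
# (chrom, anchor position, REF, ALT) so that every read supporting the same
# haplotype event maps to the same key no matter where the aligner placed
# the gap.

.indel_variables <- c("nvs", "mean_nbq", "mean_variation_rate",
                      "read_end_ratio")

#' Extract left-normalized INDEL candidates from one read
#'
#' One candidate per I/D CIGAR operation, anchored on the reference base
#' preceding the event and left-normalized against the reference.
#'
#' @param read one-row reads data.table (or named list).
#' @param reference named character vector of contigs or FASTA path.
#' @return data.table: chrom, pos, ref, alt, kind (INS/DEL), length; zero
#'   rows when the read has no gaps.
#' @export
extract_indel_candidates <- function(read, reference) {
  read <- .as_read_row(read)
  rb <- .ref_bytes(reference)
  parsed <- .parse_read(read$pos, read$cigar, read$seq, read$qual,
                        read$strand, rb[[read$chrom]])
  ev <- .read_indel_events(parsed, read$chrom, rb[[read$chrom]], reference)
  if (!length(ev)) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  kind = character(), length = integer()))
  }
  data.table::rbindlist(lapply(ev, function(e) {
    data.table::data.table(chrom = e$chrom, pos = e$pos, ref = e$ref,
                           alt = e$alt, kind = e$kind, length = e$length)
  }))
}

# normalized events of one parsed read, with the per-read covariates the
# INDEL model needs
.read_indel_events <- function(parsed, chrom, ref_raw, reference) {
  out <- list()
  for (d in parsed$dels) {
    if (d$refstart <= 1L) next  # no reference anchor before the event
    nv <- normalize_variant(chrom, d$refstart - 1L,
                            rawToChar(ref_raw[(d$refstart - 1L):(d$refstart + d$len - 1L)]),
                            rawToChar(ref_raw[d$refstart - 1L]), reference)
    qb <- max(d$qidx_before, parsed$core_start)
    out[[length(out) + 1L]] <- list(
      chrom = nv$chrom, pos = nv$pos, ref = nv$ref, alt = nv$alt,
      kind = "DEL", length = d$len,
      nbq = .del_nbq(parsed, d),
      variation_rate = parsed$variation_rate,
      near_read_end = min(.dist_end(parsed, qb),
                          .dist_end(parsed, min(qb + 1L, parsed$core_end))) <= 5L,
      strand = parsed$strand)
  }
  for (i in parsed$ins) {
    if (i$anchor < 1L) next
    insseq <- rawToChar(parsed$qbytes[i$qidx_start:(i$qidx_start + i$len - 1L)])
    nv <- normalize_variant(chrom, i$anchor,
                            rawToChar(ref_raw[i$anchor]),
                            paste0(rawToChar(ref_raw[i$anchor]), insseq),
                            reference)
    q1 <- i$qidx_start; q2 <- i$qidx_start + i$len - 1L
    out[[length(out) + 1L]] <- list(
      chrom = nv$chrom, pos = nv$pos, ref = nv$ref, alt = nv$alt,
      kind = "INS", length = i$len,
      nbq = .ins_nbq(parsed, i),
      variation_rate = parsed$variation_rate,
      near_read_end = min(.dist_end(parsed, q1), .dist_end(parsed, q2)) <= 5L,
      strand = parsed$strand)
  }
  out
}

#' Normalized variant square (NVS)
#'
#' Variant read count squared over total read depth; couples the variant
#' depth and the variant ratio in a single covariate normalized against
#' coverage.
#'
#' @param var_depth number of variant reads.
#' @param total_depth total read depth (>= var_depth, >= 1).
#' @return non-negative real.
#' @export
nvs <- function(var_depth, total_depth) {
  if (any(total_depth == 0)) stop("total_depth must be >= 1")
  if (any(var_depth < 0) || any(total_depth < var_depth)) {
    stop("need total_depth >= var_depth >= 0")
  }
  var_depth^2 / total_depth
}

#' Read-end ratio
#'
#' Fraction of variant reads where the INDEL lies within 5 bp of either read
#' end; errors from low 3'-end quality and gapped mis-mapping concentrate
#' there.
#'
#' @param near_read_end logical vector, one element per variant read.
#' @return proportion in \[0, 1\].
#' @export
read_end_ratio <- function(near_read_end) {
  if (!length(near_read_end)) stop("no variant reads")
  mean(near_read_end)
}

#' INDEL feature vector
#'
#' Computes the four INDEL model covariates for one candidate from its
#' variant-read observations and the spanning depth at the anchor.
#'
#' @param var_obs data.table with one row per variant read: columns nbq,
#'   variation_rate, near_read_end.
#' @param total_depth passing reads spanning the anchor position.
#' @return one-row data.table with feature columns plus var_depth and
#'   total_depth.
#' @export
indel_feature_vector <- function(var_obs, total_depth) {
  if (!nrow(var_obs)) stop("no variant observations for candidate")
  data.table::data.table(
    nvs = nvs(nrow(var_obs), total_depth),
    mean_nbq = mean(var_obs$nbq),
    mean_variation_rate = mean(var_obs$variation_rate),
    read_end_ratio = read_end_ratio(var_obs$near_read_end),
    var_depth = nrow(var_obs),
    total_depth = as.integer(total_depth))
}
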
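# Alignment input and the per-read parse that everything downstream uses.
#
# Reads are carried as a data.table with columns
#   qname, flag, chrom, pos (1-based leftmost), mapq, cigar, strand, seq, qual
# (qual is the phred+33 string). One row is one aligned read.
#
# `.parse_read()` walks the CIGAR once and precomputes every per-base
# covariate the feature modules need: aligned (query index, reference
# position, base, quality), deletion/insertion events, mismatch flags,
# distance to the 3' end in sequencing orientation, the neighboring base
# quality (NBQ) window mean, and the per-read variation rate. Soft-clipped
# bases are excluded from read length, NBQ windows and 3'-distances: clips
# carry no alignment evidence.

.cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(list(op = character(), len = integer()))
  parts <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  list(op = substring(parts, nchar(parts)),
       len = as.integer(substr(parts, 1L, nchar(parts) - 1L)))
}

# ref span consumed by a CIGAR (M/=/X/D/N)
.cigar_ref_span <- function(cigar) {
  ops <- .cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
}

# Full per-read parse against the reference. `read` is a one-row list/data
# row with fields pos, cigar, seq, qual, strand, chrom (chrom optional when
# ref_raw is supplied directly).
.parse_read <- function(pos, cigar, seq, qual, strand, ref_raw) {
  qbytes <- charToRaw(seq)
  q <- utf8ToInt(qual) - 33L
  qlen <- length(qbytes)
  if (length(q) != qlen) stop("sequence/quality length mismatch")

  # fast path: ungapped, unclipped alignment (the vast majority of reads)
  if (identical(cigar, paste0(qlen, "M"))) {
    refpos <- pos:(pos + qlen - 1L)
    if (pos < 1L || refpos[qlen] > length(ref_raw)) {
      stop("alignment extends outside the reference contig")
    }
    is_acgt <- qbytes %in% charToRaw("ACGT")
    mism <- is_acgt & (qbytes != ref_raw[refpos])
    n_events <- sum(mism)
    return(list(pos = pos, strand = strand, qlen = qlen,
                core_start = 1L, core_end = qlen, core_len = qlen,
                q = q, qbytes = qbytes,
                qidx = seq_len(qlen), refpos = refpos, bases = qbytes,
                mism = mism, dels = list(), ins = list(),
                span_start = pos, span_end = pos + qlen - 1L,
                n_events = n_events, variation_rate = n_events / qlen))
  }

  ops <- .cigar_ops(cigar)

  qi <- 1L; rp <- pos
  al_q <- vector("list", length(ops$op)); al_r <- al_q
  dels <- list(); ins <- list()
  lead_clip <- 0L; tail_clip <- 0L
  for (k in seq_along(ops$op)) {
    op <- ops$op[k]; l <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      al_q[[k]] <- qi:(qi + l - 1L)
      al_r[[k]] <- rp:(rp + l - 1L)
      qi <- qi + l; rp <- rp + l
    } else if (op == "I") {
      ins[[length(ins) + 1L]] <- list(anchor = rp - 1L, qidx_start = qi, len = l)
      qi <- qi + l
    } else if (op == "D") {
      dels[[length(dels) + 1L]] <- list(refstart = rp, len = l, qidx_before = qi - 1L)
      rp <- rp + l
    } else if (op == "S") {
      if (qi == 1L) lead_clip <- l else tail_clip <- tail_clip + l
      qi <- qi + l
    } else if (op == "N") {
      rp <- rp + l
    } # H and P consume nothing we track
  }
  qidx <- unlist(al_q, use.names = FALSE)
  refpos <- unlist(al_r, use.names = FALSE)
  if (is.null(qidx)) qidx <- integer()
  if (is.null(refpos)) refpos <- integer()
  if (length(refpos) && (refpos[length(refpos)] > length(ref_raw) || pos < 1L)) {
    stop("alignment extends outside the reference contig")
  }
  bases <- qbytes[qidx]
  refb <- ref_raw[refpos]
  is_acgt <- bases %in% charToRaw("ACGT")
  mism <- is_acgt & (bases != refb)

  core_start <- lead_clip + 1L
  core_end <- qlen - tail_clip
  core_len <- core_end - core_start + 1L

  n_events <- sum(mism) + length(dels) + length(ins)

  list(pos = pos, strand = strand, qlen = qlen,
       core_start = core_start, core_end = core_end, core_len = core_len,
       q = q, qbytes = qbytes,
       qidx = qidx, refpos = refpos, bases = bases, mism = mism,
       dels = dels, ins = ins,
       span_start = pos, span_end = if (length(refpos)) max(rp - 1L, pos) else pos,
       n_events = n_events,
       variation_rate = n_events / core_len)
}

# distance (bases) from query index to the read's 3' end in sequencing
# orientation, clip-excluded
.dist3 <- function(parsed, qidx) {
  ci <- qidx - parsed$core_start + 1L
  if (identical(parsed$strand, "-")) ci - 1L else parsed$core_len - ci
}

# distance from query index to the closest read end (0 = terminal base)
.dist_end <- function(parsed, qidx) {
  ci <- qidx - parsed$core_start + 1L
  pmin(ci - 1L, parsed$core_len - ci)
}

# NBQ window mean for a SNP observation: variant base plus up to 5 bases on
# each side, truncated at (clip-excluded) read boundaries
.nbq_at <- function(parsed, qidx, flank = 5L) {
  lo <- max(parsed$core_start, qidx - flank)
  hi <- min(parsed$core_end, qidx + flank)
  mean(parsed$q[lo:hi])
}

.read_sorted_check <- function(chrom, pos, state) {
  # state: environment with last_chrom, last_pos, seen (chroms completed)
  for (i in seq_along(pos)) {
    if (!identical(chrom[i], state$last_chrom)) {
      if (chrom[i] %in% state$seen) {
        stop("alignments are not coordinate-sorted (contig ", chrom[i],
             " occurs in more than one block)")
      }
      if (!is.null(state$last_chrom)) state$seen <- c(state$seen, state$last_chrom)
      state$last_chrom <- chrom[i]
      state$last_pos <- 0L
    }
    if (pos[i] < state$last_pos) {
      stop("alignments are not coordinate-sorted (", chrom[i], ":", pos[i],
           " after ", state$last_pos, ")")
    }
    state$last_pos <- pos[i]
  }
  invisible(NULL)
}

.empty_reads <- function() {
  data.table::data.table(qname = character(), flag = integer(),
                         chrom = character(), pos = integer(),
                         mapq = integer(), cigar = character(),
                         strand = character(), seq = character(),
                         qual = character())
}

#' Stream coordinate-sorted alignments in chunks
#'
#' Reads a SAM or BAM file chunk-wise (constant memory in the file size) and
#' hands each chunk of mapped, non-duplicate reads to `callback` as a
#' data.table in coordinate order. Unsorted input is rejected.
#'
#' @param path SAM or BAM file.
#' @param callback function taking one reads data.table per chunk.
#' @param chunk_size reads per chunk.
#' @return total number of reads streamed, invisibly.
#' @export
stream_alignments <- function(path, callback, chunk_size = 2000L) {
  bampath <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bampath <- Rsamtools::asBam(path,
                                destination = tempfile(fileext = ""),
                                overwrite = TRUE, indexDestination = FALSE)
  }
  bf <- Rsamtools::BamFile(bampath, yieldSize = chunk_size)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isDuplicate = FALSE))
  open(bf)
  on.exit(close(bf))
  state <- new.env(parent = emptyenv())
  state$last_chrom <- NULL; state$last_pos <- 0L; state$seen <- character()
  total <- 0L
  repeat {
    res <- Rsamtools::scanBam(bf, param = param)[[1L]]
    n <- length(res$pos)
    if (n == 0L) break
    dt <- data.table::data.table(
      qname = res$qname, flag = res$flag,
      chrom = as.character(res$rname), pos = res$pos,
      mapq = res$mapq, cigar = res$cigar,
      strand = as.character(res$strand),
      seq = as.character(res$seq), qual = as.character(res$qual))
    .read_sorted_check(dt$chrom, dt$pos, state)
    callback(dt)
    total <- total + n
  }
  invisible(total)
}

#' Read all alignments from a SAM/BAM file
#'
#' Convenience wrapper over [stream_alignments()] that collects every mapped,
#' non-duplicate read into one data.table. Use the streaming interface (or
#' pass a file path straight to [call_snps()]/[call_indels()]) when the file
#' is large.
#'
#' @inheritParams stream_alignments
#' @return reads data.table (qname, flag, chrom, pos, mapq, cigar, strand,
#'   seq, qual).
#' @export
read_alignments <- function(path, chunk_size = 2000L) {
  chunks <- list()
  stream_alignments(path, function(dt) chunks[[length(chunks) + 1L]] <<- dt,
                    chunk_size = chunk_size)
  if (!length(chunks)) return(.empty_reads())
  data.table::rbindlist(chunks)
}

.as_read_row <- function(read) {
  if (is.data.frame(read)) {
    stopifnot(nrow(read) == 1L)
    read <- as.list(read)
  }
  read
}

#' Per-read variation rate
#'
#' Number of mismatched bases plus insertion/deletion events (each gap
#' counts once regardless of length), divided by the clip-excluded read
#' length. A cheap surrogate for mapping quality.
#'
#' @param read one-row reads data.table (or equivalent named list).
#' @param reference named character vector of contigs or FASTA path.
#' @return proportion in \[0, 1\].
#' @export
variation_rate <- function(read, reference) {
  read <- .as_read_row(read)
  rb <- .ref_bytes(reference)
  if (!read$chrom %in% names(rb)) stop("reference window unavailable for contig ", read$chrom)
  p <- .parse_read(read$pos, read$cigar, read$seq, read$qual, read$strand,
                   rb[[read$chrom]])
  p$variation_rate
}

#' Distance from a read base to the 3' end
#'
#' Measured in sequencing orientation and excluding soft clips: for a
#' plus-strand read the 3' end is the last sequenced base, for a minus-strand
#' read it is the first stored base.
#'
#' @param read one-row reads data.table (or named list).
#' @param query_index 1-based index into the stored read sequence.
#' @return integer distance in bases (0 at the 3' terminal base).
#' @export
distance_to_3prime <- function(read, query_index) {
  read <- .as_read_row(read)
  qlen <- nchar(read$seq)
  if (query_index < 1L || query_index > qlen) {
    stop("query_index out of range [1, ", qlen, "]")
  }
  ops <- .cigar_ops(read$cigar)
  lead <- if (length(ops$op) && ops$op[1L] == "S") ops$len[1L] else 0L
  tail_ <- if (length(ops$op) && ops$op[length(ops$op)] == "S") ops$len[length(ops$op)] else 0L
  core_len <- qlen - lead - tail_
  ci <- as.integer(query_index) - lead
  if (ci < 1L || ci > core_len) stop("query_index falls in a soft-clipped segment")
  if (identical(read$strand, "-")) ci - 1L else core_len - ci
}

#' Per-read quality filter
#'
#' A read passes when its variant event count (mismatched bases plus gap
#' events) does not exceed `max_variant_events` and its mapping quality
#' satisfies the configured rule: `"exact255"` (uniquely-mapped convention of
#' aligners that reserve 255) or `"min:N"` (mapq >= N).
#'
#' @param read one-row reads data.table (or named list).
#' @param cfg a [filter_config()].
#' @param reference named character vector of contigs or FASTA path.
#' @return logical.
#' @export
passes_read_filters <- function(read, cfg = filter_config(), reference) {
  read <- .as_read_row(read)
  rb <- .ref_bytes(reference)
  p <- .parse_read(read$pos, read$cigar, read$seq, read$qual, read$strand,
                   rb[[read$chrom]])
  .passes_parsed(p, read$mapq, cfg)
}

.mapq_ok <- function(mapq, cfg) {
  mode <- cfg$read$mapq_mode
  if (identical(mode, "exact255")) return(mapq == 255L)
  if (grepl("^min:\\d+$", mode)) {
    return(mapq >= as.integer(sub("^min:", "", mode)))
  }
  stop("unknown mapq_mode: ", mode)
}

.passes_parsed <- function(parsed, mapq, cfg) {
  parsed$n_events <= cfg$read$max_variant_events && .mapq_ok(mapq, cfg)
}

# observation rows for one parsed read at reference position `pos`;
# returns NULL if the read does not cover pos
.observation_at <- function(parsed, read_id, pos) {
  hit <- which(parsed$refpos == pos)
  if (length(hit) == 1L) {
    qidx <- parsed$qidx[hit]
    return(list(read_id = read_id,
                base = rawToChar(parsed$bases[hit]),
                qual = parsed$q[qidx],
                dist3 = .dist3(parsed, qidx),
                strand = parsed$strand,
                variation_rate = parsed$variation_rate,
                near_read_end = .dist_end(parsed, qidx) <= 5L,
                nbq = .nbq_at(parsed, qidx)))
  }
  for (d in parsed$dels) {
    if (pos >= d$refstart && pos < d$refstart + d$len) {
      qb <- max(d$qidx_before, parsed$core_start)
      return(list(read_id = read_id, base = "-", qual = NA_integer_,
                  dist3 = .dist3(parsed, qb),
                  strand = parsed$strand,
                  variation_rate = parsed$variation_rate,
                  near_read_end = .dist_end(parsed, qb) <= 5L,
                  nbq = .del_nbq(parsed, d)))
    }
  }
  NULL
}

# deletion NBQ: up to 5 sequenced bases flanking the gap on each side
# (deleted bases have no quality)
.del_nbq <- function(parsed, d, flank = 5L) {
  qb <- d$qidx_before
  lo <- max(parsed$core_start, qb - flank + 1L)
  hi <- min(parsed$core_end, qb + flank)
  idx <- c(if (qb >= lo) lo:qb, if (qb + 1L <= hi) (qb + 1L):hi)
  mean(parsed$q[idx])
}

# insertion NBQ: inserted bases plus up to 5 flanking bases each side
.ins_nbq <- function(parsed, i, flank = 5L) {
  lo <- max(parsed$core_start, i$qidx_start - flank)
  hi <- min(parsed$core_end, i$qidx_start + i$len - 1L + flank)
  mean(parsed$q[lo:hi])
}

#' Build the pileup stack at one locus
#'
#' Collects one observation per covering read that passes the read filters:
#' aligned base and quality (or a GAP observation inside deletions), distance
#' to the 3' end, strand, per-read variation rate, read-end proximity and the
#' NBQ window mean.
#'
#' @param reads reads data.table (all reads overlapping the locus; extra
#'   reads are ignored).
#' @param chrom,pos locus (1-based).
#' @param reference named character vector of contigs or FASTA path.
#' @param cfg a [filter_config()].
#' @param apply_filters drop reads failing [passes_read_filters()] first.
#' @return a `site_stack`: list(chrom, pos, ref_base, observations,
#'   color_corrected_count).
#' @export
build_site_stack <- function(reads, chrom, pos, reference,
                             cfg = filter_config(), apply_filters = TRUE) {
  rb <- .ref_bytes(reference)
  if (!chrom %in% names(rb)) stop("unknown contig: ", chrom)
  if (pos < 1L || pos > length(rb[[chrom]])) {
    stop("position outside reference contig")
  }
  obs <- list()
  if (nrow(reads)) {
    reads <- reads[reads$chrom == chrom, , drop = FALSE]
    # cheap overlap prefilter: reference span is bounded by query length
    # plus total deleted/skipped bases
    ext <- vapply(reads$cigar, function(cg) {
      m <- regmatches(cg, gregexpr("\\d+(?=[DN])", cg, perl = TRUE))[[1]]
      sum(as.integer(m))
    }, numeric(1), USE.NAMES = FALSE)
    keep <- reads$pos <= pos & reads$pos + nchar(reads$seq) + ext > pos
    reads <- reads[keep, , drop = FALSE]
    for (i in seq_len(nrow(reads))) {
      p <- .parse_read(reads$pos[i], reads$cigar[i], reads$seq[i],
                       reads$qual[i], reads$strand[i], rb[[chrom]])
      if (apply_filters && !.passes_parsed(p, reads$mapq[i], cfg)) next
      o <- .observation_at(p, reads$qname[i], pos)
      if (!is.null(o)) obs[[length(obs) + 1L]] <- o
    }
  }
  .new_site_stack(chrom, pos, rawToChar(rb[[chrom]][pos]), obs)
}

.new_site_stack <- function(chrom, pos, ref_base, obs_list,
                            color_corrected_count = 0L) {
  observations <- if (length(obs_list)) {
    data.table::rbindlist(obs_list)
  } else {
    data.table::data.table(read_id = character(), base = character(),
                           qual = integer(), dist3 = integer(),
                           strand = character(), variation_rate = numeric(),
                           near_read_end = logical(), nbq = numeric())
  }
  structure(list(chrom = chrom, pos = pos, ref_base = ref_base,
                 observations = observations,
                 color_corrected_count = color_corrected_count),
            class = "site_stack")
}

#' @export
print.site_stack <- function(x, ...) {
  cat("site_stack ", x$chrom, ":", x$pos, " ref=", x$ref_base,
      " depth=", nrow(x$observations), "\n", sep = "")
  invisible(x)
}
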
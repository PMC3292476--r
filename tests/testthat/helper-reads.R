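# Hand-construction of reads and references for unit tests.

qstr <- function(q) intToUtf8(q + 33L)

make_ref <- function(seq, name = "seq1") {
  out <- toupper(seq)
  names(out) <- name
  out
}

make_read <- function(pos, seq, qual = NULL, cigar = NULL, strand = "+",
                      mapq = 255L, chrom = "seq1", qname = "r1",
                      flag = NULL) {
  if (is.null(qual)) qual <- rep(30L, nchar(seq))
  if (is.numeric(qual)) qual <- qstr(as.integer(qual))
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  if (is.null(flag)) flag <- if (strand == "+") 0L else 16L
  data.table::data.table(qname = qname, flag = as.integer(flag),
                         chrom = chrom, pos = as.integer(pos),
                         mapq = as.integer(mapq), cigar = cigar,
                         strand = strand, seq = toupper(seq), qual = qual)
}

make_reads <- function(...) {
  dt <- data.table::rbindlist(list(...))
  dt$qname <- sprintf("r%03d", seq_len(nrow(dt)))
  data.table::setorder(dt, chrom, pos)
  dt
}

# a read copying the reference at pos, with optional substitutions
ref_read <- function(reference, pos, len, subs = NULL, qual = 30L, ...) {
  s <- substr(reference[[1]], pos, pos + len - 1L)
  if (!is.null(subs)) {
    for (k in seq_along(subs)) {
      off <- as.integer(names(subs)[k])
      substr(s, off, off) <- subs[[k]]
    }
  }
  if (length(qual) == 1L) qual <- rep(qual, len)
  make_read(pos, s, qual = qual, ...)
}

clean_sim_config <- function(seed, n_sites = 100L, n_indel_sites = 20L,
                             reference_length = 40000L, depth_mean = 30) {
  sim_config(seed = seed, n_sites = n_sites, n_indel_sites = n_indel_sites,
             reference_length = reference_length, depth_mean = depth_mean,
             depth_log_sd = 0,
             error_profile = list(substitution_rate = 0, indel_rate = 0,
                                  hotspot_rate = 0, hotspot_density = 0))
}

noisy_sim_config <- function(seed, n_sites = 60L, n_indel_sites = 20L,
                             reference_length = 20000L, depth_mean = 25) {
  sim_config(seed = seed, n_sites = n_sites, n_indel_sites = n_indel_sites,
             reference_length = reference_length, depth_mean = depth_mean,
             error_profile = list(substitution_rate = 0.01, indel_rate = 0.01,
                                  hotspot_rate = 0.15,
                                  hotspot_density = 1 / 300))
}

call_key <- function(d) paste(d$chrom, d$pos, d$alt)

# reads carrying a shared deletion at `anchor`, plus spanning ref reads
make_del_reads <- function(ref, anchor, del_len, n_var, n_ref,
                           read_len = 40L) {
  rows <- list()
  for (i in seq_len(n_var)) {
    start <- anchor - 10L - i
    left <- anchor - start + 1L
    s <- paste0(substr(ref[[1]], start, anchor),
                substr(ref[[1]], anchor + del_len + 1L,
                       anchor + del_len + (read_len - left)))
    rows[[length(rows) + 1L]] <- make_read(start, s,
      cigar = paste0(left, "M", del_len, "D", read_len - left, "M"),
      strand = if (i %% 2L == 0L) "-" else "+")
  }
  for (i in seq_len(n_ref)) {
    # keep every reference read spanning the anchor (read_len 40)
    rows[[length(rows) + 1L]] <- ref_read(ref, anchor - 2L - (i %% 36L),
      read_len, strand = if (i %% 2L == 0L) "-" else "+")
  }
  do.call(make_reads, rows)
}
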
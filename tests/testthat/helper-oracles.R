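# Independent naive re-implementations used as oracles. Deliberately written
# with a different structure than the package code: string-based CIGAR
# parsing, per-read loops over substr(), and brute-force searches.

o_cigar <- function(cigar) {
  ops <- strsplit(gsub("[0-9]+", "", cigar), "")[[1]]
  lens <- as.integer(strsplit(cigar, "[MIDNSHP=X]")[[1]])
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

# one row per query base (refpos NA for insertions/clips) plus one row per
# deleted reference base (qi NA, base "-")
o_read_table <- function(read, reference) {
  cg <- o_cigar(read$cigar)
  refseq <- reference[[read$chrom]]
  qi <- 1L; rp <- read$pos
  quals <- utf8ToInt(read$qual) - 33L
  v_qi <- integer(); v_rp <- integer(); v_base <- character()
  v_refb <- character(); v_q <- integer(); v_op <- character()
  for (k in seq_len(nrow(cg))) {
    op <- cg$op[k]; l <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      for (j in 0:(l - 1L)) {
        v_qi <- c(v_qi, qi + j); v_rp <- c(v_rp, rp + j)
        v_base <- c(v_base, substr(read$seq, qi + j, qi + j))
        v_refb <- c(v_refb, substr(refseq, rp + j, rp + j))
        v_q <- c(v_q, quals[qi + j]); v_op <- c(v_op, op)
      }
      qi <- qi + l; rp <- rp + l
    } else if (op == "I") {
      for (j in 0:(l - 1L)) {
        v_qi <- c(v_qi, qi + j); v_rp <- c(v_rp, NA_integer_)
        v_base <- c(v_base, substr(read$seq, qi + j, qi + j))
        v_refb <- c(v_refb, NA_character_)
        v_q <- c(v_q, quals[qi + j]); v_op <- c(v_op, "I")
      }
      qi <- qi + l
    } else if (op == "D") {
      for (j in 0:(l - 1L)) {
        v_qi <- c(v_qi, NA_integer_); v_rp <- c(v_rp, rp + j)
        v_base <- c(v_base, "-")
        v_refb <- c(v_refb, substr(refseq, rp + j, rp + j))
        v_q <- c(v_q, NA_integer_); v_op <- c(v_op, "D")
      }
      rp <- rp + l
    } else if (op == "S") {
      qi <- qi + l
    } else if (op == "N") {
      rp <- rp + l
    }
  }
  data.frame(qi = v_qi, refpos = v_rp, base = v_base, refbase = v_refb,
             qual = v_q, op = v_op, stringsAsFactors = FALSE)
}

o_clips <- function(read) {
  cg <- o_cigar(read$cigar)
  lead <- if (cg$op[1] == "S") cg$len[1] else 0L
  tl <- if (cg$op[nrow(cg)] == "S") cg$len[nrow(cg)] else 0L
  list(lead = lead, tail = tl, core_len = nchar(read$seq) - lead - tl)
}

o_dist3 <- function(read, qi) {
  cl <- o_clips(read)
  ci <- qi - cl$lead
  if (read$strand == "-") ci - 1L else cl$core_len - ci
}

o_dist_end <- function(read, qi) {
  cl <- o_clips(read)
  ci <- qi - cl$lead
  min(ci - 1L, cl$core_len - ci)
}

o_nbq <- function(read, qi, flank = 5L) {
  cl <- o_clips(read)
  quals <- utf8ToInt(read$qual) - 33L
  win <- max(cl$lead + 1L, qi - flank):min(nchar(read$seq) - cl$tail, qi + flank)
  mean(quals[win])
}

o_event_counts <- function(read, reference) {
  tab <- o_read_table(read, reference)
  mm <- sum(tab$op %in% c("M", "=", "X") & tab$base != tab$refbase &
              tab$base %in% c("A", "C", "G", "T"))
  cg <- o_cigar(read$cigar)
  list(mismatches = mm, gaps = sum(cg$op %in% c("I", "D")))
}

o_variation_rate <- function(read, reference) {
  ec <- o_event_counts(read, reference)
  (ec$mismatches + ec$gaps) / o_clips(read)$core_len
}

o_passes <- function(read, reference, max_events = 3L, mapq_mode = "exact255") {
  ec <- o_event_counts(read, reference)
  mq <- if (mapq_mode == "exact255") read$mapq == 255L else
    read$mapq >= as.integer(sub("min:", "", mapq_mode))
  (ec$mismatches + ec$gaps) <= max_events && mq
}

# pass check given an already computed per-base table
o_passes_tab <- function(read, tab) {
  mm <- sum(tab$op %in% c("M", "=", "X") & tab$base != tab$refbase &
              tab$base %in% c("A", "C", "G", "T"))
  cg <- o_cigar(read$cigar)
  (mm + sum(cg$op %in% c("I", "D"))) <= 3L && read$mapq == 255L
}

# naive pileup: observations of passing reads at one locus
o_pileup <- function(reads, reference, chrom, pos) {
  out <- list()
  # generous window: no simulated read spans more than 200 bp of reference
  # (data.frame subset: the locus argument must not collide with the column)
  .at <- pos
  reads <- as.data.frame(reads)[reads$pos <= .at & reads$pos + 200L > .at, ]
  for (i in seq_len(nrow(reads))) {
    rd <- as.list(reads[i, ])
    if (rd$chrom != chrom) next
    tab <- o_read_table(rd, reference)
    if (!o_passes_tab(rd, tab)) next
    hit <- tab[!is.na(tab$refpos) & tab$refpos == pos, ]
    if (!nrow(hit)) next
    if (hit$op[1] == "D") {
      out[[length(out) + 1L]] <- data.frame(
        read = rd$qname, base = "-", qual = NA_integer_,
        dist3 = NA_integer_, strand = rd$strand, stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        read = rd$qname, base = hit$base[1], qual = hit$qual[1],
        dist3 = o_dist3(rd, hit$qi[1]), strand = rd$strand,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# naive SNP feature recomputation at one locus for one alt
o_snp_features <- function(reads, reference, chrom, pos, alt) {
  refbase <- substr(reference[[chrom]], pos, pos)
  .at <- pos
  reads <- as.data.frame(reads)[reads$pos <= .at & reads$pos + 200L > .at, ]
  nbqs <- c(); quals <- c(); d3 <- c(); strands <- c(); nref <- 0L
  for (i in seq_len(nrow(reads))) {
    rd <- as.list(reads[i, ])
    if (rd$chrom != chrom) next
    tab <- o_read_table(rd, reference)
    if (!o_passes_tab(rd, tab)) next
    hit <- tab[!is.na(tab$refpos) & tab$refpos == pos & tab$op != "D", ]
    if (!nrow(hit)) next
    if (hit$base[1] == alt) {
      nbqs <- c(nbqs, o_nbq(rd, hit$qi[1]))
      quals <- c(quals, hit$qual[1])
      d3 <- c(d3, o_dist3(rd, hit$qi[1]))
      strands <- c(strands, rd$strand)
    } else if (hit$base[1] == refbase) {
      nref <- nref + 1L
    }
  }
  sb <- as.integer(("+" %in% strands) && ("-" %in% strands))
  list(ref_var_ratio = if (nref == 0L) 0 else nref / length(nbqs),
       mean_var_base_quality = mean(quals),
       mean_nbq = mean(nbqs),
       mean_dist3 = mean(d3),
       strand_both = sb,
       nbq_x_dist3 = mean(nbqs) * mean(d3),
       strand_x_dist3 = sb * mean(d3),
       var_depth = length(nbqs), ref_depth = nref)
}

# independent left normalization by brute-force haplotype comparison
o_normalize <- function(chrom, pos, ref, alt, reference) {
  refseq <- reference[[chrom]]
  w1 <- max(1L, pos - 60L)
  w2 <- min(nchar(refseq), pos + nchar(ref) + 60L)
  apply_var <- function(p, r, a) {
    paste0(substr(refseq, w1, p - 1L), a,
           substr(refseq, p + nchar(r), w2))
  }
  target <- apply_var(pos, ref, alt)
  l <- nchar(ref) - nchar(alt)
  best <- c(pos = pos, ref = ref, alt = alt)
  if (l > 0) {        # deletion of l bases; try every anchor to the left
    for (p in w1:pos) {
      r2 <- substr(refseq, p, p + l)
      a2 <- substr(refseq, p, p)
      if (apply_var(p, r2, a2) == target) {
        return(list(chrom = chrom, pos = p, ref = r2, alt = a2))
      }
    }
  } else if (l < 0) { # insertion
    for (p in w1:pos) {
      a_len <- -l
      # try all inserted strings consistent with the target haplotype
      hap <- target
      left <- p - w1 + 1L
      ins <- substr(hap, left + 1L, left + a_len)
      r2 <- substr(refseq, p, p)
      a2 <- paste0(r2, ins)
      if (apply_var(p, r2, a2) == target) {
        return(list(chrom = chrom, pos = p, ref = r2, alt = a2))
      }
    }
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

# naive indel candidate extraction from one read (unnormalized events)
o_read_events <- function(read) {
  cg <- o_cigar(read$cigar)
  qi <- 1L; rp <- read$pos
  ev <- list()
  for (k in seq_len(nrow(cg))) {
    op <- cg$op[k]; l <- cg$len[k]
    if (op %in% c("M", "=", "X")) { qi <- qi + l; rp <- rp + l }
    else if (op == "I") {
      ev[[length(ev) + 1L]] <- list(kind = "INS", refstart = rp,
                                    qi_start = qi, len = l,
                                    seq = substr(read$seq, qi, qi + l - 1L))
      qi <- qi + l
    } else if (op == "D") {
      ev[[length(ev) + 1L]] <- list(kind = "DEL", refstart = rp,
                                    qi_start = qi, len = l, seq = "")
      rp <- rp + l
    } else if (op == "S") qi <- qi + l
    else if (op == "N") rp <- rp + l
  }
  ev
}

# naive INDEL feature recomputation for one normalized candidate
o_indel_features <- function(reads, reference, chrom, pos, ref_al, alt_al) {
  nbqs <- c(); vrates <- c(); near <- c(); total <- 0L
  .at <- pos
  reads <- as.data.frame(reads)[reads$pos <= .at + 250L & reads$pos + 250L > .at, ]
  for (i in seq_len(nrow(reads))) {
    rd <- as.list(reads[i, ])
    if (rd$chrom != chrom || !o_passes(rd, reference)) next
    cg <- o_cigar(rd$cigar)
    span <- sum(cg$len[cg$op %in% c("M", "=", "X", "D", "N")])
    if (rd$pos <= pos && rd$pos + span - 1L >= pos) total <- total + 1L
    for (ev in o_read_events(rd)) {
      norm <- if (ev$kind == "DEL") {
        o_normalize(chrom, ev$refstart - 1L,
                    substr(reference[[chrom]], ev$refstart - 1L,
                           ev$refstart + ev$len - 1L),
                    substr(reference[[chrom]], ev$refstart - 1L,
                           ev$refstart - 1L), reference)
      } else {
        anchor <- ev$refstart - 1L
        b <- substr(reference[[chrom]], anchor, anchor)
        o_normalize(chrom, anchor, b, paste0(b, ev$seq), reference)
      }
      if (norm$pos != pos || norm$ref != ref_al || norm$alt != alt_al) next
      cl <- o_clips(rd)
      quals <- utf8ToInt(rd$qual) - 33L
      if (ev$kind == "DEL") {
        qb <- ev$qi_start - 1L   # last query base before the gap
        lo <- max(cl$lead + 1L, qb - 4L)
        hi <- min(nchar(rd$seq) - cl$tail, qb + 5L)
        nbqs <- c(nbqs, mean(quals[lo:hi]))
        edge <- min(o_dist_end(rd, qb), o_dist_end(rd, qb + 1L))
      } else {
        lo <- max(cl$lead + 1L, ev$qi_start - 5L)
        hi <- min(nchar(rd$seq) - cl$tail, ev$qi_start + ev$len - 1L + 5L)
        nbqs <- c(nbqs, mean(quals[lo:hi]))
        edge <- min(o_dist_end(rd, ev$qi_start),
                    o_dist_end(rd, ev$qi_start + ev$len - 1L))
      }
      near <- c(near, edge <= 5L)
      vrates <- c(vrates, o_variation_rate(rd, reference))
    }
  }
  v <- length(nbqs)
  list(nvs = v^2 / total, mean_nbq = mean(nbqs),
       mean_variation_rate = mean(vrates), read_end_ratio = mean(near),
       var_depth = v, total_depth = total)
}

# max read coverage (any-base) across positions, from raw reads
o_max_coverage <- function(reads, reference) {
  L <- nchar(reference[[1]])
  cov <- integer(L)
  for (i in seq_len(nrow(reads))) {
    cg <- o_cigar(reads$cigar[i])
    span <- sum(cg$len[cg$op %in% c("M", "=", "X", "D", "N")])
    if (span > 0) {
      idx <- reads$pos[i]:(reads$pos[i] + span - 1L)
      cov[idx] <- cov[idx] + 1L
    }
  }
  max(cov)
}

# aligned-base (M/=/X) coverage per position, from raw reads
o_coverage <- function(reads, reference) {
  L <- nchar(reference[[1]])
  cov <- integer(L)
  for (i in seq_len(nrow(reads))) {
    cg <- o_cigar(reads$cigar[i])
    rp <- reads$pos[i]
    for (k in seq_len(nrow(cg))) {
      if (cg$op[k] %in% c("M", "=", "X")) {
        idx <- rp:(rp + cg$len[k] - 1L)
        cov[idx] <- cov[idx] + 1L
        rp <- rp + cg$len[k]
      } else if (cg$op[k] %in% c("D", "N")) {
        rp <- rp + cg$len[k]
      }
    }
  }
  cov
}
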
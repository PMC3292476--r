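# Candidate discovery, scoring, filtering and genotyping.
#
# The engine walks coordinate-sorted reads once, keeping only the reads that
# overlap the current locus window in memory ("active" set), so memory is
# bounded by local depth rather than file size. Candidate SNP loci are the
# positions where any passing read mismatches the reference; candidate
# INDELs are the left-normalized I/D events of passing reads. Candidates are
# finalized as soon as the walk has moved past them, at which point every
# read covering them is still in the active set.

# amortized O(1) row collector (growing a list through `<<-` copies it)
.acc_new <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$items <- vector("list", 64L)
  e
}
.acc_add <- function(e, x) {
  e$n <- e$n + 1L
  if (e$n > length(e$items)) length(e$items) <- 2L * length(e$items)
  e$items[[e$n]] <- x
}
.acc_list <- function(e) e$items[seq_len(e$n)]

# iterate chunks from either a reads data.table or a SAM/BAM path
.chunk_source <- function(alignments, chunk_size = 2000L) {
  if (inherits(alignments, "read_simulation")) alignments <- alignments$reads
  if (is.character(alignments) && length(alignments) == 1L) {
    return(function(cb) stream_alignments(alignments, cb, chunk_size))
  }
  if (is.data.frame(alignments)) {
    dt <- data.table::as.data.table(alignments)
    return(function(cb) {
      n <- nrow(dt)
      if (!n) return(invisible(0L))
      starts <- seq(1L, n, by = chunk_size)
      state <- new.env(parent = emptyenv())
      state$last_chrom <- NULL; state$last_pos <- 0L; state$seen <- character()
      for (s in starts) {
        chunk <- dt[s:min(s + chunk_size - 1L, n)]
        .read_sorted_check(chunk$chrom, chunk$pos, state)
        cb(chunk)
      }
      invisible(n)
    })
  }
  stop("alignments must be a reads data.table, a read_simulation, ",
       "or a SAM/BAM path")
}

# region membership: GRanges -> per-chrom interval lookup
.region_index <- function(regions) {
  if (is.null(regions)) return(NULL)
  if (is.character(regions) && length(regions) == 1L) regions <- read_bed(regions)
  gr <- GenomicRanges::reduce(regions)
  lst <- split(IRanges::ranges(gr), as.character(GenomicRanges::seqnames(gr)))
  lapply(lst, function(ir) cbind(start = IRanges::start(ir),
                                 end = IRanges::end(ir)))
}

.in_region <- function(idx, chrom, pos) {
  if (is.null(idx)) return(TRUE)
  iv <- idx[[chrom]]
  if (is.null(iv) || !nrow(iv)) return(FALSE)
  k <- findInterval(pos, iv[, "start"])
  k >= 1L && pos <= iv[k, "end"]
}

# The single-pass pileup walk. visit_snp(stack) is called for every locus
# where >= 1 passing read mismatches the reference; visit_indel(candidate,
# var_obs, total_depth) for every normalized indel candidate. Returns the
# maximum number of simultaneously retained parsed reads.
.pileup_walk <- function(alignments, reference, cfg,
                         visit_snp = NULL, visit_indel = NULL,
                         chunk_size = 2000L) {
  rb <- .ref_bytes(reference)
  source_fn <- .chunk_source(alignments, chunk_size)
  env <- new.env(parent = emptyenv())
  env$active <- list()          # parsed passing reads in the current window
  env$ids <- character()
  env$starts <- integer()       # span bounds of active reads (vectorized
  env$ends <- integer()         # bookkeeping for pruning/coverage checks)
  env$chrom <- NULL
  env$pend_snp <- integer()     # candidate mismatch positions, unsorted
  env$pend_ind <- list()        # key -> list(cand, obs=list of covariate rows)
  env$max_active <- 0L
  env$max_width <- 1L           # widest read span seen (finalization lag)
  env$diff <- NULL              # spanning-depth difference array (passing reads)
  env$cursor <- 0L; env$cum <- 0L

  depth_at_anchor <- function(anchor) {
    # anchors arrive in nondecreasing order, so a running prefix sum works
    while (env$cursor < anchor) {
      env$cursor <- env$cursor + 1L
      env$cum <- env$cum + env$diff[env$cursor]
    }
    env$cum
  }

  finalize_snp <- function(boundary) {
    if (!length(env$pend_snp)) return(invisible())
    u <- sort(unique(env$pend_snp))
    todo <- u[u < boundary]
    env$pend_snp <- env$pend_snp[env$pend_snp >= boundary]
    for (pos in todo) {
      obs <- list()
      for (k in which(env$starts <= pos & env$ends >= pos)) {
        o <- .observation_at(env$active[[k]], env$ids[k], pos)
        if (!is.null(o)) obs[[length(obs) + 1L]] <- o
      }
      stack <- .new_site_stack(env$chrom, pos,
                               rawToChar(rb[[env$chrom]][pos]), obs)
      visit_snp(stack)
    }
  }

  # Indel candidates are finalized one read-width behind the walk: a
  # later-starting read can still support the same normalized event when the
  # aligner placed its gap further right inside a repeat run. Spanning depth
  # at the anchor comes from the difference array, which is final once the
  # walk has passed the anchor.
  finalize_indels <- function(boundary) {
    if (!length(env$pend_ind)) return(invisible())
    keys <- names(env$pend_ind)
    anchors <- vapply(env$pend_ind, function(e) e$cand$pos, integer(1))
    lag <- if (is.finite(boundary)) env$max_width else 0L
    sel <- which(anchors + lag < boundary)
    for (key in keys[sel[order(anchors[sel])]]) {
      e <- env$pend_ind[[key]]
      total <- depth_at_anchor(e$cand$pos)
      var_obs <- data.table::rbindlist(e$obs)
      visit_indel(e$cand, var_obs, max(total, nrow(var_obs)))
      env$pend_ind[[key]] <- NULL
    }
  }

  flush_to <- function(boundary) {
    if (!is.null(visit_snp)) finalize_snp(boundary)
    if (!is.null(visit_indel)) finalize_indels(boundary)
    if (length(env$ends) && any(env$ends < boundary)) {
      keep <- env$ends >= boundary
      env$active <- env$active[keep]
      env$ids <- env$ids[keep]
      env$starts <- env$starts[keep]
      env$ends <- env$ends[keep]
    }
  }

  source_fn(function(chunk) {
    for (i in seq_len(nrow(chunk))) {
      chrom <- chunk$chrom[i]
      if (!identical(chrom, env$chrom)) {
        if (!is.null(env$chrom)) flush_to(Inf)
        if (!chrom %in% names(rb)) {
          stop("read aligned to unknown contig: ", chrom)
        }
        env$active <- list(); env$ids <- character()
        env$starts <- integer(); env$ends <- integer()
        env$chrom <- chrom
        env$diff <- integer(length(rb[[chrom]]) + 1L)
        env$cursor <- 0L; env$cum <- 0L
      } else {
        flush_to(chunk$pos[i])
      }
      p <- .parse_read(chunk$pos[i], chunk$cigar[i], chunk$seq[i],
                       chunk$qual[i], chunk$strand[i], rb[[chrom]])
      if (!.passes_parsed(p, chunk$mapq[i], cfg)) next
      env$active[[length(env$active) + 1L]] <- p
      env$ids <- c(env$ids, chunk$qname[i])
      env$starts <- c(env$starts, p$span_start)
      env$ends <- c(env$ends, p$span_end)
      env$max_active <- max(env$max_active, length(env$active))
      env$max_width <- max(env$max_width, p$span_end - p$span_start + 1L)
      env$diff[p$span_start] <- env$diff[p$span_start] + 1L
      if (p$span_end + 1L <= length(env$diff)) {
        env$diff[p$span_end + 1L] <- env$diff[p$span_end + 1L] - 1L
      }
      if (!is.null(visit_snp) && any(p$mism)) {
        env$pend_snp <- c(env$pend_snp, p$refpos[p$mism])
      }
      if (!is.null(visit_indel) && (length(p$dels) || length(p$ins))) {
        for (e in .read_indel_events(p, chrom, rb[[chrom]], reference)) {
          key <- paste(e$chrom, e$pos, e$ref, e$alt, sep = "\r")
          cov <- data.table::data.table(nbq = e$nbq,
                                        variation_rate = e$variation_rate,
                                        near_read_end = e$near_read_end,
                                        strand = e$strand)
          if (is.null(env$pend_ind[[key]])) {
            env$pend_ind[[key]] <- list(
              cand = list(chrom = e$chrom, pos = e$pos, ref = e$ref,
                          alt = e$alt, kind = e$kind, length = e$length),
              obs = list(cov))
          } else {
            env$pend_ind[[key]]$obs <-
              c(env$pend_ind[[key]]$obs, list(cov))
          }
        }
      }
    }
  })
  if (!is.null(env$chrom)) flush_to(Inf)
  env$max_active
}

#' Effective read depth at a site
#'
#' Count of filtered-read observations carrying the reference base or a
#' variant base (A/C/G/T); gap and ambiguous observations are excluded.
#'
#' @param stack a `site_stack` built from passing reads.
#' @return integer count.
#' @export
effective_depth <- function(stack) {
  sum(stack$observations$base %in% .BASES)
}

#' Per-position effective depth track
#'
#' @param reads reads data.table.
#' @param reference named character vector of contigs or FASTA path.
#' @param cfg a [filter_config()]; reads failing the per-read filters are
#'   excluded.
#' @return named list (one integer vector per contig, full contig length).
#' @export
effective_depth_track <- function(reads, reference, cfg = filter_config()) {
  rb <- .ref_bytes(reference)
  track <- lapply(rb, function(x) integer(length(x)))
  for (i in seq_len(nrow(reads))) {
    chrom <- reads$chrom[i]
    p <- .parse_read(reads$pos[i], reads$cigar[i], reads$seq[i],
                     reads$qual[i], reads$strand[i], rb[[chrom]])
    if (!.passes_parsed(p, reads$mapq[i], cfg)) next
    acgt <- p$bases %in% charToRaw("ACGT")
    rp <- p$refpos[acgt]
    track[[chrom]][rp] <- track[[chrom]][rp] + 1L
  }
  track
}

#' Callable regions from a depth track
#'
#' Maximal runs of positions whose effective depth is at least
#' `cfg$callable$min_effective_depth`.
#'
#' @param depth named list of per-contig integer vectors (from
#'   [effective_depth_track()]) or a data.frame(chrom, pos, depth).
#' @param cfg a [filter_config()].
#' @return GRanges of callable intervals (1-based closed, sorted, merged).
#' @export
callable_regions <- function(depth, cfg = filter_config()) {
  min_d <- cfg$callable$min_effective_depth
  if (is.data.frame(depth)) {
    mx <- tapply(depth$pos, depth$chrom, max)
    lst <- lapply(names(mx), function(ch) {
      v <- integer(mx[[ch]])
      sel <- depth$chrom == ch
      v[depth$pos[sel]] <- depth$depth[sel]
      v
    })
    names(lst) <- names(mx)
    depth <- lst
  }
  out <- list()
  for (ch in names(depth)) {
    ok <- depth[[ch]] >= min_d
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values
    out[[ch]] <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(starts[sel], ends[sel]))
  }
  if (!length(out)) {
    return(GenomicRanges::GRanges())
  }
  sort(do.call(c, unname(out)))
}

#' Total callable bp of a region set
#' @param regions GRanges.
#' @return integer sum of interval widths.
#' @export
callable_bp <- function(regions) {
  sum(IRanges::width(GenomicRanges::reduce(regions)))
}

#' Adjusted variant ratio t
#'
#' t = variant depth / (total depth - color-corrected bases). Drives
#' genotyping: het at t >= 0.1, hom at t >= 0.8 by default.
#'
#' @param var_depth variant read depth.
#' @param total_depth total read depth.
#' @param color_corrected color-corrected base count (0 unless supplied by a
#'   color-space pipeline).
#' @return numeric t.
#' @export
adjusted_variant_ratio <- function(var_depth, total_depth,
                                   color_corrected = 0L) {
  den <- total_depth - color_corrected
  if (any(den <= 0)) stop("denominator (total - color_corrected) must be >= 1")
  if (any(var_depth < 0) || any(den < var_depth)) {
    stop("need total_depth - color_corrected >= var_depth >= 0")
  }
  var_depth / den
}

#' Genotype from the adjusted variant ratio
#'
#' t >= hom_t: homozygous; hom_t > t >= het_t: heterozygous; below het_t the
#' site fails genotyping (both bounds inclusive).
#'
#' @param t adjusted variant ratio in \[0, 1\].
#' @param cfg a [filter_config()].
#' @return "hom", "het" or "none".
#' @export
genotype_from_t <- function(t, cfg = filter_config()) {
  stopifnot(all(t >= 0 & t <= 1))
  ifelse(t >= cfg$genotype$hom_t, "hom",
         ifelse(t >= cfg$genotype$het_t, "het", "none"))
}

.empty_calls <- function() {
  data.table::data.table(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         kind = character(), p = numeric(), t = numeric(),
                         genotype = character(), var_depth = integer(),
                         total_depth = integer(), effective_depth = integer(),
                         filters = character())
}

#' SNP candidate features across a read set
#'
#' Runs the pileup walk and returns one row per (locus, alternate base) with
#' at least one variant observation: the seven SNP model covariates plus
#' depths. This is the feature-export surface used for model training.
#'
#' @param alignments reads data.table, `read_simulation`, or SAM/BAM path.
#' @param reference named character vector of contigs or FASTA path.
#' @param cfg a [filter_config()].
#' @param regions optional GRanges (or BED path) restricting candidate loci.
#' @return data.table: chrom, pos, ref, alt, features, var_depth, ref_depth,
#'   effective_depth.
#' @export
snp_candidate_features <- function(alignments, reference,
                                   cfg = filter_config(), regions = NULL) {
  ridx <- .region_index(regions)
  rows <- .acc_new()
  max_active <- .pileup_walk(alignments, reference, cfg,
    visit_snp = function(stack) {
      if (!.in_region(ridx, stack$chrom, stack$pos)) return(invisible())
      eff <- effective_depth(stack)
      alts <- setdiff(unique(stack$observations$base),
                      c(stack$ref_base, "-", "N"))
      for (alt in alts) {
        fv <- snp_feature_vector(stack, alt)
        fv[, c("chrom", "pos", "ref", "alt", "effective_depth") :=
             list(stack$chrom, stack$pos, stack$ref_base, alt, eff)]
        .acc_add(rows, fv)
      }
    })
  rows <- .acc_list(rows)
  out <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(ref_var_ratio = numeric(),
                           mean_var_base_quality = numeric(),
                           mean_nbq = numeric(), mean_dist3 = numeric(),
                           strand_both = integer(), nbq_x_dist3 = numeric(),
                           strand_x_dist3 = numeric(), var_depth = integer(),
                           ref_depth = integer(), chrom = character(),
                           pos = integer(), ref = character(),
                           alt = character(), effective_depth = integer())
  data.table::setcolorder(out, c("chrom", "pos", "ref", "alt"))
  data.table::setattr(out, "max_active_reads", max_active)
  out[]
}

#' INDEL candidate features across a read set
#'
#' One row per left-normalized candidate: the four INDEL model covariates,
#' variant depth and spanning total depth at the anchor.
#'
#' @inheritParams snp_candidate_features
#' @return data.table: chrom, pos, ref, alt, kind, length, features,
#'   var_depth, total_depth.
#' @export
indel_candidate_features <- function(alignments, reference,
                                     cfg = filter_config(), regions = NULL) {
  ridx <- .region_index(regions)
  rows <- .acc_new()
  max_active <- .pileup_walk(alignments, reference, cfg,
    visit_indel = function(cand, var_obs, total_depth) {
      if (!.in_region(ridx, cand$chrom, cand$pos)) return(invisible())
      fv <- indel_feature_vector(var_obs, total_depth)
      fv[, c("chrom", "pos", "ref", "alt", "kind", "length") :=
           list(cand$chrom, cand$pos, cand$ref, cand$alt, cand$kind,
                cand$length)]
      .acc_add(rows, fv)
    })
  rows <- .acc_list(rows)
  out <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(nvs = numeric(), mean_nbq = numeric(),
                           mean_variation_rate = numeric(),
                           read_end_ratio = numeric(), var_depth = integer(),
                           total_depth = integer(), chrom = character(),
                           pos = integer(), ref = character(),
                           alt = character(), kind = character(),
                           length = integer())
  data.table::setcolorder(out, c("chrom", "pos", "ref", "alt", "kind",
                                 "length"))
  data.table::setorder(out, chrom, pos, alt)
  data.table::setattr(out, "max_active_reads", max_active)
  out[]
}

.finish_calls <- function(rows, keep_filtered, max_active) {
  out <- if (length(rows)) data.table::rbindlist(rows) else .empty_calls()
  if (nrow(out)) data.table::setorder(out, chrom, pos, alt)
  if (!keep_filtered) out <- out[out$filters == "", ]
  data.table::setattr(out, "max_active_reads", max_active)
  out[]
}

#' Call SNPs
#'
#' Builds the pileup at every candidate locus, scores each alternate base
#' with the SNP model, applies the heuristic filters (minimum p, minimum
#' variant depth, callable effective depth) and genotypes passing calls via
#' the adjusted variant ratio t. Calls whose t falls below the heterozygous
#' threshold are demoted to filtered (`low_t`), not emitted as reference.
#'
#' @param alignments reads data.table, `read_simulation`, or SAM/BAM path.
#' @param reference named character vector of contigs or FASTA path.
#' @param model SNP [logistic_model()] (or path to a model JSON).
#' @param cfg a [filter_config()].
#' @param regions optional GRanges or BED path restricting calling.
#' @param keep_filtered also return non-PASS candidates with their filter
#'   reasons.
#' @return data.table of variant calls (`filters == ""` means PASS), with
#'   attribute `max_active_reads` (peak retained-read count of the walk).
#' @export
call_snps <- function(alignments, reference, model, cfg = filter_config(),
                      regions = NULL, keep_filtered = FALSE) {
  if (is.character(model)) model <- load_model(model)
  missing <- setdiff(model$variables, .snp_variables)
  if (length(missing)) {
    stop("SNP model uses unknown variable(s): ", paste(missing, collapse = ", "))
  }
  ridx <- .region_index(regions)
  rows <- .acc_new()
  max_active <- .pileup_walk(alignments, reference, cfg,
    visit_snp = function(stack) {
      if (!.in_region(ridx, stack$chrom, stack$pos)) return(invisible())
      eff <- effective_depth(stack)
      alts <- setdiff(unique(stack$observations$base),
                      c(stack$ref_base, "-", "N"))
      for (alt in alts) {
        fv <- snp_feature_vector(stack, alt)
        p <- lr_score(model, fv)
        filters <- character()
        if (p < cfg$snp$min_p) filters <- c(filters, "low_p")
        if (fv$var_depth < cfg$snp$min_var_depth) {
          filters <- c(filters, "min_var_depth")
        }
        if (eff < cfg$callable$min_effective_depth) {
          filters <- c(filters, "not_callable")
        }
        den <- eff - stack$color_corrected_count
        t <- if (den >= fv$var_depth && den > 0) fv$var_depth / den else NA_real_
        gt <- NA_character_
        if (!length(filters)) {
          g <- genotype_from_t(t, cfg)
          if (g == "none") filters <- c(filters, "low_t") else gt <- g
        }
        .acc_add(rows, data.table::data.table(
          chrom = stack$chrom, pos = stack$pos, ref = stack$ref_base,
          alt = alt, kind = "SNP", p = p, t = t, genotype = gt,
          var_depth = fv$var_depth, total_depth = eff,
          effective_depth = eff,
          filters = paste(filters, collapse = ";")))
      }
    })
  .finish_calls(.acc_list(rows), keep_filtered, max_active)
}

#' Call INDELs
#'
#' Aggregates left-normalized I/D candidates across reads, scores each with
#' the INDEL model, applies the heuristic filters (minimum p — stricter for
#' 1 bp deletions —, minimum variant depth, minimum total depth, minimum
#' variant read ratio) and genotypes passing calls via t.
#'
#' @inheritParams call_snps
#' @param model INDEL [logistic_model()] (or path to a model JSON).
#' @return data.table of variant calls, as [call_snps()].
#' @export
call_indels <- function(alignments, reference, model, cfg = filter_config(),
                        regions = NULL, keep_filtered = FALSE) {
  if (is.character(model)) model <- load_model(model)
  missing <- setdiff(model$variables, .indel_variables)
  if (length(missing)) {
    stop("INDEL model uses unknown variable(s): ",
         paste(missing, collapse = ", "))
  }
  ridx <- .region_index(regions)
  rows <- .acc_new()
  max_active <- .pileup_walk(alignments, reference, cfg,
    visit_indel = function(cand, var_obs, total_depth) {
      if (!.in_region(ridx, cand$chrom, cand$pos)) return(invisible())
      fv <- indel_feature_vector(var_obs, total_depth)
      p <- lr_score(model, fv)
      min_p <- if (cand$kind == "DEL" && cand$length == 1L) {
        cfg$indel$min_p_1bp_del
      } else {
        cfg$indel$min_p
      }
      filters <- character()
      if (p < min_p) filters <- c(filters, "low_p")
      if (fv$var_depth < cfg$indel$min_var_depth) {
        filters <- c(filters, "min_var_depth")
      }
      if (fv$total_depth < cfg$indel$min_total_depth) {
        filters <- c(filters, "min_total_depth")
      }
      if (fv$var_depth / fv$total_depth < cfg$indel$min_var_ratio) {
        filters <- c(filters, "low_var_ratio")
      }
      t <- fv$var_depth / fv$total_depth
      gt <- NA_character_
      if (!length(filters)) {
        g <- genotype_from_t(min(t, 1), cfg)
        if (g == "none") filters <- c(filters, "low_t") else gt <- g
      }
      .acc_add(rows, data.table::data.table(
        chrom = cand$chrom, pos = cand$pos, ref = cand$ref, alt = cand$alt,
        kind = cand$kind, p = p, t = t, genotype = gt,
        var_depth = fv$var_depth, total_depth = fv$total_depth,
        effective_depth = fv$total_depth,
        filters = paste(filters, collapse = ";")))
    })
  .finish_calls(.acc_list(rows), keep_filtered, max_active)
}
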
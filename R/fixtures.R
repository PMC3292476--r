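# Synthetic alignments and training tables.
#
# The simulator emulates the discriminative structure the calling models
# rely on, as a two-component mixture:
#   * true variants: planted at well-separated loci, balanced across
#     strands, carried at uniform positions within reads, with normal base
#     qualities;
#   * errors: strand-biased, enriched toward the 3' end where quality
#     decays, with depressed base and neighboring-base qualities. A
#     configurable share of errors is systematic ("hotspots": fixed
#     position, fixed allele, preferred strand), which is what makes
#     multi-read false positives possible, as in real mapping artifacts.
# Phred qualities are integers in [2, 40] with a linear decay toward the
# 3' end. The reference is i.i.d. uniform over A/C/G/T from the seed; no
# external genome is ever required.

#' Simulation configuration
#'
#' @param seed RNG seed; identical configs give byte-identical output.
#' @param n_sites number of planted SNP sites.
#' @param n_indel_sites number of planted INDEL sites.
#' @param reference_length contig length in bp.
#' @param read_length read length in bp (>= 11 so NBQ windows fit).
#' @param depth_mean target mean per-position read depth.
#' @param depth_log_sd log-normal sd of the smooth coverage field (500 bp
#'   windows); exome capture depth is strongly heterogeneous, and this is
#'   what gives low-coverage true variants. 0 gives uniform coverage.
#' @param tp_fraction TP fraction used when resampling training tables.
#' @param error_profile list: `substitution_rate` (per bp),
#'   `end_multiplier` (3'-end error enrichment), `strand_bias` (probability
#'   an error falls on its preferred strand), `indel_rate` (per read),
#'   `hotspot_rate` (per covering read, systematic-error probability),
#'   `hotspot_density` (hotspots per bp).
#' @param quality_profile list: `mean_phred`, `end_decay` (total linear drop
#'   from 5' to 3' end).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_sites = 100L, n_indel_sites = 0L,
                       reference_length = 20000L, read_length = 50L,
                       depth_mean = 30, depth_log_sd = 0.5,
                       tp_fraction = 0.1,
                       error_profile = list(substitution_rate = 0.002,
                                            end_multiplier = 4,
                                            strand_bias = 0.8,
                                            indel_rate = 0.005,
                                            hotspot_rate = 0.12,
                                            hotspot_density = 1 / 500),
                       quality_profile = list(mean_phred = 32,
                                              end_decay = 10)) {
  ep <- utils::modifyList(list(substitution_rate = 0.002, end_multiplier = 4,
                               strand_bias = 0.8, indel_rate = 0.005,
                               hotspot_rate = 0.12, hotspot_density = 1 / 500),
                          error_profile)
  qp <- utils::modifyList(list(mean_phred = 32, end_decay = 10),
                          quality_profile)
  if (tp_fraction < 0 || tp_fraction > 1) stop("tp_fraction must lie in [0, 1]")
  rates <- c(ep$substitution_rate, ep$strand_bias, ep$indel_rate,
             ep$hotspot_rate, ep$hotspot_density)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (read_length < 11L) stop("read_length must be >= 11 (NBQ window)")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (depth_log_sd < 0) stop("depth_log_sd must be >= 0")
  if (reference_length < read_length) {
    stop("reference_length must be at least read_length")
  }
  structure(list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                 n_indel_sites = as.integer(n_indel_sites),
                 reference_length = as.integer(reference_length),
                 read_length = as.integer(read_length),
                 depth_mean = depth_mean, depth_log_sd = depth_log_sd,
                 tp_fraction = tp_fraction,
                 error_profile = ep, quality_profile = qp),
            class = "sim_config")
}

.cycle_quals <- function(R, qp) {
  q <- round(qp$mean_phred + qp$end_decay * (0.5 - (0:(R - 1)) / (R - 1)))
  pmin(pmax(as.integer(q), 2L), 40L)
}

.other_base <- function(b) {
  sample(setdiff(.BASES, b), 1L)
}

#' Simulate aligned reads with planted variants and a known truth set
#'
#' Plants `n_sites` SNPs and `n_indel_sites` short INDELs (1-6 bp) at
#' well-separated loci (heterozygous or homozygous with equal probability),
#' samples reads to the target depth, then layers sequencing/mapping errors
#' per the error profile. Reads are returned coordinate-sorted; every truth
#' variant is observable in at least one read.
#'
#' @param config a [sim_config()].
#' @return list of class `read_simulation`: `reads` (data.table),
#'   `reference` (named character), `truth` (data.table chrom/pos/ref/alt/
#'   type/genotype, left-normalized), `config`.
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$reference_length; R <- config$read_length
  ep <- config$error_profile; qp <- config$quality_profile
  reference <- random_reference(L)
  chrom <- names(reference)
  refb <- charToRaw(reference[[1L]])

  # --- plant variants on a jittered grid so no read spans two sites
  need <- config$n_sites + config$n_indel_sites
  events <- NULL
  if (need > 0L) {
    margin <- 2L * R
    grid <- seq.int(margin, L - margin, by = 2L * R)
    if (need > length(grid)) stop("reference too short for requested sites")
    pos <- sort(sample(grid, need)) +
      sample.int(R %/% 2L + 1L, need, replace = TRUE) - 1L
    type <- sample(rep(c("SNP", "INDEL"),
                       c(config$n_sites, config$n_indel_sites)))
    events <- vector("list", need)
    for (i in seq_len(need)) {
      p <- pos[i]
      gt <- sample(c("het", "hom"), 1L)
      if (type[i] == "SNP") {
        rb <- rawToChar(refb[p])
        events[[i]] <- list(pos = p, type = "SNP", kind = "SNP", len = 0L,
                            ref = rb, alt = .other_base(rb), gt = gt)
      } else {
        kind <- sample(c("INS", "DEL"), 1L)
        l <- sample(1:6, 1L)
        if (kind == "DEL") {
          events[[i]] <- list(pos = p, type = "INDEL", kind = "DEL", len = l,
                              ref = rawToChar(refb[p:(p + l)]),
                              alt = rawToChar(refb[p]), gt = gt)
        } else {
          insseq <- paste(sample(.BASES, l, replace = TRUE), collapse = "")
          events[[i]] <- list(pos = p, type = "INDEL", kind = "INS", len = l,
                              ref = rawToChar(refb[p]),
                              alt = paste0(rawToChar(refb[p]), insseq),
                              gt = gt)
        }
      }
    }
  }
  ev_pos <- if (need) vapply(events, `[[`, integer(1), "pos") else integer()

  # --- systematic error hotspots (never near planted sites)
  hotspots <- list()
  if (ep$hotspot_rate > 0 && ep$hotspot_density > 0) {
    n_hot <- max(0L, round(L * ep$hotspot_density))
    cand <- sample.int(L - 2L * R) + R
    if (length(ev_pos)) {
      keep <- vapply(cand, function(p) all(abs(p - ev_pos) > 2L * R), logical(1))
      cand <- cand[keep]
    }
    cand <- utils::head(cand, n_hot)
    for (p in cand) {
      htype <- sample(c("SUB", "SUB", "DEL", "INS"), 1L)
      # ~15% of systematic sites mimic paralogous mis-mapping: high rate,
      # both strands, normal base qualities — the errors that genuinely
      # overlap true-variant feature space
      hard <- stats::runif(1) < 0.15
      hotspots[[length(hotspots) + 1L]] <- list(
        pos = p, type = htype,
        alt = .other_base(rawToChar(refb[p])),
        strand = sample(c("+", "-"), 1L),
        rate = if (hard && htype == "SUB") stats::runif(1, 0.03, 0.07)
               else if (hard) stats::runif(1, 0.25, 0.5)
               else ep$hotspot_rate * stats::runif(1, 0.5, 2),
        bias = if (hard) 0.5 else ep$strand_bias,
        hard = hard)
    }
  }
  hs_pos <- if (length(hotspots)) vapply(hotspots, `[[`, integer(1), "pos") else integer()

  # --- sample reads (smooth log-normal coverage field: capture depth is
  # heterogeneous, which is also what produces low-coverage true variants)
  n_reads <- ceiling(config$depth_mean * L / R)
  n_start <- L - R + 1L
  starts <- if (config$depth_log_sd > 0) {
    w <- rep(exp(stats::rnorm(ceiling(n_start / 500L), 0,
                              config$depth_log_sd)), each = 500L)[1:n_start]
    sort(sample.int(n_start, n_reads, replace = TRUE, prob = w))
  } else {
    sort(sample.int(n_start, n_reads, replace = TRUE))
  }
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  cyc_q <- .cycle_quals(R, qp)

  seqs <- character(n_reads); quals <- character(n_reads)
  cigars <- character(n_reads); poss <- integer(n_reads)

  for (r in seq_len(n_reads)) {
    s <- starts[r]; strand <- strands[r]
    q <- if (strand == "+") cyc_q else rev(cyc_q)
    sq <- refb[s:(s + R - 1L)]
    cigar <- paste0(R, "M")
    pos_out <- s
    plain <- TRUE

    # planted variant overlapping this read?
    ei <- if (need) which(ev_pos >= s - 6L & ev_pos <= s + R - 1L) else integer()
    if (length(ei) == 1L) {
      e <- events[[ei]]
      carrier <- e$gt == "hom" || stats::runif(1) < 0.5
      if (carrier && e$type == "SNP" && e$pos >= s && e$pos <= s + R - 1L) {
        sq[e$pos - s + 1L] <- charToRaw(e$alt)
      } else if (carrier && e$kind == "DEL") {
        a <- e$pos; l <- e$len
        if (s > a) {            # read from the alt haplotype right of the gap
          pos_out <- s + l
          sq <- refb[pos_out:(pos_out + R - 1L)]
        } else {
          left <- a - s + 1L
          if (left < R) {       # junction-spanning read
            m2 <- R - left
            sq <- c(refb[s:a], refb[(a + l + 1L):(a + l + m2)])
            cigar <- paste0(left, "M", l, "D", m2, "M")
            plain <- FALSE
          }                     # else read ends at/before the anchor: plain
        }
      } else if (carrier && e$kind == "INS") {
        a <- e$pos; l <- e$len
        left <- a - s + 1L
        if (left >= 1L && left <= R - l - 1L) {
          insb <- charToRaw(substring(e$alt, 2L))
          right <- R - left - l
          sq <- c(refb[s:a], insb, refb[(a + 1L):(a + right)])
          cigar <- paste0(left, "M", l, "I", right, "M")
          plain <- FALSE
        }                       # else: no room to span the insertion: plain
      }
    }

    # random substitution errors (strand-biased, 3'-enriched, low quality)
    sub_rate <- 2 * ep$substitution_rate *
      (if (strand == "+") ep$strand_bias else 1 - ep$strand_bias)
    if (sub_rate > 0) {
      k <- stats::rbinom(1L, R, min(sub_rate, 1))
      if (k > 0L) {
        w <- 1 + (ep$end_multiplier - 1) * (0:(R - 1)) / (R - 1)
        cyc <- sample.int(R, k, prob = w)
        idx <- if (strand == "+") cyc else R + 1L - cyc
        for (i in idx) {
          sq[i] <- charToRaw(.other_base(rawToChar(sq[i])))
          q[i] <- sample(2:30, 1L)
          if (stats::runif(1) < 0.6) {
            for (j in intersect(c(i - 1L, i + 1L), seq_len(R))) {
              q[j] <- max(2L, q[j] - sample(0:12, 1L))
            }
          }
        }
      }
    }

    # systematic hotspot errors
    if (length(hs_pos) && plain) {
      hi <- which(hs_pos >= pos_out + 1L & hs_pos <= pos_out + R - 2L)
      for (h in hi) {
        hs <- hotspots[[h]]
        p_err <- 2 * hs$rate *
          (if (strand == hs$strand) hs$bias else 1 - hs$bias)
        if (stats::runif(1) >= min(p_err, 1)) next
        off <- hs$pos - pos_out + 1L
        if (hs$type == "SUB") {
          sq[off] <- charToRaw(hs$alt)
          if (!hs$hard) {
            q[off] <- sample(5:32, 1L)
            if (stats::runif(1) < 0.5) {
              for (j in intersect(c(off - 1L, off + 1L), seq_len(R))) {
                q[j] <- max(2L, q[j] - sample(0:10, 1L))
              }
            }
          }
        } else if (hs$type == "DEL" && off >= 2L && off <= R - 2L) {
          sq <- c(sq[1:(off - 1L)], refb[(pos_out + off):(pos_out + R)])
          cigar <- paste0(off - 1L, "M1D", R - off + 1L, "M")
          plain <- FALSE
        } else if (hs$type == "INS" && off >= 2L && off <= R - 2L) {
          sq <- c(sq[1:off], charToRaw(hs$alt), sq[(off + 1L):(R - 1L)])
          cigar <- paste0(off, "M1I", R - off - 1L, "M")
          plain <- FALSE
        }
        if (!hs$hard) {
          q[max(1L, off - 2L):min(R, off + 2L)] <-
            pmax(2L, q[max(1L, off - 2L):min(R, off + 2L)] - sample(0:8, 1L))
        }
        if (hs$hard || hs$type != "SUB") {
          # mis-mapping-style artifact: the read carries extra divergence
          # mismatches at normal quality, away from the event. Gapped
          # mis-alignment is the dominant source of multi-read false
          # indels, so every systematic indel site gets this signature.
          far <- setdiff(seq_len(R), max(1L, off - 6L):min(R, off + 6L))
          for (i in sample(far, 2L)) {
            sq[i] <- charToRaw(.other_base(rawToChar(sq[i])))
          }
        }
        break
      }
    }

    # random read-private indel errors (plain reads only)
    ind_rate <- 2 * ep$indel_rate *
      (if (strand == "+") ep$strand_bias else 1 - ep$strand_bias)
    if (plain && ind_rate > 0 && stats::runif(1) < ind_rate &&
        pos_out + R < L) {
      c0 <- sample(7:(R - 7L), 1L)
      if (stats::runif(1) < 0.5) {  # 1 bp deletion
        sq <- c(sq[1:c0], refb[(pos_out + c0 + 1L):(pos_out + R)])
        cigar <- paste0(c0, "M1D", R - c0, "M")
      } else {                       # 1 bp insertion
        sq <- c(sq[1:c0], charToRaw(sample(.BASES, 1L)), sq[(c0 + 1L):(R - 1L)])
        cigar <- paste0(c0, "M1I", R - c0 - 1L, "M")
      }
      q[max(1L, c0 - 2L):min(R, c0 + 2L)] <-
        pmax(2L, q[max(1L, c0 - 2L):min(R, c0 + 2L)] - sample(2:12, 1L))
    }

    seqs[r] <- rawToChar(sq)
    quals[r] <- intToUtf8(q + 33L)
    cigars[r] <- cigar
    poss[r] <- pos_out
  }

  reads <- data.table::data.table(
    qname = "", flag = ifelse(strands == "+", 0L, 16L), chrom = chrom,
    pos = poss, mapq = 255L, cigar = cigars, strand = strands,
    seq = seqs, qual = quals)
  data.table::setorder(reads, pos)
  reads[, "qname" := sprintf("r%06d", seq_len(nrow(reads)))]

  truth <- if (need) {
    rows <- lapply(events, function(e) {
      nv <- normalize_variant(chrom, e$pos, e$ref, e$alt, reference)
      data.table::data.table(chrom = nv$chrom, pos = nv$pos, ref = nv$ref,
                             alt = nv$alt, type = e$type, kind = e$kind,
                             genotype = e$gt)
    })
    data.table::setorder(data.table::rbindlist(rows), pos)
  } else {
    data.table::data.table(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           type = character(), kind = character(),
                           genotype = character())
  }

  structure(list(reads = reads, reference = reference, truth = truth,
                 config = config),
            class = "read_simulation")
}

#' Write a simulated read set as a SAM + FASTA fixture
#'
#' @param reads coordinate-sorted reads data.table.
#' @param reference named character vector of contigs.
#' @param dir output directory (created if needed).
#' @param prefix basename for the two files.
#' @return list(sam=, fasta=) paths.
#' @export
write_sam_fixture <- function(reads, reference, dir, prefix = "fixture") {
  if (nrow(reads) > 1L) {
    o <- order(reads$chrom, reads$pos)
    if (!identical(o, seq_len(nrow(reads)))) {
      stop("reads must be coordinate-sorted")
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  write_fasta(reference, fasta)
  sam <- file.path(dir, paste0(prefix, ".sam"))
  con <- file(sam, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (nm in names(reference)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(reference[[nm]])), con)
  }
  if (nrow(reads)) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                       reads$qname, reads$flag, reads$chrom, reads$pos,
                       reads$mapq, reads$cigar, reads$seq, reads$qual), con)
  }
  list(sam = sam, fasta = fasta)
}

#' Simulate a labeled training table from a known logistic model
#'
#' Draws feature vectors from `feature_sampler`, labels each row TP with
#' probability `plogis(intercept + beta . x)`, and (optionally) resamples
#' rows to hit a target TP fraction (within 1%). Used for parameter-recovery
#' and cross-validation tests.
#'
#' @param model a [logistic_model()].
#' @param n number of rows (>= 10).
#' @param tp_fraction target TP fraction after resampling, or NULL to keep
#'   the raw Bernoulli labels.
#' @param feature_sampler function(n) returning a data.frame whose columns
#'   cover the model's variables; defaults to i.i.d. standard normals.
#' @param seed RNG seed.
#' @return data.table of features plus a `label` column ("TP"/"FP").
#' @export
simulate_training_table <- function(model, n, tp_fraction = NULL,
                                    feature_sampler = NULL, seed = 1L) {
  stopifnot(inherits(model, "logistic_model"))
  if (n < 10L) stop("n must be at least 10 to stratify labels")
  set.seed(seed)
  if (is.null(feature_sampler)) {
    feature_sampler <- function(m) {
      as.data.frame(setNames(
        lapply(model$variables, function(v) stats::rnorm(m)),
        model$variables))
    }
  }
  x <- data.table::as.data.table(feature_sampler(as.integer(n)))
  missing <- setdiff(model$variables, names(x))
  if (length(missing)) {
    stop("feature_sampler does not provide: ", paste(missing, collapse = ", "))
  }
  eta <- model$intercept +
    as.matrix(x[, model$variables, with = FALSE]) %*% model$coefficients
  lab <- stats::rbinom(nrow(x), 1L, plogis(drop(eta)))
  x[, "label" := ifelse(lab == 1L, "TP", "FP")]
  if (!is.null(tp_fraction)) {
    x <- .resample_tp_fraction(x, tp_fraction)
  }
  x[]
}

# stratified resample to the target TP fraction, preserving total size
.resample_tp_fraction <- function(dt, tp_fraction) {
  n <- nrow(dt)
  tp <- which(dt$label == "TP"); fp <- which(dt$label == "FP")
  n_tp <- round(n * tp_fraction); n_fp <- n - n_tp
  pick <- function(idx, k) {
    if (!length(idx) && k > 0L) stop("cannot resample: class absent")
    if (k == 0L) integer() else sample(idx, k, replace = k > length(idx))
  }
  out <- dt[c(pick(tp, n_tp), pick(fp, n_fp))]
  out[sample.int(nrow(out))]
}

#' Feature-extract and label candidate sites from a simulation
#'
#' Runs candidate discovery on the simulated reads, computes the model
#' covariates at every candidate, labels each row TP when it matches the
#' planted truth set (by chrom, normalized position and alternate allele),
#' and optionally resamples to a target TP fraction. This is the route used
#' to train the bundled default models.
#'
#' @param sim a `read_simulation` from [simulate_reads()].
#' @param type `"snp"` or `"indel"`.
#' @param cfg a [filter_config()].
#' @param min_var_depth keep candidates with at least this many variant
#'   reads (2 mirrors the calling filter).
#' @param tp_fraction resample to this TP share, or NULL to keep all rows.
#' @param label_sensitivity probability that a planted variant is labeled
#'   TP. Real training labels come from an external validation call set of
#'   limited sensitivity, so a small share of true sites lands in the FP
#'   class; 1 gives exact truth labels.
#' @param seed RNG seed for the label-noise and resampling steps.
#' @return data.table: chrom/pos/ref/alt, feature columns, label.
#' @export
build_training_table <- function(sim, type = c("snp", "indel"),
                                 cfg = filter_config(), min_var_depth = 2L,
                                 tp_fraction = NULL, label_sensitivity = 1,
                                 seed = 1L) {
  type <- match.arg(type)
  feats <- if (type == "snp") {
    snp_candidate_features(sim$reads, sim$reference, cfg)
  } else {
    indel_candidate_features(sim$reads, sim$reference, cfg)
  }
  feats <- feats[feats$var_depth >= min_var_depth, ]
  truth_keys <- paste(sim$truth$chrom, sim$truth$pos, sim$truth$alt, sep = "\r")
  keys <- paste(feats$chrom, feats$pos, feats$alt, sep = "\r")
  feats[, "label" := ifelse(keys %in% truth_keys, "TP", "FP")]
  set.seed(seed)
  if (label_sensitivity < 1) {
    tp_idx <- which(feats$label == "TP")
    flip <- tp_idx[stats::runif(length(tp_idx)) > label_sensitivity]
    if (length(flip)) feats[flip, "label" := "FP"]
  }
  if (!is.null(tp_fraction)) {
    feats <- .resample_tp_fraction(feats, tp_fraction)
  }
  feats[]
}

#' Write / read a tab-delimited training table
#'
#' @param table training table from [build_training_table()] or
#'   [simulate_training_table()].
#' @param path file path.
#' @return `path` / the table.
#' @export
write_training_table <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}

#' @rdname write_training_table
#' @export
read_training_table <- function(path) {
  data.table::fread(path, sep = "\t")
}
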
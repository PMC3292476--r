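# Call-set quality metrics and call-set comparison.

.snp_key <- function(d) paste(d$chrom, d$pos, d$alt, sep = "\r")

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; every other ref/alt pair is a
#' transversion. Coding regions are expected around 3-4. With zero
#' transversions the ratio is undefined and `Inf` is returned as the
#' degenerate flag.
#'
#' @param calls data.table with ref and alt single-base columns (non-SNP
#'   rows are ignored).
#' @return ratio, or `Inf` when no transversions exist.
#' @export
ts_tv_ratio <- function(calls) {
  snv <- calls[nchar(calls$ref) == 1L & nchar(calls$alt) == 1L, ]
  if (!nrow(snv)) stop("no SNPs in call set")
  pair <- paste0(pmin(snv$ref, snv$alt), pmax(snv$ref, snv$alt))
  ts <- sum(pair %in% c("AG", "CT"))
  tv <- nrow(snv) - ts
  if (tv == 0L) return(Inf)
  ts / tv
}

#' Known-site rediscovery rate
#'
#' Fraction of calls matching a known-sites list, keyed by (chrom,
#' normalized pos, alt) — the generalization of a dbSNP rediscovery rate to
#' any supplied list. With `by_position = TRUE` the alternate allele is
#' ignored.
#'
#' @param calls calls/records data.table (chrom, pos, alt).
#' @param known_sites data.table of known sites (chrom, pos, alt).
#' @param by_position match on position only.
#' @return proportion in \[0, 1\].
#' @export
known_site_rediscovery <- function(calls, known_sites, by_position = FALSE) {
  if (!nrow(calls)) return(0)
  if (by_position) {
    mean(paste(calls$chrom, calls$pos) %in%
           paste(known_sites$chrom, known_sites$pos))
  } else {
    mean(.snp_key(calls) %in% .snp_key(known_sites))
  }
}

#' SNP density per kbp of callable sequence
#'
#' @param calls calls data.table (or a count).
#' @param callable_bp callable region size in bp (>= 1).
#' @return SNPs per 1000 bp.
#' @export
snp_density <- function(calls, callable_bp) {
  if (callable_bp < 1) stop("callable_bp must be >= 1")
  n <- if (is.data.frame(calls)) nrow(calls) else as.numeric(calls)
  1000 * n / callable_bp
}

#' In-frame (3n) INDEL rate
#'
#' Fraction of INDELs whose length |len(ref) - len(alt)| is a multiple of 3,
#' i.e. that do not cause a frameshift. Roughly half of true coding INDELs
#' are in-frame; error-dominated call sets sit far lower.
#'
#' @param calls INDEL calls/records data.table (ref, alt).
#' @return proportion in \[0, 1\].
#' @export
in_frame_rate <- function(calls) {
  len <- abs(nchar(calls$ref) - nchar(calls$alt))
  len <- len[len > 0L]
  if (!length(len)) stop("no INDELs in call set")
  mean(len %% 3L == 0L)
}

#' Pairwise call-set concordance on a shared region
#'
#' Restricts both call sets to the shared region, then reports the
#' rediscovery rate (fraction of B's calls also in A) and the confirmation
#' rate (fraction of A's calls also in B). By definition
#' `concordance(A, B)$rediscovery == concordance(B, A)$confirmation`.
#'
#' @param set_a,set_b calls/records data.tables (chrom, pos, alt).
#' @param shared_region GRanges or BED path; NULL compares everywhere.
#' @return list(n_shared_region_a, n_shared_region_b, rediscovery_rate,
#'   confirmation_rate).
#' @export
concordance <- function(set_a, set_b, shared_region = NULL) {
  restrict <- function(d) {
    if (is.null(shared_region) || !nrow(d)) return(d)
    idx <- .region_index(shared_region)
    keep <- vapply(seq_len(nrow(d)), function(i) {
      .in_region(idx, d$chrom[i], d$pos[i])
    }, logical(1))
    d[keep, ]
  }
  a <- restrict(set_a); b <- restrict(set_b)
  shared <- length(intersect(.snp_key(a), .snp_key(b)))
  list(n_shared_region_a = nrow(a), n_shared_region_b = nrow(b),
       rediscovery_rate = if (nrow(b)) shared / nrow(b) else NA_real_,
       confirmation_rate = if (nrow(a)) shared / nrow(a) else NA_real_)
}

#' Precision/sensitivity and ROC curves for scored, labeled examples
#'
#' At each cutoff: precision TP/(TP+FP), sensitivity TP/(TP+FN) and false
#' positive rate FP/(FP+TN), calling positive at score >= cutoff.
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels TP/FP (or 1/0) labels; both classes must be present.
#' @param cutoff_grid cutoffs to evaluate.
#' @return data.table: cutoff, precision (NA when nothing is called),
#'   sensitivity, fpr.
#' @export
pr_and_roc <- function(scores, labels, cutoff_grid = seq(0, 1, by = 0.01)) {
  y <- .label_to_binary(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  rows <- lapply(cutoff_grid, function(cut) {
    call <- scores >= cut
    tp <- sum(call & y == 1L); fp <- sum(call & y == 0L)
    data.table::data.table(
      cutoff = cut,
      precision = if (tp + fp) tp / (tp + fp) else NA_real_,
      sensitivity = tp / npos,
      fpr = fp / nneg)
  })
  data.table::rbindlist(rows)
}

#' Area under the ROC curve (trapezoidal, over the cutoff grid)
#'
#' @inheritParams pr_and_roc
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels, cutoff_grid = seq(0, 1, by = 0.001)) {
  cur <- pr_and_roc(scores, labels, cutoff_grid)
  x <- rev(c(1, cur$fpr, 0)); y <- rev(c(1, cur$sensitivity, 0))
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Summary metrics of a SNP + INDEL call set
#'
#' @param snp_calls,indel_calls calls data.tables (possibly empty).
#' @param callable_bp callable region size for the density.
#' @param known_sites optional known-sites table for the rediscovery rate.
#' @return list of class `call_set_metrics`.
#' @export
call_set_metrics <- function(snp_calls, indel_calls = NULL,
                             callable_bp = NULL, known_sites = NULL) {
  out <- list(n_snps = nrow(snp_calls))
  out$ts_tv <- if (nrow(snp_calls)) ts_tv_ratio(snp_calls) else NA_real_
  out$known_rate <- if (!is.null(known_sites)) {
    known_site_rediscovery(snp_calls, known_sites)
  } else NA_real_
  out$density_per_kbp <- if (!is.null(callable_bp)) {
    snp_density(snp_calls, callable_bp)
  } else NA_real_
  out$n_indels <- if (is.null(indel_calls)) 0L else nrow(indel_calls)
  out$in_frame_rate <- if (!is.null(indel_calls) && nrow(indel_calls)) {
    in_frame_rate(indel_calls)
  } else NA_real_
  structure(out, class = "call_set_metrics")
}
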
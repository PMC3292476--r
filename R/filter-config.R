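#' Calling, filtering and genotyping configuration
#'
#' Bundles every tunable cutoff of the calling pipeline. Defaults are the
#' method's standard settings: SNP calls need model probability p >= 0.5 and
#' variant read depth >= 2; INDEL calls need p >= 0.5 (0.88 for single
#' base-pair deletions), >= 2 variant reads, total depth >= 2 and variant
#' read ratio >= 0.05; reads must carry at most 3 variant events and satisfy
#' the mapping-quality rule; positions are callable at effective read depth
#' >= 6; genotypes from the adjusted variant ratio t are heterozygous at
#' t >= 0.1 and homozygous at t >= 0.8.
#'
#' @param snp_min_p minimum model probability for SNP calls.
#' @param snp_min_var_depth minimum variant read depth for SNP calls.
#' @param indel_min_p minimum model probability for INDEL calls.
#' @param indel_min_p_1bp_del stricter minimum probability for 1 bp deletions.
#' @param indel_min_var_depth minimum variant read depth for INDEL calls.
#' @param indel_min_total_depth minimum total depth at the INDEL anchor.
#' @param indel_min_var_ratio minimum variant read ratio for INDEL calls.
#' @param max_variant_events maximum mismatches + gap events per read.
#' @param mapq_mode `"exact255"` (uniquely-mapped convention) or `"min:N"`.
#' @param min_effective_depth minimum effective depth for callable positions.
#' @param het_t,hom_t adjusted-variant-ratio genotype thresholds (inclusive).
#' @return a `filter_config` (nested list).
#' @export
filter_config <- function(snp_min_p = 0.5, snp_min_var_depth = 2L,
                          indel_min_p = 0.5, indel_min_p_1bp_del = 0.88,
                          indel_min_var_depth = 2L, indel_min_total_depth = 2L,
                          indel_min_var_ratio = 0.05,
                          max_variant_events = 3L, mapq_mode = "exact255",
                          min_effective_depth = 6L,
                          het_t = 0.1, hom_t = 0.8) {
  ps <- c(snp_min_p, indel_min_p, indel_min_p_1bp_del)
  if (any(ps < 0 | ps > 1)) stop("probability cutoffs must lie in [0, 1]")
  if (!(het_t < hom_t)) stop("het_t must be below hom_t")
  depths <- c(snp_min_var_depth, indel_min_var_depth, indel_min_total_depth,
              min_effective_depth)
  if (any(depths < 0)) stop("depth thresholds must be non-negative")
  if (!identical(mapq_mode, "exact255") && !grepl("^min:\\d+$", mapq_mode)) {
    stop("mapq_mode must be \"exact255\" or \"min:N\"")
  }
  structure(list(
    snp = list(min_p = snp_min_p, min_var_depth = as.integer(snp_min_var_depth)),
    indel = list(min_p = indel_min_p, min_p_1bp_del = indel_min_p_1bp_del,
                 min_var_depth = as.integer(indel_min_var_depth),
                 min_total_depth = as.integer(indel_min_total_depth),
                 min_var_ratio = indel_min_var_ratio),
    read = list(max_variant_events = as.integer(max_variant_events),
                mapq_mode = mapq_mode),
    callable = list(min_effective_depth = as.integer(min_effective_depth)),
    genotype = list(het_t = het_t, hom_t = hom_t)
  ), class = "filter_config")
}
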
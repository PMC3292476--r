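# SNP model covariates. All features are computed over the reads that
# passed the per-read filters (the stack is built from passing reads only)
# and only over observations carrying the candidate alternate base, except
# ref_var_ratio which also counts reference-carrying observations.

.snp_variables <- c("ref_var_ratio", "mean_var_base_quality", "mean_nbq",
                    "mean_dist3", "strand_both", "nbq_x_dist3",
                    "strand_x_dist3")

#' Mean neighboring base quality (NBQ) of a SNP candidate
#'
#' Mean phred quality of the variant base and up to 5 flanking bases on each
#' side within the read (windows truncate at read boundaries), averaged over
#' all variant reads.
#'
#' @param stack a `site_stack`.
#' @param alt alternate base.
#' @return phred-scale mean.
#' @export
mean_nbq <- function(stack, alt) {
  v <- stack$observations[stack$observations$base == alt, ]
  if (!nrow(v)) stop("no variant observations for alt ", alt)
  mean(v$nbq)
}

#' Strand direction standard
#'
#' 1 when at least one variant read exists in each strand direction, else 0.
#' True variants show evidence on both strands far more often than errors do.
#'
#' @inheritParams mean_nbq
#' @return 0 or 1.
#' @export
strand_direction_standard <- function(stack, alt) {
  v <- stack$observations[stack$observations$base == alt, ]
  if (!nrow(v)) stop("no variant observations for alt ", alt)
  as.integer(all(c("+", "-") %in% v$strand))
}

#' SNP feature vector
#'
#' Computes the seven SNP model covariates from a site stack: the
#' reference/variant reads ratio (0 when no reference reads remain), mean
#' variant base quality, mean NBQ, mean distance to the 3' end, the
#' both-strands indicator, and the two literal interaction products.
#'
#' @inheritParams mean_nbq
#' @return one-row data.table with the feature columns plus var_depth and
#'   ref_depth.
#' @export
snp_feature_vector <- function(stack, alt) {
  obs <- stack$observations
  v <- obs[obs$base == alt, ]
  if (!nrow(v)) stop("no variant observations for alt ", alt)
  ref_depth <- sum(obs$base == stack$ref_base)
  var_depth <- nrow(v)
  ref_var_ratio <- if (ref_depth == 0L) 0 else ref_depth / var_depth
  m_nbq <- mean(v$nbq)
  m_d3 <- mean(v$dist3)
  sb <- as.integer(all(c("+", "-") %in% v$strand))
  data.table::data.table(
    ref_var_ratio = ref_var_ratio,
    mean_var_base_quality = mean(v$qual),
    mean_nbq = m_nbq,
    mean_dist3 = m_d3,
    strand_both = sb,
    nbq_x_dist3 = m_nbq * m_d3,
    strand_x_dist3 = sb * m_d3,
    var_depth = var_depth,
    ref_depth = ref_depth)
}
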
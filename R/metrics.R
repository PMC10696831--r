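# Array-quality metrics in the wateRmelon tradition: each exploits a probe
# class with a known expected structure (imprinted DMRs at beta 0.5,
# trimodal SNP-affected probes, sex-differentiated X probes), so that
# residual technical variation is measurable without ground truth.

#' DMRSE: imprinted-DMR standard error
#'
#' Probes in imprinted differentially methylated regions have an expected
#' beta of 0.5; their dispersion is technical. The statistic is the standard
#' deviation of the pooled DMR beta values divided by the square root of the
#' number of samples. With `per_probe = TRUE` the SD is taken per probe and
#' averaged before scaling.
#'
#' @param betas A [beta_matrix()].
#' @param dmr_ids Probe ids of the imprinted-DMR class (defaults to the
#'   annotation's `special_class == "dmr"`).
#' @param per_probe Aggregate per probe instead of pooling (default FALSE).
#' @return A non-negative scalar; lower is better.
#' @export
dmrse <- function(betas, dmr_ids = NULL, per_probe = FALSE) {
  if (is.null(dmr_ids)) {
    dmr_ids <- betas$annotation$probe_id[betas$annotation$special_class == "dmr"]
  }
  dmr_ids <- intersect(dmr_ids, rownames(betas$values))
  if (!length(dmr_ids)) stop("dmrse: no DMR probes present")
  b <- betas$values[dmr_ids, , drop = FALSE]
  n <- ncol(b)
  if (per_probe) {
    mean(apply(b, 1, stats::sd)) / sqrt(n)
  } else {
    stats::sd(as.vector(b)) / sqrt(n)
  }
}

# one probe's genotype-cluster MSE: 1-D k-means (k = 3) initialised at the
# expected genotype centres; average of the per-cluster mean squared errors
gcose_one <- function(x, centres = c(0.1, 0.5, 0.9)) {
  if (length(unique(x)) < 3) return(NA_real_)
  km <- try(suppressWarnings(
    stats::kmeans(x, centers = matrix(centres, ncol = 1))), silent = TRUE)
  if (inherits(km, "try-error")) return(NA_real_)
  mses <- vapply(seq_len(nrow(km$centers)), function(g) {
    xi <- x[km$cluster == g]
    if (!length(xi)) return(NA_real_)
    mean((xi - km$centers[g, 1])^2)
  }, numeric(1))
  mean(mses, na.rm = TRUE)
}

#' GCOSE: genotype-cluster standard error
#'
#' SNP-affected probes are trimodal (the three genotypes). Per probe, samples
#' are clustered into three groups by 1-D k-means (centres initialised at
#' 0.1/0.5/0.9); the mean squared error about each cluster centre is
#' computed and the three cluster means averaged. The statistic is the mean
#' over SNP probes. Probes with fewer than three distinct values are skipped
#' with a warning.
#'
#' @param betas A [beta_matrix()].
#' @param snp_ids SNP-class probe ids (defaults from the annotation).
#' @param centres Initial cluster centres.
#' @return A non-negative scalar; lower is better.
#' @export
gcose <- function(betas, snp_ids = NULL, centres = c(0.1, 0.5, 0.9)) {
  if (is.null(snp_ids)) {
    snp_ids <- betas$annotation$probe_id[betas$annotation$special_class == "snp"]
  }
  snp_ids <- intersect(snp_ids, rownames(betas$values))
  if (!length(snp_ids)) stop("gcose: no SNP probes present")
  vals <- apply(betas$values[snp_ids, , drop = FALSE], 1, gcose_one,
                centres = centres)
  if (all(is.na(vals))) stop("gcose: no SNP probe could be clustered")
  if (anyNA(vals)) {
    warning("gcose: ", sum(is.na(vals)), " SNP probes skipped")
  }
  mean(vals, na.rm = TRUE)
}

#' Seabird: X-chromosome sex-classification AUC
#'
#' Females carry a hypermethylated inactive X, so mean X-chromosome beta
#' separates the sexes. The per-sample score is the mean beta over the
#' X-linked probes and the statistic is the AUC for classifying female
#' versus male (females positive, ties counted one half). Computed by the
#' rank (Mann-Whitney) formula.
#'
#' @param betas A [beta_matrix()].
#' @param x_ids X-linked probe ids (defaults from the annotation's
#'   `chrX_sex` class).
#' @param sex Factor/character of `"F"`/`"M"` per sample (defaults from the
#'   sample sheet).
#' @return AUC in `[0, 1]`; higher is better (stored as `1 - AUC` in metric
#'   tables so lower is better everywhere).
#' @export
seabird_auc <- function(betas, x_ids = NULL, sex = NULL) {
  if (is.null(x_ids)) {
    x_ids <- betas$annotation$probe_id[
      betas$annotation$special_class == "chrX_sex"]
  }
  x_ids <- intersect(x_ids, rownames(betas$values))
  if (!length(x_ids)) stop("seabird_auc: no X-chromosome probes present")
  if (is.null(sex)) sex <- betas$samples$sex
  if (length(unique(sex)) < 2) {
    stop("seabird_auc: both sexes must be present")
  }
  score <- colMeans(betas$values[x_ids, , drop = FALSE])
  r <- rank(score)
  nf <- sum(sex == "F"); nm <- sum(sex == "M")
  (sum(r[sex == "F"]) - nf * (nf + 1) / 2) / (nf * nm)
}

#' Rank methods across the three quality metrics
#'
#' Builds the method-by-metric table (Seabird stored as `1 - AUC` so lower is
#' better throughout), assigns ascending per-metric ranks with average-tie
#' handling, and orders by mean rank. Missing metric values are ranked last
#' with a warning.
#'
#' @param metrics A data.frame (or named list of rows) with columns `method`,
#'   `dmrse`, `gcose`, `seabird` — `seabird` given as the AUC.
#' @return A `data.frame` of class `metric_table` sorted by `mean_rank`,
#'   with per-metric rank columns.
#' @export
rank_methods <- function(metrics) {
  metrics <- as.data.frame(metrics)
  stopifnot(all(c("method", "dmrse", "gcose", "seabird") %in% names(metrics)))
  if (nrow(metrics) < 2) stop("rank_methods: need >= 2 methods")
  tab <- data.frame(method = metrics$method,
                    dmrse = metrics$dmrse,
                    gcose = metrics$gcose,
                    seabird = 1 - metrics$seabird)
  rank_col <- function(v) {
    if (anyNA(v)) {
      warning("rank_methods: missing metric values ranked last")
      v[is.na(v)] <- Inf
    }
    rank(v, ties.method = "average")
  }
  tab$rank_dmrse <- rank_col(tab$dmrse)
  tab$rank_gcose <- rank_col(tab$gcose)
  tab$rank_seabird <- rank_col(tab$seabird)
  tab$mean_rank <- rowMeans(tab[, c("rank_dmrse", "rank_gcose",
                                    "rank_seabird")])
  tab <- tab[order(tab$mean_rank, tab$method), ]
  rownames(tab) <- NULL
  class(tab) <- c("metric_table", "data.frame")
  tab
}
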
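#' Quantile normalisation across samples
#'
#' Replaces each value by the mean of all features with the same rank across
#' columns, forcing every column's empirical distribution to the mean
#' order-statistic distribution. With a feature grouping, the transform is
#' applied within each group independently. Ties take average ranks and are
#' mapped to the mean of the tied target values, so within-column ordering is
#' preserved.
#'
#' @param x Numeric `features x samples` matrix.
#' @param feature_groups Optional factor/vector of length `nrow(x)`
#'   partitioning the features (e.g. probe design type).
#' @return A matrix of the same shape and dimnames.
#' @export
quantile_normalise <- function(x, feature_groups = NULL) {
  x <- as.matrix(x)
  if (ncol(x) < 1) stop("quantile_normalise: need >= 1 column")
  if (is.null(feature_groups)) {
    return(qn_one_group(x))
  }
  if (length(feature_groups) != nrow(x)) {
    stop("quantile_normalise: feature_groups length must equal nrow(x)")
  }
  out <- x
  for (g in unique(feature_groups)) {
    idx <- which(feature_groups == g)
    if (length(idx) < 2) {
      stop("quantile_normalise: group '", g, "' has fewer than 2 features")
    }
    out[idx, ] <- qn_one_group(x[idx, , drop = FALSE])
  }
  out
}

qn_one_group <- function(x) {
  if (ncol(x) == 1) return(x)
  n <- nrow(x)
  ref <- rowMeans(apply(x, 2, sort.int, method = "quick"))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    v <- ref
    v[o] <- ref  # ref assigned in ascending order of the column
    # ties -> mean of the tied target values
    col <- x[, j]
    if (anyDuplicated(col)) {
      v <- stats::ave(v, match(col, col), FUN = mean)
    }
    out[, j] <- v
  }
  out
}
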
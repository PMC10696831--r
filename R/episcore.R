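# Elastic-net EpiScore: a sparse weighted linear predictor over CpG
# methylation values, trained against a covariate-residualised phenotype and
# projectable onto any normalised dataset that shares (most of) the probes.

#' Residualise a phenotype against covariates
#'
#' Fits ordinary least squares of `log(BMI)` on age, sex and the ancestry
#' covariates, and returns the residuals as the EpiScore training target.
#' The fitted covariate model is kept for later de-scaling of scores back to
#' the kg/m^2 scale.
#'
#' @param samples A [sample_sheet()] with complete `bmi`, `age`, `sex` and
#'   `pc*` columns.
#' @return A list of class `residualised_phenotype`: `residuals` (named by
#'   sample id), the fitted `model`, and the `samples` used.
#' @export
residualise_phenotype <- function(samples) {
  if (any(is.na(samples$bmi)) || any(samples$bmi <= 0)) {
    stop("residualise_phenotype: BMI must be present and positive")
  }
  pcs <- pc_columns(samples)
  fml <- stats::as.formula(paste(
    "log(bmi) ~ age + sex",
    if (length(pcs)) paste("+", paste(pcs, collapse = " + ")) else ""))
  fit <- stats::lm(fml, data = samples)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("residualise_phenotype: rank-deficient design; collinear: ",
         paste(bad, collapse = ", "))
  }
  structure(list(residuals = stats::setNames(stats::resid(fit),
                                             samples$sample_id),
                 model = fit, samples = samples),
            class = "residualised_phenotype")
}

#' Select the most variable probes
#'
#' @param mvalues An [mvalue_matrix()] (or plain matrix).
#' @param k Number of probes to keep, ranked by sample standard deviation;
#'   ties broken by probe id so the selection is deterministic.
#' @return Character vector of `k` probe ids.
#' @export
top_sd_features <- function(mvalues, k) {
  x <- if (inherits(mvalues, "mvalue_matrix")) mvalues$values else
    as.matrix(mvalues)
  if (k <= 0) stop("top_sd_features: k must be positive")
  if (k > nrow(x)) stop("top_sd_features: k exceeds the number of probes")
  sds <- apply(x, 1, stats::sd)
  ord <- order(-sds, rownames(x))
  rownames(x)[ord[seq_len(k)]]
}

#' Fit an elastic-net EpiScore
#'
#' Elastic-net penalised regression (default `alpha = 0.5`) of the
#' residualised phenotype on probe M-values, with the penalty chosen to
#' minimise mean squared error in seeded k-fold cross-validation. Probes are
#' optionally pruned to the `top_k_sd` most variable beforehand.
#'
#' @param mvalues An [mvalue_matrix()] for the training samples.
#' @param target Numeric target vector named by sample id (e.g. the
#'   `residuals` of [residualise_phenotype()]), or a `residualised_phenotype`.
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (default 0.5).
#' @param n_folds Cross-validation folds (default 10).
#' @param top_k_sd Optional variance-pruning cut before fitting.
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `episcore`: intercept, sparse named weight
#'   vector, training means of the model probes (for missing-probe
#'   imputation), the declared training scale (`"mvalue"`), and fit
#'   metadata.
#' @export
fit_episcore <- function(mvalues, target, alpha = 0.5, n_folds = 10,
                         top_k_sd = NULL, seed = 1L) {
  if (inherits(target, "residualised_phenotype")) target <- target$residuals
  stopifnot(inherits(mvalues, "mvalue_matrix"))
  x <- mvalues$values
  if (is.null(names(target))) names(target) <- colnames(x)
  target <- target[colnames(x)]
  if (anyNA(target)) stop("fit_episcore: target and matrix samples misaligned")
  if (!is.null(top_k_sd)) {
    keep <- top_sd_features(mvalues, min(top_k_sd, nrow(x)))
    x <- x[keep, , drop = FALSE]
  }
  if (ncol(x) < n_folds) stop("fit_episcore: fewer samples than folds")
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), ncol(x)))
  cv <- glmnet::cv.glmnet(t(x), target, alpha = alpha, foldid = foldid,
                          family = "gaussian", standardize = TRUE)
  co <- stats::coef(cv, s = "lambda.min")
  w <- as.numeric(co)[-1]
  names(w) <- rownames(co)[-1]
  w <- w[w != 0]
  structure(list(
    intercept = as.numeric(co)[1],
    weights = w,
    training_means = rowMeans(x)[names(w)],
    scale = "mvalue",
    alpha = alpha, lambda = cv$lambda.min, n_folds = n_folds,
    feature_space = nrow(x), n_train = ncol(x), seed = seed,
    cv_error = min(cv$cvm)
  ), class = "episcore")
}

#' @export
#' @method print episcore
print.episcore <- function(x, ...) {
  cat("EpiScore model (elastic net, alpha =", x$alpha, ")\n")
  cat("  ", length(x$weights), "non-zero CpG weights of",
      x$feature_space, "features\n")
  cat("  lambda =", signif(x$lambda, 4), "; trained on", x$n_train,
      "samples; scale:", x$scale, "\n")
  invisible(x)
}

#' @export
coef.episcore <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' @export
#' @method summary episcore
summary.episcore <- function(object, ...) {
  cat("EpiScore model summary\n")
  print(object)
  w <- object$weights
  cat("  weight range: [", signif(min(w), 3), ",", signif(max(w), 3), "]\n")
  cat("  CV mean squared error at lambda.min:", signif(object$cv_error, 4),
      "\n")
  invisible(object)
}

#' Project an EpiScore onto a dataset
#'
#' `score = intercept + sum(weight_j * value_j)` over the model's probes.
#' Model probes absent from the data are imputed at their training mean and
#' counted; more than `max_missing` of them is an error.
#'
#' @param model An `episcore` (or a coefficient list from
#'   [read_coefficients()]).
#' @param data A [beta_matrix()], [mvalue_matrix()] or plain
#'   `probe x sample` matrix on the model's declared value scale.
#' @param max_missing Maximum tolerated fraction of missing model probes
#'   (default 0.2).
#' @return Named numeric vector of per-sample scores.
#' @export
project_episcore <- function(model, data, max_missing = 0.2) {
  vals <- if (inherits(data, c("beta_matrix", "mvalue_matrix"))) {
    if (inherits(data, "beta_matrix") &&
        identical(model$scale, "mvalue")) {
      warning("project_episcore: model trained on M-values but given beta ",
              "values; converting with the logit2 transform")
      beta_to_mvalue(data)$values
    } else data$values
  } else as.matrix(data)
  probes <- names(model$weights)
  if (length(probes) == 0) {
    return(stats::setNames(rep(model$intercept, ncol(vals)), colnames(vals)))
  }
  present <- probes %in% rownames(vals)
  miss_frac <- mean(!present)
  if (miss_frac > max_missing) {
    stop(sprintf("project_episcore: %.1f%% of model probes missing (limit %.1f%%)",
                 100 * miss_frac, 100 * max_missing))
  }
  if (any(!present)) {
    message(sprintf("project_episcore: %d model probes (%.1f%%) imputed at training mean",
                    sum(!present), 100 * miss_frac))
  }
  score <- rep(model$intercept, ncol(vals))
  if (any(present)) {
    score <- score + drop(crossprod(vals[probes[present], , drop = FALSE],
                                    model$weights[present]))
  }
  if (any(!present)) {
    tm <- model$training_means[probes[!present]]
    tm[is.na(tm)] <- 0
    score <- score + sum(model$weights[!present] * tm)
  }
  stats::setNames(score, colnames(vals))
}

#' @export
predict.episcore <- function(object, newdata, ...) {
  project_episcore(object, newdata, ...)
}

#' De-scale EpiScores back to kg/m^2
#'
#' Inverts the residualisation: `BMI = exp(score + covariate prediction)`,
#' using the covariate model stored by [residualise_phenotype()]. For score
#' *differences* the delta method gives `delta_kg_m2 ~ BMI * delta_score`.
#'
#' @param scores Named numeric vector of EpiScores (residual log-BMI scale).
#' @param resid_model A `residualised_phenotype` object.
#' @param samples Sample sheet rows for the scored samples (defaults to the
#'   rows stored in `resid_model` matched by name).
#' @return Numeric vector of approximate BMI values (kg/m^2).
#' @export
descale_scores <- function(scores, resid_model, samples = NULL) {
  stopifnot(inherits(resid_model, "residualised_phenotype"))
  if (is.null(samples)) {
    samples <- resid_model$samples[
      match(names(scores), resid_model$samples$sample_id), , drop = FALSE]
  }
  if (any(is.na(samples$age)) || any(is.na(samples$sex))) {
    stop("descale_scores: covariates missing for some samples")
  }
  covpred <- stats::predict(resid_model$model, newdata = samples)
  exp(scores + covpred)
}
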
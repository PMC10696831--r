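# Separate-versus-joint normalisation robustness: the same target cohort is
# normalised once on its own and once jointly with a reference cohort, the
# EpiScore is projected onto both, and per-individual score differences are
# summarised. Sample-wise (within-array) methods are invariant by
# construction; between-array methods shift with cohort composition.

#' Compare separate and joint normalisation of a target cohort
#'
#' Arm 1 normalises the target cohort alone; arm 2 normalises the target
#' jointly with the reference cohort and then subsets the target's samples.
#' Both arms are restricted up front to the harmonised probe intersection so
#' that score differences reflect normalisation alone, and the EpiScore is
#' projected onto each arm.
#'
#' @param target,reference [intensity_data()] cohorts sharing a probe space.
#' @param method Registry name or [method_spec()].
#' @param model An `episcore` model.
#' @param scale Value scale for projection: `"mvalue"` (default) or `"beta"`.
#' @return A `data.frame` of class `paired_scores` with per-sample separate
#'   and joint scores, phenotype, and within-arm percentiles
#'   (`100 * (rank - 0.5) / n`, average ranks on ties).
#' @export
separate_vs_joint <- function(target, reference, method, model,
                              scale = c("mvalue", "beta")) {
  scale <- match.arg(scale)
  combined <- harmonise_cohorts(list(target, reference))
  common <- combined$annotation$probe_id
  target <- subset_intensity(target, probes = common)

  project_arm <- function(betas) {
    vals <- if (scale == "mvalue") beta_to_mvalue(betas) else betas
    project_episcore(model, vals)
  }
  b_sep <- normalise_method(target, method)
  b_joint_all <- normalise_method(combined, method)
  joint_idx <- match(target$samples$sample_id,
                     b_joint_all$samples$sample_id)
  b_joint <- beta_matrix(b_joint_all$values[, joint_idx, drop = FALSE],
                         b_joint_all$annotation, target$samples)
  s_sep <- project_arm(b_sep)
  s_joint <- project_arm(b_joint)
  if (!identical(names(s_sep), names(s_joint))) {
    stop("separate_vs_joint: arms scored different sample sets")
  }
  pct <- function(v) 100 * (rank(v, ties.method = "average") - 0.5) / length(v)
  out <- data.frame(
    sample_id = names(s_sep),
    cohort = target$samples$cohort,
    score_separate = unname(s_sep),
    score_joint = unname(s_joint),
    phenotype = log(target$samples$bmi),
    percentile_separate = pct(s_sep),
    percentile_joint = pct(s_joint),
    stringsAsFactors = FALSE
  )
  class(out) <- c("paired_scores", "data.frame")
  out
}

#' Median absolute difference between paired scores
#'
#' The robustness statistic: the median over individuals of the absolute
#' difference between separately- and jointly-normalised EpiScores.
#'
#' @param paired A `paired_scores` data.frame.
#' @return Non-negative scalar.
#' @export
median_abs_diff <- function(paired) {
  if (nrow(paired) < 1) stop("median_abs_diff: empty input")
  stats::median(abs(paired$score_separate - paired$score_joint))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param scores,phenotype Numeric vectors of equal length (n >= 4, both
#'   with positive variance).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(r, lower, upper)`; the interval uses the
#'   Fisher z-transform with standard error `1/sqrt(n - 3)`.
#' @export
pearson_with_ci <- function(scores, phenotype, conf = 0.95) {
  n <- length(scores)
  if (n < 4) stop("pearson_with_ci: need n >= 4")
  if (stats::sd(scores) == 0 || stats::sd(phenotype) == 0) {
    stop("pearson_with_ci: zero variance input")
  }
  r <- stats::cor(scores, phenotype)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  c(r = r, lower = tanh(z - q * se), upper = tanh(z + q * se))
}

#' Incremental R-squared of an EpiScore
#'
#' The gain in variance explained when the EpiScore is added to a
#' covariate-only linear model of log BMI on age and sex, as a percentage.
#'
#' @param samples A [sample_sheet()] with `bmi`, `age`, `sex`.
#' @param scores Named numeric EpiScores for the same samples.
#' @return Scalar percentage (non-negative up to numerical tolerance, by
#'   model nesting).
#' @export
incremental_r2 <- function(samples, scores) {
  scores <- scores[samples$sample_id]
  if (anyNA(scores)) stop("incremental_r2: scores missing for some samples")
  df <- data.frame(y = log(samples$bmi), age = samples$age,
                   sex = samples$sex, score = unname(scores))
  if (anyNA(df)) stop("incremental_r2: incomplete covariates")
  r2_null <- summary(stats::lm(y ~ age + sex, data = df))$r.squared
  r2_full <- summary(stats::lm(y ~ age + sex + score, data = df))$r.squared
  100 * (r2_full - r2_null)
}

#' Percentile-shift summary between arms
#'
#' Quantifies whether individuals keep their place in the cohort
#' distribution across the two normalisation arms: per-sample absolute
#' percentile change, with the maximum, the median, and the Spearman rank
#' correlation between arms.
#'
#' @param paired A `paired_scores` data.frame (>= 2 samples).
#' @return Named numeric vector `c(max_shift, median_shift, spearman)`.
#' @export
percentile_shift <- function(paired) {
  if (nrow(paired) < 2) stop("percentile_shift: need >= 2 samples")
  d <- abs(paired$percentile_separate - paired$percentile_joint)
  c(max_shift = max(d), median_shift = stats::median(d),
    spearman = stats::cor(paired$score_separate, paired$score_joint,
                          method = "spearman"))
}

#' Run the full multi-method robustness benchmark
#'
#' For each method: the target cohort is normalised separately and jointly
#' with the reference, the EpiScore projected onto both arms, and the MAD,
#' phenotype correlations (both arms, with confidence intervals),
#' incremental R-squared and percentile shifts recorded; the three quality
#' metrics are computed on the jointly-normalised combined data and
#' rank-aggregated. The loop is fail-soft: a method that errors is recorded
#' and skipped.
#'
#' @param target,reference [intensity_data()] cohorts.
#' @param model An `episcore` model.
#' @param methods Character vector of registry names (default: all 16).
#' @param scale Projection value scale.
#' @return A list of class `norm_benchmark`: `results` (per-method
#'   data.frame), `metric_table` (ranked), `paired` (list of paired scores),
#'   and `failures`.
#' @export
full_benchmark <- function(target, reference, model,
                           methods = names(registry_16_methods()),
                           scale = "mvalue") {
  rows <- list(); paired_all <- list(); failures <- list()
  met_rows <- list()
  for (nm in methods) {
    res <- tryCatch({
      paired <- separate_vs_joint(target, reference, nm, model, scale = scale)
      combined <- harmonise_cohorts(list(target, reference))
      b_joint <- normalise_method(combined, nm)
      ct_sep <- pearson_with_ci(paired$score_separate, paired$phenotype)
      ct_joint <- pearson_with_ci(paired$score_joint, paired$phenotype)
      ps <- percentile_shift(paired)
      tgt_sheet <- target$samples
      list(row = data.frame(
        method = nm,
        mad = median_abs_diff(paired),
        max_abs_diff = max(abs(paired$score_separate - paired$score_joint)),
        r_separate = ct_sep["r"], r_sep_lo = ct_sep["lower"],
        r_sep_hi = ct_sep["upper"],
        r_joint = ct_joint["r"], r_joint_lo = ct_joint["lower"],
        r_joint_hi = ct_joint["upper"],
        incremental_r2 = incremental_r2(tgt_sheet,
                                        stats::setNames(paired$score_separate,
                                                        paired$sample_id)),
        max_pct_shift = ps["max_shift"], median_pct_shift = ps["median_shift"],
        spearman_arms = ps["spearman"],
        stringsAsFactors = FALSE),
        met = data.frame(method = nm,
                         dmrse = dmrse(b_joint),
                         gcose = gcose(b_joint),
                         seabird = seabird_auc(b_joint)),
        paired = paired)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[nm]] <- conditionMessage(res)
      warning("full_benchmark: method '", nm, "' failed: ",
              conditionMessage(res))
    } else {
      rows[[nm]] <- res$row
      met_rows[[nm]] <- res$met
      paired_all[[nm]] <- res$paired
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  mt <- if (length(met_rows) >= 2) rank_methods(do.call(rbind, met_rows))
    else NULL
  structure(list(results = results, metric_table = mt, paired = paired_all,
                 failures = failures),
            class = "norm_benchmark")
}

#' @export
#' @method print norm_benchmark
print.norm_benchmark <- function(x, digits = 4, ...) {
  cat("Normalisation robustness benchmark:", nrow(x$results), "methods",
      if (length(x$failures)) paste0("(", length(x$failures), " failed)"),
      "\n\n")
  show <- x$results[order(x$results$mad),
                    c("method", "mad", "r_separate", "r_joint",
                      "incremental_r2", "median_pct_shift")]
  print(format(show, digits = digits), row.names = FALSE)
  if (!is.null(x$metric_table)) {
    cat("\nQuality-metric mean ranks (lower is better):\n")
    print(format(x$metric_table[, c("method", "dmrse", "gcose", "seabird",
                                    "mean_rank")], digits = digits),
          row.names = FALSE)
  }
  invisible(x)
}
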
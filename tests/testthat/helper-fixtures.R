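# Small programmatic fixtures shared across test files.

tiny_annotation <- function(n_I = 4, n_II = 4) {
  n <- n_I + n_II
  probe_annotation(
    probe_id = sprintf("p%02d", seq_len(n)),
    design_type = rep(c("I", "II"), c(n_I, n_II)),
    channel = c(rep(c("Grn", "Red"), length.out = n_I), rep("both", n_II)),
    chromosome = "1",
    special_class = "plain",
    cpg_count = rep_len(1:2, n)
  )
}

tiny_samples <- function(n = 3, cohort = "A") {
  sample_sheet(sprintf("%s_s%d", cohort, seq_len(n)), cohort = cohort,
               age = 79, sex = rep_len(c("F", "M"), n), bmi = 25)
}

tiny_intensity <- function(n_I = 4, n_II = 4, n_samples = 3, seed = 1) {
  set.seed(seed)
  ann <- tiny_annotation(n_I, n_II)
  sm <- tiny_samples(n_samples)
  n <- nrow(ann)
  intensity_data(
    meth = matrix(stats::runif(n * n_samples, 100, 5000), n, n_samples),
    unmeth = matrix(stats::runif(n * n_samples, 100, 5000), n, n_samples),
    annotation = ann, samples = sm,
    oob_meth = matrix(stats::runif(n * n_samples, 50, 300), n, n_samples),
    oob_unmeth = matrix(stats::runif(n * n_samples, 50, 300), n, n_samples),
    beadcount = matrix(10L, n, n_samples),
    detection_p = matrix(1e-6, n, n_samples)
  )
}

# small but structurally complete two-cohort simulation
small_sim <- function(seed = 11, n_samples = 30, n_plain = 600, n_dmr = 50,
                      n_snp = 50, n_x = 60, ...) {
  simulate_cohorts(sim_config(n_plain = n_plain, n_dmr = n_dmr,
                              n_snp = n_snp, n_x = n_x,
                              n_samples = n_samples, seed = seed, ...),
                   n_causal = 20)
}

# a two-cohort configuration whose only batch difference is dye bias
dye_only_config <- function(seed, n_samples = 50) {
  sim_config(n_plain = 900, n_dmr = 60, n_snp = 60, n_x = 80,
             n_samples = n_samples, seed = seed,
             background = list(target = c(I = 500, II = 250),
                               reference = c(I = 500, II = 250)),
             dye = list(target = c(Grn = 1, Red = 1),
                        reference = c(Grn = 1.3, Red = 0.8)))
}

# EpiScore built from simulation ground truth (weights = causal effects)
truth_episcore <- function(truth) {
  structure(list(intercept = 0, weights = truth$causal_effects,
                 training_means = stats::setNames(
                   rep(0, length(truth$causal_effects)),
                   names(truth$causal_effects)),
                 scale = "mvalue", alpha = NA, lambda = NA, n_folds = NA,
                 feature_space = length(truth$causal_effects),
                 n_train = NA, seed = NA, cv_error = NA),
            class = "episcore")
}

expect_beta_range <- function(b) {
  testthat::expect_true(all(b$values >= 0 & b$values <= 1))
}
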
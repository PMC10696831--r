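# Two-cohort synthetic array generator. The technical model is deliberately
# simple — additive per-batch background, multiplicative per-channel dye bias,
# Gaussian read noise — so that the distinctions between normalisation
# strategies (background adjustment, between-array QN, dye-bias correction)
# are consequential and recoverable.

#' Simulation configuration
#'
#' Collects every knob of the synthetic two-cohort array generator. Defaults
#' describe two age-matched cohorts of older adults processed in different
#' batches: identical biology, batch-specific Type I/II background offsets and
#' per-channel dye bias.
#'
#' @param n_plain,n_dmr,n_snp,n_x Probe counts per special class: ordinary
#'   CpGs, imprinted-DMR probes (expected beta 0.5), SNP-affected trimodal
#'   probes, and sex-differentiated X-chromosome probes.
#' @param type2_fraction Fraction of probes on the Type II design.
#' @param n_samples Samples per cohort.
#' @param cohorts Character vector of two cohort labels.
#' @param background Named list per cohort: numeric `c(I = ..., II = ...)`
#'   additive background offsets (intensity units).
#' @param dye Named list per cohort: numeric `c(Grn = ..., Red = ...)`
#'   multiplicative channel gains.
#' @param intensity_mean,intensity_sdlog Log-normal total-intensity scale
#'   (mean intensity units and sdlog dispersion).
#' @param noise_sd Additive Gaussian read noise SD (intensity units).
#' @param bio_sd Between-individual biological SD on the beta scale at plain
#'   probes.
#' @param dmr_probe_sd Probe-level SD of DMR probe means about 0.5.
#' @param dmr_sample_sd Within-probe sample-level SD at DMR probes.
#' @param snp_maf Minor-allele frequency of the SNP-like probes, in (0, 0.5].
#' @param snp_sd Beta SD about each genotype centre.
#' @param x_male_mean Male mean beta at X probes.
#' @param x_sex_margin Female minus male mean beta at X probes.
#' @param x_sd Beta SD at X probes.
#' @param sex_ratio Proportion of females.
#' @param age_mean,age_sd Age distribution (years).
#' @param n_pcs Number of ancestry covariates (genetic principal components).
#' @param detp_fail_rate Per-cell probability of a detection failure.
#' @param beadcount_lambda,beadcount_shift Bead counts are
#'   `shift + Poisson(lambda)`.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   seed (base R Mersenne-Twister).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_plain = 4650, n_dmr = 100, n_snp = 100, n_x = 150,
                       type2_fraction = 0.5, n_samples = 200,
                       cohorts = c("target", "reference"),
                       background = list(target = c(I = 600, II = 250),
                                         reference = c(I = 900, II = 400)),
                       dye = list(target = c(Grn = 1.00, Red = 1.00),
                                  reference = c(Grn = 1.25, Red = 0.85)),
                       intensity_mean = 5000, intensity_sdlog = 0.15,
                       noise_sd = 50, bio_sd = 0.08,
                       dmr_probe_sd = 0.02, dmr_sample_sd = 0.02,
                       snp_maf = 0.3, snp_sd = 0.02,
                       x_male_mean = 0.2, x_sex_margin = 0.3, x_sd = 0.04,
                       sex_ratio = 0.5, age_mean = 79, age_sd = 0.6,
                       n_pcs = 10, detp_fail_rate = 0.001,
                       beadcount_lambda = 12, beadcount_shift = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_plain > 0, n_dmr > 0, n_snp > 0, n_x > 0,
            type2_fraction >= 0, type2_fraction <= 1,
            n_samples > 1, length(cohorts) == 2,
            snp_maf > 0, snp_maf <= 0.5,
            all(unlist(dye) > 0), intensity_mean > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a probe manifest
#'
#' @param config A [sim_config()].
#' @return A [probe_annotation()] with the configured class counts; design
#'   type is assigned by `type2_fraction`, Type I channels alternate Grn/Red,
#'   and `cpg_count` is drawn from \{1, 2, 3\} with probabilities
#'   (0.5, 0.3, 0.2).
#' @export
simulate_manifest <- function(config) {
  set.seed(config$seed)
  n <- config$n_plain + config$n_dmr + config$n_snp + config$n_x
  cls <- rep(c("plain", "dmr", "snp", "chrX_sex"),
             c(config$n_plain, config$n_dmr, config$n_snp, config$n_x))
  probe_id <- sprintf("cg%07d", seq_len(n))
  is_type2 <- stats::runif(n) < config$type2_fraction
  design <- ifelse(is_type2, "II", "I")
  channel <- ifelse(is_type2, "both",
                    ifelse(stats::runif(n) < 0.5, "Grn", "Red"))
  chrom <- ifelse(cls == "chrX_sex", "X",
                  as.character(1 + (seq_len(n) %% 22)))
  cpg_count <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  probe_annotation(probe_id, design, channel, chrom, cls, cpg_count)
}

#' Simulate a two-cohort sample sheet
#'
#' @param config A [sim_config()].
#' @return A [sample_sheet()] for `2 * n_samples` individuals with cohort and
#'   batch labels, ages, sexes and ancestry covariates (BMI is filled in by
#'   [simulate_phenotype()]).
#' @export
simulate_samples <- function(config) {
  set.seed(config$seed + 1L)
  n <- 2L * config$n_samples
  cohort <- rep(config$cohorts, each = config$n_samples)
  sample_sheet(
    sample_id = sprintf("%s_s%03d", cohort,
                        rep(seq_len(config$n_samples), 2)),
    cohort = cohort,
    batch = cohort,
    age = stats::rnorm(n, config$age_mean, config$age_sd),
    sex = ifelse(stats::runif(n) < config$sex_ratio, "F", "M"),
    bmi = NA_real_,
    pcs = matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs)
  )
}

#' Simulate ground-truth beta values
#'
#' Plain probes get a per-probe bimodal (hypo/hyper) mean shared across
#' samples plus between-individual variation; DMR probes are centred at 0.5;
#' SNP probes are trimodal with genotypes drawn under Hardy-Weinberg
#' equilibrium at `snp_maf` and beta centred at \{0.05, 0.5, 0.95\};
#' X-chromosome probes have the female mean shifted above the male mean by
#' `x_sex_margin`.
#'
#' @param manifest A [probe_annotation()].
#' @param samples A [sample_sheet()].
#' @param config A [sim_config()].
#' @return A list of class `truth_record`: `true_beta` matrix, `genotype`
#'   matrix for SNP probes, and placeholders for phenotype truth filled by
#'   [simulate_phenotype()].
#' @export
simulate_true_betas <- function(manifest, samples, config) {
  set.seed(config$seed + 2L)
  n_probes <- nrow(manifest)
  n_samp <- nrow(samples)
  beta <- matrix(NA_real_, n_probes, n_samp,
                 dimnames = list(manifest$probe_id, samples$sample_id))
  cls <- manifest$special_class

  ip <- which(cls == "plain")
  hyper <- stats::runif(length(ip)) < 0.5
  mu <- ifelse(hyper, stats::rbeta(length(ip), 8, 2),
               stats::rbeta(length(ip), 2, 8))
  beta[ip, ] <- mu + stats::rnorm(length(ip) * n_samp, 0, config$bio_sd)

  id <- which(cls == "dmr")
  mu_d <- 0.5 + stats::rnorm(length(id), 0, config$dmr_probe_sd)
  beta[id, ] <- mu_d + stats::rnorm(length(id) * n_samp, 0, config$dmr_sample_sd)

  is <- which(cls == "snp")
  p <- config$snp_maf
  geno <- matrix(sample(0:2, length(is) * n_samp, replace = TRUE,
                        prob = c((1 - p)^2, 2 * p * (1 - p), p^2)),
                 length(is), n_samp,
                 dimnames = list(manifest$probe_id[is], samples$sample_id))
  centre <- c(`0` = 0.05, `1` = 0.5, `2` = 0.95)
  beta[is, ] <- centre[as.character(geno)] +
    stats::rnorm(length(is) * n_samp, 0, config$snp_sd)

  ix <- which(cls == "chrX_sex")
  female <- samples$sex == "F"
  mu_x <- config$x_male_mean +
    outer(rep(1, length(ix)), ifelse(female, config$x_sex_margin, 0))
  beta[ix, ] <- mu_x + stats::rnorm(length(ix) * n_samp, 0, config$x_sd)

  beta <- pmin(pmax(beta, 0.001), 0.999)
  structure(list(true_beta = beta, genotype = geno,
                 causal_cpg_ids = character(), causal_effects = numeric(),
                 true_signal = NULL),
            class = "truth_record")
}

#' Render intensities from true betas through the technical model
#'
#' Per probe and sample a total intensity `T` is drawn log-normally; the raw
#' channel signals are `T * beta` (methylated) and `T * (1 - beta)`
#' (unmethylated). Each signal then receives the batch's additive background
#' (Type I or Type II offset), the per-cohort multiplicative dye gain of its
#' colour channel, and Gaussian read noise, floored at zero. Type II
#' methylated signal is read in the green channel and unmethylated in red;
#' Type I probes carry both signals in their declared channel. Out-of-band
#' intensities of Type I probes are drawn from the background distribution of
#' the opposite channel alone.
#'
#' @param truth A `truth_record` from [simulate_true_betas()].
#' @param manifest A [probe_annotation()].
#' @param samples A [sample_sheet()]; the `cohort` column selects batch
#'   parameters.
#' @param config A [sim_config()].
#' @return An [intensity_data()] with out-of-band, bead-count and
#'   detection-p matrices.
#' @export
render_intensities <- function(truth, manifest, samples, config) {
  set.seed(config$seed + 3L)
  beta <- truth$true_beta[, samples$sample_id, drop = FALSE]
  n_probes <- nrow(beta); n_samp <- ncol(beta)
  type1 <- manifest$design_type == "I"

  bg_type <- ifelse(type1, "I", "II")
  bg <- matrix(NA_real_, n_probes, n_samp)
  gain_m <- matrix(NA_real_, n_probes, n_samp)  # channel gain on M signal
  gain_u <- matrix(NA_real_, n_probes, n_samp)
  for (co in unique(samples$cohort)) {
    sc <- samples$cohort == co
    bgc <- config$background[[co]]
    dye <- config$dye[[co]]
    bg[, sc] <- bgc[bg_type]
    # Type II: M read in Grn, U in Red; Type I: both signals in own channel
    ch_m <- ifelse(type1, manifest$channel, "Grn")
    ch_u <- ifelse(type1, manifest$channel, "Red")
    gain_m[, sc] <- dye[ch_m]
    gain_u[, sc] <- dye[ch_u]
  }

  T_tot <- matrix(stats::rlnorm(n_probes * n_samp,
                                log(config$intensity_mean) -
                                  config$intensity_sdlog^2 / 2,
                                config$intensity_sdlog), n_probes, n_samp)
  noise <- function() matrix(stats::rnorm(n_probes * n_samp, 0,
                                          config$noise_sd), n_probes, n_samp)
  meth <- pmax(gain_m * (T_tot * beta + bg) + noise(), 0)
  unmeth <- pmax(gain_u * (T_tot * (1 - beta) + bg) + noise(), 0)

  # oob: Type I probes read in the opposite channel see background only
  gain_opp <- matrix(NA_real_, n_probes, n_samp)
  for (co in unique(samples$cohort)) {
    sc <- samples$cohort == co
    opp <- ifelse(manifest$channel == "Grn", "Red", "Grn")
    opp[!type1] <- "Grn"  # unused for Type II
    gain_opp[, sc] <- config$dye[[co]][opp]
  }
  oob_meth <- pmax(gain_opp * bg + noise(), 0)
  oob_unmeth <- pmax(gain_opp * bg + noise(), 0)
  oob_meth[!type1, ] <- NA_real_
  oob_unmeth[!type1, ] <- NA_real_

  beadcount <- matrix(config$beadcount_shift +
                        stats::rpois(n_probes * n_samp,
                                     config$beadcount_lambda),
                      n_probes, n_samp)
  fail <- matrix(stats::runif(n_probes * n_samp) < config$detp_fail_rate,
                 n_probes, n_samp)
  detp <- matrix(stats::runif(n_probes * n_samp, 0, 1e-4), n_probes, n_samp)
  detp[fail] <- stats::runif(sum(fail), 0.05, 1)

  intensity_data(meth, unmeth, manifest, samples,
                 oob_meth = oob_meth, oob_unmeth = oob_unmeth,
                 beadcount = beadcount, detection_p = detp)
}

#' Simulate a sparse-CpG phenotype (log BMI)
#'
#' `log(BMI)` is a linear combination of age, sex, ancestry covariates and
#' the true M-values of `n_causal` randomly chosen plain CpGs (weights drawn
#' `Normal(0, effect_sd^2)`), plus Gaussian noise.
#'
#' @param truth A `truth_record`.
#' @param manifest A [probe_annotation()].
#' @param samples A [sample_sheet()].
#' @param n_causal Number of causal plain CpGs (default 50).
#' @param effect_sd SD of the causal weights on the M-value scale.
#' @param noise_sd Residual SD of log BMI.
#' @param intercept Baseline log BMI at covariate zero (default `log(26)`,
#'   centring BMI near 26 kg/m^2).
#' @param b_age,b_sex,b_pc Covariate effects on log BMI (per year, for
#'   female vs male, and per ancestry covariate unit).
#' @param seed Integer seed.
#' @return A list with the updated `samples` (BMI filled in) and `truth`
#'   (causal ids, effects, and the per-sample methylation signal).
#' @export
simulate_phenotype <- function(truth, manifest, samples, n_causal = 50,
                               effect_sd = 0.05, noise_sd = 0.1,
                               intercept = log(26) - 0.002 * 79,
                               b_age = 0.002, b_sex = 0.02, b_pc = 0.01,
                               seed = 1L) {
  set.seed(seed + 4L)
  plain <- manifest$probe_id[manifest$special_class == "plain"]
  if (n_causal > length(plain)) {
    stop("simulate_phenotype: n_causal exceeds the number of plain probes")
  }
  # causal sites are drawn from the intermediate dynamic range: CpGs near
  # fully (un)methylated have no room for inter-individual variation, so
  # trait-associated variable CpGs sit away from the extremes
  pm <- rowMeans(truth$true_beta[plain, , drop = FALSE])
  eligible <- plain[pm > 0.2 & pm < 0.8]
  if (length(eligible) < n_causal) eligible <- plain
  causal <- sort(sample(eligible, n_causal))
  w <- stats::rnorm(n_causal, 0, effect_sd)
  bc <- pmin(pmax(truth$true_beta[causal, , drop = FALSE], 1e-6), 1 - 1e-6)
  mval <- log2(bc / (1 - bc))
  signal <- drop(crossprod(mval, w))
  pcs <- as.matrix(samples[, pc_columns(samples), drop = FALSE])
  covpart <- b_age * samples$age + b_sex * (samples$sex == "F") +
    if (ncol(pcs)) drop(pcs %*% rep(b_pc, ncol(pcs))) else 0
  logbmi <- intercept + covpart + signal +
    stats::rnorm(nrow(samples), 0, noise_sd)
  samples$bmi <- exp(logbmi)
  truth$causal_cpg_ids <- causal
  truth$causal_effects <- stats::setNames(w, causal)
  truth$true_signal <- stats::setNames(signal, samples$sample_id)
  list(samples = samples, truth = truth)
}

#' Simulate a complete two-cohort experiment
#'
#' Convenience wrapper running manifest, sample-sheet, truth, phenotype and
#' intensity generation, and splitting the result into per-cohort
#' [intensity_data()] objects rendered with their batch-specific background
#' and dye parameters.
#'
#' @param config A [sim_config()].
#' @param n_causal,effect_sd,pheno_noise_sd Forwarded to
#'   [simulate_phenotype()].
#' @return A list: `target` and `reference` intensity data (first and second
#'   configured cohort), `combined` sample sheet, `manifest`, and `truth`.
#' @export
simulate_cohorts <- function(config = sim_config(), n_causal = 50,
                             effect_sd = 0.05, pheno_noise_sd = 0.1) {
  manifest <- simulate_manifest(config)
  samples <- simulate_samples(config)
  truth <- simulate_true_betas(manifest, samples, config)
  ph <- simulate_phenotype(truth, manifest, samples, n_causal = n_causal,
                           effect_sd = effect_sd, noise_sd = pheno_noise_sd,
                           seed = config$seed)
  samples <- ph$samples; truth <- ph$truth
  data_all <- render_intensities(truth, manifest, samples, config)
  tgt <- subset_intensity(data_all,
                          samples = samples$cohort == config$cohorts[1])
  ref <- subset_intensity(data_all,
                          samples = samples$cohort == config$cohorts[2])
  list(target = tgt, reference = ref, samples = samples,
       manifest = manifest, truth = truth)
}
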
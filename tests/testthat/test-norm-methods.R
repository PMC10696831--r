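test_that("the registry pins 16 uniquely named, dispatchable methods", {
  reg <- registry_16_methods()
  expect_length(reg, 16)
  expect_false(anyDuplicated(names(reg)) > 0)
  expect_setequal(names(reg),
                  c("raw", "swan", "noob", "bmiq", "pbc", "tost", "funnorm",
                    "nasen", "dasen", "naten", "daten1", "daten2", "nanet",
                    "danet", "nanes", "danes"))
  d <- tiny_intensity(12, 12, 4)
  for (nm in names(reg)) {
    b <- suppressWarnings(suppressMessages(normalise_method(d, nm)))
    expect_s3_class(b, "beta_matrix")
    expect_true(all(b$values >= 0 & b$values <= 1), label = nm)
  }
  expect_error(normalise_method(d, "nosuch"), "registry")
})

test_that("background equalisation removes a uniform Type I offset", {
  d <- tiny_intensity(10, 10, 3)
  t1 <- d$annotation$design_type == "I"
  d$meth[t1, ] <- d$meth[!t1, ] + 50
  d$unmeth[t1, ] <- d$unmeth[!t1, ] + 50
  out <- background_equalise(d)
  for (j in 1:3) {
    q1 <- quantile(out$meth[t1, j], 0.05)
    q2 <- quantile(out$meth[!t1, j], 0.05)
    expect_equal(unname(q1), unname(q2), tolerance = 1e-9)
  }
  expect_true(all(out$meth >= 0) && all(out$unmeth >= 0))
  # already-equal backgrounds: near no-op
  d2 <- tiny_intensity(10, 10, 3)
  d2$meth[t1, ] <- d2$meth[!t1, ]
  d2$unmeth[t1, ] <- d2$unmeth[!t1, ]
  out2 <- background_equalise(d2)
  expect_equal(out2$meth, d2$meth, tolerance = 1e-9)
})

test_that("dye-bias correction equalises a pure multiplicative channel bias", {
  set.seed(13)
  n <- 500
  ann <- probe_annotation(sprintf("p%03d", 1:n),
                          rep(c("I", "II"), each = n / 2),
                          c(rep(c("Grn", "Red"), n / 4), rep("both", n / 2)),
                          "1")
  sm <- tiny_samples(2)
  base_m <- matrix(stats::rlnorm(n * 2, log(3000), 0.4), n, 2)
  base_u <- matrix(stats::rlnorm(n * 2, log(3000), 0.4), n, 2)
  grn_gain <- 1.5
  ch_m <- ifelse(ann$design_type == "II", "Grn", ann$channel)
  ch_u <- ifelse(ann$design_type == "II", "Red", ann$channel)
  d <- intensity_data(base_m * ifelse(ch_m == "Grn", grn_gain, 1),
                      base_u * ifelse(ch_u == "Grn", grn_gain, 1), ann, sm)
  out <- dye_bias_correct(d, "t")
  for (j in 1:2) {
    g <- c(out$meth[ch_m == "Grn", j], out$unmeth[ch_u == "Grn", j])
    r <- c(out$meth[ch_m == "Red", j], out$unmeth[ch_u == "Red", j])
    expect_lt(abs(mean(g) / mean(r) - 1), 0.02)
  }
  # no injected bias: distributions essentially unchanged
  d0 <- intensity_data(base_m, base_u, ann, sm)
  out0 <- dye_bias_correct(d0, "t")
  expect_lt(abs(mean(out0$meth) / mean(d0$meth) - 1), 0.02)

  # s vs t differ when the channel composition differs between types
  outs <- dye_bias_correct(d, "s")
  expect_gt(max(abs(outs$meth - out$meth)), 0)
})

test_that("combinatorial composition matches its building blocks", {
  d <- tiny_intensity(8, 8, 4)
  # all-'n' spec is raw beta
  nnn <- method_spec("nnn", "combinatorial_qn", "n", "n", "n")
  expect_equal(apply_combinatorial_method(d, nnn)$values,
               beta_from_intensities(d)$values)
  # nanet = dye-bias-correct(together) then beta
  reg <- registry_16_methods()
  expect_equal(normalise_method(d, "nanet")$values,
               beta_from_intensities(dye_bias_correct(d, "t"))$values)
  # dasen = background, then per-type QN, then beta
  manual <- background_equalise(d)
  manual$meth <- quantile_normalise(manual$meth, manual$annotation$design_type)
  manual$unmeth <- quantile_normalise(manual$unmeth,
                                      manual$annotation$design_type)
  expect_equal(normalise_method(d, "dasen")$values,
               beta_from_intensities(manual)$values)
  # daten1 vs daten2 differ (separate vs pooled M/U QN)
  expect_gt(max(abs(normalise_method(d, "daten1")$values -
                    normalise_method(d, "daten2")$values)), 0)
})

test_that("between-array 't' methods leave identical sorted intensity vectors", {
  sim <- small_sim(seed = 31, n_samples = 10)
  d <- sim$target
  spec <- method_spec("x", "combinatorial_qn", "n", "t", "n")
  dd <- d
  dd$meth <- quantile_normalise(dd$meth)
  sorted <- apply(dd$meth, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-10)
})

test_that("SWAN output is sample-wise and aligns subset quantiles", {
  sim <- small_sim(seed = 17, n_samples = 12)
  d <- sim$target
  b_all <- swan_normalise(d)
  one <- subset_intensity(d, samples = d$samples$sample_id[5])
  b_one <- swan_normalise(one)
  expect_equal(max(abs(b_all$values[, 5] - b_one$values[, 1])), 0)

  # equal subset distributions: output equals input within interpolation
  d2 <- tiny_intensity(20, 20, 2)
  t1 <- d2$annotation$design_type == "I"
  d2$meth[!t1, ] <- d2$meth[t1, ]
  d2$unmeth[!t1, ] <- d2$unmeth[t1, ]
  d2$annotation$cpg_count <- 1L
  b2 <- swan_normalise(d2)
  expect_equal(b2$values, beta_from_intensities(d2)$values, tolerance = 1e-6)
})

test_that("BMIQ pulls compressed Type II states onto Type I states", {
  set.seed(23)
  n1 <- 1500; n2 <- 1500
  ann <- probe_annotation(sprintf("p%04d", 1:(n1 + n2)),
                          rep(c("I", "II"), c(n1, n2)),
                          c(rep(c("Grn", "Red"), n1 / 2), rep("both", n2)),
                          "1")
  sm <- tiny_samples(1)
  comp <- function(n) c(stats::rbeta(n * 0.4, 3, 30), stats::rbeta(n * 0.2, 20, 20),
                        stats::rbeta(n * 0.4, 30, 3))
  b1 <- comp(n1)
  # Type II compressed toward 0.5
  b2 <- 0.5 + 0.6 * (comp(n2) - 0.5)
  b <- beta_matrix(matrix(c(b1, b2), ncol = 1), ann, sm)
  out <- bmiq_normalise(b)
  t1 <- ann$design_type == "I"
  # Type I untouched
  expect_equal(out$values[t1, 1], b$values[t1, 1])
  # state medians of corrected Type II near Type I state medians
  lowI <- median(b1[b1 < 0.25]); hiI <- median(b1[b1 > 0.75])
  v2 <- out$values[!t1, 1]
  lowII <- median(v2[v2 < 0.25]); hiII <- median(v2[v2 > 0.75])
  expect_lt(abs(lowII - lowI), 0.02)
  expect_lt(abs(hiII - hiI), 0.02)
  # identical type distributions: near-identity
  b0 <- beta_matrix(matrix(c(b1, b1[seq_len(n2)]), ncol = 1), ann, sm)
  out0 <- bmiq_normalise(b0)
  expect_lt(max(abs(out0$values - b0$values)), 0.05)
})

test_that("PBC recovers a linear M-value compression of Type II probes", {
  set.seed(29)
  n <- 1000
  ann <- probe_annotation(sprintf("p%04d", 1:(2 * n)),
                          rep(c("I", "II"), each = n),
                          c(rep(c("Grn", "Red"), n / 2), rep("both", n)),
                          "1")
  sm <- tiny_samples(1)
  m1 <- c(stats::rnorm(n / 2, -3, 0.5), stats::rnorm(n / 2, 3, 0.5))
  m2 <- 0.8 * c(stats::rnorm(n / 2, -3, 0.5), stats::rnorm(n / 2, 3, 0.5))
  tob <- function(m) 2^m / (1 + 2^m)
  b <- beta_matrix(matrix(tob(c(m1, m2)), ncol = 1), ann, sm)
  out <- pbc_normalise(b)
  t2 <- ann$design_type == "II"
  mv_out <- log2(out$values[t2, 1] / (1 - out$values[t2, 1]))
  fac <- mv_out / m2
  expect_lt(abs(median(fac) - 1 / 0.8), 0.05 * (1 / 0.8))
  # peaks already equal: identity within tolerance
  b0 <- beta_matrix(matrix(tob(c(m1, m1)), ncol = 1), ann, sm)
  out0 <- pbc_normalise(b0)
  expect_lt(max(abs(out0$values - b0$values)), 0.05)
})

test_that("Noob output is strictly positive and near-raw when background is tiny", {
  cfg <- sim_config(n_plain = 300, n_dmr = 30, n_snp = 30, n_x = 40,
                    n_samples = 6, seed = 19, noise_sd = 5,
                    background = list(target = c(I = 1, II = 1),
                                      reference = c(I = 1, II = 1)),
                    dye = list(target = c(Grn = 1, Red = 1),
                               reference = c(Grn = 1, Red = 1)))
  sim <- simulate_cohorts(cfg)
  out <- noob_normalise(sim$target)
  expect_true(all(out$meth > 0) && all(out$unmeth > 0))
  keep <- sim$target$meth > 200
  expect_lt(median(abs(out$meth[keep] - sim$target$meth[keep]) /
                     sim$target$meth[keep]), 0.05)
  # capability error without oob matrices
  d <- sim$target; d$oob_meth <- NULL; d$oob_unmeth <- NULL
  expect_error(noob_normalise(d), "out-of-band")
})

test_that("funnorm reduces dye-driven cohort separation and respects n_pcs=0", {
  sim <- small_sim(seed = 37, n_samples = 25)
  comb <- harmonise_cohorts(list(sim$target, sim$reference))
  raw_b <- beta_from_intensities(comb)
  fn_b <- funnorm_normalise(comb, n_pcs = 2)
  sep <- function(b) {
    pc <- prcomp(t(b$values[1:500, ]))$x[, 1]
    co <- comb$samples$cohort
    abs(mean(pc[co == "target"]) - mean(pc[co == "reference"])) / sd(pc)
  }
  expect_lt(sep(fn_b), sep(raw_b))
  # n_pcs = 0 is identity up to quantile interpolation
  id_b <- funnorm_normalise(comb, n_pcs = 0)
  expect_lt(max(abs(id_b$values - raw_b$values)), 0.02)
  expect_error(funnorm_normalise(subset_intensity(comb, samples = 1:2),
                                 n_pcs = 2), "more samples")
})

test_that("Tost maps Type II intensities onto the Type I anchor distribution", {
  sim <- small_sim(seed = 41, n_samples = 8)
  d <- sim$target
  b <- tost_normalise(d)
  expect_beta_range(b)
  # KS distance between type distributions decreases
  raw_b <- beta_from_intensities(d)
  t1 <- d$annotation$design_type == "I"
  ks <- function(bm, j) suppressWarnings(
    stats::ks.test(bm$values[t1, j], bm$values[!t1, j])$statistic)
  expect_lt(mean(sapply(1:4, function(j) ks(b, j))),
            mean(sapply(1:4, function(j) ks(raw_b, j))))
})

test_that("sample-order permutation only permutes method output", {
  sim <- small_sim(seed = 43, n_samples = 8)
  d <- sim$target
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  dp <- subset_intensity(d, samples = perm)
  for (nm in c("raw", "nasen", "nanet", "daten2", "swan", "funnorm")) {
    b <- suppressWarnings(normalise_method(d, nm))
    bp <- suppressWarnings(normalise_method(dp, nm))
    expect_equal(bp$values, b$values[, perm], tolerance = 1e-12,
                 label = nm)
  }
})
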
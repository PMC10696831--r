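test_that("residualisation matches closed-form OLS and is orthogonal", {
  sm <- sample_sheet(c("a", "b", "c", "d"), "A",
                     age = c(70, 75, 80, 85), sex = c("F", "M", "F", "M"),
                     bmi = c(22, 28, 25, 31))
  rp <- residualise_phenotype(sm)
  X <- cbind(1, sm$age, sm$sex == "M")
  y <- log(sm$bmi)
  manual <- y - X %*% solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(rp$residuals), drop(manual), tolerance = 1e-10)
  expect_lt(abs(sum(rp$residuals * sm$age)), 1e-8)
  expect_lt(abs(sum(rp$residuals)), 1e-8)

  sm_bad <- sm; sm_bad$bmi <- c(22, NA, 25, 31)
  expect_error(residualise_phenotype(sm_bad), "BMI")
})

test_that("top-SD pruning ranks by variability with deterministic ties", {
  x <- rbind(c(1, 1, 1, 1),          # constant
             c(0, 10, 0, 10),
             c(0, 5, 0, 5),
             c(0, 1, 0, 1),
             c(0, 2, 0, 2))
  rownames(x) <- paste0("p", 1:5)
  ann <- probe_annotation(paste0("p", 1:5), "II", "both", "1")
  sm <- tiny_samples(4)
  mv <- mvalue_matrix(x, ann, sm)
  expect_equal(top_sd_features(mv, 3), c("p2", "p3", "p5"))
  expect_setequal(top_sd_features(mv, 5), paste0("p", 1:5))
  expect_false("p1" %in% top_sd_features(mv, 4))
  expect_error(top_sd_features(mv, 0), "positive")
  expect_error(top_sd_features(mv, 6), "exceeds")
})

test_that("elastic net recovers a single dominant predictor", {
  set.seed(61)
  n <- 80; p <- 40
  x <- matrix(stats::rnorm(n * p), p, n,
              dimnames = list(sprintf("cg%03d", 1:p), sprintf("s%03d", 1:n)))
  ann <- probe_annotation(rownames(x), "II", "both", "1")
  sm <- sample_sheet(colnames(x), "A", age = 79,
                     sex = rep_len(c("F", "M"), n), bmi = 25)
  mv <- mvalue_matrix(x, ann, sm)
  y <- 3 * x["cg007", ]
  fit <- fit_episcore(mv, y, alpha = 0.5, n_folds = 5, seed = 2)
  expect_true("cg007" %in% names(fit$weights))
  expect_equal(unname(fit$weights["cg007"]), 3, tolerance = 0.1)
  expect_lt(max(abs(fit$weights[names(fit$weights) != "cg007"]), 0), 0.1)

  # ridge at vanishing penalty approaches OLS on a small full-rank problem
  xs <- x[1:5, ]
  mv5 <- mvalue_matrix(xs, ann[1:5, ], sm)
  y5 <- drop(crossprod(xs, c(1, -2, 0.5, 0, 1))) + stats::rnorm(n, 0, 0.01)
  g <- glmnet::glmnet(t(xs), y5, alpha = 0, lambda = 1e-5)
  ols <- stats::lm(y5 ~ t(xs))
  expect_equal(unname(drop(stats::coef(g))[-1]),
               unname(stats::coef(ols))[-1], tolerance = 1e-2)

  # permuted target: essentially no held-out signal
  yp <- stats::setNames(sample(unname(y)), names(y))
  fitp <- fit_episcore(mv, yp, alpha = 0.5, n_folds = 5, seed = 2)
  expect_lt(fit$cv_error, var(y))          # real fit beats null variance
  expect_gt(fitp$cv_error, 0.8 * var(yp))  # permuted fit does not
})

test_that("projection is a dot product with mean imputation and linearity", {
  model <- structure(list(intercept = 0.5,
                          weights = c(cg1 = 2, cg2 = -1),
                          training_means = c(cg1 = 0.1, cg2 = 0.2),
                          scale = "mvalue"),
                     class = "episcore")
  x <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3,
              dimnames = list(c("cg1", "cg2"), c("s1", "s2", "s3")))
  sc <- project_episcore(model, x)
  expect_equal(unname(sc), c(0.5 + 2 * 1 - 2, 0.5 + 2 * 3 - 4, 0.5 + 10 - 6))

  # all-zero weights: intercept everywhere
  m0 <- model; m0$weights[] <- 0
  expect_equal(unname(project_episcore(m0, x)), rep(0.5, 3))

  # an extra probe with no weight changes nothing
  x2 <- rbind(x, cg9 = c(7, 8, 9))
  expect_equal(project_episcore(model, x2), sc)

  # missing model probe imputed at training mean, with message
  x3 <- x["cg1", , drop = FALSE]
  expect_message(sc3 <- project_episcore(model, x3, max_missing = 0.5),
                 "imputed")
  expect_equal(unname(sc3), 0.5 + 2 * c(1, 3, 5) - 1 * 0.2)
  expect_error(project_episcore(model, x3, max_missing = 0.2), "missing")

  # linearity on the value scale
  a <- matrix(stats::rnorm(6), 2, 3, dimnames = dimnames(x))
  b <- matrix(stats::rnorm(6), 2, 3, dimnames = dimnames(x))
  m_nointercept <- model; m_nointercept$intercept <- 0
  expect_equal(project_episcore(m_nointercept, 2 * a + 3 * b),
               2 * project_episcore(m_nointercept, a) +
                 3 * project_episcore(m_nointercept, b),
               tolerance = 1e-12)
})

test_that("coefficient files round-trip to identical projections", {
  set.seed(63)
  model <- structure(list(intercept = 0.123456789012345,
                          weights = stats::setNames(stats::rnorm(5) / 3,
                                                    sprintf("cg%02d", 1:5)),
                          training_means = stats::setNames(stats::rnorm(5),
                                                           sprintf("cg%02d", 1:5)),
                          scale = "mvalue"),
                     class = "episcore")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coefficients(model, path)
  back <- read_coefficients(path)
  x <- matrix(stats::rnorm(5 * 4), 5, 4,
              dimnames = list(sprintf("cg%02d", 1:5), sprintf("s%d", 1:4)))
  expect_equal(project_episcore(back, x), project_episcore(model, x),
               tolerance = 1e-12)
})

test_that("descaling inverts the residualisation on training samples", {
  set.seed(65)
  n <- 50
  sm <- sample_sheet(sprintf("s%03d", 1:n), "A",
                     age = stats::rnorm(n, 79, 1),
                     sex = sample(c("F", "M"), n, TRUE),
                     bmi = exp(stats::rnorm(n, log(26), 0.15)),
                     pcs = matrix(stats::rnorm(n * 3), n, 3))
  rp <- residualise_phenotype(sm)
  back <- descale_scores(rp$residuals, rp)
  expect_equal(unname(back), sm$bmi, tolerance = 1e-10)

  # delta method: a 4e-4 score shift at BMI 25 is ~0.01 kg/m^2
  expect_equal(25 * 4e-4, 0.01, tolerance = 1e-12)
  s2 <- rp$residuals + 4e-4
  expect_equal(median(descale_scores(s2, rp) - back),
               median(back) * 4e-4, tolerance = 0.05)

  # monotone in the score at fixed covariates
  s_hi <- rp$residuals + 0.1
  expect_true(all(descale_scores(s_hi, rp) > back))
})
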
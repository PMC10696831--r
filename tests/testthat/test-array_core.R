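test_that("beta and M-value conversions match direct arithmetic", {
  ann <- probe_annotation("p1", "II", "both", "1")
  sm <- sample_sheet(c("s1", "s2", "s3"), "A")
  d <- intensity_data(matrix(c(100, 0, 300), 1, 3),
                      matrix(c(0, 0, 100), 1, 3), ann, sm)
  b <- beta_from_intensities(d, offset = 100)
  expect_equal(unname(b$values[1, ]), c(0.5, 0, 300 / 500))

  d2 <- intensity_data(matrix(c(100, 0, 300), 1, 3),
                       matrix(c(100, 0, 75), 1, 3), ann, sm)
  m <- mvalue_from_intensities(d2, eps = 1)
  expect_equal(unname(m$values[1, ]), c(0, 0, log2(301 / 76)))
  expect_true(all(is.finite(m$values)))

  expect_error(beta_from_intensities(d, offset = -1), "offset")
  expect_error(mvalue_from_intensities(d, eps = 0), "eps")
})

test_that("conversions are monotone in M for fixed U", {
  ann <- probe_annotation("p1", "II", "both", "1")
  ms <- seq(0, 4000, by = 250)
  sm <- sample_sheet(sprintf("s%d", seq_along(ms)), "A")
  d <- intensity_data(matrix(ms, 1), matrix(500, 1, length(ms)), ann, sm)
  expect_true(all(diff(beta_from_intensities(d)$values[1, ]) > 0))
  expect_true(all(diff(mvalue_from_intensities(d)$values[1, ]) > 0))
})

test_that("probe detection filter applies the strict 'more than' rule", {
  detp <- matrix(0.001, 3, 100,
                 dimnames = list(c("A", "B", "C"), sprintf("s%d", 1:100)))
  detp["A", 1:2] <- 0.6
  detp["B", 1] <- 0.6
  expect_setequal(filter_probes_by_detection(detp), c("B", "C"))

  # exactly 1% failing is kept (removal needs strictly more than 1%)
  d1 <- matrix(0.001, 1, 100, dimnames = list("A", sprintf("s%d", 1:100)))
  d1[1, 1] <- 0.6
  expect_equal(filter_probes_by_detection(d1), "A")

  all_ok <- matrix(0.001, 5, 10,
                   dimnames = list(letters[1:5], sprintf("s%d", 1:10)))
  expect_equal(filter_probes_by_detection(all_ok), letters[1:5])
  expect_error(filter_probes_by_detection(matrix(numeric(0), 0, 0)), "empty")
})

test_that("sample detection filter mirrors the probe rule on the other axis", {
  detp <- matrix(0.001, 1000, 3,
                 dimnames = list(sprintf("p%d", 1:1000), c("s1", "s2", "s3")))
  detp[1:11, "s1"] <- 0.9                     # 1.1% failing -> removed
  detp[1:10, "s2"] <- 0.9                     # exactly 1% -> kept
  expect_setequal(filter_samples_by_detection(detp), c("s2", "s3"))
  detp[] <- 0.001
  expect_setequal(filter_samples_by_detection(detp), c("s1", "s2", "s3"))
})

test_that("bead-count filter respects its boundary and skips when absent", {
  bc <- matrix(10L, 3, 20,
               dimnames = list(c("A", "B", "C"), sprintf("s%d", 1:20)))
  bc["A", 1:3] <- 2L    # 15% of samples below 3 -> removed
  bc["B", 1] <- 2L      # exactly 5% -> kept
  expect_setequal(filter_probes_by_beadcount(bc), c("B", "C"))
  expect_warning(out <- filter_probes_by_beadcount(NULL), "skipped")
  expect_null(out)
})

test_that("exclusion list drops present ids and ignores unknown ones", {
  ann <- tiny_annotation(5, 5)
  expect_length(drop_probe_exclusion_list(ann, ann$probe_id[c(1, 3, 5)]), 7)
  expect_equal(drop_probe_exclusion_list(ann, character()), ann$probe_id)
  expect_warning(
    keep <- drop_probe_exclusion_list(ann, c("nope1", "nope2")), "unknown")
  expect_equal(keep, ann$probe_id)
})

test_that("qc_pipeline counts reconcile and the pipeline is idempotent", {
  d <- tiny_intensity(10, 10, n_samples = 20)
  d$detection_p[1, ] <- 0.9                 # probe fails everywhere
  d$beadcount[2, ] <- 1L                    # probe low-bead everywhere
  res <- qc_pipeline(d, exclusion_ids = d$annotation$probe_id[3])
  r <- res$report
  expect_equal(r$probes_removed_exclusion_list, 1)
  expect_equal(r$probes_removed_detection, 1)
  expect_equal(r$probes_removed_beadcount, 1)
  expect_equal(r$probes_remaining, nrow(res$data$annotation))
  expect_equal(r$samples_remaining, nrow(res$data$samples))
  expect_equal(20 - r$probes_remaining,
               r$probes_removed_exclusion_list + r$probes_removed_detection +
                 r$probes_removed_beadcount)
  # second pass removes nothing
  res2 <- qc_pipeline(res$data)
  expect_equal(res2$report$probes_remaining, r$probes_remaining)
  expect_equal(res2$report$samples_remaining, r$samples_remaining)
  expect_equal(res2$data$meth, res$data$meth)
})

test_that("harmonise_cohorts intersects probes and is associative", {
  d <- tiny_intensity(6, 6, n_samples = 4)
  a <- subset_intensity(d, probes = d$annotation$probe_id[1:9])
  b0 <- subset_intensity(d, probes = d$annotation$probe_id[4:12])
  b <- b0; b$samples$sample_id <- paste0("B", b$samples$sample_id)
  b$samples$cohort <- "B"
  b <- intensity_data(b$meth, b$unmeth, b$annotation, b$samples)
  comb <- harmonise_cohorts(list(a, b))
  expect_setequal(comb$annotation$probe_id, d$annotation$probe_id[4:9])
  expect_equal(nrow(comb$samples), 8)
  expect_equal(comb$samples$cohort, rep(c("A", "B"), each = 4))

  c0 <- subset_intensity(d, probes = d$annotation$probe_id[6:12])
  c1 <- c0; c1$samples$sample_id <- paste0("C", c1$samples$sample_id)
  c1 <- intensity_data(c1$meth, c1$unmeth, c1$annotation, c1$samples)
  left <- harmonise_cohorts(list(harmonise_cohorts(list(a, b)), c1))
  right <- harmonise_cohorts(list(a, harmonise_cohorts(list(b, c1))))
  expect_setequal(left$annotation$probe_id, right$annotation$probe_id)

  # identical probe sets: probe count unchanged, samples concatenated
  comb2 <- harmonise_cohorts(list(a, {
    aa <- a; aa$samples$sample_id <- paste0("X", aa$samples$sample_id)
    intensity_data(aa$meth, aa$unmeth, aa$annotation, aa$samples)
  }))
  expect_equal(nrow(comb2$annotation), 9)
  expect_equal(nrow(comb2$samples), 8)

  # disjoint probe sets error; duplicate sample ids error
  dis <- subset_intensity(d, probes = d$annotation$probe_id[10:12])
  dis$samples$sample_id <- paste0("D", dis$samples$sample_id)
  dis <- intensity_data(dis$meth, dis$unmeth, dis$annotation, dis$samples)
  expect_error(harmonise_cohorts(list(subset_intensity(
    d, probes = d$annotation$probe_id[1:3]), dis)), "common")
  expect_error(harmonise_cohorts(list(a, a)), "duplicate")
})
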
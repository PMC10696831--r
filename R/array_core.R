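#' Probe annotation table
#'
#' Builds and validates the per-probe metadata table that drives every
#' probe-type-aware step of the pipeline. The two Infinium chemistries are
#' distinguished by `design_type`: Type I probes use two probes read in a
#' single colour channel, Type II probes use one probe read in both channels.
#'
#' @param probe_id Character vector of unique probe identifiers.
#' @param design_type `"I"` or `"II"` per probe.
#' @param channel `"Grn"`, `"Red"`, or `"both"`. Type II probes must be
#'   `"both"`.
#' @param chromosome Chromosome label (autosome labels, `"X"`, `"Y"`).
#' @param special_class One of `"plain"`, `"dmr"` (imprinted region, expected
#'   beta 0.5), `"snp"` (polymorphism-affected, trimodal beta), `"chrX_sex"`
#'   (X-linked, sex-differentiated).
#' @param cpg_count Small positive integer giving the underlying CpG content
#'   of the probe body (used for SWAN subset stratification).
#'
#' @return A `data.frame` of class `probe_annotation`.
#' @export
probe_annotation <- function(probe_id, design_type, channel, chromosome,
                             special_class = "plain", cpg_count = 1L) {
  ann <- data.frame(
    probe_id = as.character(probe_id),
    design_type = as.character(design_type),
    channel = as.character(channel),
    chromosome = as.character(chromosome),
    special_class = rep_len(as.character(special_class), length(probe_id)),
    cpg_count = rep_len(as.integer(cpg_count), length(probe_id)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ann$probe_id)) {
    stop("probe_annotation: probe_id values must be unique")
  }
  if (!all(ann$design_type %in% c("I", "II"))) {
    stop("probe_annotation: design_type must be 'I' or 'II'")
  }
  if (!all(ann$channel %in% c("Grn", "Red", "both"))) {
    stop("probe_annotation: channel must be 'Grn', 'Red' or 'both'")
  }
  if (any(ann$design_type == "II" & ann$channel != "both")) {
    stop("probe_annotation: Type II probes must have channel 'both'")
  }
  if (!all(ann$special_class %in% c("plain", "dmr", "snp", "chrX_sex"))) {
    stop("probe_annotation: unknown special_class")
  }
  if (any(ann$special_class == "chrX_sex" & ann$chromosome != "X")) {
    stop("probe_annotation: chrX_sex probes must be on chromosome X")
  }
  if (any(ann$cpg_count < 1L)) stop("probe_annotation: cpg_count must be >= 1")
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Sample sheet
#'
#' @param sample_id Unique sample identifiers.
#' @param cohort Cohort label per sample.
#' @param batch Processing batch label (defaults to the cohort).
#' @param age Age in years.
#' @param sex `"F"` or `"M"`.
#' @param bmi Body mass index (kg/m^2), strictly positive where present.
#' @param pcs Optional matrix/data.frame of ancestry covariates (genetic
#'   principal components), one row per sample; columns are named `pc1..pcK`.
#'
#' @return A `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, cohort, batch = cohort, age = NA_real_,
                         sex = NA_character_, bmi = NA_real_, pcs = NULL) {
  sm <- data.frame(
    sample_id = as.character(sample_id),
    cohort = rep_len(as.character(cohort), length(sample_id)),
    batch = rep_len(as.character(batch), length(sample_id)),
    age = rep_len(as.numeric(age), length(sample_id)),
    sex = rep_len(as.character(sex), length(sample_id)),
    bmi = rep_len(as.numeric(bmi), length(sample_id)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(sm$sample_id)) {
    stop("sample_sheet: sample_id values must be unique")
  }
  if (any(!is.na(sm$sex) & !sm$sex %in% c("F", "M"))) {
    stop("sample_sheet: sex must be 'F' or 'M'")
  }
  if (any(!is.na(sm$bmi) & sm$bmi <= 0)) {
    stop("sample_sheet: BMI must be positive where present")
  }
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (nrow(pcs) != nrow(sm)) stop("sample_sheet: pcs row count mismatch")
    colnames(pcs) <- paste0("pc", seq_len(ncol(pcs)))
    sm <- cbind(sm, as.data.frame(pcs))
  }
  class(sm) <- c("sample_sheet", "data.frame")
  sm
}

pc_columns <- function(samples) grep("^pc[0-9]+$", names(samples), value = TRUE)

check_matrix <- function(x, ann, sm, what, allow_negative = FALSE) {
  if (is.null(x)) return(NULL)
  x <- as.matrix(x)
  if (nrow(x) != nrow(ann) || ncol(x) != nrow(sm)) {
    stop(sprintf("intensity_data: %s matrix is %d x %d, expected %d x %d",
                 what, nrow(x), ncol(x), nrow(ann), nrow(sm)))
  }
  if (!allow_negative && any(x < 0, na.rm = TRUE)) {
    stop(sprintf("intensity_data: negative values in %s", what))
  }
  dimnames(x) <- list(ann$probe_id, sm$sample_id)
  x
}

#' Paired-channel intensity container
#'
#' Holds the methylated (M) and unmethylated (U) signal matrices for an array
#' experiment, plus the optional out-of-band intensities of Type I probes
#' (signal read in the opposite colour channel, a pure background
#' measurement), bead counts and detection p-values.
#'
#' @param meth,unmeth Non-negative `probe x sample` matrices.
#' @param annotation A [probe_annotation()].
#' @param samples A [sample_sheet()].
#' @param oob_meth,oob_unmeth Optional out-of-band intensity matrices
#'   (meaningful for Type I probes only; `NA` elsewhere is fine).
#' @param beadcount Optional integer matrix of bead counts.
#' @param detection_p Optional matrix of detection p-values in `[0, 1]`.
#'
#' @return An object of class `intensity_data`.
#' @export
intensity_data <- function(meth, unmeth, annotation, samples,
                           oob_meth = NULL, oob_unmeth = NULL,
                           beadcount = NULL, detection_p = NULL) {
  stopifnot(inherits(annotation, "probe_annotation"),
            inherits(samples, "sample_sheet"))
  obj <- list(
    meth = check_matrix(meth, annotation, samples, "meth"),
    unmeth = check_matrix(unmeth, annotation, samples, "unmeth"),
    oob_meth = check_matrix(oob_meth, annotation, samples, "oob_meth"),
    oob_unmeth = check_matrix(oob_unmeth, annotation, samples, "oob_unmeth"),
    beadcount = check_matrix(beadcount, annotation, samples, "beadcount"),
    detection_p = check_matrix(detection_p, annotation, samples, "detection_p"),
    annotation = annotation,
    samples = samples
  )
  if (!is.null(obj$detection_p) &&
      any(obj$detection_p < 0 | obj$detection_p > 1, na.rm = TRUE)) {
    stop("intensity_data: detection_p must lie in [0, 1]")
  }
  class(obj) <- "intensity_data"
  obj
}

#' @export
#' @method print intensity_data
print.intensity_data <- function(x, ...) {
  cat("intensity_data:", nrow(x$annotation), "probes x",
      nrow(x$samples), "samples\n")
  cat("  Type I/II:", sum(x$annotation$design_type == "I"), "/",
      sum(x$annotation$design_type == "II"), "\n")
  cat("  cohorts:", paste(unique(x$samples$cohort), collapse = ", "), "\n")
  opt <- c("oob_meth", "oob_unmeth", "beadcount", "detection_p")
  have <- opt[!vapply(x[opt], is.null, logical(1))]
  cat("  optional matrices:",
      if (length(have)) paste(have, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Subset an intensity_data object by probes and/or samples
#'
#' @param data An [intensity_data()] object.
#' @param probes Probe ids (or logical/integer index) to keep.
#' @param samples Sample ids (or logical/integer index) to keep.
#' @return A new `intensity_data` restricted to the selection.
#' @export
subset_intensity <- function(data, probes = NULL, samples = NULL) {
  resolve <- function(sel, ids) {
    if (is.null(sel)) return(seq_along(ids))
    if (is.character(sel)) {
      i <- match(sel, ids)
      if (anyNA(i)) stop("subset_intensity: unknown probe or sample id")
      return(i)
    }
    if (is.logical(sel)) return(which(sel))
    as.integer(sel)
  }
  pi <- resolve(probes, data$annotation$probe_id)
  si <- resolve(samples, data$samples$sample_id)
  ann <- data$annotation[pi, , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("probe_annotation", "data.frame")
  sm <- data$samples[si, , drop = FALSE]
  rownames(sm) <- NULL
  class(sm) <- c("sample_sheet", "data.frame")
  take <- function(m) if (is.null(m)) NULL else m[pi, si, drop = FALSE]
  intensity_data(take(data$meth), take(data$unmeth), ann, sm,
                 oob_meth = take(data$oob_meth),
                 oob_unmeth = take(data$oob_unmeth),
                 beadcount = take(data$beadcount),
                 detection_p = take(data$detection_p))
}

#' Beta-value matrix container
#'
#' @param values `probe x sample` matrix of methylation proportions in
#'   `[0, 1]`.
#' @param annotation A [probe_annotation()].
#' @param samples A [sample_sheet()].
#' @return Object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, annotation, samples) {
  values <- check_matrix(values, annotation, samples, "beta")
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    stop("beta_matrix: values must lie in [0, 1]")
  }
  structure(list(values = values, annotation = annotation, samples = samples),
            class = "beta_matrix")
}

#' M-value matrix container
#'
#' @inheritParams beta_matrix
#' @return Object of class `mvalue_matrix`.
#' @export
mvalue_matrix <- function(values, annotation, samples) {
  values <- check_matrix(values, annotation, samples, "mvalue",
                         allow_negative = TRUE)
  if (any(!is.finite(values))) stop("mvalue_matrix: values must be finite")
  structure(list(values = values, annotation = annotation, samples = samples),
            class = "mvalue_matrix")
}

#' @export
#' @method print beta_matrix
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$values), "probes x", ncol(x$values), "samples;",
      "range", sprintf("[%.3f, %.3f]", min(x$values), max(x$values)), "\n")
  invisible(x)
}

#' Convert intensities to beta values
#'
#' The methylation proportion at each probe is `beta = M / (M + U + offset)`,
#' where the offset regularises low-intensity probes.
#'
#' @param data An [intensity_data()] object.
#' @param offset Non-negative regularising constant added to the denominator
#'   (default 100, the conventional value).
#' @return A [beta_matrix()].
#' @export
beta_from_intensities <- function(data, offset = 100) {
  stopifnot(inherits(data, "intensity_data"))
  if (offset < 0) stop("beta_from_intensities: offset must be >= 0")
  denom <- data$meth + data$unmeth + offset
  b <- ifelse(denom > 0, data$meth / denom, 0)
  beta_matrix(b, data$annotation, data$samples)
}

#' Convert intensities to M-values
#'
#' `Mval = log2((M + eps) / (U + eps))`; `eps > 0` keeps the ratio finite.
#'
#' @param data An [intensity_data()] object.
#' @param eps Positive stabilising constant (default 1).
#' @return An [mvalue_matrix()].
#' @export
mvalue_from_intensities <- function(data, eps = 1) {
  stopifnot(inherits(data, "intensity_data"))
  if (eps <= 0) stop("mvalue_from_intensities: eps must be > 0")
  mvalue_matrix(log2((data$meth + eps) / (data$unmeth + eps)),
                data$annotation, data$samples)
}

#' Convert a beta matrix to M-values (logit2 transform)
#'
#' @param betas A [beta_matrix()].
#' @param clip Betas are clipped to `[clip, 1 - clip]` before the transform so
#'   the result is finite.
#' @return An [mvalue_matrix()].
#' @export
beta_to_mvalue <- function(betas, clip = 1e-6) {
  b <- pmin(pmax(betas$values, clip), 1 - clip)
  mvalue_matrix(log2(b / (1 - b)), betas$annotation, betas$samples)
}

#' @rdname beta_to_mvalue
#' @param mvalues An [mvalue_matrix()].
#' @export
mvalue_to_beta <- function(mvalues) {
  m <- 2^mvalues$values
  beta_matrix(m / (1 + m), mvalues$annotation, mvalues$samples)
}

#' Probe detection filter
#'
#' Keeps probes for which at most `sample_fraction` of samples have a
#' detection p-value above `p_threshold`; removal requires strictly *more*
#' than the allowed fraction of failing samples.
#'
#' @param detp Detection p-value matrix (`probe x sample`, rownames are probe
#'   ids).
#' @param sample_fraction Tolerated fraction of failing samples (default 1%).
#' @param p_threshold Detection p-value above which a call fails (default
#'   0.05).
#' @return Character vector of retained probe ids.
#' @export
filter_probes_by_detection <- function(detp, sample_fraction = 0.01,
                                       p_threshold = 0.05) {
  detp <- as.matrix(detp)
  if (length(detp) == 0) stop("filter_probes_by_detection: empty matrix")
  if (any(detp < 0 | detp > 1, na.rm = TRUE)) {
    stop("filter_probes_by_detection: p-values must lie in [0, 1]")
  }
  frac_fail <- rowMeans(detp > p_threshold, na.rm = TRUE)
  rownames(detp)[frac_fail <= sample_fraction]
}

#' Sample detection filter
#'
#' Mirror of [filter_probes_by_detection()] on the sample axis: samples where
#' strictly more than `probe_fraction` of probes fail detection are removed.
#'
#' @param detp Detection p-value matrix with sample ids as colnames.
#' @param probe_fraction Tolerated fraction of failing probes (default 1%).
#' @param p_threshold Failure threshold (default 0.05).
#' @return Character vector of retained sample ids.
#' @export
filter_samples_by_detection <- function(detp, probe_fraction = 0.01,
                                        p_threshold = 0.05) {
  detp <- as.matrix(detp)
  if (length(detp) == 0) stop("filter_samples_by_detection: empty matrix")
  frac_fail <- colMeans(detp > p_threshold, na.rm = TRUE)
  colnames(detp)[frac_fail <= probe_fraction]
}

#' Bead-count filter
#'
#' Probes measured by fewer than `min_beads` beads in strictly more than
#' `sample_fraction` of samples are removed. When no bead-count matrix is
#' available the filter is skipped with a warning and all probes are kept.
#'
#' @param beadcount Integer matrix of bead counts (or `NULL`).
#' @param min_beads Minimum acceptable bead count (default 3).
#' @param sample_fraction Tolerated fraction of low-bead samples (default 5%).
#' @return Character vector of retained probe ids, or `NULL` when skipped on
#'   `NULL` input with unavailable rownames.
#' @export
filter_probes_by_beadcount <- function(beadcount, min_beads = 3,
                                       sample_fraction = 0.05) {
  if (is.null(beadcount)) {
    warning("filter_probes_by_beadcount: no bead-count matrix; filter skipped")
    return(NULL)
  }
  beadcount <- as.matrix(beadcount)
  if (any(beadcount < 0, na.rm = TRUE)) {
    stop("filter_probes_by_beadcount: counts must be non-negative")
  }
  frac_low <- rowMeans(beadcount < min_beads, na.rm = TRUE)
  rownames(beadcount)[frac_low <= sample_fraction]
}

#' Drop probes on an exclusion list
#'
#' Removes probes that appear on a user-supplied exclusion list (typically
#' probes predicted to cross-hybridise or to overlap a polymorphism). Ids on
#' the list that are absent from the annotation are counted and reported, not
#' errors.
#'
#' @param annotation A [probe_annotation()].
#' @param exclusion_ids Character vector of probe ids to drop.
#' @return Character vector of retained probe ids.
#' @export
drop_probe_exclusion_list <- function(annotation, exclusion_ids) {
  exclusion_ids <- unique(as.character(exclusion_ids))
  unknown <- setdiff(exclusion_ids, annotation$probe_id)
  if (length(exclusion_ids) > 0 && length(unknown) == length(exclusion_ids)) {
    warning(sprintf("drop_probe_exclusion_list: all %d exclusion ids unknown",
                    length(unknown)))
  } else if (length(unknown) > 0) {
    message(sprintf("drop_probe_exclusion_list: %d exclusion ids not present",
                    length(unknown)))
  }
  setdiff(annotation$probe_id, exclusion_ids)
}

#' Run the full pre-normalisation QC pipeline
#'
#' Applies, in order: the probe exclusion list, the probe detection filter,
#' the sample detection filter, and the bead-count filter. Filters that need
#' an absent optional matrix are skipped with a warning. The sequence is
#' applied once (not iterated after sample removal).
#'
#' @param data An [intensity_data()] object.
#' @param exclusion_ids Optional character vector of probe ids to drop first.
#' @param sample_fraction,p_threshold,probe_fraction,min_beads,bead_fraction
#'   Thresholds forwarded to the individual filters.
#' @return A list with the filtered `data` and a `report` (class `qc_report`)
#'   whose counts reconcile exactly with the matrix shapes before and after.
#' @export
qc_pipeline <- function(data, exclusion_ids = character(),
                        sample_fraction = 0.01, p_threshold = 0.05,
                        probe_fraction = 0.01, min_beads = 3,
                        bead_fraction = 0.05) {
  stopifnot(inherits(data, "intensity_data"))
  n_probes0 <- nrow(data$annotation)
  n_samples0 <- nrow(data$samples)

  keep1 <- drop_probe_exclusion_list(data$annotation, exclusion_ids)
  removed_excl <- n_probes0 - length(keep1)
  data <- subset_intensity(data, probes = keep1)

  if (!is.null(data$detection_p)) {
    keep2 <- filter_probes_by_detection(data$detection_p, sample_fraction,
                                        p_threshold)
  } else {
    warning("qc_pipeline: no detection_p matrix; detection filters skipped")
    keep2 <- data$annotation$probe_id
  }
  removed_detp <- nrow(data$annotation) - length(keep2)
  data <- subset_intensity(data, probes = keep2)

  if (!is.null(data$detection_p)) {
    keeps <- filter_samples_by_detection(data$detection_p, probe_fraction,
                                         p_threshold)
  } else {
    keeps <- data$samples$sample_id
  }
  removed_samples <- nrow(data$samples) - length(keeps)
  data <- subset_intensity(data, samples = keeps)

  if (!is.null(data$beadcount)) {
    keep3 <- filter_probes_by_beadcount(data$beadcount, min_beads,
                                        bead_fraction)
  } else {
    warning("qc_pipeline: no bead-count matrix; bead-count filter skipped")
    keep3 <- data$annotation$probe_id
  }
  removed_bead <- nrow(data$annotation) - length(keep3)
  data <- subset_intensity(data, probes = keep3)

  report <- structure(list(
    probes_removed_exclusion_list = removed_excl,
    probes_removed_detection = removed_detp,
    samples_removed_detection = removed_samples,
    probes_removed_beadcount = removed_bead,
    probes_remaining = nrow(data$annotation),
    samples_remaining = nrow(data$samples)
  ), class = "qc_report")
  list(data = data, report = report)
}

#' @export
#' @method print qc_report
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  cat("  probes removed (exclusion list):", x$probes_removed_exclusion_list, "\n")
  cat("  probes removed (detection):     ", x$probes_removed_detection, "\n")
  cat("  samples removed (detection):    ", x$samples_removed_detection, "\n")
  cat("  probes removed (bead count):    ", x$probes_removed_beadcount, "\n")
  cat("  remaining:", x$probes_remaining, "probes x",
      x$samples_remaining, "samples\n")
  invisible(x)
}

#' Combine cohorts on their common probe space
#'
#' Restricts every dataset to the intersection of probe ids and concatenates
#' samples in input order; cohort labels travel with the sample sheet.
#'
#' @param datasets A list of two or more [intensity_data()] objects.
#' @return A combined `intensity_data`.
#' @export
harmonise_cohorts <- function(datasets) {
  if (length(datasets) < 2) stop("harmonise_cohorts: need >= 2 datasets")
  common <- Reduce(intersect, lapply(datasets, function(d) d$annotation$probe_id))
  if (length(common) == 0) {
    stop("harmonise_cohorts: no probes common to all datasets")
  }
  all_ids <- unlist(lapply(datasets, function(d) d$samples$sample_id))
  if (anyDuplicated(all_ids)) {
    stop("harmonise_cohorts: duplicate sample_id across cohorts: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  parts <- lapply(datasets, subset_intensity, probes = common)
  ann <- parts[[1]]$annotation
  sm <- do.call(rbind, lapply(parts, function(p) as.data.frame(p$samples)))
  rownames(sm) <- NULL
  class(sm) <- c("sample_sheet", "data.frame")
  bindm <- function(slot) {
    mats <- lapply(parts, `[[`, slot)
    if (any(vapply(mats, is.null, logical(1)))) return(NULL)
    do.call(cbind, mats)
  }
  intensity_data(bindm("meth"), bindm("unmeth"), ann, sm,
                 oob_meth = bindm("oob_meth"), oob_unmeth = bindm("oob_unmeth"),
                 beadcount = bindm("beadcount"),
                 detection_p = bindm("detection_p"))
}
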
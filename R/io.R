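# Plain-text tabular interchange. Intensity data travels as a long table
# (one row per probe x sample), manifests and sample sheets as one-row-per-
# entity tables, EpiScore models as two-column coefficient tables with a
# reserved "(Intercept)" row. Delimiters are auto-detected on read; writers
# emit deterministic row and column order.

#' Write / read an intensity table
#'
#' Long format with columns `probe_id, sample_id, meth, unmeth` and the
#' optional columns `oob_meth, oob_unmeth, beadcount, detection_p` when the
#' corresponding matrices are present. Round-trips losslessly.
#'
#' @param data An [intensity_data()] object.
#' @param path Output file; the extension picks the delimiter (`.csv` comma,
#'   otherwise tab).
#' @export
write_intensity_table <- function(data, path) {
  ann <- data$annotation; sm <- data$samples
  long <- data.table::data.table(
    probe_id = rep(ann$probe_id, times = nrow(sm)),
    sample_id = rep(sm$sample_id, each = nrow(ann)),
    meth = as.vector(data$meth),
    unmeth = as.vector(data$unmeth)
  )
  for (opt in c("oob_meth", "oob_unmeth", "beadcount", "detection_p")) {
    if (!is.null(data[[opt]])) long[[opt]] <- as.vector(data[[opt]])
  }
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(long, path, sep = sep)
  invisible(path)
}

#' @rdname write_intensity_table
#' @param manifest_path,samples_path Companion tables written with
#'   [write_manifest()] / [write_sample_sheet()].
#' @return `read_intensity_table()` returns an [intensity_data()].
#' @export
read_intensity_table <- function(path, manifest_path, samples_path) {
  long <- data.table::fread(path)
  need <- c("probe_id", "sample_id", "meth", "unmeth")
  if (!all(need %in% names(long))) {
    stop("read_intensity_table: header must contain ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(long[, c("probe_id", "sample_id")])) {
    d <- long[duplicated(long[, c("probe_id", "sample_id")]), ]
    stop("read_intensity_table: duplicated (probe, sample) row, e.g. ",
         d$probe_id[1], " / ", d$sample_id[1])
  }
  ann <- read_manifest(manifest_path)
  sm <- read_sample_sheet(samples_path)
  n_cells <- nrow(ann) * nrow(sm)
  if (nrow(long) != n_cells) {
    stop("read_intensity_table: expected ", n_cells, " rows (complete ",
         "probe x sample grid), found ", nrow(long))
  }
  shape <- function(col) {
    m <- matrix(NA_real_, nrow(ann), nrow(sm),
                dimnames = list(ann$probe_id, sm$sample_id))
    m[cbind(match(long$probe_id, ann$probe_id),
            match(long$sample_id, sm$sample_id))] <- long[[col]]
    m
  }
  opt <- function(col) if (col %in% names(long)) shape(col) else NULL
  intensity_data(shape("meth"), shape("unmeth"), ann, sm,
                 oob_meth = opt("oob_meth"), oob_unmeth = opt("oob_unmeth"),
                 beadcount = opt("beadcount"),
                 detection_p = opt("detection_p"))
}

#' Write / read a probe manifest
#'
#' @param annotation A [probe_annotation()].
#' @param path File path (`.csv` comma, otherwise tab).
#' @export
write_manifest <- function(annotation, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(as.data.frame(annotation), path, sep = sep)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  probe_annotation(df$probe_id, df$design_type, df$channel, df$chromosome,
                   df$special_class, df$cpg_count)
}

#' Write / read a sample sheet
#'
#' @param samples A [sample_sheet()].
#' @param path File path.
#' @export
write_sample_sheet <- function(samples, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(as.data.frame(samples), path, sep = sep)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  pcs <- df[, grep("^pc[0-9]+$", names(df)), drop = FALSE]
  sample_sheet(df$sample_id, df$cohort,
               batch = if ("batch" %in% names(df)) df$batch else df$cohort,
               age = if ("age" %in% names(df)) df$age else NA_real_,
               sex = if ("sex" %in% names(df)) df$sex else NA_character_,
               bmi = if ("bmi" %in% names(df)) df$bmi else NA_real_,
               pcs = if (ncol(pcs)) pcs else NULL)
}

#' Write an EpiScore coefficient table
#'
#' Two-column TSV `probe_id<TAB>weight` with a reserved `(Intercept)` row;
#' weights are written in full precision so projections round-trip exactly.
#'
#' @param model An `episcore` object (or any list with `intercept` and named
#'   `weights`).
#' @param path Output TSV path.
#' @export
write_coefficients <- function(model, path) {
  df <- data.frame(
    probe_id = c("(Intercept)", names(model$weights)),
    weight = c(model$intercept, unname(model$weights)),
    stringsAsFactors = FALSE
  )
  if (!is.null(model$training_means)) {
    df$training_mean <- c(NA_real_, unname(model$training_means))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EpiScore coefficient table
#'
#' @param path TSV with header `probe_id  weight` (optional `training_mean`
#'   column) and an optional `(Intercept)` row; a missing intercept row is
#'   treated as 0 with a warning.
#' @param scale Declared value scale of the coefficients.
#' @return An object of class `episcore` usable with [project_episcore()].
#' @export
read_coefficients <- function(path, scale = "mvalue") {
  df <- as.data.frame(data.table::fread(path))
  if (!all(c("probe_id", "weight") %in% names(df))) {
    stop("read_coefficients: header must contain probe_id and weight")
  }
  if (!is.numeric(df$weight)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$weight))))[1]
    stop("read_coefficients: non-numeric weight at line ", bad + 1)
  }
  if (anyDuplicated(df$probe_id)) {
    stop("read_coefficients: duplicate probe row: ",
         df$probe_id[duplicated(df$probe_id)][1])
  }
  ii <- df$probe_id == "(Intercept)"
  intercept <- if (any(ii)) df$weight[ii] else {
    warning("read_coefficients: no (Intercept) row; intercept set to 0")
    0
  }
  w <- stats::setNames(df$weight[!ii], df$probe_id[!ii])
  tm <- if ("training_mean" %in% names(df)) {
    stats::setNames(df$training_mean[!ii], df$probe_id[!ii])
  } else stats::setNames(rep(0, sum(!ii)), df$probe_id[!ii])
  structure(list(intercept = intercept, weights = w, training_means = tm,
                 scale = scale, alpha = NA_real_, lambda = NA_real_,
                 n_folds = NA_integer_, feature_space = length(w),
                 n_train = NA_integer_, seed = NA_integer_,
                 cv_error = NA_real_),
            class = "episcore")
}
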
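# The sixteen benchmark normalisation strategies. Nine are combinatorial
# quantile-normalisation variants named by a three-letter code:
#   letter 1: 'd' background adjustment / 'n' none
#   letter 3: between-array QN of Type I and II probes separately ('s'),
#             together ('t'), or not at all ('n')
#   letter 5: dye-bias correction separately ('s'), together ('t'), none ('n')
# The remainder are the named within-array methods (SWAN, BMIQ, PBC, Noob),
# functional normalisation, subset quantile normalisation (Tost) and raw.

#' Normalisation method specification
#'
#' @param name Unique method name.
#' @param family One of `"combinatorial_qn"`, `"swan"`, `"bmiq"`, `"pbc"`,
#'   `"noob"`, `"funnorm"`, `"tost"`, `"raw"`.
#' @param background `"d"` (adjust) or `"n"` (none); combinatorial only.
#' @param between_array `"s"`, `"t"` or `"n"`; combinatorial only.
#' @param dye_bias `"s"`, `"t"` or `"n"`; combinatorial only.
#' @param variant Optional small integer distinguishing sub-variants
#'   (`daten1` vs `daten2`: variant 2 pools the M and U matrices into a
#'   single between-array QN pass, variant 1 normalises them separately).
#' @return A list of class `method_spec`.
#' @export
method_spec <- function(name, family, background = NA, between_array = NA,
                        dye_bias = NA, variant = 1L) {
  fam <- c("combinatorial_qn", "swan", "bmiq", "pbc", "noob", "funnorm",
           "tost", "raw")
  if (!family %in% fam) stop("method_spec: unknown family '", family, "'")
  if (family == "combinatorial_qn") {
    stopifnot(background %in% c("d", "n"), between_array %in% c("s", "t", "n"),
              dye_bias %in% c("s", "t", "n"))
  }
  structure(list(name = name, family = family, background = background,
                 between_array = between_array, dye_bias = dye_bias,
                 variant = as.integer(variant)),
            class = "method_spec")
}

#' The pinned 16-method benchmark registry
#'
#' @return Named list of 16 [method_spec()] objects: `raw`, `swan`, `noob`,
#'   `bmiq`, `pbc`, `tost`, `funnorm`, and the combinatorial set `nasen`,
#'   `dasen`, `naten`, `daten1`, `daten2`, `nanet`, `danet`, `nanes`,
#'   `danes`.
#' @export
registry_16_methods <- function() {
  comb <- function(nm, bg, ba, dy, v = 1L)
    method_spec(nm, "combinatorial_qn", bg, ba, dy, v)
  specs <- list(
    method_spec("raw", "raw"),
    method_spec("swan", "swan"),
    method_spec("noob", "noob"),
    method_spec("bmiq", "bmiq"),
    method_spec("pbc", "pbc"),
    method_spec("tost", "tost"),
    method_spec("funnorm", "funnorm"),
    comb("nasen", "n", "s", "n"),
    comb("dasen", "d", "s", "n"),
    comb("naten", "n", "t", "n"),
    comb("daten1", "d", "t", "n", 1L),
    comb("daten2", "d", "t", "n", 2L),
    comb("nanet", "n", "n", "t"),
    comb("danet", "d", "n", "t"),
    comb("nanes", "n", "n", "s"),
    comb("danes", "d", "n", "s")
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Normalise with a named method
#'
#' Dispatcher resolving a registry name (or explicit [method_spec()]) and
#' returning beta values.
#'
#' @param data An [intensity_data()] object.
#' @param method Registry name or a [method_spec()].
#' @param offset Beta offset forwarded to [beta_from_intensities()].
#' @param ... Extra arguments for the underlying method.
#' @return A [beta_matrix()].
#' @export
normalise_method <- function(data, method, offset = 100, ...) {
  if (is.character(method)) {
    reg <- registry_16_methods()
    if (!method %in% names(reg)) {
      stop("normalise_method: unknown method '", method, "'; registry: ",
           paste(names(reg), collapse = ", "))
    }
    method <- reg[[method]]
  }
  stopifnot(inherits(method, "method_spec"))
  switch(method$family,
         raw = beta_from_intensities(data, offset),
         combinatorial_qn = apply_combinatorial_method(data, method, offset),
         swan = swan_normalise(data, offset = offset, ...),
         bmiq = bmiq_normalise(beta_from_intensities(data, offset), ...),
         pbc = pbc_normalise(beta_from_intensities(data, offset), ...),
         noob = beta_from_intensities(noob_normalise(data), offset),
         funnorm = funnorm_normalise(data, offset = offset, ...),
         tost = tost_normalise(data, offset = offset, ...))
}

## ---- combinatorial building blocks -------------------------------------

#' Equalise Type I and Type II background levels
#'
#' Per sample and per signal (M, U), Type I intensities are shifted additively
#' so that their 5th percentile matches the Type II 5th percentile; results
#' are floored at zero.
#'
#' @param data An [intensity_data()] object.
#' @return A new `intensity_data`.
#' @export
background_equalise <- function(data) {
  type1 <- data$annotation$design_type == "I"
  if (!any(type1) || all(type1)) {
    warning("background_equalise: only one probe type present; no-op")
    return(data)
  }
  adj <- function(mat) {
    q1 <- apply(mat[type1, , drop = FALSE], 2, stats::quantile, probs = 0.05)
    q2 <- apply(mat[!type1, , drop = FALSE], 2, stats::quantile, probs = 0.05)
    shift <- q2 - q1
    mat[type1, ] <- sweep(mat[type1, , drop = FALSE], 2, shift, `+`)
    pmax(mat, 0)
  }
  data$meth <- adj(data$meth)
  data$unmeth <- adj(data$unmeth)
  data
}

# channel membership of each (probe, signal) pair: Type II M reads green and
# U reads red; both signals of a Type I probe share its declared channel
channel_of <- function(ann, signal) {
  ifelse(ann$design_type == "II",
         if (signal == "meth") "Grn" else "Red",
         ann$channel)
}

# quantile-equalise two vectors (the two colour channels of one sample):
# each value moves to the mean of its own value and the rank-matched
# quantile of the other channel
equalise_two <- function(g, r) {
  m <- length(g); n <- length(r)
  pg <- (rank(g, ties.method = "average") - 0.5) / m
  pr <- (rank(r, ties.method = "average") - 0.5) / n
  qr <- stats::approx((seq_len(n) - 0.5) / n, sort.int(r), xout = pg,
                      rule = 2)$y
  qg <- stats::approx((seq_len(m) - 0.5) / m, sort.int(g), xout = pr,
                      rule = 2)$y
  list(g = (g + qr) / 2, r = (r + qg) / 2)
}

#' Dye-bias correction by cross-channel quantile equalisation
#'
#' Per sample, the red- and green-channel intensity distributions are
#' equalised by quantile normalisation across the two channels, either with
#' Type I and Type II probes pooled (`mode = "t"`) or within each design type
#' separately (`mode = "s"`). Uses only the sample's own values, so the
#' correction is sample-wise.
#'
#' @param data An [intensity_data()] object.
#' @param mode `"s"` or `"t"`.
#' @return A new `intensity_data`.
#' @export
dye_bias_correct <- function(data, mode = c("t", "s")) {
  mode <- match.arg(mode)
  ann <- data$annotation
  ch_m <- channel_of(ann, "meth")
  ch_u <- channel_of(ann, "unmeth")
  groups <- if (mode == "t") list(seq_len(nrow(ann))) else
    split(seq_len(nrow(ann)), ann$design_type)
  meth <- data$meth; unmeth <- data$unmeth
  for (j in seq_len(ncol(meth))) {
    for (idx in groups) {
      gm <- idx[ch_m[idx] == "Grn"]; rm_ <- idx[ch_m[idx] == "Red"]
      gu <- idx[ch_u[idx] == "Grn"]; ru <- idx[ch_u[idx] == "Red"]
      g <- c(meth[gm, j], unmeth[gu, j])
      r <- c(meth[rm_, j], unmeth[ru, j])
      if (length(g) < 2 || length(r) < 2) next
      eq <- equalise_two(g, r)
      if (length(gm)) meth[gm, j] <- eq$g[seq_along(gm)]
      if (length(gu)) unmeth[gu, j] <- eq$g[length(gm) + seq_along(gu)]
      if (length(rm_)) meth[rm_, j] <- eq$r[seq_along(rm_)]
      if (length(ru)) unmeth[ru, j] <- eq$r[length(rm_) + seq_along(ru)]
    }
  }
  data$meth <- pmax(meth, 0)
  data$unmeth <- pmax(unmeth, 0)
  data
}

#' Apply a combinatorial quantile-normalisation method
#'
#' Pipeline: background equalisation (if `background = "d"`), dye-bias
#' correction (if `dye_bias` is `"s"` or `"t"`), between-array quantile
#' normalisation of the M and U matrices across samples (grouped by design
#' type if `between_array = "s"`, one group if `"t"`, skipped if `"n"`), then
#' conversion to beta. `variant = 2` pools the M and U matrices into one QN
#' pass instead of normalising them separately.
#'
#' @param data An [intensity_data()] object.
#' @param spec A [method_spec()] with `family = "combinatorial_qn"`.
#' @param offset Beta offset.
#' @param return_intensities Return the normalised `intensity_data` instead
#'   of beta values (default FALSE).
#' @return A [beta_matrix()], or an `intensity_data` when
#'   `return_intensities = TRUE`.
#' @export
apply_combinatorial_method <- function(data, spec, offset = 100,
                                       return_intensities = FALSE) {
  stopifnot(inherits(spec, "method_spec"))
  if (spec$family != "combinatorial_qn") {
    stop("apply_combinatorial_method: spec family must be combinatorial_qn")
  }
  if (spec$background == "d") data <- background_equalise(data)
  if (spec$dye_bias %in% c("s", "t")) {
    data <- dye_bias_correct(data, spec$dye_bias)
  }
  if (spec$between_array %in% c("s", "t") && ncol(data$meth) > 1) {
    groups <- if (spec$between_array == "s") data$annotation$design_type
      else NULL
    if (spec$variant == 2L) {
      stacked <- rbind(data$meth, data$unmeth)
      g2 <- if (is.null(groups)) NULL else rep(groups, 2)
      stacked <- quantile_normalise(stacked, g2)
      n <- nrow(data$meth)
      data$meth <- stacked[seq_len(n), , drop = FALSE]
      data$unmeth <- stacked[n + seq_len(n), , drop = FALSE]
    } else {
      data$meth <- quantile_normalise(data$meth, groups)
      data$unmeth <- quantile_normalise(data$unmeth, groups)
    }
  }
  if (return_intensities) return(data)
  beta_from_intensities(data, offset)
}

## ---- SWAN ----------------------------------------------------------------

# deterministic string hash (multiplicative, mod 2^31 - 1) so SWAN's subset
# draw depends only on the sample id and stratum, never on cohort composition
hash32 <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# map values through the subset quantile distribution onto the averaged
# target distribution; tails handled by additive offset beyond the subset
# range
swan_map <- function(v, sub_sorted, target_sorted) {
  m <- length(sub_sorted)
  pp <- (seq_len(m) - 0.5) / m
  p <- stats::approx(sub_sorted, pp, xout = v, rule = 2, ties = mean)$y
  out <- stats::approx(pp, target_sorted, xout = p, rule = 2)$y
  hi <- v > sub_sorted[m]
  lo <- v < sub_sorted[1]
  out[hi] <- target_sorted[m] + (v[hi] - sub_sorted[m])
  out[lo] <- pmax(target_sorted[1] - (sub_sorted[1] - v[lo]), 0)
  out
}

#' Subset-quantile within-array normalisation (SWAN-style)
#'
#' Strictly per sample: within each CpG-content stratum an equal number of
#' Type I and Type II probes is selected (deterministically, seeded by a hash
#' of the sample id and stratum, so a sample's output never depends on which
#' other samples are present). The two design types' subset quantile
#' distributions are averaged, and every probe's M and U intensity is mapped
#' by linear interpolation of its within-type subset quantile onto the
#' averaged distribution.
#'
#' @param data An [intensity_data()] whose annotation carries `cpg_count`.
#' @param offset Beta offset for the final conversion.
#' @return A [beta_matrix()].
#' @export
swan_normalise <- function(data, offset = 100) {
  ann <- data$annotation
  type1 <- ann$design_type == "I"
  if (!any(type1) || all(type1)) {
    warning("swan_normalise: only one probe type present; returning raw beta")
    return(beta_from_intensities(data, offset))
  }
  strata <- sort(unique(ann$cpg_count))
  meth <- data$meth; unmeth <- data$unmeth
  for (j in seq_len(ncol(meth))) {
    sid <- colnames(meth)[j]
    sub1 <- integer(); sub2 <- integer()
    for (s in strata) {
      i1 <- which(type1 & ann$cpg_count == s)
      i2 <- which(!type1 & ann$cpg_count == s)
      if (!length(i1) || !length(i2)) {
        warning("swan_normalise: cpg_count stratum ", s,
                " empty for one design type; skipped")
        next
      }
      m <- min(length(i1), length(i2))
      sub1 <- c(sub1, with_local_seed(hash32(paste0(sid, "|I|", s)),
                                      sample(i1, m)))
      sub2 <- c(sub2, with_local_seed(hash32(paste0(sid, "|II|", s)),
                                      sample(i2, m)))
    }
    if (!length(sub1)) next
    for (signal in c("meth", "unmeth")) {
      x <- if (signal == "meth") meth[, j] else unmeth[, j]
      s1 <- sort.int(x[sub1]); s2 <- sort.int(x[sub2])
      avg <- (s1 + s2) / 2
      x[type1] <- swan_map(x[type1], s1, avg)
      x[!type1] <- swan_map(x[!type1], s2, avg)
      if (signal == "meth") meth[, j] <- x else unmeth[, j] <- x
    }
  }
  data$meth <- meth; data$unmeth <- unmeth
  beta_from_intensities(data, offset)
}

## ---- BMIQ ----------------------------------------------------------------

# 3-component beta mixture fitted by EM; components anchored near the
# unmethylated, hemimethylated and methylated states
fit_beta_mixture3 <- function(x, init_means = c(0.1, 0.5, 0.9),
                              maxit = 200, tol = 1e-5) {
  k <- 3L
  mids <- (init_means[-k] + init_means[-1]) / 2
  assign0 <- findInterval(x, mids) + 1L
  w <- tabulate(assign0, k) / length(x)
  w <- pmax(w, 0.01); w <- w / sum(w)
  mom <- function(m, v) {
    m <- min(max(m, 0.001), 0.999)
    v <- max(v, 1e-6)
    v <- min(v, m * (1 - m) * 0.95)
    c(a = m * (m * (1 - m) / v - 1), b = (1 - m) * (m * (1 - m) / v - 1))
  }
  par <- t(vapply(1:k, function(g) {
    xi <- x[assign0 == g]
    if (length(xi) < 5) xi <- c(xi, init_means[g] + c(-0.02, 0, 0.02))
    mom(mean(xi), max(stats::var(xi), 1e-5))
  }, numeric(2)))
  # beta log-density with the data logs precomputed once: per EM iteration
  # only two fused multiply-adds per component remain
  lx <- log(x); l1x <- log1p(-x)
  ldens_mat <- function(w, par) {
    vapply(1:k, function(g) {
      (par[g, 1] - 1) * lx + (par[g, 2] - 1) * l1x -
        lbeta(par[g, 1], par[g, 2]) + log(w[g])
    }, numeric(length(x)))
  }
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    ld <- ldens_mat(w, par)
    mx <- ld[cbind(seq_along(x), max.col(ld))]
    dens <- exp(ld - mx)
    tot <- rowSums(dens)
    ll <- sum(log(tot) + mx)
    r <- dens / tot
    w <- colMeans(r)
    w <- pmax(w, 1e-6); w <- w / sum(w)
    for (g in 1:k) {
      sw <- sum(r[, g])
      if (sw < 1e-8) next
      m <- sum(r[, g] * x) / sw
      v <- sum(r[, g] * (x - m)^2) / sw
      par[g, ] <- mom(m, v)
    }
    # moment-based M-steps plateau rather than strictly increase the
    # likelihood; after a short burn-in any non-improvement ends the fit
    if (is.finite(ll) && it > 10 &&
        (ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  means <- par[, 1] / rowSums(par)
  ord <- order(means)
  w <- w[ord]; par <- par[ord, , drop = FALSE]
  list(w = w, par = par, converged = TRUE, iterations = it,
       state = max.col(ldens_mat(w, par)))
}

#' Beta-mixture quantile normalisation (BMIQ-style)
#'
#' Per sample: a 3-state beta mixture (unmethylated, hemimethylated,
#' methylated) is EM-fitted separately to Type I and Type II probes, with
#' probes assigned to their maximum-probability state. Type II probes in the
#' outer states are mapped by a quantile transform onto the corresponding
#' fitted Type I beta distribution; middle-state probes are rescaled linearly
#' between the transformed state boundaries, preserving ordering and
#' continuity. Type I probes are unchanged.
#'
#' @param betas A [beta_matrix()] with both probe types present.
#' @param maxit,tol EM iteration cap and relative log-likelihood tolerance.
#' @return A [beta_matrix()].
#' @export
bmiq_normalise <- function(betas, maxit = 200, tol = 1e-5) {
  ann <- betas$annotation
  type1 <- ann$design_type == "I"
  if (!any(type1) || all(type1)) {
    warning("bmiq_normalise: only one probe type present; returning input")
    return(betas)
  }
  vals <- pmin(pmax(betas$values, 1e-6), 1 - 1e-6)
  out <- vals
  for (j in seq_len(ncol(vals))) {
    x1 <- vals[type1, j]; x2 <- vals[!type1, j]
    fit1 <- try(fit_beta_mixture3(x1, maxit = maxit, tol = tol), silent = TRUE)
    fit2 <- try(fit_beta_mixture3(x2, maxit = maxit, tol = tol), silent = TRUE)
    if (inherits(fit1, "try-error") || inherits(fit2, "try-error")) {
      warning("bmiq_normalise: mixture fit failed for sample ",
              colnames(vals)[j], "; sample left unnormalised")
      next
    }
    y <- x2
    sU <- fit2$state == 1; sM <- fit2$state == 3; sH <- fit2$state == 2
    if (any(sU)) {
      p <- stats::pbeta(x2[sU], fit2$par[1, 1], fit2$par[1, 2])
      y[sU] <- stats::qbeta(p, fit1$par[1, 1], fit1$par[1, 2])
    }
    if (any(sM)) {
      p <- stats::pbeta(x2[sM], fit2$par[3, 1], fit2$par[3, 2])
      y[sM] <- stats::qbeta(p, fit1$par[3, 1], fit1$par[3, 2])
    }
    if (any(sH) && any(sU) && any(sM)) {
      l2 <- max(x2[sU]); r2 <- min(x2[sM])
      l1 <- max(y[sU]); r1 <- min(y[sM])
      if (r2 > l2 && r1 > l1) {
        y[sH] <- l1 + (x2[sH] - l2) * (r1 - l1) / (r2 - l2)
      }
    }
    out[!type1, j] <- pmin(pmax(y, 0), 1)
  }
  beta_matrix(out, ann, betas$samples)
}

## ---- PBC -----------------------------------------------------------------

# mode of a kernel density estimate over a 512-point grid (Silverman
# bandwidth); NA when the side is empty or degenerate
kde_peak <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 10 || stats::sd(x) == 0) return(NA_real_)
  d <- stats::density(x, bw = "nrd0", n = 512)
  d$x[which.max(d$y)]
}

#' Peak-based correction (PBC-style)
#'
#' Per sample: the kernel-density peaks of the negative (unmethylated) and
#' positive (methylated) M-values are located separately for Type I and
#' Type II probes; Type II M-values are rescaled linearly on each side so
#' their peaks match the Type I peaks, then transformed back to beta.
#'
#' @param betas A [beta_matrix()].
#' @return A [beta_matrix()].
#' @export
pbc_normalise <- function(betas) {
  ann <- betas$annotation
  type1 <- ann$design_type == "I"
  if (!any(type1) || all(type1)) {
    warning("pbc_normalise: only one probe type present; returning input")
    return(betas)
  }
  mv <- beta_to_mvalue(betas)$values
  out <- mv
  for (j in seq_len(ncol(mv))) {
    m1 <- mv[type1, j]; m2 <- mv[!type1, j]
    y <- m2
    for (side in c("neg", "pos")) {
      pick <- function(v) if (side == "neg") v[v < 0] else v[v > 0]
      p1 <- kde_peak(pick(m1)); p2 <- kde_peak(pick(m2))
      if (is.na(p1) || is.na(p2) || abs(p2) < 1e-8) {
        warning("pbc_normalise: no usable ", side, " peak for sample ",
                colnames(mv)[j], "; side skipped")
        next
      }
      sel <- if (side == "neg") m2 < 0 else m2 > 0
      y[sel] <- m2[sel] * (p1 / p2)
    }
    out[!type1, j] <- y
  }
  b <- 2^out / (1 + 2^out)
  beta_matrix(pmin(pmax(b, 0), 1), ann, betas$samples)
}

## ---- Noob ----------------------------------------------------------------

#' Normal-exponential out-of-band background correction (Noob-style)
#'
#' Per sample and colour channel: the background mean and SD are estimated
#' from the out-of-band readings of Type I probes (a Grn-channel probe's
#' out-of-band signal is read in Red and vice versa), and a
#' normal-exponential deconvolution (posterior-mean signal, strictly
#' positive) is applied to the in-band intensities of that channel. The two
#' corrected channels are then scaled to a common per-sample reference level
#' (dye-bias equalisation). Entirely sample-wise.
#'
#' @param data An [intensity_data()] with out-of-band matrices.
#' @return A corrected `intensity_data`.
#' @export
noob_normalise <- function(data) {
  if (is.null(data$oob_meth) || is.null(data$oob_unmeth)) {
    stop("noob_normalise: requires out-of-band (oob) intensity matrices")
  }
  ann <- data$annotation
  type1 <- ann$design_type == "I"
  ch_m <- channel_of(ann, "meth")
  ch_u <- channel_of(ann, "unmeth")
  meth <- data$meth; unmeth <- data$unmeth
  for (j in seq_len(ncol(meth))) {
    corrected <- list()
    for (ch in c("Grn", "Red")) {
      opp <- if (ch == "Grn") "Red" else "Grn"
      bg <- c(data$oob_meth[type1 & ann$channel == opp, j],
              data$oob_unmeth[type1 & ann$channel == opp, j])
      bg <- bg[is.finite(bg)]
      if (length(bg) < 10) {
        stop("noob_normalise: too few out-of-band readings for channel ", ch)
      }
      mu <- mean(bg)
      sigma <- max(stats::sd(bg), 1)
      im <- which(ch_m == ch); iu <- which(ch_u == ch)
      x <- c(meth[im, j], unmeth[iu, j])
      alpha <- max(mean(x) - mu, 10)
      xc <- limma::normexp.signal(c(mu, log(sigma), log(alpha)), x)
      meth[im, j] <- xc[seq_along(im)]
      unmeth[iu, j] <- xc[length(im) + seq_along(iu)]
      corrected[[ch]] <- xc
    }
    # sample-wise dye equalisation. The channel level is estimated from
    # Type I probes only: their M + U total lives in a single channel and is
    # independent of methylation, so the ratio isolates the dye gain.
    lvl <- vapply(c("Grn", "Red"), function(ch) {
      i1 <- type1 & ann$channel == ch
      mean(meth[i1, j] + unmeth[i1, j])
    }, numeric(1))
    mg <- lvl[["Grn"]]; mr <- lvl[["Red"]]
    ref <- (mg + mr) / 2
    for (ch in c("Grn", "Red")) {
      f <- ref / (if (ch == "Grn") mg else mr)
      im <- which(ch_m == ch); iu <- which(ch_u == ch)
      meth[im, j] <- meth[im, j] * f
      unmeth[iu, j] <- unmeth[iu, j] * f
    }
  }
  data$meth <- meth; data$unmeth <- unmeth
  data
}

## ---- Funnorm -------------------------------------------------------------

#' Functional-normalisation-style adjustment
#'
#' Control summaries (quantiles, means and SDs of the out-of-band background
#' readings per channel) are computed per sample, z-scored, and reduced to
#' principal components. Per design type and signal, the per-sample intensity
#' quantiles are regressed on the first `n_pcs` components and the fitted
#' technical effects removed; each sample's values are then interpolated from
#' its old to its adjusted quantile function. With `n_pcs = 0` the transform
#' is the identity up to quantile-interpolation tolerance.
#'
#' @param data An [intensity_data()] with out-of-band matrices.
#' @param n_pcs Number of control principal components to remove (default 2).
#' @param n_quantiles Resolution of the quantile grid (default 200).
#' @param offset Beta offset.
#' @return A [beta_matrix()].
#' @export
funnorm_normalise <- function(data, n_pcs = 2, n_quantiles = 200,
                              offset = 100) {
  if (is.null(data$oob_meth) || is.null(data$oob_unmeth)) {
    stop("funnorm_normalise: requires out-of-band (oob) intensity matrices")
  }
  n_samp <- ncol(data$meth)
  if (n_samp <= n_pcs) stop("funnorm_normalise: need more samples than PCs")
  ann <- data$annotation
  type1 <- ann$design_type == "I"

  # per-sample control summaries from the oob background
  summ <- vapply(seq_len(n_samp), function(j) {
    g <- c(data$oob_meth[type1 & ann$channel == "Red", j],
           data$oob_unmeth[type1 & ann$channel == "Red", j])
    r <- c(data$oob_meth[type1 & ann$channel == "Grn", j],
           data$oob_unmeth[type1 & ann$channel == "Grn", j])
    g <- g[is.finite(g)]; r <- r[is.finite(r)]
    c(stats::quantile(g, c(0.05, 0.25, 0.5, 0.75, 0.95)),
      stats::quantile(r, c(0.05, 0.25, 0.5, 0.75, 0.95)),
      mean(g), stats::sd(g), mean(r), stats::sd(r))
  }, numeric(14))
  summ <- t(summ)
  keep <- apply(summ, 2, stats::sd) > 0
  Z <- scale(summ[, keep, drop = FALSE])
  scores <- if (n_pcs > 0) {
    stats::prcomp(Z, center = FALSE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                       drop = FALSE]
  } else NULL

  pp <- seq(0, 1, length.out = n_quantiles)
  adjust_signal <- function(mat) {
    out <- mat
    for (grp in list(which(type1), which(!type1))) {
      Q <- apply(mat[grp, , drop = FALSE], 2, stats::quantile, probs = pp,
                 names = FALSE)
      adjQ <- Q
      if (!is.null(scores)) {
        Zc <- scale(scores, scale = FALSE)
        hat <- Zc %*% solve(crossprod(Zc), t(Zc))
        adjQ <- Q - t(hat %*% t(Q))
      }
      adjQ <- apply(adjQ, 2, cummax)  # enforce monotone quantile functions
      for (j in seq_len(ncol(mat))) {
        out[grp, j] <- stats::approx(Q[, j], adjQ[, j], xout = mat[grp, j],
                                     rule = 2, ties = mean)$y
      }
    }
    pmax(out, 0)
  }
  data$meth <- adjust_signal(data$meth)
  data$unmeth <- adjust_signal(data$unmeth)
  beta_from_intensities(data, offset)
}

## ---- Tost (subset quantile normalisation) --------------------------------

#' Subset quantile normalisation (Tost-style)
#'
#' Type I probes (considered more stable) are quantile-normalised across
#' samples; Type II intensities are then quantile-mapped, per sample and per
#' CpG-content stratum, onto the distribution of the Type I "anchor" probes
#' of that stratum. Strata with no anchors are merged into the nearest
#' smaller stratum with a warning.
#'
#' @param data An [intensity_data()] object.
#' @param offset Beta offset.
#' @return A [beta_matrix()].
#' @export
tost_normalise <- function(data, offset = 100) {
  ann <- data$annotation
  type1 <- ann$design_type == "I"
  if (!any(type1) || all(type1)) {
    warning("tost_normalise: only one probe type present; returning raw beta")
    return(beta_from_intensities(data, offset))
  }
  meth <- data$meth; unmeth <- data$unmeth
  if (ncol(meth) > 1) {
    meth[type1, ] <- quantile_normalise(meth[type1, , drop = FALSE])
    unmeth[type1, ] <- quantile_normalise(unmeth[type1, , drop = FALSE])
  }
  strata <- sort(unique(ann$cpg_count))
  anchor_of <- list()
  for (s in strata) {
    a <- which(type1 & ann$cpg_count == s)
    if (!length(a)) {
      warning("tost_normalise: no Type I anchors in cpg_count stratum ", s,
              "; merged with nearest stratum")
      prev <- Filter(function(z) length(anchor_of[[as.character(z)]]) > 0,
                     strata[strata < s])
      a <- if (length(prev)) anchor_of[[as.character(max(prev))]] else
        which(type1)
    }
    anchor_of[[as.character(s)]] <- a
  }
  for (j in seq_len(ncol(meth))) {
    for (s in strata) {
      i2 <- which(!type1 & ann$cpg_count == s)
      if (!length(i2)) next
      a <- anchor_of[[as.character(s)]]
      for (signal in c("meth", "unmeth")) {
        mat <- if (signal == "meth") meth else unmeth
        v <- mat[i2, j]
        anc <- sort.int(mat[a, j])
        p <- (rank(v, ties.method = "average") - 0.5) / length(v)
        newv <- stats::approx((seq_along(anc) - 0.5) / length(anc), anc,
                              xout = p, rule = 2)$y
        if (signal == "meth") meth[i2, j] <- newv else unmeth[i2, j] <- newv
      }
    }
  }
  data$meth <- meth; data$unmeth <- unmeth
  beta_from_intensities(data, offset)
}
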
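#' Fluorescence titration series
#'
#' Quencher concentration vs emission intensity at a fixed emission
#' wavelength, plus the unquenched intensity I0. When the first
#' concentration is zero, its intensity defines I0 unless given
#' explicitly.
#'
#' @param conc Quencher concentrations in mol/L, non-negative, increasing.
#' @param intensity Emission intensities (a.u.), same length.
#' @param I0 Unquenched intensity (a.u., > 0); defaults to the intensity
#'   at zero concentration when present.
#' @param probe_conc Probe concentration in mol/L (metadata).
#' @param emission_nm,excitation_nm Wavelengths (metadata).
#' @param analyte Analyte name (metadata).
#' @return A `titration_series` object.
#' @export
titration_series <- function(conc, intensity, I0 = NULL,
                             probe_conc = NA_real_, emission_nm = NA_real_,
                             excitation_nm = NA_real_,
                             analyte = NA_character_) {
  conc <- as.numeric(conc)
  intensity <- as.numeric(intensity)
  if (length(conc) != length(intensity))
    .domain_error("conc and intensity lengths differ")
  if (any(conc < 0)) .domain_error("concentrations must be non-negative")
  if (any(diff(conc) <= 0)) .domain_error("concentrations must be increasing")
  if (is.null(I0)) {
    if (conc[1] == 0) I0 <- intensity[1]
    else .domain_error("I0 required when the series does not start at zero concentration")
  }
  if (I0 <= 0) .domain_error("I0 must be positive")
  structure(list(conc = conc, intensity = intensity, I0 = I0,
                 meta = list(probe_conc = probe_conc, emission_nm = emission_nm,
                             excitation_nm = excitation_nm, analyte = analyte)),
            class = "titration_series")
}

#' Stern-Volmer quenching fit
#'
#' Fits I0/I = 1 + Ksv \[Q\] by ordinary least squares of I0/I on the
#' quencher concentration. With `fix_intercept = TRUE` the model is
#' forced through the theoretical intercept: (I0/I - 1) = Ksv \[Q\].
#' A free-intercept fit far from 1 (|intercept - 1| > 0.05) is flagged,
#' since the linear Stern-Volmer form holds only in the low-concentration
#' regime; use `range_mask` to restrict the fit to that regime.
#'
#' @param t A [titration_series()].
#' @param fix_intercept Force the intercept to exactly 1.
#' @param range_mask Optional logical vector selecting the points to fit.
#' @return An `sv_fit` object: `Ksv` (M^-1), `intercept`, `r_squared`,
#'   `n_points_used`, `linear_range_mask`, `intercept_flag`.
#' @examples
#' q <- seq(0, 3e-7, length.out = 8)
#' t <- titration_series(q, 1000 / (1 + 6.5e6 * q))
#' stern_volmer_fit(t)$Ksv
#' @export
stern_volmer_fit <- function(t, fix_intercept = FALSE, range_mask = NULL) {
  stopifnot(inherits(t, "titration_series"))
  mask <- range_mask %||% rep(TRUE, length(t$conc))
  if (length(mask) != length(t$conc)) .domain_error("range_mask has wrong length")
  q <- t$conc[mask]
  I <- t$intensity[mask]
  if (any(I <= 0)) .domain_error("all intensities must be positive for I0/I")
  if (length(unique(q)) < 3L) .domain_error("need >= 3 distinct concentrations")
  y <- t$I0 / I
  if (fix_intercept) {
    fit <- lm((y - 1) ~ 0 + q)
    ksv <- unname(coef(fit)[["q"]])
    icpt <- 1
    ss_res <- sum(residuals(fit)^2)
    ss_tot <- sum((y - 1)^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  } else {
    fit <- lm(y ~ q)
    ksv <- unname(coef(fit)[["q"]])
    icpt <- unname(coef(fit)[["(Intercept)"]])
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  }
  structure(list(Ksv = ksv, intercept = icpt, r_squared = r2,
                 n_points_used = length(q), linear_range_mask = mask,
                 intercept_flag = !fix_intercept && abs(icpt - 1) > 0.05),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit: Ksv = %.4g M^-1, intercept = %.4f, R^2 = %.5f (n = %d)\n",
              x$Ksv, x$intercept, x$r_squared, x$n_points_used))
  if (isTRUE(x$intercept_flag))
    cat("  note: intercept deviates from 1 by > 0.05; consider restricting the linear range\n")
  invisible(x)
}

#' Quenching efficiency
#'
#' 100 * (1 - I/I0): the percent loss of emission. Negative values
#' indicate enhancement rather than quenching. Invariant to rescaling
#' both intensities by a common positive factor.
#'
#' @param I0 Unquenched intensity (> 0).
#' @param I Quenched intensity (>= 0). Vectorized.
#' @return Efficiency in percent.
#' @export
quenching_efficiency <- function(I0, I) {
  if (any(I0 <= 0)) .domain_error("I0 must be positive")
  if (any(I < 0)) .domain_error("I must be non-negative")
  100 * (1 - I / I0)
}

#' 3-sigma/slope limit of detection
#'
#' Regresses the chosen response on concentration over the
#' low-concentration linear regime and combines the slope with the sample
#' standard deviation of blank replicates: LOD = 3 sigma_blank / |slope|.
#'
#' @param calibration A [titration_series()] covering the linear regime.
#' @param blanks Numeric vector of >= 3 blank-replicate intensities.
#' @param response `"intensity"` (raw intensity vs concentration) or
#'   `"delta_intensity"` (I0 - I vs concentration).
#' @return A `calibration_fit`: `slope`, `intercept`, `sigma_blank`,
#'   `lod` (mol/L), `r_squared`, `n_points`. The identity
#'   `lod * |slope| == 3 * sigma_blank` holds exactly.
#' @export
detection_limit <- function(calibration, blanks,
                            response = c("intensity", "delta_intensity")) {
  stopifnot(inherits(calibration, "titration_series"))
  response <- match.arg(response)
  blanks <- as.numeric(blanks)
  if (length(blanks) < 3L) .domain_error("need >= 3 blank replicates")
  if (length(unique(calibration$conc)) < 3L)
    .domain_error("need >= 3 calibration points")
  y <- switch(response,
              intensity = calibration$intensity,
              delta_intensity = calibration$I0 - calibration$intensity)
  x <- calibration$conc
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[["x"]])
  if (slope == 0) .domain_error("zero calibration slope: LOD undefined")
  sigma <- sd(blanks)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  structure(list(slope = slope, intercept = unname(coef(fit)[["(Intercept)"]]),
                 sigma_blank = sigma, lod = 3 * sigma / abs(slope),
                 r_squared = r2,
                 n_points = length(x), response = response),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration: slope = %.4g a.u./M, sigma_blank = %.4g, LOD = %.4g M, R^2 = %.5f\n",
              x$slope, x$sigma_blank, x$lod, x$r_squared))
  invisible(x)
}

#' Continuous-variation (Job) series
#'
#' @param mole_fraction Host (probe) mole fractions in (0, 1), increasing.
#' @param signal Signal proportional to complex concentration (a.u.).
#' @return A `job_series` object.
#' @export
job_series <- function(mole_fraction, signal) {
  mole_fraction <- as.numeric(mole_fraction)
  signal <- as.numeric(signal)
  if (length(mole_fraction) != length(signal))
    .domain_error("mole_fraction and signal lengths differ")
  if (any(mole_fraction <= 0) || any(mole_fraction >= 1))
    .domain_error("mole fractions must lie strictly inside (0, 1)")
  if (any(diff(mole_fraction) <= 0))
    .domain_error("mole fractions must be increasing")
  structure(list(mole_fraction = mole_fraction, signal = signal),
            class = "job_series")
}

#' Job's-plot stoichiometry analysis
#'
#' Locates the mole fraction of maximal signal by parabolic interpolation
#' around the discrete maximum and converts it to a small-integer
#' host:guest ratio via round((1 - x_max)/x_max) (or its reciprocal when
#' x_max > 1/2). Ratios beyond 4 are reported as inconclusive, as is a
#' maximum at the edge of the sampled range. The symmetry score is
#' 1 - mean(|signal(x) - signal(1 - x)|) / max(signal); a 1:1 complex
#' gives a curve symmetric about x = 1/2 and a score near 1.
#'
#' @param j A [job_series()] with >= 5 points.
#' @param baseline_correction Subtract the straight line through the
#'   first and last points before locating the maximum.
#' @return A `job_result`: `x_max`, `ratio` (integer vector c(host,
#'   guest) or NA), `ratio_label` (e.g. "1:1"), `curve_symmetry`,
#'   `inconclusive` (logical), `reason`.
#' @export
job_analyze <- function(j, baseline_correction = FALSE) {
  stopifnot(inherits(j, "job_series"))
  x <- j$mole_fraction
  y <- j$signal
  if (length(x) < 5L) .domain_error("need >= 5 mole fractions")
  if (baseline_correction) {
    n <- length(x)
    y <- y - (y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1]))
  }
  i <- which.max(y)
  inconclusive <- FALSE
  reason <- NA_character_
  if (i == 1L || i == length(x)) {
    x_max <- x[i]
    inconclusive <- TRUE
    reason <- "maximum at edge of sampled range"
  } else {
    v <- .parabolic_vertex(x[i - 1L], x[i], x[i + 1L], y[i - 1L], y[i], y[i + 1L])
    x_max <- unname(v["x"])
  }
  ratio <- c(NA_integer_, NA_integer_)
  ratio_label <- NA_character_
  if (!inconclusive) {
    r <- (1 - x_max) / x_max   # guest per host
    if (r >= 1) {
      n_g <- round(r)
      if (n_g <= 4) { ratio <- c(1L, as.integer(n_g)); ratio_label <- sprintf("1:%d", n_g) }
    } else {
      n_h <- round(1 / r)
      if (n_h <= 4) { ratio <- c(as.integer(n_h), 1L); ratio_label <- sprintf("%d:1", n_h) }
    }
    if (is.na(ratio_label)) {
      inconclusive <- TRUE
      reason <- "implied stoichiometry beyond 4: Job's method unreliable"
    }
  }
  # symmetry about x = 1/2 via linear interpolation of the mirrored curve
  xr <- 1 - x
  ok <- xr >= min(x) & xr <= max(x)
  sym <- if (sum(ok) >= 2L && max(abs(y)) > 0) {
    mirrored <- approx(x, y, xout = xr[ok])$y
    1 - mean(abs(y[ok] - mirrored)) / max(abs(y))
  } else NA_real_
  structure(list(x_max = x_max, ratio = ratio, ratio_label = ratio_label,
                 curve_symmetry = sym, inconclusive = inconclusive,
                 reason = reason),
            class = "job_result")
}

#' @export
print.job_result <- function(x, ...) {
  cat(sprintf("Job analysis: x_max = %.4f, ratio = %s, symmetry = %s\n",
              x$x_max, x$ratio_label %||% NA,
              if (is.na(x$curve_symmetry)) "NA" else sprintf("%.4f", x$curve_symmetry)))
  if (x$inconclusive) cat("  inconclusive:", x$reason, "\n")
  invisible(x)
}

#' Selectivity panel
#'
#' Per-analyte relative turn-off response 1 - I/I0 and, optionally, an
#' interference comparison: for each competitor, the residual response of
#' the probe + competitor mixture upon adding the target analyte.
#'
#' @param probe_I0 Unperturbed probe intensity (> 0).
#' @param responses Named numeric vector: analyte -> intensity in its
#'   presence.
#' @param interference Optional data frame with columns `competitor`,
#'   `I_competitor` (probe + competitor) and `I_competitor_target`
#'   (probe + competitor + target analyte).
#' @return A `selectivity_panel`: `response` (named vector of 1 - I/I0),
#'   `selective_for` (analyte of maximal positive response or NA),
#'   `interference` (data frame with `retained_response` column or NULL).
#' @export
selectivity_panel <- function(probe_I0, responses, interference = NULL) {
  if (probe_I0 <= 0) .domain_error("probe_I0 must be positive")
  if (length(responses) == 0L) .domain_error("empty response map")
  if (is.null(names(responses)) || any(!nzchar(names(responses))))
    .domain_error("responses must be a named vector")
  rel <- 1 - responses / probe_I0
  selective <- if (max(rel) > 0) names(rel)[which.max(rel)] else NA_character_
  if (!is.null(interference)) {
    stopifnot(all(c("competitor", "I_competitor", "I_competitor_target") %in%
                    names(interference)))
    interference$retained_response <-
      1 - interference$I_competitor_target / interference$I_competitor
  }
  structure(list(response = rel, selective_for = selective,
                 interference = interference),
            class = "selectivity_panel")
}

#' @export
print.selectivity_panel <- function(x, ...) {
  cat("Selectivity panel (relative turn-off response):\n")
  for (nm in names(x$response))
    cat(sprintf("  %-8s %6.3f%s\n", nm, x$response[[nm]],
                if (identical(nm, x$selective_for)) "  <- selective" else ""))
  invisible(x)
}

#' Reversibility index
#'
#' Fraction of the quenched intensity regained after adding a competing
#' base: (I_recovered - I_quenched)/(I_probe - I_quenched). The reported
#' value is clipped to \[0, 1\]; the raw value is retained. Invariant to
#' rescaling all three intensities by a common positive factor.
#'
#' @param I_probe Intensity of the free probe (> 0).
#' @param I_quenched Intensity after quenching (< I_probe).
#' @param I_recovered Intensity after the recovery step.
#' @return List with `index` (clipped) and `raw`.
#' @export
reversibility_index <- function(I_probe, I_quenched, I_recovered) {
  if (I_probe <= 0) .domain_error("I_probe must be positive")
  if (I_quenched > I_probe) .domain_error("I_quenched exceeds I_probe: not a quench")
  if (I_probe == I_quenched) .domain_error("no quench to reverse (I_probe == I_quenched)")
  raw <- (I_recovered - I_quenched) / (I_probe - I_quenched)
  list(index = min(max(raw, 0), 1), raw = raw)
}

#' Quencher concentrations from incremental stock additions
#'
#' Converts cumulative microlitre additions of an analyte stock into the
#' concentrations actually present in the cuvette, accounting for the
#' dilution by the added volume: \[Q\] = V_added * C_stock / (V_initial +
#' V_added). Useful as a pre-processing step for titrations recorded as
#' "n uL of stock added" rather than as concentrations.
#'
#' @param v_added_uL Cumulative added stock volumes in microlitres
#'   (non-negative, increasing).
#' @param c_stock Stock concentration in mol/L.
#' @param v_initial_mL Initial cuvette volume in mL (default 2).
#' @return Concentrations in mol/L, same length as `v_added_uL`.
#' @examples
#' dilution_concentrations(c(0, 2, 4, 6), 1e-3, 2)
#' @export
dilution_concentrations <- function(v_added_uL, c_stock, v_initial_mL = 2) {
  v_added_uL <- as.numeric(v_added_uL)
  if (any(v_added_uL < 0)) .domain_error("added volumes must be non-negative")
  if (c_stock <= 0) .domain_error("stock concentration must be positive")
  if (v_initial_mL <= 0) .domain_error("initial volume must be positive")
  v_add_mL <- v_added_uL / 1000
  v_add_mL * c_stock / (v_initial_mL + v_add_mL)
}

#' Read a titration series from CSV
#'
#' Format: optional `# key: value` comment lines (keys `i0`, `probe_conc`,
#' `emission_nm`, `excitation_nm`, `analyte`), header `conc_M,intensity`.
#'
#' @param path CSV path.
#' @return A [titration_series()].
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) .spec_error(sprintf("titration file not found: %s", path))
  meta <- .read_comment_meta(path)
  df <- read.csv(path, comment.char = "#")
  if (!all(c("conc_M", "intensity") %in% names(df)))
    .spec_error(sprintf("%s lacks conc_M/intensity columns", path))
  titration_series(df$conc_M, df$intensity,
                   I0 = if (!is.null(meta$i0)) as.numeric(meta$i0),
                   probe_conc = as.numeric(meta$probe_conc %||% NA),
                   emission_nm = as.numeric(meta$emission_nm %||% NA),
                   excitation_nm = as.numeric(meta$excitation_nm %||% NA),
                   analyte = meta$analyte %||% NA_character_)
}

#' Write a titration series to CSV
#' @param t A [titration_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_titration_csv <- function(t, path) {
  stopifnot(inherits(t, "titration_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# i0: %.10g", t$I0), con)
  if (!is.na(t$meta$analyte)) writeLines(sprintf("# analyte: %s", t$meta$analyte), con)
  writeLines("conc_M,intensity", con)
  writeLines(sprintf("%.10g,%.10g", t$conc, t$intensity), con)
  invisible(path)
}

#' Read a Job series from CSV (`mole_fraction,signal`)
#' @param path CSV path.
#' @return A [job_series()].
#' @export
read_job_csv <- function(path) {
  if (!file.exists(path)) .spec_error(sprintf("job file not found: %s", path))
  df <- read.csv(path, comment.char = "#")
  if (!all(c("mole_fraction", "signal") %in% names(df)))
    .spec_error(sprintf("%s lacks mole_fraction/signal columns", path))
  job_series(df$mole_fraction, df$signal)
}

#' Write a Job series to CSV
#' @param j A [job_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_job_csv <- function(j, path) {
  stopifnot(inherits(j, "job_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("mole_fraction,signal", con)
  writeLines(sprintf("%.10g,%.10g", j$mole_fraction, j$signal), con)
  invisible(path)
}

#' Read blank replicates from a one-column CSV (`intensity`)
#' @param path CSV path.
#' @return Numeric vector of blank intensities.
#' @export
read_blanks_csv <- function(path) {
  if (!file.exists(path)) .spec_error(sprintf("blanks file not found: %s", path))
  df <- read.csv(path, comment.char = "#")
  if (!("intensity" %in% names(df)))
    .spec_error(sprintf("%s lacks an intensity column", path))
  as.numeric(df$intensity)
}

.read_comment_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  meta <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  meta
}
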
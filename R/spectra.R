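.domain_error <- function(msg) {
  stop(structure(class = c("fluorsense_domain_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Construct a spectrum
#'
#' A wavelength-gridded absorption or emission trace with the metadata the
#' photophysics functions need (solvent, concentration, path length).
#'
#' @param wavelength Wavelengths in nm, strictly increasing, >= 3 points.
#' @param signal Signal in arbitrary units (absorbance or emission
#'   intensity), same length, all finite.
#' @param kind `"absorption"` or `"emission"`.
#' @param solvent Solvent label (optional but needed for table pairing).
#' @param concentration Chromophore concentration in mol/L (optional;
#'   needed for molar absorptivity).
#' @param path_length Cuvette path length in cm (default 1).
#' @param excitation_nm Excitation wavelength for emission spectra.
#' @return A `spectrum` object.
#' @export
spectrum <- function(wavelength, signal, kind = c("absorption", "emission"),
                     solvent = NA_character_, concentration = NA_real_,
                     path_length = 1, excitation_nm = NA_real_) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  signal <- as.numeric(signal)
  if (length(wavelength) < 3L) .domain_error("a spectrum needs at least 3 points")
  if (length(signal) != length(wavelength))
    .domain_error("wavelength and signal lengths differ")
  if (any(wavelength <= 0)) .domain_error("wavelengths must be positive")
  if (any(diff(wavelength) <= 0)) .domain_error("wavelengths must be strictly increasing")
  if (any(!is.finite(signal))) .domain_error("signal must be finite")
  if (!is.na(concentration) && concentration <= 0)
    .domain_error("concentration must be positive")
  if (!is.na(path_length) && path_length <= 0)
    .domain_error("path length must be positive")
  structure(list(wavelength = wavelength, signal = signal, kind = kind,
                 meta = list(solvent = solvent, concentration = concentration,
                             path_length = path_length,
                             excitation_nm = excitation_nm)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<%s spectrum> %d points, %.1f-%.1f nm%s\n", x$kind,
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              if (!is.na(x$meta$solvent)) paste0(", solvent ", x$meta$solvent) else ""))
  invisible(x)
}

# Vertex of the parabola through three points; falls back to x2 when the
# curvature vanishes.
.parabolic_vertex <- function(x1, x2, x3, y1, y2, y3) {
  d21 <- (y2 - y1) / (x2 - x1)
  d32 <- (y3 - y2) / (x3 - x2)
  curv <- (d32 - d21) / (x3 - x1)   # half the quadratic coefficient
  if (!is.finite(curv) || curv >= 0 || abs(curv) < 1e-300)
    return(c(x = x2, y = y2))
  xv <- (x1 + x2) / 2 - d21 / (2 * curv)
  # clamp to the bracket; a refined peak cannot leave its 3-point window
  xv <- min(max(xv, x1), x3)
  yv <- y1 + d21 * (xv - x1) + curv * (xv - x1) * (xv - x2)
  c(x = xv, y = yv)
}

#' Locate peaks in a spectrum
#'
#' Local maxima with topographic prominence at least `min_prominence`
#' times the global signal maximum, refined by 3-point parabolic
#' interpolation. Plateau ties are resolved toward longer wavelength.
#'
#' @param s A [spectrum()].
#' @param min_prominence Prominence threshold as a fraction of the global
#'   maximum (default 0.05).
#' @return Data frame with columns `center_nm`, `height`, `prominence`,
#'   sorted by wavelength; zero rows for flat or monotone signals.
#' @export
find_peaks <- function(s, min_prominence = 0.05) {
  stopifnot(inherits(s, "spectrum"))
  x <- s$wavelength
  y <- s$signal
  n <- length(y)
  empty <- data.frame(center_nm = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  if (n < 3L) return(empty)
  # rightmost point of any plateau counts as the candidate (tie -> longer wl)
  idx <- which(vapply(2:(n - 1L), function(i) y[i] >= y[i - 1L] && y[i] > y[i + 1L],
                      logical(1))) + 1L
  if (length(idx) == 0L) return(empty)
  ymax <- max(y)
  prom <- vapply(idx, function(i) {
    lmin <- y[i]; j <- i - 1L
    while (j >= 1L && y[j] <= y[i]) { lmin <- min(lmin, y[j]); j <- j - 1L }
    rmin <- y[i]; j <- i + 1L
    while (j <= n && y[j] <= y[i]) { rmin <- min(rmin, y[j]); j <- j + 1L }
    y[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence * ymax & prom > 0
  idx <- idx[keep]; prom <- prom[keep]
  if (length(idx) == 0L) return(empty)
  refined <- t(vapply(idx, function(i) {
    .parabolic_vertex(x[i - 1L], x[i], x[i + 1L], y[i - 1L], y[i], y[i + 1L])
  }, numeric(2)))
  out <- data.frame(center_nm = refined[, 1], height = refined[, 2],
                    prominence = prom)
  out[order(out$center_nm), , drop = FALSE]
}

#' Stokes shift in wavenumbers
#'
#' Delta-nu = 1e7 * (1/lambda_abs - 1/lambda_em) for wavelengths in nm,
#' giving cm^-1. Positive when emission lies red of absorption;
#' antisymmetric under swapping the arguments.
#'
#' @param lambda_abs Absorption maximum (nm, > 0). Vectorized.
#' @param lambda_em Emission maximum (nm, > 0). Vectorized.
#' @return Stokes shift(s) in cm^-1.
#' @examples
#' stokes_shift(291, 430)  # ~11108 cm^-1
#' @export
stokes_shift <- function(lambda_abs, lambda_em) {
  if (any(lambda_abs <= 0) || any(lambda_em <= 0))
    .domain_error("wavelengths must be positive")
  1e7 * (1 / lambda_abs - 1 / lambda_em)
}

#' Molar absorptivity (Beer-Lambert)
#'
#' @param absorbance Absorbance (a.u., >= 0).
#' @param c Concentration in mol/L (> 0).
#' @param l Path length in cm (> 0).
#' @return Molar absorptivity in L mol^-1 cm^-1.
#' @examples
#' molar_absorptivity(0.5, 1e-5, 1)  # 5e4
#' @export
molar_absorptivity <- function(absorbance, c, l = 1) {
  if (any(c <= 0) || any(l <= 0)) .domain_error("c and l must be positive")
  if (any(absorbance < 0)) .domain_error("absorbance must be non-negative")
  absorbance / (c * l)
}

#' Normalize a spectrum to unit maximum
#'
#' @param s A [spectrum()] with positive maximum signal.
#' @return The spectrum scaled so `max(signal) == 1`; idempotent and
#'   peak-position preserving.
#' @export
normalize_spectrum <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  m <- max(s$signal)
  if (m <= 0) .domain_error("cannot normalize a spectrum with non-positive maximum")
  s$signal <- s$signal / m
  s
}

#' Photophysical summary table
#'
#' For each solvent pair of (absorption, emission) spectra, extracts all
#' absorption maxima, the emission maximum, the molar absorptivity at the
#' chosen absorption band, and the Stokes shift pairing that band with
#' the emission maximum. The default band is the shortest-wavelength
#' (pi-pi*) absorption maximum, which is the pairing under which the
#' solvatochromic Stokes shifts of push-pull fluorophores are normally
#' tabulated; `band = "longest"` pairs the n-pi* band instead.
#'
#' @param series List of pairs: each element a list with components
#'   `absorption` and `emission`, both [spectrum()] objects sharing a
#'   solvent label.
#' @param band `"shortest"` or `"longest"` absorption maximum for the
#'   epsilon / Stokes pairing.
#' @param min_prominence Peak prominence threshold (see [find_peaks()]).
#' @return Data frame with one row per solvent: `solvent`, `lambda_abs`
#'   (comma-joined maxima, nm), `lambda_abs_used`, `lambda_emi`,
#'   `epsilon`, `stokes_cm1`, `complete` (logical), `flag` (character
#'   note, e.g. negative Stokes shift).
#' @export
photophysics_table <- function(series, band = c("shortest", "longest"),
                               min_prominence = 0.05) {
  band <- match.arg(band)
  rows <- lapply(series, function(pair) {
    ab <- pair$absorption
    em <- pair$emission
    stopifnot(inherits(ab, "spectrum"), inherits(em, "spectrum"))
    solvent <- ab$meta$solvent
    if (!is.na(solvent) && !is.na(em$meta$solvent) &&
        !identical(solvent, em$meta$solvent))
      .domain_error(sprintf("absorption/emission solvent mismatch: %s vs %s",
                            solvent, em$meta$solvent))
    pa <- find_peaks(ab, min_prominence)
    pe <- find_peaks(em, min_prominence)
    if (nrow(pa) == 0L || nrow(pe) == 0L) {
      return(data.frame(solvent = solvent, lambda_abs = NA_character_,
                        lambda_abs_used = NA_real_, lambda_emi = NA_real_,
                        epsilon = NA_real_, stokes_cm1 = NA_real_,
                        complete = FALSE, flag = "missing peaks"))
    }
    la_used <- if (band == "shortest") pa$center_nm[1] else pa$center_nm[nrow(pa)]
    a_used <- if (band == "shortest") pa$height[1] else pa$height[nrow(pa)]
    le <- pe$center_nm[which.max(pe$height)]
    eps <- if (!is.na(ab$meta$concentration))
      molar_absorptivity(max(a_used, 0), ab$meta$concentration, ab$meta$path_length)
    else NA_real_
    ss <- stokes_shift(la_used, le)
    data.frame(solvent = solvent,
               lambda_abs = paste(sprintf("%.0f", pa$center_nm), collapse = ","),
               lambda_abs_used = la_used, lambda_emi = le, epsilon = eps,
               stokes_cm1 = ss, complete = TRUE,
               flag = if (ss < 0) "emission blue of absorption" else NA_character_)
  })
  do.call(rbind, rows)
}

#' Solvatochromic wavelength range
#'
#' Max minus min of the selected wavelength across solvents: the
#' bathochromic (red-shift) range of the series.
#'
#' @param rows Data frame from [photophysics_table()].
#' @param which `"emission"` (emission maxima) or `"absorption_longest"`
#'   (longest-wavelength absorption maximum per solvent).
#' @return Range in nm.
#' @export
bathochromic_range <- function(rows, which = c("emission", "absorption_longest")) {
  which <- match.arg(which)
  if (nrow(rows) < 2L) .domain_error("need at least two solvents for a range")
  vals <- if (which == "emission") {
    rows$lambda_emi
  } else {
    vapply(strsplit(rows$lambda_abs, ","), function(v) max(as.numeric(v)), numeric(1))
  }
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2L) .domain_error("fewer than two complete rows")
  max(vals) - min(vals)
}

#' Read a spectrum from CSV
#'
#' Expected format: optional leading comment lines `# key: value`
#' (recognized keys: `kind`, `solvent`, `concentration`, `path_length`,
#' `excitation_nm`), then a header `wavelength_nm,signal` and the data.
#'
#' @param path CSV file path.
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) .spec_error(sprintf("spectrum file not found: %s", path))
  lines <- readLines(path, n = 50L)
  meta <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  df <- tryCatch(read.csv(path, comment.char = "#"),
                 error = function(e) .spec_error(sprintf("cannot parse %s: %s",
                                                         path, conditionMessage(e))))
  if (!all(c("wavelength_nm", "signal") %in% names(df)))
    .spec_error(sprintf("%s lacks wavelength_nm/signal columns", path))
  spectrum(df$wavelength_nm, df$signal,
           kind = meta$kind %||% "absorption",
           solvent = meta$solvent %||% NA_character_,
           concentration = as.numeric(meta$concentration %||% NA),
           path_length = as.numeric(meta$path_length %||% 1),
           excitation_nm = as.numeric(meta$excitation_nm %||% NA))
}

#' Write a spectrum to CSV
#'
#' Inverse of [read_spectrum_csv()]: metadata as `# key: value` comment
#' lines followed by `wavelength_nm,signal` data.
#'
#' @param s A [spectrum()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", s$kind), con)
  meta <- s$meta
  if (!is.na(meta$solvent)) writeLines(sprintf("# solvent: %s", meta$solvent), con)
  if (!is.na(meta$concentration))
    writeLines(sprintf("# concentration: %.10g", meta$concentration), con)
  if (!is.na(meta$path_length))
    writeLines(sprintf("# path_length: %.10g", meta$path_length), con)
  if (!is.na(meta$excitation_nm))
    writeLines(sprintf("# excitation_nm: %.10g", meta$excitation_nm), con)
  writeLines("wavelength_nm,signal", con)
  writeLines(sprintf("%.10g,%.10g", s$wavelength, s$signal), con)
  invisible(path)
}
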
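# Run code with a fixed RNG seed without disturbing global random state.
.with_seed <- function(seed, code) {
  if (missing(seed) || is.null(seed)) .domain_error("a seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' 1:1 host-guest complex concentration
#'
#' Closed-form equilibrium concentration of HG for H + G <-> HG with
#' association constant Ka: the smaller root of the mass-balance
#' quadratic, evaluated in the cancellation-free form
#' 2 H0 G0 / (s + sqrt(s^2 - 4 H0 G0)) with s = H0 + G0 + 1/Ka.
#'
#' @param H0 Total host concentration (mol/L, >= 0). Vectorized.
#' @param G0 Total guest concentration (mol/L, >= 0). Vectorized.
#' @param Ka Association constant (M^-1, > 0).
#' @return Complex concentration in mol/L, within \[0, min(H0, G0)\].
#' @examples
#' solve_equilibrium_1_1(1e-5, 1e-5, 1e6)
#' @export
solve_equilibrium_1_1 <- function(H0, G0, Ka) {
  if (any(H0 < 0) || any(G0 < 0)) .domain_error("concentrations must be non-negative")
  if (any(Ka <= 0)) .domain_error("Ka must be positive")
  s <- H0 + G0 + 1 / Ka
  disc <- s^2 - 4 * H0 * G0
  disc[disc < 0] <- 0   # guard tiny negative round-off
  hg <- 2 * H0 * G0 / (s + sqrt(disc))
  pmin(pmax(hg, 0), pmin(H0, G0))
}

#' m:n host-guest complex concentration by bisection
#'
#' Root of the HmGn mass balance
#' Ka (H0 - m c)^m (G0 - n c)^n - c = 0 on \[0, min(H0/m, G0/n)\],
#' bisected to a relative tolerance of 1e-12. The left-hand side is
#' strictly decreasing in c, so the bracket always contains exactly one
#' root.
#'
#' @param H0,G0 Total concentrations (mol/L, >= 0), scalars.
#' @param Ka Overall association constant (M^-(m+n-1), > 0).
#' @param m,n Stoichiometric coefficients in 1..4.
#' @return Complex concentration in mol/L.
#' @export
solve_equilibrium_m_n <- function(H0, G0, Ka, m = 1L, n = 1L) {
  if (H0 < 0 || G0 < 0) .domain_error("concentrations must be non-negative")
  if (Ka <= 0) .domain_error("Ka must be positive")
  if (!(m %in% 1:4) || !(n %in% 1:4)) .domain_error("m and n must be integers in 1..4")
  hi <- min(H0 / m, G0 / n)
  if (hi == 0) return(0)
  f <- function(c) Ka * (H0 - m * c)^m * (G0 - n * c)^n - c
  lo <- 0
  if (f(hi) > 0) return(hi)   # only at hi does the complex exhaust a component
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-12 * max(hi, .Machine$double.xmin)) break
  }
  (lo + hi) / 2
}

#' Simulate a band spectrum
#'
#' Sum of Gaussian bands on a regular wavelength grid, plus i.i.d.
#' Gaussian noise. Reproducible for a fixed seed.
#'
#' @param bands Data frame (or list of lists) with columns/fields
#'   `center` (nm), `width` (Gaussian sigma, nm) and `amplitude` (a.u.).
#'   An empty band list yields an all-noise spectrum, flagged via the
#'   `all_noise` attribute.
#' @param grid Numeric c(min_nm, max_nm, step_nm).
#' @param noise_sd Noise standard deviation (a.u., >= 0).
#' @param seed RNG seed (required).
#' @param kind,solvent,concentration,path_length,excitation_nm Metadata
#'   passed to [spectrum()].
#' @return A [spectrum()].
#' @export
simulate_spectrum <- function(bands, grid = c(220, 600, 1), noise_sd = 0, seed,
                              kind = "absorption", solvent = NA_character_,
                              concentration = NA_real_, path_length = 1,
                              excitation_nm = NA_real_) {
  if (length(grid) != 3L || grid[3] <= 0 || grid[2] <= grid[1])
    .domain_error("grid must be c(min, max, step) with step > 0 and max > min")
  if (is.data.frame(bands)) bands <- lapply(seq_len(nrow(bands)), function(i) bands[i, ])
  for (b in bands) if (b$width <= 0) .domain_error("band width must be positive")
  wl <- seq(grid[1], grid[2], by = grid[3])
  sig <- rep(0, length(wl))
  for (b in bands) sig <- sig + b$amplitude * exp(-(wl - b$center)^2 / (2 * b$width^2))
  if (noise_sd > 0) sig <- sig + .with_seed(seed, rnorm(length(wl), 0, noise_sd))
  out <- spectrum(wl, sig, kind = kind, solvent = solvent,
                  concentration = concentration, path_length = path_length,
                  excitation_nm = excitation_nm)
  attr(out, "all_noise") <- length(bands) == 0L
  out
}

#' Simulate a solvatochromic series
#'
#' Generates one (absorption, emission) spectrum pair per solvent from
#' base band positions plus per-solvent offsets, emulating the
#' progressive red shift of a push-pull fluorophore from non-polar to
#' polar media. Noiseless by construction (band centers land exactly on
#' the wavelength grid when integers), so the photophysics table rebuilt
#' from the series reproduces the specified wavelengths.
#'
#' @param base_lambda_abs Numeric vector of base absorption band centers
#'   (nm), shortest first.
#' @param base_lambda_emi Base emission band center (nm).
#' @param shifts Named list: solvent -> numeric offset vector of length
#'   `length(base_lambda_abs) + 1` (offsets for each absorption band and,
#'   last, for the emission band), in nm.
#' @param abs_amplitudes Absorbance amplitudes of the absorption bands.
#' @param emi_amplitude Emission band amplitude (a.u.).
#' @param band_width Gaussian sigma of every band (nm).
#' @param concentration Chromophore concentration (mol/L) recorded in the
#'   absorption metadata.
#' @param grid Wavelength grid, as in [simulate_spectrum()].
#' @param seed RNG seed (required; used only if `noise_sd > 0`).
#' @param noise_sd Noise SD on both spectra (a.u.).
#' @return Named list (by solvent) of lists with `absorption` and
#'   `emission` spectra, ready for [photophysics_table()].
#' @export
simulate_solvatochromic_series <- function(base_lambda_abs, base_lambda_emi,
                                           shifts,
                                           abs_amplitudes = rep(0.5, length(base_lambda_abs)),
                                           emi_amplitude = 1000,
                                           band_width = 12,
                                           concentration = 1e-5,
                                           grid = c(220, 600, 1),
                                           seed, noise_sd = 0) {
  if (is.null(names(shifts)) || any(!nzchar(names(shifts))))
    .domain_error("shifts must be a named list keyed by solvent")
  nb <- length(base_lambda_abs)
  out <- list()
  sub_seed <- 0L
  for (solvent in names(shifts)) {
    off <- shifts[[solvent]]
    if (length(off) != nb + 1L)
      .domain_error(sprintf("offsets for '%s' must have length %d", solvent, nb + 1L))
    if (any(!is.finite(off))) .domain_error("offsets must be finite")
    abs_bands <- data.frame(center = base_lambda_abs + off[seq_len(nb)],
                            width = band_width, amplitude = abs_amplitudes)
    emi_bands <- data.frame(center = base_lambda_emi + off[nb + 1L],
                            width = band_width, amplitude = emi_amplitude)
    out[[solvent]] <- list(
      absorption = simulate_spectrum(abs_bands, grid, noise_sd,
                                     seed = seed + sub_seed,
                                     kind = "absorption", solvent = solvent,
                                     concentration = concentration),
      emission = simulate_spectrum(emi_bands, grid, noise_sd,
                                   seed = seed + sub_seed + 1L,
                                   kind = "emission", solvent = solvent))
    sub_seed <- sub_seed + 2L
  }
  out
}

#' Simulate a quenching titration
#'
#' Two mechanisms: `"dynamic_SV"` follows the Stern-Volmer law directly,
#' I = I0 / (1 + Ksv q); `"static_complex"` treats every probe-analyte
#' complex as fully dark, I = I0 (1 - \[HG\]/H0) with \[HG\] from the 1:1
#' equilibrium solver (pure static limit). Additive Gaussian noise is
#' applied after the mechanism. In the weak-binding regime
#' (Ka min(H0,q) << 1) the static model reduces to the Stern-Volmer form
#' with apparent Ksv ~= Ka.
#'
#' @param conc_grid Quencher concentrations (mol/L, non-negative,
#'   increasing).
#' @param mechanism `"dynamic_SV"` or `"static_complex"`.
#' @param Ksv Stern-Volmer constant (M^-1; dynamic mechanism).
#' @param Ka Association constant (M^-1; static mechanism).
#' @param I0 Unquenched intensity (a.u.).
#' @param probe_conc Probe concentration H0 (mol/L; static mechanism).
#' @param noise_sd Noise SD (a.u.).
#' @param seed RNG seed (required).
#' @return A [titration_series()] (with the true I0 recorded).
#' @export
simulate_titration <- function(conc_grid, mechanism = c("dynamic_SV", "static_complex"),
                               Ksv = NULL, Ka = NULL, I0 = 1000,
                               probe_conc = 1e-5, noise_sd = 0, seed) {
  mechanism <- match.arg(mechanism)
  conc_grid <- as.numeric(conc_grid)
  if (any(conc_grid < 0) || any(diff(conc_grid) <= 0))
    .domain_error("conc_grid must be non-negative and increasing")
  I <- switch(mechanism,
    dynamic_SV = {
      if (is.null(Ksv)) .domain_error("dynamic_SV requires Ksv")
      I0 / (1 + Ksv * conc_grid)
    },
    static_complex = {
      if (is.null(Ka)) .domain_error("static_complex requires Ka")
      hg <- solve_equilibrium_1_1(probe_conc, conc_grid, Ka)
      I0 * (1 - hg / probe_conc)
    })
  if (noise_sd > 0) I <- I + .with_seed(seed, rnorm(length(I), 0, noise_sd))
  titration_series(conc_grid, I, I0 = I0, probe_conc = probe_conc)
}

#' Simulate a continuous-variation (Job) series
#'
#' Host and guest share a fixed total concentration; the host mole
#' fraction sweeps an even grid strictly inside (0, 1) (exact 0 and 1
#' are excluded to avoid degenerate equilibria). The signal is
#' proportional to the equilibrium complex concentration.
#'
#' @param Ka Association constant (M^-1 for 1:1; overall constant for
#'   m:n).
#' @param C_total Total concentration host + guest (mol/L).
#' @param stoichiometry Integer c(m, n): host and guest coefficients.
#' @param n_points Number of mole fractions (>= 5); grid is
#'   (1:n_points)/(n_points + 1).
#' @param signal_scale Signal per mol/L of complex (a.u.).
#' @param noise_sd Noise SD (a.u.).
#' @param seed RNG seed (required).
#' @return A [job_series()].
#' @export
simulate_job_series <- function(Ka, C_total, stoichiometry = c(1L, 1L),
                                n_points = 11L, signal_scale = 1e7,
                                noise_sd = 0, seed) {
  if (n_points < 5L) .domain_error("need at least 5 mole fractions")
  m <- stoichiometry[1]; n <- stoichiometry[2]
  x <- seq_len(n_points) / (n_points + 1)
  cc <- vapply(x, function(xi) {
    solve_equilibrium_m_n(xi * C_total, (1 - xi) * C_total, Ka, m, n)
  }, numeric(1))
  sig <- signal_scale * cc
  if (noise_sd > 0) sig <- sig + .with_seed(seed, rnorm(length(sig), 0, noise_sd))
  job_series(x, sig)
}

#' Simulate an LOD calibration with blank replicates
#'
#' Linear low-concentration response I = baseline + slope * c plus
#' Gaussian noise of SD `sigma_blank`; blank replicates are drawn from
#' the same noise model at zero concentration, so the recoverable
#' detection limit is 3 sigma_blank / |slope| by construction.
#'
#' @param slope Response slope (a.u. per mol/L).
#' @param sigma_blank Blank/instrument noise SD (a.u.).
#' @param n_points Calibration points (default 12).
#' @param n_blanks Blank replicates (default 20).
#' @param conc_max Top of the calibration range (mol/L, default 5e-8).
#' @param baseline Response at zero concentration (a.u.).
#' @param seed RNG seed (required).
#' @return List with `calibration` (a [titration_series()]) and `blanks`
#'   (numeric vector).
#' @export
simulate_lod_calibration <- function(slope, sigma_blank, n_points = 12L,
                                     n_blanks = 20L, conc_max = 5e-8,
                                     baseline = 100, seed) {
  if (n_blanks < 3L) .domain_error("need >= 3 blank replicates")
  if (n_points < 3L) .domain_error("need >= 3 calibration points")
  conc <- seq(0, conc_max, length.out = n_points)
  noise <- .with_seed(seed, rnorm(n_points + n_blanks, 0, sigma_blank))
  intensity <- baseline + slope * conc +
    (if (sigma_blank > 0) noise[seq_len(n_points)] else 0)
  blanks <- baseline +
    (if (sigma_blank > 0) noise[n_points + seq_len(n_blanks)] else numeric(n_blanks))
  list(calibration = titration_series(conc, intensity, I0 = baseline),
       blanks = blanks)
}
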
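#' Third-octave DPOAE band scheme
#'
#' The five third-octave bands, labelled by their distortion-product centre
#' frequency f_DP, in which zero-latency DPOAE levels are summarised.  Band
#' edges sit at +/- 1/6 octave around each centre; membership is half-open,
#' `[centre * 2^-1/6, centre * 2^1/6)`.
#'
#' @param centers Strictly increasing centre frequencies in Hz.
#' @param width Band width as a fraction of an octave.
#' @return An object of class `band_scheme`.
#' @export
#' @examples
#' band_scheme()$centers
band_scheme <- function(centers = c(1153, 1452, 1830, 2305, 2904),
                        width = 1 / 3) {
  if (any(diff(centers) <= 0)) abort("band centers must be strictly increasing")
  if (width <= 0) abort("band width must be positive")
  structure(list(centers = centers, width = width), class = "band_scheme")
}

#' Convert a distortion-product frequency to the corresponding f2
#'
#' For the 2f1-f2 distortion product measured with a constant primary ratio
#' r = f2/f1, the cochlear generation site is at the f2 place, with
#' \deqn{f_2 = f_{DP} / (2/r - 1).}
#' At the standard r = 1.22 the factor is 1.564.
#'
#' @param f_dp Distortion-product frequency (Hz), vectorised.
#' @param r Primary frequency ratio f2/f1, in (1, 2).
#' @return f2 in Hz.
#' @export
#' @examples
#' fdp_to_f2(1000)        # 1564.1 Hz
#' fdp_to_f2(1830, 1.22)
fdp_to_f2 <- function(f_dp, r = 1.22) {
  if (!is.numeric(r) || length(r) != 1L || r <= 1 || r >= 2) {
    abort("r must lie strictly between 1 and 2 (2/r - 1 must be positive)")
  }
  f_dp / (2 / r - 1)
}

default_fdp_grid <- function() seq(1000, 4000, by = 20)

#' Synthesize elementary DPOAE complex spectra
#'
#' Builds `n` repeated complex 2f1-f2 spectra on a uniform f_DP grid as the
#' sum of a zero-latency (distortion) component with slow phase rotation, a
#' coherent-reflection component with long delay and fast phase rotation,
#' and independent complex Gaussian measurement noise.  The interference of
#' the two components produces the quasi-periodic fine structure with ripple
#' spacing approximately `1/refl_delay`.
#'
#' Levels are in dB re an arbitrary unit pressure; `-Inf` disables a
#' component.
#'
#' @param zl_level,refl_level Component levels, dB.
#' @param zl_delay,refl_delay Component delays, ms (> 0).
#' @param noise_level Per-bin noise power level, dB (`-Inf` for none).
#' @param n Number of elementary repetitions (default 20).
#' @param f_dp Uniform frequency grid, Hz (default 1--4 kHz in 20 Hz steps).
#' @param seed Integer seed.
#' @return Tibble with columns `rep`, `f_dp`, `p` (complex pressure), with
#'   attributes `n_averages`, `r`, `L1`, `L2`.
#' @export
synthesize_spectrum <- function(zl_level = 10, refl_level = 0,
                                zl_delay = 0.5, refl_delay = 10,
                                noise_level = -20, n = 20L,
                                f_dp = default_fdp_grid(), seed = 1L) {
  if (zl_delay <= 0 || refl_delay <= 0) abort("component delays must be > 0")
  if (n < 1L) abort("repetition count must be positive")
  check_uniform_grid(f_dp)
  set.seed(seed)

  amp <- function(db) if (is.infinite(db) && db < 0) 0 else 10^(db / 20)
  tau_zl <- zl_delay / 1000
  tau_rf <- refl_delay / 1000
  zl <- amp(zl_level) * exp(-2i * pi * f_dp * tau_zl)
  rf <- amp(refl_level) * exp(-2i * pi * f_dp * tau_rf)
  signal <- zl + rf

  sigma2 <- if (is.infinite(noise_level) && noise_level < 0) 0 else
    10^(noise_level / 10)
  m <- length(f_dp)
  purrr::map_dfr(seq_len(n), function(k) {
    noise <- complex(
      real = rnorm(m, 0, sqrt(sigma2 / 2)),
      imaginary = rnorm(m, 0, sqrt(sigma2 / 2))
    )
    tibble(rep = k, f_dp = f_dp, p = signal + noise)
  }) %>%
    structure(n_averages = n, r = 1.22, L1 = 61, L2 = 55)
}

check_uniform_grid <- function(f_dp) {
  if (length(f_dp) < 4L) abort("frequency grid too short")
  d <- diff(f_dp)
  if (any(abs(d - d[1]) > 1e-9 * d[1])) abort("frequency grid must be uniform")
  invisible(d[1])
}

#' Coherently average repeated DPOAE spectra
#'
#' Averages the complex spectra across repetitions (preserving phase, so
#' uncorrelated noise cancels as 1/N in power) and estimates the noise floor
#' of the average from the half-differences of paired repetitions.  The
#' per-frequency SNR is the averaged-signal level minus the noise-floor
#' level.
#'
#' @param spectra Tibble from [synthesize_spectrum()] (columns `rep`,
#'   `f_dp`, `p`) with at least 2 repetitions.
#' @param floor_db Guard value for a vanishing noise-floor estimate, dB.
#' @return List with `spectrum` (tibble `f_dp`, `p`) and `snr` (tibble
#'   `f_dp`, `signal_db`, `noise_db`, `snr_db`).
#' @export
coherent_average <- function(spectra, floor_db = -120) {
  stopifnot(all(c("rep", "f_dp", "p") %in% names(spectra)))
  reps <- sort(unique(spectra$rep))
  n <- length(reps)
  if (n < 2L) abort("need at least 2 repetitions to estimate a noise floor")

  f <- sort(unique(spectra$f_dp))
  mat <- matrix(NA_complex_, length(f), n,
                dimnames = list(NULL, as.character(reps)))
  for (k in seq_along(reps)) {
    sub <- spectra[spectra$rep == reps[k], ]
    mat[, k] <- sub$p[order(sub$f_dp)]
  }
  avg <- rowMeans(mat)

  n_pairs <- n %/% 2
  d <- (mat[, 2 * seq_len(n_pairs) - 1, drop = FALSE] -
          mat[, 2 * seq_len(n_pairs), drop = FALSE]) / 2
  # E|d|^2 = sigma^2/2 per repetition; the N-average noise power is sigma^2/N
  floor_power <- rowMeans(Mod(d)^2) * 2 / n
  floor_power <- pmax(floor_power, 10^(floor_db / 10))

  signal_db <- 10 * log10(pmax(Mod(avg)^2, 10^(floor_db / 10)))
  noise_db <- 10 * log10(floor_power)
  list(
    spectrum = tibble(f_dp = f, p = avg),
    snr = tibble(f_dp = f, signal_db = signal_db, noise_db = noise_db,
                 snr_db = signal_db - noise_db)
  )
}

#' Extract the zero-latency DPOAE component
#'
#' Transforms the complex spectrum to the delay (latency) domain with a
#' discrete Fourier transform over the uniform frequency grid, zeroes all
#' energy at latencies above `latency_cutoff`, and transforms back.  The
#' short-latency nonlinear-distortion component (delay well under the
#' cutoff) passes; the long-latency coherent-reflection component is
#' removed, and with it the amplitude fine structure their interference
#' creates.  The operation is an orthogonal projection: applying it twice
#' changes nothing, and total power never increases.
#'
#' @param spectrum Tibble with columns `f_dp`, `p` on a uniform grid.
#' @param latency_cutoff Latency gate in ms; must lie in
#'   (0, 1/(2 * grid spacing)) (25 ms for the default 20 Hz grid).
#' @return Tibble `f_dp`, `p` on the same grid.
#' @export
unmix_zero_latency <- function(spectrum, latency_cutoff = 4) {
  stopifnot(all(c("f_dp", "p") %in% names(spectrum)))
  spectrum <- spectrum[order(spectrum$f_dp), ]
  df <- check_uniform_grid(spectrum$f_dp)
  max_delay_ms <- 1000 / (2 * df)
  if (latency_cutoff <= 0 || latency_cutoff >= max_delay_ms) {
    abort(sprintf(
      "latency_cutoff must lie in (0, %.6g) ms for a %g Hz grid",
      max_delay_ms, df
    ))
  }
  p <- spectrum$p
  n <- length(p)
  g <- fft(p)
  k <- seq_len(n) - 1L
  tau_ms <- ifelse(k <= n / 2, k, k - n) / (n * df) * 1000
  g[abs(tau_ms) > latency_cutoff] <- 0
  tibble(f_dp = spectrum$f_dp, p = fft(g, inverse = TRUE) / n)
}

#' Third-octave band levels of a DPOAE spectrum
#'
#' For each band of the scheme, the level is `10 log10` of the mean power
#' of the bins whose f_DP falls in the half-open band
#' `[centre * 2^-w/2, centre * 2^w/2)`.
#'
#' @param spectrum Tibble with columns `f_dp`, `p`.
#' @param scheme A [band_scheme()].
#' @return Tibble with columns `band` (label `DP<centre>`), `center`,
#'   `level_db`, `n_bins`.
#' @export
band_levels <- function(spectrum, scheme = band_scheme()) {
  stopifnot(all(c("f_dp", "p") %in% names(spectrum)))
  half <- 2^(scheme$width / 2)
  power <- Mod(spectrum$p)^2
  purrr::map_dfr(scheme$centers, function(ctr) {
    sel <- spectrum$f_dp >= ctr / half & spectrum$f_dp < ctr * half
    if (!any(sel)) {
      abort(sprintf("band centred at %g Hz contains no frequency bins", ctr))
    }
    tibble(
      band = paste0("DP", ctr), center = ctr,
      level_db = 10 * log10(mean(power[sel])), n_bins = sum(sel)
    )
  })
}
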
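# Synthetic regional time series and two-group cohorts with known,
# controllable theta/alpha-gamma coupling. Signal model:
#
#   x(t) = lf_amplitude * cos(theta(t))
#        + hf_amplitude * m(t) * cos(2*pi*f_amp*t + psi0)
#        + 1/f^alpha Gaussian noise, sd = noise_sd
#
#   m(t) = (1 + kappa * cos(theta(t) - preferred_phase)) / (1 + kappa)
#
# theta(t) is the low-frequency phase. With lf_bandwidth > 0 (default) it is
# the instantaneous phase of a narrowband Gaussian process centred on
# f_phase, so the phase diffuses as it does in resting M/EEG; this is what
# makes time-lag surrogates informative (lagging a strictly periodic
# envelope against a periodic phase only rotates the mean vector, it never
# shortens it). lf_bandwidth = 0 recovers the deterministic sinusoid
# theta = 2*pi*f_phase*t + phi0 with phi0 ~ uniform(-pi, pi].

#' Coupling specification for one synthetic signal
#'
#' Defines the oscillatory content and the phase-amplitude coupling of one
#' generated regional time series.
#'
#' @param f_phase low-frequency (phase-giving) centre frequency in Hz,
#'   within \[4, 12\].
#' @param f_amp gamma (amplitude-giving) centre frequency in Hz, within
#'   \[30, 40\].
#' @param kappa coupling depth, >= 0; 0 means the gamma envelope is
#'   independent of low-frequency phase.
#' @param preferred_phase low-frequency phase (radians, (-pi, pi\]) at which
#'   the gamma envelope is maximal.
#' @param lf_amplitude amplitude of the low-frequency oscillation (> 0).
#' @param hf_amplitude peak amplitude of the gamma oscillation (>= 0).
#' @param noise_sd standard deviation of the 1/f^alpha background (>= 0).
#' @param noise_exponent spectral slope alpha of the background (>= 0;
#'   0 = white).
#' @param lf_bandwidth full bandwidth in Hz of the stochastic low-frequency
#'   phase process; 0 gives a deterministic sinusoid.
#' @return a `coupling_spec` object (a validated list).
#' @export
#' @examples
#' coupling_spec(kappa = 1)
coupling_spec <- function(f_phase = 6.5, f_amp = 34.5, kappa = 0,
                          preferred_phase = pi / 2, lf_amplitude = 1,
                          hf_amplitude = 0.25, noise_sd = 0.8,
                          noise_exponent = 1, lf_bandwidth = 0.8) {
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number", nm))
    }
    v
  }
  f_phase <- num1(f_phase, "f_phase")
  f_amp <- num1(f_amp, "f_amp")
  if (f_phase >= f_amp) abort("`f_phase` must be below `f_amp`")
  if (f_phase < 4 || f_phase > 12) abort("`f_phase` must lie in [4, 12] Hz")
  if (f_amp < 30 || f_amp > 40) abort("`f_amp` must lie in [30, 40] Hz")
  if (num1(kappa, "kappa") < 0) abort("`kappa` must be >= 0")
  num1(preferred_phase, "preferred_phase")
  if (num1(lf_amplitude, "lf_amplitude") <= 0) abort("`lf_amplitude` must be > 0")
  if (num1(hf_amplitude, "hf_amplitude") < 0) abort("`hf_amplitude` must be >= 0")
  if (num1(noise_sd, "noise_sd") < 0) abort("`noise_sd` must be >= 0")
  if (num1(noise_exponent, "noise_exponent") < 0) abort("`noise_exponent` must be >= 0")
  if (num1(lf_bandwidth, "lf_bandwidth") < 0) abort("`lf_bandwidth` must be >= 0")
  structure(
    list(
      f_phase = f_phase, f_amp = f_amp, kappa = kappa,
      preferred_phase = preferred_phase, lf_amplitude = lf_amplitude,
      hf_amplitude = hf_amplitude, noise_sd = noise_sd,
      noise_exponent = noise_exponent, lf_bandwidth = lf_bandwidth
    ),
    class = "coupling_spec"
  )
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf(
    "<coupling_spec> f_phase=%g Hz f_amp=%g Hz kappa=%g pref=%.2f rad lf=%g hf=%g noise=%g (1/f^%g) lf_bw=%g Hz\n",
    x$f_phase, x$f_amp, x$kappa, x$preferred_phase, x$lf_amplitude,
    x$hf_amplitude, x$noise_sd, x$noise_exponent, x$lf_bandwidth
  ))
  invisible(x)
}

#' 1/f^alpha Gaussian noise
#'
#' White Gaussian noise spectrally shaped to a power-law spectrum by scaling
#' its Fourier coefficients by f^(-alpha/2), then rescaled to the requested
#' sample standard deviation.
#'
#' @param n number of samples (>= 2).
#' @param exponent spectral slope alpha (>= 0; 0 gives white noise).
#' @param sd target sample standard deviation; 0 returns the zero vector.
#' @param seed optional integer seed (caller's RNG state is preserved).
#' @return numeric vector of length `n`.
#' @export
#' @examples
#' z <- generate_pink_noise(10000, exponent = 1, sd = 2, seed = 1)
#' sd(z)
generate_pink_noise <- function(n, exponent = 1, sd = 1, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) abort("`n` must be >= 2")
  if (!is.numeric(exponent) || exponent < 0) abort("`exponent` must be >= 0")
  if (!is.numeric(sd) || sd < 0) abort("`sd` must be >= 0")
  n <- as.integer(n)
  if (sd == 0) {
    return(numeric(n))
  }
  with_seed(seed, {
    w <- rnorm(n)
    # symmetric frequency index: 1 for DC slot, then min(k, n-k)
    fi <- pmin(c(1, seq_len(n - 1)), c(1, n - seq_len(n - 1)))
    g <- fi^(-exponent / 2)
    g[1] <- 0 # remove DC
    x <- Re(fft(fft(w) * g, inverse = TRUE) / n)
    sd * x / stats::sd(x)
  })
}

# Low-frequency phase trajectory: stochastic (narrowband process) or
# deterministic (pure sinusoid). Returns radians, length n.
lf_phase_track <- function(spec, fs, n) {
  if (spec$lf_bandwidth > 0) {
    lo <- max(0.1, spec$f_phase - spec$lf_bandwidth / 2)
    hi <- min(fs / 2 - 0.1, spec$f_phase + spec$lf_bandwidth / 2)
    Arg(band_analytic(rnorm(n), c(lo, hi), fs = fs))
  } else {
    phi0 <- runif(1, -pi, pi)
    2 * pi * spec$f_phase * seq_len(n) / fs + phi0
  }
}

#' Generate one synthetic coupled signal
#'
#' Produces a regional time series in which the gamma-band envelope is
#' modulated by the low-frequency phase with depth `kappa` and is maximal at
#' `preferred_phase`, embedded in 1/f background noise. See
#' [coupling_spec()] for the signal model parameters.
#'
#' @param spec a [coupling_spec()].
#' @param fs sampling rate in Hz; must exceed `2 * f_amp`.
#' @param duration signal length in seconds; at least `10 / f_phase`.
#' @param seed optional integer seed for reproducibility.
#' @param subject_id,group,region labels attached to the output.
#' @return a [regional_ts()] of `floor(fs * duration)` samples.
#' @export
#' @examples
#' x <- generate_coupled_signal(coupling_spec(kappa = 1), fs = 200,
#'                              duration = 20, seed = 1)
#' x
generate_coupled_signal <- function(spec, fs = 600, duration = 60,
                                    seed = NULL, subject_id = NA, group = NA,
                                    region = NA) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (fs <= 2 * spec$f_amp) {
    abort(sprintf("`fs` (%g) must exceed 2 * f_amp (%g)", fs, 2 * spec$f_amp))
  }
  if (duration < 10 / spec$f_phase) {
    abort(sprintf("`duration` must be at least 10 / f_phase = %.2f s",
                  10 / spec$f_phase))
  }
  n <- floor(fs * duration)
  samples <- with_seed(seed, {
    theta <- lf_phase_track(spec, fs, n)
    m <- (1 + spec$kappa * cos(theta - spec$preferred_phase)) / (1 + spec$kappa)
    psi0 <- runif(1, -pi, pi)
    gamma <- spec$hf_amplitude * m * cos(2 * pi * spec$f_amp * seq_len(n) / fs + psi0)
    noise <- generate_pink_noise(n, spec$noise_exponent, spec$noise_sd)
    spec$lf_amplitude * cos(theta) + gamma + noise
  })
  regional_ts(samples, fs = fs, subject_id = subject_id, group = group,
              region = region)
}

#' Two-group synthetic cohort specification
#'
#' @param n_group_a,n_group_b subjects per group (>= 2).
#' @param regions character vector of region labels (non-empty).
#' @param coupling_a,coupling_b a single [coupling_spec()] applied to every
#'   region, or a named list of `coupling_spec`s keyed by region label.
#' @param fs sampling rate in Hz (default 600, matching MEG acquisition).
#' @param duration seconds per signal (default 60, one resting epoch).
#' @param seed master integer seed; per-subject/region seeds are derived by
#'   stable hashing so the cohort is reproducible and order-independent.
#' @param group_labels length-2 character, labels for the two groups.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_group_a, n_group_b, regions,
                        coupling_a = coupling_spec(),
                        coupling_b = coupling_spec(),
                        fs = 600, duration = 60, seed = 1,
                        group_labels = c("A", "B")) {
  if (!is.numeric(n_group_a) || n_group_a < 2 ||
      !is.numeric(n_group_b) || n_group_b < 2) {
    abort("group sizes must be at least 2")
  }
  if (!is.character(regions) || length(regions) == 0) {
    abort("`regions` must be a non-empty character vector")
  }
  if (anyDuplicated(regions)) abort("`regions` must be unique")
  if (length(group_labels) != 2 || anyDuplicated(group_labels)) {
    abort("`group_labels` must be two distinct labels")
  }
  norm_coupling <- function(cp, nm) {
    if (inherits(cp, "coupling_spec")) {
      cp <- stats::setNames(rep(list(cp), length(regions)), regions)
    }
    if (!is.list(cp) || !setequal(names(cp), regions) ||
        !all(vapply(cp, inherits, TRUE, "coupling_spec"))) {
      abort(sprintf(
        "`%s` must be a coupling_spec or a named list of coupling_specs covering all regions",
        nm
      ))
    }
    cp[regions]
  }
  structure(
    list(
      n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
      regions = regions,
      coupling_a = norm_coupling(coupling_a, "coupling_a"),
      coupling_b = norm_coupling(coupling_b, "coupling_b"),
      fs = fs, duration = duration, seed = as.integer(seed),
      group_labels = group_labels
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d + %d subjects (%s/%s), %d region(s), fs=%g Hz, %g s, seed=%d\n",
    x$n_group_a, x$n_group_b, x$group_labels[1], x$group_labels[2],
    length(x$regions), x$fs, x$duration, x$seed
  ))
  invisible(x)
}

#' Generate a two-group cohort of regional time series
#'
#' One signal per subject x region, with per-subject random phase offsets
#' and noise. Deterministic under a fixed `seed` in the cohort spec: the
#' seed of each signal is derived from (seed, subject, region) by stable
#' hashing, so any single signal can be regenerated in isolation.
#'
#' @param spec a [cohort_spec()].
#' @return a tibble with columns `subject_id`, `group`, `region`, `fs`, and
#'   a list-column `ts` of [regional_ts()] objects.
#' @export
#' @examples
#' spec <- cohort_spec(2, 2, "r1", fs = 200, duration = 10,
#'                     coupling_a = coupling_spec(f_phase = 4),
#'                     coupling_b = coupling_spec(f_phase = 4))
#' generate_cohort(spec)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- tibble::tibble(
    subject_id = sprintf(
      "%s%02d",
      rep(tolower(spec$group_labels), c(spec$n_group_a, spec$n_group_b)),
      c(seq_len(spec$n_group_a), seq_len(spec$n_group_b))
    ),
    group = rep(spec$group_labels, c(spec$n_group_a, spec$n_group_b))
  )
  grid <- tidyr::expand_grid(subjects, region = spec$regions)
  grid |>
    dplyr::mutate(
      fs = spec$fs,
      ts = purrr::pmap(
        list(.data$subject_id, .data$group, .data$region),
        function(sid, grp, reg) {
          cp <- if (grp == spec$group_labels[1]) {
            spec$coupling_a[[reg]]
          } else {
            spec$coupling_b[[reg]]
          }
          generate_coupled_signal(
            cp, fs = spec$fs, duration = spec$duration,
            seed = hash_seed(spec$seed, sid, reg),
            subject_id = sid, group = grp, region = reg
          )
        }
      )
    )
}
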
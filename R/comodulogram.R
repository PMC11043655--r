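# Per-subject, per-region PAC grids over all 1 Hz phase x 1 Hz amplitude
# bins (default 8 x 10 = 80 cells).

#' Comodulogram grid specification
#'
#' @param phase_edges increasing numeric vector of phase-bin edges in Hz;
#'   default `4:12` gives eight 1 Hz half-open bins \[f, f+1).
#' @param amp_edges increasing numeric vector of amplitude-bin edges in Hz;
#'   default `30:40` gives ten 1 Hz bins.
#' @param n_surrogates surrogate count per cell (default 200).
#' @param min_lag minimal surrogate lag in seconds.
#' @param trim edge trim in seconds.
#' @param amp_band_expand either a number of Hz by which each amplitude
#'   filter band is widened on both sides (0 = filter the literal bin), or
#'   `"match"`, which widens each amplitude band by the centre frequency of
#'   the phase bin it is paired with, so the band can carry modulation
#'   sidebands at carrier +/- f_phase (the usual "amplitude bandwidth at
#'   least twice the phase frequency" rule). Grid labelling always keeps
#'   the nominal bin.
#' @param seed master integer seed; each cell's surrogate stream is derived
#'   from (seed, subject, region, phase_lo, amp_lo) by stable hashing.
#' @param method,transition filter options, see [band_analytic()].
#' @return a `grid_spec` object.
#' @export
#' @examples
#' grid_spec()          # the default 80-cell grid
grid_spec <- function(phase_edges = 4:12, amp_edges = 30:40,
                      n_surrogates = 200, min_lag = 1, trim = 1,
                      amp_band_expand = 0, seed = 1,
                      method = c("spectral", "butterworth"),
                      transition = 0.25) {
  check_edges <- function(e, nm) {
    if (!is.numeric(e) || length(e) < 2 || any(diff(e) <= 0)) {
      abort(sprintf("`%s` must be an increasing numeric vector (>= 2 values)", nm))
    }
    e
  }
  check_edges(phase_edges, "phase_edges")
  check_edges(amp_edges, "amp_edges")
  if (!(identical(amp_band_expand, "match") ||
        (is.numeric(amp_band_expand) && length(amp_band_expand) == 1 &&
         amp_band_expand >= 0))) {
    abort('`amp_band_expand` must be a nonnegative number or "match"')
  }
  structure(
    list(
      phase_edges = phase_edges, amp_edges = amp_edges,
      n_surrogates = as.integer(n_surrogates), min_lag = min_lag,
      trim = trim, amp_band_expand = amp_band_expand,
      seed = as.integer(seed), method = match.arg(method),
      transition = transition
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d phase bins [%g-%g Hz] x %d amplitude bins [%g-%g Hz] = %d cells; %d surrogates; expand=%s; %s filter\n",
    length(x$phase_edges) - 1, min(x$phase_edges), max(x$phase_edges),
    length(x$amp_edges) - 1, min(x$amp_edges), max(x$amp_edges),
    (length(x$phase_edges) - 1) * (length(x$amp_edges) - 1),
    x$n_surrogates, format(x$amp_band_expand), x$method
  ))
  invisible(x)
}

#' Compute a PAC comodulogram grid for one signal
#'
#' One [normalized_pac()] cell per (phase bin, amplitude bin) pair. Phase
#' and envelope series are extracted once per distinct filter band and
#' shared across cells; results are independent of cell evaluation order
#' because each cell's surrogate seed is derived by stable hashing.
#'
#' @param x a [regional_ts()] (labels are carried into the output) or a
#'   numeric vector with `fs`.
#' @param spec a [grid_spec()].
#' @param fs sampling rate, only for bare numeric `x`.
#' @return a tibble of class `pac_grid`, one row per cell, with the
#'   subject/group/region labels and the columns of [normalized_pac()].
#' @export
#' @examples
#' x <- generate_coupled_signal(coupling_spec(kappa = 1), fs = 200,
#'                              duration = 20, seed = 1)
#' g <- compute_grid(x, grid_spec(n_surrogates = 50, amp_band_expand = "match"))
#' dplyr::arrange(g, dplyr::desc(m_norm))
compute_grid <- function(x, spec = grid_spec(), fs = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  sig <- as_signal(x, fs)
  n <- length(sig$samples)
  if (n < 10 * sig$fs) {
    abort("signal must be at least 10 s long for a stable mean vector")
  }
  k <- round(spec$trim * sig$fs)
  idx <- (k + 1):(n - k)
  n_ph <- length(spec$phase_edges) - 1
  n_am <- length(spec$amp_edges) - 1

  phase_cache <- lapply(seq_len(n_ph), function(i) {
    phase_series(sig, spec$phase_edges[i + (0:1)],
                 method = spec$method, transition = spec$transition)[idx]
  })
  amp_cache <- new.env(parent = emptyenv())
  get_amp <- function(band) {
    key <- paste(format(band, digits = 10), collapse = "_")
    if (is.null(amp_cache[[key]])) {
      amp_cache[[key]] <- amplitude_series(
        sig, band, method = spec$method, transition = spec$transition
      )[idx]
    }
    amp_cache[[key]]
  }

  cells <- vector("list", n_ph * n_am)
  pos <- 0L
  for (i in seq_len(n_ph)) {
    p_lo <- spec$phase_edges[i]
    p_hi <- spec$phase_edges[i + 1]
    expand <- if (identical(spec$amp_band_expand, "match")) {
      (p_lo + p_hi) / 2
    } else {
      spec$amp_band_expand
    }
    ph <- phase_cache[[i]]
    for (j in seq_len(n_am)) {
      a_lo <- spec$amp_edges[j]
      a_hi <- spec$amp_edges[j + 1]
      band <- c(max(0.05, a_lo - expand), min(sig$fs / 2 - 0.05, a_hi + expand))
      am <- get_amp(band)
      m_raw <- raw_mean_vector(composite_signal(am, ph))
      surro <- surrogate_mvls(
        am, ph, sig$fs, n_surrogates = spec$n_surrogates,
        min_lag = spec$min_lag,
        seed = hash_seed(spec$seed, sig$subject_id, sig$region, p_lo, a_lo)
      )
      mu <- mean(surro)
      sigma <- stats::sd(surro)
      if (!is.finite(sigma) || sigma <= 0) {
        abort(sprintf(
          "degenerate surrogate distribution (sigma = 0) at cell [%g,%g) x [%g,%g)",
          p_lo, p_hi, a_lo, a_hi
        ))
      }
      pos <- pos + 1L
      cells[[pos]] <- tibble::tibble(
        phase_lo = p_lo, phase_hi = p_hi, amp_lo = a_lo, amp_hi = a_hi,
        m_raw_re = Re(m_raw), m_raw_im = Im(m_raw), mu = mu, sigma = sigma,
        m_norm = (Mod(m_raw) - mu) / sigma,
        phi_norm_deg = wrap_deg(Arg(m_raw) * 180 / pi)
      )
    }
  }
  out <- dplyr::bind_cols(
    tibble::tibble(
      subject_id = sig$subject_id, group = sig$group, region = sig$region
    )[rep(1, n_ph * n_am), ],
    dplyr::bind_rows(cells)
  )
  attr(out, "grid_spec") <- spec
  class(out) <- c("pac_grid", class(out))
  out
}

#' Compute PAC grids for every signal of a cohort
#'
#' @param cohort a tibble from [generate_cohort()] (or with the same shape:
#'   a `ts` list-column of [regional_ts()] objects).
#' @param spec a [grid_spec()].
#' @return a tibble of class `pac_grids`: the row-bound [compute_grid()]
#'   results for all subjects and regions.
#' @export
compute_cohort_grids <- function(cohort, spec = grid_spec()) {
  if (!is.data.frame(cohort) || !"ts" %in% names(cohort)) {
    abort("`cohort` must be a data frame with a `ts` list-column")
  }
  out <- purrr::list_rbind(purrr::map(cohort$ts, compute_grid, spec = spec))
  attr(out, "grid_spec") <- spec
  class(out) <- c("pac_grids", "pac_grid", class(out))
  out
}

#' Select a rectangular sub-block of grid cells
#'
#' Logical mask over the rows of a grid (or of any per-cell table with
#' `phase_lo`/`amp_lo` columns), true exactly for bins fully inside the
#' given frequency ranges. Ranges must align with bin edges.
#'
#' @param grid a `pac_grid` tibble (or per-cell table).
#' @param phase_range,amp_range numeric length-2 ranges in Hz.
#' @return logical vector, one element per row of `grid`.
#' @export
#' @examples
#' g <- tidyr::expand_grid(phase_lo = 4:11, amp_lo = 30:39)
#' g$phase_hi <- g$phase_lo + 1; g$amp_hi <- g$amp_lo + 1
#' sum(grid_submask(g, c(6, 8), c(30, 40)))  # 20 cells
grid_submask <- function(grid, phase_range, amp_range) {
  stopifnot(is.data.frame(grid))
  for (cl in c("phase_lo", "phase_hi", "amp_lo", "amp_hi")) {
    if (!cl %in% names(grid)) abort(sprintf("`grid` lacks column `%s`", cl))
  }
  align <- function(range, lo, hi, nm) {
    if (length(range) != 2 || range[1] >= range[2]) {
      abort(sprintf("`%s` must be an increasing length-2 range", nm))
    }
    edges <- sort(unique(c(lo, hi)))
    if (!all(range %in% edges)) {
      abort(sprintf("`%s` does not align with bin edges", nm))
    }
  }
  align(phase_range, grid$phase_lo, grid$phase_hi, "phase_range")
  align(amp_range, grid$amp_lo, grid$amp_hi, "amp_range")
  grid$phase_lo >= phase_range[1] & grid$phase_hi <= phase_range[2] &
    grid$amp_lo >= amp_range[1] & grid$amp_hi <= amp_range[2]
}

#' Welch power spectral density (quality-control helper)
#'
#' Mean periodogram over Hann-windowed, 50%-overlapping segments. Intended
#' for eyeballing that a recording (or synthetic signal) has the expected
#' spectral peaks and 1/f background before PAC analysis.
#'
#' @param x a [regional_ts()] or numeric vector.
#' @param fs sampling rate for bare numeric input.
#' @param seg_seconds segment length in seconds (default 2).
#' @return a tibble with columns `freq` (Hz, to fs/2) and `power` (density,
#'   signal units^2 / Hz).
#' @export
#' @examples
#' fs <- 200
#' spec <- qc_psd(sin(2 * pi * 10 * seq_len(10 * fs) / fs), fs = fs)
#' spec$freq[which.max(spec$power)]  # ~10 Hz
qc_psd <- function(x, fs = NULL, seg_seconds = 2) {
  sig <- as_signal(x, fs)
  n <- length(sig$samples)
  nseg <- round(seg_seconds * sig$fs)
  if (n < 2 * sig$fs || n < nseg) {
    abort("signal too short for a Welch estimate (need at least 2 s and one segment)")
  }
  step <- max(1, floor(nseg / 2))
  starts <- seq(1, n - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1)) # Hann
  norm <- sum(w^2) * sig$fs
  half <- floor(nseg / 2) + 1
  acc <- numeric(half)
  for (s in starts) {
    seg <- sig$samples[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / norm
    acc <- acc + p[seq_len(half)]
  }
  p <- acc / length(starts)
  # one-sided density: double the interior bins
  if (half > 2) p[2:(half - 1)] <- 2 * p[2:(half - 1)]
  tibble::tibble(
    freq = (seq_len(half) - 1) * sig$fs / nseg,
    power = p
  )
}
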
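# Shared fixtures, all generated in code.

# Canonical cell table of the default 8 x 10 grid, in (phase_lo, amp_lo) order.
default_cells <- function() {
  out <- tidyr::expand_grid(phase_lo = 4:11, amp_lo = 30:39)
  out$phase_hi <- out$phase_lo + 1
  out$amp_hi <- out$amp_lo + 1
  out[, c("phase_lo", "phase_hi", "amp_lo", "amp_hi")]
}

# Build a cohort grid table from an explicit subjects x cells matrix of
# m_norm values (cells in canonical order); complex cell values default to
# m_norm + 0i.
fake_grids <- function(values, groups, cells = default_cells(),
                       region = "r1", m_raw = NULL) {
  stopifnot(ncol(values) == nrow(cells), nrow(values) == length(groups))
  if (is.null(m_raw)) m_raw <- values + 0i
  rows <- lapply(seq_len(nrow(values)), function(s) {
    dplyr::mutate(
      cells,
      subject_id = sprintf("s%02d", s),
      group = groups[s],
      region = region,
      m_raw_re = Re(m_raw[s, ]),
      m_raw_im = Im(m_raw[s, ]),
      m_norm = values[s, ]
    )
  })
  dplyr::bind_rows(rows)
}

# Independent connected-components oracle: breadth-first search over the
# supra-threshold mask of a t-matrix (rows = phase bins, cols = amp bins).
# Returns a list of clusters with sorted member indices and signed mass.
bfs_clusters <- function(tm, t_crit, adjacency = 4) {
  nr <- nrow(tm)
  nc <- ncol(tm)
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tm > t_crit else tm < -t_crit
    seen <- matrix(FALSE, nr, nc)
    for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
      if (!mask[r0, c0] || seen[r0, c0]) next
      queue <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      members <- integer(0)
      while (length(queue) > 0) {
        cur <- queue[[1]]
        queue <- queue[-1]
        members <- c(members, (cur[1] - 1L) * nc + cur[2])
        offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
        if (adjacency == 8) {
          offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
        }
        for (o in offs) {
          r <- cur[1] + o[1]
          cc <- cur[2] + o[2]
          if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
              mask[r, cc] && !seen[r, cc]) {
            seen[r, cc] <- TRUE
            queue[[length(queue) + 1L]] <- c(r, cc)
          }
        }
      }
      out[[length(out) + 1L]] <- list(
        cells = sort(members),
        mass = sum(tm[matrix(c((members - 1L) %/% nc + 1L,
                               (members - 1L) %% nc + 1L), ncol = 2)])
      )
    }
  }
  out
}

# Cluster list of a pac_clusters tibble in the same (cells, mass) form as
# the oracle, for set comparison.
clusters_as_sets <- function(clusters, n_am = 10) {
  lapply(seq_len(nrow(clusters)), function(i) {
    cdf <- clusters$cells[[i]]
    idx <- sort((cdf$phase_lo - 4L) * n_am + (cdf$amp_lo - 30L) + 1L)
    list(cells = idx, mass = clusters$mass[i])
  })
}

# Small coupled test signal with the generator's default amplitudes/noise.
make_signal <- function(kappa = 1, seed = 1, fs = 200, duration = 20, ...) {
  generate_coupled_signal(coupling_spec(kappa = kappa, ...),
                          fs = fs, duration = duration, seed = seed)
}

# Single-cell PAC at the seeded (6-7 Hz, 34-35 Hz) cell with the matched
# amplitude bandwidth used throughout the coupling-recovery checks.
seeded_cell <- function(x, n_surrogates = 50, seed = 1) {
  normalized_pac(x, c(6, 7), c(34, 35), amp_band_expand = 6.5,
                 n_surrogates = n_surrogates, seed = seed)
}
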
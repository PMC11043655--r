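# Two-group comparison of PAC grids: per-cell independent t-tests,
# cluster formation on the grid under 4-neighbour adjacency, a max-cluster
# permutation null, and circular mean-phase-angle summaries.

# --- internal: canonical per-subject matrix form ---------------------------

# Reshape a cohort grid table into a subjects x cells matrix of m_norm,
# with subjects in a canonical order (group a first, subject_id sorted) and
# cells sorted by (phase_lo, amp_lo). Canonical ordering makes every
# downstream statistic independent of input row order, including the
# permutation stream.
grids_matrix <- function(grids, group_a, group_b, value = "m_norm") {
  stopifnot(is.data.frame(grids))
  need <- c("subject_id", "group", "region", "phase_lo", "amp_lo", value)
  miss <- setdiff(need, names(grids))
  if (length(miss)) {
    abort(paste0("`grids` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (dplyr::n_distinct(grids$region) != 1) {
    abort("`grids` must contain exactly one region; filter first (the test is run per region)")
  }
  grids <- dplyr::filter(grids, .data$group %in% c(group_a, group_b))
  if (nrow(grids) == 0) abort("no rows for the requested groups")
  cells <- grids |>
    dplyr::distinct(.data$phase_lo, .data$phase_hi, .data$amp_lo, .data$amp_hi) |>
    dplyr::arrange(.data$phase_lo, .data$amp_lo)
  subjects <- grids |>
    dplyr::distinct(.data$subject_id, .data$group) |>
    dplyr::arrange(match(.data$group, c(group_a, group_b)), .data$subject_id)
  if (anyDuplicated(subjects$subject_id)) {
    abort("a subject_id appears in both groups")
  }
  wide <- grids |>
    dplyr::arrange(match(.data$subject_id, subjects$subject_id),
                   .data$phase_lo, .data$amp_lo)
  if (nrow(wide) != nrow(subjects) * nrow(cells)) {
    abort("grid shape mismatch: every subject must have the same full set of cells")
  }
  V <- matrix(wide[[value]], nrow = nrow(subjects), ncol = nrow(cells),
              byrow = TRUE)
  list(V = V, subjects = subjects, cells = cells,
       is_a = subjects$group == group_a)
}

# Vectorized equal-variance two-sample t over the columns of V.
col_ttests <- function(V, is_a) {
  na <- sum(is_a)
  nb <- sum(!is_a)
  ma <- colMeans(V[is_a, , drop = FALSE])
  mb <- colMeans(V[!is_a, , drop = FALSE])
  va <- colSums(sweep(V[is_a, , drop = FALSE], 2, ma)^2)
  vb <- colSums(sweep(V[!is_a, , drop = FALSE], 2, mb)^2)
  sp2 <- (va + vb) / (na + nb - 2)
  (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Per-cell independent t-tests between two cohorts of PAC grids
#'
#' Equal-variance two-sample t on `m_norm` for every grid cell, with the
#' convention t > 0 when group A exceeds group B. Degrees of freedom are
#' `nA + nB - 2`.
#'
#' @param grids a `pac_grids` tibble (one region) containing both groups.
#' @param group_a,group_b group labels; default: the two labels present, in
#'   first-appearance order.
#' @return a tibble of class `pac_tmap` with per-cell `t`, `df`, `p`
#'   (two-sided) and the group sizes as attributes.
#' @export
cell_ttests <- function(grids, group_a = NULL, group_b = NULL) {
  gl <- unique(grids$group)
  if (is.null(group_a) || is.null(group_b)) {
    if (length(gl) != 2) {
      abort("specify `group_a` and `group_b` (found != 2 group labels)")
    }
    group_a <- gl[1]
    group_b <- gl[2]
  }
  gm <- grids_matrix(grids, group_a, group_b)
  na <- sum(gm$is_a)
  nb <- sum(!gm$is_a)
  if (na < 2 || nb < 2) abort("need at least 2 subjects per group")
  tv <- col_ttests(gm$V, gm$is_a)
  if (!all(is.finite(tv))) {
    abort("non-finite t-value (zero pooled variance in some cell)")
  }
  df <- na + nb - 2
  out <- gm$cells |>
    dplyr::mutate(
      t = tv, df = df,
      p = 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
    )
  attr(out, "groups") <- c(a = group_a, b = group_b)
  attr(out, "n") <- c(a = na, b = nb)
  class(out) <- c("pac_tmap", class(out))
  out
}

# --- internal: connected components on the bin lattice ---------------------

# Label connected TRUE cells of a logical matrix under 4- or 8-neighbour
# adjacency by iterative minimum-label propagation (vectorized over matrix
# shifts). Returns an integer matrix, 0 outside the mask.
label_components <- function(mask, adjacency = 4) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- seq_len(nr) - dr
    cs <- seq_len(nc) - dc
    ok_r <- rs >= 1 & rs <= nr
    ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (adjacency == 8) {
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  repeat {
    best <- lab
    for (o in offs) {
      nb <- shift(lab, o[1], o[2])
      upd <- mask & nb > 0L & (best == 0L | nb < best)
      best[upd] <- nb[upd]
    }
    if (identical(best, lab)) break
    lab <- best
  }
  # compact labels to 1..k
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

# Cluster decomposition of a t-vector laid out on the (phase x amp) lattice.
# Returns a list of lists(cells=integer cell indices, mass, sign).
t_clusters <- function(tv, n_ph, n_am, t_crit, adjacency = 4) {
  tm <- matrix(tv, nrow = n_ph, ncol = n_am, byrow = TRUE)
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tm > t_crit else tm < -t_crit
    if (!any(mask)) next
    lab <- label_components(mask, adjacency)
    for (k in seq_len(max(lab))) {
      sel <- which(lab == k)  # column-major indices into tm
      ij <- arrayInd(sel, dim(tm))
      cell_idx <- (ij[, 1] - 1L) * n_am + ij[, 2]  # row-major cell order
      out[[length(out) + 1L]] <- list(
        cells = cell_idx, mass = sum(tm[sel]), sign = sgn
      )
    }
  }
  out
}

#' Form clusters of supra-threshold cells on a t-map
#'
#' Cells with two-sided per-cell p below `cluster_alpha` are grouped into
#' connected components of equal sign under 4-neighbour adjacency (+/- 1
#' phase bin or +/- 1 amplitude bin; diagonals are not adjacent unless
#' `adjacency = 8`). Each cluster's mass is the signed sum of its member
#' t-values.
#'
#' @param tmap a `pac_tmap` from [cell_ttests()].
#' @param cluster_alpha cluster-forming threshold (two-sided), default 0.05.
#' @param adjacency 4 (default) or 8.
#' @return a tibble of class `pac_clusters`: one row per cluster with
#'   `cluster`, `sign`, `n_cells`, `mass`, and a `cells` list-column of the
#'   member cells with their t-values. `p_perm` is `NA` until a permutation
#'   test fills it.
#' @export
form_clusters <- function(tmap, cluster_alpha = 0.05, adjacency = 4) {
  stopifnot(inherits(tmap, "pac_tmap") || all(c("phase_lo", "amp_lo", "t", "df") %in% names(tmap)))
  if (!adjacency %in% c(4, 8)) abort("`adjacency` must be 4 or 8")
  tmap <- dplyr::arrange(tmap, .data$phase_lo, .data$amp_lo)
  n_ph <- dplyr::n_distinct(tmap$phase_lo)
  n_am <- dplyr::n_distinct(tmap$amp_lo)
  if (nrow(tmap) != n_ph * n_am) abort("`tmap` is not a full rectangular grid")
  t_crit <- stats::qt(1 - cluster_alpha / 2, df = tmap$df[1])
  cl <- t_clusters(tmap$t, n_ph, n_am, t_crit, adjacency)
  if (length(cl) == 0) {
    out <- tibble::tibble(
      cluster = integer(), sign = character(), n_cells = integer(),
      mass = numeric(), p_perm = numeric(), cells = list()
    )
  } else {
    ord <- order(-abs(vapply(cl, `[[`, 0, "mass")))
    cl <- cl[ord]
    out <- tibble::tibble(
      cluster = seq_along(cl),
      sign = vapply(cl, function(x) if (x$sign > 0) "positive" else "negative", ""),
      n_cells = vapply(cl, function(x) length(x$cells), 0L),
      mass = vapply(cl, `[[`, 0, "mass"),
      p_perm = NA_real_,
      cells = lapply(cl, function(x) tmap[x$cells, ])
    )
  }
  attr(out, "cluster_alpha") <- cluster_alpha
  attr(out, "adjacency") <- adjacency
  class(out) <- c("pac_clusters", class(out))
  out
}

#' Cluster-based max-statistic permutation test between two cohorts
#'
#' Observed clusters are formed with [form_clusters()]; under each of
#' `n_perm` random reassignments of the group labels (group sizes
#' preserved) the t-map and clusters are recomputed and the null statistic
#' is the maximum absolute cluster mass of that permutation (0 when no
#' cluster forms). The permutation p-value of an observed cluster is
#' `(1 + #\{null >= |mass|\}) / (1 + n_perm)`; clusters with `p_perm < alpha`
#' are flagged significant. The subject matrix is put in a canonical order
#' first, so the result does not depend on input row order.
#'
#' @inheritParams cell_ttests
#' @param n_perm number of permutations (default 1024); below 100 a warning
#'   is issued, below 10 an error.
#' @param cluster_alpha cluster-forming per-cell threshold.
#' @param alpha family-wise significance level for flagging clusters.
#' @param seed integer seed for the permutation stream.
#' @param adjacency 4 (default) or 8.
#' @return an object of class `pac_cluster_test`: a list with `tmap`,
#'   `clusters` (with `p_perm` and `significant` filled), `null_dist`
#'   (length `n_perm`), the group labels/sizes and parameters. Use
#'   [generics::tidy()] / [generics::glance()] to extract tibbles.
#' @export
permutation_cluster_test <- function(grids, group_a = NULL, group_b = NULL,
                                     n_perm = 1024, cluster_alpha = 0.05,
                                     alpha = 0.05, seed = 1, adjacency = 4) {
  if (n_perm < 10) abort("`n_perm` must be at least 10")
  if (n_perm < 100) warn("`n_perm` below 100 gives a very coarse permutation null")
  tmap <- cell_ttests(grids, group_a, group_b)
  groups <- attr(tmap, "groups")
  gm <- grids_matrix(grids, groups["a"], groups["b"])
  n_sub <- nrow(gm$V)
  if (n_sub < 4) abort("need a combined n of at least 4 subjects")
  n_ph <- dplyr::n_distinct(gm$cells$phase_lo)
  n_am <- dplyr::n_distinct(gm$cells$amp_lo)
  df <- n_sub - 2
  t_crit <- stats::qt(1 - cluster_alpha / 2, df = df)

  clusters <- form_clusters(tmap, cluster_alpha, adjacency)

  na <- sum(gm$is_a)
  null_dist <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx_a <- sample.int(n_sub, na)
      is_a <- logical(n_sub)
      is_a[idx_a] <- TRUE
      tv <- col_ttests(gm$V, is_a)
      cl <- t_clusters(tv, n_ph, n_am, t_crit, adjacency)
      if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
    }, 0)
  })

  if (nrow(clusters) > 0) {
    clusters$p_perm <- vapply(
      clusters$mass,
      function(m) (1 + sum(null_dist >= abs(m))) / (1 + n_perm),
      0
    )
    clusters$significant <- clusters$p_perm < alpha
  } else {
    clusters$significant <- logical()
  }

  structure(
    list(
      tmap = tmap, clusters = clusters, null_dist = null_dist,
      groups = groups, n = attr(tmap, "n"),
      region = unique(grids$region),
      params = list(
        n_perm = n_perm, cluster_alpha = cluster_alpha, alpha = alpha,
        seed = seed, adjacency = adjacency
      )
    ),
    class = "pac_cluster_test"
  )
}

#' @export
print.pac_cluster_test <- function(x, ...) {
  cat(sprintf(
    "<pac_cluster_test> region %s: %s (n=%d) vs %s (n=%d), %d permutations\n",
    x$region, x$groups["a"], x$n["a"], x$groups["b"], x$n["b"],
    x$params$n_perm
  ))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf(
        "  cluster %d (%s): %d cells, mass %.3f, p_perm %.4f%s\n",
        x$clusters$cluster[i], x$clusters$sign[i], x$clusters$n_cells[i],
        x$clusters$mass[i], x$clusters$p_perm[i],
        if (isTRUE(x$clusters$significant[i])) " *" else ""
      ))
    }
  }
  invisible(x)
}

#' Cells belonging to significant clusters
#'
#' Union of member cells of all clusters with `p_perm < alpha`, for use as
#' the mask in phase-angle summaries.
#'
#' @param test a `pac_cluster_test`.
#' @param alpha significance level (defaults to the one used in the test).
#' @return a tibble of cells (columns `phase_lo`, `phase_hi`, `amp_lo`,
#'   `amp_hi`), possibly empty.
#' @export
significant_cells <- function(test, alpha = NULL) {
  stopifnot(inherits(test, "pac_cluster_test"))
  alpha <- alpha %||% test$params$alpha
  keep <- which(test$clusters$p_perm < alpha)
  if (length(keep) == 0) {
    return(tibble::tibble(
      phase_lo = numeric(), phase_hi = numeric(),
      amp_lo = numeric(), amp_hi = numeric()
    ))
  }
  dplyr::distinct(
    dplyr::bind_rows(test$clusters$cells[keep])[, c("phase_lo", "phase_hi", "amp_lo", "amp_hi")]
  )
}

#' Per-subject mean phase angle over a cell mask
#'
#' For each subject, the complex cell values `M_raw` over the masked cells
#' are averaged and the angle of the resultant vector is reported in
#' degrees on \[0, 360). Averaging is over complex values, never over
#' angles, so wraparound is handled correctly.
#'
#' @param grids a `pac_grids` tibble (one region).
#' @param cells the mask: a data frame with `phase_lo` and `amp_lo`
#'   columns (e.g. from [significant_cells()]), or a logical vector over
#'   the cells of one grid in (phase_lo, amp_lo) sort order.
#' @param normalize if `TRUE`, each cell's `M_raw` is scaled to unit
#'   magnitude before averaging, weighting all cells equally; the default
#'   `FALSE` averages the raw complex values.
#' @return a tibble with `subject_id`, `group`, `angle_deg`.
#' @export
subject_mean_phase <- function(grids, cells, normalize = FALSE) {
  stopifnot(is.data.frame(grids))
  cell_tbl <- grids |>
    dplyr::distinct(.data$phase_lo, .data$amp_lo) |>
    dplyr::arrange(.data$phase_lo, .data$amp_lo)
  if (is.logical(cells)) {
    if (length(cells) != nrow(cell_tbl)) {
      abort("logical `cells` mask must have one entry per grid cell")
    }
    cells <- cell_tbl[cells, ]
  }
  if (!is.data.frame(cells) || !all(c("phase_lo", "amp_lo") %in% names(cells))) {
    abort("`cells` must be a logical mask or a data frame with phase_lo/amp_lo")
  }
  if (nrow(cells) == 0) abort("empty cell mask")
  sel <- dplyr::semi_join(grids, cells, by = c("phase_lo", "amp_lo"))
  if (nrow(sel) == 0) abort("mask selects no cells present in `grids`")
  sel |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::summarise(
      angle_deg = {
        z <- complex(real = .data$m_raw_re, imaginary = .data$m_raw_im)
        if (normalize) z <- z / Mod(z)
        wrap_deg(Arg(sum(z)) * 180 / pi)
      },
      .groups = "drop"
    )
}

#' Between-group contrast of per-subject phase angles
#'
#' Unpaired equal-variance t-test on per-subject mean phase angles in
#' degrees (a linear test on wrapped angles; see the vignette for the
#' wraparound caveat), reported together with each group's circular mean.
#'
#' @param angles_a,angles_b numeric vectors of per-subject angles in
#'   degrees (at least 2 per group).
#' @return an object of class `pac_phase_summary`: a list with the group
#'   circular means, `t_statistic`, `df`, `p_value`, and the input angles.
#' @export
phase_angle_contrast <- function(angles_a, angles_b) {
  if (length(angles_a) < 2 || length(angles_b) < 2) {
    abort("need at least 2 angles per group")
  }
  if (stats::sd(angles_a) == 0 && stats::sd(angles_b) == 0) {
    abort("degenerate variance: both groups have constant angles")
  }
  tt <- stats::t.test(angles_a, angles_b, var.equal = TRUE)
  structure(
    list(
      angles_a = wrap_deg(angles_a), angles_b = wrap_deg(angles_b),
      circ_mean_a = circular_mean_deg(angles_a),
      circ_mean_b = circular_mean_deg(angles_b),
      t_statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value
    ),
    class = "pac_phase_summary"
  )
}

#' @export
print.pac_phase_summary <- function(x, ...) {
  cat(sprintf(
    "<pac_phase_summary> circular means %.1f deg (n=%d) vs %.1f deg (n=%d); t = %.4f, df = %g, p = %.4f\n",
    x$circ_mean_a, length(x$angles_a), x$circ_mean_b, length(x$angles_b),
    x$t_statistic, x$df, x$p_value
  ))
  invisible(x)
}
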
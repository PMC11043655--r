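#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cluster permutation test
#'
#' One row per observed cluster with its sign, size, mass and permutation
#' p-value.
#'
#' @param x a `pac_cluster_test`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.pac_cluster_test <- function(x, ...) {
  cl <- x$clusters
  tibble::tibble(
    region = x$region,
    cluster = cl$cluster,
    sign = cl$sign,
    n_cells = cl$n_cells,
    mass = cl$mass,
    p_perm = cl$p_perm,
    significant = cl$significant
  )
}

#' Glance at a cluster permutation test
#'
#' @param x a `pac_cluster_test`.
#' @param ... unused.
#' @return a one-row tibble summarising the contrast.
#' @export
glance.pac_cluster_test <- function(x, ...) {
  cl <- x$clusters
  tibble::tibble(
    region = x$region,
    group_a = unname(x$groups["a"]),
    group_b = unname(x$groups["b"]),
    n_a = unname(x$n["a"]),
    n_b = unname(x$n["b"]),
    df = unname(x$tmap$df[1]),
    n_clusters = nrow(cl),
    n_significant = sum(cl$significant %in% TRUE),
    max_abs_mass = if (nrow(cl)) max(abs(cl$mass)) else NA_real_,
    min_p_perm = if (nrow(cl)) min(cl$p_perm) else NA_real_,
    n_perm = x$params$n_perm
  )
}

#' Tidy a phase-angle contrast
#'
#' @param x a `pac_phase_summary`.
#' @param ... unused.
#' @return a one-row tibble with circular means and the t-test.
#' @export
tidy.pac_phase_summary <- function(x, ...) {
  tibble::tibble(
    circ_mean_a = x$circ_mean_a,
    circ_mean_b = x$circ_mean_b,
    n_a = length(x$angles_a),
    n_b = length(x$angles_b),
    t_statistic = x$t_statistic,
    df = x$df,
    p_value = x$p_value
  )
}
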
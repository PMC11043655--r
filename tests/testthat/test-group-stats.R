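test_that("per-cell t-tests match hand-computed pooled t values", {
  cells <- default_cells()[1:2, ]
  # cell 1: A = {1,2} vs B = {1,2} -> t = 0
  # cell 2: A = {2,4} vs B = {1,3} -> pooled sd sqrt(2), t = 1/sqrt(2)
  gA <- fake_grids(rbind(c(1, 2), c(2, 4)), groups = c("A", "A"), cells = cells)
  gB <- fake_grids(rbind(c(1, 1), c(2, 3)), groups = c("B", "B"), cells = cells)
  gB$subject_id <- paste0("b_", gB$subject_id)
  tm <- cell_ttests(dplyr::bind_rows(gA, gB), "A", "B")
  expect_equal(tm$t[1], 0)
  expect_equal(tm$t[2], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(tm$df[1], 2)

  g3 <- fake_grids(rbind(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3),
                   cells = default_cells()[1, ])
  g3$subject_id <- paste0(g3$group, g3$subject_id)
  tm3 <- cell_ttests(g3, "A", "B")
  expect_equal(tm3$t, 0)
  expect_equal(tm3$df, 4)
})

test_that("cluster formation follows 4-connectivity and signed masses", {
  # 3 x 3 map, threshold |t| > 2: {(1,1),(1,2)} mass 5.5 and {(3,3)} mass -2.6
  cells <- tidyr::expand_grid(phase_lo = 4:6, amp_lo = 30:32)
  cells$phase_hi <- cells$phase_lo + 1
  cells$amp_hi <- cells$amp_lo + 1
  tvals <- c(3.0, 2.5, 0, 0, 0, 0, 0, 0, -2.6) # row-major (phase, amp)
  tmap <- dplyr::mutate(cells, t = tvals, df = 1e6,
                        p = 2 * stats::pt(abs(tvals), 1e6, lower.tail = FALSE))
  class(tmap) <- c("pac_tmap", class(tmap))
  alpha_for_t2 <- 2 * stats::pt(2, 1e6, lower.tail = FALSE)
  cl <- form_clusters(tmap, cluster_alpha = alpha_for_t2)
  expect_equal(nrow(cl), 2)
  expect_equal(sort(cl$mass), c(-2.6, 5.5))
  expect_equal(cl$n_cells[cl$mass == 5.5], 2)
  expect_equal(cl$sign[cl$mass == -2.6], "negative")

  # all-zero map: no clusters
  tmap0 <- dplyr::mutate(cells, t = 0, df = 1e6, p = 1)
  class(tmap0) <- c("pac_tmap", class(tmap0))
  expect_equal(nrow(form_clusters(tmap0, alpha_for_t2)), 0)

  # diagonal cells are not adjacent under 4-connectivity
  tvals_d <- c(3, 0, 0, 0, 3, 0, 0, 0, 0)
  tmap_d <- dplyr::mutate(cells, t = tvals_d, df = 1e6,
                          p = 2 * stats::pt(abs(tvals_d), 1e6, lower.tail = FALSE))
  class(tmap_d) <- c("pac_tmap", class(tmap_d))
  cl_d <- form_clusters(tmap_d, alpha_for_t2)
  expect_equal(nrow(cl_d), 2)
  expect_equal(cl_d$n_cells, c(1L, 1L))
  # ... but they merge under 8-connectivity
  expect_equal(nrow(form_clusters(tmap_d, alpha_for_t2, adjacency = 8)), 1)
})

test_that("cluster decomposition matches a breadth-first-search oracle", {
  cells <- default_cells()
  alpha_for_t2 <- 2 * stats::pt(2, 1e6, lower.tail = FALSE)
  set.seed(42)
  for (rep in 1:100) {
    tvals <- rnorm(80, sd = 1.6)
    tmap <- dplyr::mutate(cells, t = tvals, df = 1e6,
                          p = 2 * stats::pt(abs(tvals), 1e6, lower.tail = FALSE))
    class(tmap) <- c("pac_tmap", class(tmap))
    got <- clusters_as_sets(form_clusters(tmap, alpha_for_t2))
    want <- bfs_clusters(matrix(tvals, 8, 10, byrow = TRUE), t_crit = 2)
    key <- function(cl) paste(sapply(cl, function(x) {
      paste0(paste(x$cells, collapse = ","), "|", signif(x$mass, 12))
    }), collapse = ";")
    expect_identical(
      sort(sapply(got, function(x) paste(x$cells, collapse = ","))),
      sort(sapply(want, function(x) paste(x$cells, collapse = ",")))
    )
    expect_equal(sort(sapply(got, `[[`, "mass")),
                 sort(sapply(want, `[[`, "mass")), tolerance = 1e-12)
  }
})

test_that("the permutation null has n_perm entries and sane p-values", {
  set.seed(8)
  v <- matrix(rnorm(10 * 80), nrow = 10)
  g <- fake_grids(v, groups = rep(c("A", "B"), each = 5))
  tst <- suppressWarnings(
    permutation_cluster_test(g, "A", "B", n_perm = 64, seed = 3)
  )
  expect_length(tst$null_dist, 64)
  expect_true(all(tst$clusters$p_perm > 0 & tst$clusters$p_perm <= 1))
  expect_error(permutation_cluster_test(g, "A", "B", n_perm = 5), "at least 10")
  expect_warning(permutation_cluster_test(g, "A", "B", n_perm = 32, seed = 1),
                 "coarse")
})

test_that("identical groups produce a zero t-map and no significant cluster", {
  set.seed(9)
  vals <- matrix(rnorm(6 * 80), nrow = 6)
  v <- rbind(vals, vals) # group B duplicates group A subject-for-subject
  g <- fake_grids(v, groups = rep(c("A", "B"), each = 6))
  tst <- permutation_cluster_test(g, "A", "B", n_perm = 128, seed = 2)
  expect_true(all(abs(tst$tmap$t) < 1e-12))
  expect_equal(nrow(tst$clusters), 0)
})

test_that("results are invariant to subject row order (exchangeability)", {
  set.seed(10)
  v <- matrix(rnorm(12 * 80), nrow = 12)
  v[1:6, 21:30] <- v[1:6, 21:30] + 2
  g <- fake_grids(v, groups = rep(c("A", "B"), each = 6))
  perm_rows <- sample(nrow(g))
  g_shuffled <- g[perm_rows, ]
  t1 <- permutation_cluster_test(g, "A", "B", n_perm = 128, seed = 7)
  t2 <- permutation_cluster_test(g_shuffled, "A", "B", n_perm = 128, seed = 7)
  expect_identical(t1$tmap$t, t2$tmap$t)
  expect_identical(t1$clusters$mass, t2$clusters$mass)
  expect_identical(t1$clusters$p_perm, t2$clusters$p_perm)
  expect_identical(t1$null_dist, t2$null_dist)
})

test_that("subject mean phase averages complex values, not angles", {
  cells <- default_cells()[1:2, ]
  m_raw <- rbind(c(exp(0i), exp(1i * pi / 2))) # 0 and 90 deg, equal magnitude
  g <- fake_grids(matrix(1, 1, 2), groups = "A", cells = cells, m_raw = m_raw)
  ang <- subject_mean_phase(g, cells)
  expect_equal(ang$angle_deg, 45)

  m_raw2 <- rbind(c(exp(1i * 10 * pi / 180), exp(1i * 350 * pi / 180)))
  g2 <- fake_grids(matrix(1, 1, 2), groups = "A", cells = cells, m_raw = m_raw2)
  expect_equal(subject_mean_phase(g2, cells)$angle_deg, 0, tolerance = 1e-8)

  m_raw3 <- rbind(0.3 * exp(1i * 231.8 * pi / 180))
  g3 <- fake_grids(matrix(1), groups = "A", cells = cells[1, ], m_raw = m_raw3)
  expect_equal(subject_mean_phase(g3, cells[1, ])$angle_deg, 231.8,
               tolerance = 1e-8)

  expect_error(subject_mean_phase(g, cells[0, ]), "empty")
})

test_that("phase-angle contrast reports t-test and circular means", {
  expect_equal(phase_angle_contrast(c(10, 20, 30), c(10, 20, 30))$t_statistic, 0)
  expect_error(phase_angle_contrast(c(90, 90, 90), c(270, 270, 270)),
               "degenerate")
  s <- phase_angle_contrast(c(80, 90, 100), c(350, 0, 10))
  expect_equal(s$circ_mean_a, 90)
  expect_equal(s$circ_mean_b, 0, tolerance = 1e-8)
  expect_error(phase_angle_contrast(90, c(1, 2)), "at least 2")
})

test_that("tidy and glance return well-formed tibbles", {
  set.seed(12)
  v <- matrix(rnorm(12 * 80), nrow = 12)
  v[1:6, 21:30] <- v[1:6, 21:30] + 2.5
  g <- fake_grids(v, groups = rep(c("A", "B"), each = 6))
  tst <- permutation_cluster_test(g, "A", "B", n_perm = 200, seed = 4)
  td <- tidy(tst)
  expect_true(all(c("cluster", "sign", "mass", "p_perm", "significant")
                  %in% names(td)))
  gl <- glance(tst)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_a, 6)
  expect_equal(gl$n_perm, 200)
  expect_equal(gl$n_clusters, nrow(td))
})
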
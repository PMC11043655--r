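test_that("composite signal and mean vector follow their definitions", {
  expect_identical(composite_signal(rep(1, 4), rep(0, 4)), rep(1 + 0i, 4))
  z <- composite_signal(rep(2, 4), rep(pi / 2, 4))
  expect_equal(z, rep(2i, 4))
  expect_error(composite_signal(1:3, 1:4), "length")

  expect_identical(raw_mean_vector(rep(3 + 4i, 10)), 3 + 4i)
  expect_error(raw_mean_vector(complex(0)), "nonempty")

  # constant amplitude, phase uniform over exactly K full cycles: symmetry
  phi <- 2 * pi * seq(0, 5, length.out = 5001)[-5001]
  expect_lt(Mod(raw_mean_vector(composite_signal(rep(1, 5000), phi))), 1e-6)

  # A = 1 + cos(phi): E[(1 + cos phi) e^{i phi}] = 1/2
  fs <- 600
  phi <- 2 * pi * 6 * seq_len(60 * fs) / fs
  m <- raw_mean_vector(composite_signal(1 + cos(phi), phi))
  expect_gt(Mod(m), 0.49)
  expect_lt(Mod(m), 0.51)
  expect_lt(abs(Arg(m)), 0.01)
})

test_that("mean vector matches a brute-force per-sample loop", {
  x <- make_signal(kappa = 1, seed = 7, duration = 20)
  ph <- phase_series(x, c(6, 7))
  am <- amplitude_series(x, c(27.5, 41.5))
  idx <- 201:1200 # 5 s window
  ph <- ph[idx]
  am <- am[idx]
  m_pipe <- raw_mean_vector(composite_signal(am, ph))
  acc <- 0 + 0i
  for (k in seq_along(am)) {
    acc <- acc + am[k] * exp(1i * ph[k])
  }
  expect_lt(Mod(m_pipe - acc / length(am)), 1e-10)
})

test_that("FFT-based surrogate lengths equal explicit circular shifts", {
  x <- make_signal(kappa = 1, seed = 3, duration = 20)
  ph <- phase_series(x, c(6, 7))[201:3800]
  am <- amplitude_series(x, c(27.5, 41.5))[201:3800]
  fs <- 200
  s_fft <- surrogate_mvls(am, ph, fs, n_surrogates = 50, seed = 11)
  m <- length(am)
  set.seed(11)
  lags <- sample(round(fs):(m - round(fs)), 50, replace = TRUE)
  s_direct <- vapply(lags, function(tau) {
    shifted <- am[((seq_len(m) - 1 + tau) %% m) + 1]
    Mod(mean(shifted * exp(1i * ph)))
  }, 0)
  expect_lt(max(abs(s_fft - s_direct)), 1e-10)
})

test_that("surrogate contract: count, degenerate amplitude, minimum lag", {
  x <- make_signal(kappa = 0, seed = 5, duration = 20)
  ph <- phase_series(x, c(6, 7))[201:3800]
  s <- surrogate_mvls(rep(0.5, length(ph)), ph, 200, n_surrogates = 200, seed = 1)
  expect_length(s, 200)
  # constant amplitude: every surrogate equals |mean(e^{i phi})| exactly
  expect_lt(diff(range(s)), 1e-12)
  expect_equal(s[1], Mod(mean(exp(1i * ph))) * 0.5, tolerance = 1e-10)

  expect_error(surrogate_mvls(rep(1, 300), rep(0, 300), fs = 200,
                              n_surrogates = 50), "min_lag")
  expect_error(surrogate_mvls(rep(1, 4000), rep(0, 4000), fs = 200,
                              n_surrogates = 10), "n_surrogates")
})

test_that("an all-zero signal raises the degenerate-surrogate error", {
  expect_error(
    normalized_pac(numeric(4000), c(6, 7), c(34, 35), fs = 200,
                   n_surrogates = 50, seed = 1),
    "degenerate"
  )
})

test_that("a strongly coupled signal exceeds its surrogate null", {
  x <- make_signal(kappa = 1, seed = 2, duration = 60)
  ph <- phase_series(x, c(6, 7))[201:11800]
  am <- amplitude_series(x, c(27.5, 41.5))[201:11800]
  obs <- Mod(raw_mean_vector(composite_signal(am, ph)))
  surro <- surrogate_mvls(am, ph, 200, n_surrogates = 200, seed = 9)
  expect_gt(obs, stats::quantile(surro, 0.99))
})

test_that("normalized_pac is deterministic and scale invariant", {
  x <- make_signal(kappa = 1, seed = 4, duration = 20)
  c1 <- seeded_cell(x, seed = 21)
  c2 <- seeded_cell(x, seed = 21)
  expect_identical(c1$m_norm, c2$m_norm)
  expect_identical(c1$phi_norm_deg, c2$phi_norm_deg)

  scaled <- regional_ts(100 * x$samples, fs = x$fs)
  c3 <- seeded_cell(scaled, seed = 21)
  expect_lt(abs(c1$m_norm - c3$m_norm), 1e-6)
  expect_lt(abs(c1$phi_norm_deg - c3$phi_norm_deg), 1e-6)

  # definitional identities of the cell
  m_raw <- complex(real = c1$m_raw_re, imaginary = c1$m_raw_im)
  expect_equal(c1$m_norm, (Mod(m_raw) - c1$mu) / c1$sigma)
  expect_equal(c1$phi_norm_deg, (Arg(m_raw) * 180 / pi) %% 360, tolerance = 1e-8)
})

test_that("negative m_norm values are preserved, never clipped", {
  zs <- vapply(1:10, function(s) {
    x <- make_signal(kappa = 0, seed = s, duration = 20)
    seeded_cell(x, seed = s + 300)$m_norm
  }, 0)
  expect_true(any(zs < 0))
})
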
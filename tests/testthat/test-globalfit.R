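# Variable-projection global fitting and model selection.

# tiny dataset with arbitrary per-pixel traces on a given basis
traces_dataset <- function(t2, trace_matrix, omega1 = NULL, omega3 = NULL) {
  npix <- ncol(trace_matrix)
  n1 <- if (is.null(omega1)) npix else length(omega1)
  n3 <- if (is.null(omega3)) 1L else length(omega3)
  if (is.null(omega1)) omega1 <- seq(15000, by = 10, length.out = n1)
  if (is.null(omega3)) omega3 <- 15000
  dataset_2des(omega1, omega3, t2,
               array(trace_matrix, c(length(t2), n1, n3)))
}

test_that("amplitude solving is exact on its own basis", {
  t2 <- seq(0, 1000, by = 7.5)
  ds <- traces_dataset(t2, cbind(3 * exp(-t2 / 100)))
  sol <- solve_amplitudes(ds, taus = 100, t2_min = 15)
  expect_equal(as.numeric(sol$amplitudes), 3, tolerance = 1e-9)
  expect_lt(sol$ssr, 1e-18)
  # signed amplitudes: a rising (negative DAS) component
  ds2 <- traces_dataset(t2, cbind(2 * exp(-t2 / 100) - 1 * exp(-t2 / 20)))
  sol2 <- solve_amplitudes(ds2, taus = c(20, 100), t2_min = 15)
  expect_equal(as.numeric(sol2$amplitudes), c(-1, 2), tolerance = 1e-9)
})

test_that("amplitude maps equal a brute-force normal-equations solve", {
  set.seed(11)
  t2 <- seq(0, 500, by = 12.5)
  Y <- matrix(stats::rnorm(length(t2) * 5), length(t2), 5)
  ds <- traces_dataset(t2, Y)
  taus <- c(30, 250)
  sol <- solve_amplitudes(ds, taus, t2_min = 15)
  keep <- t2 >= 15
  X <- exp(-outer(t2[keep], 1 / taus))
  A_oracle <- solve(t(X) %*% X, t(X) %*% Y[keep, ])
  expect_equal(matrix(sol$amplitudes, 2, 5), unname(A_oracle),
               tolerance = 1e-8)
  # nearly equal time constants give an ill-conditioned basis
  expect_error(solve_amplitudes(ds, c(100, 100 + 1e-9), t2_min = 15),
               "ill-conditioned")
})

test_that("variable projection equals a brute-force joint nonlinear fit", {
  set.seed(21)
  t2 <- seq(0, 950, by = 50)          # 20 points
  taus_true <- c(60, 500)
  A_true <- matrix(stats::rnorm(8, sd = 1), 2, 4)
  X <- exp(-outer(t2, 1 / taus_true))
  Y <- X %*% A_true + matrix(stats::rnorm(length(t2) * 4, sd = 0.01),
                             length(t2), 4)
  ds <- traces_dataset(t2, Y, omega1 = c(15000, 15010),
                       omega3 = c(15000, 15010))
  fit <- global_fit(ds, fit_config(2, t2_min = 0, seed = 1,
                                   convergence_tol = 1e-14,
                                   max_iterations = 2000))
  # oracle: joint quasi-Newton fit over (log taus, all 8 amplitudes)
  joint <- function(par) {
    Xb <- exp(-outer(t2, 1 / exp(par[1:2])))
    sum((Y - Xb %*% matrix(par[3:10], 2, 4))^2)
  }
  op <- stats::nlminb(c(log(c(50, 600)), as.numeric(A_true)), joint,
                      control = list(iter.max = 20000, eval.max = 50000,
                                     rel.tol = 1e-14))
  expect_equal(sort(fit$taus), sort(exp(op$par[1:2])), tolerance = 1e-4)
  expect_equal(fit$ssr, op$objective, tolerance = 1e-6)
  # and the pooled SSR at the optimum is no worse than at the start values
  start_ssr <- solve_amplitudes(ds, c(50, 600), t2_min = 0)$ssr
  expect_lte(fit$ssr, start_ssr)
})

test_that("a single-component fit nails single-exponential data", {
  t2 <- seq(0, 1000, by = 7.5)
  y <- 5 * exp(-t2 / 300)
  ds <- traces_dataset(t2, cbind(y, 0.5 * y, -2 * y))
  fit <- global_fit(ds, fit_config(1, seed = 2))
  expect_equal(fit$taus, 300, tolerance = 1e-4)
  expect_lt(sqrt(fit$ssr), 1e-8 * sqrt(sum(y^2)))
})

test_that("noiseless fixtures are recovered to high accuracy with correct DAS signs", {
  rec <- coarse_recipes(seed = 1)[["Lv-a"]]
  rec$noise_sigma <- 0
  ds <- generate_dataset(rec)
  fit <- global_fit(ds, fit_config(2, seed = 1))
  expect_equal(fit$taus, c(100, 2000), tolerance = 0.01)
  fast <- fit$components[[1]]$amplitude_map
  i <- nearest_idx(ds$omega1, 15070)
  jlo <- nearest_idx(ds$omega3, 14850)
  expect_gt(fast[i, i], 0)       # decaying diagonal peak
  expect_lt(fast[i, jlo], 0)     # rising below-diagonal cross peak
  # slow component is positive (everything eventually decays)
  expect_gt(fit$components[[2]]$amplitude_map[i, jlo], 0)
  # Chl-b: the 10 fs coherence constant survives the 15 fs exclusion window
  recb <- coarse_recipes(seed = 1)[["Bo-b"]]
  recb$noise_sigma <- 0
  fitb <- global_fit(generate_dataset(recb), fit_config(3, seed = 1))
  expect_lt(abs(min(fitb$taus) - 10) / 10, 0.25)
  expect_equal(fitb$taus[2], 100, tolerance = 0.01)
})

test_that("fits are invariant under pixel permutation and deterministic", {
  rec <- coarse_recipes(seed = 4)[["Lv-a"]]
  ds <- generate_dataset(rec)
  cfg <- fit_config(2, seed = 4)
  fit1 <- global_fit(ds, cfg)
  fit2 <- global_fit(ds, cfg)
  expect_identical(fit1$taus, fit2$taus)
  # shuffle the pixel traces among positions: pooled SSR is unchanged, so
  # the fitted time constants must be bit-identical
  set.seed(99)
  nt <- length(ds$t2); npix <- length(ds$omega1) * length(ds$omega3)
  Y <- matrix(ds$maps, nt)[, sample(npix)]
  ds_perm <- dataset_2des(ds$omega1, ds$omega3, ds$t2,
                          array(Y, dim(ds$maps)))
  fit3 <- global_fit(ds_perm, cfg)
  expect_identical(fit1$taus, fit3$taus)
})

test_that("fast time-constant recovery is robust across noise realizations", {
  fast <- vapply(1:20, function(s) {
    rec <- coarse_recipes(seed = 1000 + s)[["Lv-a"]]
    rec$noise_sigma <- 0.02
    min(global_fit(generate_dataset(rec), fit_config(2, seed = s))$taus)
  }, 0)
  expect_lt(abs(stats::median(fast) - 100) / 100, 0.05)
  expect_lt(stats::IQR(fast) / 100, 0.15)
})

test_that("BIC model selection finds the true component count", {
  cfg <- fit_config(1, seed = 5)
  # Chl-a fixture: two true components at the default 1% noise
  sel_a <- suppressWarnings(
    select_components(generate_dataset(coarse_recipes(5)[["Lv-a"]]), cfg, 3))
  expect_identical(sel_a$chosen_k, 2L)
  expect_true(all(diff(sel_a$criteria$ssr) <= 0))
  # pure noise: one component, explaining almost nothing
  set.seed(6)
  nax <- length(coarse_axis)
  dn <- dataset_2des(coarse_axis, coarse_axis, coarse_t2,
                     array(stats::rnorm(length(coarse_t2) * nax^2),
                           c(length(coarse_t2), nax, nax)))
  sel_n <- suppressWarnings(select_components(dn, cfg, 3))
  expect_identical(sel_n$chosen_k, 1L)
  # one component per pixel can only absorb ~1/nt of the variance by chance
  nt_kept <- sum(coarse_t2 >= 15)
  tss <- sum(dn$maps[coarse_t2 >= 15, , ]^2)
  expect_gt(sel_n$fits[[1]]$ssr / tss, 1 - 2 / nt_kept)
})

test_that("an optional plateau component captures non-decaying background", {
  t2 <- seq(0, 1000, by = 7.5)
  y <- 2 * exp(-t2 / 150) + 0.7
  ds <- traces_dataset(t2, cbind(y, y))
  fit <- global_fit(ds, fit_config(1, plateau = TRUE, seed = 1))
  expect_equal(fit$taus[1], 150, tolerance = 1e-3)
  expect_true(is.infinite(fit$taus[2]))
  expect_equal(as.numeric(fit$components[[2]]$amplitude_map[1, 1]), 0.7,
               tolerance = 1e-6)
})
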
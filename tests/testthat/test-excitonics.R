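# Point-dipole couplings, Frenkel Hamiltonian construction and
# diagonalization.

test_that("point-dipole coupling matches the closed form for textbook geometries", {
  mk <- function(center, dir, mu = 4.58)
    chromophore(paste(center, collapse = "_"), center, dir, mu, 15000)
  # parallel dipoles perpendicular to the separation: kappa = +1
  cp <- point_dipole_coupling(mk(c(0, 0, 0), c(0, 0, 1)),
                              mk(c(10, 0, 0), c(0, 0, 1)))
  expect_equal(cp$kappa, 1, tolerance = 1e-12)
  expect_equal(cp$distance_R, 10)
  expect_equal(cp$V, 5034.1 * 4.58^2 / 1000, tolerance = 1e-12)
  expect_equal(cp$V, 105.59729, tolerance = 1e-6)
  # orthogonal dipoles, both perpendicular to R: kappa = 0
  cp0 <- point_dipole_coupling(mk(c(0, 0, 0), c(0, 0, 1)),
                               mk(c(10, 0, 0), c(0, 1, 0)))
  expect_equal(cp0$kappa, 0, tolerance = 1e-12)
  expect_equal(cp0$V, 0, tolerance = 1e-12)
  # collinear head-to-tail: kappa = -2
  cpc <- point_dipole_coupling(mk(c(0, 0, 0), c(1, 0, 0)),
                               mk(c(10, 0, 0), c(1, 0, 0)))
  expect_equal(cpc$kappa, -2, tolerance = 1e-12)
  # symmetry under pair swap
  a <- mk(c(0, 0, 0), c(0.3, 1, -0.2)); b <- mk(c(4, 5, -3), c(1, 0.1, 0.5))
  expect_equal(point_dipole_coupling(a, b)$V, point_dipole_coupling(b, a)$V)
})

test_that("coupling scales as mu_a mu_b / R^3 and flags invalid geometry", {
  set.seed(42)
  for (rep in 1:25) {
    ctr <- stats::runif(3, -5, 5); sep <- stats::rnorm(3)
    sep <- 4 * sep / sqrt(sum(sep^2))
    d1 <- stats::rnorm(3); d2 <- stats::rnorm(3)
    mu1 <- stats::runif(1, 2, 6); mu2 <- stats::runif(1, 2, 6)
    base <- point_dipole_coupling(
      chromophore("a", ctr, d1, mu1, 15000),
      chromophore("b", ctr + sep, d2, mu2, 15000))
    doubled_mu <- point_dipole_coupling(
      chromophore("a", ctr, d1, 2 * mu1, 15000),
      chromophore("b", ctr + sep, d2, 2 * mu2, 15000))
    doubled_R <- point_dipole_coupling(
      chromophore("a", ctr, d1, mu1, 15000),
      chromophore("b", ctr + 2 * sep, d2, mu2, 15000))
    expect_equal(doubled_mu$V, 4 * base$V, tolerance = 1e-9)
    expect_equal(doubled_R$V, base$V / 8, tolerance = 1e-9)
    expect_true(abs(base$kappa) <= 2 + 1e-12)
  }
  a <- chromophore("a", c(0, 0, 0), c(0, 0, 1), 4, 15000)
  expect_error(point_dipole_coupling(a, a), "coincident")
  close_b <- chromophore("b", c(1.5, 0, 0), c(0, 0, 1), 4, 15000)
  expect_warning(cp <- point_dipole_coupling(a, close_b), "point-dipole")
  expect_false(cp$point_dipole_valid)
})

test_that("Hamiltonian assembly places site energies and couplings correctly", {
  ch <- list(chromophore("x", c(0, 0, 0), c(0, 0, 1), 4, 15100),
             chromophore("y", c(8, 0, 0), c(0, 0, 1), 4, 14900))
  m <- build_hamiltonian(ch, list(coupling_term(c("x", "y"), 80)))
  expect_equal(unname(m$hamiltonian),
               matrix(c(15100, 80, 80, 14900), 2, 2))
  expect_equal(sum(diag(m$hamiltonian)), 15100 + 14900, tolerance = 1e-6)
  # a missing pair defaults to zero, with a notice
  ch3 <- c(ch, list(chromophore("z", c(0, 8, 0), c(0, 0, 1), 4, 15000)))
  expect_message(
    m3 <- build_hamiltonian(ch3, list(coupling_term(c("x", "y"), 80),
                                      coupling_term(c("y", "z"), 10))),
    "without a coupling")
  expect_equal(m3$hamiltonian["x", "z"], 0)
  # duplicate labels rejected
  expect_error(build_hamiltonian(list(ch[[1]], ch[[1]])), "duplicate")
})

test_that("diagonalization: closed form, dark states, reconstruction, gaps", {
  dim102 <- degenerate_dimer(102, e0 = 15000)
  expect_equal(dim102$exciton_energies, c(15000 - 102, 15000 + 102))
  expect_equal(exciton_gap(dim102, 1, 2), 204, tolerance = 1e-9)
  expect_equal(exciton_gap(dim102, 2, 1), -204, tolerance = 1e-9)
  expect_equal(exciton_gap(degenerate_dimer(108), 1, 2), 216, tolerance = 1e-9)
  expect_equal(exciton_gap(degenerate_dimer(67), 1, 2), 134, tolerance = 1e-9)
  expect_equal(exciton_gap(degenerate_dimer(66), 1, 2), 132, tolerance = 1e-9)
  expect_equal(exciton_gap(degenerate_dimer(1e-12), 1, 2), 0, tolerance = 1e-9)
  expect_error(exciton_gap(dim102, 1, 3), "out of range")
  expect_error(exciton_gap(dim102, 2, 2), "differ")
  # degenerate homodimer with parallel dipoles: all strength in one exciton
  strength <- rowSums(dim102$exciton_dipoles^2)
  expect_equal(min(strength), 0, tolerance = 1e-6)
  expect_equal(max(strength), 2 * 4.58^2, tolerance = 1e-6)
  # eigen reconstruction
  m <- random_model(6, seed = 7)
  H <- m$hamiltonian
  rec <- m$exciton_vectors %*% diag(m$exciton_energies) %*%
    t(m$exciton_vectors)
  expect_lt(norm(H - rec, "F"), 1e-8 * norm(H, "F"))
  # non-symmetric input rejected
  bad <- m; bad$hamiltonian[1, 2] <- bad$hamiltonian[1, 2] + 5
  expect_error(diagonalize(bad), "symmetric")
})

test_that("dipole-strength sum rule holds for random assemblies of size 2-8", {
  for (seed in 1:100) {
    n <- 2L + seed %% 7L
    m <- random_model(n, seed = seed)
    expect_equal(sum(m$exciton_dipoles^2),
                 sum(vapply(m$chromophores,
                            function(c) c$dipole_magnitude^2, 0)),
                 tolerance = 1e-6)
    expect_true(all(diff(m$exciton_energies) >= 0))
  }
})

test_that("uncoupled dimers: 4x4 spectrum is the union of the 2x2 spectra", {
  ch <- list(chromophore("a1", c(0, 0, 0), c(0, 0, 1), 4.58, 15000),
             chromophore("a2", c(10, 0, 0), c(0, 0, 1), 4.58, 15050),
             chromophore("b1", c(0, 40, 0), c(0, 1, 0), 3.83, 14950),
             chromophore("b2", c(10, 40, 0), c(0, 1, 0), 3.83, 15020))
  intra <- list(point_dipole_coupling(ch[[1]], ch[[2]]),
                point_dipole_coupling(ch[[3]], ch[[4]]))
  m4 <- suppressMessages(diagonalize(build_hamiltonian(ch, intra)))
  mA <- diagonalize(build_hamiltonian(ch[1:2], intra[1]))
  mB <- diagonalize(build_hamiltonian(ch[3:4], intra[2]))
  expect_equal(m4$exciton_energies,
               sort(c(mA$exciton_energies, mB$exciton_energies)))
})

test_that("broadened spectra conserve area and reduce to single bands", {
  single <- diagonalize(build_hamiltonian(
    list(chromophore("s", c(0, 0, 0), c(0, 0, 1), 4, 15000))))
  sp <- stick_absorption(single, 100)
  expect_equal(sp$wavenumber[which.max(sp$intensity)], 15000)
  # degenerate parallel homodimer: only one visible band
  dimer <- degenerate_dimer(102)
  sp2 <- stick_absorption(dimer, 60)
  expect_lt(sp2$intensity[which.min(abs(sp2$wavenumber - 14898))],
            1e-6 * max(sp2$intensity))
  # integrated area independent of broadening
  axis <- seq(13000, 17000, by = 0.5)
  a50 <- sum(stick_absorption(dimer, 50, axis)$intensity) * 0.5
  a200 <- sum(stick_absorption(dimer, 200, axis)$intensity) * 0.5
  expect_equal(a50, a200, tolerance = 1e-6)
  expect_error(stick_absorption(dimer, -5), "broadening")
})

test_that("structure parsing yields validated chromophores and dimer geometry", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_tetramer(f)
  ch <- parse_structure(f)
  expect_length(ch, 4L)
  for (c in ch) {
    expect_equal(sqrt(sum(c$qy_unit^2)), 1, tolerance = 1e-9)
    expect_equal(c$dipole_magnitude, 4.58)
  }
  # two close pairs: intradimer Mg-Mg distance below interdimer distance
  centers <- t(vapply(ch, `[[`, numeric(3), "center"))
  d <- as.matrix(dist(centers))
  intra <- sort(d[upper.tri(d)])[1:2]
  inter <- sort(d[upper.tri(d)])[-(1:2)]
  expect_true(max(intra) < min(inter))
  # per-residue validation and empty-selection errors
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_tetramer(f2, drop_atom = "ND")
  expect_error(parse_structure(f2), "lacks atom ND")
  expect_error(parse_structure(f2, pigment_selector = "BCL"),
               "no pigments found")
})
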
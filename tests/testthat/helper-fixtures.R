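# Shared fixture builders: scaled-down grids keep the unit tests fast while
# preserving the fixtures' kinetic and spectral structure.

coarse_t2 <- seq(0, 1000, by = 15)
coarse_axis <- seq(14400, 15800, by = 25)

coarse_recipes <- function(seed = 1L) {
  fixture_recipes(seed, t2 = coarse_t2, axis = coarse_axis)
}

# a degenerate homodimer exciton model with a prescribed coupling V (cm^-1)
degenerate_dimer <- function(V, e0 = 15000, mu = 4.58) {
  ch <- list(chromophore("d1", c(0, 0, 0), c(0, 0, 1), mu, e0),
             chromophore("d2", c(10, 0, 0), c(0, 0, 1), mu, e0))
  diagonalize(build_hamiltonian(ch, list(coupling_term(c("d1", "d2"), V))))
}

# random chromophore set with all pairwise point-dipole couplings
random_model <- function(n, seed) {
  set.seed(seed)
  ch <- lapply(seq_len(n), function(i)
    chromophore(paste0("c", i), stats::runif(3, -20, 20), stats::rnorm(3),
                stats::runif(1, 2, 6), stats::runif(1, 14000, 16000)))
  # random placements may fall below the 2 A point-dipole validity bound;
  # that warning is irrelevant to the algebraic properties tested here
  suppressWarnings(diagonalize(build_hamiltonian(ch)))
}

# value of the laser envelope used by the generator
laser_weight <- function(omega, center = 15380, fwhm = 1840) {
  exp(-4 * log(2) * (omega - center)^2 / fwhm^2)
}

# index of the axis point closest to a wavenumber
nearest_idx <- function(axis, omega) which.min(abs(axis - omega))
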
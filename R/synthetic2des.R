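# Synthetic 2D electronic spectroscopy datasets: Gaussian exciton peaks whose
# amplitudes follow first-order relaxation kinetics and overdamped coherence
# decay, weighted by the laser spectrum, with additive Gaussian noise.

#' One 2D peak of a simulation recipe
#'
#' A 2D Gaussian feature with principal axes along the diagonal and
#' antidiagonal of the (excitation, emission) plane, whose time-dependent
#' amplitude follows a named kinetic channel.
#'
#' @param omega1,omega3 Excitation / emission center, cm^-1.
#' @param fwhm_diag,fwhm_antidiag FWHM along the diagonal / antidiagonal
#'   direction, cm^-1 (> 0).
#' @param channel Name of the kinetic channel supplying the amplitude trace.
#' @param scale Static amplitude multiplier (default 1); the sign convention
#'   is positive for ground-state bleach / stimulated emission.
#'
#' @return Object of class `peak_spec`.
#' @export
peak_spec <- function(omega1, omega3, fwhm_diag, fwhm_antidiag, channel,
                      scale = 1) {
  stopifnot(is.numeric(omega1), is.numeric(omega3),
            fwhm_diag > 0, fwhm_antidiag > 0,
            is.character(channel), length(channel) == 1L)
  structure(list(omega1 = omega1, omega3 = omega3, fwhm_diag = fwhm_diag,
                 fwhm_antidiag = fwhm_antidiag, channel = channel,
                 scale = scale),
            class = "peak_spec")
}

#' Full specification of a synthetic 2DES dataset
#'
#' @param peaks List of [peak_spec()] objects; every referenced channel must
#'   exist in `kinetics`.
#' @param kinetics A [kinetic_scheme()].
#' @param t2 Strictly increasing population-time grid, fs.
#' @param omega1_axis,omega3_axis Strictly increasing wavenumber axes, cm^-1.
#' @param laser_center,laser_fwhm Gaussian laser-spectrum envelope (cm^-1);
#'   peak amplitudes are weighted by the envelope value at omega1 and at
#'   omega3.
#' @param noise_sigma Additive i.i.d. Gaussian noise standard deviation as a
#'   fraction of the global maximum |noiseless signal| (>= 0).
#' @param seed Integer RNG seed; identical seeds give bit-identical datasets.
#' @param name Recipe name (metadata only).
#'
#' @return Object of class `sim_recipe`.
#' @export
simulation_recipe <- function(peaks, kinetics, t2,
                              omega1_axis, omega3_axis,
                              laser_center = 15380, laser_fwhm = 1840,
                              noise_sigma = 0, seed = 1L, name = "custom") {
  stopifnot(is.list(peaks), length(peaks) >= 1L,
            all(vapply(peaks, inherits, TRUE, "peak_spec")),
            inherits(kinetics, "kinetic_scheme"),
            all(diff(t2) > 0), all(diff(omega1_axis) > 0),
            all(diff(omega3_axis) > 0),
            laser_fwhm > 0, noise_sigma >= 0)
  chans <- scheme_channels(kinetics)
  bad <- setdiff(vapply(peaks, `[[`, "", "channel"), chans)
  if (length(bad) > 0L)
    stop("peak channel(s) not in the kinetic scheme: ",
         paste(bad, collapse = ", "))
  structure(list(peaks = peaks, kinetics = kinetics, t2 = as.numeric(t2),
                 omega1_axis = as.numeric(omega1_axis),
                 omega3_axis = as.numeric(omega3_axis),
                 laser_center = laser_center, laser_fwhm = laser_fwhm,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 name = name),
            class = "sim_recipe")
}

# Gaussian laser envelope (amplitude weighting), max 1 at center
laser_envelope <- function(omega, center, fwhm) {
  exp(-4 * log(2) * (omega - center)^2 / fwhm^2)
}

# npix x npeaks matrix of static peak shapes (incl. laser weighting and
# scale); pixel index runs omega1-fastest, matching array (n1, n3) layout.
peak_shapes <- function(recipe) {
  w1 <- recipe$omega1_axis; w3 <- recipe$omega3_axis
  n1 <- length(w1); n3 <- length(w3)
  W1 <- matrix(w1, n1, n3)
  W3 <- matrix(w3, n1, n3, byrow = TRUE)
  L <- laser_envelope(W1, recipe$laser_center, recipe$laser_fwhm) *
    laser_envelope(W3, recipe$laser_center, recipe$laser_fwhm)
  shapes <- vapply(recipe$peaks, function(pk) {
    if (pk$omega1 < min(w1) || pk$omega1 > max(w1) ||
        pk$omega3 < min(w3) || pk$omega3 > max(w3))
      warning("peak (", pk$omega1, ", ", pk$omega3,
              ") lies outside the axes; rendered truncated")
    d1 <- W1 - pk$omega1; d3 <- W3 - pk$omega3
    u <- (d1 + d3) / sqrt(2)   # along-diagonal coordinate
    v <- (d3 - d1) / sqrt(2)   # antidiagonal coordinate
    g <- exp(-4 * log(2) * (u^2 / pk$fwhm_diag^2 + v^2 / pk$fwhm_antidiag^2))
    as.numeric(pk$scale * g * L)
  }, numeric(n1 * n3))
  matrix(shapes, nrow = n1 * n3)
}

# noiseless stack, array (nt, n1, n3)
render_stack <- function(recipe) {
  traces <- solve_kinetics(recipe$kinetics, recipe$t2)
  amps <- t(traces[, vapply(recipe$peaks, `[[`, "", "channel"),
                   drop = FALSE])               # npeaks x nt
  shapes <- peak_shapes(recipe)                 # npix x npeaks
  flat <- shapes %*% amps                       # npix x nt
  n1 <- length(recipe$omega1_axis); n3 <- length(recipe$omega3_axis)
  aperm(array(flat, dim = c(n1, n3, length(recipe$t2))), c(3, 1, 2))
}

#' Render the noiseless 2D map at one population time
#'
#' @param recipe A [simulation_recipe()].
#' @param t2 A single population time (fs).
#' @return Matrix of dim `length(omega1_axis) x length(omega3_axis)`
#'   (excitation along rows, emission along columns).
#' @export
render_map <- function(recipe, t2) {
  stopifnot(inherits(recipe, "sim_recipe"), length(t2) == 1L)
  r <- recipe; r$t2 <- as.numeric(t2)
  m <- render_stack(r)[1, , ]
  matrix(m, length(recipe$omega1_axis), length(recipe$omega3_axis))
}

#' Generate a synthetic 2DES dataset
#'
#' Renders the noiseless stack of 2D maps over the recipe's t2 grid and adds
#' i.i.d. Gaussian noise with standard deviation
#' `noise_sigma * max(abs(noiseless signal))`, drawn from the recipe seed.
#' The same recipe (same seed) always yields a bit-identical dataset.
#'
#' @param recipe A [simulation_recipe()].
#' @return Object of class `dataset_2des` with fields `omega1`, `omega3`,
#'   `t2`, `maps` (array `nt x n1 x n3`) and `metadata`.
#' @export
generate_dataset <- function(recipe) {
  stopifnot(inherits(recipe, "sim_recipe"))
  if (length(recipe$t2) == 0L) stop("empty t2 grid")
  stack <- render_stack(recipe)
  if (recipe$noise_sigma > 0) {
    sigma <- recipe$noise_sigma * max(abs(stack))
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(recipe$seed)
    stack <- stack + array(stats::rnorm(length(stack), sd = sigma), dim(stack))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  dataset_2des(recipe$omega1_axis, recipe$omega3_axis, recipe$t2, stack,
               metadata = list(name = recipe$name, seed = recipe$seed,
                               noise_sigma = recipe$noise_sigma,
                               recipe_hash = recipe_hash(recipe),
                               generator = paste0("exciton2des ",
                                                  pkg_version())))
}

pkg_version <- function() {
  as.character(utils::packageVersion("exciton2des"))
}

# md5 of the canonical JSON serialization of a recipe
recipe_hash <- function(recipe) {
  canon <- list(
    name = recipe$name, seed = recipe$seed, noise_sigma = recipe$noise_sigma,
    laser = c(recipe$laser_center, recipe$laser_fwhm),
    t2 = recipe$t2, omega1 = recipe$omega1_axis, omega3 = recipe$omega3_axis,
    peaks = lapply(recipe$peaks, unclass),
    K = as.numeric(recipe$kinetics$K), p0 = recipe$kinetics$p0,
    channels = recipe$kinetics$channels,
    coherences = lapply(recipe$kinetics$coherences, unclass))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(canon, digits = NA, auto_unbox = TRUE), f)
  unname(tools::md5sum(f))
}

#' Construct a 2DES dataset container
#'
#' @param omega1,omega3 Ascending wavenumber axes, cm^-1.
#' @param t2 Population times, fs.
#' @param maps Array of dim `(length(t2), length(omega1), length(omega3))`.
#' @param metadata Named list of provenance information.
#' @return Object of class `dataset_2des`.
#' @export
dataset_2des <- function(omega1, omega3, t2, maps, metadata = list()) {
  maps <- as.array(maps)
  stopifnot(length(dim(maps)) == 3L,
            dim(maps)[1] == length(t2),
            dim(maps)[2] == length(omega1),
            dim(maps)[3] == length(omega3))
  if (!all(is.finite(maps))) stop("maps contain non-finite values")
  structure(list(omega1 = as.numeric(omega1), omega3 = as.numeric(omega3),
                 t2 = as.numeric(t2), maps = maps, metadata = metadata),
            class = "dataset_2des")
}

#' @export
print.dataset_2des <- function(x, ...) {
  cat(sprintf(
    "<dataset_2des%s>  %d maps of %d x %d (omega1 x omega3), t2 %.1f-%.1f fs\n",
    if (!is.null(x$metadata$name)) paste0(" ", x$metadata$name) else "",
    length(x$t2), length(x$omega1), length(x$omega3),
    min(x$t2), max(x$t2)))
  invisible(x)
}

# ---- fixture recipes ------------------------------------------------------

# Downhill relaxation within each dimer plus a shared slow channel:
# two-state complexes (Chl a) have channels P2 -> P1 and a slow ground-state
# bleach channel G; four-state complexes (Chl b) have two such dimer chains
# plus a 10 fs coherence channel feeding diagonal and symmetric cross peaks.
chla_recipe <- function(name, e_hi, e_lo, tau_relax, tau_slow,
                        fwhm_diag, fwhm_antidiag, t2, axis,
                        noise_sigma, seed) {
  K <- matrix(0, 3, 3, dimnames = list(c("P2", "P1", "G"),
                                       c("P2", "P1", "G")))
  K["P2", "P2"] <- -1 / tau_relax
  K["P1", "P2"] <- 1 / tau_relax
  K["P1", "P1"] <- -1 / tau_slow
  K["G", "G"] <- -1 / tau_slow
  kin <- kinetic_scheme(K, p0 = c(1, 0, 1))
  # upper diagonal: decaying stimulated emission plus bleach; lower diagonal:
  # bleach plus a weak rising stimulated-emission term; below-diagonal cross
  # peak: stimulated emission from the relaxed exciton (rises at tau_relax)
  pk <- function(w1, w3, ch, sc)
    peak_spec(w1, w3, fwhm_diag, fwhm_antidiag, ch, scale = sc)
  peaks <- list(
    pk(e_hi, e_hi, "P2", 0.6), pk(e_hi, e_hi, "G", 0.5),
    pk(e_lo, e_lo, "G", 1), pk(e_lo, e_lo, "P1", 0.3),
    pk(e_hi, e_lo, "P1", 0.7))
  simulation_recipe(peaks, kin, t2, axis, axis,
                    noise_sigma = noise_sigma, seed = seed, name = name)
}

chlb_recipe <- function(name, energies, tau_relax, tau_slow, tau_deph,
                        fwhm_diag, fwhm_antidiag, t2, axis,
                        noise_sigma, seed) {
  stopifnot(length(energies) == 4L)
  e <- sort(energies)   # e[1] lowest .. e[4] highest
  nm <- c("P1", "P2", "P3", "P4", "G")
  K <- matrix(0, 5, 5, dimnames = list(nm, nm))
  K["P4", "P4"] <- -1 / tau_relax   # dimer A: P4 -> P3
  K["P3", "P4"] <- 1 / tau_relax
  K["P3", "P3"] <- -1 / tau_slow
  K["P2", "P2"] <- -1 / tau_relax   # dimer B: P2 -> P1
  K["P1", "P2"] <- 1 / tau_relax
  K["P1", "P1"] <- -1 / tau_slow
  K["G", "G"] <- -1 / tau_slow
  kin <- kinetic_scheme(K, p0 = c(0, 1, 0, 1, 1),
                        coherences = list(list(name = "C", amplitude = 1,
                                               tau_deph = tau_deph)))
  pk <- function(w1, w3, ch, sc)
    peak_spec(w1, w3, fwhm_diag, fwhm_antidiag, ch, scale = sc)
  peaks <- list(
    pk(e[4], e[4], "P4", 1), pk(e[2], e[2], "P2", 1),
    pk(e[3], e[3], "G", 1), pk(e[1], e[1], "G", 1),
    pk(e[4], e[3], "P3", 0.7), pk(e[2], e[1], "P1", 0.7))
  for (i in 1:4) peaks[[length(peaks) + 1L]] <- pk(e[i], e[i], "C", 0.6)
  for (i in 1:3) for (j in seq.int(i + 1L, 4L)) {
    peaks[[length(peaks) + 1L]] <- pk(e[j], e[i], "C", 0.8)
    peaks[[length(peaks) + 1L]] <- pk(e[i], e[j], "C", 0.8)
  }
  simulation_recipe(peaks, kin, t2, axis, axis,
                    noise_sigma = noise_sigma, seed = seed, name = name)
}

#' Named simulation recipes for the four WSCP complexes
#'
#' Ground-truth synthetic 2DES recipes emulating the four chlorophyll-protein
#' complexes: Chl a complexes (`Lv-a`, `Bo-a`) have two exciton states with
#' diagonal peaks, a below-diagonal relaxation cross peak, ~100 fs downhill
#' relaxation and a slow 2 ps channel; Chl b complexes (`Lv-b`, `Bo-b`) have
#' four exciton states with the same population kinetics plus a 10 fs
#' overdamped coherence-dephasing channel feeding diagonal and symmetric
#' cross-peak positions. State energies (cm^-1): Lv-a 15070/14850,
#' Bo-a 14830/14600, Lv-b 14660/15050/15400/15660,
#' Bo-b 14620/14900/15300/15650. All recipes use t2 = 0-1000 fs in 7.5 fs
#' steps, a laser envelope centered at 15380 cm^-1 with 1840 cm^-1 FWHM, and
#' wavenumber axes 14200-16200 cm^-1 in 10 cm^-1 steps. Noise is 1% of the
#' signal maximum for Chl a recipes and 0.5% for Chl b recipes.
#'
#' @param seed Integer base seed; recipe i uses `seed + i - 1`.
#' @param t2,axis Optional overrides of the t2 grid (fs) and the shared
#'   wavenumber axis (cm^-1), mainly to scale problems down.
#'
#' @return Named list of four [simulation_recipe()] objects
#'   (`Lv-a`, `Lv-b`, `Bo-a`, `Bo-b`).
#' @export
fixture_recipes <- function(seed = 1L,
                            t2 = seq(0, 1000, by = 7.5),
                            axis = seq(14200, 16200, by = 10)) {
  seed <- as.integer(seed)
  list(
    "Lv-a" = chla_recipe("Lv-a", 15070, 14850, 100, 2000, 150, 70,
                         t2, axis, 0.01, seed),
    "Lv-b" = chlb_recipe("Lv-b", c(14660, 15050, 15400, 15660), 100, 2000, 10,
                         150, 70, t2, axis, 0.005, seed + 1L),
    "Bo-a" = chla_recipe("Bo-a", 14830, 14600, 100, 2000, 150, 70,
                         t2, axis, 0.01, seed + 2L),
    "Bo-b" = chlb_recipe("Bo-b", c(14620, 14900, 15300, 15650), 100, 2000, 10,
                         150, 70, t2, axis, 0.005, seed + 3L))
}
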
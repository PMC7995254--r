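# Interpretation of 2D decay-associated spectra: extremum picking, exciton
# energies and state counts, downhill relaxation gaps, and effective
# transition-dipole rescaling from observed vs calculated splittings.

# separable Gaussian smoothing with edge renormalization; fwhm in pixels
smooth_map <- function(m, fwhm_px) {
  if (fwhm_px <= 0) return(m)
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  conv1 <- function(x) {                 # convolve columns of a matrix
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    wt <- numeric(n)
    for (o in -r:r) {
      src <- pmin(pmax(seq_len(n) + o, 1L), n)   # replicate edges
      out <- out + k[o + r + 1L] * x[src, , drop = FALSE]
    }
    out / sum(k)
  }
  t(conv1(t(conv1(m))))
}

#' Locate extrema of a decay-associated spectrum
#'
#' Finds local extrema of |amplitude| (8-neighborhood) exceeding
#' `min_prominence` times the global maximum |amplitude|, and classifies
#' each as `diagonal` (|omega1 - omega3| within `diagonal_tolerance`),
#' `cross_above` (omega3 > omega1) or `cross_below` (omega3 < omega1).
#' The map is lightly Gaussian-smoothed first so that amplitude noise on
#' broad features does not fragment them into spurious extrema; the default
#' kernel (3 grid steps) is far below typical 2DES linewidths, so positions
#' move by at most about one grid step. Extremum positions are invariant
#' under uniform scaling of the map.
#'
#' @param das A [das_component()].
#' @param min_prominence Fraction of the global |amplitude| maximum that an
#'   extremum must exceed (0 < value < 1).
#' @param diagonal_tolerance Half-width of the diagonal band, cm^-1; default
#'   2 grid steps (half an antidiagonal linewidth is a good choice when the
#'   lineshape is known).
#' @param smooth_fwhm FWHM of the Gaussian pre-smoothing kernel, cm^-1;
#'   default 3 grid steps, 0 disables smoothing.
#'
#' @return Object of class `peak_set`: a data frame `peaks` with columns
#'   `omega1`, `omega3`, `amplitude`, `kind`, ordered by descending
#'   |amplitude| (ties by omega1 then omega3), plus the tolerance used and
#'   the source component's tau.
#' @export
find_extrema <- function(das, min_prominence = 0.2, diagonal_tolerance = NULL,
                         smooth_fwhm = NULL) {
  stopifnot(inherits(das, "das_component"),
            min_prominence > 0, min_prominence < 1)
  m <- das$amplitude_map
  if (!all(is.finite(m))) stop("amplitude map contains non-finite values")
  if (length(m) == 0L) stop("empty amplitude map")
  step <- stats::median(diff(das$omega1))
  if (is.null(diagonal_tolerance)) diagonal_tolerance <- 2 * step
  if (is.null(smooth_fwhm)) smooth_fwhm <- 3 * step
  m <- smooth_map(m, smooth_fwhm / step)
  a <- abs(m)
  thr <- min_prominence * max(a)
  n1 <- nrow(m); n3 <- ncol(m)
  # pad with -Inf so edges are compared only against in-map neighbors
  ap <- matrix(-Inf, n1 + 2L, n3 + 2L)
  ap[2:(n1 + 1L), 2:(n3 + 1L)] <- a
  core <- ap[2:(n1 + 1L), 2:(n3 + 1L)]
  is_max <- core > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    is_max <- is_max &
      core >= ap[(2 + di):(n1 + 1L + di), (2 + dj):(n3 + 1L + dj)]
  }
  # strict on at least one side to drop flat regions
  strict <- matrix(FALSE, n1, n3)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    strict <- strict |
      core > ap[(2 + di):(n1 + 1L + di), (2 + dj):(n3 + 1L + dj)]
  }
  idx <- which(is_max & strict, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    peaks <- data.frame(omega1 = numeric(0), omega3 = numeric(0),
                        amplitude = numeric(0), kind = character(0))
  } else {
    w1 <- das$omega1[idx[, 1]]
    w3 <- das$omega3[idx[, 2]]
    amp <- m[idx]
    kind <- ifelse(abs(w1 - w3) <= diagonal_tolerance, "diagonal",
                   ifelse(w3 > w1, "cross_above", "cross_below"))
    ord <- order(-abs(amp), w1, w3)
    peaks <- data.frame(omega1 = w1, omega3 = w3, amplitude = amp,
                        kind = kind)[ord, , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(list(peaks = peaks, diagonal_tolerance = diagonal_tolerance,
                 tau = das$tau),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set>  %d extrema (tau = %.4g fs, diagonal tol %.3g cm^-1)\n",
              nrow(x$peaks), x$tau, x$diagonal_tolerance))
  if (nrow(x$peaks) > 0L) print(x$peaks, ...)
  invisible(x)
}

#' Estimate the downhill relaxation gap from a fast-component DAS
#'
#' A downhill exciton relaxation appears in the DAS of the fast component as
#' a positive (decaying) diagonal extremum paired with a negative (rising)
#' below-diagonal extremum in the same excitation column. The emission-
#' frequency difference of the strongest such pair estimates the energy gap
#' between the initial (donor) and final (acceptor) exciton states.
#'
#' @param peakset A [find_extrema()] result from a fast-component DAS.
#' @param column_tolerance Maximum |omega1| mismatch for "same excitation
#'   column", cm^-1; defaults to the peak set's diagonal tolerance.
#'
#' @return Object of class `gap_estimate` with `donor_energy`,
#'   `acceptor_energy`, `gap` (all cm^-1) and `source_component_tau` (fs).
#' @export
estimate_relaxation_gap <- function(peakset, column_tolerance = NULL) {
  stopifnot(inherits(peakset, "peak_set"))
  if (is.null(column_tolerance)) column_tolerance <- peakset$diagonal_tolerance
  pk <- peakset$peaks
  pos <- pk[pk$kind == "diagonal" & pk$amplitude > 0, , drop = FALSE]
  neg <- pk[pk$kind == "cross_below" & pk$amplitude < 0, , drop = FALSE]
  if (nrow(pos) == 0L || nrow(neg) == 0L)
    stop("no relaxation signature: need a positive diagonal and a negative ",
         "below-diagonal extremum")
  best <- NULL
  for (i in seq_len(nrow(pos))) for (j in seq_len(nrow(neg))) {
    if (abs(pos$omega1[i] - neg$omega1[j]) > column_tolerance) next
    strength <- abs(pos$amplitude[i]) * abs(neg$amplitude[j])
    if (is.null(best) || strength > best$strength)
      best <- list(strength = strength, donor = pos$omega3[i],
                   acceptor = neg$omega3[j])
  }
  if (is.null(best))
    stop("no relaxation signature: no positive-diagonal / negative-below ",
         "pair shares an excitation column within ", column_tolerance,
         " cm^-1")
  structure(list(donor_energy = best$donor, acceptor_energy = best$acceptor,
                 gap = best$donor - best$acceptor,
                 source_component_tau = peakset$tau),
            class = "gap_estimate")
}

#' @export
print.gap_estimate <- function(x, ...) {
  cat(sprintf(
    "<gap_estimate>  %.0f -> %.0f cm^-1, gap %.0f cm^-1 (tau = %.4g fs)\n",
    x$donor_energy, x$acceptor_energy, x$gap, x$source_component_tau))
  invisible(x)
}

#' Count exciton states from the fastest-component DAS
#'
#' The diagonal extrema of the fastest DAS (coherence-dephasing amplitude)
#' mark the exciton energies. Diagonal energies closer than `dedup_width` are
#' merged (amplitude-weighted). Also reports which diagonal pairs are
#' connected by symmetric cross peaks, the hallmark of excitonic coupling.
#'
#' @param das A [das_component()] (use the smallest-tau component).
#' @param min_prominence Passed to [find_extrema()].
#' @param diagonal_tolerance Passed to [find_extrema()].
#' @param dedup_width Energies within this distance (cm^-1) count as one
#'   state; default one antidiagonal linewidth estimate (4 grid steps).
#'
#' @return List with `n_states`, `energies` (ascending, cm^-1) and
#'   `connected_pairs` (data frame of diagonal-energy pairs linked by
#'   symmetric cross peaks).
#' @export
count_exciton_states <- function(das, min_prominence = 0.2,
                                 diagonal_tolerance = NULL,
                                 dedup_width = NULL) {
  ps <- find_extrema(das, min_prominence, diagonal_tolerance)
  if (is.null(dedup_width)) dedup_width <- 4 * stats::median(diff(das$omega1))
  pk <- ps$peaks
  dg <- pk[pk$kind == "diagonal", , drop = FALSE]
  if (nrow(dg) == 0L)
    return(list(n_states = 0L, energies = numeric(0),
                connected_pairs = data.frame(e_lo = numeric(0),
                                             e_hi = numeric(0))))
  e <- sort((dg$omega1 + dg$omega3) / 2)
  w <- abs(dg$amplitude)[order((dg$omega1 + dg$omega3) / 2)]
  groups <- cumsum(c(1, diff(e) > dedup_width))
  energies <- as.numeric(tapply(e * w, groups, sum) / tapply(w, groups, sum))
  # symmetric cross-peak connectivity between deduplicated diagonal energies
  cross <- pk[pk$kind != "diagonal", , drop = FALSE]
  has_cross <- function(a, b) {
    any(abs(cross$omega1 - a) <= dedup_width &
        abs(cross$omega3 - b) <= dedup_width)
  }
  pairs <- list()
  n <- length(energies)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (has_cross(energies[j], energies[i]) &&
        has_cross(energies[i], energies[j]))
      pairs[[length(pairs) + 1L]] <- data.frame(e_lo = energies[i],
                                                e_hi = energies[j])
  }
  connected <- if (length(pairs) > 0L) do.call(rbind, pairs) else
    data.frame(e_lo = numeric(0), e_hi = numeric(0))
  list(n_states = length(energies), energies = energies,
       connected_pairs = connected)
}

#' Effective transition dipole from observed vs calculated splittings
#'
#' At fixed geometry the point-dipole coupling scales as mu^2 and the
#' exciton gap as 2V, so an observed gap larger than the one calculated with
#' a reference dipole implies an effective dipole
#' `mu_eff = mu_ref * sqrt(gap_observed / gap_calculated)`.
#'
#' @param gap_observed,gap_calculated Observed and calculated exciton
#'   splittings, cm^-1 (> 0).
#' @param mu_reference Reference (monomer) transition dipole, Debye (> 0).
#'
#' @return Object of class `dipole_rescale` with `mu_effective` (Debye).
#' @export
infer_effective_dipole <- function(gap_observed, gap_calculated,
                                   mu_reference) {
  if (!all(c(gap_observed, gap_calculated, mu_reference) > 0))
    stop("all inputs must be > 0")
  structure(list(mu_reference = mu_reference, gap_observed = gap_observed,
                 gap_calculated = gap_calculated,
                 mu_effective = mu_reference *
                   sqrt(gap_observed / gap_calculated)),
            class = "dipole_rescale")
}

#' @export
print.dipole_rescale <- function(x, ...) {
  cat(sprintf(
    "<dipole_rescale>  mu_ref = %.2f D, gap obs/calc = %.0f/%.0f cm^-1 -> mu_eff = %.2f D\n",
    x$mu_reference, x$gap_observed, x$gap_calculated, x$mu_effective))
  invisible(x)
}

#' Summarize a global fit: states, relaxation gap, optional dipole rescale
#'
#' Convenience wrapper tying the DAS-analysis steps together: exciton-state
#' count/energies from the fastest DAS, and the downhill relaxation gap from
#' the fastest component that shows a positive-diagonal / negative-below
#' signature (for two-state complexes this is the fastest component; for
#' four-state complexes with a coherence channel it is typically the second).
#'
#' @param fit A `global_fit_result`.
#' @param min_prominence Passed to the extremum search.
#' @param mu_reference,gap_calculated If both given, an effective-dipole
#'   rescale is computed from the estimated gap.
#'
#' @return List with `states`, `gap` (a `gap_estimate` or `NULL`),
#'   `gap_component_tau` and `dipole` (a `dipole_rescale` or `NULL`).
#' @export
analyze_fit <- function(fit, min_prominence = 0.2, mu_reference = NULL,
                        gap_calculated = NULL) {
  stopifnot(inherits(fit, "global_fit_result"))
  finite <- which(is.finite(vapply(fit$components, `[[`, 0, "tau")))
  states <- count_exciton_states(fit$components[[finite[1]]], min_prominence)
  gap <- NULL
  for (i in finite) {
    gap <- tryCatch(
      estimate_relaxation_gap(find_extrema(fit$components[[i]],
                                           min_prominence)),
      error = function(e) NULL)
    if (!is.null(gap)) break
  }
  dipole <- if (!is.null(gap) && !is.null(mu_reference) &&
                !is.null(gap_calculated))
    infer_effective_dipole(gap$gap, gap_calculated, mu_reference)
  list(states = states, gap = gap,
       gap_component_tau = if (!is.null(gap)) gap$source_component_tau,
       dipole = dipole)
}
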
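# First-order kinetic networks for exciton population relaxation, plus
# overdamped coherence-dephasing channels.

#' First-order kinetic scheme
#'
#' Describes the population dynamics dp/dt = K p of a set of named channels
#' (rates in fs^-1; off-diagonal K[i, j] >= 0 is flow from channel j into
#' channel i), plus optional coherence channels that decay as
#' a * exp(-t2 / tau_deph) independently of K. Coherence channels model the
#' ultrafast non-oscillatory loss of exciton-superposition amplitude.
#'
#' @param K Square rate matrix in fs^-1 with non-positive diagonal and
#'   non-negative off-diagonal entries; column sums must be <= 0 (population
#'   is conserved up to terminal loss).
#' @param p0 Non-negative initial populations, one per channel.
#' @param channels Channel names (default from `dimnames(K)` or `P1..Pn`).
#' @param coherences Optional list of coherence channels, each a list with
#'   `name`, `amplitude`, and `tau_deph` (fs, > 0).
#'
#' @return Object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(K, p0, channels = NULL, coherences = list()) {
  K <- as.matrix(K)
  stopifnot(nrow(K) == ncol(K), all(is.finite(K)),
            length(p0) == nrow(K), all(is.finite(p0)))
  if (any(p0 < 0)) stop("initial populations must be >= 0")
  offdiag <- K; diag(offdiag) <- 0
  if (any(offdiag < 0)) stop("off-diagonal rates must be >= 0")
  if (any(colSums(K) > 1e-12))
    stop("column sums of K must be <= 0 (no net population gain)")
  if (is.null(channels)) channels <- rownames(K)
  if (is.null(channels)) channels <- paste0("P", seq_len(nrow(K)))
  stopifnot(length(channels) == nrow(K), !anyDuplicated(channels))
  for (co in coherences) {
    stopifnot(is.list(co), !is.null(co$name), is.numeric(co$amplitude),
              is.numeric(co$tau_deph), co$tau_deph > 0)
    if (co$name %in% channels)
      stop("coherence channel '", co$name, "' clashes with a population channel")
  }
  dimnames(K) <- list(channels, channels)
  structure(list(K = K, p0 = as.numeric(p0), channels = channels,
                 coherences = coherences),
            class = "kinetic_scheme")
}

#' All channel names of a scheme (populations then coherences)
#' @param scheme A `kinetic_scheme`.
#' @return Character vector.
#' @export
scheme_channels <- function(scheme) {
  c(scheme$channels, vapply(scheme$coherences, `[[`, "", "name"))
}

# exp(A) for a small square matrix: scaling-and-squaring Taylor series.
expm_small <- function(A) {
  n <- nrow(A)
  nrm <- max(colSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  E <- diag(n); term <- diag(n)
  for (k in 1:30) {
    term <- term %*% As / k
    E <- E + term
    if (max(abs(term)) < 1e-17 * max(abs(E))) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

#' Solve a kinetic scheme on a time grid
#'
#' Populations solve dp/dt = K p exactly (eigen-decomposition of K, with a
#' scaling-and-squaring matrix exponential fallback when K is defective);
#' coherence channels are evaluated as a * exp(-t2 / tau_deph).
#'
#' @param scheme A [kinetic_scheme()].
#' @param t2 Numeric vector of times (fs).
#'
#' @return Matrix of dim `length(t2) x n_channels` with channel names as
#'   column names (populations first, then coherence channels).
#' @export
solve_kinetics <- function(scheme, t2) {
  stopifnot(inherits(scheme, "kinetic_scheme"), is.numeric(t2),
            all(is.finite(t2)))
  K <- scheme$K
  n <- nrow(K)
  ev <- eigen(K)
  use_eigen <- is.finite(rcond(ev$vectors)) && rcond(ev$vectors) > 1e-10
  if (use_eigen) {
    c0 <- solve(ev$vectors, scheme$p0)
    P <- Re(exp(outer(t2, ev$values)) %*% (diag(c0, n) %*% t(ev$vectors)))
  } else {
    P <- t(vapply(t2, function(tt) as.numeric(expm_small(K * tt) %*% scheme$p0),
                  numeric(n)))
  }
  P <- matrix(P, nrow = length(t2), ncol = n)
  colnames(P) <- scheme$channels
  if (length(scheme$coherences) > 0L) {
    Cc <- vapply(scheme$coherences,
                 function(co) co$amplitude * exp(-t2 / co$tau_deph),
                 numeric(length(t2)))
    Cc <- matrix(Cc, nrow = length(t2))
    colnames(Cc) <- vapply(scheme$coherences, `[[`, "", "name")
    P <- cbind(P, Cc)
  }
  P
}

#' Transform-limited Gaussian pulse bandwidth
#'
#' Converts a Gaussian pulse's intensity-FWHM duration to its spectral FWHM
#' bandwidth using the time-bandwidth product 0.441:
#' `delta_nu (cm^-1) = 0.441 / (delta_t * c)` with c in cm/fs. An 8 fs pulse
#' corresponds to about 1839 cm^-1.
#'
#' @param duration_fwhm Pulse duration FWHM in fs (> 0).
#' @return Spectral bandwidth FWHM in cm^-1.
#' @export
pulse_bandwidth <- function(duration_fwhm) {
  if (!is.numeric(duration_fwhm) || any(duration_fwhm <= 0))
    stop("duration_fwhm must be > 0")
  c_cm_fs <- 2.99792458e-5  # speed of light, cm per fs
  0.441 / (duration_fwhm * c_cm_fs)
}
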
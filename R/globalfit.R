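# Global multiexponential fitting of 2DES datasets by variable projection:
# shared time constants across all pixels, per-pixel linear amplitudes, the
# amplitude maps being the 2D decay-associated spectra (2D-DAS). Positive DAS
# amplitude means the signal decays with that time constant, negative that it
# rises.

#' Configuration of a global multiexponential fit
#'
#' @param n_components Number of exponential components k (>= 1).
#' @param tau_initial Optional numeric vector of k initial time constants
#'   (fs); used as the first multi-start point.
#' @param tau_bounds Length-2 positive increasing vector bounding all time
#'   constants (fs).
#' @param t2_min Population times below this threshold (fs) are excluded from
#'   the fit; default 15 fs, suppressing pulse-overlap artifacts.
#' @param max_iterations Maximum outer (simplex) iterations per start.
#' @param convergence_tol Relative tolerance on the pooled sum of squared
#'   residuals for outer convergence.
#' @param seed Integer seed for the multi-start jitter.
#' @param n_starts Number of multi-start initial tau sets (log-spaced over
#'   the bounds with seeded jitter); best final SSR wins, ties broken by the
#'   smallest fast tau.
#' @param plateau If `TRUE`, add a constant (infinite-tau) component,
#'   representing dynamics much slower than the observation window.
#'
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(n_components, tau_initial = NULL,
                       tau_bounds = c(1, 20000), t2_min = 15,
                       max_iterations = 400, convergence_tol = 1e-10,
                       seed = 1L, n_starts = 5L, plateau = FALSE) {
  stopifnot(n_components >= 1L, length(tau_bounds) == 2L,
            tau_bounds[1] > 0, tau_bounds[2] > tau_bounds[1],
            t2_min >= 0, max_iterations >= 1, convergence_tol > 0,
            n_starts >= 1L)
  if (!is.null(tau_initial)) {
    stopifnot(length(tau_initial) == n_components, all(tau_initial > 0))
  }
  structure(list(n_components = as.integer(n_components),
                 tau_initial = tau_initial, tau_bounds = tau_bounds,
                 t2_min = t2_min, max_iterations = max_iterations,
                 convergence_tol = convergence_tol, seed = as.integer(seed),
                 n_starts = as.integer(n_starts), plateau = isTRUE(plateau)),
            class = "fit_config")
}

#' One decay-associated spectrum
#'
#' @param tau Time constant in fs (> 0), or `Inf` for a plateau component.
#' @param amplitude_map Matrix over (omega1, omega3) in signal units.
#' @param omega1,omega3 The dataset's wavenumber axes (cm^-1).
#' @return Object of class `das_component`.
#' @export
das_component <- function(tau, amplitude_map, omega1, omega3) {
  stopifnot(tau > 0, is.matrix(amplitude_map),
            nrow(amplitude_map) == length(omega1),
            ncol(amplitude_map) == length(omega3))
  structure(list(tau = tau, amplitude_map = amplitude_map,
                 omega1 = as.numeric(omega1), omega3 = as.numeric(omega3)),
            class = "das_component")
}

#' @export
print.das_component <- function(x, ...) {
  cat(sprintf("<das_component>  tau = %.4g fs, map %d x %d, range [%.3g, %.3g]\n",
              x$tau, nrow(x$amplitude_map), ncol(x$amplitude_map),
              min(x$amplitude_map), max(x$amplitude_map)))
  invisible(x)
}

# retained-time mask and pixel-trace matrix Y (nt_kept x npix);
# pixel index runs omega1-fastest.
dataset_traces <- function(dataset, t2_min) {
  keep <- dataset$t2 >= t2_min
  if (!any(keep)) stop("no t2 points retained above t2_min = ", t2_min)
  nt <- sum(keep)
  Y <- matrix(dataset$maps[keep, , ], nrow = nt)
  list(t2 = dataset$t2[keep], Y = Y, keep = keep)
}

exp_basis <- function(t2, taus, plateau = FALSE) {
  X <- exp(-outer(t2, 1 / taus))
  if (plateau) X <- cbind(X, 1)
  X
}

#' Per-pixel linear amplitudes for fixed time constants
#'
#' For fixed shared time constants, solves the exact ordinary-least-squares
#' problem of every pixel's t2 trace on the exponential basis
#' `exp(-t2 / tau_i)` (the linear subproblem of variable projection).
#'
#' @param dataset A `dataset_2des`.
#' @param taus Distinct positive time constants, fs.
#' @param t2_min Exclusion threshold (fs): only `t2 >= t2_min` is fitted.
#' @param plateau If `TRUE`, append a constant basis column.
#'
#' @return List with `amplitudes` (array `k x n1 x n3`), `residuals` (array
#'   `nt_kept x n1 x n3`), `ssr`, `taus`, `t2_used` and `n_points`.
#' @export
solve_amplitudes <- function(dataset, taus, t2_min = 15, plateau = FALSE) {
  stopifnot(inherits(dataset, "dataset_2des"), all(taus > 0))
  if (anyDuplicated(taus)) stop("taus must be distinct")
  tr <- dataset_traces(dataset, t2_min)
  if (length(tr$t2) < length(taus) + 1L)
    stop("need at least length(taus)+1 retained t2 points")
  X <- exp_basis(tr$t2, taus, plateau)
  cn <- kappa(X, exact = TRUE)
  if (!is.finite(cn) || cn > 1e10) {
    lt <- sort(log(taus))
    w <- which.min(diff(lt))
    stop(sprintf(
      "ill-conditioned exponential basis (condition %.3g); nearly equal taus %.4g and %.4g fs",
      cn, exp(lt[w]), exp(lt[w + 1])))
  }
  qrX <- qr(X)
  A <- qr.coef(qrX, tr$Y)                       # (k[+1]) x npix
  resid <- tr$Y - X %*% A
  n1 <- length(dataset$omega1); n3 <- length(dataset$omega3)
  list(amplitudes = array(A, dim = c(nrow(A), n1, n3)),
       residuals = array(resid, dim = c(nrow(resid), n1, n3)),
       ssr = sum(resid^2), taus = taus, t2_used = tr$t2,
       n_points = length(resid))
}

# fast pooled SSR for the outer search (normal equations; Y2 = sum(Y^2))
varpro_ssr <- function(t2, Y, Y2, taus, plateau) {
  X <- exp_basis(t2, taus, plateau)
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  A <- tryCatch(solve(XtX, XtY), error = function(e) NULL)
  if (is.null(A)) return(Inf)
  max(Y2 - sum(A * XtY), 0)
}

# deterministic multi-start tau sets (list of numeric vectors)
multistart_taus <- function(config) {
  k <- config$n_components
  lo <- log(5); hi <- log(5000)
  base <- if (k == 1L) sqrt(5 * 5000) else
    exp(seq(lo, hi, length.out = k + 2L))[2:(k + 1L)]
  starts <- list(base)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(config$seed)
  while (length(starts) < config$n_starts)
    starts[[length(starts) + 1L]] <- base * exp(stats::runif(k, -1.2, 1.2))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  if (!is.null(config$tau_initial))
    starts <- c(list(as.numeric(config$tau_initial)), starts)
  starts
}

#' Global multiexponential fit of a 2DES dataset
#'
#' Variable projection: an outer search over the k shared time constants
#' (parameterized on a log scale, multi-start) minimizes the pooled sum of
#' squared residuals, with all per-pixel amplitudes solved exactly by linear
#' least squares at each step ([solve_amplitudes()]). The result is one
#' decay-associated spectrum per time constant, sorted by ascending tau.
#' Deterministic for a given dataset and configuration.
#'
#' @param dataset A `dataset_2des`.
#' @param config A [fit_config()].
#'
#' @return Object of class `global_fit_result` with fields `components`
#'   (list of [das_component()], ascending tau), `taus`, `ssr`,
#'   `residual_maps` (array over retained t2), `n_points_used`, `bic`,
#'   `converged` and `at_bound` flags, and the configuration used.
#' @export
global_fit <- function(dataset, config) {
  stopifnot(inherits(dataset, "dataset_2des"), inherits(config, "fit_config"))
  tr <- dataset_traces(dataset, config$t2_min)
  k <- config$n_components
  if (length(tr$t2) < k + 1L)
    stop("need at least n_components+1 retained t2 points")
  Y2 <- sum(tr$Y^2)
  lb <- log(config$tau_bounds[1]); ub <- log(config$tau_bounds[2])
  obj <- function(lt) {
    lt <- pmin(pmax(lt, lb), ub)
    varpro_ssr(tr$t2, tr$Y, Y2, exp(lt), config$plateau)
  }
  best <- NULL
  for (start in multistart_taus(config)) {
    lt0 <- pmin(pmax(log(start), lb), ub)
    if (k == 1L) {
      op <- stats::optimize(function(l) obj(l), interval = c(lb, ub),
                            tol = 1e-10)
      cand <- list(lt = op$minimum, ssr = op$objective, converged = TRUE)
    } else {
      op <- stats::optim(lt0, obj, method = "Nelder-Mead",
                         control = list(maxit = config$max_iterations,
                                        reltol = config$convergence_tol))
      cand <- list(lt = pmin(pmax(op$par, lb), ub), ssr = op$value,
                   converged = op$convergence == 0)
    }
    if (is.null(best) || cand$ssr < best$ssr - 1e-12 * abs(best$ssr) ||
        (abs(cand$ssr - best$ssr) <= 1e-12 * abs(best$ssr) &&
         min(cand$lt) < min(best$lt)))
      best <- cand
  }
  taus <- sort(exp(best$lt))
  at_bound <- any(abs(log(taus) - lb) < 1e-3) || any(abs(log(taus) - ub) < 1e-3)
  if (at_bound)
    warning("a fitted time constant sits at a bound of tau_bounds")
  if (!best$converged)
    warning("outer search did not converge within max_iterations; ",
            "best-so-far returned")
  sol <- solve_amplitudes(dataset, taus, config$t2_min, config$plateau)
  comp_taus <- c(taus, if (config$plateau) Inf)
  components <- lapply(seq_along(comp_taus), function(i)
    das_component(comp_taus[i],
                  matrix(sol$amplitudes[i, , ],
                         length(dataset$omega1), length(dataset$omega3)),
                  dataset$omega1, dataset$omega3))
  npix <- length(dataset$omega1) * length(dataset$omega3)
  structure(list(components = components, taus = comp_taus, ssr = sol$ssr,
                 residual_maps = sol$residuals,
                 n_points_used = sol$n_points,
                 bic = fit_bic(sol$ssr, sol$n_points, k, npix, config$plateau),
                 converged = best$converged, at_bound = at_bound,
                 t2_used = sol$t2_used, config = config),
            class = "global_fit_result")
}

# Pooled BIC over n = retained points x pixels. Each parameter is penalized
# by the log of the number of observations that inform it: the k shared time
# constants see all n points, but each pixel's amplitudes are determined only
# by that pixel's nt retained trace points (effective-sample-size BIC for
# grouped data). Penalizing the k*npix amplitudes with log(n) instead would
# make the criterion blind to any shared component whose pooled evidence is
# large but whose per-pixel amplitude is modest.
fit_bic <- function(ssr, n, k, npix, plateau = FALSE) {
  nt <- n / npix
  n * log(ssr / n) + k * log(n) + (k + plateau) * npix * log(nt)
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat(sprintf("<global_fit_result>  k = %d, tau = %s fs, SSR = %.6g%s\n",
              length(x$taus),
              paste(sprintf("%.4g", x$taus), collapse = ", "),
              x$ssr, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Choose the number of exponential components by BIC
#'
#' Fits k = 1..k_max components and reports the pooled Bayesian information
#' criterion for each; the chosen k minimizes BIC.
#'
#' @param dataset A `dataset_2des`.
#' @param config A [fit_config()]; its `n_components` is overridden by each
#'   candidate k.
#' @param k_max Largest candidate model size (>= 1).
#'
#' @return List with `chosen_k`, `criteria` (data frame: k, ssr, bic,
#'   converged) and `fits` (list of `global_fit_result`, indexed by k).
#' @export
select_components <- function(dataset, config, k_max) {
  stopifnot(k_max >= 1L)
  fits <- vector("list", k_max)
  rows <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    cfg <- config; cfg$n_components <- as.integer(k)
    if (!is.null(cfg$tau_initial) && length(cfg$tau_initial) != k)
      cfg$tau_initial <- NULL
    fits[[k]] <- global_fit(dataset, cfg)
    rows[[k]] <- data.frame(k = k, ssr = fits[[k]]$ssr, bic = fits[[k]]$bic,
                            converged = fits[[k]]$converged)
  }
  criteria <- do.call(rbind, rows)
  list(chosen_k = criteria$k[which.min(criteria$bic)], criteria = criteria,
       fits = fits)
}
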
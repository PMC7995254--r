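# Frenkel exciton model of coupled chlorophylls: transition dipoles from
# structure, point-dipole couplings, site Hamiltonian, eigenstates.

# Point-dipole prefactor in cm^-1 when mu is in Debye and R in Angstrom:
# V = C * kappa * mu_a * mu_b / R^3 with
# C = 1 D^2 / (4 pi eps0 * 1 A^3), expressed in wavenumbers:
#   (1e-36 statC^2 cm^2) / (1e-24 cm^3) / (h c) = 5034.1 cm^-1 A^3 D^-2.
DIPOLE_COUPLING_CM <- 5034.1

#' Chromophore with a Qy transition dipole
#'
#' A minimal description of one pigment for excitonic modelling: where it
#' sits, in which direction its Qy transition dipole points, how strong the
#' dipole is, and its site (monomer) transition energy.
#'
#' @param label Short unique identifier, e.g. `"Chl1"`.
#' @param center Numeric length-3 position of the dipole origin
#'   (conventionally the central Mg atom), in Angstrom.
#' @param qy_unit Numeric length-3 direction of the Qy transition dipole;
#'   normalized internally, must be non-zero.
#' @param dipole_magnitude Transition dipole strength in Debye (> 0).
#'   Literature monomer values: 4.58 D for Chl a, 3.83 D for Chl b.
#' @param site_energy Site transition energy in cm^-1 (> 0).
#'
#' @return An object of class `chromophore`.
#' @export
chromophore <- function(label, center, qy_unit, dipole_magnitude, site_energy) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(center), length(center) == 3L, all(is.finite(center)),
            is.numeric(qy_unit), length(qy_unit) == 3L, all(is.finite(qy_unit)))
  nrm <- sqrt(sum(qy_unit^2))
  if (nrm < 1e-12)
    stop("qy_unit must be a non-zero vector for chromophore '", label, "'")
  if (!is.numeric(dipole_magnitude) || dipole_magnitude <= 0)
    stop("dipole_magnitude must be > 0 for chromophore '", label, "'")
  if (!is.numeric(site_energy) || site_energy <= 0)
    stop("site_energy must be > 0 (cm^-1) for chromophore '", label, "'")
  structure(
    list(label = label, center = as.numeric(center),
         qy_unit = as.numeric(qy_unit) / nrm,
         dipole_magnitude = as.numeric(dipole_magnitude),
         site_energy = as.numeric(site_energy)),
    class = "chromophore")
}

#' @export
print.chromophore <- function(x, ...) {
  cat(sprintf("<chromophore %s>  mu = %.2f D, E = %.0f cm^-1\n",
              x$label, x$dipole_magnitude, x$site_energy))
  invisible(x)
}

# dipole vector in Debye
dipole_vector <- function(ch) ch$dipole_magnitude * ch$qy_unit

#' Excitonic coupling term between a labelled pair of chromophores
#'
#' Usually produced by [point_dipole_coupling()]; the constructor is exposed
#' so that couplings tabulated elsewhere (e.g. from transition charges) can
#' be fed into [build_hamiltonian()] directly.
#'
#' @param pair Character vector of the two chromophore labels.
#' @param V Coupling in cm^-1 (symmetric under pair swap by construction).
#' @param distance_R Center-center distance in Angstrom (> 0, `NA` allowed).
#' @param kappa Orientation factor in \[-2, 2\] (`NA` allowed).
#' @param point_dipole_valid Whether the point-dipole approximation holds.
#'
#' @return Object of class `coupling_term`.
#' @export
coupling_term <- function(pair, V, distance_R = NA_real_, kappa = NA_real_,
                          point_dipole_valid = TRUE) {
  stopifnot(is.character(pair), length(pair) == 2L, pair[1] != pair[2],
            is.numeric(V), length(V) == 1L, is.finite(V))
  if (!is.na(distance_R) && distance_R <= 0)
    stop("distance_R must be > 0")
  if (!is.na(kappa) && (kappa < -2 || kappa > 2))
    stop("kappa must lie in [-2, 2]")
  structure(list(pair = pair, distance_R = distance_R, kappa = kappa, V = V,
                 point_dipole_valid = isTRUE(point_dipole_valid)),
            class = "coupling_term")
}

#' Point-dipole excitonic coupling between two chromophores
#'
#' Evaluates the dipole-dipole interaction
#' \deqn{V = C \kappa \mu_a \mu_b / R^3,\qquad
#'       \kappa = \hat\mu_a\cdot\hat\mu_b -
#'                3(\hat\mu_a\cdot\hat R)(\hat\mu_b\cdot\hat R),}
#' with C = 5034.1 cm^-1 A^3 D^-2 (vacuum, unscreened). An optional
#' `screening` factor multiplies V to emulate a dielectric environment.
#'
#' @param a,b `chromophore` objects with distinct centers.
#' @param screening Multiplicative screening factor applied to V (default 1,
#'   i.e. unscreened vacuum coupling).
#'
#' @return An object of class `coupling_term` with fields `pair`,
#'   `distance_R` (Angstrom), `kappa`, `V` (cm^-1) and a logical
#'   `point_dipole_valid` flag (FALSE when R < 2 Angstrom, where the
#'   point-dipole approximation breaks down).
#' @export
point_dipole_coupling <- function(a, b, screening = 1) {
  stopifnot(inherits(a, "chromophore"), inherits(b, "chromophore"))
  rvec <- b$center - a$center
  R <- sqrt(sum(rvec^2))
  if (R < 1e-9)
    stop("coincident centers for pair (", a$label, ", ", b$label, ")")
  valid <- TRUE
  if (R < 2) {
    warning("center-center distance ", signif(R, 3),
            " A < 2 A: point-dipole approximation invalid for pair (",
            a$label, ", ", b$label, ")")
    valid <- FALSE
  }
  rhat <- rvec / R
  kappa <- sum(a$qy_unit * b$qy_unit) -
    3 * sum(a$qy_unit * rhat) * sum(b$qy_unit * rhat)
  V <- screening * DIPOLE_COUPLING_CM * kappa *
    a$dipole_magnitude * b$dipole_magnitude / R^3
  coupling_term(c(a$label, b$label), V, distance_R = R, kappa = kappa,
                point_dipole_valid = valid)
}

#' @export
print.coupling_term <- function(x, ...) {
  cat(sprintf("<coupling %s-%s>  R = %.2f A, kappa = %+.3f, V = %+.1f cm^-1\n",
              x$pair[1], x$pair[2], x$distance_R, x$kappa, x$V))
  invisible(x)
}

#' Assemble the Frenkel exciton Hamiltonian
#'
#' Builds the N x N site Hamiltonian of a pigment assembly: site energies on
#' the diagonal, pairwise couplings off-diagonal. Pairs missing from
#' `couplings` default to zero with a notice.
#'
#' @param chromophores List of `chromophore` objects with unique labels.
#' @param couplings List of `coupling_term` objects, or `NULL` to compute all
#'   pairwise point-dipole couplings from the geometry.
#' @param screening Screening factor forwarded to [point_dipole_coupling()]
#'   when `couplings` is `NULL`.
#'
#' @return An object of class `exciton_model` (not yet diagonalized; see
#'   [diagonalize()]).
#' @export
build_hamiltonian <- function(chromophores, couplings = NULL, screening = 1) {
  stopifnot(is.list(chromophores), length(chromophores) >= 1L,
            all(vapply(chromophores, inherits, TRUE, "chromophore")))
  labels <- vapply(chromophores, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicate chromophore labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  n <- length(chromophores)
  if (is.null(couplings)) {
    couplings <- list()
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
      couplings[[length(couplings) + 1L]] <-
        point_dipole_coupling(chromophores[[i]], chromophores[[j]], screening)
  }
  H <- diag(vapply(chromophores, `[[`, 0, "site_energy"), n)
  dimnames(H) <- list(labels, labels)
  seen <- matrix(FALSE, n, n)
  for (cp in couplings) {
    i <- match(cp$pair[1], labels); j <- match(cp$pair[2], labels)
    if (is.na(i) || is.na(j))
      stop("coupling pair (", paste(cp$pair, collapse = ", "),
           ") refers to unknown chromophore")
    H[i, j] <- H[j, i] <- cp$V
    seen[i, j] <- seen[j, i] <- TRUE
  }
  if (n > 1L) {
    miss <- which(upper.tri(seen) & !seen, arr.ind = TRUE)
    if (nrow(miss) > 0L)
      message("build_hamiltonian: ", nrow(miss),
              " pair(s) without a coupling term set to 0: ",
              paste(sprintf("(%s,%s)", labels[miss[, 1]], labels[miss[, 2]]),
                    collapse = " "))
  }
  structure(
    list(chromophores = chromophores, couplings = couplings, hamiltonian = H,
         exciton_energies = NULL, exciton_vectors = NULL,
         exciton_dipoles = NULL, gaps = NULL),
    class = "exciton_model")
}

#' Diagonalize an exciton model
#'
#' Solves the site Hamiltonian for exciton energies (ascending) and
#' orthonormal eigenvectors, and forms exciton transition dipoles as the
#' eigenvector-weighted sums of the site dipole vectors. The sign of each
#' eigenvector is fixed so its first non-zero component is positive.
#'
#' @param model An `exciton_model` from [build_hamiltonian()].
#'
#' @return The model with `exciton_energies`, `exciton_vectors` (columns are
#'   eigenvectors), `exciton_dipoles` (N x 3 matrix, Debye) and `gaps`
#'   (pairwise energy differences, cm^-1) filled in.
#' @export
diagonalize <- function(model) {
  stopifnot(inherits(model, "exciton_model"))
  H <- model$hamiltonian
  if (max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H))))
    stop("hamiltonian is not symmetric")
  es <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(es$values)              # ascending
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vecs))) {     # reproducible sign convention
    nz <- which(abs(vecs[, k]) > 1e-12)[1]
    if (!is.na(nz) && vecs[nz, k] < 0) vecs[, k] <- -vecs[, k]
  }
  mu_site <- t(vapply(model$chromophores, dipole_vector, numeric(3)))
  mu_exc <- t(vecs) %*% mu_site        # N x 3, Debye
  model$exciton_energies <- vals
  model$exciton_vectors <- vecs
  model$exciton_dipoles <- mu_exc
  model$gaps <- outer(vals, vals, `-`)
  model
}

#' @export
print.exciton_model <- function(x, ...) {
  n <- length(x$chromophores)
  cat(sprintf("<exciton_model>  %d sites", n))
  if (!is.null(x$exciton_energies)) {
    cat("; exciton energies (cm^-1): ",
        paste(sprintf("%.1f", x$exciton_energies), collapse = ", "), sep = "")
  } else cat(" (not diagonalized)")
  cat("\n")
  invisible(x)
}

#' Signed energy gap between two exciton states
#'
#' For a degenerate dimer with coupling V the gap between the two exciton
#' states is exactly 2V.
#'
#' @param model A diagonalized `exciton_model`.
#' @param i,j State indices (ascending energy order, 1-based).
#'
#' @return `exciton_energies[j] - exciton_energies[i]` in cm^-1.
#' @export
exciton_gap <- function(model, i, j) {
  stopifnot(inherits(model, "exciton_model"))
  if (is.null(model$exciton_energies)) stop("model not diagonalized")
  n <- length(model$exciton_energies)
  if (i == j) stop("i and j must differ")
  if (i < 1 || j < 1 || i > n || j > n)
    stop("state index out of range 1..", n)
  model$exciton_energies[j] - model$exciton_energies[i]
}

#' Broadened stick absorption spectrum of an exciton model
#'
#' Sum of Gaussians centered at the exciton energies with areas proportional
#' to the exciton dipole strengths |mu_k|^2. The integrated area is
#' independent of the broadening.
#'
#' @param model A diagonalized `exciton_model`.
#' @param broadening_fwhm Gaussian FWHM in cm^-1 (> 0).
#' @param axis Optional wavenumber axis; default spans the exciton energies
#'   plus/minus 4 FWHM in 1 cm^-1 steps.
#'
#' @return A data frame with columns `wavenumber` (cm^-1) and `intensity`
#'   (arbitrary units, dipole strength per cm^-1).
#' @export
stick_absorption <- function(model, broadening_fwhm, axis = NULL) {
  stopifnot(inherits(model, "exciton_model"))
  if (is.null(model$exciton_energies)) stop("model not diagonalized")
  if (!is.numeric(broadening_fwhm) || broadening_fwhm <= 0)
    stop("broadening_fwhm must be > 0")
  E <- model$exciton_energies
  strength <- rowSums(model$exciton_dipoles^2)
  if (is.null(axis))
    axis <- seq(min(E) - 4 * broadening_fwhm, max(E) + 4 * broadening_fwhm,
                by = 1)
  sigma <- broadening_fwhm / (2 * sqrt(2 * log(2)))
  intensity <- rep(0, length(axis))
  for (k in seq_along(E))
    intensity <- intensity +
      strength[k] * stats::dnorm(axis, mean = E[k], sd = sigma)
  data.frame(wavenumber = axis, intensity = intensity)
}

#' Coupling table of an exciton model
#'
#' @param model An `exciton_model`.
#' @return Data frame with one row per coupling term: labels, distance
#'   (Angstrom), orientation factor kappa and V (cm^-1).
#' @export
coupling_table <- function(model) {
  stopifnot(inherits(model, "exciton_model"))
  do.call(rbind, lapply(model$couplings, function(cp)
    data.frame(a = cp$pair[1], b = cp$pair[2],
               distance_A = cp$distance_R, kappa = cp$kappa, V_cm1 = cp$V)))
}

#' Extract chromophores from a macromolecular structure
#'
#' Reads a PDB or mmCIF file and returns one [chromophore()] per selected
#' pigment residue. The dipole origin is the central Mg atom and the Qy
#' direction is the normalized vector from atom `NB` to atom `ND` of the
#' chlorin ring (a common convention; both atom names and the center atom are
#' configurable since conventions differ between studies).
#'
#' @param path Path to a PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param pigment_selector Residue names to select (default chlorophyll a/b:
#'   `c("CLA", "CHL")`).
#' @param dipole_magnitudes Named numeric vector of per-residue-name dipole
#'   magnitudes in Debye (defaults: literature monomer values, Chl a 4.58 D,
#'   Chl b 3.83 D).
#' @param site_energies Named numeric vector of per-residue-name site
#'   energies in cm^-1 (defaults near the Qy maxima of protein-bound Chl a/b).
#' @param qy_atoms Length-2 character vector naming the tail and head atoms
#'   of the Qy direction (default `c("NB", "ND")`).
#' @param center_atom Atom used as the dipole origin (default `"MG"`).
#'
#' @return List of `chromophore` objects labelled `<resid><chain><resno>`.
#' @export
parse_structure <- function(path,
                            pigment_selector = c("CLA", "CHL"),
                            dipole_magnitudes = c(CLA = 4.58, CHL = 3.83),
                            site_energies = c(CLA = 14900, CHL = 15250),
                            qy_atoms = c("NB", "ND"),
                            center_atom = "MG") {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  sel <- at[at$resid %in% pigment_selector, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no pigments found: no residues named ",
         paste(pigment_selector, collapse = "/"), " in ", path)
  key <- paste(sel$resid, sel$chain, sel$resno)
  out <- list()
  for (k in unique(key)) {
    res <- sel[key == k, , drop = FALSE]
    resid <- res$resid[1]
    lab <- paste0(resid, res$chain[1], res$resno[1])
    coord <- function(name) {
      row <- res[trimws(res$elety) == name, , drop = FALSE]
      if (nrow(row) == 0L)
        stop("residue ", res$resid[1], " ", res$resno[1], " chain ",
             res$chain[1], " lacks atom ", name)
      as.numeric(row[1, c("x", "y", "z")])
    }
    mg <- coord(center_atom)
    qy <- coord(qy_atoms[2]) - coord(qy_atoms[1])
    mu <- dipole_magnitudes[[resid]]
    e0 <- site_energies[[resid]]
    if (is.null(mu) || is.null(e0))
      stop("no dipole_magnitude/site_energy default for residue name ", resid)
    out[[lab]] <- chromophore(lab, mg, qy, mu, e0)
  }
  unname(out)
}

#' Write the coupling table and Hamiltonian as delimited text
#'
#' @param model An `exciton_model`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_exciton_tables <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, "couplings.tsv")
  hpath <- file.path(dir, "hamiltonian.tsv")
  ct <- coupling_table(model)
  names(ct) <- c("a", "b", "distance_A", "kappa", "V_cm1")
  writeLines("# point-dipole couplings: distance in Angstrom, V in cm^-1",
             cpath)
  suppressWarnings(utils::write.table(ct, cpath, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  writeLines("# site Hamiltonian, cm^-1", hpath)
  suppressWarnings(utils::write.table(
    format(model$hamiltonian, digits = 9), hpath, sep = "\t", quote = FALSE,
    col.names = NA, append = TRUE))
  invisible(c(cpath, hpath))
}
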
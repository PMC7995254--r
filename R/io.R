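# Dataset container I/O and the end-to-end pipeline: one delimited-text
# matrix per t2 value plus a JSON metadata sidecar; simulate -> fit ->
# analyze with a reproducible manifest.

#' Write a 2DES dataset to a directory container
#'
#' The container holds one tab-delimited matrix per t2 value
#' (`map_0001.tsv`, ...; omega1 along rows, omega3 along columns, 9
#' significant digits) and a `metadata.json` sidecar with the axes, t2 list,
#' units, and provenance metadata. Reading the container back reproduces the
#' data to 9 significant digits.
#'
#' @param dataset A `dataset_2des`.
#' @param path Directory to create/fill.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "dataset_2des"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nt <- length(dataset$t2)
  files <- sprintf("map_%04d.tsv", seq_len(nt))
  for (i in seq_len(nt)) {
    m <- matrix(dataset$maps[i, , ],
                length(dataset$omega1), length(dataset$omega3))
    utils::write.table(formatC(m, digits = 9, format = "g"),
                       file.path(path, files[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  meta <- list(format = "exciton2des dataset container v1",
               units = list(omega = "cm^-1", t2 = "fs"),
               layout = "omega1 along rows (ascending), omega3 along columns (ascending)",
               omega1 = dataset$omega1, omega3 = dataset$omega3,
               t2 = dataset$t2, map_files = files,
               metadata = dataset$metadata)
  writeLines(jsonlite::toJSON(meta, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(path, "metadata.json"))
  invisible(path)
}

#' Read a 2DES dataset from a directory container
#'
#' @param path Directory written by [write_dataset()].
#' @return A `dataset_2des`.
#' @export
read_dataset <- function(path) {
  side <- file.path(path, "metadata.json")
  if (!file.exists(side))
    stop("schema error: missing metadata sidecar ", side)
  meta <- jsonlite::fromJSON(side, simplifyVector = TRUE)
  for (field in c("omega1", "omega3", "t2", "map_files"))
    if (is.null(meta[[field]]))
      stop("schema error: metadata field '", field, "' missing")
  if (length(meta$t2) != length(meta$map_files))
    stop("schema error: t2 count (", length(meta$t2),
         ") does not match map file count (", length(meta$map_files), ")")
  n1 <- length(meta$omega1); n3 <- length(meta$omega3)
  maps <- array(NA_real_, c(length(meta$t2), n1, n3))
  for (i in seq_along(meta$map_files)) {
    f <- file.path(path, meta$map_files[i])
    if (!file.exists(f)) stop("schema error: missing map file ", f)
    m <- as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
    if (nrow(m) != n1 || ncol(m) != n3)
      stop("schema error: map ", meta$map_files[i], " is ", nrow(m), " x ",
           ncol(m), ", expected ", n1, " x ", n3)
    maps[i, , ] <- m
  }
  md <- meta$metadata
  dataset_2des(meta$omega1, meta$omega3, meta$t2, maps,
               metadata = if (is.null(md)) list() else md)
}

#' Pipeline configuration
#'
#' @param complex One of `"Lv-a"`, `"Lv-b"`, `"Bo-a"`, `"Bo-b"` (selects the
#'   corresponding fixture recipe) or `"custom"` (then `recipe` must be
#'   given).
#' @param structure_path Optional PDB/mmCIF file; if given, the coupling
#'   stage runs first.
#' @param mu_chla,mu_chlb Species transition-dipole defaults in Debye
#'   (literature monomer values 4.58 and 3.83 D).
#' @param recipe Optional [simulation_recipe()] overriding the named fixture.
#' @param k_max Largest candidate component count for model selection.
#' @param t2_min Fit exclusion threshold, fs.
#' @param min_prominence DAS extremum threshold fraction.
#' @param out_dir Output directory.
#' @param seed Integer seed governing the synthetic dataset and the fit
#'   multi-start.
#'
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(complex = c("Lv-a", "Lv-b", "Bo-a", "Bo-b",
                                        "custom"),
                            structure_path = NULL, mu_chla = 4.58,
                            mu_chlb = 3.83, recipe = NULL, k_max = 4L,
                            t2_min = 15, min_prominence = 0.2,
                            out_dir = tempfile("exciton2des_run_"),
                            seed = 1L) {
  complex <- match.arg(complex)
  stopifnot(mu_chla > 0, mu_chlb > 0, k_max >= 1L)
  if (complex == "custom" && is.null(recipe))
    stop("complex = 'custom' requires a recipe")
  structure(list(complex = complex, structure_path = structure_path,
                 mu_chla = mu_chla, mu_chlb = mu_chlb, recipe = recipe,
                 k_max = as.integer(k_max), t2_min = t2_min,
                 min_prominence = min_prominence, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_log <- function(stage, ..., quiet = FALSE) {
  if (!quiet) message("[", stage, "] ", ...)
}

#' Run the full pipeline: couplings, simulate, fit, analyze
#'
#' Executes the stages in order, writing every intermediate under the
#' configured output directory, and a `manifest.json` recording seeds, file
#' hashes, fitted time constants and the chosen model size. Identical
#' configuration and seed give identical manifest hashes.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage log messages.
#'
#' @return Invisibly, a list with `recipe`, `dataset`, `selection`, `fit`,
#'   `analysis`, `manifest` and `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(complex = config$complex, seed = config$seed,
                   package_version = pkg_version())

  # stage 1: excitonic couplings from structure (optional)
  model <- NULL
  if (!is.null(config$structure_path)) {
    pipeline_log("couplings", "parsing ", config$structure_path,
                 quiet = quiet)
    chrom <- parse_structure(
      config$structure_path,
      dipole_magnitudes = c(CLA = config$mu_chla, CHL = config$mu_chlb))
    model <- diagonalize(build_hamiltonian(chrom))
    write_exciton_tables(model, file.path(config$out_dir, "couplings"))
    manifest$n_chromophores <- length(chrom)
    manifest$exciton_energies_cm1 <- model$exciton_energies
  } else {
    pipeline_log("couplings", "no structure supplied; stage skipped",
                 quiet = quiet)
    manifest$couplings <- "skipped (no structure_path)"
  }

  # stage 2: synthetic dataset
  recipe <- config$recipe
  if (is.null(recipe)) recipe <- fixture_recipes(config$seed)[[config$complex]]
  pipeline_log("simulate", "recipe ", recipe$name, ", seed ", recipe$seed,
               quiet = quiet)
  dataset <- generate_dataset(recipe)
  ds_dir <- file.path(config$out_dir, "dataset")
  write_dataset(dataset, ds_dir)
  manifest$recipe_hash <- dataset$metadata$recipe_hash

  # stage 3: global fit with model selection
  pipeline_log("fit", "model selection k = 1..", config$k_max, quiet = quiet)
  cfg <- fit_config(n_components = 1L, t2_min = config$t2_min,
                    seed = config$seed)
  selection <- select_components(dataset, cfg, config$k_max)
  fit <- selection$fits[[selection$chosen_k]]
  manifest$chosen_k <- selection$chosen_k
  manifest$taus_fs <- fit$taus
  manifest$ssr <- fit$ssr
  fit_dir <- file.path(config$out_dir, "fit")
  dir.create(fit_dir, showWarnings = FALSE)
  for (i in seq_along(fit$components)) {
    utils::write.table(
      formatC(fit$components[[i]]$amplitude_map, digits = 9, format = "g"),
      file.path(fit_dir, sprintf("das_%02d.tsv", i)), sep = "\t",
      quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(selection$criteria,
                     file.path(fit_dir, "model_selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 4: DAS analysis
  pipeline_log("analyze", "DAS interpretation", quiet = quiet)
  analysis <- analyze_fit(fit, min_prominence = config$min_prominence)
  summary_df <- data.frame(
    complex = config$complex, chosen_k = selection$chosen_k,
    taus_fs = paste(sprintf("%.6g", fit$taus), collapse = ","),
    n_states = analysis$states$n_states,
    state_energies_cm1 = paste(sprintf("%.1f", analysis$states$energies),
                               collapse = ","),
    relaxation_gap_cm1 = if (!is.null(analysis$gap)) analysis$gap$gap else NA)
  utils::write.table(summary_df, file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$n_states <- analysis$states$n_states
  manifest$state_energies_cm1 <- analysis$states$energies
  manifest$relaxation_gap_cm1 <- if (!is.null(analysis$gap))
    analysis$gap$gap else NA

  # manifest with content hashes of every machine-readable output
  outputs <- sort(setdiff(
    list.files(config$out_dir, recursive = TRUE, full.names = TRUE),
    file.path(config$out_dir, "manifest.json")))
  hashes <- tools::md5sum(outputs)
  names(hashes) <- sub(paste0("^", config$out_dir, "/?"), "", names(hashes))
  manifest$files <- as.list(hashes)
  writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(config$out_dir, "manifest.json"))
  pipeline_log("done", "outputs in ", config$out_dir, quiet = quiet)
  invisible(list(recipe = recipe, dataset = dataset, selection = selection,
                 fit = fit, analysis = analysis, manifest = manifest,
                 out_dir = config$out_dir, exciton_model = model))
}
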
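#' Run the full synthetic analysis pipeline
#'
#' Generates synthetic inputs with known ground truth and runs all five
#' analyses — composition conversions, assembly-energy profile,
#' conformational landscape, preferential-solvation profile and
#' umbrella-sampling WHAM — writing their tabular outputs and a run manifest
#' (parameters, seed, package version, output checksums) into `out_dir`.
#' Numeric outputs are deterministic for a fixed seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; all randomness derives from it.
#' @param n_per_family Conformations per planted family (default 60).
#' @param n_frames Solvated frames for the solvation profile (default 30).
#' @param n_per_window Metropolis samples per umbrella window (default 1000).
#' @return (Invisibly) the manifest as a list.
#' @export
run_demo <- function(out_dir, seed = 42, n_per_family = 60, n_frames = 30,
                     n_per_window = 1000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    stop("`out_dir` is not writable: ", out_dir, call. = FALSE)
  }
  t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  outputs <- character(0)
  put <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(tibble::as_tibble(x), path)
    outputs <<- c(outputs, path)
    path
  }

  # 1. solvent compositions of the named study mixtures
  comps <- dplyr::bind_rows(
    composition_table(mass_fraction = 0.5, label = "~50% wt"),
    composition_table(molarity = 4, label = "4 M"),
    composition_table(volume_fraction = 0.05, label = "5% vol"),
    composition_table(molar_ratio = 0, label = "pure water")
  )
  put(comps, "compositions.csv")

  # 2. assembly-energy profile with a planted -5 kJ/mol per molecule
  tab <- make_energy_table(
    epsilon_per_molecule = -5, e_solvent_unit = -12,
    systems = tibble::tibble(
      n_peptoid = c(1, 6, 12, 24), m_units = c(400, 380, 360, 320),
      label = c("isolated", "6-mer stack", "nanofiber", "nanosheet")
    )
  )
  put(assembly_profile(tab$records, tab$reference), "assembly_profile.csv")

  # 3. conformational landscape on three planted families
  confset <- make_conformation_set(
    tibble::tibble(shape = c("coiled_C", "semi_open", "extended"),
                   count = n_per_family, noise_sigma = 0.3),
    seed = seed
  )
  land <- conformational_landscape(confset, seed = seed)
  put(land$points, "landscape_points.csv")
  put(tidy(land), "landscape_clusters.csv")
  put(rmsd_histogram(confset, make_backbone(20, "coiled_C")), "rmsd_histogram.csv")

  # 4. preferential solvation with a planted 3.5x surface enhancement
  solute <- make_backbone(20, "extended")
  frames <- lapply(seq_len(n_frames), function(i) {
    make_solvated_frame(solute, n_thf = 150, n_water = 2000,
                        enhancement = list(factor = 3.5, decay = 3),
                        seed = seed + i)
  })
  prof <- solvation_profile(frames, bin_width = 0.5)
  put(prof, "solvation_profile.csv")

  # 5. umbrella sampling + WHAM on the 5 kJ/mol double well
  samples <- sample_umbrella("doublewell", build_windows(-0.15, 1.25, 0.1),
                             force_constant = 200,
                             n_per_window = n_per_window, seed = seed)
  pmf <- wham(samples, bin_width = 0.05, range = c(-0.3, 1.3))
  pmf_path <- file.path(out_dir, "pmf.tsv")
  write_pmf_tsv(pmf, pmf_path)
  outputs <- c(outputs, pmf_path)

  manifest <- list(
    command = "run_demo",
    package = "peptoidsolv",
    version = as.character(utils::packageVersion("peptoidsolv")),
    seed = seed,
    parameters = list(n_per_family = n_per_family, n_frames = n_frames,
                      n_per_window = n_per_window),
    started = t0,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
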
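#' Read backbone conformations from a PDB file
#'
#' Reads single- or multi-model PDB files and extracts one conformation per
#' model. By default all heavy atoms are kept (hydrogen stripped); an atom
#' selection narrows this to, e.g., specific atom names or residues. Parsing
#' is delegated to \pkg{bio3d}.
#'
#' @param file Path to a PDB file.
#' @param atom_names Optional character vector of atom names (PDB `elety`)
#'   to keep, e.g. backbone heavy atoms.
#' @param resid Optional residue-name filter.
#' @param source,solvent_label Provenance recorded on every conformation.
#' @return A conformation-set tibble (see [conformation_set()]).
#' @export
read_conformations_pdb <- function(file, atom_names = NULL, resid = NULL,
                                   source = "isolated", solvent_label = "") {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  keep <- !grepl("^H", trimws(pdb$atom$elety))
  if (!is.null(atom_names)) keep <- keep & trimws(pdb$atom$elety) %in% atom_names
  if (!is.null(resid)) keep <- keep & trimws(pdb$atom$resid) %in% resid
  if (!any(keep)) stop("atom selection matched nothing", call. = FALSE)
  xyz_idx <- bio3d::atom2xyz(which(keep))
  xyz <- pdb$xyz[, xyz_idx, drop = FALSE]
  confs <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  conformation_set(confs, source = source, solvent_label = solvent_label)
}

#' Write a conformation to PDB
#'
#' @param conf A [conformation()] or n x 3 matrix.
#' @param file Output path.
#' @param elety Atom names to write (recycled; default `"CA"` so generic
#'   viewers render the chain).
#' @export
write_conformation_pdb <- function(conf, file, elety = "CA") {
  m <- as.matrix(conf)
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(m)),
    elety = rep_len(elety, nrow(m)),
    resid = rep("GLY", nrow(m)),
    resno = seq_len(nrow(m))
  )
  invisible(file)
}

#' Read / write multi-frame XYZ trajectories
#'
#' The XYZ trajectory format is a concatenation of frames, each an atom
#' count line, a comment line and one `element x y z` line per atom.
#'
#' @param file Path to an XYZ file.
#' @return For `read_xyz_trajectory`: a list of n x 3 coordinate matrices
#'   with the element symbols in attribute `elements`.
#' @export
read_xyz_trajectory <- function(file) {
  lines <- readLines(file)
  frames <- list()
  elements <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i, call. = FALSE)
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    elements <- vapply(parts, `[[`, character(1), 1)
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- coords
    i <- i + 2 + n
  }
  attr(frames, "elements") <- elements
  frames
}

#' @rdname read_xyz_trajectory
#' @param frames List of n x 3 coordinate matrices.
#' @param elements Element symbols (recycled; default `"C"`).
#' @param comment Comment line written per frame.
#' @export
write_xyz_trajectory <- function(frames, file, elements = "C", comment = "") {
  if (!is.list(frames)) frames <- list(frames)
  con <- file(file, "w")
  on.exit(close(con))
  for (fr in frames) {
    fr <- as.matrix(fr)
    el <- rep_len(elements, nrow(fr))
    writeLines(c(
      as.character(nrow(fr)), comment,
      sprintf("%s %.6f %.6f %.6f", el, fr[, 1], fr[, 2], fr[, 3])
    ), con)
  }
  invisible(file)
}

#' Read umbrella-sampling windows from a metadata file
#'
#' The common umbrella-sampling layout: a metadata file with one line per
#' window — `timeseries_path center force_constant` — where each time-series
#' file holds two whitespace-separated columns (time, collective variable).
#' Relative time-series paths are resolved against the metadata file's
#' directory.
#'
#' @param meta_file Path to the metadata file.
#' @return A long tibble (`center`, `force_constant`, `cv`) for [wham()].
#' @export
read_umbrella_meta <- function(meta_file) {
  meta <- utils::read.table(meta_file, header = FALSE,
                            col.names = c("path", "center", "force_constant"))
  base <- dirname(meta_file)
  purrr::pmap(meta, function(path, center, force_constant) {
    p <- if (file.exists(path)) path else file.path(base, path)
    ts <- utils::read.table(p, header = FALSE)
    umbrella_window(center, ts[[2]], force_constant)
  }) |> purrr::list_rbind()
}

#' Write a PMF profile as TSV
#'
#' @param pmf A `pmf_result` (or the tibble from [pmf_uncertainty()]).
#' @param file Output path.
#' @export
write_pmf_tsv <- function(pmf, file) {
  readr::write_tsv(tibble::as_tibble(pmf), file)
  invisible(file)
}

#' Read assembly-energy records from CSV
#'
#' Expects columns `label`, `solvent_label`, `n_peptoid`, `m_units`,
#' `e_total`.
#'
#' @param file CSV path.
#' @return A validated tibble of energy records.
#' @export
read_energy_records <- function(file) {
  rec <- readr::read_csv(file, show_col_types = FALSE)
  needed <- c("label", "solvent_label", "n_peptoid", "m_units", "e_total")
  miss <- setdiff(needed, names(rec))
  if (length(miss)) {
    stop("energy CSV lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  rec
}

#' Export a density map as a text grid or OpenDX file
#'
#' `write_density_grid` writes one `ix iy iz density` row per voxel (TSV);
#' `write_density_dx` writes an OpenDX scalar field readable by common
#' molecular viewers.
#'
#' @param map A [density_map()].
#' @param file Output path.
#' @export
write_density_grid <- function(map, file) {
  d <- dim(map)
  grid <- expand.grid(ix = seq_len(d[1]), iy = seq_len(d[2]), iz = seq_len(d[3]))
  grid$density <- as.vector(unclass(map))
  readr::write_tsv(tibble::as_tibble(grid), file)
  invisible(file)
}

#' @rdname write_density_grid
#' @export
write_density_dx <- function(map, file) {
  d <- dim(map)
  vox <- attr(map, "voxel")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", vox[1] / 2, vox[2] / 2, vox[3] / 2),
    sprintf("delta %.4f 0 0", vox[1]),
    sprintf("delta 0 %.4f 0", vox[2]),
    sprintf("delta 0 0 %.4f", vox[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", prod(d))
  ), con)
  # OpenDX expects z fastest
  vals <- as.vector(aperm(unclass(map), c(3, 2, 1)))
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0) {
    writeLines(sprintf("%.6g %.6g %.6g",
                       vals[seq(1, n3, 3)], vals[seq(2, n3, 3)], vals[seq(3, n3, 3)]), con)
  }
  if (n3 < length(vals)) {
    writeLines(paste(sprintf("%.6g", vals[(n3 + 1):length(vals)]), collapse = " "), con)
  }
  writeLines('attribute "dep" string "positions"', con)
  invisible(file)
}
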
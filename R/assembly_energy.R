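#' Per-unit potential energy of a solvent-only reference box
#'
#' The assembly-energy statistic measures peptoid stability against an
#' equilibrated solvent-only system: a box of `m_units` virtual solvent units
#' with total potential energy `e_box` defines the per-unit reference
#' `e(S) = e_box / m_units`. For mixtures, units are counted as virtual
#' THF+water units (see [virtual_unit()]); for pure solvents a unit is one
#' molecule.
#'
#' @param e_box Total potential energy of the solvent box, kJ/mol.
#' @param m_units Number of virtual solvent units in the box (> 0).
#' @param solvent_label Text label identifying the solvent condition.
#' @return A one-row tibble with columns `solvent_label`, `e_per_unit`.
#' @export
solvent_reference <- function(e_box, m_units, solvent_label = "") {
  stopifnot(is.numeric(e_box), is.numeric(m_units))
  if (any(m_units <= 0)) stop("`m_units` must be positive", call. = FALSE)
  if (any(!is.finite(e_box))) stop("`e_box` must be finite", call. = FALSE)
  tibble::tibble(solvent_label = solvent_label, e_per_unit = e_box / m_units)
}

#' Per-molecule assembly energy
#'
#' For a system of `n_peptoid` peptoid molecules immersed in `m_units` virtual
#' solvent units with total potential energy `e_total`, the assembly energy is
#'
#'   e(A in S) = (e_total - m_units * e(S)) / n_peptoid
#'
#' i.e. the per-molecule potential energy relative to the same amount of pure
#' solvent. Lower values mean a more stable (better solvated or better packed)
#' state; comparing structure classes traces the thermodynamic driving force
#' of self-assembly.
#'
#' @param records A data frame of energy records with columns `label`
#'   (structure class), `solvent_label`, `n_peptoid`, `m_units`, `e_total`
#'   (kJ/mol).
#' @param refs A data frame of solvent references with columns
#'   `solvent_label`, `e_per_unit` (one row per solvent), as produced by
#'   [solvent_reference()].
#' @return `records` as a tibble with an added `assembly_energy` column
#'   (kJ/mol per peptoid molecule).
#' @examples
#' recs <- tibble::tibble(label = "dimer", solvent_label = "w",
#'                        n_peptoid = 2, m_units = 100, e_total = -1010)
#' refs <- solvent_reference(-1000, 100, "w")
#' assembly_energy(recs, refs)$assembly_energy  # -5
#' @export
assembly_energy <- function(records, refs) {
  records <- tibble::as_tibble(records)
  needed <- c("label", "solvent_label", "n_peptoid", "m_units", "e_total")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("`records` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$n_peptoid < 1)) {
    stop("`n_peptoid` must be >= 1", call. = FALSE)
  }
  if (any(records$m_units <= 0)) {
    stop("`m_units` must be positive (vacuum systems are not defined for this statistic)",
         call. = FALSE)
  }
  unmatched <- setdiff(records$solvent_label, refs$solvent_label)
  if (length(unmatched)) {
    stop("no solvent reference for: ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  }
  records |>
    dplyr::left_join(
      dplyr::select(refs, "solvent_label", "e_per_unit"),
      by = "solvent_label"
    ) |>
    dplyr::mutate(
      assembly_energy = (.data$e_total - .data$m_units * .data$e_per_unit) /
        .data$n_peptoid
    ) |>
    dplyr::select(-"e_per_unit")
}

#' Assembly-energy profile across structure classes
#'
#' Tabulates the assembly energy for every (structure class, solvent) pair and
#' the energy change between consecutive classes along a caller-specified
#' ordering (isolated molecules, stacks, nanofibers, nanosheet, ...). The
#' step from the last finite-width nanofiber to the nanosheet is the
#' two-dimensional growth driving force the profile is built to expose.
#'
#' @inheritParams assembly_energy
#' @param class_order Character vector giving the ordering of structure-class
#'   labels; defaults to their order of first appearance in `records`.
#' @return A tibble with one row per (label, solvent_label):
#'   `assembly_energy` and `delta_from_previous` (energy change from the
#'   preceding class in `class_order`; `NA` for the first class).
#' @export
assembly_profile <- function(records, refs, class_order = NULL) {
  scored <- assembly_energy(records, refs)
  if (is.null(class_order)) class_order <- unique(records$label)
  unknown <- setdiff(scored$label, class_order)
  if (length(unknown)) {
    stop("`class_order` is missing labels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  scored |>
    dplyr::mutate(label = factor(.data$label, levels = class_order)) |>
    dplyr::arrange(.data$solvent_label, .data$label) |>
    dplyr::group_by(.data$solvent_label) |>
    dplyr::mutate(
      delta_from_previous = .data$assembly_energy -
        dplyr::lag(.data$assembly_energy)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(label = as.character(.data$label)) |>
    dplyr::select("label", "solvent_label", "assembly_energy",
                  "delta_from_previous")
}

#' Block-averaged standard error of a per-frame energy series
#'
#' Upstream simulations usually report time-averaged energies; when a
#' per-frame series is available, splitting it into equal consecutive blocks
#' gives a standard error that is robust to short-time correlation.
#'
#' @param series Numeric vector of per-frame energies, kJ/mol.
#' @param n_blocks Number of equal consecutive blocks (default 5).
#' @return A one-row tibble with `mean`, `se`, `n_blocks`.
#' @export
block_standard_error <- function(series, n_blocks = 5) {
  stopifnot(is.numeric(series), n_blocks >= 2)
  if (length(series) < n_blocks) {
    stop("series shorter than the number of blocks", call. = FALSE)
  }
  idx <- cut(seq_along(series), breaks = n_blocks, labels = FALSE)
  block_means <- vapply(split(series, idx), mean, numeric(1))
  tibble::tibble(
    mean = mean(series),
    se = stats::sd(block_means) / sqrt(n_blocks),
    n_blocks = n_blocks
  )
}
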
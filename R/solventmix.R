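#' THF/water composition conversions
#'
#' Experimental protocols quote the organic content of a THF/water mixture in
#' three different conventions: mass fraction ("~50% wt"), molarity of THF per
#' litre of water ("4 M"), and volume fraction ("5% vol"). All downstream
#' bookkeeping in this package works with a single dimensionless quantity, the
#' THF/water molar ratio, which is 0 for pure water and `Inf` for pure THF.
#' These helpers convert each convention to the molar ratio using the fixed
#' constants in [solvent_constants].
#'
#' @param w_thf THF mass fraction in `[0, 1]`.
#' @return Nonnegative molar ratio (`Inf` when the mixture holds no water).
#' @examples
#' molar_ratio_from_mass_fraction(0.5)   # ~0.25
#' molar_ratio_from_molarity(4)          # ~0.072
#' molar_ratio_from_volume_fraction(0.05) # ~0.012
#' @seealso [virtual_unit()], [composition_table()]
#' @export
molar_ratio_from_mass_fraction <- function(w_thf) {
  stopifnot(is.numeric(w_thf))
  if (any(w_thf < 0 | w_thf > 1)) {
    stop("`w_thf` must lie in [0, 1]", call. = FALSE)
  }
  k <- solvent_constants
  n_thf <- w_thf / k$mw_thf
  n_water <- (1 - w_thf) / k$mw_water
  ifelse(w_thf == 1, Inf, n_thf / n_water)
}

#' @rdname molar_ratio_from_mass_fraction
#' @param c_thf THF molarity, mol per litre of water.
#' @export
molar_ratio_from_molarity <- function(c_thf) {
  stopifnot(is.numeric(c_thf))
  if (any(c_thf < 0)) stop("`c_thf` must be nonnegative", call. = FALSE)
  c_thf / solvent_constants$water_molarity
}

#' @rdname molar_ratio_from_mass_fraction
#' @param phi_thf THF volume fraction in `[0, 1]` (ideal mixing assumed).
#' @export
molar_ratio_from_volume_fraction <- function(phi_thf) {
  stopifnot(is.numeric(phi_thf))
  if (any(phi_thf < 0 | phi_thf > 1)) {
    stop("`phi_thf` must lie in [0, 1]", call. = FALSE)
  }
  k <- solvent_constants
  n_thf <- phi_thf * k$rho_thf / k$mw_thf
  n_water <- (1 - phi_thf) * k$rho_water / k$mw_water
  ifelse(phi_thf == 1, Inf, n_thf / n_water)
}

#' Solvent composition records
#'
#' A `solvent_composition` couples a THF/water molar ratio with a free-text
#' label ("4 M", "pure water", ...). The ratio is 0 exactly when the solvent
#' is pure water and `Inf` exactly when it is pure THF.
#'
#' @param thf_water_molar_ratio Nonnegative molar ratio (may be `Inf`).
#' @param label Text label carried through analyses.
#' @return An object of class `solvent_composition`.
#' @export
solvent_composition <- function(thf_water_molar_ratio, label = "") {
  stopifnot(is.numeric(thf_water_molar_ratio), length(thf_water_molar_ratio) == 1)
  if (is.na(thf_water_molar_ratio) || thf_water_molar_ratio < 0) {
    stop("molar ratio must be a nonnegative number or Inf", call. = FALSE)
  }
  structure(
    list(thf_water_molar_ratio = thf_water_molar_ratio, label = label),
    class = "solvent_composition"
  )
}

#' @export
print.solvent_composition <- function(x, ...) {
  cat(sprintf(
    "<solvent_composition> %s (THF/water molar ratio %s)\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    format(x$thf_water_molar_ratio)
  ))
  invisible(x)
}

#' Mixed-solvent virtual unit
#'
#' For the assembly-energy bookkeeping a THF/water mixture is counted in
#' "virtual units": one THF molecule together with the composition-matched
#' (possibly fractional) number of water molecules. Pure water degenerates to
#' one water molecule per unit, pure THF to one THF per unit.
#'
#' @param comp A [solvent_composition()], or a bare nonnegative molar ratio.
#' @return A tibble with columns `n_thf` and `n_water` (per virtual unit).
#' @examples
#' virtual_unit(0.25)  # 1 THF + 4 water
#' virtual_unit(0)     # pure water
#' @export
virtual_unit <- function(comp) {
  r <- if (inherits(comp, "solvent_composition")) comp$thf_water_molar_ratio else comp
  stopifnot(is.numeric(r), length(r) == 1, !is.na(r), r >= 0)
  if (r == 0) {
    tibble::tibble(n_thf = 0, n_water = 1)
  } else if (is.infinite(r)) {
    tibble::tibble(n_thf = 1, n_water = 0)
  } else {
    tibble::tibble(n_thf = 1, n_water = 1 / r)
  }
}

#' All composition conventions for one mixture
#'
#' Convert whichever single convention is supplied into the molar ratio and
#' report all conventions side by side, together with the virtual-unit
#' composition. Exactly one of the four arguments must be given.
#'
#' @param mass_fraction,molarity,volume_fraction,molar_ratio One of the four
#'   composition conventions (see [molar_ratio_from_mass_fraction()]).
#' @param label Optional text label.
#' @return A one-row tibble with columns `label`, `molar_ratio`,
#'   `mass_fraction`, `molarity`, `volume_fraction`, `n_thf_per_unit`,
#'   `n_water_per_unit`.
#' @export
composition_table <- function(mass_fraction = NULL, molarity = NULL,
                              volume_fraction = NULL, molar_ratio = NULL,
                              label = "") {
  given <- !vapply(
    list(mass_fraction, molarity, volume_fraction, molar_ratio),
    is.null, logical(1)
  )
  if (sum(given) != 1) {
    stop("supply exactly one composition convention", call. = FALSE)
  }
  r <- if (!is.null(mass_fraction)) {
    molar_ratio_from_mass_fraction(mass_fraction)
  } else if (!is.null(molarity)) {
    molar_ratio_from_molarity(molarity)
  } else if (!is.null(volume_fraction)) {
    molar_ratio_from_volume_fraction(volume_fraction)
  } else {
    stopifnot(molar_ratio >= 0)
    molar_ratio
  }
  k <- solvent_constants
  # invert the ratio into the other conventions
  w <- if (is.infinite(r)) 1 else r * k$mw_thf / (r * k$mw_thf + k$mw_water)
  c_thf <- if (is.infinite(r)) Inf else r * k$water_molarity
  phi <- if (is.infinite(r)) {
    1
  } else {
    v_thf <- r * k$mw_thf / k$rho_thf
    v_wat <- k$mw_water / k$rho_water
    v_thf / (v_thf + v_wat)
  }
  vu <- virtual_unit(r)
  tibble::tibble(
    label = label,
    molar_ratio = r,
    mass_fraction = w,
    molarity = c_thf,
    volume_fraction = phi,
    n_thf_per_unit = vu$n_thf,
    n_water_per_unit = vu$n_water
  )
}
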
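#' @keywords internal
# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Synthetic backbone conformations
#'
#' Geometric idealisations of the backbone conformational spectrum between a
#' coiled C-shape and a fully extended strand: a circular arc subtending 300
#' degrees (`coiled_C`), an arc of 150 degrees (`semi_open`), and a planar
#' zig-zag with 1.5 A bonds (`extended`), optionally scaled uniformly to a
#' target end-to-end distance and perturbed with isotropic Gaussian noise.
#' These templates are deliberately not force-field minimisations; they exist
#' to exercise featurization, embedding, clustering, reconstruction and the
#' scalar metrics with known ground truth.
#'
#' @param n_atoms Number of backbone heavy atoms (>= 4, default 20).
#' @param shape One of `"coiled_C"`, `"semi_open"`, `"extended"`.
#' @param target_end_to_end Optional target end-to-end distance, Angstrom;
#'   the template is scaled uniformly to reach it exactly (at zero noise).
#'   Targets beyond the 1.5 A/bond contour length are rejected.
#' @param noise_sigma Isotropic per-coordinate Gaussian noise, Angstrom.
#' @param seed Optional RNG seed (same seed, same output).
#' @return A [conformation()].
#' @examples
#' end_to_end(make_backbone(20, "extended", target_end_to_end = 26))  # 26
#' @export
make_backbone <- function(n_atoms = 20, shape = c("coiled_C", "semi_open", "extended"),
                          target_end_to_end = NULL, noise_sigma = 0,
                          seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(n_atoms >= 4, noise_sigma >= 0)
  bond <- 1.5
  n_bonds <- n_atoms - 1
  coords <- switch(shape,
    extended = {
      dx <- 1.25
      h <- sqrt(bond^2 - dx^2)
      cbind(x = (seq_len(n_atoms) - 1) * dx,
            y = rep_len(c(0, h), n_atoms), z = 0)
    },
    coiled_C = arc_chain(n_atoms, span_deg = 300, bond = bond),
    semi_open = arc_chain(n_atoms, span_deg = 150, bond = bond)
  )
  if (!is.null(target_end_to_end)) {
    if (target_end_to_end <= 0 || target_end_to_end > n_bonds * bond) {
      stop("target end-to-end unreachable for ", n_bonds, " bonds of ",
           bond, " A", call. = FALSE)
    }
    coords <- coords * (target_end_to_end / end_to_end(coords))
  }
  if (noise_sigma > 0) {
    coords <- with_seed(seed, coords + matrix(
      stats::rnorm(length(coords), sd = noise_sigma), ncol = 3))
  }
  conformation(coords, label = shape)
}

# n atoms equally spaced on a circular arc (xy-plane) with adjacent chords `bond`
arc_chain <- function(n_atoms, span_deg, bond) {
  dtheta <- span_deg * pi / 180 / (n_atoms - 1)
  r <- bond / (2 * sin(dtheta / 2))
  theta <- (seq_len(n_atoms) - 1) * dtheta
  cbind(x = r * cos(theta), y = r * sin(theta), z = 0)
}

#' Synthetic conformation sets with planted family labels
#'
#' Draws noisy copies of the backbone templates and keeps the planted family
#' label, so downstream embedding/clustering can be scored against the known
#' partition (e.g. with the adjusted Rand index).
#'
#' @param families A data frame (or list coercible to one) with columns
#'   `shape`, `count`, `noise_sigma` and optionally `target_end_to_end`.
#' @param n_atoms Atom count shared by all conformations.
#' @param seed RNG seed for the whole set.
#' @return A conformation-set tibble (see [conformation_set()]) with an
#'   additional `family` column holding the planted label.
#' @export
make_conformation_set <- function(families, n_atoms = 20, seed = NULL) {
  families <- tibble::as_tibble(families)
  stopifnot(all(c("shape", "count", "noise_sigma") %in% names(families)),
            all(families$count >= 1))
  if (!"target_end_to_end" %in% names(families)) {
    families$target_end_to_end <- NA_real_
  }
  with_seed(seed, {
    sets <- purrr::pmap(families, function(shape, count, noise_sigma,
                                           target_end_to_end, ...) {
      confs <- purrr::map(seq_len(count), function(i) {
        make_backbone(
          n_atoms, shape,
          target_end_to_end = if (is.na(target_end_to_end)) NULL else target_end_to_end,
          noise_sigma = noise_sigma, seed = NULL
        )
      })
      dplyr::mutate(conformation_set(confs), family = shape)
    })
    purrr::list_rbind(sets)
  })
}

#' Synthetic multi-chain agglomerates
#'
#' Pools several backbone chains into one agglomerate: a `"stack"` piles
#' chains along z (a molecular stack), a `"sheet"` lays them side by side in
#' a plane (a nanosheet patch, also a convenient large-surface solute for
#' solvation analyses). The `scale` factor multiplies the inter-chain
#' spacing, so 0.7 vs 1.3 produce tight vs loose agglomerates with ordered
#' radii of gyration.
#'
#' @param n_chains Number of chains (default 6).
#' @param n_atoms Atoms per chain.
#' @param arrangement `"stack"` or `"sheet"`.
#' @param spacing Inter-chain spacing, Angstrom (default 4.5).
#' @param scale Multiplier on the spacing (compactness control).
#' @param noise_sigma Per-coordinate Gaussian noise, Angstrom.
#' @param seed RNG seed.
#' @return A pooled (n_chains * n_atoms) x 3 coordinate matrix with
#'   attributes `n_chains` and `chain` (per-atom chain index).
#' @export
make_agglomerate <- function(n_chains = 6, n_atoms = 20,
                             arrangement = c("stack", "sheet"),
                             spacing = 4.5, scale = 1, noise_sigma = 0,
                             seed = NULL) {
  arrangement <- match.arg(arrangement)
  stopifnot(n_chains >= 1, spacing > 0, scale > 0)
  chain <- as.matrix(make_backbone(n_atoms, "extended"))
  offs <- (seq_len(n_chains) - (n_chains + 1) / 2) * spacing * scale
  coords <- do.call(rbind, lapply(offs, function(o) {
    sweep(chain, 2, switch(arrangement,
                           stack = c(0, 0, -o),
                           sheet = c(0, -o, 0)))
  }))
  if (noise_sigma > 0) {
    coords <- with_seed(seed, coords + matrix(
      stats::rnorm(length(coords), sd = noise_sigma), ncol = 3))
  }
  structure(coords, n_chains = n_chains,
            chain = rep(seq_len(n_chains), each = n_atoms))
}

#' Synthetic solvated frames with a planted solvation enhancement
#'
#' Places water centres uniformly in an orthorhombic box and THF centres by
#' rejection sampling so that the local THF/water ratio at surface distance
#' `d` follows `bulk_ratio * (1 + (factor - 1) * exp(-d / decay))`; with
#' `enhancement = NULL` both species are uniform and the true enhancement is
#' 1 everywhere. Solvent molecules are point centres with masses 72.11 amu
#' (THF) and 18.015 amu (water).
#'
#' @param solute A conformation (or n x 3 matrix) placed at the box centre.
#' @param n_thf,n_water Molecule counts (the box must stay below liquid
#'   water's number density of ~0.034 centres/A^3).
#' @param box Box edge lengths, Angstrom (default 60 x 60 x 60).
#' @param enhancement `NULL`, or `list(factor =, decay =)` with the surface
#'   enhancement factor and its exponential decay length (Angstrom).
#' @param seed RNG seed.
#' @return A [solvated_frame()].
#' @export
make_solvated_frame <- function(solute, n_thf, n_water, box = c(60, 60, 60),
                                enhancement = NULL, seed = NULL) {
  solute <- as.matrix(solute)
  stopifnot(n_thf >= 0, n_water >= 0, n_thf + n_water > 0)
  if ((n_thf + n_water) / prod(box) > 0.034) {
    stop("overfilled box: more solvent centres than liquid-like density allows",
         call. = FALSE)
  }
  # centre the solute in the box
  solute <- sweep(solute, 2, colMeans(solute)) +
    matrix(box / 2, nrow(solute), 3, byrow = TRUE)
  with_seed(seed, {
    water <- matrix(stats::runif(3 * n_water), ncol = 3) %*% diag(box)
    thf <- matrix(numeric(0), ncol = 3)
    if (n_thf > 0) {
      if (is.null(enhancement)) {
        thf <- matrix(stats::runif(3 * n_thf), ncol = 3) %*% diag(box)
      } else {
        f <- enhancement$factor; lam <- enhancement$decay
        stopifnot(f > 0, lam > 0)
        got <- 0
        acc <- matrix(0, n_thf, 3)
        gmax <- max(f, 1)
        while (got < n_thf) {
          m <- max(2 * (n_thf - got), 100)
          cand <- matrix(stats::runif(3 * m), ncol = 3) %*% diag(box)
          d <- min_surface_distance(cand, solute, box)
          g <- 1 + (f - 1) * exp(-d / lam)
          keep <- stats::runif(m) < g / gmax
          k <- which(keep)
          if (length(k)) {
            take <- utils::head(k, n_thf - got)
            acc[(got + 1):(got + length(take)), ] <- cand[take, , drop = FALSE]
            got <- got + length(take)
          }
        }
        thf <- acc
      }
    }
    solvent <- tibble::tibble(
      x = c(thf[, 1], water[, 1]),
      y = c(thf[, 2], water[, 2]),
      z = c(thf[, 3], water[, 3]),
      species = c(rep("THF", nrow(thf)), rep("water", nrow(water))),
      mass = c(rep(solvent_constants$mw_thf, nrow(thf)),
               rep(solvent_constants$mw_water, nrow(water)))
    )
    solvated_frame(solute, solvent, box)
  })
}

#' Analytic double-well potential
#'
#' `U(xi) = 16 dg [x (1 - x)]^2` with `x = (xi - a) / L`: minima at `a` and
#' `a + L`, a barrier of exactly `dg` at the midpoint.
#'
#' @param xi Collective-variable values, nm.
#' @param dg Barrier height, kJ/mol.
#' @param a Position of the first minimum, nm.
#' @param L Separation of the minima, nm.
#' @return Potential energy, kJ/mol.
#' @export
doublewell_potential <- function(xi, dg = 5, a = 0, L = 1) {
  x <- (xi - a) / L
  16 * dg * (x * (1 - x))^2
}

#' Metropolis-sampled umbrella windows from analytic potentials
#'
#' Draws biased samples from `exp(-(U(xi) + K/2 (xi - c)^2) / kT)` per
#' window with a Metropolis chain: the step size is adapted during burn-in
#' toward 30-50% acceptance, the burn-in (10% of the chain) is discarded,
#' and the production acceptance rate is recorded per window.
#'
#' @param potential `"flat"`, `"doublewell"` or `"linear"`.
#' @param windows Vector of window centres (see [build_windows()]).
#' @param force_constant Harmonic bias force constant, kJ/mol/nm^2.
#' @param n_per_window Production samples per window (>= 100).
#' @param stride Metropolis updates between recorded samples (default 5);
#'   recording every few updates decorrelates the stored series the same way
#'   an MD engine's output interval does.
#' @param temperature Temperature, K.
#' @param seed RNG seed.
#' @param dg,a,L Double-well parameters (see [doublewell_potential()]).
#' @param slope Slope of the linear potential, kJ/mol/nm.
#' @return A long tibble (`center`, `force_constant`, `cv`) ready for
#'   [wham()], with an `acceptance` attribute tabulating per-window
#'   acceptance rates.
#' @export
sample_umbrella <- function(potential = c("flat", "doublewell", "linear"),
                            windows, force_constant = 200,
                            n_per_window = 5000, stride = 5,
                            temperature = 300, seed = NULL, dg = 5, a = 0,
                            L = 1, slope = 0) {
  potential <- match.arg(potential)
  stopifnot(n_per_window >= 100, force_constant > 0, stride >= 1)
  U <- switch(potential,
    flat = function(x) 0 * x,
    doublewell = function(x) doublewell_potential(x, dg, a, L),
    linear = function(x) slope * x
  )
  kt <- kT(temperature)
  n_burn <- ceiling(0.1 * n_per_window)
  with_seed(seed, {
    res <- purrr::map(windows, function(ctr) {
      etot <- function(x) U(x) + 0.5 * force_constant * (x - ctr)^2
      step <- 2.4 * sqrt(kt / force_constant)
      x <- ctr
      ex <- etot(x)
      # burn-in with step adaptation every 50 proposals
      acc_win <- 0
      for (i in seq_len(n_burn)) {
        prop <- x + stats::runif(1, -step, step)
        ep <- etot(prop)
        if (log(stats::runif(1)) < (ex - ep) / kt) {
          x <- prop; ex <- ep; acc_win <- acc_win + 1
        }
        if (i %% 50 == 0) {
          rate <- acc_win / 50
          if (rate > 0.5) step <- step * 1.2
          if (rate < 0.3) step <- step * 0.8
          acc_win <- 0
        }
      }
      out <- numeric(n_per_window)
      n_acc <- 0
      n_prop <- n_per_window * stride
      for (i in seq_len(n_prop)) {
        prop <- x + stats::runif(1, -step, step)
        ep <- etot(prop)
        if (log(stats::runif(1)) < (ex - ep) / kt) {
          x <- prop; ex <- ep; n_acc <- n_acc + 1
        }
        if (i %% stride == 0) out[i %/% stride] <- x
      }
      if (n_acc == 0) {
        stop("Metropolis chain at centre ", ctr, " accepted no moves",
             call. = FALSE)
      }
      list(samples = umbrella_window(ctr, out, force_constant),
           acceptance = n_acc / n_prop)
    })
    samples <- purrr::list_rbind(purrr::map(res, "samples"))
    attr(samples, "acceptance") <- tibble::tibble(
      center = windows,
      acceptance = purrr::map_dbl(res, "acceptance")
    )
    samples
  })
}

#' Synthetic assembly-energy tables with planted ground truth
#'
#' Builds energy records `e_total = N * epsilon + M * e_solvent_unit`
#' exactly, so the assembly-energy statistic must recover `epsilon` for
#' every system size, and shifting `e_solvent_unit` must leave the statistic
#' unchanged (gauge invariance of the solvent reference).
#'
#' @param epsilon_per_molecule Planted per-molecule assembly energy, kJ/mol.
#' @param e_solvent_unit Per-unit solvent energy, kJ/mol.
#' @param systems Data frame with columns `n_peptoid`, `m_units` (and
#'   optionally `label`).
#' @param solvent_label Label shared by records and reference.
#' @return A list with elements `records` (energy-record tibble) and
#'   `reference` (one-row solvent-reference tibble).
#' @export
make_energy_table <- function(epsilon_per_molecule, e_solvent_unit, systems,
                              solvent_label = "synthetic") {
  systems <- tibble::as_tibble(systems)
  stopifnot(all(c("n_peptoid", "m_units") %in% names(systems)),
            all(systems$n_peptoid >= 1), all(systems$m_units > 0))
  if (!"label" %in% names(systems)) {
    systems$label <- paste0("system_", seq_len(nrow(systems)))
  }
  records <- systems |>
    dplyr::mutate(
      solvent_label = solvent_label,
      e_total = .data$n_peptoid * epsilon_per_molecule +
        .data$m_units * e_solvent_unit
    ) |>
    dplyr::select("label", "solvent_label", "n_peptoid", "m_units", "e_total")
  list(
    records = records,
    reference = solvent_reference(e_solvent_unit * 1000, 1000, solvent_label)
  )
}
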
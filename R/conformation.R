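#' Backbone conformations
#'
#' A `conformation` is an ordered set of backbone heavy-atom coordinates
#' (Angstrom, N-terminus first) with provenance metadata: a free-text label,
#' a structural source class and the solvent condition it was sampled in.
#'
#' @param coords Numeric n x 3 matrix of atom positions, Angstrom, in chain
#'   order. At least 4 atoms, all coordinates finite.
#' @param label Free-text label.
#' @param source One of `"isolated"`, `"dimer_C"`, `"dimer_O"`, `"fiber_C"`,
#'   `"sheet"`.
#' @param solvent_label Solvent condition the conformation was sampled in.
#' @return An object of class `conformation` (the coordinate matrix with
#'   metadata attributes).
#' @export
conformation <- function(coords, label = "", source = "isolated",
                         solvent_label = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("`coords` must be an n x 3 matrix", call. = FALSE)
  if (nrow(coords) < 4) stop("a conformation needs >= 4 atoms", call. = FALSE)
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  source <- match.arg(source, c("isolated", "dimer_C", "dimer_O", "fiber_C", "sheet"))
  structure(coords,
    label = label, source = source, solvent_label = solvent_label,
    class = c("conformation", "matrix", "array")
  )
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf(
    "<conformation> %d atoms | source=%s | solvent=%s | end-to-end %.2f A\n",
    nrow(x), attr(x, "source"), attr(x, "solvent_label"), end_to_end(x)
  ))
  invisible(x)
}

coords_of <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  m
}

#' Sets of conformations as tibbles
#'
#' A conformation set is an ordinary tibble with a `coords` list-column of
#' n x 3 matrices plus provenance columns (`label`, `source`,
#' `solvent_label`, and optionally a planted `family` label from the
#' synthetic generator), so it pipes straight into dplyr verbs.
#'
#' @param confs A list of [conformation()] objects or bare n x 3 matrices.
#' @param source,solvent_label Recycled provenance columns (overridden by a
#'   conformation's own attributes when present).
#' @return A tibble with columns `coords`, `label`, `source`,
#'   `solvent_label`.
#' @export
conformation_set <- function(confs, source = "isolated", solvent_label = "") {
  stopifnot(is.list(confs), length(confs) > 0)
  tibble::tibble(
    coords = lapply(confs, function(c) coords_of(as.matrix(c))),
    label = vapply(confs, function(c) attr(c, "label") %||% "", character(1)),
    source = vapply(confs, function(c) attr(c, "source") %||% source, character(1)),
    solvent_label = vapply(
      confs,
      function(c) {
        s <- attr(c, "solvent_label")
        if (is.null(s) || !nzchar(s)) solvent_label else s
      },
      character(1)
    )
  )
}

#' Minimum RMSD under optimal rigid superposition
#'
#' Root-mean-square deviation between two equally sized conformations after
#' removing the centroid and applying the optimal proper rotation (Kabsch,
#' SVD-based, determinant +1). Reflections are excluded on purpose: an
#' improper superposition would silently cancel chirality changes.
#'
#' @param conf,ref Conformations or n x 3 coordinate matrices with equal atom
#'   counts.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(conf, ref) {
  a <- as.matrix(conf); b <- as.matrix(ref)
  if (!all(dim(a) == dim(b))) {
    stop("atom counts differ between `conf` and `ref`", call. = FALSE)
  }
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  r <- kabsch_rotation(a, b)
  sqrt(mean(rowSums((a %*% r - b)^2)))
}

# optimal proper rotation R (3x3) minimising ||a R - b|| for centred a, b
kabsch_rotation <- function(a, b) {
  h <- crossprod(a, b)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Mass-weighted radius of gyration
#'
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param masses Per-atom masses, amu (recycled scalar allowed; all > 0).
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses = 1) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 1, ncol(coords) == 3)
  masses <- rep_len(masses, nrow(coords))
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  com <- colSums(coords * masses) / sum(masses)
  dev2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(masses * dev2) / sum(masses))
}

#' Backbone end-to-end distance
#'
#' Euclidean distance between the first and last backbone heavy atoms; the
#' standard scalar for backbone extension (a coiled C-shape sits near 9 A,
#' the maximally extended decyl-block backbone near 26 A).
#'
#' @param conf A conformation or n x 3 matrix with at least 2 atoms.
#' @return Distance in Angstrom.
#' @export
end_to_end <- function(conf) {
  m <- as.matrix(conf)
  if (nrow(m) < 2) stop("need at least 2 atoms", call. = FALSE)
  sqrt(sum((m[nrow(m), ] - m[1, ])^2))
}

#' Internal-distance featurization
#'
#' Converts Cartesian coordinates into the distances from every atom to the
#' first three atoms of the chain (the anchors). The representation is exactly
#' invariant under rotations and translations, which makes it suitable input
#' for manifold embedding; distances to three non-collinear anchors determine
#' each position up to the global mirror. Anchor-anchor rows are included so
#' the feature is self-contained for reconstruction.
#'
#' @param conf A conformation or n x 3 matrix (>= 4 atoms).
#' @param collinear_tol Anchors within this perpendicular distance (Angstrom)
#'   of a common line trigger a degeneracy warning (featurization proceeds).
#' @return An n x 3 matrix of distances, Angstrom; column j holds the
#'   distances to anchor atom j.
#' @export
featurize <- function(conf, collinear_tol = 1e-6) {
  m <- as.matrix(conf)
  if (nrow(m) < 4) stop("featurization needs >= 4 atoms", call. = FALSE)
  # perpendicular distance of anchor 3 from the line through anchors 1-2
  v12 <- m[2, ] - m[1, ]
  v13 <- m[3, ] - m[1, ]
  cr <- c(
    v12[2] * v13[3] - v12[3] * v13[2],
    v12[3] * v13[1] - v12[1] * v13[3],
    v12[1] * v13[2] - v12[2] * v13[1]
  )
  if (sqrt(sum(cr^2)) / sqrt(sum(v12^2)) < collinear_tol) {
    warning("anchor atoms 1-3 are nearly collinear; reconstruction from this feature is ill-conditioned")
  }
  f <- vapply(1:3, function(j) sqrt(rowSums(sweep(m, 2, m[j, ])^2)), numeric(nrow(m)))
  dimnames(f) <- NULL
  f
}

# flatten featurized conformations of a set into a samples x (3 n_atoms) matrix
#' Feature matrix for a conformation set
#'
#' Applies [featurize()] to every conformation and flattens each n x 3
#' distance matrix into one row, giving the samples-by-features matrix the
#' embedding step consumes. All conformations must share the atom count.
#'
#' @param confset A conformation set tibble (see [conformation_set()]) or a
#'   list of conformations.
#' @return A numeric matrix, one row per conformation.
#' @export
featurize_set <- function(confset) {
  coords <- if (is.data.frame(confset)) confset$coords else confset
  n_atoms <- unique(vapply(coords, nrow, integer(1)))
  if (length(n_atoms) != 1) {
    stop("all conformations must have the same atom count", call. = FALSE)
  }
  t(vapply(coords, function(m) as.vector(featurize(m)), numeric(3 * n_atoms)))
}

#' Distance-geometry reconstruction from an internal-distance feature
#'
#' Rebuilds Cartesian coordinates from the per-atom distances to the three
#' anchor atoms: anchor 1 at the origin, anchor 2 on +x, anchor 3 in the
#' xy-plane with y > 0, and every further atom trilaterated from its three
#' anchor distances. Distances to three anchors cannot encode chirality, so
#' the z-sign of each atom is chosen to keep the backbone bond to its
#' predecessor closest to the 1.5 A target (tie falls back to z >= 0); the
#' result is exact up to a rigid motion, and up to a global mirror for chiral
#' inputs. Slightly infeasible distances (negative trilateration discriminant
#' within tolerance, as arise when averaging features over a cluster) are
#' clamped to the xy-plane and flagged.
#'
#' @param feature An n x 3 internal-distance matrix (or its flattened
#'   vector), Angstrom.
#' @param bond_target Backbone bond length used to resolve the mirror
#'   ambiguity, Angstrom.
#' @param tol Feasibility tolerance for the squared-distance discriminant.
#' @return A [conformation()] with attribute `clamped` giving the indices of
#'   atoms whose z had to be clamped to 0.
#' @export
reconstruct <- function(feature, bond_target = 1.5, tol = 1e-6) {
  f <- if (is.matrix(feature)) feature else matrix(feature, ncol = 3)
  n <- nrow(f)
  if (n < 4) stop("feature must describe >= 4 atoms", call. = FALSE)
  if (any(f < 0)) stop("distances must be nonnegative", call. = FALSE)
  d21 <- f[2, 1]
  d31 <- f[3, 1]; d32 <- f[3, 2]
  out <- matrix(0, n, 3)
  out[2, ] <- c(d21, 0, 0)
  x3 <- (d31^2 - d32^2 + d21^2) / (2 * d21)
  y3sq <- d31^2 - x3^2
  out[3, ] <- c(x3, sqrt(max(y3sq, 0)), 0)
  clamped <- integer(0)
  x2 <- out[2, 1]; p3 <- out[3, ]
  for (i in 4:n) {
    di1 <- f[i, 1]; di2 <- f[i, 2]; di3 <- f[i, 3]
    x <- (di1^2 - di2^2 + x2^2) / (2 * x2)
    y <- (di1^2 - di3^2 + p3[1]^2 + p3[2]^2 - 2 * x * p3[1]) / (2 * p3[2])
    z2 <- di1^2 - x^2 - y^2
    if (z2 < 0) {
      if (z2 < -tol) clamped <- c(clamped, i)
      z <- 0
    } else {
      z <- sqrt(z2)
      # cancellation in di1^2 - x^2 - y^2 leaves O(eps * d^2) noise; a z below
      # 1e-5 A is numerical residue of a planar atom, not structure
      if (z < 1e-5) z <- 0
    }
    # mirror ambiguity: pick the z sign giving the more chain-like bond
    prev <- out[i - 1, ]
    bond_plus <- sqrt(sum((c(x, y, z) - prev)^2))
    bond_minus <- sqrt(sum((c(x, y, -z) - prev)^2))
    if (abs(bond_minus - bond_target) < abs(bond_plus - bond_target)) z <- -z
    out[i, ] <- c(x, y, z)
  }
  res <- conformation(out, label = "reconstructed")
  attr(res, "clamped") <- clamped
  res
}

#' RMSD histogram against a reference conformation
#'
#' Computes the minimum RMSD of every conformation in a set to a common
#' reference (typically the most coiled C-shape backbone) and bins the values
#' per solvent condition into a normalised density histogram (left-closed,
#' right-open bins).
#'
#' @param confset A conformation-set tibble.
#' @param ref Reference conformation with matching atom count.
#' @param bin_width Histogram bin width, Angstrom (default 0.5).
#' @return A tibble with columns `solvent_label`, `bin_left`, `bin_right`,
#'   `count`, `density` (density integrates to 1 per solvent).
#' @export
rmsd_histogram <- function(confset, ref, bin_width = 0.5) {
  stopifnot(is.data.frame(confset), bin_width > 0)
  vals <- tibble::tibble(
    solvent_label = confset$solvent_label,
    rmsd = vapply(confset$coords, rmsd, numeric(1), ref = ref)
  )
  vals |>
    dplyr::mutate(bin = floor(.data$rmsd / bin_width)) |>
    dplyr::count(.data$solvent_label, .data$bin, name = "count") |>
    dplyr::group_by(.data$solvent_label) |>
    tidyr::complete(bin = seq(0, max(.data$bin)),
                    fill = list(count = 0L)) |>
    dplyr::mutate(
      bin_left = .data$bin * bin_width,
      bin_right = .data$bin_left + bin_width,
      density = .data$count / (sum(.data$count) * bin_width)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("solvent_label", "bin_left", "bin_right", "count", "density")
}

#' Pooled radius-of-gyration time series of a multi-chain trajectory
#'
#' For an agglomerate trajectory, pools all peptoid atoms of each frame into
#' one radius-of-gyration value, giving a compactness time series; its mean
#' and standard deviation over frames summarise how tightly (and how stably)
#' the chains cluster.
#'
#' @param frames A list of n x 3 coordinate matrices (one per frame, atoms
#'   pooled over chains).
#' @param masses Per-atom masses, amu (recycled).
#' @return A tibble of class `rg_series` with columns `frame`, `rg`;
#'   [glance()] yields `mean_rg`, `sd_rg`, `n_frames`.
#' @export
aggregate_rg_series <- function(frames, masses = 1) {
  if (!is.list(frames) || length(frames) == 0) {
    stop("`frames` must be a nonempty list of coordinate matrices", call. = FALSE)
  }
  out <- tibble::tibble(
    frame = seq_along(frames),
    rg = vapply(frames, radius_of_gyration, numeric(1), masses = masses)
  )
  class(out) <- c("rg_series", class(out))
  out
}

#' @method glance rg_series
#' @export
glance.rg_series <- function(x, ...) {
  # population standard deviation: the frames ARE the ensemble of interest
  tibble::tibble(
    mean_rg = mean(x$rg),
    sd_rg = sqrt(mean((x$rg - mean(x$rg))^2)),
    n_frames = nrow(x)
  )
}
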
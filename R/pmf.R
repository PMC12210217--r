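#' Smooth minimum distance collective variable
#'
#' The adsorption collective variable is the minimal distance from a tagged
#' THF molecule to the nearest atom of the hydrophobic block. A hard minimum
#' is non-differentiable where the nearest atom changes, so the bias acts on
#' the smooth-minimum switching function
#'
#'   s = beta / ln( sum_i exp(beta / s_i) )
#'
#' which reduces exactly to `s_1` for a single distance, is continuous in all
#' inputs, and approaches `min(s_i)` monotonically from below as `beta` grows.
#' (The literature sometimes prints the inverted form `exp(beta * s_i)`,
#' which diverges with distance and has the wrong one-term limit; this
#' package implements the standard convention above.)
#'
#' @param distances Positive distances, nm.
#' @param beta Sharpness weight (default 100, the value used for the THF
#'   desorption profile).
#' @return Smooth minimum distance, nm.
#' @examples
#' softmin_distance(c(0.4, 4.0))       # ~0.4
#' softmin_distance(1.0)               # exactly 1.0
#' @export
softmin_distance <- function(distances, beta = 100) {
  stopifnot(is.numeric(distances), length(distances) >= 1, beta > 0)
  if (any(distances <= 0)) stop("distances must be positive", call. = FALSE)
  # log-sum-exp guard: exponents beta/s_i can be large for small distances
  e <- beta / distances
  m <- max(e)
  beta / (m + log(sum(exp(e - m))))
}

#' Umbrella window schedule
#'
#' Window centres on the half-open interval `[start, stop)` at the given
#' increment. The THF desorption schedule (0.35 to 4.4 nm at 0.05 nm) gives
#' 81 windows, 0.35 through 4.35 nm.
#'
#' @param start,stop Range of the collective variable, nm (`stop > start`).
#' @param step Increment between window centres, nm (> 0).
#' @return Numeric vector of window centres.
#' @examples
#' length(build_windows())  # 81
#' @export
build_windows <- function(start = 0.35, stop = 4.4, step = 0.05) {
  if (!(step > 0) || !(stop > start)) {
    stop("need step > 0 and stop > start", call. = FALSE)
  }
  n <- ceiling((stop - start) / step - 1e-9)
  start + step * (seq_len(n) - 1)
}

#' Tidy container for biased window samples
#'
#' @param center Window centre, nm.
#' @param samples Collective-variable samples from that window, nm.
#' @param force_constant Harmonic bias force constant, kJ/mol/nm^2
#'   (default 3000).
#' @return A tibble with columns `center`, `force_constant`, `cv`, one row
#'   per sample; several windows row-bind into the long table [wham()]
#'   consumes.
#' @export
umbrella_window <- function(center, samples, force_constant = 3000) {
  stopifnot(force_constant > 0, length(samples) >= 1)
  tibble::tibble(center = center, force_constant = force_constant,
                 cv = as.numeric(samples))
}

#' Weighted histogram analysis (WHAM) potential of mean force
#'
#' Solves the standard WHAM self-consistent equations for umbrella-sampled
#' data: with per-window bias `w_k(xi) = K_k/2 (xi - c_k)^2`, the unbiased
#' probability and window free energies are iterated as
#'
#'   p(xi_b) = sum_k n_k(b) / sum_k N_k exp((f_k - w_k(xi_b)) / kT)
#'   f_k     = -kT ln sum_b p(xi_b) exp(-w_k(xi_b) / kT)
#'
#' (Jacobi-style simultaneous update, log-sum-exp throughout) until the
#' largest change in any `f_k` falls below `tol * kT`. The PMF is
#' `-kT ln p`, anchored to 0 at its minimum over the adsorbed region (the
#' first `anchor_width` nm of the covered range). Bins with no samples are
#' reported as `NA`.
#'
#' @param windows Long tibble with columns `center`, `force_constant`, `cv`
#'   (see [umbrella_window()] and [sample_umbrella()]).
#' @param temperature Temperature, K (default 300).
#' @param bin_width Histogram bin width in CV units, nm (default 0.05).
#' @param tol Convergence tolerance on window free energies, in units of kT
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 1e5).
#' @param range Optional CV range `c(min, max)` for binning; defaults to the
#'   sampled range snapped outward to multiples of `bin_width` (pass
#'   explicitly when replicates must share a bin grid).
#' @param anchor_width Width of the adsorbed anchor region, nm (default 1).
#' @return A `pmf_result` tibble with columns `bin` (centre, nm),
#'   `free_energy` (kJ/mol), `n_samples`; attributes `kT`, `f_k` (per-window
#'   free energies), `converged`, `iterations`, `bin_width`.
#' @export
wham <- function(windows, temperature = 300, bin_width = 0.05, tol = 1e-8,
                 max_iter = 1e5, range = NULL, anchor_width = 1.0) {
  stopifnot(is.data.frame(windows),
            all(c("center", "force_constant", "cv") %in% names(windows)))
  kt <- kT(temperature)
  by_win <- windows |>
    dplyr::group_by(.data$center, .data$force_constant) |>
    dplyr::summarise(cv = list(.data$cv), .groups = "drop") |>
    dplyr::arrange(.data$center)
  empty <- lengths(by_win$cv) == 0
  if (any(empty)) {
    warning(sum(empty), " empty window(s) dropped")
    by_win <- by_win[!empty, ]
  }
  if (nrow(by_win) == 0) stop("no windows with samples", call. = FALSE)
  all_cv <- unlist(by_win$cv)
  if (is.null(range)) {
    range <- c(floor(min(all_cv) / bin_width), ceiling(max(all_cv) / bin_width)) * bin_width
  }
  edges <- seq(range[1], range[2], by = bin_width)
  if (utils::tail(edges, 1) < range[2] - 1e-12) edges <- c(edges, range[2])
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(centers)
  K <- nrow(by_win)
  # adjacent-window overlap check
  if (K > 1) {
    rng <- t(vapply(by_win$cv, range, numeric(2)))
    gaps <- which(rng[-K, 2] < rng[-1, 1])
    if (length(gaps)) {
      warning("no sampling overlap between adjacent windows at centres ",
              paste(sprintf("%.3f-%.3f", by_win$center[gaps],
                            by_win$center[gaps + 1]), collapse = ", "),
              "; the PMF may be disconnected there")
    }
  }
  n_kb <- t(vapply(by_win$cv, function(s) {
    b <- pmin(pmax(floor((s - range[1]) / bin_width) + 1, 1), nb)
    tabulate(b, nbins = nb)
  }, numeric(nb)))                       # K x B
  N_k <- rowSums(n_kb)
  n_b <- colSums(n_kb)
  w_kb <- 0.5 * outer(by_win$force_constant, rep(1, nb)) *
    (outer(by_win$center, centers, `-`))^2   # K x B
  logsumexp <- function(m) {             # over rows of a K x B matrix -> B
    mx <- apply(m, 2, max)
    mx + log(colSums(exp(sweep(m, 2, mx))))
  }
  f_k <- rep(0, K)
  converged <- FALSE
  iter <- 0L
  log_nb <- ifelse(n_b > 0, log(n_b), -Inf)
  while (iter < max_iter) {
    iter <- iter + 1L
    log_den <- logsumexp(log(N_k) + (f_k - w_kb) / kt)  # length B
    log_p <- log_nb - log_den
    # f_k update: -kT * logsumexp_b(log p_b - w_kb/kT)
    mat <- sweep(-w_kb / kt, 2, log_p, `+`)             # K x B
    mx <- apply(mat, 1, max)
    f_new <- -kt * (mx + log(rowSums(exp(mat - mx))))
    f_new <- f_new - f_new[1]
    if (max(abs(f_new - f_k)) < tol * kt) {
      f_k <- f_new
      converged <- TRUE
      break
    }
    f_k <- f_new
  }
  log_den <- logsumexp(log(N_k) + (f_k - w_kb) / kt)
  log_p <- log_nb - log_den
  fe <- -kt * log_p
  fe[n_b == 0] <- NA_real_
  # anchor: minimum over the adsorbed region (first anchor_width of range)
  anchor_sel <- centers <= centers[1] + anchor_width & !is.na(fe)
  if (!any(anchor_sel)) anchor_sel <- !is.na(fe)
  fe <- fe - min(fe[anchor_sel])
  out <- tibble::tibble(bin = centers, free_energy = fe, n_samples = n_b)
  class(out) <- c("pmf_result", class(out))
  attr(out, "kT") <- kt
  attr(out, "f_k") <- f_k
  attr(out, "window_centers") <- by_win$center
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  attr(out, "bin_width") <- bin_width
  attr(out, "anchor_width") <- anchor_width
  if (!converged) warning("WHAM did not converge within max_iter")
  out
}

#' @method tidy pmf_result
#' @export
tidy.pmf_result <- function(x, ...) {
  tibble::tibble(bin = x$bin, free_energy = x$free_energy,
                 n_samples = x$n_samples)
}

#' @method glance pmf_result
#' @export
glance.pmf_result <- function(x, ...) {
  tibble::tibble(
    n_bins = nrow(x),
    n_windows = length(attr(x, "f_k")),
    converged = attr(x, "converged"),
    iterations = attr(x, "iterations"),
    kT = attr(x, "kT")
  )
}

#' Replicate-based PMF uncertainty
#'
#' Each replicate profile is shifted to its own anchor (so the arbitrary
#' free-energy zero drops out) and the per-bin mean and standard deviation
#' across replicates are reported.
#'
#' @param replicates List of `pmf_result` objects on an identical bin grid.
#' @return A tibble with columns `bin`, `mean_fe`, `sd_fe`, `n_replicates`.
#' @export
pmf_uncertainty <- function(replicates) {
  stopifnot(is.list(replicates), length(replicates) >= 2)
  bins <- replicates[[1]]$bin
  for (r in replicates) {
    if (length(r$bin) != length(bins) || any(abs(r$bin - bins) > 1e-9)) {
      stop("replicates are binned differently; rerun wham() with a common `range`",
           call. = FALSE)
    }
  }
  fe <- vapply(replicates, function(r) {
    v <- r$free_energy
    v - min(v, na.rm = TRUE)      # re-anchor each replicate
  }, numeric(length(bins)))
  tibble::tibble(
    bin = bins,
    mean_fe = rowMeans(fe),
    sd_fe = apply(fe, 1, stats::sd),
    n_replicates = length(replicates)
  )
}

#' Desorption cost from a PMF
#'
#' The free-energy cost of moving the molecule from its adsorbed minimum to
#' the bulk: the plateau value (mean over the last `plateau_width` of the
#' profile) minus the minimum over the adsorbed anchor region. A slope test
#' over the plateau region warns when the profile has not levelled off.
#'
#' @param pmf A `pmf_result`.
#' @param plateau_width Width of the terminal plateau region, nm
#'   (default 0.5).
#' @return Desorption cost, kJ/mol.
#' @export
desorption_cost <- function(pmf, plateau_width = 0.5) {
  stopifnot(inherits(pmf, "pmf_result"))
  ok <- !is.na(pmf$free_energy)
  bins <- pmf$bin[ok]; fe <- pmf$free_energy[ok]
  sel <- bins >= max(bins) - plateau_width
  if (sum(sel) >= 2) {
    slope <- stats::coef(stats::lm(fe[sel] ~ bins[sel]))[2]
    if (abs(slope) > attr(pmf, "kT") / 1) {
      warning(sprintf("no plateau: terminal slope %.2f kJ/mol/nm exceeds 1 kT/nm",
                      slope))
    }
  }
  anchor_sel <- bins <= bins[1] + attr(pmf, "anchor_width")
  mean(fe[sel]) - min(fe[anchor_sel])
}

#' @rdname wham
#' @param object,x A `pmf_result`.
#' @param ... Unused.
#' @method autoplot pmf_result
#' @export
autoplot.pmf_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$bin, y = .data$free_energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "collective variable (nm)",
                  y = "free energy (kJ/mol)") +
    ggplot2::theme_minimal()
}
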
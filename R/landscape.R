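#' @importFrom rlang %||% .data
NULL

# Locate the python interpreter serving UMAP/HDBSCAN. Overridable through
# options(peptoidsolv.python = "...") or the PEPTOIDSOLV_PYTHON env var.
find_python <- function() {
  cand <- getOption("peptoidsolv.python",
                    Sys.getenv("PEPTOIDSOLV_PYTHON", unset = ""))
  if (!nzchar(cand)) cand <- Sys.which("python")
  if (!nzchar(cand)) {
    stop("no python interpreter found; set options(peptoidsolv.python=) ",
         "to one with umap-learn and scikit-learn installed", call. = FALSE)
  }
  cand
}

run_landscape_backend <- function(features, mode, n_neighbors = 15,
                                  min_dist = 0.0, seeds = 42,
                                  min_cluster_size = 10, min_samples = 3,
                                  merge_threshold = 0.2) {
  script <- system.file("python", "landscape.py", package = "peptoidsolv")
  stopifnot(nzchar(script))
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(features, fin, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  status <- system2(find_python(), c(
    shQuote(script),
    "--features", shQuote(fin), "--out", shQuote(fout),
    "--mode", mode,
    "--n-neighbors", n_neighbors, "--min-dist", min_dist,
    "--seeds", paste(seeds, collapse = ","),
    "--min-cluster-size", min_cluster_size,
    "--min-samples", min_samples, "--epsilon", merge_threshold
  ), stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0 || !file.exists(fout)) {
    stop("landscape backend failed:\n", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  readr::read_csv(fout, show_col_types = FALSE, progress = FALSE)
}

#' Two-dimensional embedding of internal-distance features
#'
#' Projects the internal-distance feature matrix of a conformational ensemble
#' onto two dimensions with UMAP (uniform manifold approximation and
#' projection), so that proximity on the plane reflects conformational
#' similarity. Defaults follow the landscape analysis this package
#' implements: 15 neighbours and a minimal embedded distance of 0.0, with a
#' fixed random seed recorded in the output. Embeddings are comparable only
#' within a single run/version; all downstream claims (clustering, overlap)
#' are made within one embedding.
#'
#' @param features Samples-by-features numeric matrix (see
#'   [featurize_set()]), or a data frame of numeric columns.
#' @param n_neighbors UMAP neighbourhood size (default 15).
#' @param min_dist Minimal distance between close embedded points (default 0).
#' @param seed Random seed (default 42); recorded as an attribute.
#' @return A tibble with columns `x`, `y` (one row per sample) and
#'   attributes `seed`, `n_neighbors`, `min_dist`.
#' @export
embed_conformations <- function(features, n_neighbors = 15, min_dist = 0.0,
                                seed = 42) {
  features <- as.matrix(features)
  if (nrow(features) < n_neighbors + 1) {
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1, " samples",
         call. = FALSE)
  }
  res <- run_landscape_backend(features, "embed", n_neighbors = n_neighbors,
                               min_dist = min_dist, seeds = seed)
  out <- tibble::tibble(x = res$x, y = res$y)
  attr(out, "seed") <- seed
  attr(out, "n_neighbors") <- n_neighbors
  attr(out, "min_dist") <- min_dist
  out
}

#' Density-based clustering of an embedded landscape
#'
#' Groups embedded conformations with HDBSCAN (hierarchical density-based
#' clustering with noise): points in low-density regions are labelled noise
#' (-1) rather than forced into a cluster. Defaults follow the landscape
#' analysis: minimal cluster size 10, minimal core-point neighbourhood 3 and
#' a merge (cluster-selection) distance threshold of 0.2 in embedded units.
#'
#' @param embedding A two-column matrix/tibble of embedded points.
#' @param min_cluster_size Smallest allowed cluster (default 10).
#' @param min_samples Neighbours required for a core point (default 3).
#' @param merge_threshold Distance below which adjacent clusters merge
#'   (default 0.2).
#' @return Integer vector of cluster labels, `-1` for noise.
#' @export
cluster_embedding <- function(embedding, min_cluster_size = 10,
                              min_samples = 3, merge_threshold = 0.2) {
  emb <- as.matrix(as.data.frame(embedding)[, c(1, 2)])
  if (nrow(emb) == 0) stop("embedding is empty", call. = FALSE)
  res <- run_landscape_backend(emb, "cluster",
                               min_cluster_size = min_cluster_size,
                               min_samples = min_samples,
                               merge_threshold = merge_threshold)
  as.integer(res$label)
}

#' Per-cluster conformational summaries
#'
#' For every cluster: its population fraction (noise points stay in the
#' denominator, so the reported percentages are fractions of all sampled
#' conformations), the mean internal-distance feature, the mean backbone
#' conformation reconstructed from it by distance geometry, and that
#' reconstruction's end-to-end distance.
#'
#' @param labels Integer cluster labels (-1 = noise), aligned with the rows
#'   of `features`.
#' @param features Samples-by-features matrix of flattened internal-distance
#'   features (see [featurize_set()]).
#' @return A tibble with one row per cluster (noise excluded): `cluster`,
#'   `n`, `population_fraction`, `end_to_end`, plus list-columns
#'   `mean_feature` and `reconstructed`. The noise fraction is stored in the
#'   `noise_fraction` attribute; cluster fractions plus noise sum to 1.
#' @export
summarize_clusters <- function(labels, features) {
  features <- as.matrix(features)
  if (length(labels) != nrow(features)) {
    stop("`labels` and `features` are misaligned", call. = FALSE)
  }
  n_total <- length(labels)
  ids <- sort(unique(labels[labels >= 0]))
  rows <- purrr::map(ids, function(id) {
    sel <- labels == id
    mf <- matrix(colMeans(features[sel, , drop = FALSE]), ncol = 3)
    rec <- reconstruct(mf)
    tibble::tibble(
      cluster = id,
      n = sum(sel),
      population_fraction = sum(sel) / n_total,
      end_to_end = end_to_end(rec),
      mean_feature = list(mf),
      reconstructed = list(rec)
    )
  })
  out <- if (length(rows)) purrr::list_rbind(rows) else
    tibble::tibble(cluster = integer(), n = integer(),
                   population_fraction = numeric(), end_to_end = numeric(),
                   mean_feature = list(), reconstructed = list())
  attr(out, "noise_fraction") <- sum(labels < 0) / max(n_total, 1)
  out
}

#' Full conformational-landscape pipeline
#'
#' Featurize, embed, cluster and summarise a conformation set in one call
#' (one backend process). Provenance columns of the set are carried onto the
#' embedded points so sources can be compared on the plane.
#'
#' @param confset A conformation-set tibble (see [conformation_set()]).
#' @inheritParams embed_conformations
#' @inheritParams cluster_embedding
#' @return An object of class `landscape_result`: a list with `points` (a
#'   tibble `x`, `y`, `cluster` plus the set's provenance columns),
#'   `clusters` (see [summarize_clusters()]) and `params`.
#' @export
conformational_landscape <- function(confset, n_neighbors = 15,
                                     min_dist = 0.0, seed = 42,
                                     min_cluster_size = 10, min_samples = 3,
                                     merge_threshold = 0.2) {
  features <- featurize_set(confset)
  if (nrow(features) < n_neighbors + 1) {
    stop("need at least n_neighbors + 1 samples", call. = FALSE)
  }
  res <- run_landscape_backend(
    features, "pipeline", n_neighbors = n_neighbors, min_dist = min_dist,
    seeds = seed, min_cluster_size = min_cluster_size,
    min_samples = min_samples, merge_threshold = merge_threshold
  )
  points <- tibble::tibble(
    x = res$x, y = res$y, cluster = as.integer(res$label)
  )
  if (is.data.frame(confset)) {
    meta <- dplyr::select(confset, -dplyr::any_of("coords"))
    points <- dplyr::bind_cols(points, meta)
  }
  structure(
    list(
      points = points,
      clusters = summarize_clusters(points$cluster, features),
      params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                    seed = seed, min_cluster_size = min_cluster_size,
                    min_samples = min_samples,
                    merge_threshold = merge_threshold)
    ),
    class = "landscape_result"
  )
}

#' @export
print.landscape_result <- function(x, ...) {
  cat(sprintf(
    "<landscape_result> %d points, %d clusters (noise %.1f%%), seed %d\n",
    nrow(x$points), nrow(x$clusters),
    100 * attr(x$clusters, "noise_fraction"), x$params$seed
  ))
  invisible(x)
}

#' @method tidy landscape_result
#' @export
tidy.landscape_result <- function(x, ...) {
  dplyr::select(x$clusters, "cluster", "n", "population_fraction",
                "end_to_end")
}

#' @method glance landscape_result
#' @export
glance.landscape_result <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x$points),
    n_clusters = nrow(x$clusters),
    noise_fraction = attr(x$clusters, "noise_fraction"),
    seed = x$params$seed
  )
}

#' Multi-seed replicates of the embed + cluster pipeline
#'
#' Runs the embedding and clustering for several random seeds inside one
#' backend process, for stability analyses (e.g. agreement of the recovered
#' partition with planted families across seeds).
#'
#' @param features Samples-by-features matrix.
#' @param seeds Integer vector of seeds.
#' @inheritParams conformational_landscape
#' @return A tibble with columns `seed`, `point` (row index), `x`, `y`,
#'   `cluster`.
#' @export
landscape_replicates <- function(features, seeds, n_neighbors = 15,
                                 min_dist = 0.0, min_cluster_size = 10,
                                 min_samples = 3, merge_threshold = 0.2) {
  features <- as.matrix(features)
  res <- run_landscape_backend(
    features, "pipeline", n_neighbors = n_neighbors, min_dist = min_dist,
    seeds = seeds, min_cluster_size = min_cluster_size,
    min_samples = min_samples, merge_threshold = merge_threshold
  )
  res |>
    dplyr::group_by(.data$seed) |>
    dplyr::mutate(point = dplyr::row_number(), cluster = as.integer(.data$label)) |>
    dplyr::ungroup() |>
    dplyr::select("seed", "point", "x", "y", "cluster")
}
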
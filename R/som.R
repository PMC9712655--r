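# Self-organizing-map clustering of the standardized descriptor matrix,
# grid-size scanning, and per-cluster activity-enrichment and similarity
# summaries.
#
# Online SOM with a rectangular (non-toroidal) grid, Gaussian
# neighbourhood, and linearly decaying radius and learning rate over
# 10 * n presentation steps.

#' Fit a self-organizing map
#'
#' Trains an online SOM on a standardized descriptor matrix. Codebook
#' vectors are initialised from randomly drawn data rows; at each of
#' `steps` presentations one random chemical updates its best-matching node
#' and the node's Gaussian neighbourhood. Learning rate decays linearly
#' from `alpha[1]` to `alpha[2]`; the neighbourhood radius from half the
#' larger grid dimension to 0.5 (in grid units).
#'
#' @param mat A standardized `descriptor_matrix` (see
#'   [standardize_descriptors()]), or a plain numeric matrix with row
#'   names.
#' @param grid Integer vector `c(rows, cols)`, both >= 2. An 8 x 8 grid (64
#'   clusters) is the default used for screening-library profiling.
#' @param seed Integer seed; training is deterministic given the seed.
#' @param steps Number of presentation steps; default `10 * nrow`.
#' @param alpha Start and end learning rate.
#' @return Object of class `som_model`: `codebook` (nodes x descriptors),
#'   `grid`, `node_xy` (grid coordinates per node), training config.
#' @export
fit_som <- function(mat, grid = c(8L, 8L), seed = 1L, steps = NULL,
                    alpha = c(0.5, 0.01)) {
  X <- if (inherits(mat, "descriptor_matrix")) mat$values else mat
  stopifnot(is.matrix(X), nrow(X) >= 1L)
  if (length(grid) != 2L || any(grid < 2L))
    stop("grid must be c(rows, cols) with both dimensions >= 2")
  grid <- as.integer(grid)
  n_nodes <- prod(grid)
  if (n_nodes > nrow(X))
    warning("more SOM nodes (", n_nodes, ") than chemicals (", nrow(X),
            "); empty clusters are expected")
  if (is.null(steps)) steps <- 10L * nrow(X)

  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  node_xy <- as.matrix(expand.grid(row = seq_len(grid[1]),
                                   col = seq_len(grid[2])))
  grid_d2 <- as.matrix(stats::dist(node_xy))^2

  init_idx <- sample.int(nrow(X), n_nodes, replace = n_nodes > nrow(X))
  codebook <- X[init_idx, , drop = FALSE] +
    matrix(stats::rnorm(n_nodes * ncol(X), sd = 0.01), n_nodes)
  rownames(codebook) <- NULL

  sigma0 <- max(grid) / 2
  sigma1 <- 0.5
  pres <- sample.int(nrow(X), steps, replace = TRUE)
  for (t in seq_len(steps)) {
    frac <- (t - 1) / max(1, steps - 1)
    a <- alpha[1] + (alpha[2] - alpha[1]) * frac
    sigma <- sigma0 + (sigma1 - sigma0) * frac
    x <- X[pres[t], ]
    d2 <- rowSums(sweep(codebook, 2, x)^2)
    bmu <- which.min(d2)
    h <- exp(-grid_d2[, bmu] / (2 * sigma^2))
    active <- h > 1e-3
    codebook[active, ] <- codebook[active, , drop = FALSE] +
      a * h[active] * (rep(x, each = sum(active)) -
                         codebook[active, , drop = FALSE])
  }
  structure(list(codebook = codebook, grid = grid, node_xy = node_xy,
                 seed = seed, steps = steps, alpha = alpha,
                 descriptor_names = colnames(X)),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat("SOM model:", x$grid[1], "x", x$grid[2], "grid (",
      prod(x$grid), "clusters ) on", length(x$descriptor_names),
      "descriptors\n")
  invisible(x)
}

#' Assign chemicals to SOM clusters
#'
#' @param model A `som_model`.
#' @param mat Standardized `descriptor_matrix` (same descriptors as
#'   training) or plain matrix.
#' @return Named integer vector of cluster ids (1..rows*cols) per chemical.
#' @export
som_assign <- function(model, mat) {
  X <- if (inherits(mat, "descriptor_matrix")) mat$values else mat
  stopifnot(is.matrix(X), ncol(X) == ncol(model$codebook))
  cb <- model$codebook
  cb_sq <- rowSums(cb^2)
  # argmin over nodes of |x - w|^2 = |x|^2 - 2 x.w + |w|^2
  cross <- X %*% t(cb)
  assign <- max.col(cross - matrix(cb_sq / 2, nrow(X), nrow(cb),
                                   byrow = TRUE), ties.method = "first")
  stats::setNames(assign, rownames(X))
}

#' Scan candidate SOM grid sizes
#'
#' Fits one SOM per candidate grid and reports cluster occupancy so the
#' grid size can be chosen as a balance between the number of clusters and
#' the chemicals per cluster.
#'
#' @param mat Standardized descriptor matrix.
#' @param grids List of `c(rows, cols)` candidates.
#' @param seed Seed shared across candidates.
#' @return Data frame (one row per candidate, sorted by cluster count):
#'   rows, cols, n_clusters, n_empty, min_size, median_size, max_size.
#' @export
scan_grid_sizes <- function(mat, grids, seed = 1L) {
  stopifnot(length(grids) >= 1L)
  rows <- lapply(grids, function(g) {
    model <- fit_som(mat, grid = g, seed = seed)
    asg <- som_assign(model, mat)
    sizes <- tabulate(asg, nbins = prod(g))
    data.frame(rows = g[1], cols = g[2], n_clusters = prod(g),
               n_empty = sum(sizes == 0L),
               min_size = min(sizes[sizes > 0]),
               median_size = stats::median(sizes[sizes > 0]),
               max_size = max(sizes))
  })
  out <- do.call(rbind, rows)
  out[order(out$n_clusters), , drop = FALSE]
}

#' Per-cluster activity enrichment
#'
#' For each cluster and endpoint, the proportion of active chemicals in the
#' cluster (actives in cluster / cluster size, a value in 0..1). When more
#' than one endpoint is given, the intersection set (active for every
#' endpoint) is summarised as endpoint `"both"`.
#'
#' @param assignments Named cluster vector from [som_assign()].
#' @param labels Data frame (id, endpoint, active 0/1); ids not assigned
#'   are ignored, assigned ids missing a label for an endpoint are treated
#'   as label-excluded and do not count towards that endpoint's
#'   proportions.
#' @param n_clusters Total clusters (defaults to `max(assignments)`).
#' @return Data frame of class `cluster_profiles`: cluster, size, endpoint,
#'   n_active, proportion (NA for empty clusters).
#' @export
cluster_activity_enrichment <- function(assignments, labels,
                                        n_clusters = max(assignments)) {
  stopifnot(!is.null(names(assignments)),
            all(c("id", "endpoint", "active") %in% names(labels)))
  endpoints <- unique(labels$endpoint)
  sizes <- tabulate(assignments, nbins = n_clusters)
  sets <- lapply(endpoints, function(ep) {
    lab <- labels[labels$endpoint == ep, ]
    lab$id[lab$active == 1]
  })
  names(sets) <- endpoints
  if (length(endpoints) > 1L)
    sets$both <- Reduce(intersect, sets)
  out <- do.call(rbind, lapply(names(sets), function(ep) {
    act <- names(assignments) %in% sets[[ep]]
    n_act <- vapply(seq_len(n_clusters), function(k)
      sum(act[assignments == k]), numeric(1))
    data.frame(cluster = seq_len(n_clusters), size = sizes, endpoint = ep,
               n_active = n_act,
               proportion = ifelse(sizes > 0, n_act / sizes, NA_real_))
  }))
  class(out) <- c("cluster_profiles", class(out))
  out
}

#' Per-cluster mean reference similarity
#'
#' Arithmetic mean of a reference-similarity profile within each cluster
#' (e.g. mean similarity to estradiol per SOM cluster).
#'
#' @param assignments Named cluster vector from [som_assign()].
#' @param profile A [similarity_profile()] covering all assigned ids.
#' @param n_clusters Total clusters.
#' @return Data frame: cluster, size, mean_similarity (NA for empty
#'   clusters).
#' @export
cluster_similarity_summary <- function(assignments, profile,
                                       n_clusters = max(assignments)) {
  stopifnot(inherits(profile, "similarity_profile"))
  sc <- stats::setNames(profile$scores$score, profile$scores$id)
  if (!all(names(assignments) %in% names(sc)))
    stop("profile does not cover all assigned chemicals")
  sizes <- tabulate(assignments, nbins = n_clusters)
  means <- vapply(seq_len(n_clusters), function(k) {
    ids <- names(assignments)[assignments == k]
    if (length(ids) == 0L) NA_real_ else mean(sc[ids])
  }, numeric(1))
  data.frame(cluster = seq_len(n_clusters), size = sizes,
             mean_similarity = means)
}
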
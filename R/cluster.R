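#' Complete-linkage clustergram dendrogram
#'
#' Agglomerative hierarchical clustering with complete linkage on Euclidean
#' distances, over cells (expression rows) or genes (columns). This is the
#' ordering used for clustergram heatmaps; complete linkage guarantees
#' monotone merge heights.
#'
#' @param e An `expression_matrix`, or a plain numeric matrix of
#'   observations in rows.
#' @param axis `"cells"` clusters rows, `"genes"` clusters columns.
#' @return An [stats::hclust] object (merge heights in Euclidean units,
#'   `$order` the leaf order, `$labels` the item names).
#' @export
hierarchical_clustergram <- function(e, axis = c("cells", "genes")) {
  axis <- match.arg(axis)
  x <- .expr_of(e)
  if (axis == "genes") x <- t(x)
  if (nrow(x) < 2) stop("need at least 2 items on axis '", axis, "'")
  stats::hclust(stats::dist(x, method = "euclidean"), method = "complete")
}

.expr_of <- function(e) {
  if (inherits(e, "expression_matrix")) e$expr
  else if (is.matrix(e) && is.numeric(e)) e
  else stop("expected an expression_matrix or numeric matrix")
}

# k-means++ initial centers: first uniform, then proportional to squared
# distance from the nearest chosen center.
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    pick <- if (sum(d2) > 0) sample.int(n, 1, prob = d2) else sample.int(n, 1)
    centers[j + 1, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

# Squared Euclidean distances of every row of x to every center.
.dist2 <- function(x, centers) {
  cross <- x %*% t(centers)
  sweep(-2 * cross, 2, rowSums(centers^2), "+") + rowSums(x^2)
}

# Lloyd iterations from given centers. Ties in assignment go to the lowest
# cluster index; a cluster emptied during iteration is re-seeded from the
# point farthest from its current centroid.
.lloyd <- function(x, centers, max_iter = 100L) {
  k <- nrow(centers)
  assign_prev <- integer(0)
  for (it in seq_len(max_iter)) {
    d2 <- .dist2(x, centers)
    assignment <- max.col(-d2, ties.method = "first")
    for (j in which(tabulate(assignment, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), assignment)])
      centers[j, ] <- x[far, ]
      d2[, j] <- rowSums(sweep(x, 2, centers[j, ])^2)
      assignment <- max.col(-d2, ties.method = "first")
    }
    if (identical(assignment, assign_prev)) break
    assign_prev <- assignment
    for (j in seq_len(k)) centers[j, ] <- colMeans(x[assignment == j, , drop = FALSE])
  }
  d2 <- .dist2(x, centers)
  list(assignment = assignment, centers = centers,
       wcss = sum(d2[cbind(seq_len(nrow(x)), assignment)]),
       cell_d = sqrt(pmax(d2[cbind(seq_len(nrow(x)), assignment)], 0)))
}

#' Partition cells by k-means
#'
#' Lloyd's algorithm minimizing the within-cluster sum of squared Euclidean
#' distances (WCSS), with k-means++ seeding and `n_init` independent
#' restarts; the restart with the lowest WCSS is kept. Fully reproducible
#' given `seed`, `n_init` and the input row order. Within each cluster,
#' cells are sub-grouped by complete-linkage hierarchical clustering and
#' the clusters themselves ordered by a dendrogram on their centroids,
#' giving the clustergram leaf order (see [subgroup_order()]).
#'
#' @param e An `expression_matrix` or numeric matrix (cells in rows).
#' @param k Number of clusters (at most the number of cells).
#' @param seed Integer RNG seed.
#' @param n_init Number of k-means++ restarts (default 50).
#' @param max_iter Maximum Lloyd iterations per restart.
#' @return An object of class `cluster_model`: `k`, `assignment` (named,
#'   values 1..k, every cluster non-empty), `centroids` (k x genes, the
#'   member means), `wcss`, `sizes`, `cell_dist` (per-cell Euclidean
#'   distance to its centroid), `leaf_order`, `groups` (per-cell group
#'   labels if available), `genes`, `bound`, `seed`, `n_init`.
#' @export
kmeans_partition <- function(e, k, seed = 1L, n_init = 50L, max_iter = 100L) {
  x <- .expr_of(e)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  if (k > nrow(x)) stop("`k` (", k, ") exceeds the number of cells (", nrow(x), ")")
  if (any(!is.finite(x))) stop("expression values must be finite")
  best <- NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (r in seq_len(n_init)) {
    fit <- .lloyd(x, .kmeanspp_init(x, k), max_iter)
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  assignment <- stats::setNames(best$assignment, rownames(x))
  centroids <- best$centers
  for (j in seq_len(k)) centroids[j, ] <- colMeans(x[assignment == j, , drop = FALSE])
  colnames(centroids) <- colnames(x)
  d2 <- pmax(.dist2(x, centroids)[cbind(seq_len(nrow(x)), assignment)], 0)
  model <- structure(list(
    k = as.integer(k), assignment = assignment, centroids = centroids,
    wcss = sum(d2), sizes = tabulate(assignment, k),
    cell_dist = stats::setNames(sqrt(d2), rownames(x)),
    groups = if (inherits(e, "expression_matrix")) stats::setNames(e$meta$group, rownames(x)) else NULL,
    genes = colnames(x),
    bound = if (inherits(e, "expression_matrix")) e$bound else NA_real_,
    seed = as.integer(seed), n_init = as.integer(n_init)),
    class = "cluster_model")
  model$leaf_order <- subgroup_order(x, model)
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, wcss = %.4g, sizes: %s\n",
              x$k, x$wcss, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Choose the number of clusters by mean silhouette width
#'
#' Fits [kmeans_partition()] for each candidate k and selects the k with
#' the largest mean silhouette width ([cluster::silhouette]). The per-k
#' WCSS and silhouette are returned so alternative criteria can be
#' audited. If no candidate reaches mean silhouette 0.25 the data are
#' flagged as showing no cluster structure; if all cells are identical,
#' k = 1 is returned with a warning.
#'
#' @param e An `expression_matrix` or numeric matrix.
#' @param k_range Candidate k values (within `[2, cells - 1]`).
#' @param seed Integer RNG seed.
#' @param n_init Restarts per candidate k (default 10; the final model at
#'   the chosen k is typically refit at a higher `n_init`).
#' @return List with `k` (chosen), `no_structure` (logical),
#'   `diagnostics` (data frame of k, wcss, silhouette), and `models`
#'   (the fitted `cluster_model` per candidate, named by k).
#' @export
select_k <- function(e, k_range = 2:8, seed = 1L, n_init = 10L) {
  x <- .expr_of(e)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > nrow(x) - 1))
    stop("`k_range` must lie within [2, cells - 1]")
  if (all(apply(x, 2, function(col) length(unique(col)) == 1L))) {
    warning("all cells identical; no partition possible, returning k = 1")
    return(list(k = 1L, no_structure = TRUE,
                diagnostics = data.frame(k = integer(), wcss = numeric(),
                                         silhouette = numeric()),
                models = list()))
  }
  d <- stats::dist(x)
  models <- list()
  diag_df <- data.frame(k = k_range, wcss = NA_real_, silhouette = NA_real_)
  for (i in seq_along(k_range)) {
    mod <- kmeans_partition(e, k_range[i], seed = seed, n_init = n_init)
    models[[as.character(k_range[i])]] <- mod
    sil <- cluster::silhouette(as.integer(mod$assignment), d)
    diag_df$wcss[i] <- mod$wcss
    diag_df$silhouette[i] <- mean(sil[, "sil_width"])
  }
  best <- which.max(diag_df$silhouette)
  list(k = k_range[best], no_structure = diag_df$silhouette[best] < 0.25,
       diagnostics = diag_df, models = models)
}

#' Clustergram leaf order from a fitted partition
#'
#' Orders cells for heatmap display: clusters are arranged by a
#' complete-linkage dendrogram over their centroids, and within each
#' cluster cells follow their own complete-linkage dendrogram leaf order.
#' Cells of the same cluster therefore occupy a contiguous block.
#'
#' @param e An `expression_matrix` or numeric matrix (same cells as `model`).
#' @param model A `cluster_model`.
#' @return Integer permutation of `1:cells`.
#' @export
subgroup_order <- function(e, model) {
  x <- .expr_of(e)
  k <- model$k
  cluster_seq <- if (k >= 3) {
    stats::hclust(stats::dist(model$centroids), method = "complete")$order
  } else seq_len(k)
  out <- integer(0)
  for (j in cluster_seq) {
    members <- which(model$assignment == j)
    if (length(members) > 2) {
      hc <- stats::hclust(stats::dist(x[members, , drop = FALSE]), method = "complete")
      members <- members[hc$order]
    }
    out <- c(out, members)
  }
  out
}
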
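# Exact minimum-cost one-to-one assignment (Hungarian algorithm, O(n^3),
# potentials + shortest augmenting path). `cost` must be square; returns
# for each row the assigned column.
.hungarian_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost))
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)        # p[j]: row assigned to column j (0 = none); slot n+1 is virtual
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      u[p[n + 1L]] <- u[p[n + 1L]] + delta * used[n + 1L]
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) assignment[p[j]] <- j
  assignment
}

#' Match clusters between two independently clustered groups
#'
#' When each experimental group is clustered separately on the same
#' normalized gene panel, clusters can be aligned by an exact one-to-one
#' assignment minimizing total centroid Euclidean distance. Pairs whose
#' centroid distance exceeds `max_dist` are broken and reported as
#' unmatched — candidates for a subpopulation absent from the other group.
#'
#' @param model_a,model_b `cluster_model` objects fitted on the same gene
#'   panel and normalization bound.
#' @param max_dist Distance above which a matched pair is rejected.
#'   Default: the 95th percentile of cell-to-centroid distances in
#'   `model_a`, a scale-aware notion of "within one cluster's spread".
#' @return An object of class `cluster_match`: `pairs` (data frame of
#'   cluster_a, cluster_b, dist), `unmatched_a`, `unmatched_b`,
#'   `abundance_a`, `abundance_b` (per-group relative abundances, each
#'   summing to 1), and `max_dist`.
#' @export
match_clusters <- function(model_a, model_b, max_dist = NULL) {
  stopifnot(inherits(model_a, "cluster_model"), inherits(model_b, "cluster_model"))
  if (!identical(model_a$genes, model_b$genes))
    stop("models were fitted on different gene panels")
  if (!isTRUE(all.equal(model_a$bound, model_b$bound)))
    stop("models use different normalization bounds")
  if (is.null(max_dist))
    max_dist <- stats::quantile(model_a$cell_dist, 0.95, names = FALSE)
  ka <- model_a$k
  kb <- model_b$k
  n <- max(ka, kb)
  d <- matrix(0, n, n)   # pad with zero-cost dummies; constant offset, exact on the real block
  for (i in seq_len(ka)) for (j in seq_len(kb))
    d[i, j] <- sqrt(sum((model_a$centroids[i, ] - model_b$centroids[j, ])^2))
  assignment <- .hungarian_min(d)
  pairs <- data.frame(cluster_a = integer(), cluster_b = integer(), dist = numeric())
  unmatched_a <- integer(0)
  for (i in seq_len(ka)) {
    j <- assignment[i]
    if (j <= kb && d[i, j] <= max_dist) {
      pairs <- rbind(pairs, data.frame(cluster_a = i, cluster_b = j, dist = d[i, j]))
    } else {
      unmatched_a <- c(unmatched_a, i)
    }
  }
  structure(list(pairs = pairs,
                 unmatched_a = unmatched_a,
                 unmatched_b = setdiff(seq_len(kb), pairs$cluster_b),
                 abundance_a = model_a$sizes / sum(model_a$sizes),
                 abundance_b = model_b$sizes / sum(model_b$sizes),
                 max_dist = max_dist),
            class = "cluster_match")
}

#' @export
print.cluster_match <- function(x, ...) {
  cat(sprintf("<cluster_match> %d matched pair(s); unmatched A: %s; unmatched B: %s\n",
              nrow(x$pairs),
              if (length(x$unmatched_a)) paste(x$unmatched_a, collapse = ",") else "none",
              if (length(x$unmatched_b)) paste(x$unmatched_b, collapse = ",") else "none"))
  invisible(x)
}

#' Classify each reference-group cluster as present, depleted or absent
#'
#' Labels each cluster of group A according to its fate in group B:
#' `absent` if it found no match or its matched B abundance falls strictly
#' below `minority_floor`; `depleted` if matched but the B/A abundance
#' ratio falls below `depletion_ratio`; `present` otherwise. A B abundance
#' exactly at the floor is not absent (strict inequality) and is then
#' judged by the depletion ratio.
#'
#' @param match A `cluster_match`.
#' @param minority_floor Relative abundance below which a matched cluster
#'   counts as effectively absent (default 0.02).
#' @param depletion_ratio B/A abundance ratio below which a matched
#'   cluster counts as depleted (default 0.5).
#' @return Data frame: cluster_a, matched_b (NA if unmatched), dist,
#'   abundance_a, abundance_b, ratio, status.
#' @export
absence_report <- function(match, minority_floor = 0.02, depletion_ratio = 0.5) {
  stopifnot(inherits(match, "cluster_match"))
  ka <- length(match$abundance_a)
  out <- data.frame(cluster_a = seq_len(ka), matched_b = NA_integer_,
                    dist = NA_real_, abundance_a = match$abundance_a,
                    abundance_b = 0, ratio = NA_real_,
                    status = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(ka)) {
    row <- match$pairs[match$pairs$cluster_a == i, ]
    if (nrow(row) == 0) {
      out$status[i] <- "absent"
      next
    }
    ab <- match$abundance_b[row$cluster_b]
    out$matched_b[i] <- row$cluster_b
    out$dist[i] <- row$dist
    out$abundance_b[i] <- ab
    out$ratio[i] <- ab / out$abundance_a[i]
    out$status[i] <- if (ab < minority_floor) "absent"
                     else if (out$ratio[i] < depletion_ratio) "depleted"
                     else "present"
  }
  out
}
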
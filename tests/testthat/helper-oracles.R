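# Independent brute-force oracles used to validate the implementation.

# Complete-linkage agglomeration, O(n^3): repeatedly merge the pair of
# active clusters with the smallest maximum pairwise member distance.
# Returns the sorted merge heights.
oracle_complete_linkage_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf
    bi <- bj <- 0
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          h <- max(d[clusters[[i]], clusters[[j]]])
          if (h < best) { best <- h; bi <- i; bj <- j }
        }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# Exhaustive k-means oracle: minimum WCSS over every assignment of n
# points to k non-empty clusters (centroid = member mean).
oracle_min_wcss <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  labels <- rep(1L, n)
  repeat {
    if (length(unique(labels)) == k) {
      w <- 0
      for (j in seq_len(k)) {
        m <- x[labels == j, , drop = FALSE]
        if (nrow(m)) w <- w + sum(sweep(m, 2, colMeans(m))^2)
      }
      best <- min(best, w)
    }
    i <- 1L
    while (i <= n && labels[i] == k) { labels[i] <- 1L; i <- i + 1L }
    if (i > n) break
    labels[i] <- labels[i] + 1L
  }
  best
}

# ECDF-sweep K-S oracle: evaluate both empirical CDFs at every pooled
# observation by direct counting.
oracle_ks_D <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# Exact assignment oracle: minimum total cost over all permutations.
oracle_min_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

# Tiny hand-built ct_matrix: 4 cells x 3 genes with two failures.
tiny_ct <- function() {
  ct <- matrix(c(20, 21, 22, 23,
                 30, NA, 31, 33,
                 25, 26, NA, 24), 4, 3,
               dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  ct_matrix(ct, meta = data.frame(plate = "P1", well = paste0("W", 1:4),
                                  group = c("WT", "WT", "eKO", "eKO")))
}

# Two well-separated Gaussian blobs for separable clustering cases.
two_blobs <- function(n_per = 20, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2, 0, sd), ncol = 2),
             matrix(rnorm(n_per * 2, sep, sd), ncol = 2))
  rownames(x) <- paste0("c", seq_len(2 * n_per))
  x
}
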
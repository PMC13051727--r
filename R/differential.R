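#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the K-S statistic D, the supremum over t of the absolute
#' difference between the two empirical CDFs, and an asymptotic p-value
#' from the Kolmogorov distribution using the standard effective-sample-size
#' finite-sample correction
#' \eqn{\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})\,D} with
#' \eqn{n_e = nm/(n+m)}. Ties (e.g. many cells at the expression floor)
#' are handled directly by the ECDF definition; no continuity correction
#' is applied.
#'
#' @param x,y Numeric samples (each non-empty; a warning is issued below
#'   5 observations).
#' @return List with `D` (in `[0, 1]`) and `p` (in `(0, 1]`).
#' @examples
#' ks_two_sample(c(1, 3, 5, 7), c(2, 4, 6, 8))$D  # 0.25
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  if (min(length(x), length(y)) < 5)
    warning("K-S test with fewer than 5 observations in a sample")
  z <- sort(unique(c(x, y)))
  D <- max(abs(findInterval(z, sort(x)) / length(x) -
               findInterval(z, sort(y)) / length(y)))
  list(D = D, p = .ks_p_asymptotic(D, length(x), length(y)))
}

.ks_p_asymptotic <- function(D, n, m) {
  if (D <= 0) return(1)
  ne <- n * m / (n + m)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  j <- seq_len(101)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(1, max(p, .Machine$double.xmin))
}

.ks_panel <- function(expr, sel_focal, sel_rest, alpha, comparison, m_tests = NULL) {
  genes <- colnames(expr)
  m <- if (is.null(m_tests)) length(genes) else m_tests
  D <- p_raw <- dir <- numeric(length(genes))
  for (i in seq_along(genes)) {
    xf <- expr[sel_focal, i]
    xr <- expr[sel_rest, i]
    ks <- suppressWarnings(ks_two_sample(xf, xr))
    D[i] <- ks$D
    p_raw[i] <- ks$p
    dir[i] <- sign(stats::median(xf) - stats::median(xr))
  }
  p_bonf <- pmin(1, m * p_raw)
  structure(data.frame(gene = genes, D = D, p_raw = p_raw, p_bonf = p_bonf,
                       significant = p_bonf < alpha, direction = dir,
                       stringsAsFactors = FALSE, row.names = NULL),
            alpha = alpha, m = m, comparison = comparison,
            class = c("diff_result", "data.frame"))
}

#' Differential expression of one cluster against all remaining cells
#'
#' For each gene, the empirical expression distribution of the cells in
#' `cluster_id` is compared against that of all remaining cells with a
#' two-sample K-S test; p-values are Bonferroni-corrected over the gene
#' panel (one family per cluster comparison by default). Direction is the
#' sign of the focal-minus-rest median difference.
#'
#' @param e An `expression_matrix`.
#' @param model A `cluster_model` fitted on the same cells.
#' @param cluster_id Cluster label in `1:model$k`.
#' @param alpha Family-wise significance cutoff (default 0.05).
#' @param m_scope `"genes"` corrects over the gene panel (default);
#'   `"genes_by_clusters"` over genes times the number of clusters.
#' @return A `diff_result` data frame: gene, D, p_raw, p_bonf,
#'   significant, direction.
#' @export
cluster_vs_rest <- function(e, model, cluster_id, alpha = 0.05,
                            m_scope = c("genes", "genes_by_clusters")) {
  stopifnot(inherits(e, "expression_matrix"), inherits(model, "cluster_model"))
  m_scope <- match.arg(m_scope)
  if (!identical(names(model$assignment), rownames(e$expr)))
    stop("`model` was fitted on different cells than `e`")
  focal <- which(model$assignment == cluster_id)
  rest <- which(model$assignment != cluster_id)
  if (length(focal) == 0) stop("cluster ", cluster_id, " is empty")
  if (length(rest) == 0) stop("cluster ", cluster_id, " covers all cells; no rest to compare")
  m_tests <- if (m_scope == "genes") ncol(e$expr) else ncol(e$expr) * model$k
  .ks_panel(e$expr, focal, rest, alpha,
            sprintf("cluster-%s-vs-rest", cluster_id), m_tests)
}

#' Differential expression between two cell groups
#'
#' Per-gene two-sample K-S tests splitting cells on a two-level group
#' label (e.g. wild-type vs conditional knockout), Bonferroni-corrected
#' over the gene panel. Direction is the sign of the first-group-minus-
#' second-group median difference; the first group is the first factor
#' level, or for plain labels the first in C-locale sort order (so that
#' exchanging the two labels between the cell sets flips every direction).
#'
#' @param e An `expression_matrix`.
#' @param groups Per-cell labels (exactly two distinct values); defaults
#'   to the `group` metadata column.
#' @param alpha Family-wise significance cutoff.
#' @return A `diff_result` data frame.
#' @export
group_vs_group <- function(e, groups = NULL, alpha = 0.05) {
  stopifnot(inherits(e, "expression_matrix"))
  if (is.null(groups)) groups <- e$meta$group
  if (length(groups) != nrow(e$expr)) stop("`groups` must label every cell")
  lev <- if (is.factor(groups)) levels(droplevels(groups))
         else sort(unique(as.character(groups)), method = "radix")
  if (length(lev) != 2)
    stop("`groups` has ", length(lev), " labels; run pairwise comparisons of two labels")
  .ks_panel(e$expr, which(groups == lev[1]), which(groups == lev[2]), alpha,
            sprintf("%s-vs-%s", lev[1], lev[2]))
}

#' Export significant genes as a seed list
#'
#' Writes the significant genes of a differential result to CSV (columns
#' gene, D, p_bonf, direction) — the hand-off to external pathway/network
#' tools, which take these as seed genes.
#'
#' @param r A `diff_result`.
#' @param path Output CSV path.
#' @export
export_seed_genes <- function(r, path) {
  stopifnot(inherits(r, "diff_result"))
  out <- r[r$significant, c("gene", "D", "p_bonf", "direction"), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(NULL)
}
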
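#' Bounded log2 expression relative to pooled per-gene medians
#'
#' Converts raw Ct values to relative log2 expression. For each gene the
#' median Ct is computed over all non-failed reactions, pooled across every
#' cell in the experiment (both groups share one reference by default).
#' Expression is the median minus the observed Ct — one cycle fewer than
#' the median means twice the transcript, so lower Ct maps to positive
#' log2 expression — clipped to the closed interval `[-bound, +bound]`.
#' Failed reactions (non-expressers) are excluded from the median and then
#' assigned to the floor `-bound`.
#'
#' @param m A [ct_matrix()].
#' @param bound Positive absolute bound in cycle thresholds (log2 units).
#'   The default 5 caps expression at 32-fold above or below the median
#'   (see [fold_change_bound()]).
#' @param pool `"global"` pools the median across all cells (default);
#'   `"group"` computes medians within each metadata group.
#' @return An object of class `expression_matrix`: list with `expr`
#'   (cells x genes, values in `[-bound, bound]`), `nonexpresser` (logical
#'   mask), `meta`, `bound`, and `all_failed` (genes with no successful
#'   reaction, retained at the floor with a warning).
#' @examples
#' ct <- matrix(c(20, 21, 22, 25, 25, 25), 3, 2,
#'              dimnames = list(paste0("c", 1:3), c("g1", "g2")))
#' e <- pooled_median_normalize(ct_matrix(ct))
#' e$expr[, "g1"]   # +1, 0, -1
#' @export
pooled_median_normalize <- function(m, bound = 5, pool = c("global", "group")) {
  stopifnot(inherits(m, "ct_matrix"))
  pool <- match.arg(pool)
  if (!is.numeric(bound) || length(bound) != 1 || bound <= 0)
    stop("`bound` must be a single positive number")
  ct <- m$ct
  failed <- m$failed
  masked <- ct
  masked[failed] <- NA_real_
  med_for <- function(rows) apply(masked[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  expr <- matrix(NA_real_, nrow(ct), ncol(ct), dimnames = dimnames(ct))
  if (pool == "global") {
    med <- med_for(seq_len(nrow(ct)))
    expr[] <- rep(med, each = nrow(ct)) - ct
  } else {
    for (g in unique(m$meta$group)) {
      rows <- which(m$meta$group == g)
      expr[rows, ] <- rep(med_for(rows), each = length(rows)) - ct[rows, ]
    }
  }
  all_failed <- colnames(ct)[colSums(!failed) == 0]
  if (length(all_failed))
    warning("gene(s) with no successful amplification, kept at floor: ",
            paste(all_failed, collapse = ", "))
  expr <- pmin(pmax(expr, -bound), bound)
  expr[failed] <- -bound
  structure(list(expr = expr, nonexpresser = failed, meta = m$meta,
                 bound = bound, all_failed = all_failed),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes; bound +/-%g (%g-fold); %.1f%% non-expressers\n",
              nrow(x$expr), ncol(x$expr), x$bound, fold_change_bound(x$bound),
              100 * mean(x$nonexpresser)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$expr)

#' Maximal linear fold change under a log2 clipping bound
#'
#' An absolute bound of B cycle thresholds around the per-gene median
#' corresponds to a maximal representable change of `2^B`-fold in linear
#' expression; the default bound of 5 gives 32-fold.
#'
#' @param bound Non-negative bound in log2 (cycle-threshold) units.
#' @return `2^bound`.
#' @examples
#' fold_change_bound(5)  # 32
#' @export
fold_change_bound <- function(bound) {
  if (!is.numeric(bound) || any(bound < 0)) stop("`bound` must be non-negative")
  2^bound
}

#' Fraction of non-expressing cells for a gene
#'
#' The fraction of cells in a subset whose reaction for `gene` failed to
#' amplify — the "failed to amplify" bar reported alongside differential
#' gene panels.
#'
#' @param e An `expression_matrix`.
#' @param gene Gene symbol.
#' @param subset Cell ids, integer indices, or a logical vector selecting
#'   cells; defaults to all cells.
#' @return A fraction in `[0, 1]`.
#' @export
nonexpresser_fraction <- function(e, gene, subset = NULL) {
  stopifnot(inherits(e, "expression_matrix"))
  if (!gene %in% colnames(e$expr)) stop("unknown gene: ", gene)
  if (is.null(subset)) subset <- seq_len(nrow(e$expr))
  v <- e$nonexpresser[subset, gene]
  if (length(v) == 0) stop("empty cell subset")
  mean(v)
}
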
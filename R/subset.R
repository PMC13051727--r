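#' Subset an expression matrix by cells
#'
#' @param e An `expression_matrix`.
#' @param cells Cell ids, integer indices, or a logical selector.
#' @return An `expression_matrix` restricted to the selected cells.
#' @export
subset_cells <- function(e, cells) {
  stopifnot(inherits(e, "expression_matrix"))
  if (is.character(cells)) cells <- match(cells, rownames(e$expr))
  if (anyNA(cells)) stop("unknown cell id(s)")
  out <- e
  out$expr <- e$expr[cells, , drop = FALSE]
  out$nonexpresser <- e$nonexpresser[cells, , drop = FALSE]
  out$meta <- e$meta[cells, , drop = FALSE]
  rownames(out$meta) <- NULL
  if (nrow(out$expr) == 0) stop("empty cell subset")
  out
}

#' Split an expression matrix by experimental group
#'
#' Convenience wrapper around [subset_cells()] for per-group analyses
#' (e.g. clustering each genotype independently before cross-group
#' cluster matching).
#'
#' @param e An `expression_matrix`.
#' @return Named list of `expression_matrix`, one per group, in order of
#'   appearance.
#' @export
split_by_group <- function(e) {
  stopifnot(inherits(e, "expression_matrix"))
  lev <- unique(e$meta$group)
  stats::setNames(lapply(lev, function(g) subset_cells(e, e$meta$group == g)), lev)
}
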
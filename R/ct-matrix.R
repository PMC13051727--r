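#' Construct a Ct matrix
#'
#' A `ct_matrix` holds raw cycle-threshold (Ct) observations from a
#' single-cell qPCR experiment: a cells-by-genes numeric matrix, a parallel
#' logical mask marking reactions that failed to amplify, and per-cell
#' metadata (plate, well, experimental group). Wherever `failed` is `TRUE`
#' the Ct value is ignored by all downstream computation.
#'
#' @param ct Numeric matrix of Ct values (cycles), cells in rows, genes in
#'   columns. Must carry unique row (cell) and column (gene) names.
#' @param failed Logical matrix of the same dimension; `TRUE` marks a
#'   failed amplification. Defaults to `is.na(ct)`.
#' @param meta Data frame with one row per cell and columns `plate`, `well`
#'   and `group`; defaults to placeholder metadata (one plate, wells in row
#'   order, a single group `"all"`).
#' @return An object of class `ct_matrix`: a list with elements `ct`,
#'   `failed` and `meta` (which gains a `cell` column).
#' @examples
#' ct <- matrix(c(21, 22, 30, NA), 2, 2,
#'              dimnames = list(c("c1", "c2"), c("g1", "g2")))
#' m <- ct_matrix(ct)
#' m$failed["c2", "g2"]
#' @export
ct_matrix <- function(ct, failed = NULL, meta = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (cells x genes)")
  if ((is.null(rownames(ct)) && nrow(ct) > 0) ||
      (is.null(colnames(ct)) && ncol(ct) > 0))
    stop("`ct` must have cell (row) and gene (column) names")
  if (is.null(failed)) failed <- is.na(ct)
  if (!is.logical(failed) || !identical(dim(failed), dim(ct)))
    stop("`failed` must be a logical matrix with the same dimensions as `ct`")
  dimnames(failed) <- dimnames(ct)
  dup <- rownames(ct)[duplicated(rownames(ct))]
  if (length(dup)) stop("duplicate cell id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(ct)[duplicated(colnames(ct))]
  if (length(dup)) stop("duplicate gene symbol(s): ", paste(unique(dup), collapse = ", "))
  if (any(!failed & is.na(ct)))
    stop("non-failed entries must carry finite Ct values")
  if (is.null(meta)) {
    meta <- data.frame(plate = "P1", well = as.character(seq_len(nrow(ct))),
                       group = "all", stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(ct)) stop("`meta` must have one row per cell")
  need <- setdiff(c("plate", "well", "group"), names(meta))
  if (length(need)) stop("`meta` is missing column(s): ", paste(need, collapse = ", "))
  meta <- data.frame(cell = rownames(ct),
                     meta[, c("plate", "well", "group"), drop = FALSE],
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(ct = ct, failed = failed, meta = meta), class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d cells x %d genes; %d failed amplifications (%.1f%%)\n",
              nrow(x$ct), ncol(x$ct), sum(x$failed),
              100 * mean(x$failed)))
  cat("groups:", paste(sprintf("%s (%d)", names(table(x$meta$group)),
                               table(x$meta$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

# Default set of tokens read as failed amplification. Fluidigm exports
# conventionally report 999 for no amplification.
#' @export
default_na_tokens <- c("", "NA", "No Call", "999")

#' Read a Ct table from CSV
#'
#' Two dialects are supported. `wide`: first column the cell id, then the
#' metadata columns `plate`, `well`, `group`, then one column per gene.
#' `long`: columns `cell`, `plate`, `well`, `group`, `gene`, `ct` (the three
#' metadata columns may be omitted). In the long dialect a (cell, gene)
#' combination absent from the file is treated as failed amplification.
#' Row and column order in the file is preserved; nothing is sorted.
#'
#' @param path Path to a CSV file.
#' @param dialect `"wide"` or `"long"`.
#' @param na_tokens Character vector of tokens marking failed amplification.
#' @return A [ct_matrix()].
#' @export
read_ct_csv <- function(path, dialect = c("wide", "long"),
                        na_tokens = default_na_tokens) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         stringsAsFactors = FALSE)
  if (dialect == "wide") .read_ct_wide(raw, na_tokens) else .read_ct_long(raw, na_tokens)
}

.parse_ct_tokens <- function(tok, na_tokens, where) {
  failed <- tok %in% na_tokens | is.na(tok)
  ct <- suppressWarnings(as.numeric(tok))
  bad <- which(!failed & is.na(ct))
  if (length(bad)) {
    stop(sprintf("non-numeric Ct value %s at %s",
                 dQuote(tok[bad[1]]), where[bad[1]]))
  }
  ct[failed] <- NA_real_
  list(ct = ct, failed = failed)
}

.read_ct_wide <- function(raw, na_tokens) {
  meta_cols <- intersect(c("plate", "well", "group"), names(raw))
  gene_cols <- setdiff(names(raw)[-1], meta_cols)
  cells <- raw[[1]]
  n <- nrow(raw)
  ct <- matrix(NA_real_, n, length(gene_cols),
               dimnames = list(cells, gene_cols))
  failed <- matrix(FALSE, n, length(gene_cols), dimnames = dimnames(ct))
  for (j in seq_along(gene_cols)) {
    where <- sprintf("row %d, column %s", seq_len(n) + 1L, dQuote(gene_cols[j]))
    p <- .parse_ct_tokens(raw[[gene_cols[j]]], na_tokens, where)
    ct[, j] <- p$ct
    failed[, j] <- p$failed
  }
  meta <- if (length(meta_cols)) raw[, meta_cols, drop = FALSE] else NULL
  ct_matrix(ct, failed, meta)
}

.read_ct_long <- function(raw, na_tokens) {
  need <- setdiff(c("cell", "gene", "ct"), names(raw))
  if (length(need)) stop("long dialect requires column(s): ", paste(need, collapse = ", "))
  cells <- unique(raw$cell)
  genes <- unique(raw$gene)
  key <- paste(raw$cell, raw$gene, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (cell, gene) entry: ",
         sub("\r", " / ", key[duplicated(key)][1]))
  ct <- matrix(NA_real_, length(cells), length(genes),
               dimnames = list(cells, genes))
  failed <- matrix(TRUE, length(cells), length(genes), dimnames = dimnames(ct))
  where <- sprintf("row %d, column \"ct\"", seq_len(nrow(raw)) + 1L)
  p <- .parse_ct_tokens(raw$ct, na_tokens, where)
  idx <- cbind(match(raw$cell, cells), match(raw$gene, genes))
  ct[idx] <- p$ct
  failed[idx] <- p$failed
  meta <- NULL
  if (all(c("plate", "well", "group") %in% names(raw))) {
    first <- !duplicated(raw$cell)
    meta <- raw[first, c("plate", "well", "group"), drop = FALSE]
    meta <- meta[match(cells, raw$cell[first]), , drop = FALSE]
  }
  ct_matrix(ct, failed, meta)
}

#' Write a Ct table to CSV
#'
#' Inverse of [read_ct_csv()]: the written file round-trips losslessly in
#' Ct values, failed mask and metadata. Failed entries are written as the
#' token `"999"` in both dialects (so a long file has one row per
#' cell-gene pair).
#'
#' @param m A [ct_matrix()].
#' @param path Output path.
#' @param dialect `"wide"` or `"long"`.
#' @export
write_ct_csv <- function(m, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(m, "ct_matrix"))
  fmt <- function(ct, failed) {
    out <- sprintf("%.17g", ct)   # full double precision for lossless round-trip
    out[failed] <- "999"
    out
  }
  if (dialect == "wide") {
    df <- data.frame(cell = rownames(m$ct),
                     m$meta[, c("plate", "well", "group"), drop = FALSE],
                     stringsAsFactors = FALSE, check.names = FALSE)
    vals <- matrix(fmt(m$ct, m$failed), nrow(m$ct),
                   dimnames = dimnames(m$ct))
    df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  } else {
    genes <- colnames(m$ct)
    n <- nrow(m$ct)
    df <- data.frame(
      cell = rep(rownames(m$ct), times = length(genes)),
      plate = rep(m$meta$plate, times = length(genes)),
      well = rep(m$meta$well, times = length(genes)),
      group = rep(m$meta$group, times = length(genes)),
      gene = rep(genes, each = n),
      ct = as.vector(fmt(m$ct, m$failed)),
      stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(NULL)
}
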
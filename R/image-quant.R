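#' Read an RGB image file
#'
#' Reads a PNG or TIFF micrograph into an height x width x 3 array with
#' intensities on `[0, 1]` (8- and 16-bit images are auto-scaled by the
#' readers). An alpha channel, if present, is dropped; grayscale input is
#' rejected.
#'
#' @param path Image file (`.png`, `.tif`, `.tiff`).
#' @return Numeric array `h x w x 3`.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("image is not RGB: ", path)
  img
}

# 8-connected component labeling by iterative minimum-label propagation.
# Returns an integer matrix: 0 background, components numbered 1..n.
.label_components8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  pad <- function(m) {
    out <- matrix(Inf, nr + 2L, nc + 2L)
    out[2:(nr + 1L), 2:(nc + 1L)] <- ifelse(mask, m, Inf)
    out
  }
  repeat {
    p <- pad(lab)
    nb <- pmin(p[1:nr, 1:nc],       p[1:nr, 2:(nc + 1L)],       p[1:nr, 3:(nc + 2L)],
               p[2:(nr + 1L), 1:nc],                            p[2:(nr + 1L), 3:(nc + 2L)],
               p[3:(nr + 2L), 1:nc], p[3:(nr + 2L), 2:(nc + 1L)], p[3:(nr + 2L), 3:(nc + 2L)])
    new_lab <- lab
    upd <- mask & is.finite(nb) & nb < lab
    new_lab[upd] <- nb[upd]
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

#' Quantify immunofluorescent staining in one RGB image
#'
#' Implements stain-area-per-cell quantification: the image is split into
#' its RGB channels; the blue (DAPI) channel is binarized with an
#' automated image-specific threshold (Otsu's method by default); the red
#' and green stain channels are binarized at a fixed threshold (default
#' 0.30 on unit-scaled intensity, pixels strictly above count); nuclei are
#' 8-connected components of the DAPI mask strictly larger than
#' `min_nucleus_px` pixels; stain area is divided by the nucleus count to
#' give area per cell.
#'
#' @param img An `h x w x 3` array on `[0, 1]`, or a path readable by
#'   [read_rgb_image()].
#' @param stain_threshold Fixed binarization threshold for the red and
#'   green channels (default 0.3).
#' @param min_nucleus_px Nuclei must exceed this pixel count (strictly;
#'   default 15).
#' @param dapi_method `"otsu"` (automated, image-specific) or `"fixed"`
#'   (use `dapi_threshold`).
#' @param dapi_threshold Threshold for `dapi_method = "fixed"`.
#' @return An `image_quant_result` list: `nuclei_count`, per-channel
#'   `red`/`green` lists (`area_px`, `area_fraction`, `area_per_cell` —
#'   `NA` with a warning when no nuclei are found), and the thresholds
#'   used. `as.data.frame()` flattens it to one row.
#' @export
quantify_image <- function(img, stain_threshold = 0.3, min_nucleus_px = 15L,
                           dapi_method = c("otsu", "fixed"), dapi_threshold = NULL) {
  dapi_method <- match.arg(dapi_method)
  if (is.character(img)) img <- read_rgb_image(img)
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("`img` must be an RGB array (h x w x 3)")
  if (min(img) < 0 || max(img) > 1)
    stop("intensities must be scaled to [0, 1]")
  blue <- img[, , 3]
  dapi_thr <- if (dapi_method == "otsu") {
    if (length(unique(as.vector(blue))) > 1) EBImage::otsu(blue, range = c(0, 1)) else 0.5
  } else {
    if (is.null(dapi_threshold)) stop("`dapi_threshold` required for dapi_method = \"fixed\"")
    dapi_threshold
  }
  lab <- .label_components8(blue > dapi_thr)
  comp_sizes <- tabulate(lab[lab > 0L])
  nuclei <- sum(comp_sizes > min_nucleus_px)
  if (nuclei == 0) warning("no nuclei detected; area_per_cell undefined")
  total_px <- prod(dim(blue))
  channel <- function(ch) {
    area <- sum(img[, , ch] > stain_threshold)
    list(area_px = area, area_fraction = area / total_px,
         area_per_cell = if (nuclei > 0) area / nuclei else NA_real_)
  }
  structure(list(nuclei_count = nuclei,
                 red = channel(1L), green = channel(2L),
                 dapi_threshold = dapi_thr, dapi_method = dapi_method,
                 stain_threshold = stain_threshold,
                 min_nucleus_px = as.integer(min_nucleus_px)),
            class = "image_quant_result")
}

#' @export
print.image_quant_result <- function(x, ...) {
  cat(sprintf("<image_quant_result> %d nuclei (DAPI %s threshold %.3f, >%d px)\n",
              x$nuclei_count, x$dapi_method, x$dapi_threshold, x$min_nucleus_px))
  cat(sprintf("  red:   %d px (%.2f%%), %s px/cell\n", x$red$area_px,
              100 * x$red$area_fraction, format(x$red$area_per_cell)))
  cat(sprintf("  green: %d px (%.2f%%), %s px/cell\n", x$green$area_px,
              100 * x$green$area_fraction, format(x$green$area_per_cell)))
  invisible(x)
}

#' @export
as.data.frame.image_quant_result <- function(x, ...) {
  data.frame(nuclei_count = x$nuclei_count,
             red_area_px = x$red$area_px,
             red_area_fraction = x$red$area_fraction,
             red_area_per_cell = x$red$area_per_cell,
             green_area_px = x$green$area_px,
             green_area_fraction = x$green$area_fraction,
             green_area_per_cell = x$green$area_per_cell,
             dapi_threshold = x$dapi_threshold)
}

#' Quantify a folder of fluorescence micrographs
#'
#' Runs [quantify_image()] on every PNG/TIFF in a directory; unreadable
#' images are skipped with a warning. When a `groups` mapping is given,
#' per-group mean and SEM of each stain measure are summarized, mirroring
#' per-wound quantification averaged within experimental arms.
#'
#' @param dir Directory of images.
#' @param groups Optional named character vector mapping file name to
#'   group label.
#' @param ... Passed to [quantify_image()].
#' @return List with `images` (one row per image) and `summary`
#'   (per-group mean ± SEM per measure; `NULL` without `groups`).
#' @export
batch_quantify <- function(dir, groups = NULL, ...) {
  files <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  rows <- list()
  for (f in files) {
    res <- tryCatch(quantify_image(file.path(dir, f), ...),
                    error = function(e) {
                      warning("skipping unreadable image ", f, ": ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) rows[[f]] <- cbind(data.frame(file = f), as.data.frame(res))
  }
  images <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
            else data.frame(file = character())
  summary_df <- NULL
  if (!is.null(groups) && nrow(images) > 0) {
    images$group <- unname(groups[images$file])
    measures <- c("nuclei_count", "red_area_per_cell", "green_area_per_cell",
                  "red_area_fraction", "green_area_fraction")
    sem <- function(v) stats::sd(v) / sqrt(length(v))
    summary_df <- do.call(rbind, lapply(split(images, images$group), function(d) {
      out <- data.frame(group = d$group[1], n = nrow(d))
      for (msr in measures) {
        out[[paste0(msr, "_mean")]] <- mean(d[[msr]])
        out[[paste0(msr, "_sem")]] <- sem(d[[msr]])
      }
      out
    }))
    rownames(summary_df) <- NULL
  }
  list(images = images, summary = summary_df)
}
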
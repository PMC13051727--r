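#' Specification for a synthetic single-cell qPCR experiment
#'
#' Describes the generative model used for end-to-end validation. The
#' defaults emulate the design the pipeline targets: 384 cells in four
#' 96-well plates, a 96-gene panel, two groups splitting the plates
#' evenly, four latent subpopulations with distinct mean Ct profiles in
#' the first group — one completely missing and one strongly reduced in
#' the second group — gene-wise dropout (failed amplification), and
#' Gaussian Ct noise.
#'
#' Each cluster owns a disjoint block of `markers_per_cluster` marker
#' genes whose mean Ct sits `marker_shift` cycles below the gene baseline
#' (lower Ct = higher expression, so markers are overexpressed by
#' `2^marker_shift`-fold in their cluster).
#'
#' @param n_plates Number of 96-well plates (default 4).
#' @param wells_per_plate Wells per plate (default 96).
#' @param n_genes Genes on the panel (default 96).
#' @param n_clusters Latent subpopulations (default 4).
#' @param markers_per_cluster Marker genes owned by each cluster (default 8).
#' @param marker_shift Ct shift of a cluster's markers below baseline, in
#'   cycles = log2 units (default 4).
#' @param ct_sd Within-cluster Gaussian Ct standard deviation (default 1).
#' @param dropout Failed-amplification probability: a scalar, a per-gene
#'   vector, or an `n_clusters x n_genes` matrix for cluster-specific
#'   dropout (default 0.1).
#' @param baseline_ct Range from which per-gene baseline mean Ct values
#'   are drawn uniformly (default `c(18, 28)`).
#' @param groups Two group labels (default `c("WT", "eKO")`).
#' @param prop_a,prop_b Cluster mixing proportions per group (must each
#'   sum to 1). Defaults plant cluster 2 absent (`prop_b[2] = 0`) and
#'   cluster 3 depleted in the second group.
#' @param gene_names Optional panel gene symbols (length `n_genes`).
#' @param seed Integer RNG seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_plates = 4L, wells_per_plate = 96L, n_genes = 96L,
                           n_clusters = 4L, markers_per_cluster = 8L,
                           marker_shift = 4, ct_sd = 1, dropout = 0.1,
                           baseline_ct = c(18, 28),
                           groups = c("WT", "eKO"),
                           prop_a = c(0.30, 0.25, 0.25, 0.20),
                           prop_b = c(0.45, 0.00, 0.10, 0.45),
                           gene_names = NULL, seed = 1L) {
  if (length(groups) != 2) stop("exactly two group labels are required")
  if (length(prop_a) != n_clusters || length(prop_b) != n_clusters)
    stop("proportions must have one entry per cluster")
  for (p in list(prop_a, prop_b)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("per-group cluster proportions must be non-negative and sum to 1")
  }
  if (any(dropout < 0) || any(dropout > 1)) stop("dropout must lie in [0, 1]")
  if (n_clusters * markers_per_cluster > n_genes)
    stop("marker blocks exceed the gene panel")
  if (is.null(gene_names)) gene_names <- sprintf("G%03d", seq_len(n_genes))
  if (length(gene_names) != n_genes) stop("`gene_names` must have length n_genes")
  structure(list(n_plates = as.integer(n_plates),
                 wells_per_plate = as.integer(wells_per_plate),
                 n_genes = as.integer(n_genes), n_clusters = as.integer(n_clusters),
                 markers_per_cluster = as.integer(markers_per_cluster),
                 marker_shift = marker_shift, ct_sd = ct_sd, dropout = dropout,
                 baseline_ct = baseline_ct, groups = groups,
                 prop_a = prop_a, prop_b = prop_b,
                 gene_names = gene_names, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic Ct matrix with ground truth
#'
#' Draws each cell's Ct for each gene from a Normal distribution with the
#' cell's cluster-specific mean and `ct_sd`, independently masks entries
#' failed with the gene's dropout probability, and assigns cells to
#' plates/wells sequentially in sort order (group A fills the first
#' plates). Bit-reproducible given the seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return List with `ct` (a [ct_matrix()]) and `truth`: `cells` (data
#'   frame cell, group, plate, well, cluster), `genes` (data frame gene,
#'   marker_of: owning cluster or `NA` for background), `cluster_means`
#'   (n_clusters x n_genes mean Ct matrix).
#' @export
generate_ct <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_cells <- spec$n_plates * spec$wells_per_plate
  n_a <- floor(n_cells / 2)
  n_b <- n_cells - n_a
  baseline <- stats::runif(spec$n_genes, spec$baseline_ct[1], spec$baseline_ct[2])
  marker_of <- rep(NA_integer_, spec$n_genes)
  means <- matrix(rep(baseline, each = spec$n_clusters), spec$n_clusters, spec$n_genes)
  for (j in seq_len(spec$n_clusters)) {
    block <- ((j - 1) * spec$markers_per_cluster + 1):(j * spec$markers_per_cluster)
    marker_of[block] <- j
    means[j, block] <- means[j, block] - spec$marker_shift
  }
  cl_a <- sample.int(spec$n_clusters, n_a, replace = TRUE, prob = spec$prop_a)
  cl_b <- sample.int(spec$n_clusters, n_b, replace = TRUE, prob = spec$prop_b)
  clusters <- c(cl_a, cl_b)
  group <- rep(spec$groups, c(n_a, n_b))
  ct <- means[clusters, , drop = FALSE] +
    matrix(stats::rnorm(n_cells * spec$n_genes, 0, spec$ct_sd), n_cells, spec$n_genes)
  drop_p <- if (is.matrix(spec$dropout)) spec$dropout[clusters, , drop = FALSE]
            else matrix(spec$dropout, n_cells, spec$n_genes, byrow = TRUE)
  failed <- matrix(stats::runif(n_cells * spec$n_genes), n_cells, spec$n_genes) < drop_p
  ct[failed] <- NA_real_
  cells <- sprintf("cell%03d", seq_len(n_cells))
  dimnames(ct) <- list(cells, spec$gene_names)
  dimnames(failed) <- dimnames(ct)
  meta <- data.frame(
    plate = sprintf("P%d", ceiling(seq_len(n_cells) / spec$wells_per_plate)),
    well = sprintf("W%02d", ((seq_len(n_cells) - 1) %% spec$wells_per_plate) + 1L),
    group = group, stringsAsFactors = FALSE)
  truth <- list(
    cells = data.frame(cell = cells, group = group, plate = meta$plate,
                       well = meta$well, cluster = clusters,
                       stringsAsFactors = FALSE),
    genes = data.frame(gene = spec$gene_names, marker_of = marker_of,
                       stringsAsFactors = FALSE),
    cluster_means = means)
  list(ct = ct_matrix(ct, failed, meta), truth = truth)
}

#' Generate a ground-truthed synthetic fluorescence image
#'
#' Draws non-overlapping blue (DAPI) disks on a black canvas, paints
#' axis-aligned stain rectangles on the red/green channels, adds optional
#' Gaussian noise and clips to `[0, 1]`. A pixel belongs to a disk of
#' radius r when its squared center distance is at most r^2 (a radius-4
#' disk covers 49 pixels, radius 2 covers 13).
#'
#' @param width,height Canvas size in pixels.
#' @param n_nuclei Number of blue disks.
#' @param nucleus_radius Disk radius in pixels (scalar or per-nucleus).
#' @param stain_boxes List of boxes: each
#'   `list(channel = "red"|"green", x, y, w, h, intensity)` with `(x, y)`
#'   the top-left pixel (1-based).
#' @param noise_sd Gaussian noise SD added to every channel (default 0).
#' @param nucleus_intensity Disk intensity on the blue channel (default 0.9).
#' @param seed Integer RNG seed.
#' @param max_tries Placement retries before giving up (packing too tight).
#' @return List with `img` (`h x w x 3` array) and `truth` (`nuclei`
#'   data frame row, col, radius, area_px; `boxes` the input list).
#' @export
generate_image <- function(width = 128L, height = 128L, n_nuclei = 5L,
                           nucleus_radius = 4L, stain_boxes = list(),
                           noise_sd = 0, nucleus_intensity = 0.9,
                           seed = 1L, max_tries = 2000L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  radius <- rep_len(nucleus_radius, max(n_nuclei, 1L))
  img <- array(0, c(height, width, 3))
  centers <- matrix(NA_real_, 0, 2)
  placed_r <- numeric(0)
  tries <- 0L
  while (nrow(centers) < n_nuclei) {
    tries <- tries + 1L
    if (tries > max_tries) stop("could not place nuclei without overlap; canvas too small")
    r <- radius[nrow(centers) + 1L]
    cand <- c(sample((r + 1):(height - r), 1), sample((r + 1):(width - r), 1))
    # keep disks separated so 8-connected components never merge
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) > (placed_r + r + 2))) {
      centers <- rbind(centers, cand)
      placed_r <- c(placed_r, r)
    }
  }
  area_px <- integer(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    rr <- placed_r[i]
    rows <- (centers[i, 1] - rr):(centers[i, 1] + rr)
    cols <- (centers[i, 2] - rr):(centers[i, 2] + rr)
    d2 <- outer((rows - centers[i, 1])^2, (cols - centers[i, 2])^2, "+")
    inside <- d2 <= rr^2
    area_px[i] <- sum(inside)
    img[, , 3][cbind(rep(rows, times = length(cols))[inside],
                     rep(cols, each = length(rows))[inside])] <- nucleus_intensity
  }
  ch_index <- c(red = 1L, green = 2L)
  for (b in stain_boxes) {
    ch <- ch_index[[b$channel]]
    img[b$y:(b$y + b$h - 1L), b$x:(b$x + b$w - 1L), ch] <- b$intensity
  }
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
    img <- pmin(pmax(img, 0), 1)
  }
  truth <- list(nuclei = if (nrow(centers)) data.frame(row = centers[, 1],
                                                       col = centers[, 2],
                                                       radius = placed_r,
                                                       area_px = area_px)
                         else data.frame(row = numeric(), col = numeric(),
                                         radius = numeric(), area_px = integer()),
                boxes = stain_boxes)
  list(img = img, truth = truth)
}

#' Generate a synthetic caliper measurement table
#'
#' Simulates logistic tumor growth measured by calipers every other day:
#' per-subject volume follows `v_max / (1 + exp(-rate * (t - t_mid)))`,
#' converted to equal caliper dimensions `L = W = H = (2V)^(1/3)` with
#' multiplicative log-normal noise; the explant mass on the final day is
#' consistent with `density_target` (up to the same noise).
#'
#' @param n_subjects Number of subjects.
#' @param days Measurement days (default every 2 days to day 28).
#' @param v_max Plateau volume in cm^3.
#' @param rate Logistic growth rate per day.
#' @param t_mid Inflection day.
#' @param noise_sd SD of the log-normal measurement noise (0 = exact).
#' @param density_target Target density in g/cm^3 for the explant mass.
#' @param seed Integer RNG seed.
#' @return Data frame: subject, day, L, W, H (cm), mass (g; `NA` except
#'   on the final, explant day).
#' @export
generate_tumor_table <- function(n_subjects = 5L, days = seq(0, 28, by = 2),
                                 v_max = 1.5, rate = 0.3, t_mid = 14,
                                 noise_sd = 0.05, density_target = 1.0,
                                 seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- list()
  for (s in seq_len(n_subjects)) {
    v <- v_max / (1 + exp(-rate * (days - t_mid)))
    dim_cm <- (2 * v)^(1 / 3) * exp(stats::rnorm(length(days), 0, noise_sd))
    mass <- rep(NA_real_, length(days))
    # explant mass carries its own measurement noise, independent of the calipers
    mass[length(days)] <- density_target * v[length(days)] *
      exp(stats::rnorm(1, 0, noise_sd))
    out[[s]] <- data.frame(subject = sprintf("S%02d", s), day = days,
                           L = dim_cm, W = dim_cm, H = dim_cm, mass = mass,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
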
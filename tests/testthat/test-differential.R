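test_that("K-S statistic handles identical, disjoint and interleaved samples", {
  expect_equal(ks_two_sample(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))$D, 1)
  expect_warning(r <- ks_two_sample(c(1, 3, 5, 7), c(2, 4, 6, 8)), "fewer than 5")
  expect_equal(r$D, 0.25)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("K-S D matches the ECDF-sweep oracle to 1e-12 on random samples", {
  set.seed(41)
  for (rep in 1:50) {
    x <- rnorm(sample(5:15, 1))
    y <- rnorm(sample(5:15, 1), sample(c(0, 1), 1))
    expect_equal(ks_two_sample(x, y)$D, oracle_ks_D(x, y), tolerance = 1e-12)
  }
  # and agrees with the reference implementation's statistic
  for (rep in 1:20) {
    x <- rnorm(20); y <- rnorm(25, 0.5)
    expect_equal(ks_two_sample(x, y)$D,
                 unname(suppressWarnings(ks.test(x, y))$statistic), tolerance = 1e-12)
  }
})

test_that("heavy flooring ties keep D in [0,1] and p in (0,1]", {
  set.seed(42)
  for (rep in 1:20) {
    x <- c(rep(-5, sample(5:25, 1)), rnorm(10))
    y <- c(rep(-5, sample(5:25, 1)), rnorm(10, 1))
    r <- ks_two_sample(x, y)
    expect_true(r$D >= 0 && r$D <= 1)
    expect_true(r$p > 0 && r$p <= 1)
    expect_equal(r$D, oracle_ks_D(x, y), tolerance = 1e-12)
  }
})

make_marked_expr <- function(n_focal = 30, n_rest = 60, n_genes = 10,
                             shift = 4, seed = 1) {
  set.seed(seed)
  n <- n_focal + n_rest
  x <- matrix(rnorm(n * n_genes), n, n_genes,
              dimnames = list(paste0("c", 1:n), paste0("g", 1:n_genes)))
  x[seq_len(n_focal), 1] <- x[seq_len(n_focal), 1] + shift  # g1 is the marker
  meta <- data.frame(cell = rownames(x), plate = "P1", well = "W1",
                     group = rep(c("A", "B"), c(n_focal, n_rest)))
  structure(list(expr = x, nonexpresser = matrix(FALSE, n, n_genes),
                 meta = meta, bound = 5), class = "expression_matrix")
}

test_that("cluster-vs-rest flags a planted marker and respects Bonferroni bookkeeping", {
  e <- make_marked_expr()
  model <- kmeans_partition(e, 2, seed = 1, n_init = 10)
  focal <- as.integer(names(which.max(table(model$assignment[1:30]))))
  r <- cluster_vs_rest(e, model, focal)
  expect_s3_class(r, "diff_result")
  expect_true(r$significant[r$gene == "g1"])
  expect_equal(r$direction[r$gene == "g1"], 1)
  expect_true(all(r$p_bonf >= r$p_raw))
  expect_true(all(r$p_bonf[r$significant] < 0.05))
  expect_equal(attr(r, "m"), 10)
  expect_equal(attr(cluster_vs_rest(e, model, focal, m_scope = "genes_by_clusters"), "m"), 20)
  r0 <- cluster_vs_rest(e, model, focal, alpha = 0)
  expect_false(any(r0$significant))
  one <- structure(list(k = 1L, assignment = setNames(rep(1L, 90), rownames(e$expr))),
                   class = "cluster_model")
  expect_error(cluster_vs_rest(e, one, 1), "covers all cells")
})

test_that("identical groups yield no significant genes; label swap flips direction only", {
  set.seed(44)
  x <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(paste0("c", 1:60), paste0("g", 1:8)))
  e <- structure(list(expr = x, nonexpresser = matrix(FALSE, 60, 8),
                      meta = data.frame(cell = rownames(x), plate = "P1", well = "W",
                                        group = rep(c("WT", "eKO"), each = 30)),
                      bound = 5), class = "expression_matrix")
  r <- group_vs_group(e)
  expect_false(any(r$significant))
  swapped <- group_vs_group(e, groups = ifelse(e$meta$group == "WT", "eKO", "WT"))
  expect_equal(r$D, swapped$D)
  expect_equal(r$p_raw, swapped$p_raw)
  nz <- r$direction != 0
  expect_equal(r$direction[nz], -swapped$direction[nz])
  expect_error(group_vs_group(e, groups = rep(c("a", "b", "c"), 20)), "pairwise")
})

test_that("genes overexpressed by a group-specific cluster are detected group-vs-group", {
  # cluster 2 (~25% of WT cells, markers G009..G016) is absent from eKO, so its
  # markers shift the WT distribution upward; per-gene power after Bonferroni
  # is moderate at this subpopulation size, so aggregate calls over seeds.
  sig <- total <- 0
  for (s in 51:55) {
    sim <- generate_ct(synthetic_spec(seed = s))
    e <- pooled_median_normalize(sim$ct)
    r <- group_vs_group(e)   # WT vs eKO
    markers2 <- sim$truth$genes$gene[which(sim$truth$genes$marker_of == 2)]
    hit <- r$gene %in% markers2
    sig <- sig + sum(r$significant[hit])
    total <- total + sum(hit)
    expect_true(all(r$direction[hit & r$significant] > 0))
  }
  expect_gte(sig / total, 0.5)
})

test_that("seed-gene export writes exactly the significant genes and round-trips", {
  e <- make_marked_expr(shift = 5, seed = 2)
  r <- group_vs_group(e, groups = e$meta$group)
  f <- withr::local_tempfile(fileext = ".csv")
  export_seed_genes(r, f)
  back <- read.csv(f)
  expect_equal(nrow(back), sum(r$significant))
  expect_setequal(back$gene, r$gene[r$significant])
  # no significant genes -> header-only file
  r0 <- r
  r0$significant <- FALSE
  export_seed_genes(r0, f)
  expect_equal(nrow(read.csv(f)), 0)
})
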
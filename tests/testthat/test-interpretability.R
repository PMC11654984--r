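# Shapley attribution: exact small-model oracles, estimator properties, and
# peak-to-gene interval mapping.

test_that("sampling Shapley matches the exact enumeration on a 3-feature model", {
  # nonlinear but exactly solvable by 2^3 enumeration
  f <- function(m) m[, 1] * 2 + m[, 2] * m[, 3] - 0.5 * m[, 2]
  x <- c(1, 2, 3)
  b <- c(0, 0, 0)
  exact <- oracle_shapley(f, x, matrix(b, 1))
  got <- sampling_shapley(f, x, matrix(b, 1), n_perm = 400, seed = 1)
  expect_equal(as.vector(got$phi), exact, tolerance = 0.05)
  # local accuracy holds exactly for a single-row background
  expect_equal(sum(got$phi), f(matrix(x, 1)) - f(matrix(b, 1)),
               tolerance = 1e-12)
})

test_that("Shapley values of a linear model equal weight times offset", {
  w <- c(0.5, -2, 1, 3)
  f <- function(m) m %*% w
  x <- c(1, 1, 1, 1)
  bg <- matrix(rnorm(40, sd = 0.3), 10, 4)
  got <- sampling_shapley(f, x, bg, n_perm = 200, seed = 2)
  want <- w * (x - colMeans(bg))
  expect_equal(as.vector(got$phi), as.vector(want), tolerance = 0.15)
})

test_that("the estimator is seeded and converges with more permutations", {
  f <- function(m) m[, 1]^2 + m[, 2]
  x <- c(2, 1)
  bg <- matrix(rnorm(20), 10, 2)
  a <- sampling_shapley(f, x, bg, n_perm = 50, seed = 7)
  b <- sampling_shapley(f, x, bg, n_perm = 50, seed = 7)
  expect_identical(a$phi, b$phi)
  exact_mean <- mean(apply(bg, 1, function(r)
    oracle_shapley(function(m) m[, 1]^2 + m[, 2], x, matrix(r, 1))[1]))
  big <- sampling_shapley(f, x, bg, n_perm = 800, seed = 8)
  expect_equal(big$phi[1, 1], exact_mean, tolerance = 0.1)
})

test_that("a constant model attributes nothing", {
  f <- function(m) rep(1, nrow(m))
  got <- sampling_shapley(f, c(1, 2, 3), matrix(0, 2, 3), n_perm = 20, seed = 3)
  expect_equal(as.vector(got$phi), rep(0, 3))
})

local_attr_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simulation_config(n_cells = 240, n_types = 3,
                             type_proportions = c(0.4, 0.35, 0.25),
                             n_rna = 30, n_atac = 30, n_markers_per_type = 5,
                             marker_fold_change = 6, seed = 91)
    sim <- generate_paired_dataset(cfg)
    ds <- suppressWarnings(normalize_counts(sim$dataset))
    mc <- model_config(30, 30, 3, modality_embed_dim = 10, cell_embed_dim = 6,
                       enc_hidden = 16, cell_hidden = 12, dec_hidden = 12,
                       dis_hidden = c(8, 8), seed = 15)
    fit <- train_scmomtf(ds, mc, train_config(epochs = 120, batch_size = 32,
                                              seed = 16))
    cache <<- list(ds = ds, state = fit$state, gt = sim$ground_truth)
    cache
  }
})

test_that("attribution tables rank planted markers at the top for their type", {
  m <- local_attr_model()
  tabs <- attribute_features(m$state, m$ds, task = "classification",
                             background_size = 40, n_cells_per_type = 8,
                             seed = 21)
  expect_named(tabs, c("modality_1", "modality_2"))
  rna <- tabs$modality_1
  expect_equal(dim(rna$scores), c(30, 3))
  expect_true(all(rna$normalized_scores >= 0 & rna$normalized_scores <= 1))
  # min-max contract on a non-constant table
  expect_equal(min(rna$normalized_scores), 0)
  expect_equal(max(rna$normalized_scores), 1)
  hits <- vapply(paste0("type_", 1:3), function(ty) {
    top <- rank_markers(rna, ty, top_k = 5)$feature
    mean(top %in% m$gt$marker_features_of_type[[ty]]$RNA)
  }, 0)
  expect_gt(mean(hits), 0.7)
})

test_that("attribution is reproducible per seed", {
  m <- local_attr_model()
  args <- list(m$state, m$ds, task = "classification", background_size = 10,
               n_samples = 200, n_cells_per_type = 2, seed = 33)
  a <- do.call(attribute_features, args)
  b <- do.call(attribute_features, args)
  expect_identical(a$modality_1$scores, b$modality_1$scores)
})

test_that("dimension-reduction attributions also surface the planted markers", {
  m <- local_attr_model()
  tabs <- attribute_features(m$state, m$ds, task = "dimension_reduction",
                             background_size = 30, n_cells_per_type = 5,
                             seed = 22)
  rna <- tabs$modality_1
  expect_equal(rna$task, "dimension_reduction")
  all_markers <- unlist(lapply(m$gt$marker_features_of_type, `[[`, "RNA"))
  top10 <- rank_markers(rna, "type_1", top_k = 10)$feature
  expect_gt(mean(top10 %in% all_markers), 0.5)
})

test_that("undersized sampling budgets are increased with a warning", {
  m <- local_attr_model()
  expect_warning(
    attribute_features(m$state, m$ds, background_size = 5, n_samples = 10,
                       n_cells_per_type = 1, seed = 1),
    "increasing")
})

test_that("rank_markers orders by score with lexicographic tie-breaks", {
  tab <- structure(list(
    scores = matrix(c(0, 2, 2, 1), 4, 1, dimnames = list(NULL, "t")),
    normalized_scores = matrix(c(0, 1, 1, 0.5), 4, 1,
                               dimnames = list(NULL, "t")),
    feature_ids = c("d", "c", "a", "b"), modality = "RNA",
    task = "classification", classes = "t"), class = "attribution_table")
  got <- rank_markers(tab, "t", top_k = 3)
  expect_equal(got$feature, c("a", "c", "b"))
  expect_equal(rank_markers(tab, "t", top_k = 99)$feature, c("a", "c", "b", "d"))
  expect_error(rank_markers(tab, "zz", 3), "unknown cell type")
  # single nonzero feature normalizes to exactly 1 at rank 1
  one <- attribute_normalize_helper <- matrix(c(0, 0, 3), 3, 1,
                                              dimnames = list(NULL, "t"))
  rng <- range(one)
  norm <- (one - rng[1]) / diff(rng)
  expect_equal(unname(norm[3, 1]), 1)
})

test_that("peaks map to genes through strand-aware promoter windows", {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr2", "chr1"),
    start = c(150, 100, 1000),
    end = c(500, 200, 2000),
    strand = c("+", "+", "+"),
    stringsAsFactors = FALSE)
  got <- map_peaks_to_genes(c("chr1:100-200", "chr1:0-50", "chr3:5-10"),
                            genes, window = 2000)
  expect_equal(got[["chr1:100-200"]], c("gA", "gC"))  # direct + promoter
  expect_equal(got[["chr1:0-50"]], c("gA", "gC"))     # promoter windows
  expect_equal(got[["chr3:5-10"]], character(0))
  # different chromosome never maps
  got2 <- map_peaks_to_genes("chr1:100-200", genes[2, ], window = 0)
  expect_equal(got2[[1]], character(0))
  # without the window, upstream peaks stop mapping
  got3 <- map_peaks_to_genes("chr1:0-50", genes, window = 0)
  expect_equal(got3[[1]], character(0))
  # minus-strand promoter extends downstream of the interval end
  gm <- data.frame(gene_id = "gM", chrom = "chr1", start = 100, end = 200,
                   strand = "-", stringsAsFactors = FALSE)
  expect_equal(map_peaks_to_genes("chr1:300-400", gm, window = 2000)[[1]], "gM")
  expect_equal(map_peaks_to_genes("chr1:300-400", gm, window = 50)[[1]],
               character(0))
  expect_error(map_peaks_to_genes("chr1:abc", genes), "malformed")
})

test_that("gene annotations load from BED6", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "genes.bed")
  writeLines(c("chr1\t100\t500\tgA\t0\t+", "chr2\t0\t50\tgB\t0\t-"), bed)
  ann <- read_gene_annotation(bed)
  expect_equal(ann$gene_id, c("gA", "gB"))
  expect_equal(ann$start, c(100, 0))
  got <- map_peaks_to_genes("chr1:120-130", bed, window = 0)
  expect_equal(got[[1]], "gA")
})
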
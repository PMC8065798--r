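cfg_fast <- function(seed = 1L, ...) clustering_config(seed = seed, ...)

test_that("k-means closed-form cases: singleton clusters and the global centroid", {
  set.seed(42)
  pts <- matrix(rnorm(12), 6, 2)
  rownames(pts) <- paste0("p", 1:6)

  all_k <- km_cluster(pts, k = 6, cfg_fast())
  expect_equal(all_k$within_cost, 0)

  one <- km_cluster(pts, k = 1, cfg_fast())
  expect_equal(unname(one$centers[1, ]), colMeans(pts))
  expect_equal(one$within_cost,
               mean(sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2))))

  expect_error(km_cluster(pts[c(1, 1, 2), ], k = 3, cfg_fast()),
               "distinct points")
})

test_that("small-sample solutions attain the exhaustive-partition optimum", {
  ## two well-separated triads, k = 2: recovered partition is the optimum
  triads <- rbind(matrix(rnorm(6, 0, 0.1), 3, 2),
                  matrix(rnorm(6, 10, 0.1), 3, 2))
  rownames(triads) <- paste0("t", 1:6)
  sol <- km_cluster(triads, 2, cfg_fast(seed = 3))
  expect_equal(sol$within_cost, exhaustive_kmeans_cost(triads, 2),
               tolerance = 1e-10)
  expect_equal(length(unique(sol$assignment[1:3])), 1L)
  expect_equal(length(unique(sol$assignment[4:6])), 1L)

  for (seed in 1:3) {
    set.seed(seed)
    pts <- matrix(runif(16), 8, 2)
    rownames(pts) <- paste0("p", 1:8)
    for (k in 2:3) {
      sol <- km_cluster(pts, k, cfg_fast(seed = seed, n_restarts = 25L))
      expect_equal(sol$within_cost, exhaustive_kmeans_cost(pts, k),
                   tolerance = 1e-10,
                   label = sprintf("seed %d k %d", seed, k))
    }
  }
})

test_that("every point is assigned to its nearest center, ties to the lowest label", {
  set.seed(7)
  pts <- matrix(rnorm(40), 20, 2)
  rownames(pts) <- paste0("p", 1:20)
  sol <- km_cluster(pts, 3, cfg_fast(seed = 7))
  D <- mcakm:::dist_to_centers(pts, sol$centers)
  expect_equal(unname(sol$assignment),
               unname(apply(D, 1, which.min)))
})

test_that("the Lloyd objective is non-increasing across iterations", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- matrix(rnorm(60), 30, 2)
    rownames(pts) <- paste0("p", 1:30)
    sol <- km_cluster(pts, 4, cfg_fast(seed = seed, n_restarts = 1L))
    expect_true(all(diff(sol$iter_costs) <= 1e-12))
  }
})

test_that("k-means matches the reference implementation on easy geometry", {
  b <- generate_blobs(3, n_per = 20, seed = 44)
  sol <- km_cluster(b$points, 3, cfg_fast(seed = 44, metric = "squared"))
  ref <- kmeans(b$points, 3, nstart = 10)
  ## same partition up to label renaming
  expect_equal(ari(sol$assignment, ref$cluster), 1)
  expect_equal(sol$within_cost, ref$tot.withinss / nrow(b$points),
               tolerance = 1e-8)
})

test_that("folds cover every point exactly once with near-equal sizes", {
  f <- make_folds(23, 5, seed = 2)
  expect_length(f, 23L)
  expect_setequal(unique(f), 1:5)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  ## leave-one-out
  f1 <- make_folds(8, 8, seed = 2)
  expect_true(all(table(f1) == 1L))
  expect_identical(make_folds(23, 5, seed = 2), f)
})

test_that("cross-validated cost approximates the within-cost on duplicated data", {
  b <- generate_blobs(3, n_per = 10, seed = 5)
  dup <- rbind(b$points, b$points)
  rownames(dup) <- paste0("d", seq_len(nrow(dup)))
  cfg <- cfg_fast(seed = 5)
  sol <- km_cluster(dup, 3, cfg)
  vc <- vfold_cost(dup, 3, cfg)
  expect_lt(abs(vc$cv_cost - sol$within_cost),
            0.1 * max(sol$within_cost, 1e-12) + 1e-6)
  expect_equal(vc$cv_cost, mean(vc$fold_costs))
})

test_that("matching k on separated blobs halves the cross-validated cost", {
  b <- generate_blobs(3, n_per = 20, seed = 6)
  cfg <- cfg_fast(seed = 6)
  folds <- make_folds(nrow(b$points), cfg$v, cfg$seed)
  c2 <- vfold_cost(b$points, 2, cfg, folds = folds)$cv_cost
  c3 <- vfold_cost(b$points, 3, cfg, folds = folds)$cv_cost
  expect_lt(c3 / c2, 0.5)
})

test_that("an over-rich k against a thin training complement errors helpfully", {
  pts <- matrix(seq_len(12), 6, 2)
  rownames(pts) <- paste0("p", 1:6)
  expect_error(vfold_cost(pts, 5, cfg_fast(v = 3)), "smaller k or v")
})

test_that("the plateau rule selects the planted blob count and flat costs stop at k_min", {
  for (k_true in c(2, 5)) {
    b <- generate_blobs(k_true, n_per = 25, seed = 30 + k_true)
    sel <- select_k(b$points, cfg_fast(seed = 30 + k_true))
    expect_equal(sel$optimal_k, k_true)
    expect_false(sel$flagged)
  }
  ## a single tight cloud: costs below tolerance everywhere -> k_min
  set.seed(9)
  cloud <- matrix(rnorm(24, sd = 1e-3), 12, 2)
  rownames(cloud) <- paste0("p", 1:12)
  sel <- select_k(cloud, cfg_fast(seed = 9, k_max = 5))
  expect_equal(sel$optimal_k, 2L)
})

test_that("the fold-significance rule also recovers clear blob structure", {
  b <- generate_blobs(3, n_per = 25, seed = 77)
  sel <- select_k(b$points,
                  cfg_fast(seed = 77, selection_rule = "fold_significance"))
  expect_equal(sel$optimal_k, 3L)
})

test_that("selection is deterministic given the seed and records a full trace", {
  b <- generate_blobs(3, n_per = 15, seed = 12)
  s1 <- select_k(b$points, cfg_fast(seed = 12, k_max = 6))
  s2 <- select_k(b$points, cfg_fast(seed = 12, k_max = 6))
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$solutions[["3"]]$assignment,
                   s2$solutions[["3"]]$assignment)
  expect_equal(s1$trace$k, 2:6)
})

test_that("category classification renumbers clusters by first appearance and co-clusters planted pairs", {
  spec <- cohort_spec(
    2000,
    list(cohort_variable("Anxiety", c("No", "Yes"), c(0.95, 0.05)),
         cohort_variable("Osteoporosis", c("No", "Yes"), c(0.95, 0.05)),
         cohort_variable("Sex", c("Female", "Male"), c(0.5, 0.5))),
    blocks = list(planted_block(c("Anxiety=Yes", "Osteoporosis=Yes"), 1)),
    seed = 31L)
  fit <- mca_kmeans(generate_cohort(spec), k_min = 2, k_max = 4, seed = 31)
  cls <- fit$classification
  expect_equal(cls$cluster[cls$variable == "Anxiety" & cls$level == "Yes"],
               cls$cluster[cls$variable == "Osteoporosis" & cls$level == "Yes"])
  ## renumbering: first appearance order, sorted output
  expect_equal(min(cls$cluster), 1L)
  expect_true(all(diff(cls$cluster) >= 0))

  ## identical coordinates -> identical labels; k = 1 labels everything 1
  pts <- matrix(c(0, 0, 0, 0, 5, 5), 3, 2, byrow = TRUE)
  rownames(pts) <- c("a", "b", "c")
  sol1 <- km_cluster(pts, 1, cfg_fast())
  labs <- data.frame(variable = c("a", "b", "c"), level = "x")
  expect_true(all(classify_categories(sol1, labs)$cluster == 1L))
  sol2 <- km_cluster(pts, 2, cfg_fast())
  cc2 <- classify_categories(sol2, labs)
  expect_equal(cc2$cluster[cc2$variable == "a"],
               cc2$cluster[cc2$variable == "b"])
})
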
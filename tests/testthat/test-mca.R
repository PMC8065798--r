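test_that("indicator encoding expands every level with one active level per variable", {
  df <- table1_exact_df()
  X <- encode_indicator(df)
  expect_equal(ncol(X$values), 33L)           # 15 binary x 2 + CCI x 3
  expect_true(all(rowSums(X$values) == 16L))
  expect_equal(unname(colSums(X$values)[match("Sex=Male",
                                              colnames(X$values))]), 520)
  expect_equal(unname(colSums(X$values)[match("Depression=Yes",
                                              colnames(X$values))]), 25)

  tiny <- data.frame(A = factor(c("Yes", "No")))
  expect_equal(unname(encode_indicator(tiny)$values),
               matrix(c(0, 1, 1, 0), 2, 2))

  expect_error(encode_indicator(data.frame(A = factor(c("x", "x")),
                                           B = factor(c("u", "v")))),
               "variable 'A' has a single observed level")
  expect_error(encode_indicator(data.frame(A = factor(c("x", NA)))),
               "missing cells")
})

test_that("the Burt matrix is the indicator cross-product with contingency blocks", {
  ## complete 2x2 factorial: off-diagonal block is all ones
  df <- data.frame(A = factor(c("a1", "a1", "a2", "a2")),
                   B = factor(c("b1", "b2", "b1", "b2")))
  B <- build_burt(encode_indicator(df))
  expect_true(isSymmetric(B))
  expect_equal(unname(B[1:2, 3:4]), matrix(1, 2, 2))
  expect_equal(unname(diag(B)), c(2, 2, 2, 2))

  X <- encode_indicator(table1_exact_df())
  Bt <- build_burt(X)
  expect_equal(Bt, crossprod(X$values))
  expect_equal(unname(Bt["Sex=Male", "Sex=Male"]), 520)
  ## Burt trace equals the total of all column sums, I * K
  expect_equal(sum(diag(Bt)), 1022 * 16)
})

test_that("coordinates agree with an independent eigendecomposition oracle", {
  for (cfg in list(c(10, 3, 11), c(30, 4, 12), c(50, 5, 13))) {
    df <- random_categorical_table(cfg[1], cfg[2], seed = cfg[3])
    X <- encode_indicator(df)
    fit <- fit_mca(X)
    orc <- ca_eigen_oracle(X$values)
    nd <- length(fit$singular_values)
    expect_equal(fit$eigenvalues, orc$eigenvalues[seq_len(nd)],
                 tolerance = 1e-8)
    expect_lt(coord_diff_up_to_sign(fit$G, orc$G[, seq_len(nd), drop = FALSE]),
              1e-6)
    expect_lt(coord_diff_up_to_sign(fit$F, orc$F[, seq_len(nd), drop = FALSE]),
              1e-6)
  }
})

test_that("indicator-basis total inertia equals (J - K)/K on any table", {
  for (seed in 14:16) {
    df <- random_categorical_table(25, 4, seed = seed)
    X <- encode_indicator(df)
    J <- ncol(X$values); K <- ncol(df)
    expect_equal(fit_mca(X)$total_inertia, J / K - 1, tolerance = 1e-8)
  }
  Xt <- encode_indicator(table1_exact_df())
  expect_equal(fit_mca(Xt)$total_inertia, 33 / 16 - 1, tolerance = 1e-8)
  expect_equal(33 / 16 - 1, 1.0625)
})

test_that("Burt-basis eigenvalues are the squared indicator-basis eigenvalues", {
  df <- random_categorical_table(20, 3, seed = 17)
  X <- encode_indicator(df)
  ev_ind <- fit_mca(X, basis = "indicator")$eigenvalues
  ev_burt <- fit_mca(X, basis = "burt")$eigenvalues
  expect_equal(ev_burt, (ev_ind^2)[seq_along(ev_burt)], tolerance = 1e-8)
})

test_that("model invariants hold: ordering, centering, reconstruction", {
  df <- random_categorical_table(40, 5, seed = 18)
  X <- encode_indicator(df)
  fit <- fit_mca(X)
  expect_true(all(diff(fit$singular_values) <= 1e-12))
  expect_true(all(fit$singular_values >= 0))
  expect_equal(fit$eigenvalues, fit$singular_values^2, tolerance = 1e-10)
  ## mass centering of principal coordinates
  expect_lt(max(abs(crossprod(fit$c, fit$G))), 1e-8)
  expect_lt(max(abs(crossprod(fit$r, fit$F))), 1e-8)
  expect_equal(sum(fit$eigenvalues), fit$total_inertia, tolerance = 1e-8)
  ## SVD reconstruction of the standardized residual matrix
  P <- X$values / sum(X$values)
  S <- (P - outer(fit$r, fit$c)) / outer(sqrt(fit$r), sqrt(fit$c))
  U <- sweep(fit$F, 1L, sqrt(fit$r), `*`) %*%
    diag(1 / fit$singular_values, length(fit$singular_values))
  Q <- sweep(fit$G, 1L, sqrt(fit$c), `*`) %*%
    diag(1 / fit$singular_values, length(fit$singular_values))
  recon <- U %*% diag(fit$singular_values, nrow = ncol(U)) %*% t(Q)
  expect_lt(max(abs(S - recon)), 1e-8)
})

test_that("the barycentric transition relation links F and G", {
  df <- random_categorical_table(30, 4, seed = 19)
  X <- encode_indicator(df)
  fit <- fit_mca(X)
  P <- X$values / sum(X$values)
  G_from_F <- (t(P) %*% fit$F) / fit$c
  G_from_F <- sweep(G_from_F, 2L, fit$singular_values, `/`)
  expect_equal(unname(G_from_F), unname(fit$G), tolerance = 1e-8)
})

test_that("row permutation permutes F and leaves G unchanged (up to axis sign)", {
  ## axes whose largest |loading| is attained by two symmetric categories
  ## can flip orientation between runs, so compare with per-axis alignment
  df <- random_categorical_table(20, 3, seed = 20)
  fit <- fit_mca(encode_indicator(df))
  set.seed(1); perm <- sample.int(nrow(df))
  fitp <- fit_mca(encode_indicator(df[perm, , drop = FALSE]))
  flips <- vapply(seq_len(ncol(fit$G)), function(s) {
    if (max(abs(fitp$G[, s] - fit$G[, s])) <=
        max(abs(fitp$G[, s] + fit$G[, s]))) 1 else -1
  }, 0)
  expect_equal(unname(sweep(fitp$G, 2L, flips, `*`)), unname(fit$G),
               tolerance = 1e-8)
  expect_equal(unname(sweep(fitp$F, 2L, flips, `*`)),
               unname(fit$F[perm, ]), tolerance = 1e-8)
})

test_that("duplicated categories receive identical column coordinates", {
  df <- random_categorical_table(25, 2, seed = 21)
  df$V3 <- df$V1                       # duplicated variable
  fit <- fit_mca(encode_indicator(df))
  i1 <- which(fit$labels$variable == "V1")
  i3 <- which(fit$labels$variable == "V3")
  expect_equal(unname(fit$G[i1, ]), unname(fit$G[i3, ]), tolerance = 1e-8)
})

test_that("degenerate masses are rejected with the offending index named", {
  A <- rbind(c(1, 2), c(0, 0))
  expect_error(mcakm:::ca_decompose(A), "zero row mass")
  A2 <- cbind(c(1, 2), c(0, 0))
  expect_error(mcakm:::ca_decompose(A2), "zero column mass")
})

test_that("an exactly independent matrix has zero inertia and empty coordinates", {
  r <- c(0.2, 0.3, 0.5); cc <- c(0.25, 0.75)
  A <- outer(r, cc) * 400              # P = r c' exactly
  dec <- mcakm:::ca_decompose(A)
  expect_length(dec$singular_values, 0L)
  expect_equal(ncol(dec$F), 0L)
  expect_lt(dec$total_inertia, 1e-20)
})

test_that("inertia decomposes over axes and over points", {
  df <- random_categorical_table(30, 3, seed = 22)
  X <- encode_indicator(df)
  fit <- fit_mca(X)
  prof <- inertia_profile(fit)
  expect_equal(sum(prof$per_dimension$proportion), 1, tolerance = 1e-8)
  expect_true(all(diff(prof$per_dimension$cumulative) >= -1e-12))
  expect_equal(sum(prof$column_point_inertias), sum(fit$eigenvalues),
               tolerance = 1e-8)
  ## per-column inertias match a direct chi-squared decomposition
  expect_equal(unname(prof$column_point_inertias),
               unname(chi2_column_inertia(X$values)), tolerance = 1e-8)

  ## subsetting the axes
  prof1 <- inertia_profile(fit, subset_dims = 1L)
  expect_equal(sum(prof1$column_point_inertias), fit$eigenvalues[1],
               tolerance = 1e-8)
  expect_error(inertia_profile(fit, subset_dims = 999L))
})

test_that("dimension selection follows the cumulative-inertia rule", {
  fake <- structure(list(per_dimension = data.frame(
    dim = 1:2, eigenvalue = c(0.7, 0.3), proportion = c(0.7, 0.3),
    cumulative = c(0.7, 1.0))), class = "inertia_profile")
  expect_equal(select_dimensions(fake, threshold = 0.8), 2L)
  expect_equal(select_dimensions(fake, threshold = 0.7), 1L)
  expect_equal(select_dimensions(fake, threshold = 1.0), 2L)
  expect_equal(select_dimensions(fake, rule = "all"), 2L)

  ## planted-block cohort keeps at least 2 axes at the 0.8 threshold
  coh <- generate_cohort(table1_planted_spec(seed = 5L))
  fit <- fit_mca(encode_indicator(coh))
  expect_gte(select_dimensions(inertia_profile(fit), threshold = 0.8), 2L)
})
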
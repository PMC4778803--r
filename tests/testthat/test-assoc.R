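test_that("GLS with identity covariance reproduces lm() to 1e-10", {
  set.seed(101)
  n <- 200
  ids <- sprintf("s%03d", 1:n)
  x <- setNames(rbinom(n, 2, 0.3), ids)
  D <- setNames(rbinom(n, 1, 0.5), ids)
  y <- setNames(0.5 + 0.2 * x + 0.3 * D + 0.25 * D * x + rnorm(n), ids)
  res <- test_variant(y, x, D, model = "ols")
  ref <- summary(lm(y ~ D + x + x:D))$coefficients
  expect_equal(res$beta_snp, ref["x", 1], tolerance = 1e-10)
  expect_equal(res$gamma_gei, ref["D:x", 1], tolerance = 1e-10)
  expect_equal(res$se_snp, ref["x", 2], tolerance = 1e-10)
  expect_equal(res$p_snp, ref["x", 4], tolerance = 1e-10)
  expect_equal(res$p_gei, ref["D:x", 4], tolerance = 1e-10)
  expect_equal(res$delta_env, ref["D", 1], tolerance = 1e-10)

  # a mixed model whose covariance collapses to the identity matches OLS
  K <- diag(n); dimnames(K) <- list(ids, ids)
  vc <- fixed_components(c(genetic = 0, residual = 1), "genetic", ids)
  res2 <- test_variant(y, x, D, model = "one_re", vc = vc, K = K)
  expect_equal(res2$p_gei, res$p_gei, tolerance = 1e-10)
})

test_that("a six-sample design matches the hand-solvable normal equations", {
  ids <- letters[1:6]
  y <- setNames(c(1.2, 0.4, -0.3, 2.1, 1.0, 0.6), ids)
  x <- setNames(c(0, 1, 2, 1, 0, 2), ids)
  D <- setNames(c(0, 0, 0, 1, 1, 1), ids)
  X <- cbind(1, D, x, D * x)
  beta <- solve(crossprod(X), crossprod(X, y))   # direct 4x4 solve
  res <- test_variant(y, x, D, model = "ols")
  expect_equal(res$beta_snp, beta[3L], tolerance = 1e-12)
  expect_equal(res$gamma_gei, beta[4L], tolerance = 1e-12)
  expect_equal(res$delta_env, beta[2L], tolerance = 1e-12)
  rss <- sum((y - X %*% beta)^2)
  se_gei <- sqrt(rss / 2 * solve(crossprod(X))[4L, 4L])
  expect_equal(res$se_gei, se_gei, tolerance = 1e-12)
})

test_that("GEI p-values are uniform under a correctly specified two-RE null", {
  st <- make_structured_study(seed = 23, n_per_pop = 125, m = 10000)
  vc <- fixed_components(
    c(genetic = 0.4, gxe = 0.2, residual = 0.4), c("genetic", "gxe"),
    names(st$y))
  sc <- gxe_scan(st$G, st$y, st$D, model = "two_re", vc = vc,
                 K = st$K, KD = st$KD)
  expect_gt(stats::ks.test(sc$p_gei, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(sc$p_snp, "punif")$p.value, 0.01)
})

test_that("scan equals per-variant testing, tolerates monomorphic and missing variants", {
  st <- make_structured_study(seed = 24, n_per_pop = 40, m = 100)
  d <- st$G$dosages
  d[, 3] <- 2                                   # monomorphic
  d[cbind(c(5, 9), c(7, 7))] <- NA              # missing dosages
  G <- geno_matrix(d, st$G$variants)
  vc <- suppressWarnings(
    fit_reml(st$y, list(genetic = st$K, gxe = st$KD), D = st$D))
  sc <- gxe_scan(G, st$y, st$D, model = "two_re", vc = vc, K = st$K, KD = st$KD)
  rows <- lapply(seq_len(ncol(d)), function(j) {
    test_variant(st$y, d[, j], st$D, model = "two_re", vc = vc,
                 K = st$K, KD = st$KD, id = colnames(d)[j])
  })
  looped <- do.call(rbind, rows)
  for (col in c("beta_snp", "se_snp", "p_snp", "gamma_gei", "se_gei", "p_gei")) {
    expect_equal(sc[[col]], looped[[col]], tolerance = 1e-12, label = col)
  }
  expect_identical(sc$note[3L], "rank_deficient")
  expect_true(all(is.na(sc[3L, c("p_snp", "p_gei")])))
  expect_equal(sc$n[7L], 78)                    # complete-case for that variant

  # a variant carried only by exposed samples: X_r collinear with D*X_r
  x_only <- setNames(as.numeric(st$D == 1), names(st$D))
  one <- test_variant(st$y, x_only, st$D, model = "ols")
  expect_identical(one$note, "rank_deficient")
  expect_true(is.na(one$p_gei))
})

test_that("variant order only permutes output rows; sample order does not matter", {
  st <- make_structured_study(seed = 25, n_per_pop = 30, m = 40)
  sc <- gxe_scan(st$G, st$y, st$D, model = "ols")
  perm <- sample(ncol(st$G$dosages))
  sc_p <- gxe_scan(st$G[, perm], st$y, st$D, model = "ols")
  expect_equal(sc_p$p_gei, sc$p_gei[perm], tolerance = 1e-12)
  # shuffling sample rows of every input leaves statistics untouched
  sperm <- sample(rownames(st$G$dosages))
  sc_s <- gxe_scan(st$G[sperm, ], st$y[sperm], st$D[sperm], model = "ols")
  expect_equal(sc_s$p_gei, sc$p_gei, tolerance = 1e-12)
})

test_that("affine rescaling of the phenotype leaves p-values unchanged", {
  st <- make_structured_study(seed = 26, n_per_pop = 30, m = 50)
  vc <- fixed_components(c(genetic = 0.4, gxe = 0.2, residual = 0.4),
                         c("genetic", "gxe"), names(st$y))
  for (mod in c("ols", "two_re")) {
    a <- gxe_scan(st$G, st$y, st$D, model = mod, vc = vc, K = st$K, KD = st$KD)
    b <- gxe_scan(st$G, 2.5 * st$y - 7, st$D, model = mod, vc = vc,
                  K = st$K, KD = st$KD)
    expect_equal(b$p_gei, a$p_gei, tolerance = 1e-9)
    expect_equal(b$p_snp, a$p_snp, tolerance = 1e-9)
  }
})

test_that("two-RE with a zero GxE component reproduces one-RE p-values exactly", {
  st <- make_structured_study(seed = 27, n_per_pop = 30, m = 50)
  ids <- names(st$y)
  vc2 <- fixed_components(c(genetic = 0.5, gxe = 0, residual = 0.5),
                          c("genetic", "gxe"), ids)
  vc1 <- fixed_components(c(genetic = 0.5, residual = 0.5), "genetic", ids)
  a <- gxe_scan(st$G, st$y, st$D, model = "two_re", vc = vc2,
                K = st$K, KD = st$KD)
  b <- gxe_scan(st$G, st$y, st$D, model = "one_re", vc = vc1, K = st$K)
  expect_equal(a$p_snp, b$p_snp, tolerance = 1e-12)
  expect_equal(a$p_gei, b$p_gei, tolerance = 1e-12)
})

test_that("PC-by-environment covariates recover two-block structure and stay full rank", {
  # two populations of unequal size so the leading eigenvalue is simple
  blockK <- matrix(0, 8, 8)
  blockK[1:5, 1:5] <- 0.5
  blockK[6:8, 6:8] <- 0.5
  diag(blockK) <- 1
  ids <- paste0("s", 1:8)
  dimnames(blockK) <- list(ids, ids)
  D <- setNames(rep(c(1, 0), 4), ids)
  M <- pc_env_covariates(blockK, D, 2)
  pc1 <- M[, "PC1"]
  # PC1 of a block matrix is constant within blocks and separates them
  expect_equal(length(unique(round(pc1, 10))), 2L)
  expect_equal(pc1[1:5], rep(pc1[[1L]], 5), ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(pc1[[1L]], pc1[[6L]])))
  expect_equal(M[, "PC1xD"], pc1 * D, ignore_attr = TRUE)
  # constant exposure duplicates every product column: they must be dropped
  M1 <- pc_env_covariates(blockK, setNames(rep(1, 8), ids), 2)
  expect_lte(ncol(M1), 2L)
  expect_identical(ncol(pc_env_covariates(blockK, D, 0)), 0L)
  expect_error(pc_env_covariates(blockK, D, 8), "n = 8")
})

test_that("inflation factor honours its definitional identities", {
  stats_chi <- c(0.1, 0.4549364231, 2)
  p <- pchisq(stats_chi, 1, lower.tail = FALSE)
  expect_equal(inflation_factor(p), 1, tolerance = 1e-7)
  p2 <- pchisq(2 * stats_chi, 1, lower.tail = FALSE)
  expect_equal(inflation_factor(p2), 2, tolerance = 1e-7)
  set.seed(42)
  expect_equal(inflation_factor(runif(1e5)), 1, tolerance = 0.02)
  expect_error(inflation_factor(c(NA_real_, NA_real_)), "no valid")
  expect_equal(inflation_factor(c(p, NA)), 1, tolerance = 1e-7)
})

test_that("qq_data sorts deterministically with ties broken by id", {
  p <- c(0.5, 0.1, 0.5, 0.01)
  ids <- c("b", "c", "a", "d")
  q <- qq_data(p, ids)
  expect_identical(q$id, c("d", "c", "a", "b"))
  expect_equal(q$observed, sort(-log10(p), decreasing = TRUE))
  expect_equal(q$expected, -log10((1:4 - 0.5) / 4))
})
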
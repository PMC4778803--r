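# The REML oracle here evaluates the exact restricted likelihood as the
# multivariate-normal density of error contrasts A'y, with the total
# variance profiled out on a dense grid over the fraction simplex --
# entirely independent of the AI-REML implementation.

test_that("AI-REML optimum matches the dense-grid error-contrast oracle at n=12", {
  set.seed(42)
  n <- 12
  st <- make_structured_study(seed = 13, n_per_pop = 6, m = 120, fst = 0.2)
  K <- unclass(st$K); KD <- unclass(gxe_kinship(st$K, st$D))
  X <- cbind(1, st$D)
  y <- st$y
  fit <- suppressWarnings(
    fit_reml(y, list(genetic = st$K, gxe = gxe_kinship(st$K, st$D)), D = st$D,
             tol_loglik = 1e-10, tol_grad = 1e-6))
  Vs <- list(K, KD, diag(n))
  oracle <- grid_reml_oracle(y, X, Vs, step = 0.01)
  ll_at_fit <- reml_contrast_ll(y, X, Vs, fit$sigma2)
  # the fitted point must be at least as good as the best grid point
  expect_gte(ll_at_fit, oracle$ll - 1e-4)
  expect_lt(max(abs(fit$fractions - oracle$fractions)), 0.02)
})

test_that("rescaling the phenotype rescales components and preserves fractions", {
  st <- make_structured_study(seed = 14, n_per_pop = 50, m = 400)
  KD <- gxe_kinship(st$K, st$D)
  f1 <- fit_reml(st$y, list(genetic = st$K, gxe = KD), D = st$D)
  f2 <- fit_reml(3 * st$y, list(genetic = st$K, gxe = KD), D = st$D)
  expect_equal(f2$sigma2, 9 * f1$sigma2, tolerance = 1e-5)
  expect_equal(f2$fractions, f1$fractions, tolerance = 1e-6)
})

test_that("eigendecomposition and direct paths agree for a single kinship", {
  st <- make_structured_study(seed = 15, n_per_pop = 40, m = 300)
  fe <- fit_reml(st$y, st$K, D = st$D, method = "eigen")
  fd <- fit_reml(st$y, st$K, D = st$D, method = "direct")
  expect_equal(fe$sigma2, fd$sigma2, tolerance = 1e-6)
  expect_equal(fe$loglik, fd$loglik, tolerance = 1e-6)
  expect_error(fit_reml(st$y, list(st$K, gxe_kinship(st$K, st$D)),
                        D = st$D, method = "eigen"), "single kinship")
})

test_that("null phenotypes put the genetic fraction near the boundary", {
  # a compact panel gives the GRM visible eigenvalue spread, which is what
  # identifies sigma_g2 against sigma_e2 and concentrates the null estimate
  d <- make_geno(500, 200, seed = 16)
  K <- compute_grm(d)
  set.seed(17)
  fracs <- vapply(1:100, function(i) {
    y <- setNames(rnorm(500), rownames(K))
    suppressWarnings(fit_reml(y, K))$fractions[["genetic"]]
  }, numeric(1L))
  expect_gte(mean(fracs < 0.1), 0.95)
})

test_that("estimator recovers implanted GxE variance; spread grows with sigma_d2", {
  st <- make_structured_study(seed = 18, n_per_pop = 150, m = 1000, fst = 0.1)
  KD <- gxe_kinship(st$K, st$D)
  ests <- lapply(c(0.05, 0.2), function(sd2) {
    cfg <- sim_config(n_per_pop = 150, m_variants = 1000, fst = 0.1,
                      sigma_g2 = 0.4, sigma_d2 = sd2, sigma_e2 = 0.6 - sd2,
                      seed = 1)
    vapply(1:20, function(r) {
      y <- simulate_phenotype(st$K, KD, cfg, seed = 3000 + r)
      suppressWarnings(
        fit_reml(y, list(genetic = st$K, gxe = KD), D = st$D)
      )$fractions[["gxe"]]
    }, numeric(1L))
  })
  for (i in 1:2) {
    truth <- c(0.05, 0.2)[i]
    mc_se <- sd(ests[[i]]) / sqrt(20)
    expect_lt(abs(mean(ests[[i]]) - truth), 3 * mc_se)
  }
  expect_gt(sd(ests[[2]]), 0.6 * sd(ests[[1]]))
})

test_that("one-RE fits systematically overestimate the genetic fraction when GxE variance exists", {
  st <- make_structured_study(seed = 19, n_per_pop = 150, m = 1000, fst = 0.1)
  KD <- gxe_kinship(st$K, st$D)
  cfg <- sim_config(n_per_pop = 150, m_variants = 1000, fst = 0.1, seed = 1)
  fracs <- vapply(1:20, function(r) {
    y <- simulate_phenotype(st$K, KD, cfg, seed = 4000 + r)
    suppressWarnings(fit_reml(y, st$K, D = st$D))$fractions[["genetic"]]
  }, numeric(1L))
  expect_gt(median(fracs), 0.4)     # implanted genetic fraction was 0.4
  expect_gt(mean(fracs > 0.4), 0.7)
})

test_that("variance fractions normalise correctly and carry delta-method SEs", {
  ft <- gxelmm:::.fraction_table
  expect_equal(ft(c(0.4, 0.2, 0.4), diag(0, 3))$fraction, c(0.4, 0.2, 0.4))
  expect_equal(ft(c(2, 1, 1), diag(0, 3))$fraction, c(0.5, 0.25, 0.25))
  # two-component delta method against the hand derivation:
  # f1 = t1/(t1+t2); Var(f1) = (t2^2 v1 + t1^2 v2) / S^4 for diagonal cov
  t1 <- 0.7; t2 <- 0.3; v1 <- 0.04; v2 <- 0.01
  tab <- ft(c(t1, t2), diag(c(v1, v2)))
  S <- t1 + t2
  expect_equal(tab$fraction_se[1L], sqrt((t2^2 * v1 + t1^2 * v2) / S^4))
  expect_equal(tab$fraction_se[1L], tab$fraction_se[2L])
  expect_error(ft(c(0, 0), diag(0, 2)), "total variance")
})

test_that("fractions sum to one and the report round trips key numbers", {
  st <- make_structured_study(seed = 20, n_per_pop = 40, m = 300)
  fit <- suppressWarnings(
    fit_reml(st$y, list(genetic = st$K, gxe = gxe_kinship(st$K, st$D)),
             D = st$D))
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-10)
  expect_true(all(fit$sigma2 >= 0))
  path <- withr::local_tempfile(fileext = ".hsq")
  write_reml_report(fit, path)
  lines <- readLines(path)
  expect_match(lines[1L], "^Source")
  expect_length(grep("^V\\(", lines), 6L)   # three variances + three ratios
  tab <- variance_fractions(fit)
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-10)
})
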
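test_that("GRM formula reproduces the hand-computed single-variant case", {
  d <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "v1"))
  K <- compute_grm(d)
  # p = 0.5, standardized genotypes (x - 1)/sqrt(0.5)
  expect_equal(unclass(K)[, ], matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3,
                                      dimnames = dimnames(K)),
               ignore_attr = TRUE)
})

test_that("identical dosage rows yield identical GRM rows", {
  d <- make_geno(6, 80, seed = 3)
  d[2, ] <- d[1, ]
  K <- compute_grm(d)
  expect_equal(K[1, ], K[2, ], ignore_attr = TRUE)
  expect_equal(K[1, 1], K[1, 2])
  expect_equal(K, t(K), ignore_attr = TRUE)
})

test_that("GRM diagonal averages to 1 for unrelated individuals", {
  d <- make_geno(300, 3000, seed = 21)
  K <- compute_grm(d)
  dg <- diag(K)
  mc_se <- sd(dg) / sqrt(length(dg))
  expect_lt(abs(mean(dg) - 1), 3 * mc_se + 2 / nrow(d))
})

test_that("monomorphic variants are excluded and an all-monomorphic panel errors", {
  d <- cbind(v1 = c(0, 1, 2, 1), v2 = c(2, 2, 2, 2))
  rownames(d) <- paste0("s", 1:4)
  K <- compute_grm(d)
  expect_identical(attr(K, "n_variants"), 1L)
  expect_equal(unclass(K), unclass(compute_grm(d[, 1, drop = FALSE])),
               ignore_attr = TRUE)
  expect_error(compute_grm(d[, 2, drop = FALSE]), "polymorphic")
  # missing dosages are mean-imputed: contribute zero after centring
  d2 <- cbind(v1 = c(0, 1, 2, NA))
  rownames(d2) <- paste0("s", 1:4)
  K2 <- compute_grm(d2)
  expect_equal(K2[4, ], rep(0, 4), ignore_attr = TRUE)
})

test_that("binary GxE kinship masks exactly the differing-exposure pairs", {
  K <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unclass(gxe_kinship(K, c(a = 1, b = 1))), unclass(K),
               ignore_attr = TRUE)
  expect_equal(unclass(gxe_kinship(K, c(a = 1, b = 0))), diag(2),
               ignore_attr = TRUE)
  # label flip leaves K^D unchanged; applying the mask twice is a no-op
  st <- make_structured_study(seed = 7, n_per_pop = 25, m = 200)
  KD <- gxe_kinship(st$K, st$D)
  expect_equal(KD, gxe_kinship(st$K, 1 - st$D))
  expect_equal(KD, gxe_kinship(KD, st$D))
  expect_equal(diag(unclass(KD)), diag(unclass(st$K)))
  expect_error(gxe_kinship(K, c(a = 0.5, b = 1)), "not binary")
})

test_that("continuous kernels preserve the diagonal and never exceed |K|", {
  st <- make_structured_study(seed = 8, n_per_pop = 25, m = 200)
  D <- setNames(runif(nrow(st$K), 0, 10), rownames(st$K))
  for (kind in c("range", "normcdf")) {
    KD <- gxe_kinship(st$K, D, kernel = exposure_kernel(kind))
    expect_equal(diag(unclass(KD)), diag(unclass(st$K)))
    expect_true(all(abs(KD) <= abs(st$K) + 1e-12))
    # equal exposures keep the full kinship entry
    D2 <- setNames(rep(3.7, nrow(st$K)), rownames(st$K))
    if (kind == "normcdf") {
      expect_error(gxe_kinship(st$K, D2, kernel = exposure_kernel(kind)),
                   "degenerate")
    }
  }
})

test_that("range kernel hits 0 at the exposure extremes and 1 on equal values", {
  K <- matrix(c(1, 0.4, 0.3, 0.4, 1, 0.2, 0.3, 0.2, 1), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  D <- c(a = 0, b = 10, c = 10)
  KD <- gxe_kinship(K, D, kernel = exposure_kernel("range"))
  expect_equal(KD[["a", "b"]], 0)     # |D_i - D_j| = R
  expect_equal(KD[["b", "c"]], K[["b", "c"]])
  expect_error(gxe_kinship(K, c(a = 2, b = 2, c = 2),
                           kernel = exposure_kernel("range")), "range is zero")
})

test_that("a custom kernel function matches its closed-form counterpart", {
  st <- make_structured_study(seed = 12, n_per_pop = 15, m = 100)
  D <- setNames(runif(nrow(st$K), 2, 9), rownames(st$K))
  R <- diff(range(D))
  kust <- exposure_kernel("custom", fn = function(a, b) 1 - abs(a - b) / R)
  expect_equal(gxe_kinship(st$K, D, kust),
               gxe_kinship(st$K, D, exposure_kernel("range")))
  expect_error(exposure_kernel("custom"), "similarity function")
})

test_that("range kernel on a binary exposure reproduces the binary mask exactly", {
  st <- make_structured_study(seed = 9, n_per_pop = 30, m = 300)
  KD_bin <- gxe_kinship(st$K, st$D)
  KD_rng <- gxe_kinship(st$K, st$D, kernel = exposure_kernel("range"))
  expect_equal(unclass(KD_rng), unclass(KD_bin), ignore_attr = TRUE)
})

test_that("permuting sample order conjugates K and K^D consistently", {
  st <- make_structured_study(seed = 10, n_per_pop = 20, m = 150)
  perm <- sample(rownames(st$K))
  Kp <- compute_grm(st$G$dosages[perm, ])
  expect_equal(unclass(Kp), unclass(st$K)[perm, perm], ignore_attr = TRUE)
  KD <- gxe_kinship(st$K, st$D)
  KDp <- gxe_kinship(st$K[perm, perm], st$D)   # D joined on ID, any order
  expect_equal(unclass(KDp), unclass(KD)[perm, perm], ignore_attr = TRUE)
})
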
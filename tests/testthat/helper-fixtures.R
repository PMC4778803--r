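# Shared fixtures and independent oracles for the test suite.

# iid (unstructured) genotype panel with sample/variant names
make_geno <- function(n, m, seed, maf_range = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf_range[1L], maf_range[2L])
  d <- matrix(as.double(rbinom(n * m, 2L, rep(p, each = n))), n,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("v%04d", seq_len(m))))
  d
}

# small structured study (two populations) reused across files
make_structured_study <- function(seed = 11, n_per_pop = 150, m = 1500,
                                  fst = 0.05, ...) {
  cfg <- sim_config(n_per_pop = n_per_pop, m_variants = m, fst = fst,
                    seed = seed, ...)
  simulate_gxe_study(cfg)
}

# Hudson-type Fst estimator (ratio of averages) with block-jackknife SE
hudson_fst <- function(d1, d2, n_blocks = 50) {
  f1 <- colMeans(d1) / 2; f2 <- colMeans(d2) / 2
  n1 <- 2 * nrow(d1);     n2 <- 2 * nrow(d2)
  num <- (f1 - f2)^2 - f1 * (1 - f1) / (n1 - 1) - f2 * (1 - f2) / (n2 - 1)
  den <- f1 * (1 - f2) + f2 * (1 - f1)
  est <- sum(num) / sum(den)
  blocks <- cut(seq_along(num), n_blocks, labels = FALSE)
  loo <- vapply(seq_len(n_blocks), function(b) {
    keep <- blocks != b
    sum(num[keep]) / sum(den[keep])
  }, numeric(1L))
  se <- sqrt((n_blocks - 1) / n_blocks * sum((loo - mean(loo))^2))
  list(fst = est, se = se)
}

# Restricted likelihood through error contrasts: the exact log-density of
# A'y ~ N(0, A' Sigma A) where A spans the orthogonal complement of the
# fixed-effect design. Independent of the package's AI-REML formulation.
reml_contrast_ll <- function(y, X, Vs, theta) {
  n <- length(y); p <- ncol(X)
  A <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  Sigma <- Reduce(`+`, Map(`*`, theta, Vs))
  C <- crossprod(A, Sigma %*% A)
  z <- drop(crossprod(A, y))
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, z, transpose = TRUE)^2))
}

# Dense grid search over the variance-fraction simplex with the total
# variance profiled out analytically at each grid point.
grid_reml_oracle <- function(y, X, Vs, step = 0.01) {
  n <- length(y); p <- ncol(X)
  A <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  z <- drop(crossprod(A, y))
  Cs <- lapply(Vs, function(V) crossprod(A, V %*% A))
  best <- list(ll = -Inf)
  fr <- seq(0, 1, by = step)
  for (fg in fr) for (fd in fr) {
    fe <- 1 - fg - fd
    if (fe < -1e-12) next
    C <- fg * Cs[[1L]] + fd * Cs[[2L]] + max(fe, 0) * Cs[[3L]]
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) next
    q <- sum(backsolve(ch, z, transpose = TRUE)^2)
    s_hat <- q / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi) + 1 + log(s_hat)) +
                    2 * sum(log(diag(ch))))
    if (ll > best$ll) {
      best <- list(ll = ll, fractions = c(fg, fd, max(fe, 0)),
                   theta = s_hat * c(fg, fd, max(fe, 0)))
    }
  }
  best
}

# gxe_reml stand-in carrying known (true) variance components, for tests
# that need a correctly specified covariance rather than an estimated one
fixed_components <- function(sigma2, kinship_names, samples) {
  structure(list(sigma2 = sigma2, kinship_names = kinship_names,
                 samples = samples,
                 cov = diag(0, length(sigma2)),
                 converged = TRUE),
            class = "gxe_reml")
}
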
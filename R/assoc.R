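# Per-variant association testing. For each variant r the fixed-effect
# design is [1, D, covariates..., X_r, D*X_r]; the model differs only in the
# residual covariance Sigma:
#   OLS:     Sigma = I
#   one RE:  Sigma = sigma_g^2 K + sigma_e^2 I
#   two RE:  Sigma = sigma_g^2 K + sigma_d^2 K^D + sigma_e^2 I
#   PC x E:  Sigma = I, with top kinship PCs and PC*D products as covariates
# Variance components are estimated once per phenotype (fit_reml) and the
# Cholesky factor of Sigma is reused for every variant (EMMAX strategy);
# testing reduces to OLS on rotated data, so the SNP and GEI F statistics
# are (coefficient/SE)^2 on F(1, n - p).

.gls_fit_rotated <- function(Xr, yr, test_cols) {
  n <- nrow(Xr); p <- ncol(Xr)
  if (qr(Xr)$rank < p) return(NULL)
  XtX <- crossprod(Xr)
  R <- chol(XtX)
  XtXinv <- chol2inv(R)
  beta <- drop(XtXinv %*% crossprod(Xr, yr))
  res <- yr - drop(Xr %*% beta)
  df <- n - p
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(XtXinv))
  fstat <- (beta / se)^2
  pval <- stats::pf(fstat, 1, df, lower.tail = FALSE)
  b2 <- beta[test_cols]
  V2 <- s2 * XtXinv[test_cols, test_cols]
  f2 <- tryCatch(drop(crossprod(b2, solve(V2, b2))) / 2,
                 error = function(e) NA_real_)
  list(beta = beta, se = se, p = pval, df = df,
       p_joint = stats::pf(f2, 2, df, lower.tail = FALSE))
}

.assoc_row_names <- c("n", "beta_snp", "se_snp", "p_snp", "delta_env",
                      "gamma_gei", "se_gei", "p_gei", "p_joint")

.assoc_fit_to_row <- function(fit, n_used) {
  if (is.null(fit)) {
    return(stats::setNames(c(n_used, rep(NA_real_, 8L)), .assoc_row_names))
  }
  p <- length(fit$beta)
  snp <- p - 1L; gei <- p
  stats::setNames(
    c(n_used, fit$beta[snp], fit$se[snp], fit$p[snp], fit$beta[2L],
      fit$beta[gei], fit$se[gei], fit$p[gei], fit$p_joint),
    .assoc_row_names)
}

.assoc_sigma <- function(model, vc, K, KD) {
  switch(model,
    ols = , pc_x_env = NULL,
    one_re = {
      if (is.null(vc) || is.null(K)) stop("one_re needs vc and K")
      if (length(vc$kinship_names) != 1L) {
        stop("one_re expects variance components fitted to a single kinship")
      }
      reml_sigma(vc, list(K))
    },
    two_re = {
      if (is.null(vc) || is.null(K) || is.null(KD)) stop("two_re needs vc, K and KD")
      if (length(vc$kinship_names) != 2L) {
        stop("two_re expects variance components fitted to two kinships")
      }
      reml_sigma(vc, list(K, KD))
    })
}

.assoc_design <- function(y, D, covar, model, vc, K, KD, pcs, pc_source) {
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), D = D)
  if (!is.null(covar)) X0 <- cbind(X0, covar)
  if (model == "pc_x_env" && pcs > 0L) {
    src <- if (pc_source == "gxe") {
      if (is.null(KD)) stop("pc_x_env with pc_source='gxe' needs KD")
      KD
    } else {
      if (is.null(K)) stop("pc_x_env needs K")
      K
    }
    X0 <- cbind(X0, pc_env_covariates(src[names(y), names(y)], D, pcs,
                                      context = X0))
  }
  Sigma <- .assoc_sigma(model, vc, K, KD)
  if (!is.null(Sigma)) {
    Sigma <- Sigma[names(y), names(y)]
    R <- chol(Sigma)
    yr <- backsolve(R, y, transpose = TRUE)
    X0r <- backsolve(R, X0, transpose = TRUE)
    colnames(X0r) <- colnames(X0)
  } else {
    R <- NULL; yr <- y; X0r <- X0
  }
  list(X0 = X0, X0r = X0r, yr = yr, R = R, Sigma = Sigma)
}

#' Genome-wide SNP and GEI association scan
#'
#' Tests every variant for a main (SNP) effect and a gene-by-environment
#' interaction (GEI) effect under one of four models. For the mixed models,
#' pass the [fit_reml()] fit obtained once for this phenotype; its
#' components define the covariance that is factorised a single time and
#' applied to all variants.
#'
#' Variants whose design is rank deficient after missing-sample exclusion
#' (monomorphic dosages, or a variant carried only by exposed samples) are
#' retained as rows with missing p-values and a `note`. Samples with a
#' missing dosage are dropped for that variant only, with the covariance
#' re-factorised on the remaining samples.
#'
#' @param G [geno_matrix()] or dosage matrix (samples x variants).
#' @param y named phenotype vector.
#' @param D named exposure vector.
#' @param model `"ols"`, `"one_re"`, `"two_re"` or `"pc_x_env"`.
#' @param vc [fit_reml()] fit (required for the mixed models).
#' @param K,KD genetic and GxE kinship matrices as the model requires.
#' @param covar optional fixed covariate matrix.
#' @param pcs number of principal components for `pc_x_env`.
#' @param pc_source eigenvectors of the genetic (`"genetic"`) or GxE
#'   (`"gxe"`) kinship for `pc_x_env`.
#' @return data.frame of class `gxe_scan`: one row per variant with
#'   `beta_snp`, `se_snp`, `p_snp`, `delta_env`, `gamma_gei`, `se_gei`,
#'   `p_gei`, `p_joint`, `model`, `note`.
#' @seealso [test_variant()], [inflation_factor()], [write_assoc_results()]
#' @export
gxe_scan <- function(G, y, D, model = c("ols", "one_re", "two_re", "pc_x_env"),
                     vc = NULL, K = NULL, KD = NULL, covar = NULL,
                     pcs = 10L, pc_source = c("genetic", "gxe")) {
  model <- match.arg(model)
  pc_source <- match.arg(pc_source)
  d <- if (inherits(G, "geno_matrix")) G$dosages else as.matrix(G)
  variants <- if (inherits(G, "geno_matrix")) G$variants else
    data.frame(id = colnames(d) %||% paste0("v", seq_len(ncol(d))),
               chrom = "0", pos = seq_len(ncol(d)), stringsAsFactors = FALSE)
  y <- y[!is.na(y)]
  args <- list(y, .as_named(D, names(y)), d)
  if (!is.null(covar)) args <- c(args, list(.as_named_mat(covar, names(y))))
  al <- do.call(align_samples, c(args, list(.require_all = FALSE)))
  y <- al[[1L]]; D <- al[[2L]]; d <- al[[3L]]
  covar <- if (!is.null(covar)) al[[4L]]
  prep <- .assoc_design(y, D, covar, model, vc, K, KD, pcs, pc_source)
  n <- length(y)

  has_na <- colSums(is.na(d)) > 0L
  d0 <- d
  d0[is.na(d0)] <- 0
  if (is.null(prep$R)) {
    gr <- d0; dgr <- D * d0
  } else {
    gr <- backsolve(prep$R, d0, transpose = TRUE)
    dgr <- backsolve(prep$R, D * d0, transpose = TRUE)
  }

  m <- ncol(d)
  out <- matrix(NA_real_, m, length(.assoc_row_names),
                dimnames = list(NULL, .assoc_row_names))
  note <- character(m)
  for (j in seq_len(m)) {
    if (!has_na[j]) {
      Xv <- cbind(prep$X0r, snp = gr[, j], gei = dgr[, j])
      fit <- .gls_fit_rotated(Xv, prep$yr, c(ncol(Xv) - 1L, ncol(Xv)))
      out[j, ] <- .assoc_fit_to_row(fit, n)
    } else {
      cc <- !is.na(d[, j])
      fit <- .test_complete_case(y[cc], d[cc, j], D[cc],
                                 if (!is.null(covar)) covar[cc, , drop = FALSE],
                                 prep, cc)
      out[j, ] <- .assoc_fit_to_row(fit, sum(cc))
    }
    if (anyNA(out[j, -1L])) note[j] <- "rank_deficient"
  }
  res <- data.frame(id = variants$id, chrom = variants$chrom,
                    pos = variants$pos, out, model = model, note = note,
                    stringsAsFactors = FALSE)
  class(res) <- c("gxe_scan", "data.frame")
  res
}

# complete-case path for a variant with missing dosages: subset the fixed
# design and covariance, re-factorise, and fit with the shared kernel
.test_complete_case <- function(y, g, D, covar, prep, cc) {
  X0 <- prep$X0[cc, , drop = FALSE]
  if (!is.null(prep$Sigma)) {
    R <- chol(prep$Sigma[cc, cc])
    yr <- backsolve(R, y, transpose = TRUE)
    X0r <- backsolve(R, X0, transpose = TRUE)
    gr <- backsolve(R, g, transpose = TRUE)
    dgr <- backsolve(R, D * g, transpose = TRUE)
  } else {
    yr <- y; X0r <- X0; gr <- g; dgr <- D * g
  }
  Xv <- cbind(X0r, snp = gr, gei = dgr)
  .gls_fit_rotated(Xv, yr, c(ncol(Xv) - 1L, ncol(Xv)))
}

#' Test a single variant for SNP and GEI effects
#'
#' Single-variant counterpart of [gxe_scan()]; results are identical to the
#' corresponding scan row.
#'
#' @param y named phenotype vector.
#' @param x dosage vector for the variant (named, 0/1/2, `NA` allowed).
#' @param D named exposure vector.
#' @inheritParams gxe_scan
#' @param id variant label for the output row.
#' @return one-row `gxe_scan` data.frame.
#' @export
test_variant <- function(y, x, D, model = c("ols", "one_re", "two_re", "pc_x_env"),
                         vc = NULL, K = NULL, KD = NULL, covar = NULL,
                         pcs = 10L, pc_source = c("genetic", "gxe"),
                         id = "variant") {
  x <- .as_named(x, names(y))
  G <- matrix(x, ncol = 1L, dimnames = list(names(x), id))
  gxe_scan(G, y, D, model = model, vc = vc, K = K, KD = KD, covar = covar,
           pcs = pcs, pc_source = pc_source)
}

#' Principal-component-by-environment covariates
#'
#' Top-`k` eigenvectors of a kinship matrix and their elementwise products
#' with the exposure, for fixed-effect structure correction in the style of
#' EIGENSTRAT extended to interactions. Eigenvectors are ordered by
#' descending eigenvalue and sign-fixed so that the largest-magnitude
#' loading is positive. Product columns that are collinear with columns
#' already present (e.g. when the exposure is constant) are dropped to keep
#' the design full rank.
#'
#' @param K kinship matrix.
#' @param D exposure vector aligned to `K`.
#' @param k number of leading principal components (0 returns a
#'   zero-column matrix).
#' @param context optional matrix of covariates already in the design,
#'   used only for the collinearity check.
#' @return matrix with up to `2k` columns `PC1..PCk, PC1xD..PCkxD`.
#' @export
pc_env_covariates <- function(K, D, k, context = NULL) {
  n <- nrow(K)
  if (k == 0L) return(matrix(numeric(0), n, 0L, dimnames = list(rownames(K), NULL)))
  if (k >= n) .stop_fmt("k = %d principal components requested for n = %d samples", k, n)
  eg <- eigen(K, symmetric = TRUE)
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- U[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1L))
  U <- sweep(U, 2L, flip, `*`)
  colnames(U) <- paste0("PC", seq_len(k))
  prod <- U * D
  colnames(prod) <- paste0("PC", seq_len(k), "xD")
  M <- cbind(U, prod)
  rownames(M) <- rownames(K)
  base <- if (is.null(context)) cbind(rep(1, n), D) else context
  keep <- logical(ncol(M))
  acc <- base
  for (j in seq_len(ncol(M))) {
    cand <- cbind(acc, M[, j])
    if (qr(cand)$rank == ncol(cand)) {
      keep[j] <- TRUE
      acc <- cand
    }
  }
  M[, keep, drop = FALSE]
}

#' Genomic-control inflation factor
#'
#' `lambda_GC` = median of the 1-df chi-square statistics implied by the
#' p-values, divided by the null median `qchisq(0.5, 1)` (0.4549364...).
#' A well-calibrated test gives 1; values above 1 indicate inflation.
#'
#' @param pvalues numeric vector of p-values; `NA`s are excluded.
#' @return scalar inflation factor.
#' @export
inflation_factor <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (length(p) == 0L) stop("no valid p-values")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Observed vs expected quantiles for a QQ plot
#'
#' @param pvalues p-values; `NA`s excluded. Ties in the sort order are
#'   broken by `ids` for determinism.
#' @param ids optional labels parallel to `pvalues`.
#' @return data.frame with `id`, `expected`, `observed` (-log10 scales).
#' @export
qq_data <- function(pvalues, ids = NULL) {
  keep <- !is.na(pvalues)
  p <- pvalues[keep]
  ids <- if (is.null(ids)) as.character(seq_along(pvalues))[keep] else ids[keep]
  o <- order(p, ids)
  m <- length(p)
  data.frame(id = ids[o],
             expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(p[o]), stringsAsFactors = FALSE)
}

#' @export
print.gxe_scan <- function(x, ...) {
  cat(sprintf("gxe_scan: %d variants, model = %s\n", nrow(x), x$model[1L]))
  if (any(!is.na(x$p_gei))) {
    cat(sprintf("  lambda_GC: SNP = %.4f, GEI = %.4f\n",
                inflation_factor(x$p_snp), inflation_factor(x$p_gei)))
  }
  print.data.frame(utils::head(as.data.frame(x), 6L), digits = 4)
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' QQ plot of scan p-values
#'
#' @param x a `gxe_scan` data.frame.
#' @param family `"gei"`, `"snp"` or both.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gxe_scan <- function(x, family = c("gei", "snp"), ...) {
  family <- match.arg(family, several.ok = TRUE)
  cols <- c(gei = "#D55E00", snp = "#0072B2")
  qs <- lapply(family, function(f) {
    qq_data(x[[paste0("p_", f)]], x$id)
  })
  lim <- c(0, max(unlist(lapply(qs, function(q) c(q$expected, q$observed)))))
  graphics::plot(NA, xlim = lim, ylim = lim,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)), ...)
  graphics::abline(0, 1, col = "grey50")
  for (i in seq_along(family)) {
    graphics::points(qs[[i]]$expected, qs[[i]]$observed,
                     pch = 20, col = cols[family[i]])
  }
  lam <- vapply(family, function(f) inflation_factor(x[[paste0("p_", f)]]),
                numeric(1L))
  graphics::legend("topleft", bty = "n", col = cols[family], pch = 20,
                   legend = sprintf("%s  lambda = %.3f", toupper(family), lam))
  invisible(x)
}
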
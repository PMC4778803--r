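#' Genetic relationship matrix from dosages
#'
#' Standardised-genotype GRM: with sample allele frequency `p_s` of variant
#' `s`, `K_ij = (1/m) * sum_s (x_is - 2 p_s)(x_js - 2 p_s) / (2 p_s (1 - p_s))`.
#' Missing dosages are mean-imputed (set to `2 p_s`) before standardisation,
#' matching common GRM tooling, so they contribute nothing to any pair.
#' Monomorphic variants (`p_s` of 0 or 1) are excluded and `m` counts only
#' the retained variants. Tested markers are deliberately left in the GRM;
#' leave-one-chromosome-out construction is out of scope.
#'
#' @param G a [geno_matrix()] or a samples x variants dosage matrix.
#' @param maf_floor additionally drop variants with minor allele frequency
#'   below this value (default 0: polymorphism check only).
#' @return symmetric n x n matrix, sample IDs as dimnames, `role` attribute
#'   `"genetic"`, and attribute `n_variants` = number of variants averaged.
#' @export
compute_grm <- function(G, maf_floor = 0) {
  d <- if (inherits(G, "geno_matrix")) G$dosages else as.matrix(G)
  if (is.null(rownames(d))) rownames(d) <- paste0("S", seq_len(nrow(d)))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- is.finite(p) & p > 0 & p < 1 & maf >= maf_floor
  if (!any(keep)) stop("no polymorphic variant passes the MAF floor; cannot estimate a GRM")
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(d, 2L, 2 * p, `-`)
  Z[is.na(Z)] <- 0                      # mean imputation after centring
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), `/`)
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(d), rownames(d))
  attr(K, "role") <- "genetic"
  attr(K, "n_variants") <- ncol(Z)
  K
}

#' Continuous-exposure similarity kernels
#'
#' A kernel maps a pair of exposure values to a similarity factor
#' `f(D_i, D_j)` in `[0, 1]` with `f(d, d) = 1`:
#' * `range`: `f = 1 - |D_i - D_j| / R` with `R` the exposure range;
#' * `normcdf`: `f = 1 - |Phi((D_i - mu)/sd) - Phi((D_j - mu)/sd)`| with
#'   `mu`, `sd` the exposure mean and standard deviation.
#'
#' Parameters default to the empirical range / moments of the exposure the
#' kernel is applied to. Which kernel suits a study depends on the scale of
#' the exposure; neither is recommended over the other.
#'
#' A custom kernel (`kind = "custom"`) supplies `fn(d_i, d_j)`, vectorised
#' over both arguments; values are clipped to `[0, 1]`.
#'
#' @param kind `"range"`, `"normcdf"` or `"custom"`.
#' @param R range for the `range` kernel.
#' @param mu,sd moments for the `normcdf` kernel.
#' @param fn similarity function for the `custom` kernel.
#' @return object of class `exposure_kernel`.
#' @export
exposure_kernel <- function(kind = c("range", "normcdf", "custom"),
                            R = NULL, mu = NULL, sd = NULL, fn = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom" && !is.function(fn)) {
    stop("a custom kernel needs a similarity function fn(d_i, d_j)")
  }
  structure(list(kind = kind, R = R, mu = mu, sd = sd, fn = fn),
            class = "exposure_kernel")
}

.kernel_factor <- function(kernel, D) {
  if (kernel$kind == "custom") {
    f <- outer(D, D, kernel$fn)
  } else if (kernel$kind == "range") {
    R <- kernel$R %||% diff(range(D))
    if (R <= 0) stop("degenerate exposure: range is zero, the range kernel is undefined")
    f <- 1 - abs(outer(D, D, `-`)) / R
  } else {
    mu <- kernel$mu %||% mean(D)
    sd <- kernel$sd %||% stats::sd(D)
    if (!is.finite(sd) || sd <= 0) stop("degenerate exposure: zero standard deviation")
    u <- stats::pnorm((D - mu) / sd)
    f <- 1 - abs(outer(u, u, `-`))
  }
  pmin(pmax(f, 0), 1)
}

#' GxE kinship matrix
#'
#' Builds the gene-by-environment kinship `K^D` from the genetic kinship
#' `K` and a per-sample exposure `D`. For a binary exposure,
#' `K^D_ij = K_ij` when `D_i = D_j` and 0 otherwise, so only pairs sharing
#' an exposure keep their relatedness. For a continuous exposure,
#' `K^D_ij = K_ij * f(D_i, D_j)` with `f` a similarity kernel
#' ([exposure_kernel()]). In both cases the diagonal of `K` is preserved
#' and `|K^D_ij| <= |K_ij|` elementwise. `K^D` is not forced positive
#' semidefinite; only the combined covariance
#' `sigma_g^2 K + sigma_d^2 K^D + sigma_e^2 I` must be positive definite,
#' which is checked where it is factorised.
#'
#' @param K genetic kinship matrix with sample-ID dimnames.
#' @param D named exposure vector (joined to `K` on sample ID).
#' @param kernel `NULL` for a binary exposure, or an [exposure_kernel()]
#'   for a continuous one.
#' @return kinship matrix with `role = "gxe"`.
#' @export
gxe_kinship <- function(K, D, kernel = NULL) {
  if (is.null(names(D))) {
    stopifnot(length(D) == nrow(K))
    names(D) <- rownames(K)
  }
  al <- align_samples(K, D)
  K <- al[[1L]]; D <- al[[2L]]
  if (is.null(kernel)) {
    if (!.is_binary01(D)) {
      stop("exposure is not binary {0,1}; pass an exposure_kernel() for continuous exposures")
    }
    f <- outer(D, D, `==`) * 1
  } else {
    stopifnot(inherits(kernel, "exposure_kernel"))
    f <- .kernel_factor(kernel, D)
  }
  KD <- K * f
  attr(KD, "role") <- "gxe"
  KD
}

#' @rdname gxe_kinship
#' @export
gxe_kinship_binary <- function(K, D) gxe_kinship(K, D, kernel = NULL)

#' @rdname gxe_kinship
#' @export
gxe_kinship_continuous <- function(K, D, kernel = exposure_kernel("range")) {
  gxe_kinship(K, D, kernel = kernel)
}
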
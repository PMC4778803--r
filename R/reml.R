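#' Restricted maximum likelihood for kinship variance components
#'
#' Fits the variance-component model
#' `y ~ N(X b, sum_k sigma_k^2 V_k + sigma_e^2 I)` by average-information
#' (AI) REML, where each `V_k` is a kinship matrix — the genetic
#' relationship matrix `K` alone (one random effect) or `K` together with
#' the GxE kinship `K^D` (two random effects). The fixed-effect design is
#' an intercept, the exposure `D` when supplied, and any user covariates;
#' no per-variant term enters, so one fit per phenotype supplies the
#' covariance reused for every variant's test ([gxe_scan()]).
#'
#' Starting values split the phenotypic variance equally across components;
#' one EM step precedes the AI updates. Convergence requires the restricted
#' log-likelihood to move by less than `tol_loglik` and the score of every
#' interior component to fall below `tol_grad`. Components driven negative
#' are clamped to `1e-6` times the phenotypic variance and flagged as
#' boundary estimates. Standard errors come from the inverse AI matrix at
#' the optimum. With a single kinship all iterations run in the
#' eigenbasis of `K` (one decomposition, O(n) per iteration); with two
#' kinships each iteration factorises the covariance by Cholesky.
#'
#' @param y named numeric phenotype vector; missing values are dropped.
#' @param kinships one kinship matrix or a (preferably named) list of them,
#'   e.g. `list(genetic = K, gxe = KD)`. The residual component is added
#'   automatically.
#' @param D optional exposure vector, included as a fixed effect.
#' @param X optional matrix of additional fixed covariates (samples in
#'   rows); an intercept is always included.
#' @param max_iter,tol_loglik,tol_grad AI iteration controls.
#' @param method `"eigen"` (single kinship only), `"direct"`, or `"auto"`.
#' @return object of class `gxe_reml` with components `sigma2`, `se`,
#'   `fractions`, `fractions_se`, `cov`, `loglik`, `gradient`,
#'   `iterations`, `converged`, `boundary`.
#' @examples
#' set.seed(1)
#' G <- matrix(rbinom(60 * 200, 2, 0.4), 60,
#'             dimnames = list(paste0("s", 1:60), paste0("v", 1:200)))
#' K <- compute_grm(G)
#' y <- setNames(rnorm(60), rownames(K))
#' fit_reml(y, K)
#' @export
fit_reml <- function(y, kinships, D = NULL, X = NULL,
                     max_iter = 100L, tol_loglik = 1e-6, tol_grad = 1e-4,
                     method = c("auto", "eigen", "direct")) {
  method <- match.arg(method)
  cl <- match.call()
  if (is.matrix(kinships)) kinships <- list(kinships)
  if (is.null(names(kinships)) || any(names(kinships) == "")) {
    names(kinships) <- if (length(kinships) == 1L) "genetic"
                       else c("genetic", "gxe", paste0("K", seq_along(kinships)))[seq_along(kinships)]
  }
  ids <- names(y) %||% rownames(kinships[[1L]])
  if (is.null(names(y))) names(y) <- ids
  keep <- !is.na(y)
  if (sum(keep) < 2L) stop("need at least 2 non-missing phenotype values")
  y <- y[keep]
  al <- do.call(align_samples, c(list(y), kinships,
                                 if (!is.null(D)) list(.as_named(D, ids)),
                                 if (!is.null(X)) list(.as_named_mat(X, ids)),
                                 list(.require_all = FALSE)))
  y <- al[[1L]]
  kinships[] <- al[seq_along(kinships) + 1L]
  idx <- 1L + length(kinships)
  Xfix <- cbind(`(Intercept)` = rep(1, length(y)))
  if (!is.null(D)) {
    idx <- idx + 1L
    Xfix <- cbind(Xfix, D = al[[idx]])
  }
  if (!is.null(X)) Xfix <- cbind(Xfix, al[[idx + 1L]])
  n <- length(y)
  p <- ncol(Xfix)
  ncomp <- length(kinships) + 1L
  if (n <= p + ncomp) stop("too few samples for the number of fixed effects and components")
  if (qr(Xfix)$rank < p) stop("fixed-effect design is rank deficient")
  if (method == "auto") method <- if (length(kinships) == 1L) "eigen" else "direct"
  if (method == "eigen" && length(kinships) > 1L) {
    stop("the eigen method applies only to a single kinship")
  }

  vp <- stats::var(y)
  floor_val <- 1e-6 * vp
  eval_state <- if (method == "eigen") {
    .reml_state_eigen(y, Xfix, kinships[[1L]])
  } else {
    .reml_state_direct(y, Xfix, kinships)
  }

  theta <- rep(vp / ncomp, ncomp)
  st <- eval_state(theta)
  if (is.null(st)) stop("covariance matrix not positive definite at the starting values")
  # one EM step, then AI updates
  theta_em <- pmax(theta + theta^2 * st$residual_score / n, floor_val)
  st_em <- eval_state(theta_em)
  if (!is.null(st_em)) { theta <- theta_em; st <- st_em }

  converged <- FALSE
  iters <- 1L
  for (it in seq_len(max_iter)) {
    iters <- it
    # active-set step: components pinned at the floor with a negative score
    # stay fixed, so the boundary does not distort the step for the rest
    pinned <- theta <= floor_val * (1 + 1e-8) & st$grad < 0
    delta <- numeric(ncomp)
    delta[!pinned] <- tryCatch(
      solve(st$AI[!pinned, !pinned, drop = FALSE], st$grad[!pinned]),
      error = function(e) st$grad[!pinned] / diag(st$AI)[!pinned])
    step <- 1
    st_p <- NULL
    prop <- theta
    while (step >= 1e-6) {
      cand_theta <- pmax(theta + step * delta, floor_val)
      cand <- eval_state(cand_theta)
      if (!is.null(cand) && cand$ll >= st$ll - 1e-10) {
        st_p <- cand; prop <- cand_theta; break
      }
      step <- step / 2
    }
    if (is.null(st_p)) {
      # AI direction unusable; fall back to an EM step, which cannot go downhill
      cand_theta <- pmax(theta + theta^2 * st$residual_score / n, floor_val)
      cand <- eval_state(cand_theta)
      if (!is.null(cand) && cand$ll >= st$ll - 1e-10) {
        st_p <- cand; prop <- cand_theta
      }
    }
    if (is.null(st_p)) break
    dll <- st_p$ll - st$ll
    theta <- prop
    st <- st_p
    at_floor <- theta <= floor_val * (1 + 1e-8)
    free_grad <- st$grad[!(at_floor & st$grad < 0)]
    if (abs(dll) < tol_loglik &&
        (length(free_grad) == 0L || max(abs(free_grad)) < tol_grad)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("AI-REML did not meet convergence tolerances after ", iters,
            " iterations (|grad| = ", signif(max(abs(st$grad)), 3), ")")
  }

  comp_names <- c(names(kinships), "residual")
  sigma2 <- stats::setNames(theta, comp_names)
  covmat <- tryCatch(solve(st$AI), error = function(e) matrix(NA_real_, ncomp, ncomp))
  dimnames(covmat) <- list(comp_names, comp_names)
  se <- sqrt(pmax(diag(covmat), 0))
  boundary <- stats::setNames(theta <= floor_val * (1 + 1e-8), comp_names)
  fr <- .fraction_table(sigma2, covmat)
  structure(list(
    sigma2 = sigma2, se = se, cov = covmat,
    fractions = stats::setNames(fr$fraction, comp_names),
    fractions_se = stats::setNames(fr$fraction_se, comp_names),
    loglik = st$ll, gradient = stats::setNames(st$grad, comp_names),
    iterations = iters, converged = converged, boundary = boundary,
    n = n, n_fixed = p, samples = names(y), method = method,
    kinship_names = names(kinships), call = cl
  ), class = "gxe_reml")
}

.as_named <- function(x, ids) {
  if (is.null(names(x))) { stopifnot(length(x) == length(ids)); names(x) <- ids }
  x
}

.as_named_mat <- function(X, ids) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) { stopifnot(nrow(X) == length(ids)); rownames(X) <- ids }
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  X
}

# Shared state evaluated at a component vector theta: restricted
# log-likelihood, score, average-information matrix, and the EM residual
# score (y'P V_k P y - tr(P V_k)).  Returns NULL if Sigma is not PD.

.reml_state_direct <- function(y, X, kinships) {
  n <- length(y)
  Vs <- c(kinships, list(diag(n)))
  k <- length(Vs)
  function(theta) {
    Sigma <- matrix(0, n, n)
    for (i in seq_len(k)) Sigma <- Sigma + theta[i] * Vs[[i]]
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Sinv <- chol2inv(ch)
    SiX <- Sinv %*% X
    XtSiX <- crossprod(X, SiX)
    cXX <- tryCatch(chol(XtSiX), error = function(e) NULL)
    if (is.null(cXX)) return(NULL)
    B <- chol2inv(cXX)
    Py <- drop(Sinv %*% y - SiX %*% (B %*% crossprod(SiX, y)))
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cXX))) + sum(y * Py))
    VPy <- lapply(Vs, function(V) drop(V %*% Py))
    quad <- vapply(VPy, function(v) sum(Py * v), numeric(1L))
    WB <- SiX %*% B
    trPV <- vapply(seq_len(k), function(i) {
      # tr(P V) = tr(Sinv V) - tr(B X'Sinv V Sinv X); both via elementwise sums
      sum(Sinv * Vs[[i]]) - sum(WB * (Vs[[i]] %*% SiX))
    }, numeric(1L))
    PVPy <- lapply(VPy, function(v) {
      drop(Sinv %*% v - SiX %*% (B %*% crossprod(SiX, v)))
    })
    AI <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in i:k) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(VPy[[i]] * PVPy[[j]])
    }
    list(ll = ll, grad = -0.5 * (trPV - quad), AI = AI,
         residual_score = quad - trPV, Py = Py)
  }
}

.reml_state_eigen <- function(y, X, K) {
  eg <- eigen(K, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, y))
  Xt <- crossprod(eg$vectors, X)
  n <- length(y)
  vs <- list(lam, rep(1, n))       # rotated kinship and identity diagonals
  function(theta) {
    d <- theta[1L] * lam + theta[2L]
    if (any(d <= 0)) return(NULL)
    W <- Xt / d
    XtSiX <- crossprod(Xt, W)
    cXX <- tryCatch(chol(XtSiX), error = function(e) NULL)
    if (is.null(cXX)) return(NULL)
    B <- chol2inv(cXX)
    Py <- yt / d - drop(W %*% (B %*% crossprod(W, yt)))
    ll <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(cXX))) + sum(yt * Py))
    Pu <- function(u) u / d - drop(W %*% (B %*% crossprod(W, u)))
    VPy <- lapply(vs, function(v) v * Py)
    quad <- vapply(VPy, function(u) sum(Py * u), numeric(1L))
    trPV <- vapply(vs, function(v) {
      sum(v / d) - sum(B * crossprod(W, v * W))
    }, numeric(1L))
    PVPy <- lapply(VPy, Pu)
    AI <- matrix(0, 2L, 2L)
    for (i in 1:2) for (j in i:2) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(VPy[[i]] * PVPy[[j]])
    }
    list(ll = ll, grad = -0.5 * (trPV - quad), AI = AI,
         residual_score = quad - trPV, Py = Py)
  }
}

.fraction_table <- function(sigma2, covmat) {
  S <- sum(sigma2)
  if (S <= 0) stop("total variance is zero; fractions are undefined")
  k <- length(sigma2)
  f <- sigma2 / S
  J <- (diag(k) * S - matrix(sigma2, k, k)) / S^2   # d f_i / d sigma_j
  Vf <- J %*% covmat %*% t(J)
  data.frame(fraction = as.numeric(f),
             fraction_se = sqrt(pmax(diag(Vf), 0)))
}

#' Variance fractions with delta-method standard errors
#'
#' Ratios of each variance component to the total phenotypic variance,
#' with standard errors propagated from the component covariance matrix by
#' the delta method.
#'
#' @param vc a [fit_reml()] object.
#' @return data.frame with columns `component`, `variance`, `se`,
#'   `fraction`, `fraction_se`.
#' @export
variance_fractions <- function(vc) {
  stopifnot(inherits(vc, "gxe_reml"))
  fr <- .fraction_table(vc$sigma2, vc$cov)
  data.frame(component = names(vc$sigma2),
             variance = as.numeric(vc$sigma2), se = as.numeric(vc$se),
             fraction = fr$fraction, fraction_se = fr$fraction_se,
             row.names = NULL)
}

#' Covariance matrix implied by a REML fit
#'
#' Reassembles `Sigma = sum_k sigma_k^2 V_k + sigma_e^2 I` from fitted
#' components and the kinship matrices they were fitted to.
#'
#' @param vc a [fit_reml()] object.
#' @param kinships the same kinship matrices (order matched by name where
#'   available).
#' @return dense covariance matrix over the fit's samples.
#' @export
reml_sigma <- function(vc, kinships) {
  if (is.matrix(kinships)) kinships <- list(kinships)
  stopifnot(length(kinships) == length(vc$kinship_names))
  ids <- vc$samples
  Sigma <- diag(vc$sigma2[["residual"]], length(ids))
  dimnames(Sigma) <- list(ids, ids)
  for (i in seq_along(kinships)) {
    Ki <- kinships[[i]][ids, ids]
    Sigma <- Sigma + vc$sigma2[[vc$kinship_names[i]]] * Ki
  }
  Sigma
}

#' @export
print.gxe_reml <- function(x, ...) {
  cat("Variance components (AI-REML", if (!x$converged) ", NOT converged", ")\n",
      sep = "")
  tab <- variance_fractions(x)
  print(cbind(tab[1L], round(tab[-1L], 4)), row.names = FALSE)
  cat(sprintf("logL = %.4f  n = %d  iterations = %d\n",
              x$loglik, x$n, x$iterations))
  if (any(x$boundary)) {
    cat("boundary components:", paste(names(which(x$boundary)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.gxe_reml <- function(object, ...) {
  structure(list(fit = object, table = variance_fractions(object)),
            class = "summary.gxe_reml")
}

#' @export
print.summary.gxe_reml <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' @export
coef.gxe_reml <- function(object, ...) object$sigma2

#' @export
logLik.gxe_reml <- function(object, ...) {
  structure(object$loglik, df = length(object$sigma2), nobs = object$n,
            class = "logLik")
}

#' @export
vcov.gxe_reml <- function(object, ...) object$cov

#' Write a GCTA-style variance report
#'
#' Plain-text summary in the spirit of `.hsq` files: one line per variance
#' component with its SE, the total, each fraction of the total, the
#' restricted log-likelihood, and convergence metadata.
#'
#' @param vc a [fit_reml()] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_reml_report <- function(vc, path) {
  tab <- variance_fractions(vc)
  lines <- c("Source\tVariance\tSE",
             sprintf("V(%s)\t%.6f\t%.6f", tab$component, tab$variance, tab$se),
             sprintf("Vp\t%.6f\tNA", sum(tab$variance)),
             sprintf("V(%s)/Vp\t%.6f\t%.6f", tab$component, tab$fraction,
                     tab$fraction_se),
             sprintf("logL\t%.6f", vc$loglik),
             sprintf("n\t%d", vc$n),
             sprintf("iterations\t%d", vc$iterations),
             sprintf("converged\t%s", vc$converged))
  writeLines(lines, path)
  invisible(path)
}
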
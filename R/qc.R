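# Phenotype and genotype quality control as applied before a GxE scan:
# the linear model assumes normal phenotypes, so non-normal and
# outlier-ridden phenotypes are removed; variants are screened on MAF,
# Hardy-Weinberg equilibrium and completeness.

.as_pheno_list <- function(phenotypes) {
  if (is.matrix(phenotypes) || is.data.frame(phenotypes)) {
    phenotypes <- as.data.frame(phenotypes)
    stats::setNames(lapply(phenotypes, as.numeric), colnames(phenotypes))
  } else if (!is.list(phenotypes)) {
    list(phenotype = phenotypes)
  } else phenotypes
}

.qc_report <- function(id, reason, threshold) {
  data.frame(id = id, reason = reason,
             threshold = rep_len(threshold, length(id)),
             stringsAsFactors = FALSE)
}

#' Filter phenotypes on normality
#'
#' Retains a phenotype iff its Shapiro–Wilk p-value is at least `alpha`
#' (default 0.05). Constant phenotypes are dropped with reason
#' `"degenerate"`.
#'
#' @param phenotypes a named list of numeric vectors, or a matrix /
#'   data.frame with one phenotype per column.
#' @param alpha significance threshold; `alpha = 0` retains everything
#'   non-degenerate.
#' @return list with `retained` (named list) and `report` (dropped ids
#'   with reason codes).
#' @export
normality_filter <- function(phenotypes, alpha = 0.05) {
  ph <- .as_pheno_list(phenotypes)
  drop_reason <- vapply(ph, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3L) return("too_few_values")
    if (stats::sd(x) == 0) return("degenerate")
    if (alpha > 0 && stats::shapiro.test(x)$p.value < alpha) return("non_normal")
    ""
  }, character(1L))
  dropped <- drop_reason != ""
  list(retained = ph[!dropped],
       report = .qc_report(names(ph)[dropped], drop_reason[dropped],
                           sprintf("shapiro_alpha=%g", alpha)))
}

#' Filter phenotypes on outlier count
#'
#' Counts values more than `sd_limit` standard deviations from the mean
#' (mean and SD computed on all values, single pass) and drops the
#' phenotype when the count reaches `max_outliers`.
#'
#' @inheritParams normality_filter
#' @param sd_limit distance from the mean, in SDs, that marks an outlier.
#' @param max_outliers drop the phenotype iff it has at least this many
#'   outliers.
#' @return list with `retained` and `report`.
#' @export
outlier_filter <- function(phenotypes, sd_limit = 2, max_outliers = 5L) {
  ph <- .as_pheno_list(phenotypes)
  n_out <- vapply(ph, function(x) {
    x <- x[!is.na(x)]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(NA_integer_)
    sum(abs(x - mean(x)) > sd_limit * s)
  }, integer(1L))
  reason <- ifelse(is.na(n_out), "degenerate",
                   ifelse(n_out >= max_outliers, "outliers", ""))
  dropped <- reason != ""
  list(retained = ph[!dropped],
       report = .qc_report(names(ph)[dropped], reason[dropped],
                           sprintf("sd_limit=%g,max_outliers=%d",
                                   sd_limit, max_outliers)))
}

#' Hardy-Weinberg equilibrium p-value for one variant
#'
#' Default is the 1-df chi-square goodness-of-fit test of observed genotype
#' counts against expectations from the allele frequency, without
#' continuity correction; `method = "exact"` uses the standard exact test
#' that sums the probabilities of heterozygote counts no more likely than
#' the observed one.
#'
#' @param dosages 0/1/2 vector for one variant (`NA` ignored).
#' @param method `"chisq"` or `"exact"`.
#' @return p-value.
#' @export
hwe_test <- function(dosages, method = c("chisq", "exact")) {
  method <- match.arg(method)
  x <- dosages[!is.na(dosages)]
  n_aa <- sum(x == 0); n_ab <- sum(x == 1); n_bb <- sum(x == 2)
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(NA_real_)
  p <- (2 * n_bb + n_ab) / (2 * n)
  if (p == 0 || p == 1) return(1)
  if (method == "chisq") {
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((c(n_aa, n_ab, n_bb) - expd)^2 / expd)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  n_a <- 2 * n_aa + n_ab           # rarer-or-not allele counts
  n_b <- 2 * n_bb + n_ab
  n_rare <- min(n_a, n_b)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1L))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  sum(prob[prob <= prob[match(n_ab, hets)] * (1 + 1e-12)])
}

#' Variant-level quality control
#'
#' Retains a variant iff its minor allele frequency is at least `maf`, its
#' Hardy-Weinberg p-value is at least `hwe_alpha`, and its missing-call
#' fraction is at most `max_missing`. A variant failing several checks is
#' reported under the first failing one (missingness, then MAF, then HWE).
#'
#' @param G a [geno_matrix()] or dosage matrix.
#' @param maf minimum minor allele frequency.
#' @param hwe_alpha minimum HWE p-value.
#' @param max_missing maximum fraction of missing calls.
#' @param hwe_method passed to [hwe_test()].
#' @return list with `retained` ([geno_matrix()]) and `report`.
#' @export
genotype_qc <- function(G, maf = 0.10, hwe_alpha = 1e-4, max_missing = 0.05,
                        hwe_method = c("chisq", "exact")) {
  hwe_method <- match.arg(hwe_method)
  gm <- if (inherits(G, "geno_matrix")) G else geno_matrix(as.matrix(G))
  d <- gm$dosages
  if (ncol(d) == 0L) stop("empty genotype matrix")
  miss <- colMeans(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  mafs <- pmin(p, 1 - p)
  hwe <- apply(d, 2L, hwe_test, method = hwe_method)
  reason <- rep("", ncol(d))
  reason[hwe < hwe_alpha] <- "hwe"
  reason[mafs < maf] <- "maf"
  reason[miss > max_missing] <- "missing"
  keep <- reason == ""
  list(retained = gm[, keep],
       report = .qc_report(colnames(d)[!keep], reason[!keep],
                           sprintf("maf=%g,hwe=%g,missing=%g",
                                   maf, hwe_alpha, max_missing)))
}

#' Rank-based quantile normalization
#'
#' Replaces values by standard-normal quantiles
#' `qnorm((rank - 0.5) / n)` with tied ranks averaged, either over the
#' whole sample or separately within each exposure group. Output is rank
#' invariant: any strictly monotone transform of the input yields the same
#' result.
#'
#' @param y named numeric phenotype vector.
#' @param group `NULL` for whole-sample normalization, or a vector of
#'   group labels (e.g. the exposure) aligned to `y`.
#' @return normalized vector, same names and order as `y`.
#' @export
quantile_normalize <- function(y, group = NULL) {
  qn <- function(x) {
    obs <- !is.na(x)
    n <- sum(obs)
    if (n < 2L) stop("cannot quantile-normalize a group with fewer than 2 values")
    x[obs] <- stats::qnorm((rank(x[obs], ties.method = "average") - 0.5) / n)
    x
  }
  if (is.null(group)) return(qn(y))
  stopifnot(length(group) == length(y))
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) < 2L) {
      .stop_fmt("exposure group '%s' has fewer than 2 samples", g)
    }
    y[idx] <- qn(y[idx])
  }
  y
}
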
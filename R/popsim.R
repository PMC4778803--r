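#' Configuration for the structured GxE simulation
#'
#' Describes one condition of the two-population null simulation: a
#' Balding–Nichols genotype panel, a dichotomous exposure assigned within
#' populations, and a phenotype drawn from
#' `y ~ N(0, sigma_g^2 K + sigma_d^2 K^D + sigma_e^2 I)` with no causal
#' variant, so both the SNP and GEI statistic families are null and a
#' calibrated test should give `lambda_GC` near 1.
#'
#' Defaults are the study conditions used throughout the package's
#' calibration experiments: 1,000 individuals per population, 10,000
#' variants with a 5% minor-allele-frequency floor in both populations,
#' Fst 0.004 (the order of divergence between two close European
#' populations), balanced exposure, and variance fractions
#' (0.4, 0.2, 0.4) for the genetic, GxE and residual components.
#'
#' @param n_per_pop individuals per population.
#' @param m_variants number of variants kept after the MAF floor.
#' @param fst Balding–Nichols divergence, in (0, 0.5).
#' @param maf_floor minimum realized minor allele frequency required in
#'   each population.
#' @param exposure_scheme `"balanced"` (each population half exposed) or
#'   `"biased"` (`exposure_ratio` exposed in population 1 and
#'   `1 - exposure_ratio` in population 2).
#' @param exposure_ratio exposed fraction in population 1 under the biased
#'   scheme, in `[0.5, 1)`.
#' @param sigma_g2,sigma_d2,sigma_e2 variance fractions of the genetic,
#'   GxE and residual components; must sum to 1.
#' @param seed master seed; every stage derives sub-seeds from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_pop = 1000L, m_variants = 10000L, fst = 0.004,
                       maf_floor = 0.05,
                       exposure_scheme = c("balanced", "biased"),
                       exposure_ratio = 0.6,
                       sigma_g2 = 0.4, sigma_d2 = 0.2, sigma_e2 = 0.4,
                       seed = 1L) {
  exposure_scheme <- match.arg(exposure_scheme)
  stopifnot(n_per_pop >= 2L, m_variants >= 1L)
  if (!(fst > 0 && fst < 0.5)) stop("fst must lie in (0, 0.5)")
  if (!(maf_floor >= 0 && maf_floor < 0.5)) stop("maf_floor must lie in [0, 0.5)")
  if (exposure_scheme == "biased" &&
      !(exposure_ratio >= 0.5 && exposure_ratio < 1)) {
    stop("exposure_ratio must lie in [0.5, 1)")
  }
  s <- c(sigma_g2, sigma_d2, sigma_e2)
  if (any(s < 0) || abs(sum(s) - 1) > 1e-12) {
    stop("variance fractions must be non-negative and sum to 1")
  }
  structure(list(n_per_pop = as.integer(n_per_pop),
                 m_variants = as.integer(m_variants), fst = fst,
                 maf_floor = maf_floor, exposure_scheme = exposure_scheme,
                 exposure_ratio = exposure_ratio,
                 sigma_g2 = sigma_g2, sigma_d2 = sigma_d2,
                 sigma_e2 = sigma_e2, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate two-population genotypes under the Balding–Nichols model
#'
#' Ancestral allele frequencies are drawn uniformly on
#' `[maf_floor, 1 - maf_floor]`; each population's frequency is Beta
#' distributed around the ancestral value with concentration
#' `(1 - Fst)/Fst`, and dosages are Binomial(2, p). Variants whose
#' realized minor allele frequency falls below the floor in either
#' population are rejected and redrawn, mimicking the common-variant
#' filter of chip-based studies.
#'
#' @param cfg a [sim_config()].
#' @param seed overrides `cfg$seed`.
#' @return a [geno_matrix()] with attribute `truth`: a list carrying the
#'   per-sample population labels and the seed.
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  n1 <- cfg$n_per_pop
  n <- 2L * n1
  shape <- (1 - cfg$fst) / cfg$fst
  blocks <- list()
  got <- 0L
  tries <- 0L
  while (got < cfg$m_variants) {
    need <- cfg$m_variants - got
    mb <- max(100L, ceiling(need * 1.4))
    p_anc <- stats::runif(mb, cfg$maf_floor, 1 - cfg$maf_floor)
    p1 <- stats::rbeta(mb, p_anc * shape, (1 - p_anc) * shape)
    p2 <- stats::rbeta(mb, p_anc * shape, (1 - p_anc) * shape)
    g1 <- matrix(stats::rbinom(n1 * mb, 2L, rep(p1, each = n1)), n1)
    g2 <- matrix(stats::rbinom(n1 * mb, 2L, rep(p2, each = n1)), n1)
    f1 <- colMeans(g1) / 2
    f2 <- colMeans(g2) / 2
    ok <- pmin(f1, 1 - f1) >= cfg$maf_floor & pmin(f2, 1 - f2) >= cfg$maf_floor
    keep <- which(ok)[seq_len(min(sum(ok), need))]
    if (length(keep)) {
      blocks[[length(blocks) + 1L]] <- rbind(g1[, keep, drop = FALSE],
                                             g2[, keep, drop = FALSE])
      got <- got + length(keep)
    }
    tries <- tries + 1L
    if (tries > 1000L) stop("variant rejection rate too high; lower maf_floor")
  }
  d <- do.call(cbind, blocks)
  ids <- c(sprintf("P1_%04d", seq_len(n1)), sprintf("P2_%04d", seq_len(n1)))
  vid <- sprintf("v%05d", seq_len(cfg$m_variants))
  dimnames(d) <- list(ids, vid)
  G <- geno_matrix(d, data.frame(id = vid, chrom = "1",
                                 pos = seq_len(cfg$m_variants),
                                 a1 = "A", a2 = "B", stringsAsFactors = FALSE))
  attr(G, "truth") <- list(
    pop = stats::setNames(rep(c("pop1", "pop2"), each = n1), ids),
    seed = seed, config = cfg)
  G
}

#' Assign a dichotomous exposure within populations
#'
#' Under the balanced scheme each population receives exactly half exposed
#' and half unexposed individuals; under the biased scheme population 1
#' receives `exposure_ratio` exposed and population 2 receives
#' `1 - exposure_ratio` (counts rounded toward the stated ratio). Which
#' individuals are exposed is random within population.
#'
#' @param cfg a [sim_config()].
#' @param pop named character vector of population labels.
#' @param seed RNG seed.
#' @return named 0/1 vector, attribute `mode = "binary"`.
#' @export
assign_exposure <- function(cfg, pop, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), !is.null(names(pop)))
  set.seed(seed)
  ratios <- if (cfg$exposure_scheme == "balanced") c(0.5, 0.5)
            else c(cfg$exposure_ratio, 1 - cfg$exposure_ratio)
  D <- stats::setNames(numeric(length(pop)), names(pop))
  for (i in seq_along(unique(pop))) {
    members <- names(pop)[pop == unique(pop)[i]]
    n_exp <- round(length(members) * ratios[min(i, 2L)])
    D[sample(members, n_exp)] <- 1
  }
  attr(D, "mode") <- "binary"
  D
}

#' Draw a null phenotype from the two-kinship covariance
#'
#' One multivariate-normal draw `y ~ N(0, sigma_g^2 K + sigma_d^2 K^D +
#' sigma_e^2 I)`. No causal variant is implanted, so every per-variant
#' test is null. If the combined covariance is numerically indefinite
#' (zeroed GxE entries can break positive semidefiniteness), eigenvalues
#' are floored at a small positive value and a warning is raised.
#'
#' @param K,KD genetic and GxE kinship matrices (shared sample order).
#' @param cfg a [sim_config()] carrying the variance fractions.
#' @param seed RNG seed.
#' @return named phenotype vector.
#' @export
simulate_phenotype <- function(K, KD, cfg, seed = cfg$seed) {
  stopifnot(identical(rownames(K), rownames(KD)))
  n <- nrow(K)
  Sigma <- cfg$sigma_g2 * K + cfg$sigma_d2 * KD + diag(cfg$sigma_e2, n)
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    eg <- eigen(Sigma, symmetric = TRUE)
    floor_ev <- 1e-8 * max(eg$values)
    if (max(eg$values) <= 0) stop("phenotype covariance has no positive eigenvalue")
    warning("phenotype covariance not positive definite; eigenvalues floored")
    lam <- pmax(eg$values, floor_ev)
    R <- t(eg$vectors %*% (sqrt(lam) * t(eg$vectors)))
  }
  set.seed(seed)
  y <- drop(crossprod(R, stats::rnorm(n)))
  names(y) <- rownames(K)
  y
}

#' Simulate one complete structured GxE study
#'
#' Genotypes, GRM, exposure, GxE kinship and one null phenotype, each stage
#' seeded from the master seed.
#'
#' @param cfg a [sim_config()].
#' @param seed overrides `cfg$seed`.
#' @return list with `G`, `K`, `KD`, `D`, `y`, `truth`, `config`.
#' @export
simulate_gxe_study <- function(cfg, seed = cfg$seed) {
  ss <- derive_seeds(seed, 3L)
  G <- simulate_genotypes(cfg, seed = ss[1L])
  truth <- attr(G, "truth")
  K <- compute_grm(G)
  D <- assign_exposure(cfg, truth$pop, seed = ss[2L])
  KD <- gxe_kinship(K, D)
  y <- simulate_phenotype(K, KD, cfg, seed = ss[3L])
  list(G = G, K = K, KD = KD, D = D, y = y, truth = truth, config = cfg)
}

#' Replicate the null simulation and measure inflation per model
#'
#' Runs the full loop — genotypes, kinships, exposure, null phenotype,
#' REML (for the mixed models), genome-wide scan — for each replicate and
#' model, and records `lambda_GC` for the SNP and GEI statistic families.
#' Variance-component estimates from the one- and two-random-effect fits
#' are retained for parameter-recovery analyses.
#'
#' @param cfg a [sim_config()].
#' @param n_replicates number of independent replicates (fresh genotype
#'   draw each).
#' @param modes subset of `"ols"`, `"one_re"`, `"two_re"`, `"pc_x_env"`.
#' @param pcs principal components for `"pc_x_env"`.
#' @param verbose print one line per replicate.
#' @return object of class `gxe_replicates`: `table` (replicate, mode,
#'   lambda_snp, lambda_gei), `vc` (per-replicate variance fractions),
#'   `config`, `seeds`.
#' @export
run_replicates <- function(cfg, n_replicates = 20L,
                           modes = c("ols", "one_re", "two_re"),
                           pcs = 10L, verbose = FALSE) {
  modes <- match.arg(modes, c("ols", "one_re", "two_re", "pc_x_env"),
                     several.ok = TRUE)
  seeds <- derive_seeds(cfg$seed, n_replicates)
  rows <- list()
  vcs <- list()
  for (r in seq_len(n_replicates)) {
    st <- simulate_gxe_study(cfg, seed = seeds[r])
    vc1 <- if ("one_re" %in% modes) {
      fit_reml(st$y, list(genetic = st$K), D = st$D)
    }
    vc2 <- if ("two_re" %in% modes) {
      fit_reml(st$y, list(genetic = st$K, gxe = st$KD), D = st$D)
    }
    for (mode in modes) {
      sc <- gxe_scan(st$G, st$y, st$D, model = mode,
                     vc = switch(mode, one_re = vc1, two_re = vc2),
                     K = st$K, KD = st$KD, pcs = pcs)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, mode = mode,
        lambda_snp = inflation_factor(sc$p_snp),
        lambda_gei = inflation_factor(sc$p_gei))
    }
    for (fit in list(vc1, vc2)) {
      if (!is.null(fit)) {
        tab <- variance_fractions(fit)
        tab$replicate <- r
        tab$model <- if (length(fit$kinship_names) == 1L) "one_re" else "two_re"
        vcs[[length(vcs) + 1L]] <- tab
      }
    }
    if (verbose) {
      message(sprintf("replicate %d/%d done", r, n_replicates))
    }
  }
  structure(list(table = do.call(rbind, rows),
                 vc = if (length(vcs)) do.call(rbind, vcs),
                 config = cfg, seeds = seeds),
            class = "gxe_replicates")
}

#' @export
summary.gxe_replicates <- function(object, ...) {
  tab <- object$table
  agg <- do.call(rbind, lapply(split(tab, tab$mode), function(s) {
    data.frame(mode = s$mode[1L], n_replicates = nrow(s),
               median_lambda_snp = stats::median(s$lambda_snp),
               max_lambda_snp = max(s$lambda_snp),
               median_lambda_gei = stats::median(s$lambda_gei),
               max_lambda_gei = max(s$lambda_gei))
  }))
  rownames(agg) <- NULL
  agg
}

#' @export
print.gxe_replicates <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("gxe_replicates: %d replicates, %d x 2 samples, %d variants, Fst = %g\n",
              max(x$table$replicate), cfg$n_per_pop, cfg$m_variants, cfg$fst))
  print(summary(x), row.names = FALSE, digits = 4)
  invisible(x)
}
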
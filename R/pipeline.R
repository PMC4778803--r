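#' Read a pipeline configuration file
#'
#' Plain-text `key: value` lines (Debian-control layout, read with
#' [read.dcf()]); values that parse as numbers are converted, and
#' `modes` may be a comma-separated list.
#'
#' @param path config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  m <- read.dcf(path)
  cfg <- as.list(m[1L, ])
  cfg <- lapply(cfg, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  if (!is.null(cfg$modes)) cfg$modes <- trimws(strsplit(cfg$modes, ",")[[1L]])
  cfg
}

.pipeline_defaults <- list(
  modes = "two_re", seed = 1, pcs = 10,
  quantile_normalize = "none",
  qc_maf = NA, qc_hwe = NA, qc_missing = NA)

#' Run the full GxE association pipeline
#'
#' Wires the stages end to end: obtain genotypes, phenotype and exposure
#' (from files, or freshly simulated when `simulate: true`), optional
#' genotype QC and phenotype quantile normalization, kinship construction,
#' REML variance components for the mixed models, a genome-wide scan per
#' requested model, and inflation diagnostics. All outputs are new files
#' under `out_dir`; a `manifest.json` recording inputs, seed and
#' thresholds makes the run reproducible, and a `FAILED` marker is left
#' behind if any stage errors.
#'
#' @param config named list or path to a config file
#'   ([read_run_config()]). Recognised keys: `simulate` plus
#'   [sim_config()] fields, or `geno`/`pheno`/`exposure` (+ optional
#'   `grm`, `gxe_grm`, `covar`) paths; `modes` (subset of ols, one_re,
#'   two_re, pc_x_env), `pcs`, `seed`, `qc_maf`, `qc_hwe`, `qc_missing`,
#'   `quantile_normalize` (none, all, by-exposure).
#' @param out_dir output directory (created; must be empty or absent).
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  cfg <- utils::modifyList(.pipeline_defaults, config)
  modes <- match.arg(cfg$modes, c("ols", "one_re", "two_re", "pc_x_env"),
                     several.ok = TRUE)
  simulate <- isTRUE(cfg$simulate) || identical(cfg$simulate, "true")
  if (!simulate) {
    for (key in c("geno", "pheno")) {
      if (is.null(cfg[[key]])) .stop_fmt("config lacks '%s'", key)
    }
    if (is.null(cfg$exposure)) {
      stop("config lacks 'exposure'; GEI testing requires an exposure for every mode")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(dir(out_dir))) .stop_fmt("output directory %s is not empty", out_dir)
  ok <- FALSE
  on.exit(if (!ok) writeLines("pipeline failed; partial outputs retained",
                              file.path(out_dir, "FAILED")))

  if (simulate) {
    sim_keys <- intersect(names(cfg), names(formals(sim_config)))
    scfg <- do.call(sim_config, c(cfg[sim_keys],
                                  if (!"seed" %in% sim_keys) list(seed = cfg$seed)))
    st <- simulate_gxe_study(scfg)
    G <- st$G; y <- st$y; D <- st$D; K <- st$K; KD <- st$KD
    write_genotypes(G, file.path(out_dir, "genotypes"), format = "plink-bed")
    write_sample_values(y, file.path(out_dir, "phenotype.tsv"))
    write_sample_values(D, file.path(out_dir, "exposure.tsv"))
  } else {
    G <- read_genotypes(cfg$geno)
    y <- read_sample_values(cfg$pheno)
    D <- read_exposure(cfg$exposure)
    K <- KD <- NULL
  }
  covar <- if (!is.null(cfg$covar)) {
    tab <- utils::read.table(cfg$covar, header = TRUE, row.names = 1L)
    as.matrix(tab)
  }

  if (!is.na(cfg$qc_maf) || !is.na(cfg$qc_hwe) || !is.na(cfg$qc_missing)) {
    qc <- genotype_qc(G,
                      maf = if (is.na(cfg$qc_maf)) 0 else cfg$qc_maf,
                      hwe_alpha = if (is.na(cfg$qc_hwe)) 0 else cfg$qc_hwe,
                      max_missing = if (is.na(cfg$qc_missing)) 1 else cfg$qc_missing)
    G <- qc$retained
    utils::write.table(qc$report, file.path(out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    K <- KD <- NULL                      # kinship must follow the QC'd panel
  }
  if (cfg$quantile_normalize != "none") {
    grp <- if (cfg$quantile_normalize == "by-exposure") D[names(y)]
    y <- quantile_normalize(y, group = grp)
  }

  if (is.null(K)) {
    K <- if (!is.null(cfg$grm)) read_kinship(cfg$grm) else compute_grm(G)
  }
  if (is.null(KD)) {
    KD <- if (!is.null(cfg$gxe_grm)) read_kinship(cfg$gxe_grm, role = "gxe")
          else gxe_kinship(K, D[rownames(K)])
  }
  write_kinship(K, file.path(out_dir, "kinship.grm.gz"),
                n_snps = attr(K, "n_variants") %||% NA_integer_)
  write_kinship(KD, file.path(out_dir, "kinship_gxe.grm.gz"))

  vc1 <- if ("one_re" %in% modes) fit_reml(y, list(genetic = K), D = D)
  vc2 <- if ("two_re" %in% modes) fit_reml(y, list(genetic = K, gxe = KD), D = D)
  if (!is.null(vc1)) write_reml_report(vc1, file.path(out_dir, "reml_one_re.hsq"))
  if (!is.null(vc2)) write_reml_report(vc2, file.path(out_dir, "reml_two_re.hsq"))

  lam <- list()
  for (mode in modes) {
    sc <- gxe_scan(G, y, D, model = mode,
                   vc = switch(mode, one_re = vc1, two_re = vc2),
                   K = K, KD = KD, covar = covar, pcs = cfg$pcs)
    write_assoc_results(sc, file.path(out_dir, paste0("assoc_", mode, ".tsv")))
    utils::write.table(qq_data(sc$p_gei, sc$id),
                       file.path(out_dir, paste0("qq_gei_", mode, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    lam[[mode]] <- data.frame(mode = mode,
                              lambda_snp = inflation_factor(sc$p_snp),
                              lambda_gei = inflation_factor(sc$p_gei))
  }
  utils::write.table(do.call(rbind, lam), file.path(out_dir, "lambda_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("gxelmm")),
    r_version = R.version.string,
    config = cfg,
    n_samples = length(y), n_variants = ncol(G$dosages),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ok <- TRUE
  invisible(out_dir)
}
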
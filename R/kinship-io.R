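# Kinship matrices travel as either a square TSV (header row of sample IDs,
# first column sample IDs) or the GCTA GRM dialects: gzipped text triples
# "i j n_snps value" plus a .grm.id file, or the float32 lower-triangle
# .grm.bin plus .grm.id.

.new_kinship <- function(values, ids, role = c("genetic", "gxe"),
                         check_psd = FALSE) {
  role <- match.arg(role)
  values <- as.matrix(values)
  dimnames(values) <- list(ids, ids)
  if (nrow(values) != ncol(values)) stop("kinship matrix must be square")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-8) .stop_fmt("kinship matrix asymmetric (max |K - K'| = %g)", asym)
  values <- (values + t(values)) / 2
  if (check_psd) {
    ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      .stop_fmt("genetic kinship is not positive semidefinite (min eigenvalue %g)",
                min(ev))
    }
  }
  attr(values, "role") <- role
  values
}

kinship_role <- function(K) attr(K, "role") %||% "genetic"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a kinship matrix
#'
#' @param path a square TSV, a `.grm.gz`/`.grm` text file, or a `.grm.bin`
#'   file (the paired `.grm.id` must sit next to the GCTA files).
#' @param dialect `"auto"` detects by extension.
#' @param role `"genetic"` (checked positive semidefinite) or `"gxe"`.
#' @return symmetric numeric matrix with sample IDs as dimnames and a
#'   `role` attribute.
#' @export
read_kinship <- function(path, dialect = c("auto", "square-tsv", "gcta-grm"),
                         role = c("genetic", "gxe")) {
  dialect <- match.arg(dialect)
  role <- match.arg(role)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.grm(\\.gz|\\.bin)?$", path)) "gcta-grm" else "square-tsv"
  }
  K <- if (dialect == "gcta-grm") .read_gcta_grm(path) else .read_square_tsv(path)
  .new_kinship(K, rownames(K), role, check_psd = role == "genetic")
}

.read_square_tsv <- function(path) {
  if (!file.exists(path)) .stop_fmt("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1L)
  K <- as.matrix(tab)
  if (nrow(K) != ncol(K)) {
    .stop_fmt("%s: matrix is %d x %d, expected square", path, nrow(K), ncol(K))
  }
  if (!identical(rownames(K), colnames(K))) {
    .stop_fmt("%s: row IDs do not match column IDs", path)
  }
  asym <- max(abs(K - t(K)))
  if (asym > 1e-8) {
    .stop_fmt("%s: matrix asymmetric beyond tolerance (max deviation %g)",
              path, asym)
  }
  K
}

.gcta_paths <- function(path) {
  prefix <- sub("\\.grm(\\.gz|\\.bin)?$", "", path)
  kind <- if (grepl("\\.grm\\.bin$", path)) "bin"
          else if (grepl("\\.grm\\.gz$", path)) "gz" else "text"
  list(prefix = prefix, kind = kind, id = paste0(prefix, ".grm.id"))
}

.read_gcta_grm <- function(path) {
  p <- .gcta_paths(path)
  if (!file.exists(p$id)) .stop_fmt("missing GRM id file: %s", p$id)
  idtab <- utils::read.table(p$id, colClasses = "character")
  ids <- idtab[[min(2L, ncol(idtab))]]
  n <- length(ids)
  npair <- n * (n + 1L) / 2
  K <- matrix(0, n, n)
  low <- lower.tri(K, diag = TRUE)
  if (p$kind == "bin") {
    vals <- readBin(path, "numeric", n = npair + 1L, size = 4L)
    if (length(vals) != npair) {
      .stop_fmt("%s: %d values for %d IDs (expected %d)",
                path, length(vals), n, npair)
    }
    # .grm.bin stores the lower triangle row-wise (i >= j); R fills
    # lower.tri column-wise, so go through the transpose's upper triangle
    K <- matrix(0, n, n)
    K[upper.tri(K, diag = TRUE)] <- vals
    K <- t(K)
  } else {
    con <- if (p$kind == "gz") gzfile(path) else file(path)
    tab <- utils::read.table(con)
    if (nrow(tab) != npair) {
      .stop_fmt("%s: %d rows for %d IDs (expected %d)", path, nrow(tab), npair)
    }
    K[cbind(tab[[1L]], tab[[2L]])] <- tab[[4L]]
  }
  K[upper.tri(K)] <- t(K)[upper.tri(K)]
  dimnames(K) <- list(ids, ids)
  K
}

#' Write a kinship matrix
#'
#' @param K symmetric matrix with sample-ID dimnames.
#' @param path output path; extension selects the dialect under `"auto"`.
#' @param dialect `"square-tsv"`, `"gcta-grm"` (gzipped text triple) or
#'   `"gcta-grm-bin"` (float32 lower triangle).
#' @param n_snps marker count recorded in the GCTA text dialect.
#' @return the path, invisibly.
#' @export
write_kinship <- function(K, path,
                          dialect = c("auto", "square-tsv", "gcta-grm",
                                      "gcta-grm-bin"),
                          n_snps = NA_integer_) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.grm\\.bin$", path)) "gcta-grm-bin"
               else if (grepl("\\.grm(\\.gz)?$", path)) "gcta-grm"
               else "square-tsv"
  }
  ids <- rownames(K)
  if (dialect == "square-tsv") {
    out <- data.frame(id = ids,
                      format(K, digits = 17, trim = TRUE, scientific = NA),
                      check.names = FALSE)
    colnames(out) <- c("id", ids)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  p <- .gcta_paths(path)
  utils::write.table(data.frame(ids, ids), p$id, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- nrow(K)
  ij <- which(lower.tri(K, diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]  # row-wise i >= j
  if (dialect == "gcta-grm-bin") {
    con <- file(paste0(p$prefix, ".grm.bin"), "wb")
    on.exit(close(con))
    writeBin(K[ij], con, size = 4L)
  } else {
    con <- gzfile(paste0(p$prefix, ".grm.gz"), "w")
    on.exit(close(con))
    nmiss <- if (is.na(n_snps)) 0L else n_snps
    utils::write.table(
      data.frame(ij[, 1L], ij[, 2L], nmiss,
                 format(K[ij], digits = 17, trim = TRUE)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write association results
#'
#' Tab-delimited, one row per variant, fixed column order; p-values are kept
#' to full double precision so a round trip is exact to 15 significant
#' digits.
#'
#' @param results a `gxe_scan` data.frame (see [gxe_scan()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_assoc_results <- function(results, path) {
  if (NROW(results) == 0L) stop("refusing to write an empty results table")
  cols <- c("id", "chrom", "pos", "beta_snp", "se_snp", "p_snp",
            "gamma_gei", "se_gei", "p_gei", "p_joint", "model")
  out <- as.data.frame(results)[, cols]
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read association results written by [write_assoc_results()]
#'
#' @param path results TSV.
#' @return data.frame of class `gxe_scan`.
#' @export
read_assoc_results <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(id = "character", chrom = "character",
                                          model = "character"))
  class(tab) <- c("gxe_scan", "data.frame")
  tab
}
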
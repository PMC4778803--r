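#' Genotype matrix container
#'
#' Holds an n (samples) x m (variants) dosage matrix coded 0/1/2 (count of
#' the A1 allele) with `NA` for missing calls, together with per-variant
#' metadata. Sample IDs are the rownames of the dosage matrix and variant
#' IDs the colnames; all downstream operations join on these IDs.
#'
#' @param dosages numeric matrix, samples x variants, values in
#'   \{0, 1, 2, NA\}; must have row and column names.
#' @param variants optional data.frame with columns `id`, `chrom`, `pos`,
#'   `a1`, `a2`; defaults are synthesised from the colnames.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, variants = NULL) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)) || is.null(colnames(dosages))) {
    stop("dosage matrix must carry sample rownames and variant colnames")
  }
  if (anyDuplicated(rownames(dosages))) stop("duplicate sample IDs")
  if (anyDuplicated(colnames(dosages))) stop("duplicate variant IDs")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(dosages)), arr.ind = TRUE)[1L, ]
    .stop_fmt("non-{0,1,2} dosage %g at sample '%s', variant '%s'",
              dosages[idx[1L], idx[2L]],
              rownames(dosages)[idx[1L]], colnames(dosages)[idx[2L]])
  }
  if (is.null(variants)) {
    variants <- data.frame(id = colnames(dosages), chrom = "0",
                           pos = seq_len(ncol(dosages)),
                           a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  }
  stopifnot(identical(variants$id, colnames(dosages)))
  structure(list(dosages = dosages, variants = variants),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  d <- x$dosages
  cat(sprintf("geno_matrix: %d samples x %d variants (%.2f%% missing)\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param x a [geno_matrix()].
#' @param i sample index or IDs; `j` variant index or IDs.
#' @param ... ignored.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  d <- x$dosages
  if (missing(i)) i <- seq_len(nrow(d))
  if (missing(j)) j <- seq_len(ncol(d))
  d <- d[i, j, drop = FALSE]
  v <- x$variants[match(colnames(d), x$variants$id), , drop = FALSE]
  rownames(v) <- NULL
  geno_matrix(d, v)
}

#' Read genotypes from disk
#'
#' Supports PLINK binary triples (`.bed`/`.bim`/`.fam`, SNP-major) and a
#' plain dosage TSV whose first column is the sample ID, whose header row
#' carries variant IDs, and whose cells are 0/1/2 with `NA` for missing.
#'
#' @param path file path; for PLINK either the `.bed` file or the shared
#'   prefix.
#' @param format `"auto"` (by extension), `"plink-bed"` or `"dosage-tsv"`.
#' @return a [geno_matrix()].
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("auto", "plink-bed", "dosage-tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path) || file.exists(paste0(path, ".bed")))
      "plink-bed" else "dosage-tsv"
  }
  if (format == "plink-bed") read_plink(path) else read_dosage_tsv(path)
}

read_dosage_tsv <- function(path) {
  if (!file.exists(path)) .stop_fmt("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", na.strings = character(0))
  ids <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  d <- suppressWarnings(matrix(as.numeric(vals), nrow(vals),
                               dimnames = list(ids, colnames(vals))))
  bad <- which(!(vals == "NA" | d %in% c(0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(d))
    .stop_fmt("%s: invalid dosage '%s' at row %d (sample '%s'), column '%s'",
              path, vals[bad[1L]], rc[1L], ids[rc[1L]], colnames(d)[rc[2L]])
  }
  geno_matrix(d)
}

#' Write genotypes to disk
#'
#' @param G a [geno_matrix()].
#' @param path output path (for PLINK, the prefix).
#' @param format `"dosage-tsv"` or `"plink-bed"`.
#' @return the path, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("dosage-tsv", "plink-bed")) {
  format <- match.arg(format)
  if (format == "plink-bed") return(write_plink(G, path))
  d <- G$dosages
  out <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample value table (phenotype or exposure)
#'
#' Whitespace-delimited, two columns: sample ID then value; `NA` allowed.
#' A header line is detected (non-numeric second field) and skipped.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
read_sample_values <- function(path) {
  if (!file.exists(path)) .stop_fmt("file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           na.strings = character(0))
  if (ncol(tab) < 2L) .stop_fmt("%s: expected two columns (id, value)", path)
  if (is.na(suppressWarnings(as.numeric(tab[1L, 2L]))) && tab[1L, 2L] != "NA") {
    tab <- tab[-1L, , drop = FALSE]
  }
  v <- suppressWarnings(as.numeric(tab[[2L]]))
  bad <- is.na(v) & tab[[2L]] != "NA"
  if (any(bad)) .stop_fmt("%s: non-numeric value '%s' for sample '%s'",
                          path, tab[[2L]][which(bad)[1L]], tab[[1L]][which(bad)[1L]])
  if (anyDuplicated(tab[[1L]])) .stop_fmt("%s: duplicate sample IDs", path)
  stats::setNames(v, tab[[1L]])
}

#' Write a per-sample value table
#'
#' @param x named numeric vector.
#' @param path output path.
#' @param header write an `id value` header line.
#' @return the path, invisibly.
#' @export
write_sample_values <- function(x, path, header = TRUE) {
  stopifnot(!is.null(names(x)))
  out <- data.frame(id = names(x), value = format(x, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read an environmental exposure vector
#'
#' @param path file path (see [read_sample_values()] for the layout).
#' @param mode `"auto"` classifies values in \{0,1\} as binary.
#' @return named numeric vector with attribute `mode`.
#' @export
read_exposure <- function(path, mode = c("auto", "binary", "continuous")) {
  mode <- match.arg(mode)
  x <- read_sample_values(path)
  if (mode == "auto") mode <- if (.is_binary01(x)) "binary" else "continuous"
  if (mode == "binary" && !.is_binary01(x)) {
    .stop_fmt("%s: declared binary but contains values outside {0,1}", path)
  }
  attr(x, "mode") <- mode
  x
}
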
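#' @keywords internal
"_PACKAGE"

# Common sample-ID alignment: all multi-input operations join on IDs, never
# on row position, so shuffling file order cannot change a statistic.

.sample_ids <- function(x) {
  if (is.matrix(x)) rownames(x) else names(x)
}

#' Align named objects on shared sample IDs
#'
#' Takes named vectors and/or matrices (rows = samples) and returns them
#' subset and reordered to the sample IDs shared by all of them, in the
#' order of the first object. Errors if any object is unnamed or if no
#' common samples remain.
#'
#' @param ... named vectors or row-named matrices.
#' @param .require_all error (default) if the objects do not share an
#'   identical sample set, rather than silently intersecting.
#' @return list of the inputs, aligned.
#' @keywords internal
align_samples <- function(..., .require_all = TRUE) {
  objs <- list(...)
  ids <- lapply(objs, .sample_ids)
  if (any(vapply(ids, is.null, logical(1L)))) {
    stop("all inputs must carry sample IDs (names or rownames)")
  }
  common <- Reduce(intersect, ids)
  if (length(common) == 0L) stop("no samples shared across inputs")
  if (.require_all && !all(lengths(ids) == length(common))) {
    sizes <- paste(lengths(ids), collapse = ", ")
    stop("sample sets differ across inputs (sizes ", sizes,
         ", shared ", length(common), "); subset explicitly first")
  }
  common <- ids[[1L]][ids[[1L]] %in% common]
  lapply(objs, function(o) {
    if (is.matrix(o)) {
      if (nrow(o) == ncol(o) && identical(rownames(o), colnames(o))) {
        o[common, common, drop = FALSE]
      } else {
        o[common, , drop = FALSE]
      }
    } else {
      o[common]
    }
  })
}

#' Derive independent sub-seeds from one master seed
#'
#' A single run-level seed deterministically spawns one seed per stage or
#' replicate so that replicates can be regenerated individually.
#'
#' @param seed integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.is_binary01 <- function(x) all(x %in% c(0, 1) | is.na(x))

.stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
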
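#' Representational dissimilarity matrices
#'
#' An `rdm` is a symmetric stimulus-by-stimulus matrix of correlation
#' distances (1 minus Pearson r between response patterns), with zero
#' diagonal and entries in \[0, 2\]. Stimulus identifiers live in the
#' dimnames.
#'
#' @param x Square numeric matrix.
#' @param stimulus_ids Optional character vector of stimulus labels; defaults
#'   to existing rownames or `"s1"..."sn"`.
#' @return An object of class `rdm` (a numeric matrix).
#' @export
as_rdm <- function(x, stimulus_ids = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n != ncol(x) || n < 2) {
    abort("An RDM must be a square matrix with at least 2 stimuli.")
  }
  if (is.null(stimulus_ids)) {
    stimulus_ids <- rownames(x) %||% paste0("s", seq_len(n))
  }
  if (length(stimulus_ids) != n || anyDuplicated(stimulus_ids)) {
    abort("`stimulus_ids` must be unique and match the matrix dimension.")
  }
  dimnames(x) <- list(stimulus_ids, stimulus_ids)
  if (any(!is.finite(x))) abort("RDM entries must be finite.")
  if (max(abs(x - t(x))) > 1e-10) abort("RDM must be symmetric (tol 1e-10).")
  if (any(abs(diag(x)) > 0)) abort("RDM diagonal must be exactly zero.")
  if (min(x) < -1e-12 || max(x) > 2 + 1e-12) {
    abort("Correlation-distance entries must lie in [0, 2].")
  }
  structure(x, class = c("rdm", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm: %d stimuli, correlation distance>\n", nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], ...)
  invisible(x)
}

#' Stimulus identifiers of an RDM
#' @param rdm An `rdm`.
#' @return Character vector of stimulus labels.
#' @export
stimulus_ids <- function(rdm) rownames(rdm)

#' Compute a correlation-distance RDM from an activation matrix
#'
#' Each row of `acts` is the response pattern of one stimulus across
#' measurement channels (network units or voxels). Dissimilarity between
#' stimuli i and j is `1 - cor(acts[i, ], acts[j, ])`; the diagonal is
#' exactly zero. Pattern rows with zero variance have no defined correlation
#' and are rejected by name.
#'
#' @param acts Numeric matrix, stimuli x units, with at least 2 rows and 2
#'   columns; rownames (if present) become stimulus identifiers.
#' @return An [as_rdm()] object.
#' @examples
#' acts <- matrix(rnorm(40), nrow = 4)
#' compute_rdm(acts)
#' @export
compute_rdm <- function(acts) {
  acts <- as.matrix(acts)
  if (nrow(acts) < 2 || ncol(acts) < 2) {
    abort("`acts` needs at least 2 stimuli and 2 units.")
  }
  if (any(!is.finite(acts))) {
    abort("`acts` contains non-finite values; clean activations first.")
  }
  ids <- rownames(acts) %||% paste0("s", seq_len(nrow(acts)))
  v <- apply(acts, 1, stats::var)
  if (any(v == 0)) {
    abort(sprintf("Zero-variance response pattern for stimulus: %s.",
                  paste(ids[v == 0], collapse = ", ")))
  }
  d <- 1 - stats::cor(t(acts))
  d <- (d + t(d)) / 2          # remove floating-point asymmetry
  diag(d) <- 0
  d[d < 0] <- 0                # guard tiny negative rounding at r ~ 1
  as_rdm(d, stimulus_ids = ids)
}

#' Upper-triangle vector of an RDM
#'
#' Returns the strictly-upper entries in row-major order
#' ((1,2), (1,3), ..., (1,n), (2,3), ...), length n(n-1)/2 — the standard
#' vectorisation fed to RDM-comparison statistics.
#'
#' @param rdm An `rdm` (or square symmetric matrix).
#' @return Numeric vector of length `n * (n - 1) / 2`.
#' @export
upper_triangle <- function(rdm) {
  m <- as.matrix(rdm)
  t(m)[lower.tri(m)]
}

#' Average a collection of RDMs
#'
#' Element-wise arithmetic mean in dissimilarity space; all RDMs must share
#' the same stimuli in the same order.
#'
#' @param rdms List of `rdm` objects.
#' @return An `rdm`.
#' @export
average_rdm <- function(rdms) {
  if (length(rdms) < 1) abort("Need at least one RDM to average.")
  ids <- stimulus_ids(rdms[[1]])
  for (r in rdms) {
    if (!identical(stimulus_ids(r), ids)) {
      abort("All RDMs must share identical stimulus ids and order.")
    }
  }
  m <- Reduce(`+`, lapply(rdms, unclass)) / length(rdms)
  as_rdm(m, stimulus_ids = ids)
}

#' Read / write an RDM as CSV
#'
#' The CSV holds the full square matrix with stimulus ids as header and
#' first column.
#'
#' @param rdm An `rdm`.
#' @param path File path.
#' @return `write_rdm_csv` returns `path` invisibly; `read_rdm_csv` an `rdm`.
#' @export
write_rdm_csv <- function(rdm, path) {
  df <- data.frame(stimulus = stimulus_ids(rdm), unclass(rdm),
                   check.names = FALSE)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_rdm_csv
#' @export
read_rdm_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1])
  as_rdm(m, stimulus_ids = ids)
}
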
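#' Construct a signature matrix
#'
#' A `signature_matrix` is a 96 x N numeric matrix of channel probabilities:
#' rows are the SBS96 channels in canonical order ([sbs96_channels()]), columns
#' are uniquely named signatures, every entry is non-negative and every column
#' sums to one. Columns whose sums deviate from one by at most `tol` are
#' renormalized (published catalogs carry rounding error); larger deviations
#' are rejected.
#'
#' @param values Numeric matrix, 96 rows. Rownames must be channel labels;
#'   rows in any order are re-aligned to the canonical order by label.
#' @param tol Maximum tolerated deviation of a column sum from 1 before
#'   renormalization fails (default `1e-3`).
#' @return A numeric matrix of class `signature_matrix` with canonical
#'   rownames and column sums exactly 1 (to machine precision).
#' @export
signature_matrix <- function(values, tol = 1e-3) {
  values <- as.matrix(values)
  canon <- sbs96_channels()
  if (nrow(values) != 96L) {
    stop("signature matrix must have exactly 96 channel rows, got ",
         nrow(values), call. = FALSE)
  }
  if (is.null(rownames(values))) {
    stop("signature matrix rows must be labelled with SBS96 channel names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate channel labels: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(canon, rownames(values))
  if (length(missing) > 0) {
    stop("missing channel labels: ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  }
  values <- values[canon, , drop = FALSE]
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("signature names must be present and unique", call. = FALSE)
  }
  if (!is.numeric(values) || anyNA(values)) {
    stop("signature matrix entries must be numeric and non-missing", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("signature matrix entries must be non-negative", call. = FALSE)
  }
  sums <- colSums(values)
  bad <- which(abs(sums - 1) > tol)
  if (length(bad) > 0) {
    stop("signature column(s) do not sum to 1 within ", tol, ": ",
         paste(colnames(values)[utils::head(bad, 5)], collapse = ", "),
         call. = FALSE)
  }
  if (any(sums <= 0)) stop("signature column sums must be positive", call. = FALSE)
  # renormalize only where needed so an already-normalized matrix
  # round-trips bit-identically
  off <- abs(sums - 1) > 1e-12
  if (any(off)) {
    values[, off] <- sweep(values[, off, drop = FALSE], 2, sums[off], "/")
  }
  class(values) <- c("signature_matrix", "matrix", "array")
  values
}

#' Read a reference mutational-signature matrix
#'
#' Reads a tab-delimited catalog whose first column holds the SBS96 channel
#' labels (header `Type`) and whose remaining columns hold one signature each.
#' Rows may appear in any order; they are matched to the canonical channel
#' order by label. Columns are renormalized to sum exactly one.
#'
#' @param path Path to a tab-delimited file.
#' @inheritParams signature_matrix
#' @return A [signature_matrix()].
#' @seealso [synthetic_signature_catalog()] for the packaged catalog.
#' @export
read_signature_matrix <- function(path, tol = 1e-3) {
  if (!file.exists(path)) stop("signature matrix file not found: ", path, call. = FALSE)
  tbl <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tbl) < 2) stop("signature matrix needs a channel column plus >= 1 signature column", call. = FALSE)
  values <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("signature columns must be numeric", call. = FALSE)
  rownames(values) <- as.character(tbl[[1]])
  signature_matrix(values, tol = tol)
}

#' Write a signature matrix to a tab-delimited file
#'
#' Inverse of [read_signature_matrix()]: header `Type` plus one column per
#' signature, 96 body rows in canonical channel order.
#'
#' @param x A `signature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(x, path) {
  stopifnot(inherits(x, "signature_matrix"))
  vals <- unclass(x)
  # 17 significant digits so doubles round-trip exactly
  chr <- apply(vals, 2, function(col) sprintf("%.17g", col))
  tbl <- data.frame(Type = rownames(x), chr, check.names = FALSE)
  colnames(tbl) <- c("Type", colnames(x))
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default artifact-signature subset
#'
#' The 18 COSMIC v3 single-base-substitution signatures attributed to
#' sequencing artifacts rather than biology: SBS27, SBS43, and SBS45 through
#' SBS60. Every name must be present in the supplied matrix; a catalog that
#' lacks one fails loudly so an artifact subset is never silently truncated.
#'
#' @param signatures A `signature_matrix` containing the COSMIC v3 names.
#' @return Character vector of 18 signature names.
#' @export
default_artifact_signatures <- function(signatures) {
  stopifnot(inherits(signatures, "signature_matrix"))
  artifacts <- c("SBS27", "SBS43", paste0("SBS", 45:60))
  missing <- setdiff(artifacts, colnames(signatures))
  if (length(missing) > 0) {
    stop("signature matrix lacks designated artifact signature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  artifacts
}

#' Validate an artifact-signature subset against a matrix
#'
#' @param signatures A `signature_matrix`.
#' @param artifacts Character vector of signature names designated artifactual.
#' @return `artifacts`, validated.
#' @export
artifact_set <- function(signatures, artifacts) {
  stopifnot(inherits(signatures, "signature_matrix"))
  artifacts <- as.character(artifacts)
  if (length(artifacts) == 0) stop("artifact set must be non-empty", call. = FALSE)
  missing <- setdiff(artifacts, colnames(signatures))
  if (length(missing) > 0) {
    stop("artifact signature(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unique(artifacts)
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("<signature_matrix> 96 channels x ", ncol(x), " signatures\n", sep = "")
  cat("signatures:", paste(utils::head(colnames(x), 8), collapse = ", "),
      if (ncol(x) > 8) "...", "\n")
  invisible(x)
}
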
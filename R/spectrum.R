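#' Build an SBS96 trinucleotide spectrum from a mutation set
#'
#' Tabulates mutation channels into the 96-class spectrum. The empty set is
#' allowed and yields an all-zero spectrum flagged degenerate; such spectra
#' cannot be fitted.
#'
#' @param mutations A mutation tibble with a `channel` column of SBS96 labels
#'   (as produced by [read_mutations()] or [sample_mutations()]).
#' @return An object of class `sbs_spectrum`: list with `counts` (named
#'   integer, length 96), `proportions` (sums to 1, or all zero when
#'   degenerate), `n`, and `degenerate`.
#' @export
build_spectrum <- function(mutations) {
  canon <- sbs96_channels()
  if (is.character(mutations)) {
    ch <- mutations
  } else {
    stopifnot(is.data.frame(mutations), "channel" %in% names(mutations))
    ch <- mutations$channel
  }
  bad <- setdiff(unique(ch), canon)
  if (length(bad) > 0) {
    stop("unknown channel label(s): ", paste(utils::head(bad, 3), collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(ch, levels = canon))
  counts <- stats::setNames(as.integer(counts), canon)
  n <- sum(counts)
  props <- if (n > 0) counts / n else stats::setNames(rep(0, 96), canon)
  structure(
    list(counts = counts, proportions = props, n = n, degenerate = n == 0L),
    class = "sbs_spectrum"
  )
}

#' @export
print.sbs_spectrum <- function(x, ...) {
  cat("<sbs_spectrum> n =", x$n,
      if (x$degenerate) "(degenerate: empty set)", "\n")
  top <- sort(x$proportions, decreasing = TRUE)[1:5]
  cat("top channels:", paste(sprintf("%s %.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Cosine similarity between two spectra
#'
#' @param a,b Numeric vectors of equal length with nonzero norm.
#' @return `a . b / (||a|| ||b||)`.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for a zero-norm (degenerate) spectrum",
         call. = FALSE)
  }
  sum(a * b) / (na * nb)
}

#' Refit a spectrum against reference signatures
#'
#' Non-negative least-squares deconvolution of an observed SBS96 spectrum
#' against a candidate subset of reference signature columns, with iterative
#' pruning: after each fit the weights are normalized to sum one and any
#' signature below `min_weight` is dropped, then the remaining candidates are
#' refitted; this repeats until the selected set is stable. The reported
#' cosine similarity is computed between the observed proportions and the
#' pruned, renormalized reconstruction; the cosine against the unpruned
#' reconstruction is recorded alongside.
#'
#' @param x An `sbs_spectrum` (or a mutation tibble, which is tabulated
#'   first). Must contain at least one mutation.
#' @param signatures A [signature_matrix()].
#' @param candidates Optional character vector restricting the fit to a subset
#'   of signature columns (default: all).
#' @param min_weight Minimum normalized weight a signature must retain to stay
#'   in the fit (default 0.06, the usual refitting convention).
#' @param opportunity Optional positive 96-vector of per-channel opportunity
#'   weights; observed proportions are divided by it (then renormalized)
#'   before fitting. Default none.
#' @return An object of class `signature_fit`: list with `signatures`
#'   (selected names), `weights` (named, non-negative, sums to 1), `cosine`,
#'   `cosine_unpruned`, `reconstruction` (96-vector direction of the fitted
#'   mixture), `observed` (96 proportions), and `n`.
#' @export
fit_signatures <- function(x, signatures, candidates = NULL, min_weight = 0.06,
                           opportunity = NULL) {
  if (!inherits(x, "sbs_spectrum")) x <- build_spectrum(x)
  stopifnot(inherits(signatures, "signature_matrix"))
  if (x$degenerate) {
    stop("cannot fit a degenerate (empty) spectrum", call. = FALSE)
  }
  if (is.null(candidates)) candidates <- colnames(signatures)
  if (length(candidates) == 0) stop("candidate signature subset is empty", call. = FALSE)
  missing <- setdiff(candidates, colnames(signatures))
  if (length(missing) > 0) {
    stop("candidate signature(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  target <- as.numeric(x$proportions)
  if (!is.null(opportunity)) {
    stopifnot(length(opportunity) == 96, all(opportunity > 0))
    target <- target / opportunity
    target <- target / sum(target)
  }

  nnls_weights <- function(cand) {
    A <- unclass(signatures)[, cand, drop = FALSE]
    w <- if (length(cand) == 1L) {
      # single-column least squares with non-negativity
      max(0, sum(A[, 1] * target) / sum(A[, 1]^2))
    } else {
      pracma::lsqnonneg(A, target)$x
    }
    stats::setNames(as.numeric(w), cand)
  }

  selected <- candidates
  w_raw <- nnls_weights(selected)
  if (sum(w_raw) <= 0) {
    stop("non-negative least squares returned an all-zero fit", call. = FALSE)
  }
  w_full_norm <- w_raw / sum(w_raw)
  recon_unpruned <- as.numeric(unclass(signatures)[, selected, drop = FALSE] %*% w_full_norm)
  cos_unpruned <- cosine_similarity(target, recon_unpruned)

  repeat {
    w_norm <- w_raw / sum(w_raw)
    keep <- names(w_norm)[w_norm >= min_weight]
    if (length(keep) == 0) keep <- names(which.max(w_norm))
    if (setequal(keep, selected)) break
    selected <- keep
    w_raw <- nnls_weights(selected)
    if (sum(w_raw) <= 0) {
      selected <- names(which.max(w_full_norm))
      w_raw <- nnls_weights(selected)
      break
    }
  }
  weights <- w_raw / sum(w_raw)
  weights <- weights[order(-weights)]
  recon <- as.numeric(unclass(signatures)[, names(weights), drop = FALSE] %*% weights)
  structure(
    list(
      signatures = names(weights),
      weights = weights,
      cosine = cosine_similarity(target, recon),
      cosine_unpruned = cos_unpruned,
      reconstruction = stats::setNames(recon, sbs96_channels()),
      observed = stats::setNames(target, sbs96_channels()),
      n = x$n,
      min_weight = min_weight
    ),
    class = "signature_fit"
  )
}

#' Summed weight of artifact signatures in a fit
#'
#' @param fit A `signature_fit`.
#' @param artifacts Character vector of artifact signature names.
#' @return Sum of fitted weights over selected signatures in `artifacts`,
#'   in \[0, 1\].
#' @export
artifact_weight <- function(fit, artifacts) {
  stopifnot(inherits(fit, "signature_fit"))
  sum(fit$weights[names(fit$weights) %in% artifacts])
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("<signature_fit> n =", x$n, " cosine =", sprintf("%.4f", x$cosine), "\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a signature fit
#'
#' @param x A `signature_fit`.
#' @param ... Unused.
#' @return A tibble with one row per selected signature: `signature`, `weight`.
#' @export
tidy.signature_fit <- function(x, ...) {
  tibble::tibble(signature = names(x$weights), weight = as.numeric(x$weights))
}

#' One-row summary of a signature fit
#'
#' @param x A `signature_fit`.
#' @param ... Unused.
#' @return Tibble with `n`, `n_signatures`, `cosine`, `cosine_unpruned`.
#' @export
glance.signature_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_signatures = length(x$weights),
    cosine = x$cosine,
    cosine_unpruned = x$cosine_unpruned
  )
}
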
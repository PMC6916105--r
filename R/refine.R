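# Partitioning, the four-term objective, candidate generation, and the
# preliminary gate. The GA itself lives in ga.R.

# subset a mutation_set keeping the parallel source-record attributes
subset_mutations <- function(mutations, idx) {
  out <- mutations[idx, , drop = FALSE]
  for (a in c("source", "meta", "samples", "config", "dropped")) {
    attr(out, a) <- attr(mutations, a)
  }
  fix <- attr(mutations, "fix"); gt <- attr(mutations, "gt")
  attr(out, "fix") <- if (!is.null(fix)) fix[idx, , drop = FALSE]
  attr(out, "gt") <- if (!is.null(gt)) gt[idx, , drop = FALSE]
  class(out) <- class(mutations)
  out
}

# logical pass vector for one filter at one cutoff
.filter_pass <- function(values, cutoff, direction, missing_policy) {
  ok <- if (direction == "keep_if_at_least") values >= cutoff else values <= cutoff
  ok[is.na(ok)] <- missing_policy == "pass_filter"
  ok
}

#' Split a mutation set by a conjunction of filter cutoffs
#'
#' A mutation lands in the refined set iff it satisfies every enabled filter's
#' cutoff in that filter's direction; the artifactual set is the complement.
#' Missing parameter values fail or pass per each filter's `missing_policy`.
#'
#' @param mutations A `mutation_set`.
#' @param cutoffs Named numeric vector with one cutoff per enabled filter.
#' @param config A `refinement_config` (default: the one attached to
#'   `mutations`).
#' @return List with `refined` and `artifactual` mutation sets; their row
#'   counts always sum to `nrow(mutations)`.
#' @export
partition_mutations <- function(mutations, cutoffs, config = attr(mutations, "config")) {
  stopifnot(inherits(config, "refinement_config"))
  filt <- enabled_filters(config)
  missing <- setdiff(filt$name, names(cutoffs))
  if (length(missing) > 0) {
    abort_config("cutoffs missing for enabled filter(s): ",
                 paste(missing, collapse = ", "))
  }
  pass <- rep(TRUE, nrow(mutations))
  for (i in seq_len(nrow(filt))) {
    f <- filt[i, ]
    pass <- pass & .filter_pass(mutations[[f$name]], cutoffs[[f$name]],
                                f$direction, f$missing_policy)
  }
  list(refined = subset_mutations(mutations, pass),
       artifactual = subset_mutations(mutations, !pass))
}

# objective from two channel-index count vectors; shared by the public
# objective and the GA's cached evaluator
.objective_from_counts <- function(counts_h, counts_l, signatures, artifacts,
                                   min_weight, components = FALSE) {
  n_h <- sum(counts_h); n_l <- sum(counts_l)
  if (n_h == 0 || n_l == 0) {
    if (!components) return(0)
    return(list(value = 0, cos_h = NA_real_, art_h = NA_real_,
                cos_l = NA_real_, art_l = NA_real_))
  }
  sp_h <- structure(list(counts = counts_h, proportions = counts_h / n_h,
                         n = n_h, degenerate = FALSE), class = "sbs_spectrum")
  sp_l <- structure(list(counts = counts_l, proportions = counts_l / n_l,
                         n = n_l, degenerate = FALSE), class = "sbs_spectrum")
  fit_h <- fit_signatures(sp_h, signatures, min_weight = min_weight)
  cos_h <- fit_h$cosine
  art_h <- artifact_weight(fit_h, artifacts)
  # M_l is fitted twice: against the artifact columns for its cosine and
  # against the full catalog for its artifact weight sum
  fit_l_art <- fit_signatures(sp_l, signatures, candidates = artifacts,
                              min_weight = min_weight)
  cos_l <- fit_l_art$cosine
  fit_l_full <- fit_signatures(sp_l, signatures, min_weight = min_weight)
  art_l <- artifact_weight(fit_l_full, artifacts)
  value <- max(0, cos_h) * (1 - art_h) * max(0, cos_l) * art_l
  if (!components) return(value)
  list(value = value, cos_h = cos_h, art_h = art_h, cos_l = cos_l, art_l = art_l)
}

#' Four-term refinement objective
#'
#' The score of a refined/artifactual split:
#' `cos_h * (1 - A_h) * cos_l_art * A_l`, where `cos_h` and `A_h` are the
#' cosine similarity and summed artifact weight of the refined set fitted
#' against the full catalog, `cos_l_art` is the artifactual set's cosine when
#' fitted against the artifact columns only, and `A_l` its summed artifact
#' weight when fitted against the full catalog. High when the refined
#' mutations look biological and the artifactual mutations look like
#' sequencing artifacts. A partition with an empty side scores 0; the value
#' always lies in \[0, 1\].
#'
#' @param refined,artifactual Mutation sets (tibbles with a `channel` column).
#' @param signatures A [signature_matrix()].
#' @param artifacts Character vector of artifact signature names.
#' @param min_weight Pruning threshold passed to [fit_signatures()].
#' @param components Return the four factors alongside the value?
#' @return A number in \[0, 1\], or a list when `components = TRUE`.
#' @export
objective_value <- function(refined, artifactual, signatures, artifacts,
                            min_weight = 0.06, components = FALSE) {
  counts_h <- build_spectrum(refined)$counts
  counts_l <- build_spectrum(artifactual)$counts
  .objective_from_counts(counts_h, counts_l, signatures, artifacts,
                         min_weight, components)
}

# grid of cutoff values traversed for one filter: integer parameters step by
# one when that takes <= 100 steps, otherwise 100 quantile steps; continuous
# parameters use `steps` quantile steps
.filter_grid <- function(values, value_type, steps = 20) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(numeric(0))
  lo <- min(values); hi <- max(values)
  if (lo == hi) return(lo)
  if (value_type == "integer" && (hi - lo) <= 100) {
    return(seq(ceiling(lo), floor(hi), by = 1))
  }
  n <- if (value_type == "integer") 100 else steps
  qs <- unique(stats::quantile(values, probs = seq(0, 1, length.out = n + 1),
                               names = FALSE, type = 7))
  if (value_type == "integer") unique(round(qs)) else qs
}

# loosest cutoff per enabled filter (everything passes)
.loosest_cutoffs <- function(mutations, filt) {
  vapply(seq_len(nrow(filt)), function(i) {
    v <- mutations[[filt$name[i]]]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(0)
    if (filt$direction[i] == "keep_if_at_least") min(v) else max(v)
  }, numeric(1)) |> stats::setNames(filt$name)
}

#' Generate single-filter candidate solutions
#'
#' Traverses each enabled filter from its minimum to maximum observed value
#' (all other filters held at their loosest bound), scores the induced
#' partition with [objective_value()], and returns every cutoff vector with a
#' nonzero objective, sorted by decreasing objective. These seed the genetic
#' algorithm so it starts from single-filter refinements that already work.
#'
#' @inheritParams partition_mutations
#' @inheritParams objective_value
#' @param steps Quantile steps per continuous filter (default 20).
#' @return Tibble with one column per enabled filter plus `filter` (the
#'   traversed one) and `objective`, sorted descending.
#' @export
generate_candidates <- function(mutations, config = attr(mutations, "config"),
                                signatures, artifacts, steps = 20,
                                min_weight = 0.06) {
  filt <- enabled_filters(config)
  if (nrow(filt) == 0) abort_config("no enabled filters")
  loosest <- .loosest_cutoffs(mutations, filt)
  ch_idx <- channel_index(mutations$channel)
  param <- sapply(filt$name, function(nm) as.numeric(mutations[[nm]]))
  if (!is.matrix(param)) param <- matrix(param, nrow = nrow(mutations))
  colnames(param) <- filt$name

  rows <- list()
  for (i in seq_len(nrow(filt))) {
    f <- filt[i, ]
    grid <- .filter_grid(param[, f$name], f$value_type, steps)
    for (g in grid) {
      cut <- loosest; cut[[f$name]] <- g
      pass <- .filter_pass(param[, f$name], g, f$direction, f$missing_policy)
      # other filters are at their loosest bound; only their missing values
      # can still fail a variant
      for (j in seq_len(nrow(filt))) {
        if (j == i) next
        pass <- pass & .filter_pass(param[, filt$name[j]], loosest[[filt$name[j]]],
                                    filt$direction[j], filt$missing_policy[j])
      }
      counts_h <- tabulate(ch_idx[pass], nbins = 96)
      counts_l <- tabulate(ch_idx[!pass], nbins = 96)
      obj <- .objective_from_counts(counts_h, counts_l, signatures, artifacts,
                                    min_weight)
      if (obj > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          !!!as.list(cut), filter = f$name, objective = obj)
      }
    }
  }
  if (length(rows) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      rep(list(numeric(0)), nrow(filt)), filt$name))
    out$filter <- character(0); out$objective <- numeric(0)
    return(out)
  }
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$objective))
}

#' Preliminary refinement gate
#'
#' Refinement is skipped when the input has fewer than `min_mutations` point
#' mutations (too few for a stable spectrum fit), or when the full set's
#' fitted artifact weight is already below `min_artifact_weight` (the calls
#' are deemed already refined).
#'
#' @inheritParams objective_value
#' @param mutations A `mutation_set`.
#' @param min_mutations Minimum number of point mutations (default 50).
#' @param min_artifact_weight Minimum initial summed artifact weight required
#'   to attempt refinement (default 0.05).
#' @return List with `decision` (`"proceed"`, `"skip_too_few"`, or
#'   `"skip_already_refined"`), `initial_fit` (a `signature_fit`, `NULL` when
#'   too few mutations), and `artifact_weight`.
#' @export
preliminary_check <- function(mutations, signatures, artifacts,
                              min_mutations = 50, min_artifact_weight = 0.05,
                              min_weight = 0.06) {
  if (nrow(mutations) < min_mutations) {
    return(list(decision = "skip_too_few", initial_fit = NULL,
                artifact_weight = NA_real_))
  }
  fit <- fit_signatures(build_spectrum(mutations), signatures,
                        min_weight = min_weight)
  aw <- artifact_weight(fit, artifacts)
  decision <- if (aw < min_artifact_weight) "skip_already_refined" else "proceed"
  list(decision = decision, initial_fit = fit, artifact_weight = aw)
}
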
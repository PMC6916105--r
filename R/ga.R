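#' Genetic-algorithm parameters
#'
#' Defaults follow the published run configuration (population 200, at most
#' 100 generations); the operator suite is a standard real-coded GA —
#' tournament selection, blend (BLX-0.5) crossover, bounded Gaussian
#' mutation, elitism — with early stopping after `stagnation_limit`
#' generations without improvement of the best-ever objective.
#'
#' @param population_size Number of cutoff vectors per generation (>= 2,
#'   default 200).
#' @param max_iterations Maximum generations (default 100).
#' @param crossover_rate Probability a selected parent pair is blended
#'   (default 0.8).
#' @param mutation_rate Per-gene probability of a bounded Gaussian
#'   perturbation (default 0.1).
#' @param elite_fraction Fraction of the population copied unchanged into the
#'   next generation (default 0.05).
#' @param stagnation_limit Generations without improvement before early stop
#'   (default 25).
#' @param seed RNG seed making the whole search reproducible (default 1).
#' @return A list of class `ga_params`.
#' @export
ga_params <- function(population_size = 200, max_iterations = 100,
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      elite_fraction = 0.05, stagnation_limit = 25,
                      seed = 1) {
  stopifnot(population_size >= 2, max_iterations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elite_fraction >= 0, elite_fraction <= 1)
  structure(list(population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elite_fraction = elite_fraction,
                 stagnation_limit = as.integer(stagnation_limit),
                 seed = as.integer(seed)),
            class = "ga_params")
}

#' Refine a mutation set by genetic-algorithm cutoff search
#'
#' Runs the full refinement: the preliminary gate, single-filter candidate
#' generation, and a seeded real-coded genetic algorithm over the cutoff
#' vectors (bounded by each parameter's observed range) maximizing
#' [objective_value()]. The initial population is the best candidate
#' solutions (at most half the population) topped up with uniform random
#' cutoff vectors. Because the elites always survive and the candidates seed
#' generation one, the returned objective is never below the best candidate
#' objective. Identical inputs and seed give identical results; objective
#' ties keep the earliest-found solution.
#'
#' @inheritParams generate_candidates
#' @param ga A [ga_params()] object.
#' @param min_mutations,min_artifact_weight Gate thresholds, see
#'   [preliminary_check()].
#' @param check Run the preliminary gate (default `TRUE`); when it skips, the
#'   result has `skipped` set and the whole input is returned as refined.
#' @return An object of class `refinement`: list with `best_solution`
#'   (named cutoffs), `best_objective`, `refined`, `artifactual`, `trace`
#'   (tibble: generation, best, mean, cutoffs), `candidates`, `initial_fit`,
#'   `refined_fit`, `artifact_fit` (full-catalog fits of the input, refined,
#'   and artifactual sets), `skipped` (`NA` or a reason), `ga`, `config`.
#' @export
refine_mutations <- function(mutations, config = attr(mutations, "config"),
                             signatures, artifacts, ga = ga_params(),
                             min_weight = 0.06, steps = 20,
                             min_mutations = 50, min_artifact_weight = 0.05,
                             check = TRUE) {
  stopifnot(inherits(config, "refinement_config"), inherits(ga, "ga_params"))
  artifacts <- artifact_set(signatures, artifacts)
  filt <- enabled_filters(config)
  if (nrow(filt) == 0) abort_config("no enabled filters to optimize")

  gate <- if (check) {
    preliminary_check(mutations, signatures, artifacts,
                      min_mutations = min_mutations,
                      min_artifact_weight = min_artifact_weight,
                      min_weight = min_weight)
  } else {
    list(decision = "proceed",
         initial_fit = fit_signatures(build_spectrum(mutations), signatures,
                                      min_weight = min_weight),
         artifact_weight = NA_real_)
  }
  if (gate$decision != "proceed") {
    empty <- subset_mutations(mutations, rep(FALSE, nrow(mutations)))
    return(structure(list(
      best_solution = NULL, best_objective = NA_real_,
      refined = mutations, artifactual = empty,
      trace = NULL, candidates = NULL,
      initial_fit = gate$initial_fit, refined_fit = gate$initial_fit,
      artifact_fit = NULL,
      initial_artifact_weight = gate$artifact_weight,
      skipped = gate$decision, ga = ga, config = config
    ), class = "refinement"))
  }

  candidates <- generate_candidates(mutations, config, signatures, artifacts,
                                    steps = steps, min_weight = min_weight)
  k <- nrow(filt)
  param <- sapply(filt$name, function(nm) as.numeric(mutations[[nm]]))
  if (!is.matrix(param)) param <- matrix(param, nrow = nrow(mutations))
  colnames(param) <- filt$name
  bounds <- t(apply(param, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) c(0, 0) else range(v)
  }))
  ch_idx <- channel_index(mutations$channel)
  miss_pass <- filt$missing_policy == "pass_filter"
  at_least <- filt$direction == "keep_if_at_least"
  # per-filter sorted thresholds: two cutoffs between the same adjacent
  # observed values induce the same partition, which keys the cache
  thresholds <- lapply(seq_len(k), function(j) sort(unique(param[, j])))
  cache <- new.env(parent = emptyenv())

  pass_vector <- function(x) {
    pass <- rep(TRUE, nrow(param))
    for (j in seq_len(k)) {
      ok <- if (at_least[j]) param[, j] >= x[j] else param[, j] <= x[j]
      ok[is.na(ok)] <- miss_pass[j]
      pass <- pass & ok
    }
    pass
  }
  evaluate <- function(x) {
    key <- paste(vapply(seq_len(k), function(j) {
      findInterval(x[j], thresholds[[j]], left.open = !at_least[j])
    }, numeric(1)), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    pass <- pass_vector(x)
    val <- .objective_from_counts(tabulate(ch_idx[pass], nbins = 96),
                                  tabulate(ch_idx[!pass], nbins = 96),
                                  signatures, artifacts, min_weight)
    cache[[key]] <- val
    val
  }

  res <- with_private_seed(ga$seed, {
    pop_n <- ga$population_size
    seed_n <- min(nrow(candidates), pop_n %/% 2L)
    pop <- matrix(0, nrow = pop_n, ncol = k)
    for (j in seq_len(k)) {
      pop[, j] <- stats::runif(pop_n, bounds[j, 1], bounds[j, 2])
    }
    if (seed_n > 0) {
      pop[seq_len(seed_n), ] <- as.matrix(candidates[seq_len(seed_n), filt$name,
                                                     drop = FALSE])
    }
    colnames(pop) <- filt$name
    best_x <- NULL; best_f <- -Inf; stagnant <- 0L
    trace <- vector("list", ga$max_iterations)
    n_elite <- max(1L, ceiling(ga$elite_fraction * pop_n))
    for (gen in seq_len(ga$max_iterations)) {
      fit <- apply(pop, 1, evaluate)
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_f) {
        best_f <- fit[gen_best]; best_x <- pop[gen_best, ]; stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }
      trace[[gen]] <- tibble::tibble(
        generation = gen, best = best_f, mean = mean(fit),
        !!!as.list(stats::setNames(best_x, filt$name)))
      if (stagnant >= ga$stagnation_limit || gen == ga$max_iterations) {
        trace <- dplyr::bind_rows(trace[seq_len(gen)])
        break
      }
      ord <- order(fit, decreasing = TRUE)
      elites <- pop[ord[seq_len(n_elite)], , drop = FALSE]
      tournament <- function() {
        cand <- sample.int(pop_n, 3)
        cand[which.max(fit[cand])]
      }
      children <- matrix(NA_real_, nrow = pop_n - n_elite, ncol = k)
      ci <- 1L
      while (ci <= nrow(children)) {
        p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
        if (stats::runif(1) < ga$crossover_rate) {
          # BLX-0.5 blend crossover
          lo <- pmin(p1, p2); hi <- pmax(p1, p2); d <- hi - lo
          c1 <- stats::runif(k, lo - 0.5 * d, hi + 0.5 * d)
          c2 <- stats::runif(k, lo - 0.5 * d, hi + 0.5 * d)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (ci > nrow(children)) break
          mut <- stats::runif(k) < ga$mutation_rate
          if (any(mut)) {
            child[mut] <- child[mut] +
              stats::rnorm(sum(mut), 0, 0.1 * (bounds[mut, 2] - bounds[mut, 1]))
          }
          children[ci, ] <- pmin(pmax(child, bounds[, 1]), bounds[, 2])
          ci <- ci + 1L
        }
      }
      pop <- rbind(elites, children)
    }
    list(best_x = stats::setNames(best_x, filt$name), best_f = best_f,
         trace = trace)
  })

  split <- partition_mutations(mutations, res$best_x, config)
  refined_fit <- if (nrow(split$refined) > 0) {
    fit_signatures(build_spectrum(split$refined), signatures,
                   min_weight = min_weight)
  }
  artifact_fit <- if (nrow(split$artifactual) > 0) {
    fit_signatures(build_spectrum(split$artifactual), signatures,
                   min_weight = min_weight)
  }
  structure(list(
    best_solution = res$best_x,
    best_objective = res$best_f,
    refined = split$refined,
    artifactual = split$artifactual,
    trace = res$trace,
    candidates = candidates,
    initial_fit = gate$initial_fit,
    refined_fit = refined_fit,
    artifact_fit = artifact_fit,
    initial_artifact_weight = gate$artifact_weight,
    skipped = NA_character_,
    ga = ga, config = config,
    artifacts = artifacts
  ), class = "refinement")
}

#' @export
print.refinement <- function(x, ...) {
  if (!is.na(x$skipped %||% NA_character_)) {
    cat("<refinement> skipped:", x$skipped, "\n")
    return(invisible(x))
  }
  cat("<refinement> ", nrow(x$refined), " refined / ", nrow(x$artifactual),
      " artifactual; objective = ", sprintf("%.4f", x$best_objective), "\n",
      sep = "")
  cat("cutoffs:", paste(sprintf("%s = %.4g", names(x$best_solution),
                                x$best_solution), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a refinement result
#'
#' @param x A `refinement`.
#' @param ... Unused.
#' @return Tibble with one row per enabled filter: `filter`, `cutoff`,
#'   `direction`.
#' @export
tidy.refinement <- function(x, ...) {
  filt <- enabled_filters(x$config)
  if (is.null(x$best_solution)) {
    return(tibble::tibble(filter = character(0), cutoff = numeric(0),
                          direction = character(0)))
  }
  tibble::tibble(filter = names(x$best_solution),
                 cutoff = as.numeric(x$best_solution),
                 direction = filt$direction[match(names(x$best_solution),
                                                  filt$name)])
}

#' One-row summary of a refinement result
#'
#' @param x A `refinement`.
#' @param ... Unused.
#' @return Tibble with counts, best objective, generations run, and the
#'   artifact-weight sums before/after (against the artifact set used).
#' @export
glance.refinement <- function(x, ...) {
  arts <- x$artifacts %||% character(0)
  tibble::tibble(
    n_input = nrow(x$refined) + nrow(x$artifactual),
    n_refined = nrow(x$refined),
    n_artifactual = nrow(x$artifactual),
    best_objective = x$best_objective,
    generations = if (is.null(x$trace)) NA_integer_ else max(x$trace$generation),
    artifact_weight_before = x$initial_artifact_weight %||% NA_real_,
    artifact_weight_after = if (!is.null(x$refined_fit) && length(arts) > 0)
      artifact_weight(x$refined_fit, arts) else NA_real_,
    skipped = x$skipped %||% NA_character_
  )
}
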
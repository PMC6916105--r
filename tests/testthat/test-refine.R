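test_that("partition applies the filter conjunction with its directions", {
  b <- bench_data()
  m <- b$mutations
  # loosest cutoffs keep everything
  loose <- c(vaf = min(m$vaf), bq = min(m$bq))
  split <- partition_mutations(m, loose)
  expect_identical(nrow(split$refined), nrow(m))
  expect_identical(nrow(split$artifactual), 0L)
  # a variant must satisfy every filter
  cut <- c(vaf = 0.05, bq = 0)
  toy <- m[1:2, ]
  toy$vaf <- c(0.04, 0.20); toy$bq <- c(30, 12)
  s <- partition_mutations(toy, cut, b$config)
  expect_identical(s$refined$key, toy$key[2])
  expect_identical(s$artifactual$key, toy$key[1])
  # conservation under random cutoffs
  set.seed(5)
  for (i in 1:20) {
    cuts <- c(vaf = runif(1, 0, 0.6), bq = runif(1, 0, 45))
    s <- partition_mutations(m, cuts)
    expect_identical(nrow(s$refined) + nrow(s$artifactual), nrow(m))
  }
  expect_error(partition_mutations(m, c(vaf = 0.1)), "bq",
               class = "sigrefine_config_error")
})

test_that("missing parameter values follow the missing policy", {
  b <- bench_data()
  m <- b$mutations[1:10, ]
  m$vaf[1:3] <- NA
  cut <- c(vaf = 0, bq = 0)
  s <- partition_mutations(m, cut, b$config)
  expect_identical(nrow(s$artifactual), 3L) # fail_filter default
  cfg2 <- b$config
  cfg2$filters$missing_policy[cfg2$filters$name == "vaf"] <- "pass_filter"
  s2 <- partition_mutations(m, cut, cfg2)
  expect_identical(nrow(s2$artifactual), 0L)
})

test_that("objective is bounded, degenerate partitions score zero", {
  b <- bench_data()
  m <- b$mutations
  empty <- m[0, ]
  expect_identical(objective_value(m, empty, fx_sigs, fx_arts), 0)
  expect_identical(objective_value(empty, m, fx_sigs, fx_arts), 0)
  set.seed(9)
  for (i in 1:50) {
    cuts <- c(vaf = runif(1, 0, 0.6), bq = runif(1, 0, 45))
    s <- partition_mutations(m, cuts)
    v <- objective_value(s$refined, s$artifactual, fx_sigs, fx_arts)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("identical artifact-free spectra on both sides score ~0", {
  smoke <- sample_mutations("SYN.SMOKE", 1000, tiny_fasta(), seed = 21)
  set.seed(22)
  half <- sample(nrow(smoke), 500)
  v <- objective_value(smoke[half, ], smoke[-half, ], fx_sigs, fx_arts)
  expect_lt(v, 1e-6)
})

test_that("a clean true/artifact split scores near one", {
  smoke <- sample_mutations("SYN.SMOKE", 1000, tiny_fasta(), seed = 23)
  oxog <- sample_mutations("SYN.OXOG", 1000, tiny_fasta(), seed = 24)
  v <- objective_value(smoke, oxog, fx_sigs, fx_arts, components = TRUE)
  expect_gte(v$value, 0.9)
  expect_gte(v$cos_h, 0.95)
  expect_lte(v$art_h, 0.05)
  expect_gte(v$art_l, 0.95)
})

test_that("candidate generation traverses each filter and finds the gap", {
  b <- bench_data()
  cand <- generate_candidates(b$mutations, b$config, fx_sigs, fx_arts)
  expect_true(all(cand$objective > 0))
  expect_false(is.unsorted(rev(cand$objective)))
  top_vaf <- cand[cand$filter == "vaf", ][1, ]
  expect_gte(top_vaf$vaf, 0.06)
  expect_lte(top_vaf$vaf, 0.15)
  # no variant separable by a filter -> no candidates from it
  m2 <- b$mutations
  m2$vaf <- 0.3
  m2$bq <- 30
  expect_identical(nrow(generate_candidates(m2, b$config, fx_sigs, fx_arts)), 0L)
})

test_that("the preliminary gate applies both thresholds", {
  b <- bench_data()
  m <- b$mutations
  expect_identical(preliminary_check(m[1:49, ], fx_sigs, fx_arts)$decision,
                   "skip_too_few")
  smoke <- sample_mutations("SYN.SMOKE", 500, tiny_fasta(), seed = 31)
  pure <- preliminary_check(smoke, fx_sigs, fx_arts)
  expect_identical(pure$decision, "skip_already_refined")
  expect_lt(pure$artifact_weight, 0.05)
  # 40% artifact contamination proceeds
  oxog <- sample_mutations("SYN.OXOG", 333, tiny_fasta(), seed = 32)
  mixed <- dplyr::bind_rows(smoke[1:500, ], oxog)
  mix <- preliminary_check(mixed, fx_sigs, fx_arts)
  expect_identical(mix$decision, "proceed")
  expect_gte(mix$artifact_weight, 0.05)
  # exactly 50 mutations proceeds past the count gate
  at50 <- preliminary_check(m[1:50, ], fx_sigs, fx_arts)
  expect_true(at50$decision %in% c("proceed", "skip_already_refined"))
  expect_false(is.null(at50$initial_fit))
})

test_that("the GA dominates its candidate seeds and is seed-deterministic", {
  b <- bench_data()
  ga <- ga_params(population_size = 30, max_iterations = 8, seed = 11)
  r1 <- refine_mutations(b$mutations, b$config, fx_sigs, fx_arts, ga = ga)
  expect_gte(r1$best_objective, max(r1$candidates$objective))
  r2 <- refine_mutations(b$mutations, b$config, fx_sigs, fx_arts, ga = ga)
  expect_identical(r1$best_solution, r2$best_solution)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$refined$key, r2$refined$key)
  # conservation and internal consistency
  expect_identical(nrow(r1$refined) + nrow(r1$artifactual), nrow(b$mutations))
  recomputed <- objective_value(r1$refined, r1$artifactual, fx_sigs, fx_arts)
  expect_equal(r1$best_objective, recomputed, tolerance = 1e-12)
})

test_that("refinement recovers the planted labels on the canonical benchmark", {
  b <- bench_data()
  res <- .bench$res_seed1
  if (is.null(res)) {
    res <- refine_mutations(b$mutations, b$config, fx_sigs, fx_arts,
                            ga = ga_params(seed = 1))
  }
  truth_class <- b$truth$class[match(b$mutations$key, b$truth$key)]
  refined <- b$mutations$key %in% res$refined$key
  sens <- mean(refined[truth_class == "true"])
  spec <- mean(!refined[truth_class == "artifact"])
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
  # the recovered vaf cutoff clears the artifact support entirely; its exact
  # position above the gap trades a small true-class tail for spectrum purity
  # (the objective rewards trimming low-quality true variants), so the upper
  # side is bounded by the sensitivity guarantee rather than the support edge
  expect_gt(res$best_solution[["vaf"]], 0.06)
  expect_lte(mean(!refined[truth_class == "true"]), 0.05)
  # artifact weight falls after refinement
  aw_before <- artifact_weight(res$initial_fit, fx_arts)
  aw_after <- artifact_weight(res$refined_fit, fx_arts)
  expect_lt(aw_after, aw_before)
  .bench$res_seed1 <- res
})

test_that("tidy and glance summarize a refinement", {
  b <- bench_data()
  res <- .bench$res_seed1
  if (is.null(res)) {
    res <- refine_mutations(b$mutations, b$config, fx_sigs, fx_arts,
                            ga = ga_params(seed = 1))
  }
  td <- tidy(res)
  expect_named(td, c("filter", "cutoff", "direction"))
  expect_setequal(td$filter, c("vaf", "bq"))
  gl <- glance(res)
  expect_identical(gl$n_input, nrow(b$mutations))
  expect_lt(gl$artifact_weight_after, gl$artifact_weight_before)
})
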
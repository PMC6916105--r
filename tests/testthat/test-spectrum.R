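test_that("build_spectrum tabulates channels and handles the empty set", {
  empty <- build_spectrum(character(0))
  expect_true(empty$degenerate)
  expect_identical(sum(empty$counts), 0L)
  three <- build_spectrum(rep("A[C>A]A", 3))
  expect_identical(unname(three$counts[1]), 3L)
  expect_identical(unname(three$proportions[1]), 1)
  expect_identical(three$n, 3L)
  expect_error(build_spectrum("B[C>A]A"), "unknown channel")
})

test_that("large multinomial samples reproduce the generating distribution", {
  p <- as.numeric(fx_sigs[, "SYN.SMOKE"])
  set.seed(7)
  draws <- sample(sbs96_channels(), 10000, replace = TRUE, prob = p)
  sp <- build_spectrum(draws)
  expect_lte(max(abs(sp$proportions - p)), 0.02)
  expect_identical(sum(sp$counts), 10000L)
})

test_that("cosine similarity matches hand computations", {
  v <- c(1, 2, 3, rep(0, 93))
  w <- c(3, 2, 1, rep(0, 93))
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(v, w), 10 / 14)
  disjoint <- c(rep(0, 3), 1, rep(0, 92))
  expect_equal(cosine_similarity(v, disjoint), 0)
  expect_error(cosine_similarity(v, rep(0, 96)), "degenerate")
})

test_that("a pure signature spectrum is recovered exactly", {
  sp <- structure(list(counts = NULL, proportions = fx_sigs[, "SYN.OXOG"],
                       n = 1000L, degenerate = FALSE), class = "sbs_spectrum")
  fit <- fit_signatures(sp, fx_sigs)
  expect_identical(fit$signatures, "SYN.OXOG")
  expect_equal(unname(fit$weights), 1)
  expect_equal(fit$cosine, 1, tolerance = 1e-9)
})

test_that("two-signature mixtures match the exhaustive simplex oracle", {
  A <- unclass(fx_sigs)[, c("SYN.SMOKE", "SYN.OXOG")]
  for (w1 in c(0.7, 0.5, 0.2)) {
    target <- as.numeric(A %*% c(w1, 1 - w1))
    sp <- structure(list(proportions = target, n = 1000L, degenerate = FALSE),
                    class = "sbs_spectrum")
    fit <- fit_signatures(sp, fx_sigs,
                          candidates = c("SYN.SMOKE", "SYN.OXOG"),
                          min_weight = 0)
    oracle <- grid_fit_oracle(target, A)
    expect_lte(max(abs(fit$weights[colnames(A)] - oracle)), 2e-3)
    expect_lte(abs(fit$weights[["SYN.SMOKE"]] - w1), 0.01)
  }
})

test_that("three-signature noisy mixtures match the oracle within 2e-3", {
  A <- unclass(fx_sigs)[, c("SYN.SMOKE", "SYN.OXOG", "SYN.FFPE")]
  set.seed(11)
  for (i in 1:3) {
    w <- c(0.5, 0.3, 0.2)[sample(3)]
    mix <- as.numeric(A %*% w)
    counts <- as.integer(rmultinom(1, 5000, mix))
    target <- counts / sum(counts)
    sp <- structure(list(proportions = target, n = 5000L, degenerate = FALSE),
                    class = "sbs_spectrum")
    fit <- fit_signatures(sp, fx_sigs, candidates = colnames(A), min_weight = 0)
    oracle <- grid_fit_oracle(target, A)
    got <- sapply(colnames(A), function(s) {
      w <- unname(fit$weights[s])
      ifelse(is.na(w), 0, w)
    })
    expect_lte(max(abs(got - oracle)), 2e-3)
  }
})

test_that("restricting candidates forces weight onto the allowed signature", {
  target <- as.numeric(fx_sigs[, "SYN.SMOKE"])
  sp <- structure(list(proportions = target, n = 500L, degenerate = FALSE),
                  class = "sbs_spectrum")
  fit <- fit_signatures(sp, fx_sigs, candidates = "SYN.OXOG")
  expect_equal(unname(fit$weights), 1)
  c_expected <- cosine_similarity(fx_sigs[, "SYN.SMOKE"], fx_sigs[, "SYN.OXOG"])
  expect_equal(fit$cosine, c_expected, tolerance = 1e-9)
  expect_error(fit_signatures(sp, fx_sigs, candidates = character(0)), "empty")
})

test_that("fitting is scale invariant and pruning is monotone", {
  A <- unclass(fx_sigs)
  target <- as.numeric(A %*% c(0.55, 0.25, 0.15, 0.05))
  sp <- function(t) structure(list(proportions = t, n = 1000L, degenerate = FALSE),
                              class = "sbs_spectrum")
  f1 <- fit_signatures(sp(target), fx_sigs, min_weight = 0)
  f2 <- fit_signatures(sp(target * 7), fx_sigs, min_weight = 0)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-9)
  expect_equal(f1$cosine, f2$cosine, tolerance = 1e-12)
  # min_weight 0 keeps everything with positive weight; raising it never
  # grows the selected set
  sizes <- sapply(c(0, 0.06, 0.1, 0.2, 0.5),
                  function(mw) length(fit_signatures(sp(target), fx_sigs,
                                                     min_weight = mw)$signatures))
  expect_identical(sizes[1], 4L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("artifact weight sums the selected artifact signatures", {
  A <- unclass(fx_sigs)
  target <- as.numeric(A %*% c(0.75, 0.25, 0, 0))
  sp <- structure(list(proportions = target, n = 1000L, degenerate = FALSE),
                  class = "sbs_spectrum")
  fit <- fit_signatures(sp, fx_sigs, min_weight = 0)
  expect_equal(artifact_weight(fit, fx_arts), 0.25, tolerance = 5e-3)
  # pure non-artifact fit
  pure <- fit_signatures(
    structure(list(proportions = as.numeric(fx_sigs[, "SYN.SMOKE"]), n = 100L,
                   degenerate = FALSE), class = "sbs_spectrum"), fx_sigs)
  expect_equal(artifact_weight(pure, fx_arts), 0)
  # simulated pure artifact sample scores >= 0.95
  sampled <- sample_mutations("SYN.OXOG", 2000, tiny_fasta(), seed = 5)
  afit <- fit_signatures(build_spectrum(sampled), fx_sigs)
  expect_gte(artifact_weight(afit, fx_arts), 0.95)
})

test_that("tidy and glance expose the fit as tibbles", {
  fit <- fit_signatures(
    structure(list(proportions = as.numeric(fx_sigs[, "SYN.FFPE"]), n = 10L,
                   degenerate = FALSE), class = "sbs_spectrum"), fx_sigs)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("signature", "weight"))
  expect_equal(sum(td$weight), 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$cosine, fit$cosine)
})

test_that("degenerate spectra are refused", {
  expect_error(fit_signatures(build_spectrum(character(0)), fx_sigs),
               "degenerate")
})
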
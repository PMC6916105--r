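mut_with_counts <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  tibble::tibble(
    key = paste0("chr1:", seq_along(ref_fwd), ":C:A"),
    ref_fwd = ref_fwd, ref_rev = ref_rev, alt_fwd = alt_fwd, alt_rev = alt_rev
  )
}

test_that("strand-bias p-values match exact hypergeometric enumeration", {
  # proportional strands: no evidence of bias
  m <- mut_with_counts(10, 10, 5, 5)
  res <- strand_bias_test(m)
  expect_equal(res$p_value, 1)
  # all alternate reads on one strand
  m2 <- mut_with_counts(10, 10, 20, 0)
  res2 <- strand_bias_test(m2)
  expect_equal(res2$p_value, fisher_oracle(10, 10, 20, 0), tolerance = 1e-9)
  # a spread of tables against the enumeration oracle
  tables <- list(c(3, 7, 9, 1), c(12, 8, 2, 14), c(0, 5, 5, 0), c(6, 6, 6, 6))
  for (tb in tables) {
    got <- strand_bias_test(mut_with_counts(tb[1], tb[2], tb[3], tb[4]))$p_value
    expect_equal(got, fisher_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-9)
  }
})

test_that("q-values are a Benjamini-Hochberg step-up of the p-values", {
  set.seed(13)
  n <- 40
  m <- mut_with_counts(rpois(n, 10), rpois(n, 10), rpois(n, 4),
                       rbinom(n, 4, 0.3))
  res <- strand_bias_test(m)
  expect_equal(res$q_value, bh_oracle(res$p_value), tolerance = 1e-12)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  # constant p = 1 stays 1 after correction
  res1 <- strand_bias_test(mut_with_counts(rep(10, 100), rep(10, 100),
                                           rep(5, 100), rep(5, 100)))
  expect_true(all(res1$q_value == 1))
  # single test: q equals p
  single <- strand_bias_test(mut_with_counts(10, 10, 20, 0))
  expect_equal(single$q_value, single$p_value)
})

test_that("variants without counts are skipped; negative counts refused", {
  m <- mut_with_counts(c(10, NA, 8), c(10, 5, 9), c(5, 5, 2), c(5, 5, 3))
  res <- strand_bias_test(m)
  expect_identical(nrow(res), 2L)
  expect_identical(attr(res, "n_skipped"), 1L)
  bad <- mut_with_counts(-1, 10, 5, 5)
  expect_error(strand_bias_test(bad), "negative",
               class = "sigrefine_format_error")
})

test_that("parameter tests distinguish separated and identical distributions", {
  b <- bench_data()
  cfg <- b$config
  mk <- function(vaf, bq) {
    tibble::tibble(key = paste0("k", seq_along(vaf)), vaf = vaf, bq = bq)
  }
  set.seed(17)
  # complete separation: rank-sum U = 0, p astronomically small
  m_h <- mk(runif(50, 0.2, 0.5), rnorm(50, 35, 2))
  m_l <- mk(runif(50, 0.01, 0.05), rnorm(50, 35, 2))
  res <- parameter_tests(dplyr::bind_rows(m_h, m_l), m_h, m_l, cfg)
  p_vaf <- res$p_value[res$filter == "vaf" &
                         res$comparison == "refined_vs_artifactual"]
  expect_lt(p_vaf, 1e-10)
  # identical distributions: p not extreme
  m_l2 <- mk(runif(200, 0.2, 0.5), rnorm(200, 35, 2))
  m_h2 <- mk(runif(200, 0.2, 0.5), rnorm(200, 35, 2))
  res2 <- parameter_tests(dplyr::bind_rows(m_h2, m_l2), m_h2, m_l2, cfg)
  expect_gt(min(res2$p_value[res2$comparison == "refined_vs_artifactual"]),
            0.001)
  # one empty side: NA, no crash
  res3 <- parameter_tests(m_h, m_h, m_h[0, ], cfg)
  expect_true(all(is.na(
    res3$p_value[res3$comparison == "refined_vs_artifactual"])))
  expect_identical(nrow(res3), 6L) # 2 filters x 3 comparisons
})

test_that("motif profiles count reference bases around variants", {
  fa <- tiny_fasta()
  ref <- read_reference(fa)
  seq1 <- as.character(ref[[1]])
  # all variants at reference C: position 0 frequency of C is 1
  c_pos <- gregexpr("C", substr(seq1, 100, 5000))[[1]] + 99
  m <- tibble::tibble(chrom = "chr1", pos = as.integer(c_pos[1:200]))
  prof <- motif_profile(m, fa)
  at0 <- prof[prof$position == 0, ]
  expect_equal(at0$frequency[at0$base == "C"], 1)
  # frequencies sum to one at every position
  sums <- tapply(prof$frequency, prof$position, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_identical(length(unique(prof$position)), 21L)
  # planted G-rich +1 flanks stand out against the ~25% background
  g_next <- which(strsplit(seq1, "")[[1]] == "G")
  g_next <- g_next[g_next > 11 & g_next < nchar(seq1) - 11]
  set.seed(19)
  n_bias <- 140; n_other <- 60
  pos_biased <- sample(g_next - 1L, n_bias)      # +1 base is G
  pos_other <- sample(setdiff(500:50000, c(pos_biased, g_next - 1L)), n_other)
  mg <- tibble::tibble(chrom = "chr1", pos = as.integer(c(pos_biased, pos_other)))
  profg <- motif_profile(mg, fa)
  g_at1 <- profg$frequency[profg$position == 1 & profg$base == "G"]
  expect_gte(g_at1, 0.6)
  # variants at contig edges are skipped and tallied
  edge <- tibble::tibble(chrom = "chr1", pos = c(3L, 1000L))
  prof_edge <- motif_profile(edge, fa)
  expect_identical(attr(prof_edge, "n_skipped"), 1L)
})

test_that("rescue moves matching artifacts and conserves the total", {
  b <- bench_data()
  res <- .bench$res_seed1
  if (is.null(res)) {
    res <- refine_mutations(b$mutations, b$config, fx_sigs, fx_arts,
                            ga = ga_params(seed = 1))
    .bench$res_seed1 <- res
  }
  art <- res$artifactual
  # empty table: nothing moves
  empty <- tibble::tibble(key = character(0), label = character(0))
  r0 <- rescue_variants(art, empty)
  expect_identical(nrow(r0$moved), 0L)
  expect_identical(nrow(r0$remaining), nrow(art))
  # one matching entry moves exactly once, flagged
  tbl <- tibble::tibble(chrom = art$chrom[5], pos = art$pos[5],
                        ref = art$ref[5], alt = art$alt[5], label = "pathogenic")
  p <- tempfile(fileext = ".tsv")
  write.table(tbl, p, sep = "\t", quote = FALSE, row.names = FALSE)
  r1 <- rescue_variants(art, p)
  expect_identical(nrow(r1$moved), 1L)
  expect_true(all(r1$moved$rescued))
  expect_identical(nrow(r1$moved) + nrow(r1$remaining), nrow(art))
  expect_false(r1$moved$key %in% r1$remaining$key)
  # malformed rows are skipped with a warning
  bad <- rbind(tbl, tibble::tibble(chrom = "chr1", pos = NA, ref = "Z",
                                   alt = "A", label = "x"))
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(tb2 <- read_rescue_table(p), "malformed")
  expect_identical(nrow(tb2), 1L)
})
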
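small_ga <- function(seed = 2) ga_params(population_size = 30,
                                         max_iterations = 8, seed = seed)

test_that("an end-to-end run produces the full output bundle", {
  b <- bench_data()
  out <- tempfile("run")
  r <- run_refinement(b$sim$vcf, b$sim$fasta, b$config,
                      signatures = fx_sigs, artifacts = fx_arts,
                      out_dir = out, ga = small_ga())
  files <- list.files(out)
  expect_true(all(c("output.refined.vcf", "output.artifactual.vcf",
                    "optimization_log.tsv", "summary.json", "manifest.json",
                    "report.html") %in% files))
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_identical(summ$decision, "proceed")
  expect_identical(summ$n_refined + summ$n_artifactual, summ$n_input)
  expect_lt(summ$artifact_weight_after, summ$artifact_weight_before)
  # summary and refinement object agree (single source of truth)
  expect_equal(summ$best_objective, r$result$best_objective, tolerance = 1e-12)
  expect_equal(summ$cutoffs$vaf, r$result$best_solution[["vaf"]],
               tolerance = 1e-12)
  # log has one row per generation with the cutoff columns
  log <- read.delim(file.path(out, "optimization_log.tsv"))
  expect_identical(nrow(log), as.integer(summ$generations))
  expect_true(all(c("generation", "best", "mean", "vaf", "bq") %in% names(log)))
  # report mentions every sibling output by name
  html <- paste(readLines(file.path(out, "report.html")), collapse = "\n")
  for (f in c("output.refined.vcf", "output.artifactual.vcf", "summary.json")) {
    expect_match(html, f, fixed = TRUE)
  }
})

test_that("reruns with the same manifest give identical VCF digests", {
  b <- bench_data()
  out1 <- tempfile("runA"); out2 <- tempfile("runB")
  for (o in c(out1, out2)) {
    run_refinement(b$sim$vcf, b$sim$fasta, b$config, signatures = fx_sigs,
                   artifacts = fx_arts, out_dir = o, ga = small_ga(),
                   report = FALSE)
  }
  for (f in c("output.refined.vcf", "output.artifactual.vcf")) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))))
  }
  m1 <- jsonlite::read_json(file.path(out1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(out2, "manifest.json"))
  expect_identical(m1$digests, m2$digests)
  expect_identical(m1$decision, "proceed")
})

test_that("too few mutations refuses refinement but reports why", {
  fa <- tempfile(fileext = ".fasta")
  make_reference(fa, 100000, seed = 51)
  m49 <- sample_mutations("SYN.OXOG", 49, fa, seed = 52)
  body <- paste("chr1", m49$pos, ".", m49$ref, m49$alt, ".", "PASS", "BQ=20",
                "GT:AF:DP:SC", "0/1:0.05:60:28,28,3,1", "0/0:0.0:50:25,25,0,0",
                sep = "\t")
  vcf <- write_tiny_vcf(tempfile(fileext = ".vcf"), body)
  out <- tempfile("skip")
  r <- run_refinement(vcf, fa, generic_sim_config(), signatures = fx_sigs,
                      artifacts = fx_arts, out_dir = out, ga = small_ga())
  expect_identical(r$result$skipped, "skip_too_few")
  expect_false(file.exists(file.path(out, "output.refined.vcf")))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(manifest$decision, "skip_too_few")
  html <- paste(readLines(file.path(out, "report.html")), collapse = "\n")
  expect_match(html, "skipped", ignore.case = TRUE)
})

test_that("already-refined input is passed through unchanged", {
  sim <- simulate_dataset(sim_spec(n_true = 200, n_artifact = 0,
                                   contig_length = 100000, seed = 53),
                          tempfile("pure"))
  out <- tempfile("passthrough")
  r <- run_refinement(sim$vcf, sim$fasta, generic_sim_config(),
                      signatures = fx_sigs, artifacts = fx_arts,
                      out_dir = out, ga = small_ga())
  expect_identical(r$result$skipped, "skip_already_refined")
  n_ref <- length(grep("^[^#]",
                       readLines(file.path(out, "output.refined.vcf"))))
  expect_identical(n_ref, 200L)
  n_art <- length(grep("^[^#]",
                       readLines(file.path(out, "output.artifactual.vcf"))))
  expect_identical(n_art, 0L)
})

test_that("rescued variants land in the refined VCF with the INFO flag", {
  b <- bench_data()
  base <- run_refinement(b$sim$vcf, b$sim$fasta, b$config, signatures = fx_sigs,
                         artifacts = fx_arts, out_dir = tempfile("r0"),
                         ga = small_ga(), report = FALSE)
  art <- base$result$artifactual
  tbl <- tibble::tibble(chrom = art$chrom[1:3], pos = art$pos[1:3],
                        ref = art$ref[1:3], alt = art$alt[1:3],
                        label = "pathogenic")
  rt <- tempfile(fileext = ".tsv")
  write.table(tbl, rt, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- tempfile("rescue")
  r <- run_refinement(b$sim$vcf, b$sim$fasta, b$config, signatures = fx_sigs,
                      artifacts = fx_arts, out_dir = out, ga = small_ga(),
                      rescue_table = rt, report = FALSE)
  expect_identical(r$summary$n_rescued, 3L)
  lines <- readLines(file.path(out, "output.refined.vcf"))
  flagged <- grep("SIGREFINE_RESCUE", lines, value = TRUE)
  flagged <- flagged[!startsWith(flagged, "#")]
  expect_identical(length(flagged), 3L)
  # conservation across the two files still holds
  n_ref <- length(grep("^[^#]", lines))
  n_art <- length(grep("^[^#]",
                       readLines(file.path(out, "output.artifactual.vcf"))))
  expect_identical(n_ref + n_art, nrow(b$mutations))
})
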
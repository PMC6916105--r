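#' End-to-end refinement run
#'
#' Single entry point: reads the inputs, applies the preliminary gate, runs
#' the genetic-algorithm refinement, the post-hoc analyses (strand bias,
#' per-filter significance, motif profiles, clinical rescue), and writes the
#' output bundle to `out_dir`:
#'
#' * `refined.vcf` / `artifactual.vcf` — the partition (rescued variants go
#'   to the refined file with a `SIGREFINE_RESCUE` INFO flag);
#' * `optimization_log.tsv` — one row per generation;
#' * `summary.json` — machine-readable result (single source of truth for
#'   the report);
#' * `manifest.json` — inputs, digests, parameters, gate decision;
#' * `report.html` — human-readable report.
#'
#' When the gate decides `skip_already_refined`, the input is copied to the
#' refined output unchanged and the report explains why. When it decides
#' `skip_too_few`, no VCFs are written and the manifest/report state the
#' reason; the CLI maps this to a failure exit.
#'
#' @param vcf,fasta Input VCF and reference FASTA paths.
#' @param config Filter configuration (path or `refinement_config`).
#' @param signatures Reference catalog (path or `signature_matrix`; default
#'   the packaged synthetic COSMIC-shaped catalog).
#' @param artifacts Artifact signature names (default
#'   [default_artifact_signatures()] of the catalog).
#' @param out_dir Output directory (created if needed).
#' @param ga A [ga_params()].
#' @param min_mutations,min_artifact_weight,min_weight Gate and fit
#'   thresholds.
#' @param pass_only Restrict input to FILTER == PASS records.
#' @param rescue_table Optional rescue table path or tibble.
#' @param report Render the HTML report (default `TRUE`).
#' @return Invisibly, a list with the `refinement` object, post-hoc results,
#'   the manifest, and output paths.
#' @export
run_refinement <- function(vcf, fasta, config,
                           signatures = NULL, artifacts = NULL,
                           out_dir, ga = ga_params(),
                           min_mutations = 50, min_artifact_weight = 0.05,
                           min_weight = 0.06, pass_only = FALSE,
                           rescue_table = NULL, report = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(config)) config <- read_filter_config(config)
  sig_path <- NULL
  if (is.null(signatures)) {
    sig_path <- system.file("extdata", "synthetic_sbs_catalog_v3shape.tsv",
                            package = "sigrefine", mustWork = TRUE)
    signatures <- read_signature_matrix(sig_path)
  } else if (is.character(signatures)) {
    sig_path <- signatures
    signatures <- read_signature_matrix(signatures)
  }
  if (is.null(artifacts)) artifacts <- default_artifact_signatures(signatures)
  artifacts <- artifact_set(signatures, artifacts)

  mutations <- read_mutations(vcf, fasta, config, pass_only = pass_only)
  result <- refine_mutations(mutations, config, signatures, artifacts, ga = ga,
                             min_weight = min_weight,
                             min_mutations = min_mutations,
                             min_artifact_weight = min_artifact_weight)

  paths <- list(summary = file.path(out_dir, "summary.json"),
                manifest = file.path(out_dir, "manifest.json"),
                report = file.path(out_dir, "report.html"))
  posthoc <- NULL
  rescued <- NULL
  if (is.na(result$skipped) || result$skipped == "skip_already_refined") {
    refined <- result$refined
    artifactual <- result$artifactual
    if (!is.null(rescue_table) && nrow(artifactual) > 0) {
      r <- rescue_variants(artifactual, rescue_table)
      rescued <- r$moved
      refined <- bind_mutation_sets(refined, r$moved)
      artifactual <- r$remaining
      result$refined <- refined
      result$artifactual <- artifactual
    }
    vcf_paths <- write_partition(refined, artifactual,
                                 file.path(out_dir, "output"),
                                 cutoffs = result$best_solution)
    paths$refined_vcf <- vcf_paths[["refined"]]
    paths$artifactual_vcf <- vcf_paths[["artifactual"]]
    posthoc <- list(
      strand_bias = strand_bias_test(mutations),
      parameter_tests = if (nrow(artifactual) > 0)
        parameter_tests(mutations, refined, artifactual, config),
      motif_refined = motif_profile(refined, fasta),
      motif_artifactual = if (nrow(artifactual) > 0)
        motif_profile(artifactual, fasta),
      rescued = rescued
    )
  }
  if (is.na(result$skipped) && !is.null(result$trace)) {
    paths$log <- file.path(out_dir, "optimization_log.tsv")
    utils::write.table(result$trace, paths$log, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  manifest <- run_manifest(vcf, fasta, sig_path, config, ga, result)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  summary <- .run_summary(result, posthoc, artifacts)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (report) {
    render_report(result, posthoc, manifest, paths$report, artifacts = artifacts,
                  out_paths = paths)
  }
  invisible(list(result = result, posthoc = posthoc, manifest = manifest,
                 summary = summary, paths = paths))
}

#' Build a run manifest
#'
#' Records the inputs (with md5 digests), parameters, package version, and
#' the gate decision; digests are recomputable from the inputs, and no
#' timestamp-free field differs between identical reruns.
#'
#' @param vcf,fasta,sig_path Input paths (`sig_path` may be `NULL`).
#' @param config A `refinement_config`.
#' @param ga A `ga_params`.
#' @param result A `refinement`.
#' @return A named list.
#' @export
run_manifest <- function(vcf, fasta, sig_path, config, ga, result) {
  digest <- function(p) {
    if (is.null(p) || !is.character(p) || !file.exists(p)) NA_character_
    else unname(tools::md5sum(p))
  }
  list(
    tool = "sigrefine",
    version = as.character(utils::packageVersion("sigrefine")),
    inputs = list(vcf = vcf, fasta = fasta, signatures = sig_path),
    digests = list(vcf = digest(vcf), fasta = digest(fasta),
                   signatures = digest(sig_path)),
    filters = config$filters$name[config$filters$enabled],
    ga = unclass(ga),
    decision = if (is.na(result$skipped)) "proceed" else result$skipped
  )
}

.run_summary <- function(result, posthoc, artifacts) {
  g <- glance.refinement(result)
  list(
    decision = if (is.na(result$skipped)) "proceed" else result$skipped,
    n_input = g$n_input,
    n_refined = g$n_refined,
    n_artifactual = g$n_artifactual,
    best_objective = g$best_objective,
    cutoffs = if (!is.null(result$best_solution)) as.list(result$best_solution),
    generations = g$generations,
    artifact_weight_before = result$initial_artifact_weight,
    artifact_weight_after = if (!is.null(result$refined_fit))
      artifact_weight(result$refined_fit, artifacts) else NA_real_,
    n_rescued = if (!is.null(posthoc$rescued)) nrow(posthoc$rescued) else 0L,
    n_strand_bias_q05 = if (!is.null(posthoc$strand_bias))
      sum(posthoc$strand_bias$q_value < 0.05) else NA_integer_
  )
}
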
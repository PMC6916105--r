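# Static single-file HTML report with base64-embedded PNG figures.

.png_b64 <- function(plot, width = 900, height = 340) {
  if (is.null(plot) || !capabilities("png")) return(NULL)
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f))
  grDevices::png(f, width = width, height = height, res = 96)
  ok <- tryCatch({ print(plot); TRUE },
                 error = function(e) FALSE)
  grDevices::dev.off()
  if (!ok || !file.exists(f)) return(NULL)
  jsonlite::base64_enc(readBin(f, "raw", file.size(f)))
}

.html_img <- function(b64, alt) {
  if (is.null(b64)) return(sprintf("<p><em>%s: not computed</em></p>", alt))
  sprintf("<img alt=\"%s\" src=\"data:image/png;base64,%s\" style=\"max-width:100%%\">",
          alt, gsub("\n", "", b64))
}

.html_table <- function(df, digits = 4) {
  if (is.null(df) || nrow(df) == 0) return("<p><em>not computed</em></p>")
  fmt <- function(x) {
    if (is.numeric(x)) signif(x, digits) else x
  }
  df <- as.data.frame(lapply(df, fmt), check.names = FALSE,
                      stringsAsFactors = FALSE)
  head <- paste0("<tr>", paste0("<th>", names(df), "</th>", collapse = ""), "</tr>")
  rows <- apply(df, 1, function(r) {
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
  })
  paste0("<table>", head, paste(rows, collapse = ""), "</table>")
}

#' Render the refinement report
#'
#' Writes a single static HTML file covering the whole run: before/after
#' 96-channel spectra, signature-weight tables with artifact sums, the
#' objective trace, the cutoff table with per-filter significance, the
#' strand-bias summary, motif-profile panels, and the rescue list. Sections
#' without data render as "not computed".
#'
#' @param result A `refinement`.
#' @param posthoc Post-hoc result list from [run_refinement()] (may be
#'   `NULL`).
#' @param manifest Manifest list from [run_manifest()].
#' @param path Output HTML path.
#' @param artifacts Artifact signature names (for highlighting and sums).
#' @param out_paths Optional named list of sibling output files, linked by
#'   relative path.
#' @return `path`, invisibly.
#' @export
render_report <- function(result, posthoc, manifest, path,
                          artifacts = character(0), out_paths = NULL) {
  sec <- function(title, body) {
    c(sprintf("<h2>%s</h2>", title), body)
  }
  fit_tbl <- function(fit) {
    if (is.null(fit)) return(NULL)
    df <- tidy(fit)
    df$artifact <- df$signature %in% artifacts
    df
  }
  aw <- function(fit) if (is.null(fit)) NA_real_ else artifact_weight(fit, artifacts)

  skipped <- !is.na(result$skipped %||% NA_character_)
  spectra <- list()
  spectra$initial <- if (!is.null(result$initial_fit)) {
    .html_img(.png_b64(autoplot(
      structure(list(counts = NULL,
                     proportions = result$initial_fit$observed,
                     n = result$initial_fit$n, degenerate = FALSE),
                class = "sbs_spectrum"),
      title = "Unrefined mutations")), "unrefined spectrum")
  } else "<p><em>not computed</em></p>"
  spectra$refined <- if (!skipped && !is.null(result$refined_fit)) {
    .html_img(.png_b64(autoplot(build_spectrum(result$refined),
                                title = "Refined mutations")),
              "refined spectrum")
  } else "<p><em>not computed</em></p>"
  spectra$artifactual <- if (!skipped && nrow(result$artifactual) > 0) {
    .html_img(.png_b64(autoplot(build_spectrum(result$artifactual),
                                title = "Artifactual mutations")),
              "artifactual spectrum")
  } else "<p><em>not computed</em></p>"

  weights_html <- paste0(
    "<h3>Unrefined (artifact weight sum = ",
    sprintf("%.3f", aw(result$initial_fit)), ")</h3>",
    .html_table(fit_tbl(result$initial_fit)),
    if (!skipped) paste0(
      "<h3>Refined (artifact weight sum = ",
      sprintf("%.3f", aw(result$refined_fit)), ")</h3>",
      .html_table(fit_tbl(result$refined_fit)),
      "<h3>Artifactual (artifact weight sum = ",
      sprintf("%.3f", aw(result$artifact_fit)), ")</h3>",
      .html_table(fit_tbl(result$artifact_fit))) else ""
  )

  cutoff_df <- tidy.refinement(result)
  if (!is.null(posthoc$parameter_tests) && nrow(cutoff_df) > 0) {
    pt <- posthoc$parameter_tests
    pt <- pt[pt$comparison == "refined_vs_artifactual", c("filter", "p_value")]
    cutoff_df <- dplyr::left_join(cutoff_df, pt, by = "filter")
  }

  sb_html <- if (!is.null(posthoc$strand_bias)) {
    sb <- posthoc$strand_bias
    paste0(sprintf("<p>%d variants tested; %d with q &lt; 0.05; %d skipped (no counts).</p>",
                   nrow(sb), sum(sb$q_value < 0.05),
                   attr(sb, "n_skipped") %||% 0L),
           .html_table(utils::head(sb[order(sb$q_value), ], 20)))
  } else "<p><em>not computed</em></p>"

  motif_html <- paste0(
    "<h3>Refined</h3>",
    if (!is.null(posthoc$motif_refined))
      .html_img(.png_b64(plot_motif_profile(posthoc$motif_refined)),
                "refined motif profile") else "<p><em>not computed</em></p>",
    "<h3>Artifactual</h3>",
    if (!is.null(posthoc$motif_artifactual))
      .html_img(.png_b64(plot_motif_profile(posthoc$motif_artifactual)),
                "artifactual motif profile") else "<p><em>not computed</em></p>")

  rescue_html <- if (!is.null(posthoc$rescued) && nrow(posthoc$rescued) > 0) {
    .html_table(posthoc$rescued[, c("key", "chrom", "pos", "ref", "alt")])
  } else "<p>No variants rescued.</p>"

  links <- if (!is.null(out_paths)) {
    files <- unlist(out_paths[!vapply(out_paths, is.null, logical(1))])
    files <- setdiff(basename(files), basename(path))
    paste0("<ul>", paste0("<li><a href=\"", files, "\">", files, "</a></li>",
                          collapse = ""), "</ul>")
  } else ""

  status <- if (skipped) {
    reason <- switch(result$skipped,
      skip_too_few = "fewer point mutations than the minimum required for a stable spectrum fit; no refinement attempted",
      skip_already_refined = "initial artifact signature weight below the refinement threshold; input passed through as refined")
    sprintf("<p><strong>Refinement skipped:</strong> %s.</p>", reason)
  } else {
    sprintf("<p>Refined %d of %d mutations (%d artifactual); best objective %.4f after %d generations.</p>",
            nrow(result$refined), nrow(result$refined) + nrow(result$artifactual),
            nrow(result$artifactual), result$best_objective,
            max(result$trace$generation))
  }

  html <- c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    "<title>sigrefine report</title>",
    "<style>body{font-family:sans-serif;margin:2em;max-width:1000px}",
    "table{border-collapse:collapse}td,th{border:1px solid #ccc;padding:2px 8px;font-size:90%}</style>",
    "</head><body>",
    "<h1>Variant refinement report</h1>",
    status,
    sec("Run", .html_table(tibble::tibble(
      field = c("tool", "version", "vcf", "fasta", "decision"),
      value = c(manifest$tool, manifest$version,
                manifest$inputs$vcf %||% "", manifest$inputs$fasta %||% "",
                manifest$decision)))),
    sec("Output files", links),
    sec("Mutation spectra", c(spectra$initial, spectra$refined,
                              spectra$artifactual)),
    sec("Signature weights", weights_html),
    sec("Optimization trace",
        .html_img(.png_b64(autoplot(result)), "objective trace")),
    sec("Filter cutoffs", .html_table(cutoff_df)),
    sec("Strand bias", sb_html),
    sec("Sequence-context motifs", motif_html),
    sec("Rescued variants", rescue_html),
    "</body></html>"
  )
  writeLines(html, path)
  invisible(path)
}
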
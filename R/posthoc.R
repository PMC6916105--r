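# Post-refinement analyses: none of these feed back into the partition; they
# annotate the report.

#' Per-variant strand-bias test
#'
#' Tests each variant's 2x2 table of forward/reverse read counts for the
#' reference and alternate alleles with a two-sided Fisher exact test, and
#' corrects across tested variants (Benjamini-Hochberg by default). Variants
#' lacking strand counts are skipped and tallied in the `n_skipped`
#' attribute. Strong strand bias is a hallmark of several artifact classes
#' (for instance 8-oxoG damage, whose spurious alternate reads come almost
#' entirely from one strand).
#'
#' @param mutations A `mutation_set` with `ref_fwd`, `ref_rev`, `alt_fwd`,
#'   `alt_rev` columns.
#' @param method Multiple-testing correction (default `"BH"`; any
#'   [stats::p.adjust()] method).
#' @return Tibble with `key`, the four counts, `p_value`, and `q_value`;
#'   attribute `n_skipped` counts variants without usable counts.
#' @export
strand_bias_test <- function(mutations, method = "BH") {
  cols <- c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev")
  stopifnot(all(cols %in% names(mutations)))
  counts <- as.matrix(mutations[, cols])
  usable <- stats::complete.cases(counts)
  if (any(counts[usable, ] < 0)) {
    abort_format("negative strand counts")
  }
  tested <- mutations[usable, c("key", cols)]
  p <- vapply(which(usable), function(i) {
    tbl <- matrix(as.numeric(counts[i, ]), nrow = 2, byrow = TRUE)
    stats::fisher.test(tbl)$p.value
  }, numeric(1))
  out <- tibble::as_tibble(tested)
  out$p_value <- p
  out$q_value <- stats::p.adjust(p, method = method)
  attr(out, "n_skipped") <- sum(!usable)
  out
}

#' Filter-parameter significance tests
#'
#' After refinement, tests per enabled filter whether the parameter's value
#' distributions differ among the original, refined, and artifactual mutation
#' sets (two-sided Mann-Whitney rank-sum), telling the reader which filter
#' actually drove the outcome. Comparisons with fewer than two non-missing
#' values on either side are reported as `NA`.
#'
#' @param mutations,refined,artifactual The original set and its partition.
#' @param config A `refinement_config` (default: attached to `mutations`).
#' @return Tibble with one row per enabled filter and comparison
#'   (`refined_vs_artifactual`, `original_vs_refined`,
#'   `original_vs_artifactual`): `filter`, `comparison`, `p_value`,
#'   `n_left`, `n_right`.
#' @export
parameter_tests <- function(mutations, refined, artifactual,
                            config = attr(mutations, "config")) {
  filt <- enabled_filters(config)
  combos <- list(
    refined_vs_artifactual = list(refined, artifactual),
    original_vs_refined = list(mutations, refined),
    original_vs_artifactual = list(mutations, artifactual)
  )
  purrr::map_dfr(filt$name, function(nm) {
    purrr::imap_dfr(combos, function(pair, label) {
      a <- pair[[1]][[nm]]; a <- a[!is.na(a)]
      b <- pair[[2]][[nm]]; b <- b[!is.na(b)]
      p <- if (length(a) >= 2 && length(b) >= 2) {
        suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = FALSE)$p.value)
      } else {
        NA_real_
      }
      tibble::tibble(filter = nm, comparison = label, p_value = p,
                     n_left = length(a), n_right = length(b))
    })
  })
}

#' Position-specific base frequencies around variants
#'
#' Builds a per-position base-frequency matrix over a window centred on each
#' variant (default 10 bases up- and downstream, 21 positions), from the
#' reference sequence. Artifact classes often leave a sequence-context
#' footprint here (e.g., guanine enrichment immediately flanking
#' oxidative-damage calls). Variants whose window would run off the contig
#' are skipped and tallied.
#'
#' @param mutations A `mutation_set` (needs `chrom`, `pos`).
#' @param fasta Reference FASTA path or `DNAStringSet`.
#' @param flank Bases on each side (default 10).
#' @return Tibble of class `motif_profile` with columns `position`
#'   (-flank..flank), `base` (A/C/G/T), `frequency`; frequencies at each
#'   position sum to 1. Attribute `n_skipped` counts skipped variants.
#' @export
motif_profile <- function(mutations, fasta, flank = 10) {
  ref <- read_reference(fasta)
  stopifnot(flank >= 1)
  if (nrow(mutations) == 0) {
    out <- tibble::tibble(position = integer(0), base = character(0),
                          frequency = numeric(0))
    class(out) <- c("motif_profile", class(out))
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  miss <- setdiff(unique(mutations$chrom), names(ref))
  if (length(miss) > 0) {
    abort_reference("contig(s) absent from FASTA: ", paste(miss, collapse = ", "))
  }
  clen <- stats::setNames(Biostrings::width(ref), names(ref))
  ok <- mutations$pos - flank >= 1 & mutations$pos + flank <= clen[mutations$chrom]
  n_skipped <- sum(!ok)
  m <- mutations[ok, ]
  windows <- .fetch_bases(ref, m$chrom, m$pos - flank, m$pos + flank)
  mat <- do.call(rbind, strsplit(windows, ""))
  positions <- seq(-flank, flank)
  out <- purrr::map_dfr(seq_along(positions), function(j) {
    tab <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    tot <- sum(tab)
    tibble::tibble(position = positions[j], base = names(tab),
                   frequency = if (tot > 0) as.numeric(tab) / tot else 0)
  })
  class(out) <- c("motif_profile", class(out))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a clinical rescue table
#'
#' Tab-delimited with a header and columns `chrom`, `pos` (1-based), `ref`,
#' `alt`, and optionally `label`. Malformed rows are skipped with a warning
#' tally. Typically prepared from a local export of pathogenic ClinVar or
#' COSMIC entries.
#'
#' @param path Path to the table.
#' @return Tibble with `key` and `label` columns.
#' @export
read_rescue_table <- function(path) {
  if (!file.exists(path)) abort_format("rescue table not found: ", path)
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tbl))) {
    abort_format("rescue table must have columns: ", paste(need, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(tbl$pos))
  ok <- !is.na(pos) & !is.na(tbl$chrom) & tbl$ref %in% c("A", "C", "G", "T") &
    tbl$alt %in% c("A", "C", "G", "T")
  if (any(!ok)) {
    warning(sum(!ok), " malformed rescue table row(s) skipped", call. = FALSE)
  }
  tbl <- tbl[ok, , drop = FALSE]
  tibble::tibble(
    key = variant_key(tbl$chrom, pos[ok], tbl$ref, tbl$alt),
    label = if ("label" %in% names(tbl)) as.character(tbl$label) else NA_character_
  )
}

#' Rescue clinically significant variants from the artifactual set
#'
#' Artifactual variants matching a rescue-table key (chrom, pos, ref, alt)
#' are moved back to the refined output and flagged `rescued`; the total
#' variant count is conserved and no record is duplicated.
#'
#' @param artifactual The artifactual `mutation_set`.
#' @param rescue_table A tibble from [read_rescue_table()] (or a path).
#' @return List with `moved` (rescued mutations, flagged) and `remaining`.
#' @export
rescue_variants <- function(artifactual, rescue_table) {
  if (is.character(rescue_table)) rescue_table <- read_rescue_table(rescue_table)
  hit <- artifactual$key %in% rescue_table$key
  moved <- subset_mutations(artifactual, hit)
  if (nrow(moved) > 0) moved$rescued <- TRUE
  list(moved = moved, remaining = subset_mutations(artifactual, !hit))
}

# append rescued rows to a refined set, keeping write attributes aligned
bind_mutation_sets <- function(a, b) {
  out <- dplyr::bind_rows(tibble::as_tibble(a), tibble::as_tibble(b))
  for (at in c("source", "meta", "samples", "config", "dropped")) {
    attr(out, at) <- attr(a, at)
  }
  attr(out, "fix") <- rbind(attr(a, "fix"), attr(b, "fix"))
  ga <- attr(a, "gt"); gb <- attr(b, "gt")
  attr(out, "gt") <- if (is.null(ga) && is.null(gb)) NULL else rbind(ga, gb)
  class(out) <- class(a)
  out
}
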
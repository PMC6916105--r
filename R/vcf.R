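#' Read a reference genome FASTA
#'
#' @param fasta Path to a FASTA file (or an existing `DNAStringSet`, returned
#'   as is with cleaned names).
#' @return A `Biostrings::DNAStringSet` named by contig (description text
#'   after the first whitespace is dropped).
#' @export
read_reference <- function(fasta) {
  if (inherits(fasta, "DNAStringSet")) {
    ref <- fasta
  } else {
    if (!file.exists(fasta)) abort_format("FASTA file not found: ", fasta)
    ref <- Biostrings::readDNAStringSet(fasta)
  }
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Read point mutations from a VCF
#'
#' Selects single-base substitutions (multi-allelic records are split into
#' biallelic SNV candidates; indels and MNVs are dropped), assigns each the
#' pyrimidine-collapsed SBS96 channel using the flanking reference bases, and
#' derives every configured filter parameter plus strand-specific read counts.
#' Variants whose trinucleotide context contains a base other than A/C/G/T,
#' or that sit at a contig edge, are dropped and counted.
#'
#' @param vcf Path to a VCF (4.x) file.
#' @param fasta Reference genome FASTA path (or `DNAStringSet`) covering all
#'   VCF contigs.
#' @param config A [read_filter_config()] object (or a path to one).
#' @param pass_only Restrict to records whose FILTER is `PASS` or `.`
#'   (default `FALSE`: whatever is in the file is refined).
#' @return A `mutation_set`: a tibble with columns `key`, `chrom`, `pos`,
#'   `ref`, `alt`, `channel`, one numeric column per configured filter,
#'   `ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev`, and `rescued`. Attributes
#'   carry the source path, VCF header, per-record verbatim fields for
#'   re-writing, and drop tallies.
#' @export
read_mutations <- function(vcf, fasta, config, pass_only = FALSE) {
  if (is.character(config)) config <- read_filter_config(config)
  stopifnot(inherits(config, "refinement_config"))
  if (!file.exists(vcf)) abort_format("VCF file not found: ", vcf)
  v <- tryCatch(vcfR::read.vcfR(vcf, verbose = FALSE),
                error = function(e) abort_format("failed to parse VCF: ",
                                                 conditionMessage(e)))
  ref_genome <- read_reference(fasta)
  fix <- v@fix
  gt <- v@gt
  if (is.null(fix) || nrow(fix) == 0) {
    return(.empty_mutation_set(config, vcf, v@meta))
  }
  samples <- if (!is.null(gt) && ncol(gt) > 1) colnames(gt)[-1] else character(0)

  keep <- rep(TRUE, nrow(fix))
  if (pass_only) keep <- fix[, "FILTER"] %in% c("PASS", ".")
  # split multi-allelic ALTs into candidate biallelic records
  alts <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- rep(seq_len(nrow(fix)), n_alt)
  alt <- unlist(alts)
  sel <- keep[rec]
  rec <- rec[sel]; alt <- alt[sel]
  refb <- fix[rec, "REF"]
  is_snv <- nchar(refb) == 1L & nchar(alt) == 1L &
    refb %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    refb != alt
  n_dropped_nonsnv <- sum(!is_snv)
  rec <- rec[is_snv]; alt <- alt[is_snv]; refb <- refb[is_snv]
  chrom <- fix[rec, "CHROM"]
  pos <- as.integer(fix[rec, "POS"])

  miss_contig <- setdiff(unique(chrom), names(ref_genome))
  if (length(miss_contig) > 0) {
    abort_reference("contig(s) absent from FASTA: ",
                    paste(miss_contig, collapse = ", "))
  }
  clen <- stats::setNames(Biostrings::width(ref_genome), names(ref_genome))
  at_edge <- pos <= 1L | pos >= clen[chrom]
  flank5 <- flank3 <- rep(NA_character_, length(pos))
  if (any(!at_edge)) {
    ctx <- .fetch_bases(ref_genome, chrom[!at_edge], pos[!at_edge] - 1L,
                        pos[!at_edge] + 1L)
    flank5[!at_edge] <- substr(ctx, 1, 1)
    flank3[!at_edge] <- substr(ctx, 3, 3)
    ref_at <- substr(ctx, 2, 2)
    mismatch <- ref_at != refb[!at_edge]
    if (any(mismatch)) {
      i <- which(!at_edge)[which(mismatch)[1]]
      abort_reference("VCF REF allele disagrees with FASTA at ",
                      chrom[i], ":", pos[i])
    }
  }
  channel <- classify_channel(refb, alt, flank5, flank3)
  ok <- !is.na(channel)
  n_dropped_context <- sum(!ok)
  rec <- rec[ok]; alt <- alt[ok]; refb <- refb[ok]
  chrom <- chrom[ok]; pos <- pos[ok]; channel <- channel[ok]

  out <- tibble::tibble(
    key = variant_key(chrom, pos, refb, alt),
    chrom = chrom, pos = pos, ref = refb, alt = alt, channel = channel
  )
  # derive configured filter parameters
  for (i in seq_len(nrow(config$filters))) {
    spec <- config$filters[i, ]
    out[[spec$name]] <- .locate_values(v, config, as.list(spec), rec)
  }
  sc <- .strand_count_values(v, config, rec)
  out$ref_fwd <- sc$ref_fwd; out$ref_rev <- sc$ref_rev
  out$alt_fwd <- sc$alt_fwd; out$alt_rev <- sc$alt_rev
  out$rescued <- FALSE

  if (anyDuplicated(out$key)) {
    dup <- out$key[duplicated(out$key)][1]
    abort_format("duplicate variant record in VCF: ", dup)
  }
  structure(
    out,
    class = c("mutation_set", class(out)),
    source = if (is.character(vcf)) vcf else NA_character_,
    meta = v@meta,
    samples = samples,
    config = config,
    fix = fix[rec, , drop = FALSE],
    gt = if (is.null(gt)) NULL else gt[rec, , drop = FALSE],
    dropped = c(non_snv = n_dropped_nonsnv, bad_context = n_dropped_context)
  )
}

.empty_mutation_set <- function(config, source, meta) {
  out <- tibble::tibble(
    key = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), channel = character(0)
  )
  for (nm in config$filters$name) out[[nm]] <- numeric(0)
  out$ref_fwd <- out$ref_rev <- out$alt_fwd <- out$alt_rev <- numeric(0)
  out$rescued <- logical(0)
  structure(out, class = c("mutation_set", class(out)),
            source = source, meta = meta, samples = character(0),
            config = config, fix = NULL, gt = NULL,
            dropped = c(non_snv = 0L, bad_context = 0L))
}

.fetch_bases <- function(ref_genome, chrom, start, end) {
  res <- character(length(chrom))
  for (cn in unique(chrom)) {
    i <- chrom == cn
    res[i] <- as.character(Biostrings::extractAt(
      ref_genome[[cn]], IRanges::IRanges(start[i], end[i])))
  }
  toupper(res)
}

# resolve one locator spec to a numeric vector over split records `rec`
.locate_values <- function(v, config, spec, rec) {
  kind <- spec$kind
  if (kind == "expr") {
    env <- new.env(parent = baseenv())
    for (f in config$fields) {
      assign(f$name, .locate_values(v, config, f, rec), envir = env)
    }
    return(as.numeric(eval(str2lang(spec$expr), envir = env)))
  }
  raw <- if (kind == "info") {
    vcfR::extract.info(v, element = spec$key)
  } else {
    smp <- .resolve_sample(v, config, spec$sample)
    gt <- vcfR::extract.gt(v, element = spec$key)
    if (!smp %in% colnames(gt)) {
      abort_config("sample '", smp, "' not present in VCF")
    }
    gt[, smp]
  }
  idx <- spec$index
  if (!is.null(idx) && !is.na(idx)) {
    raw <- vapply(strsplit(ifelse(is.na(raw), "", raw), ",", fixed = TRUE),
                  function(p) if (length(p) >= idx) p[[idx]] else NA_character_,
                  character(1))
  }
  suppressWarnings(as.numeric(raw))[rec]
}

.resolve_sample <- function(v, config, role) {
  nm <- if (identical(role, "normal")) config$normal_sample else config$tumor_sample
  if (is.na(nm) || !nzchar(nm)) {
    abort_config("configuration does not name the ", role, " sample")
  }
  nm
}

.strand_count_values <- function(v, config, rec) {
  n <- length(rec)
  empty <- list(ref_fwd = rep(NA_real_, n), ref_rev = rep(NA_real_, n),
                alt_fwd = rep(NA_real_, n), alt_rev = rep(NA_real_, n))
  sc <- config$strand_counts
  if (is.null(sc)) return(empty)
  grab <- function(loc, k) {
    loc <- as.list(loc)
    loc$index <- k
    .locate_values(v, config, loc, rec)
  }
  vals <- if (!is.null(sc$kind)) {
    list(ref_fwd = grab(sc, 1L), ref_rev = grab(sc, 2L),
         alt_fwd = grab(sc, 3L), alt_rev = grab(sc, 4L))
  } else {
    list(ref_fwd = grab(sc$ref, 1L), ref_rev = grab(sc$ref, 2L),
         alt_fwd = grab(sc$alt, 1L), alt_rev = grab(sc$alt, 2L))
  }
  neg <- vapply(vals, function(x) any(x < 0, na.rm = TRUE), logical(1))
  if (any(neg)) abort_format("negative strand counts in VCF")
  vals
}

#' Write a refined/artifactual partition as two VCF files
#'
#' Every selected SNV is written to exactly one of the two outputs. Records
#' are emitted with the original fixed fields and genotypes (multi-allelic
#' records carry the split SNV's own ALT allele); the header is preserved with
#' one added line documenting the tool and the applied cutoffs. Rescued
#' variants gain a `SIGREFINE_RESCUE` INFO flag. Output bytes depend only on
#' the inputs, so identical runs produce identical files.
#'
#' @param refined,artifactual `mutation_set` tibbles from one source VCF (as
#'   produced by [partition_mutations()] / [refine_mutations()]).
#' @param out_prefix Output path prefix; writes `<prefix>.refined.vcf` and
#'   `<prefix>.artifactual.vcf`.
#' @param cutoffs Optional named numeric cutoffs recorded in the added header
#'   line.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_partition <- function(refined, artifactual, out_prefix, cutoffs = NULL) {
  paths <- c(refined = paste0(out_prefix, ".refined.vcf"),
             artifactual = paste0(out_prefix, ".artifactual.vcf"))
  .write_vcf_subset(refined, paths[["refined"]], cutoffs)
  .write_vcf_subset(artifactual, paths[["artifactual"]], cutoffs)
  invisible(paths)
}

.write_vcf_subset <- function(mutations, path, cutoffs = NULL) {
  meta <- attr(mutations, "meta") %||% "##fileformat=VCFv4.2"
  fix <- attr(mutations, "fix")
  gt <- attr(mutations, "gt")
  tool <- paste0("##sigrefine=<Version=",
                 as.character(utils::packageVersion("sigrefine")),
                 if (!is.null(cutoffs) && length(cutoffs) > 0) {
                   paste0(",Cutoffs=\"",
                          paste(sprintf("%s%s", names(cutoffs),
                                        formatC(cutoffs, format = "g", digits = 6)),
                                collapse = ";"), "\"")
                 }, ">")
  rescue_hdr <- "##INFO=<ID=SIGREFINE_RESCUE,Number=0,Type=Flag,Description=\"Artifact call rescued by clinical annotation\">"
  header <- c(meta[-length(meta)], meta[length(meta)], tool, rescue_hdr)
  # column header line
  samples <- attr(mutations, "samples") %||% character(0)
  chdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                  if (length(samples) > 0) c("FORMAT", samples)), collapse = "\t")
  lines <- character(0)
  if (nrow(mutations) > 0) {
    if (is.null(fix)) stop("mutation set lacks source records; cannot write VCF",
                           call. = FALSE)
    info <- ifelse(is.na(fix[, "INFO"]), ".", fix[, "INFO"])
    resc <- isTRUE_vec(mutations$rescued)
    info[resc] <- ifelse(info[resc] == ".", "SIGREFINE_RESCUE",
                         paste0(info[resc], ";SIGREFINE_RESCUE"))
    body <- cbind(
      fix[, "CHROM"], fix[, "POS"], na_dot(fix[, "ID"]), mutations$ref,
      mutations$alt, na_dot(fix[, "QUAL"]), na_dot(fix[, "FILTER"]), info,
      if (!is.null(gt)) apply(gt, 2, na_dot)
    )
    lines <- apply(body, 1, paste, collapse = "\t")
  }
  writeLines(c(header, chdr, lines), path)
  invisible(path)
}

na_dot <- function(x) ifelse(is.na(x), ".", x)
isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.mutation_set <- function(x, ...) {
  cat("<mutation_set> ", nrow(x), " point mutations\n", sep = "")
  NextMethod()
}
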
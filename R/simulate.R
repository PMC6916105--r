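# Self-contained simulator: reference FASTA, signature-sampled SNVs with
# artifact-conditional quality metrics, VCF + truth labels. Everything is
# deterministic per seed so fixtures are generated at test time, never stored.

#' Write a random reference contig
#'
#' Single-contig FASTA with i.i.d. bases (25% each unless `gc` is supplied),
#' deterministic per seed.
#'
#' @param path Output FASTA path.
#' @param contig_length Contig length (>= 1000).
#' @param seed RNG seed.
#' @param gc G+C fraction (default 0.5).
#' @param contig Contig name (default `"chr1"`).
#' @return `path`, invisibly.
#' @export
make_reference <- function(path, contig_length = 2e5, seed = 1, gc = 0.5,
                           contig = "chr1") {
  if (contig_length < 1000) stop("contig_length must be >= 1000", call. = FALSE)
  stopifnot(gc > 0, gc < 1)
  bases <- with_private_seed(seed, {
    sample(c("A", "C", "G", "T"), contig_length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  seq <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(seq) <- contig
  Biostrings::writeXStringSet(seq, path)
  invisible(path)
}

# pyrimidine-collapsed trinucleotide context key for every interior position
.site_contexts <- function(contig_seq) {
  s <- strsplit(as.character(contig_seq), "")[[1]]
  n <- length(s)
  if (n < 3) return(tibble::tibble(pos = integer(0), context = character(0)))
  pos <- 2:(n - 1)
  refb <- s[pos]; f5 <- s[pos - 1]; f3 <- s[pos + 1]
  pur <- refb %in% c("A", "G")
  ctx <- ifelse(pur,
                paste0(.complement[f3], .complement[refb], .complement[f5]),
                paste0(f5, refb, f3))
  ok <- !grepl("N", ctx, fixed = TRUE)
  tibble::tibble(pos = pos[ok], context = ctx[ok], purine = pur[ok])
}

.channel_context <- function(channel) {
  paste0(substr(channel, 1, 1), substr(channel, 3, 3), substr(channel, 7, 7))
}

# core sampler shared by sample_mutations and simulate_dataset: draws channels
# for each (signature, n, label) block and places them on distinct sites
.place_mutations <- function(blocks, ref, contig) {
  canon <- sbs96_channels()
  sites <- .site_contexts(ref[[contig]])
  pools <- split(seq_len(nrow(sites)), sites$context)
  draws <- lapply(blocks, function(b) {
    if (b$n == 0) return(integer(0))
    p <- as.numeric(b$signature)
    stopifnot(length(p) == 96)
    as.integer(stats::rmultinom(1, b$n, p))
  })
  # demand per context across all blocks, sampled jointly so positions never repeat
  taken <- new.env(parent = emptyenv())
  out <- list()
  for (bi in seq_along(blocks)) {
    cnt <- draws[[bi]]
    if (length(cnt) == 0) next
    rows <- list()
    for (ci in which(cnt > 0)) {
      chan <- canon[ci]
      ctx <- .channel_context(chan)
      pool <- pools[[ctx]]
      used <- taken[[ctx]] %||% integer(0)
      avail <- setdiff(pool, used)
      if (length(avail) < cnt[ci]) {
        stop("reference has too few sites for channel ", chan,
             " (need ", cnt[ci], ", have ", length(avail), ")", call. = FALSE)
      }
      pick <- if (length(avail) == 1) avail else sample(avail, cnt[ci])
      taken[[ctx]] <- c(used, pick)
      pur <- sites$purine[pick]
      alt_pyr <- substr(chan, 5, 5)
      refb <- ifelse(pur, .complement[substr(chan, 3, 3)], substr(chan, 3, 3))
      altb <- ifelse(pur, .complement[alt_pyr], alt_pyr)
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = contig, pos = sites$pos[pick],
        ref = unname(refb), alt = unname(altb), channel = chan,
        class = blocks[[bi]]$label)
    }
    out[[bi]] <- dplyr::bind_rows(rows)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$pos)
}

#' Sample SNVs from a mutational signature onto a reference
#'
#' Draws SBS96 channels from the signature's distribution and places each on
#' a uniformly random unused reference site with the matching pyrimidine-
#' collapsed trinucleotide context; sites whose reference base is a purine
#' realize the reverse-complemented substitution. The inverse of
#' [build_spectrum()]: the fitted spectrum of a large sample matches the
#' generating signature.
#'
#' @param signature A 96-vector of channel probabilities (canonical order),
#'   or the name of a [fixture_signatures()] column.
#' @param n Number of SNVs.
#' @param fasta Reference FASTA path or `DNAStringSet`.
#' @param seed RNG seed.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `channel`, sorted by
#'   position.
#' @export
sample_mutations <- function(signature, n, fasta, seed = 1) {
  ref <- read_reference(fasta)
  if (is.character(signature) && length(signature) == 1) {
    signature <- fixture_signatures()[, signature]
  }
  with_private_seed(seed, {
    .place_mutations(list(list(signature = signature, n = n, label = "sampled")),
                     ref, names(ref)[1])[, c("chrom", "pos", "ref", "alt", "channel")]
  })
}

#' Simulation specification
#'
#' Defines the canonical synthetic benchmark: a mixture of biological
#' (`SYN.SMOKE`-drawn) and artifactual (`SYN.OXOG`-drawn) SNVs whose quality
#' metrics come from class-conditional distributions. Defaults encode the
#' qualitative artifact profile seen in tumor sequencing — artifacts carry
#' low variant allele fractions, low base qualities, and strand-skewed
#' alternate reads — as well-separated distributions: true VAF ~ U(0.15,
#' 0.50) vs artifact VAF ~ U(0.01, 0.06); true base quality ~ N(35, 3) vs
#' artifact ~ N(22, 3), truncated at 0; alternate reads split
#' Binomial(p = 0.5) across strands for true calls vs p = 0.9 for artifacts.
#'
#' @param n_true,n_artifact Counts per class (default 1000 each).
#' @param true_signature,artifact_signature 96-vectors or fixture-signature
#'   names (defaults `"SYN.SMOKE"`, `"SYN.OXOG"`).
#' @param vaf_true,vaf_artifact Uniform VAF ranges per class.
#' @param bq_true,bq_artifact Normal (mean, sd) base-quality parameters per
#'   class, truncated at 0.
#' @param strand_p_true,strand_p_artifact Per-class probability an alternate
#'   read maps to the forward strand.
#' @param depth_lambda Poisson mean of sequencing depth above a floor of 20.
#' @param contig_length,gc Reference contig parameters.
#' @param seed RNG seed governing every random draw.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(n_true = 1000, n_artifact = 1000,
                     true_signature = "SYN.SMOKE",
                     artifact_signature = "SYN.OXOG",
                     vaf_true = c(0.15, 0.50), vaf_artifact = c(0.01, 0.06),
                     bq_true = c(35, 3), bq_artifact = c(22, 3),
                     strand_p_true = 0.5, strand_p_artifact = 0.9,
                     depth_lambda = 80, contig_length = 2e5, gc = 0.5,
                     seed = 1) {
  stopifnot(n_true >= 0, n_artifact >= 0, contig_length >= 1000,
            vaf_true[1] <= vaf_true[2], vaf_artifact[1] <= vaf_artifact[2])
  structure(as.list(environment()), class = "sim_spec")
}

#' Simulate a labelled somatic VCF
#'
#' Writes a complete synthetic dataset: reference FASTA, a VCF in the
#' packaged generic dialect (FORMAT `GT:AF:DP:AD:SC` for tumor and normal
#' samples, INFO `BQ` mean alternate base quality; `SC` holds ref-forward,
#' ref-reverse, alt-forward, alt-reverse read counts), a tab-delimited truth
#' table labelling every variant `true` or `artifact`, and a JSON recipe
#' recording the spec. Byte-identical across runs with the same spec.
#'
#' @param spec A [sim_spec()].
#' @param out_prefix Path prefix for `<prefix>.fasta`, `<prefix>.vcf`,
#'   `<prefix>.truth.tsv`, `<prefix>.recipe.json`.
#' @return Named list of the four paths plus the variant tibble, invisibly.
#' @export
simulate_dataset <- function(spec, out_prefix) {
  stopifnot(inherits(spec, "sim_spec"))
  paths <- list(fasta = paste0(out_prefix, ".fasta"),
                vcf = paste0(out_prefix, ".vcf"),
                truth = paste0(out_prefix, ".truth.tsv"),
                recipe = paste0(out_prefix, ".recipe.json"))
  make_reference(paths$fasta, spec$contig_length, seed = spec$seed, gc = spec$gc)
  ref <- read_reference(paths$fasta)
  sig <- function(s) {
    if (is.character(s) && length(s) == 1) fixture_signatures()[, s] else s
  }
  variants <- with_private_seed(spec$seed + 1L, {
    v <- .place_mutations(list(
      list(signature = sig(spec$true_signature), n = spec$n_true, label = "true"),
      list(signature = sig(spec$artifact_signature), n = spec$n_artifact,
           label = "artifact")
    ), ref, names(ref)[1])
    n <- nrow(v)
    is_art <- v$class == "artifact"
    v$vaf <- ifelse(is_art,
                    stats::runif(n, spec$vaf_artifact[1], spec$vaf_artifact[2]),
                    stats::runif(n, spec$vaf_true[1], spec$vaf_true[2]))
    v$bq <- pmax(0, ifelse(is_art,
                           stats::rnorm(n, spec$bq_artifact[1], spec$bq_artifact[2]),
                           stats::rnorm(n, spec$bq_true[1], spec$bq_true[2])))
    v$dp <- stats::rpois(n, spec$depth_lambda) + 20L
    v$alt_dp <- pmax(1L, as.integer(round(v$vaf * v$dp)))
    v$ref_dp <- v$dp - v$alt_dp
    p_fwd <- ifelse(is_art, spec$strand_p_artifact, spec$strand_p_true)
    v$alt_fwd <- stats::rbinom(n, v$alt_dp, p_fwd)
    v$alt_rev <- v$alt_dp - v$alt_fwd
    v$ref_fwd <- stats::rbinom(n, v$ref_dp, 0.5)
    v$ref_rev <- v$ref_dp - v$ref_fwd
    v$n_dp <- stats::rpois(n, spec$depth_lambda) + 20L
    v$n_fwd <- stats::rbinom(n, v$n_dp, 0.5)
    v
  })
  .write_sim_vcf(variants, names(ref)[1], Biostrings::width(ref)[1], paths$vcf)
  truth <- tibble::tibble(
    key = variant_key(variants$chrom, variants$pos, variants$ref, variants$alt),
    chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
    alt = variants$alt, class = variants$class)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  recipe <- unclass(spec)
  recipe$true_signature <- if (is.character(spec$true_signature))
    spec$true_signature else "custom"
  recipe$artifact_signature <- if (is.character(spec$artifact_signature))
    spec$artifact_signature else "custom"
  jsonlite::write_json(recipe, paths$recipe, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(variants = variants)))
}

.write_sim_vcf <- function(v, contig, contig_length, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, contig_length),
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Mean alternate allele base quality in tumor\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=SC,Number=4,Type=Integer,Description=\"Strand counts: ref_fwd,ref_rev,alt_fwd,alt_rev\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "TUMOR", "NORMAL"), collapse = "\t")
  )
  # AF carries the class-conditional allele fraction itself (a caller's
  # model-based estimate); AD holds the realized integer depths
  af <- formatC(v$vaf, format = "f", digits = 4)
  tumor <- sprintf("0/1:%s:%d:%d,%d:%d,%d,%d,%d", af, v$dp, v$ref_dp, v$alt_dp,
                   v$ref_fwd, v$ref_rev, v$alt_fwd, v$alt_rev)
  normal <- sprintf("0/0:0.0000:%d:%d,0:%d,%d,0,0", v$n_dp, v$n_dp,
                    v$n_fwd, v$n_dp - v$n_fwd)
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                sprintf("BQ=%s", formatC(v$bq, format = "f", digits = 2)),
                "GT:AF:DP:AD:SC", tumor, normal, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a simulation truth table
#'
#' @param path `<prefix>.truth.tsv` written by [simulate_dataset()].
#' @return Tibble with `key` and `class` (`true`/`artifact`).
#' @export
read_truth_labels <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble::as_tibble(tbl)
}

#' Packaged generic filter configuration
#'
#' The two-filter configuration matching [simulate_dataset()]'s VCF dialect:
#' `vaf` (tumor FORMAT `AF`, keep if at least) and `bq` (INFO `BQ`, keep if
#' at least), with strand counts from the tumor `SC` field.
#'
#' @return A `refinement_config`.
#' @export
generic_sim_config <- function() {
  read_filter_config(system.file("extdata", "config_generic.json",
                                 package = "sigrefine", mustWork = TRUE))
}
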
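# Shared fixtures, built once per test run.

.bench <- new.env(parent = emptyenv())

# canonical two-filter benchmark: 1000 true (SYN.SMOKE) + 1000 artifact
# (SYN.OXOG) SNVs with separated VAF / base-quality distributions, seed 1
bench_data <- function() {
  if (is.null(.bench$sim)) {
    prefix <- file.path(tempdir(), "sigrefine-bench-seed1")
    .bench$sim <- simulate_dataset(sim_spec(seed = 1), prefix)
    .bench$config <- generic_sim_config()
    .bench$mutations <- read_mutations(.bench$sim$vcf, .bench$sim$fasta,
                                       .bench$config)
    .bench$truth <- read_truth_labels(.bench$sim$truth)
  }
  as.list(.bench)
}

fx_sigs <- fixture_signatures()
fx_arts <- fixture_artifact_signatures()

catalog_path <- function() {
  system.file("extdata", "synthetic_sbs_catalog_v3shape.tsv",
              package = "sigrefine", mustWork = TRUE)
}

# a tiny hand-written VCF in the generic dialect
write_tiny_vcf <- function(path, body) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"mean alt bq\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"vaf\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##FORMAT=<ID=SC,Number=4,Type=Integer,Description=\"strand counts\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "TUMOR", "NORMAL"), collapse = "\t")
  )
  writeLines(c(header, body), path)
  path
}

# reference FASTA shared by small VCF tests
tiny_fasta <- function() {
  if (is.null(.bench$tiny_fasta)) {
    p <- file.path(tempdir(), "sigrefine-tiny.fasta")
    make_reference(p, contig_length = 100000, seed = 99)
    .bench$tiny_fasta <- p
  }
  .bench$tiny_fasta
}

fasta_base <- function(fasta, pos) {
  ref <- read_reference(fasta)
  substr(as.character(ref[[1]]), pos, pos)
}

# exhaustive simplex grid-search oracle for NNLS refitting: returns the
# normalized weight vector on the k-simplex (step `by`) whose scaled
# reconstruction has the smallest residual against `target`
grid_fit_oracle <- function(target, A, by = 1e-3) {
  k <- ncol(A)
  grid <- seq(0, 1, by = by)
  best <- NULL; best_res <- Inf
  if (k == 2) {
    combos <- cbind(grid, 1 - grid)
  } else if (k == 3) {
    combos <- do.call(rbind, lapply(grid, function(w1) {
      w2 <- seq(0, 1 - w1, by = by)
      cbind(w1, w2, 1 - w1 - w2)
    }))
  } else {
    stop("oracle supports 2-3 signatures")
  }
  recon <- A %*% t(combos)
  # optimal scale per column, then residual
  num <- colSums(recon * target)
  den <- colSums(recon^2)
  s <- ifelse(den > 0, num / den, 0)
  res <- colSums((target - sweep(recon, 2, s, "*"))^2)
  combos[which.min(res), ]
}

# Benjamini-Hochberg step-up reference computation
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# two-sided Fisher exact p by full hypergeometric enumeration on one 2x2 table
fisher_oracle <- function(a, b, c, d) {
  # margins fixed: row1 = a+b, row2 = c+d, col1 = a+c
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
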
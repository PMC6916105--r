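# Handcrafted synthetic signatures and the synthetic COSMIC-shaped catalog.
# None of these are COSMIC signatures; they are normalized stand-in vectors
# designed so that tests and simulations never depend on redistributed data.

# run code with a private, restored RNG stream
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.fixture_vector <- function(major, major_mass, minor, minor_mass = 1 - major_mass) {
  canon <- sbs96_channels()
  v <- stats::setNames(rep(0, 96), canon)
  v[major] <- major_mass / length(major)
  v[minor] <- v[minor] + minor_mass / length(minor)
  v <- v / sum(v)
  # small uniform floor: like published catalogs, every channel keeps a
  # positive probability, so restricted refits never degenerate
  v <- 0.99 * v + 0.01 / 96
  v / sum(v)
}

#' Handcrafted fixture signatures
#'
#' Four synthetic, fully documented signature vectors used by the simulator
#' and the test suite; they emulate the channel concentrations of well-known
#' processes without reproducing any catalog values:
#'
#' * `SYN.SMOKE` — C>A concentrated in A/T 5'-flank contexts, with minor C>G
#'   and T>A mass (a tobacco-smoking-like biological signature);
#' * `SYN.OXOG` — C>A concentrated in C/G 5'-flank contexts (an
#'   8-oxoG-damage-like artifact, G>T on the purine strand);
#' * `SYN.FFPE` — C>T concentrated at NpCpG contexts (a formalin-fixation
#'   deamination-like artifact);
#' * `SYN.TG` — T>G concentrated at the G\[T>G\]G context.
#'
#' The two C>A signatures have disjoint major supports, so mixtures of them
#' are well separated for deconvolution.
#'
#' @return A [signature_matrix()] with 4 columns.
#' @export
fixture_signatures <- function() {
  canon <- sbs96_channels()
  bases <- c("A", "C", "G", "T")
  ca <- function(p5, p3) paste0(p5, "[C>A]", p3)
  smoke_major <- as.vector(outer(c("A", "T"), bases, ca))
  oxog_major <- as.vector(outer(c("C", "G"), bases, ca))
  ffpe_major <- paste0(bases, "[C>T]G")
  smoke <- .fixture_vector(smoke_major, 0.75,
                           c(paste0("A[C>G]", bases), paste0("T[T>A]", bases)))
  oxog <- .fixture_vector(oxog_major, 0.90, paste0(bases, "[T>G]C"))
  ffpe <- .fixture_vector(ffpe_major, 0.70,
                          grep("\\[C>T\\]", canon, value = TRUE))
  tg <- .fixture_vector("G[T>G]G", 0.85, grep("\\[T>G\\]", canon, value = TRUE))
  m <- cbind(SYN.SMOKE = smoke, SYN.OXOG = oxog, SYN.FFPE = ffpe, SYN.TG = tg)
  rownames(m) <- canon
  signature_matrix(m)
}

#' Artifact subset of the fixture signatures
#'
#' @return `c("SYN.OXOG", "SYN.FFPE", "SYN.TG")` — the three fixture
#'   signatures that emulate artifact processes (`SYN.SMOKE` is the
#'   biological one).
#' @export
fixture_artifact_signatures <- function() {
  c("SYN.OXOG", "SYN.FFPE", "SYN.TG")
}

#' COSMIC v3 signature names
#'
#' The 65 single-base-substitution signature identifiers of the v3 catalog
#' (SBS1..SBS60 with the SBS7a-d, SBS10a-b, SBS17a-b splits).
#'
#' @return Character vector of length 65.
#' @export
cosmic_v3_signature_names <- function() {
  nm <- character(0)
  for (i in 1:60) {
    nm <- c(nm, switch(as.character(i),
      "7" = paste0("SBS7", c("a", "b", "c", "d")),
      "10" = paste0("SBS10", c("a", "b")),
      "17" = paste0("SBS17", c("a", "b")),
      paste0("SBS", i)))
  }
  nm
}

#' Synthetic catalog with the COSMIC v3 shape
#'
#' A deterministic, fully synthetic 96 x 65 signature catalog carrying the
#' COSMIC v3 signature names. It is NOT the COSMIC catalog: every column is a
#' sparse random probability vector generated from a fixed internal seed,
#' except that the four [fixture_signatures()] are embedded in the columns
#' whose real-world counterparts they emulate (SYN.SMOKE in SBS4, SYN.OXOG in
#' SBS45, SYN.FFPE in SBS46, SYN.TG in SBS51). It exists so the package ships
#' a catalog of the documented shape without redistributing COSMIC data; any
#' real analysis should load the genuine catalog with
#' [read_signature_matrix()].
#'
#' @return A [signature_matrix()] with 65 columns.
#' @export
synthetic_signature_catalog <- function() {
  canon <- sbs96_channels()
  nm <- cosmic_v3_signature_names()
  vals <- with_private_seed(20190301, {
    sapply(seq_along(nm), function(j) {
      w <- stats::rgamma(96, shape = 0.25, rate = 1)
      w / sum(w)
    })
  })
  rownames(vals) <- canon
  colnames(vals) <- nm
  fx <- fixture_signatures()
  vals[, "SBS4"] <- fx[, "SYN.SMOKE"]
  vals[, "SBS45"] <- fx[, "SYN.OXOG"]
  vals[, "SBS46"] <- fx[, "SYN.FFPE"]
  vals[, "SBS51"] <- fx[, "SYN.TG"]
  signature_matrix(vals)
}
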
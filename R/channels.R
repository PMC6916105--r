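#' Canonical SBS96 channel labels
#'
#' The 96 single-base-substitution classes in the conventional catalog order:
#' substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then the 5' flanking base
#' cycling A, C, G, T in the outer loop and the 3' flank A, C, G, T in the
#' inner loop. Labels are formatted like `"A[C>A]A"`. All spectra and
#' signature matrices in this package are aligned to this order by label,
#' never by row position.
#'
#' @return Character vector of length 96.
#' @examples
#' head(sbs96_channels())
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    unlist(lapply(bases, function(p5) {
      paste0(p5, "[", s, "]", bases)
    }))
  }))
}

# strand complement lookup, vectorized over single characters
.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify single-base substitutions into SBS96 channels
#'
#' Collapses each substitution onto the pyrimidine strand: when the reference
#' allele is a purine (A or G), the reference, alternate, and both flanking
#' bases are reverse-complemented before the class is formed. This makes
#' classification involutive under strand representation.
#'
#' @param ref,alt Single reference/alternate bases (A/C/G/T), vectorized.
#' @param flank5,flank3 Bases immediately 5' and 3' of the variant on the
#'   reference strand.
#' @return Character vector of channel labels (`NA` where any base is not
#'   A/C/G/T or `ref == alt`).
#' @export
classify_channel <- function(ref, alt, flank5, flank3) {
  ref <- toupper(ref); alt <- toupper(alt)
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  n <- length(ref)
  stopifnot(length(alt) == n, length(flank5) == n, length(flank3) == n)
  valid <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    flank5 %in% c("A", "C", "G", "T") & flank3 %in% c("A", "C", "G", "T") &
    ref != alt
  out <- rep(NA_character_, n)
  if (!any(valid)) return(out)
  r <- ref[valid]; a <- alt[valid]; f5 <- flank5[valid]; f3 <- flank3[valid]
  pur <- r %in% c("A", "G")
  # reverse complement purine-reference records onto the pyrimidine strand;
  # the 5' flank of the reverse strand is the complement of the 3' flank
  r2 <- ifelse(pur, .complement[r], r)
  a2 <- ifelse(pur, .complement[a], a)
  f5c <- ifelse(pur, .complement[f3], f5)
  f3c <- ifelse(pur, .complement[f5], f3)
  out[valid] <- paste0(f5c, "[", r2, ">", a2, "]", f3c)
  out
}

#' @rdname classify_channel
#' @param channel Channel labels as returned by [classify_channel()].
#' @return `channel_index()`: integer position (1-based) of each label in
#'   [sbs96_channels()].
#' @export
channel_index <- function(channel) {
  match(channel, sbs96_channels())
}
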
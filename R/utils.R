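# classed conditions so callers (and the CLI) can map failures to exit codes

abort_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("sigrefine_config_error", "error")))
}

abort_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("sigrefine_format_error", "error")))
}

abort_reference <- function(...) {
  stop(errorCondition(paste0(...), class = c("sigrefine_reference_error", "error")))
}

# stable per-variant record key
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
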
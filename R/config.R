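#' Read a filter configuration
#'
#' The JSON configuration declares how each per-variant filter parameter is
#' derived from the VCF and how its cutoff acts. Schema:
#'
#' ```json
#' {
#'   "tumor_sample": "TUMOR", "normal_sample": "NORMAL",
#'   "fields": [
#'     {"name": "alt_dp", "kind": "format", "key": "AD", "index": 2,
#'      "sample": "tumor"}
#'   ],
#'   "filters": [
#'     {"name": "vaf", "source": {"kind": "format", "key": "AF",
#'      "sample": "tumor"}, "direction": "keep_if_at_least",
#'      "type": "real", "enabled": true, "missing_policy": "fail_filter"}
#'   ],
#'   "strand_counts": {"kind": "format", "key": "SC", "sample": "tumor"}
#' }
#' ```
#'
#' Source kinds: `info` (INFO key), `format` (FORMAT key of the tumor or
#' normal sample), or `expr` — an arithmetic expression (`+ - * /` and
#' parentheses only) over the declared `fields` names and numeric constants,
#' e.g. `"alt_dp / (alt_dp + ref_dp)"`. Multi-valued comma-separated fields
#' are addressed with 1-based `index`. `direction` is `keep_if_at_least` or
#' `keep_if_at_most`; `missing_policy` (default `fail_filter`) decides whether
#' a variant with a missing value fails or passes that filter.
#' `strand_counts` locates a 4-integer field ordered
#' ref-forward, ref-reverse, alt-forward, alt-reverse (or paired 2-integer
#' `ref`/`alt` fields ordered forward, reverse).
#'
#' @param x Path to a JSON file, or an equivalent nested list.
#' @return An object of class `refinement_config`: list with `filters`
#'   (tibble), `fields`, `tumor_sample`, `normal_sample`, `strand_counts`.
#' @export
read_filter_config <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) abort_config("configuration file not found: ", x)
    x <- jsonlite::read_json(x, simplifyVector = FALSE)
  }
  if (!is.list(x)) abort_config("configuration must be a JSON object")
  filters <- x$filters
  if (is.null(filters) || length(filters) == 0) {
    abort_config("configuration declares no filters")
  }
  fields <- x$fields %||% list()
  field_names <- vapply(fields, function(f) as.character(f$name %||% ""), "")
  if (any(field_names == "")) abort_config("every entry in 'fields' needs a name")
  if (anyDuplicated(field_names)) {
    abort_config("duplicate field name: ",
                 field_names[duplicated(field_names)][1])
  }
  for (f in fields) .validate_locator(f, paste0("fields/", f$name), field_names = NULL)

  rows <- lapply(seq_along(filters), function(i) {
    f <- filters[[i]]
    at <- function(part) paste0("filters[", i, "]/", part)
    name <- as.character(f$name %||% "")
    if (name == "") abort_config("missing filter name at ", at("name"))
    src <- f$source
    if (is.null(src)) abort_config("missing source at ", at("source"))
    .validate_locator(src, at("source"), field_names = field_names)
    direction <- as.character(f$direction %||% "")
    if (!direction %in% c("keep_if_at_least", "keep_if_at_most")) {
      abort_config("unknown direction '", direction, "' at ", at("direction"))
    }
    type <- as.character(f$type %||% "real")
    if (!type %in% c("integer", "real")) {
      abort_config("unknown type '", type, "' at ", at("type"))
    }
    missing_policy <- as.character(f$missing_policy %||% "fail_filter")
    if (!missing_policy %in% c("fail_filter", "pass_filter")) {
      abort_config("unknown missing_policy '", missing_policy, "' at ",
                   at("missing_policy"))
    }
    tibble::tibble(
      name = name,
      kind = as.character(src$kind),
      key = as.character(src$key %||% NA_character_),
      index = as.integer(src$index %||% NA_integer_),
      sample = as.character(src$sample %||% NA_character_),
      expr = as.character(src$expr %||% NA_character_),
      direction = direction,
      value_type = type,
      enabled = isTRUE(f$enabled %||% TRUE),
      missing_policy = missing_policy
    )
  })
  filters_tbl <- dplyr::bind_rows(rows)
  if (anyDuplicated(filters_tbl$name)) {
    abort_config("duplicate filter name: ",
                 filters_tbl$name[duplicated(filters_tbl$name)][1])
  }
  sc <- x$strand_counts
  if (!is.null(sc)) {
    if (!is.null(sc$kind)) {
      .validate_locator(sc, "strand_counts", field_names = NULL)
    } else if (!is.null(sc$ref) && !is.null(sc$alt)) {
      .validate_locator(sc$ref, "strand_counts/ref", field_names = NULL)
      .validate_locator(sc$alt, "strand_counts/alt", field_names = NULL)
    } else {
      abort_config("strand_counts must be one locator or {ref, alt} locators")
    }
  }
  structure(
    list(
      filters = filters_tbl,
      fields = fields,
      tumor_sample = as.character(x$tumor_sample %||% NA_character_),
      normal_sample = as.character(x$normal_sample %||% NA_character_),
      strand_counts = sc
    ),
    class = "refinement_config"
  )
}

.validate_locator <- function(loc, where, field_names) {
  kind <- as.character(loc$kind %||% "")
  if (kind == "expr") {
    if (is.null(field_names)) abort_config("expr locator not allowed at ", where)
    expr <- as.character(loc$expr %||% "")
    if (expr == "") abort_config("empty expression at ", where)
    refs <- tryCatch(.expr_names(str2lang(expr)),
                     error = function(e) abort_config("malformed expression at ",
                                                      where, ": ", expr))
    unknown <- setdiff(refs, field_names)
    if (length(unknown) > 0) {
      abort_config("expression at ", where, " references undeclared field(s): ",
                   paste(unknown, collapse = ", "))
    }
  } else if (kind %in% c("info", "format")) {
    if (is.null(loc$key)) abort_config("missing key at ", where)
    if (kind == "format" &&
        !as.character(loc$sample %||% "") %in% c("tumor", "normal")) {
      abort_config("format locator at ", where,
                   " needs sample = 'tumor' or 'normal'")
    }
  } else {
    abort_config("unknown source kind '", kind, "' at ", where)
  }
  invisible(TRUE)
}

# names referenced by an arithmetic expression; rejects anything but + - * / ( )
.expr_names <- function(e) {
  if (is.numeric(e)) return(character(0))
  if (is.name(e)) return(as.character(e))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (!op %in% c("+", "-", "*", "/", "(")) {
      stop("operator not allowed: ", op, call. = FALSE)
    }
    return(unique(unlist(lapply(as.list(e)[-1], .expr_names))))
  }
  stop("unsupported expression element", call. = FALSE)
}

#' Enabled filters of a configuration
#'
#' @param config A `refinement_config`.
#' @return Tibble of enabled filter rows.
#' @export
enabled_filters <- function(config) {
  stopifnot(inherits(config, "refinement_config"))
  dplyr::filter(config$filters, .data$enabled)
}

#' @export
print.refinement_config <- function(x, ...) {
  cat("<refinement_config> tumor =", x$tumor_sample,
      " normal =", x$normal_sample, "\n")
  print(x$filters[, c("name", "kind", "key", "direction", "enabled")])
  invisible(x)
}
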
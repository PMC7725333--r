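#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# classed conditions so callers (and the CLI) can map failures to exit codes
glyco_abort <- function(msg, class, ...) {
  rlang::abort(message = msg, class = c(class, "glyco_error"), ...)
}

input_error <- function(msg) glyco_abort(msg, "glyco_input_error")

validation_error <- function(violations) {
  msg <- paste0(
    "registry/config validation failed (", length(violations), " violation",
    if (length(violations) > 1) "s" else "", "):\n",
    paste0("  - ", violations, collapse = "\n")
  )
  glyco_abort(msg, "glyco_validation_error", violations = violations)
}

is_gpe_id <- function(x) grepl("^GPE[0-9]{5}$", x)

# deterministic, locale-independent ordering used everywhere ids are sorted
sort_ids <- function(x) x[order(x, method = "radix")]
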
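#' @keywords internal
"_PACKAGE"

# Internal condition helpers. Validation failures signal classed conditions so
# callers (and the CLI) can distinguish contract violations from plain errors.

fm_stop <- function(..., class = "fredmag_error", call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "fredmag_error")))
}

fm_warn <- function(...) {
  warning(paste0(...), call. = FALSE)
}

# stderr logging used by the CLI; verbosity 0 silences it
fm_log <- function(..., verbose = getOption("fredmag.verbose", 1L)) {
  if (verbose > 0L) message(paste0(...))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# check a character vector is non-empty, unique, no NA
check_ids <- function(x, what) {
  if (length(x) == 0L) fm_stop("no ", what, " found", class = "fredmag_validation_error")
  if (anyNA(x)) fm_stop("missing ", what, " identifier", class = "fredmag_validation_error")
  if (anyDuplicated(x)) {
    fm_stop("duplicated ", what, ": ", paste(unique(x[duplicated(x)]), collapse = ", "),
            class = "fredmag_validation_error")
  }
  invisible(x)
}
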
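# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Report-layer rounding: 0.5 always rounds up, unlike [round()]'s
#' round-half-even. Used for all printed percentages so that e.g. 14.05
#' reports as 14.1.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (>= 0).
#' @return `x` rounded to `digits` places, half up.
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# stop() with a classed condition so the CLI can map errors to exit codes
config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("genetrapr_config_error", "error")))
}

data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("genetrapr_data_error", "error")))
}

# deterministic TSV writer: no quoting, no row names, NA as empty string
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", eol = "\n")
  invisible(path)
}

parse_logical <- function(x, what = "field") {
  out <- rep(NA, length(x))
  lx <- tolower(trimws(as.character(x)))
  out[lx %in% c("1", "true", "t", "yes")] <- TRUE
  out[lx %in% c("0", "false", "f", "no")] <- FALSE
  bad <- which(!is.na(lx) & lx != "" & is.na(out))
  if (length(bad) > 0) {
    data_error(sprintf("cannot parse %s as logical at row %d: '%s'",
                       what, bad[1], x[bad[1]]))
  }
  out
}
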
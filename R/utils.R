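# Internal helpers: condition classes, RNG scoping, flat config files.

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("sowpose_validation_error", "sowpose_error")))
}

stop_io <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("sowpose_io_error", "sowpose_error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stop_validation("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_validation("`seed` must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Read a flat key-value configuration file
#'
#' Parses `key = value` lines (one per line, `#` comments allowed).  Values
#' that parse as numbers are returned numeric; everything else is returned
#' as a character string.
#'
#' @param path Path to the configuration file.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop_io("malformed config line (expected 'key = value'): %s", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
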
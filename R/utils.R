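# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fr <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_fr("'%s' must be a single non-missing number", name)
  bad <- if (strict) x <= lower else x < lower
  if (bad)
    stop_fr("'%s' must be %s %s (got %g)", name,
            if (strict) ">" else ">=", format(lower), x)
  invisible(x)
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "fishrisk")
  if (!nzchar(path)) stop_fr("packaged data file '%s' not found", file)
  path
}
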
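# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_qmri <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop_qmri(msg, ...)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Degrees -> radians
deg2rad <- function(deg) deg * pi / 180

# Structured one-line log messages; silenced via option qmritk.quiet.
qmri_log <- function(stage, fmt, ...) {
  if (isTRUE(getOption("qmritk.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}
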
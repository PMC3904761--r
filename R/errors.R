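#' Structured error conditions
#'
#' All failure modes in physdep are signalled as classed conditions whose first
#' class is a stable machine-readable code (e.g. `"E_BAD_CONSTITUTIVE"`), so
#' callers can dispatch with `tryCatch(..., E_BAD_CONSTITUTIVE = ...)` and the
#' test suite can assert on the code rather than on message wording.
#'
#' @param code Stable error code, one of the `E_*` identifiers.
#' @param message Human-readable message.
#' @param ... Named data attached to the condition (e.g. offending ids).
#' @return Does not return; signals a condition of classes
#'   `c(code, "physdepError", "error", "condition")`.
#' @keywords internal
physdepStop <- function(code, message, ...) {
  cond <- structure(
    class = c(code, "physdepError", "error", "condition"),
    list(message = paste0("[", code, "] ", message), call = sys.call(-1), data = list(...))
  )
  stop(cond)
}
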
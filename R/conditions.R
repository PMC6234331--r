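# Classed error conditions so callers can distinguish capture-rule failures
# from programming errors.

hm_error <- function(class, message, ...) {
  stop(structure(
    class = c(paste0("handmetry_", class), "handmetry_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Test whether a condition is a handmetry error of a given class
#'
#' @param cnd A condition object.
#' @param class Short class name, e.g. `"no_paper_found"`.
#' @return Logical scalar.
#' @export
is_handmetry_error <- function(cnd, class = NULL) {
  if (!inherits(cnd, "handmetry_error")) return(FALSE)
  if (is.null(class)) return(TRUE)
  inherits(cnd, paste0("handmetry_", class))
}
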
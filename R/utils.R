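`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, ..., call. = FALSE) {
  if (isTRUE(cond)) stop(..., call. = call.)
  invisible(NULL)
}

#' Amino-acid alphabets used throughout the package
#'
#' Standard one-letter amino-acid codes ('X' is the canonical stop symbol on
#' input mutation tokens; '*' is accepted and normalized to 'X').
#' @keywords internal
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")

STOP_SYMBOL <- "X"

as_scalar_chr <- function(x) {
  x <- as.character(x)
  abort_if(length(x) != 1L, "expected a single string")
  x
}

as_scalar_int <- function(x, what = "value") {
  abort_if(length(x) != 1L || is.na(suppressWarnings(as.numeric(x))),
           sprintf("'%s' must be a single number", what))
  xi <- as.integer(round(as.numeric(x)))
  xi
}
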
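# Internal helpers: classed conditions and small predicates.

herbq_error <- function(message, class) {
  stop(errorCondition(message, class = c(class, "herbq_error")))
}

herbq_warning <- function(message, class = "herbq_warning") {
  warning(warningCondition(paste0(message, "\n"),
                           class = c(class, "herbq_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}

# Unambiguous nucleotides and the full accepted alignment alphabet.
.ACGT <- c("A", "C", "G", "T")
.ALN_ALPHABET <- c(.ACGT, "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "-")
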
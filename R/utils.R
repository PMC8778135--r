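#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a parent seed and a stage label.
# Keeps results < 2^31 so they are valid R integer seeds.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_mc <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "microconfound_error")))
}
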
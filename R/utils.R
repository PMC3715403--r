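# internal condition helpers: every user-facing failure carries a vardb_*
# class so callers (and tests) can distinguish format, parse, validation,
# bounds, version and integrity errors.

vardb_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "vardb_error", "error", "condition")))
}

vardb_warn <- function(msg, class = "vardb_warning") {
  warning(warningCondition(msg, class = c(class, "vardb_warning", "warning", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a private RNG stream; the caller's .Random.seed is untouched
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

trimws2 <- function(x) trimws(x, which = "both")

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
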
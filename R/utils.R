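#' @keywords internal
"_PACKAGE"

# Validation helpers used across modules. All user-facing errors go through
# stop_input() so they carry a consistent class for testing.

stop_input <- function(...) {
  stop(structure(
    class = c("gpcrtraffic_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_input(name, " must be finite and > 0")
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_input(name, " must be finite and >= 0")
  }
  invisible(x)
}

check_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_input(name, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Evaluate expr under a local RNG state seeded from `seed`, restoring the
# caller's RNG afterwards. Generators derive per-stream seeds so that one
# global seed fans out reproducibly without coupling the streams.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a sub-seed for a named generator stream from a single global seed.
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 9973L) * 7L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
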
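#' @keywords internal
"_PACKAGE"

# Internal validation helpers -------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, type = c("numeric", "integer", "logical"),
                         lower = -Inf, upper = Inf,
                         lower_open = FALSE, upper_open = FALSE) {
  type <- match.arg(type)
  if (length(x) != 1L || is.na(x)) stop_field(field, "must be a single non-NA value")
  if (type %in% c("numeric", "integer")) {
    if (!is.numeric(x)) stop_field(field, "must be numeric")
    if (type == "integer" && x != round(x)) stop_field(field, "must be a whole number")
    if (!is.finite(x)) stop_field(field, "must be finite")
    ok_lo <- if (lower_open) x > lower else x >= lower
    ok_hi <- if (upper_open) x < upper else x <= upper
    if (!ok_lo || !ok_hi) {
      stop_field(field, sprintf(
        "must be in %s%s, %s%s (got %g)",
        if (lower_open) "(" else "[", lower, upper,
        if (upper_open) ")" else "]", x
      ))
    }
  } else if (!is.logical(x)) {
    stop_field(field, "must be logical")
  }
  invisible(x)
}

# Deterministic sub-seed derivation: one master seed fans out to named
# streams (data, init, shuffle, ...) so runs are reproducible end to end.
derive_seed <- function(seed, stream) {
  offsets <- c(
    structure_ = 0L, samples = 1L, holdout = 2L, split = 3L,
    init = 4L, shuffle = 5L, dropout = 6L, tune = 7L, misc = 8L
  )
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  as.integer((as.double(seed) * 48271 + offsets[[stream]] * 104729) %% 2147483399) + 1L
}

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

msg_verbose <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
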
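# Internal helpers shared across modules.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' @noRd
stop_onhmorph <- function(msg, class = "onhmorph_error", ...) {
  stop(structure(
    class = c(class, "onhmorph_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_validation <- function(msg, ...) {
  stop_onhmorph(msg, class = "onhmorph_validation_error", ...)
}

stop_stats <- function(msg, ...) {
  stop_onhmorph(msg, class = "onhmorph_stats_error", ...)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_validation("`seed` must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed; stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + as.double(offset)) %% 2147483587)
}

# Fold an undirected axis angle into [0, 90] degrees.
fold_axis_angle <- function(x) {
  m <- x %% 180
  pmin(m, 180 - m)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) v / sqrt(sum(v^2))

check_number <- function(x, name, lo = -Inf, hi = Inf,
                         lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(sprintf("`%s` must be a single finite number", name))
  }
  bad_lo <- if (lo_open) x <= lo else x < lo
  bad_hi <- if (hi_open) x >= hi else x > hi
  if (bad_lo || bad_hi) {
    stop_validation(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s",
      name, x, if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ))
  }
  invisible(x)
}

check_laterality <- function(x) {
  if (!is.character(x) || length(x) != 1L || !(x %in% c("OD", "OS"))) {
    stop_validation("`laterality` must be \"OD\" or \"OS\"")
  }
  x
}
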
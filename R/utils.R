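#' @keywords internal
"_PACKAGE"

# Input checking helpers. All user-facing errors name the offending argument.

stop_input <- function(...) stop(..., call. = FALSE)

check_prob_vector <- function(p, name, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop_input(sprintf("'%s' must be a vector of nonnegative probabilities", name))
  }
  if (abs(sum(p) - 1) > tol) {
    stop_input(sprintf("'%s' must sum to 1 (got %.12g)", name, sum(p)))
  }
  invisible(p)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input(sprintf("'%s' must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    stop_input(sprintf("'%s' must be > %g", name, lower))
  }
  if (!strict_lower && x < lower) {
    stop_input(sprintf("'%s' must be >= %g", name, lower))
  }
  if (x > upper) stop_input(sprintf("'%s' must be <= %g", name, upper))
  invisible(x)
}

# Derive a child seed from a master seed and a stream label, keeping the
# result inside the 32-bit signed integer range that set.seed() accepts.
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483587 + 1)
}

# Evaluate code under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ANTIBODIES <- c("iaa", "gada", "ia2a")
SOURCES <- c("BABYDIAB", "DAISY", "DEW-IT", "DiPiS", "DIPP")
HLA_GROUPS <- c("A", "B", "C", "D")
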
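#' @keywords internal
"_PACKAGE"

# Canonical channel order used throughout: matches the wrist-device layout.
#' Names of the six wrist-sensor channels
#'
#' Channel order used by every array in the package: three-axis acceleration,
#' blood volume pulse, electrodermal activity, skin temperature.
#' @export
e4_signals <- c("ACC_x", "ACC_y", "ACC_z", "BVP", "EDA", "TEMP")

# Deterministic 31-bit hash of a character string (polynomial rolling hash).
# Used to derive per-subject / per-fold seeds that stay below 2^31.
str_hash31 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Derive a child seed from a base seed and one or more mix-in values.
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (m in list(...)) {
    if (is.character(m)) m <- str_hash31(m)
    h <- (h * 69069 + as.numeric(m)) %% 2147483647
  }
  as.integer(h)
}

# with_seed: evaluate expr under a local RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
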
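#' Evaluate an expression under a local RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards. All randomness in the package flows through this
#' helper so no call site leaks global random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive child seeds from a parent seed
#'
#' Deterministic, collision-unlikely child seeds in `[1, 2^31 - 2]` so that
#' per-section / per-replicate generators can be seeded independently.
#'
#' @param seed parent integer seed.
#' @param n number of child seeds.
#' @param salt optional integer mixed into the parent.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n, salt = 0L) {
  with_seed(as.integer(seed) %% 2147483646L + as.integer(salt),
            sample.int(2147483645L, n))
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# short non-cryptographic hash of an R object (FNV-1a over its JSON form),
# embedded in output files so a run's exact configuration is traceable
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}
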
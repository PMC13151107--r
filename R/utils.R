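# Internal helpers shared across modules.

#' @importFrom data.table data.table as.data.table setkeyv setorderv := .N .SD
NULL

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# per-pathway RNG streams from a master seed so results do not depend on the
# order in which pathways are scored.
.hash_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (code in utf8ToInt(x)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

.derive_seed <- function(master_seed, id) {
  as.integer((as.numeric(master_seed) + .hash_string(id)) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}
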
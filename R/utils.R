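# Seeding utilities and internal helpers.

#' Evaluate code under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the
#' caller's RNG state, so package internals never perturb user-level
#' reproducibility.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Maps a master seed and a stage label to a deterministic child seed
#' below `2^31 - 1`, so every pipeline stage gets its own independent
#' but reproducible RNG stream.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# Format a double so it round-trips exactly through text.
.num_to_chr <- function(x) sprintf("%.17g", x)
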
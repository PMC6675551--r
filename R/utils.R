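# Shared constants and small helpers.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes used throughout the package.
#'
#' @format Character vector of length 20.
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

is_canonical_sequence <- function(x) {
  nzchar(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
# Each generator derives its own sub-seed from the config seed so that
# changing one generator's parameters never perturbs another's stream.
local_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
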
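#' @importFrom rlang .data %||%
#' @importFrom stats rnorm quantile
NULL

# Run `code` under `set.seed(seed)` and restore the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
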
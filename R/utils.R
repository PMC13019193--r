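# internal helpers shared across modules

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Derive a child seed from a campaign seed
#'
#' One global seed expands deterministically into per-campaign child seeds
#' (`offset` 1 = cohort sampling, 2 = robustness LHS, 3 = healed-run
#' selection, 4 = synthetic time courses, 5 = fit multistarts), so each
#' campaign can be rerun independently. Values stay below 2^31.
#'
#' @param seed integer master seed.
#' @param offset positive integer campaign index.
#' @return An integer seed.
#' @export
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483647 + 1000003 * offset) %% 2147483647)
}
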
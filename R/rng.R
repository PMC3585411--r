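# Deterministic RNG management: one seeded L'Ecuyer-CMRG master stream with
# named substreams per stochastic module, so that adding draws to one module
# never perturbs another and fixed seeds give bit-identical runs.

#' Create named reproducible RNG substreams
#'
#' @param seed Integer master seed.
#' @param names Substream names.
#' @return An environment holding one independent L'Ecuyer-CMRG stream per
#'   name; pass to [rng_eval()].
#' @export
make_rng <- function(seed, names = c("angiogenesis", "hematocrit", "ecm")) {
  rng <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  for (nm in names) {
    s <- parallel::nextRNGStream(s)
    assign(nm, s, envir = rng)
  }
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  rng
}

#' Evaluate a function under a named RNG substream
#'
#' Swaps the substream state in, calls \code{fun} (which may use the usual
#' \code{runif}/\code{sample} machinery), and saves the advanced state back.
#'
#' @param rng Environment from [make_rng()].
#' @param name Substream name.
#' @param fun Zero-argument function performing the draws.
#' @return The value of \code{fun()}.
#' @export
rng_eval <- function(rng, name, fun) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(name, envir = rng), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", globalenv()), envir = rng)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  fun()
}
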
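#' Derive a replicate seed from a master seed
#'
#' Counter-based scheme used by the experiment layer: the replicate index is
#' mixed into the master seed through a fixed affine map modulo the largest
#' 32-bit prime, so every replicate (and every grid point of a sweep) gets a
#' reproducible seed without touching global RNG state.  All intermediate
#' products stay below 2^53, so the arithmetic is exact in doubles.
#'
#' @param master Master seed (integer-valued scalar).
#' @param index Non-negative counter (replicate or grid index).
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @export
replicate_seed <- function(master, index) {
  m <- 2147483647
  as.integer(((as.numeric(master) %% m) * 100003 + as.numeric(index)) %% m)
}

#' Draw a synthetic sample from a scenario model
#'
#' Subjects are i.i.d.; nodes are sampled in a fixed topological order
#' (lexicographic among incomparable nodes), each Bernoulli with
#' [conditional_probability()] given its already-sampled parents.  The same
#' `(model, n, seed)` always yields the identical table; the caller's RNG
#' state is left untouched.
#'
#' @param model A [scenario_model()].
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed.
#' @return A `data.frame` with one 0/1 integer column per node of the
#'   scenario DAG (in DAG node order) and `n` rows.
#'
#' @examples
#' m <- build_scenario("fig1a")
#' d <- simulate_dataset(m, 100, seed = 1)
#' colMeans(d)
#' @export
simulate_dataset <- function(model, n, seed) {
  stopifnot(inherits(model, "scenario_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  n <- as.integer(n)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  dag <- model$dag
  cols <- vector("list", length(dag$nodes))
  names(cols) <- dag$nodes
  for (v in dag$topo_order) {
    pars <- dag$parents[[v]]
    p <- if (!length(pars)) {
      model$root_prevalence[[v]]
    } else {
      eta <- rep(model$intercept[[v]], n)
      for (pa in pars)
        eta <- eta + model$edge_effect[[paste0(pa, "->", v)]] * cols[[pa]]
      stats::plogis(eta)
    }
    cols[[v]] <- stats::rbinom(n, 1L, p)
  }
  as.data.frame(cols[dag$nodes])
}
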
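# Single-shot local search: grow the seed, pick a subset of offspring,
# evaluate, sort.  Not an iterated optimizer — one grow-pick-evaluate
# sweep around a (typically posed) seed molecule.

#' Local grow-pick-evaluate search around a seed
#'
#' Grows the seed at hydrogen positions using the fragment table, keeps a
#' uniform-random subset of \code{pick} children (all of them when
#' \code{pick} exceeds the child count; none when \code{pick = 0}),
#' evaluates seed plus kept children and returns them sorted by ascending
#' cost.  The seed is always present in the output.
#'
#' @param seed SMILES, mol block or \linkS4class{Individual}.
#' @param growParams \linkS4class{MutationParams} for the grow step.
#' @param table \linkS4class{FragmentTable}.
#' @param pick number of offspring to keep (>= 0).
#' @param fitness \linkS4class{FitnessSpec}.
#' @param seedRng integer seed for the picking step (default 1).
#' @param njobs parallel evaluation width.
#' @return list of evaluated \linkS4class{Individual}, cost ascending.
#' @export
localRun <- function(seed, growParams = mutationParams(), table,
                     pick = 10L, fitness = fitnessSpec(), seedRng = 1L,
                     njobs = 1L) {
  stopifnot(pick >= 0)
  seedInd <- if (is(seed, "Individual")) seed else makeIndividual(seed, 0L)
  set.seed(seedRng)
  kids <- growMol(seedInd, growParams, table)
  kids <- setdiff(kids, seedInd@smiles)
  if (pick < length(kids)) kids <- sample(kids, pick)
  inds <- c(list(seedInd),
            lapply(seq_along(kids), function(i)
              makeIndividual(kids[i], idx = i)))
  inds <- evaluatePopulation(inds, fitness, njobs)
  costs <- vapply(inds, function(x) x@cost, numeric(1))
  ids <- vapply(inds, function(x) x@idx, integer(1))
  inds[order(costs, ids)]
}

#' Tabulate evaluated individuals
#'
#' One row per individual: identifier, SMILES, cost and the recorded
#' property values.  An empty input yields an empty table with headers.
#'
#' @param results list of \linkS4class{Individual}.
#' @return data.frame with columns idx, smiles, cost, score, qed,
#'   sa_score.
#' @export
resultsTable <- function(results) {
  getp <- function(x, nm) {
    v <- x@props[nm]
    if (is.null(v) || is.na(v)) NA_real_ else unname(v)
  }
  data.frame(
    idx = vapply(results, function(x) x@idx, integer(1)),
    smiles = vapply(results, function(x) x@smiles, character(1)),
    cost = vapply(results, function(x) x@cost, numeric(1)),
    score = vapply(results, getp, numeric(1), nm = "score"),
    qed = vapply(results, getp, numeric(1), nm = "qed"),
    sa_score = vapply(results, getp, numeric(1), nm = "sa_score"))
}
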
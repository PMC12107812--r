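# The crossover-free genetic algorithm: initialization, Boltzmann
# roulette selection, mutation-only offspring, elitist merge-and-truncate,
# multi-call statefulness and checkpointing.

#' Create a new (uninitialized) campaign state
#'
#' @param seedMols character vector of seed SMILES (or list of
#'   \linkS4class{Individual}); at least one valid molecule.
#' @param popsize target population size.
#' @param pc proportion of children per generation, in (0, 1]; each
#'   generation requests \code{max(1, round(pc * popsize))} children.
#' @param beta Boltzmann selection pressure (>= 0; 0 = uniform selection).
#' @param maxiter default number of generations per \code{\link{runGA}}
#'   call.
#' @param fitness \linkS4class{FitnessSpec}.
#' @param mutation \linkS4class{MutationParams}.
#' @param fragments \linkS4class{FragmentTable}.
#' @param seed integer master seed; every random draw of the campaign is
#'   derived from it and the generation number, so results are
#'   reproducible and independent of \code{njobs}.
#' @param njobs parallel evaluation width.
#' @param deffnm output file prefix.
#' @return An initialized, evaluated \linkS4class{GAState} at
#'   generation 0.
#' @export
newGA <- function(seedMols, popsize = 20L, pc = 0.5, beta = 1,
                  maxiter = 10L, fitness = fitnessSpec(),
                  mutation = mutationParams(), fragments,
                  seed = 1L, njobs = 1L, deffnm = "moldesirer") {
  state <- new("GAState", population = list(), generation = 0L,
               popsize = as.integer(popsize), pc = pc, beta = beta,
               maxiter = as.integer(maxiter), fitness = fitness,
               mutation = mutation, fragments = fragments,
               seedSmiles = character(0), rngSeed = as.integer(seed),
               seenSmiles = character(0),
               history = .empty_history(), popHistory = .empty_history(),
               generationStats = .empty_stats(), njobs = as.integer(njobs),
               deffnm = deffnm, idxCounter = 0L)
  initializePopulation(seedMols, state)
}

.empty_history <- function() {
  data.frame(generation = integer(0), idx = integer(0),
             smiles = character(0), cost = numeric(0), score = numeric(0),
             qed = numeric(0), sa_score = numeric(0), accepted = logical(0))
}

.empty_stats <- function() {
  data.frame(generation = integer(0), n_generated = integer(0),
             n_accepted = integer(0), acceptance_rate = numeric(0),
             best_cost = numeric(0), mean_cost = numeric(0))
}

.derive_seed <- function(master, generation) {
  as.integer((as.numeric(master) + as.numeric(generation) * 1000003) %%
               2147483647)
}

.history_rows <- function(inds, generation, accepted) {
  getp <- function(x, nm) {
    v <- x@props[nm]
    if (is.null(v) || is.na(v)) NA_real_ else unname(v)
  }
  data.frame(
    generation = generation,
    idx = vapply(inds, function(x) x@idx, integer(1)),
    smiles = vapply(inds, function(x) x@smiles, character(1)),
    cost = vapply(inds, function(x) x@cost, numeric(1)),
    score = vapply(inds, getp, numeric(1), nm = "score"),
    qed = vapply(inds, getp, numeric(1), nm = "qed"),
    sa_score = vapply(inds, getp, numeric(1), nm = "sa_score"),
    accepted = accepted)
}

#' Initialize the population from seed molecules
#'
#' Deduplicated seeds enter first; the population is then padded with
#' unique mutated variants of the seeds until \code{popsize} distinct
#' SMILES are collected (fewer, with a warning, when the mutator is
#' exhausted — padding with evaluation-identical copies is never done).
#' All members are evaluated and the generation-0 snapshot recorded.
#'
#' @param seedMols character SMILES vector or list of
#'   \linkS4class{Individual}.
#' @param state a \linkS4class{GAState} (its population is replaced).
#' @return the updated \linkS4class{GAState}.
#' @export
initializePopulation <- function(seedMols, state) {
  if (is.list(seedMols))
    seedMols <- vapply(seedMols, function(x)
      if (is(x, "Individual")) x@smiles else as.character(x), character(1))
  seeds <- character(0)
  for (s in seedMols) {
    smi <- try(.ob_canonical(s), silent = TRUE)
    if (!inherits(smi, "try-error")) seeds <- c(seeds, smi)
  }
  seeds <- unique(seeds)
  if (!length(seeds))
    stop("configuration error: no valid seed molecule", call. = FALSE)
  set.seed(.derive_seed(state@rngSeed, 0L))
  pool <- seeds
  # pad with mutated variants of the seeds (then of the pool) until full
  attempts <- 0L
  src_i <- 1L
  while (length(pool) < state@popsize && attempts < 10L * state@popsize) {
    src <- pool[((src_i - 1L) %% length(pool)) + 1L]
    src_i <- src_i + 1L
    attempts <- attempts + 1L
    kids <- try(mutateMol(src, state@mutation, state@fragments),
                silent = TRUE)
    if (inherits(kids, "try-error") || !length(kids)) next
    kids <- setdiff(kids, pool)
    if (!length(kids)) next
    take <- min(length(kids), state@popsize - length(pool))
    pool <- c(pool, sample(kids, take))
  }
  if (length(pool) < state@popsize)
    warning("mutator exhausted during initialization: population starts ",
            "with ", length(pool), " of ", state@popsize, " members",
            call. = FALSE)
  inds <- lapply(seq_along(pool), function(i)
    makeIndividual(pool[i], idx = i - 1L))
  inds <- evaluatePopulation(inds, state@fitness, state@njobs)
  state@population <- inds
  state@idxCounter <- length(inds)
  state@seedSmiles <- seeds
  state@seenSmiles <- pool
  state@generation <- 0L
  rows <- .history_rows(inds, 0L, TRUE)
  state@history <- rows
  state@popHistory <- rows
  costs <- vapply(inds, function(x) x@cost, numeric(1))
  state@generationStats <- data.frame(
    generation = 0L, n_generated = length(inds),
    n_accepted = length(inds), acceptance_rate = 1,
    best_cost = min(costs), mean_cost = mean(costs[is.finite(costs)]))
  validObject(state)
  state
}

#' Boltzmann roulette selection probabilities
#'
#' \eqn{P_i = e^{-\beta cost_i} / \sum_j e^{-\beta cost_j}} over the
#' finite-cost members; infinite-cost members get probability 0.  The
#' minimum cost is subtracted before exponentiation for numerical
#' stability (the distribution is invariant under cost shifts).
#' \code{beta = 0} yields uniform probabilities; large \code{beta}
#' concentrates on the best individual.
#'
#' @param costs numeric vector.
#' @param beta selection pressure, >= 0.
#' @return probability vector summing to 1.
#' @export
selectionProbabilities <- function(costs, beta) {
  stopifnot(beta >= 0)
  p <- numeric(length(costs))
  fin <- is.finite(costs)
  if (!any(fin))
    stop("selection error: all costs are infinite", call. = FALSE)
  x <- costs[fin] - min(costs[fin])
  e <- exp(-beta * x)
  p[fin] <- e / sum(e)
  p
}

#' Draw parents by roulette selection
#'
#' \code{n} independent draws with replacement from the Boltzmann
#' distribution over the current population.
#'
#' @param state a \linkS4class{GAState} with an evaluated population.
#' @param n number of draws.
#' @return list of \linkS4class{Individual} (possibly with repeats).
#' @export
selectParents <- function(state, n) {
  if (n <= 0) return(list())
  costs <- vapply(state@population, function(x) x@cost, numeric(1))
  p <- selectionProbabilities(costs, state@beta)
  state@population[sample.int(length(p), n, replace = TRUE, prob = p)]
}

#' Produce and evaluate one generation of offspring
#'
#' Requests \code{max(1, round(pc * popsize))} children.  Each roulette-
#' drawn parent contributes one child sampled from its mutation set;
#' children whose SMILES were generated before (campaign-wide) or already
#' sit in the population are discarded, with bounded retries.  Every
#' sampled child is recorded in \code{seenSmiles} whether or not it is
#' kept, so no structure is ever evaluated twice.  Accepted children are
#' evaluated in a batch.
#'
#' @param state a \linkS4class{GAState}.
#' @return list with \code{offspring} (evaluated individuals),
#'   \code{nGenerated} (children sampled, including discarded
#'   duplicates) and the updated \code{state} bookkeeping
#'   (\code{seenSmiles}, \code{idxCounter}).
#' @export
produceOffspring <- function(state) {
  nChildren <- max(1L, round(state@pc * state@popsize))
  popSmiles <- vapply(state@population, function(x) x@smiles, character(1))
  newSmiles <- character(0)
  nGenerated <- 0L
  attempts <- 0L
  maxAttempts <- 4L * nChildren
  while (length(newSmiles) < nChildren && attempts < maxAttempts) {
    attempts <- attempts + 1L
    parent <- selectParents(state, 1L)[[1]]
    kids <- try(mutateMol(parent, state@mutation, state@fragments),
                silent = TRUE)
    if (inherits(kids, "try-error") || !length(kids)) next
    child <- if (length(kids) == 1) kids else sample(kids, 1L)
    nGenerated <- nGenerated + 1L
    if (child %in% state@seenSmiles || child %in% popSmiles ||
        child %in% newSmiles) next
    state@seenSmiles <- c(state@seenSmiles, child)
    newSmiles <- c(newSmiles, child)
  }
  if (!length(newSmiles)) {
    warning("mutator produced no new offspring this generation",
            call. = FALSE)
    return(list(offspring = list(), nGenerated = nGenerated,
                state = state))
  }
  inds <- lapply(seq_along(newSmiles), function(i) {
    makeIndividual(newSmiles[i], idx = state@idxCounter + i - 1L)
  })
  state@idxCounter <- state@idxCounter + length(inds)
  inds <- evaluatePopulation(inds, state@fitness, state@njobs)
  list(offspring = inds, nGenerated = nGenerated, state = state)
}

#' Elitist merge-and-truncate
#'
#' Combines the current population with the offspring, sorts ascending by
#' cost (ties broken by lower identifier, i.e. older individuals first)
#' and keeps the best \code{popsize}.  The survivors always dominate:
#' the sorted cost vector after truncation is pointwise no worse than
#' before.
#'
#' @param population,offspring lists of evaluated
#'   \linkS4class{Individual}.
#' @param popsize number of survivors.
#' @return list of \code{popsize} (or fewer) individuals, unique SMILES.
#' @export
mergeAndTruncate <- function(population, offspring, popsize) {
  all <- uniqueIndividuals(c(population, offspring))
  costs <- vapply(all, function(x) x@cost, numeric(1))
  ids <- vapply(all, function(x) x@idx, integer(1))
  all[order(costs, ids)][seq_len(min(popsize, length(all)))]
}

#' Run the genetic algorithm
#'
#' Loops select-mutate-evaluate-merge for \code{generations} iterations
#' (default: the state's \code{maxiter}), recording per-generation
#' history.  The state is resumable: attributes such as \code{beta},
#' \code{maxiter} or the mutation parameters may be changed between calls
#' and the loop continues from the stored population; with an unchanged
#' configuration, split runs reproduce an uninterrupted run exactly.
#' Evaluation failures never abort the run (failed individuals carry
#' \code{cost = Inf} and lose truncation).
#'
#' @param state an initialized \linkS4class{GAState}.
#' @param generations number of generations to advance (0 = no-op).
#' @return the updated \linkS4class{GAState}.
#' @export
runGA <- function(state, generations = state@maxiter) {
  stopifnot(is(state, "GAState"), length(state@population) >= 1)
  if (generations <= 0) return(state)
  for (g in seq_len(generations)) {
    gen <- state@generation + 1L
    set.seed(.derive_seed(state@rngSeed, gen))
    off <- produceOffspring(state)
    state <- off$state
    newpop <- mergeAndTruncate(state@population, off$offspring,
                               state@popsize)
    keptSmiles <- vapply(newpop, function(x) x@smiles, character(1))
    accepted <- vapply(off$offspring, function(x)
      x@smiles %in% keptSmiles, logical(1))
    state@population <- newpop
    state@generation <- gen
    if (length(off$offspring))
      state@history <- rbind(state@history,
                             .history_rows(off$offspring, gen, accepted))
    state@popHistory <- rbind(state@popHistory,
                              .history_rows(newpop, gen, TRUE))
    costs <- vapply(newpop, function(x) x@cost, numeric(1))
    rate <- if (off$nGenerated > 0) sum(accepted) / off$nGenerated else 0
    state@generationStats <- rbind(state@generationStats, data.frame(
      generation = gen, n_generated = off$nGenerated,
      n_accepted = sum(accepted), acceptance_rate = rate,
      best_cost = min(costs),
      mean_cost = mean(costs[is.finite(costs)])))
    .log_info(sprintf(
      "generation %d: best %.4f mean %.4f acceptance %.2f",
      gen, min(costs), mean(costs[is.finite(costs)]), rate))
  }
  validObject(state)
  state
}

#' Checkpoint and resume a campaign
#'
#' \code{saveCheckpoint} writes the complete state as a bzip2-compressed
#' serialized object (conventional extension \code{.pbz2});
#' \code{loadCheckpoint} restores it and verifies integrity.  A resumed
#' run continues exactly where the saved run stopped: running 5 + 5
#' generations across a checkpoint equals 10 straight generations under
#' the same master seed.
#'
#' @param state a \linkS4class{GAState}.
#' @param path file path (e.g. \code{"run.pbz2"}).
#' @return \code{saveCheckpoint}: the path, invisibly;
#'   \code{loadCheckpoint}: a \linkS4class{GAState}.
#' @export
saveCheckpoint <- function(state, path) {
  stopifnot(is(state, "GAState"))
  saveRDS(state, path, compress = "bzip2")
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("load error: cannot read checkpoint ", sQuote(path), ": ",
         conditionMessage(e), call. = FALSE))
  if (!is(obj, "GAState"))
    stop("load error: ", sQuote(path), " does not contain a campaign ",
         "state", call. = FALSE)
  validObject(obj)
  obj
}

#' Write campaign outputs
#'
#' Writes the three standard artifacts for prefix
#' \code{state@deffnm} under \code{dir}: the compressed checkpoint
#' (\code{<prefix>.pbz2}), the final population SDF
#' (\code{<prefix>_pop.sdf}; members without 3D poses are skipped with a
#' warning) and the candidate history table
#' (\code{<prefix>_history.tsv}).
#'
#' @param state a \linkS4class{GAState}.
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
writeCampaignOutputs <- function(state, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, state@deffnm)
  paths <- c(checkpoint = paste0(base, ".pbz2"),
             sdf = paste0(base, "_pop.sdf"),
             history = paste0(base, "_history.tsv"))
  saveCheckpoint(state, paths["checkpoint"])
  suppressWarnings(writeIndividualsSDF(state@population, paths["sdf"]))
  utils::write.table(state@history, paths["history"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# ---- accessors -------------------------------------------------------------

#' GAState accessors
#'
#' @param object a \linkS4class{GAState}.
#' @return \code{population}: list of individuals; \code{generation}:
#'   integer; \code{campaignHistory}: candidate log data.frame;
#'   \code{generationStats}: per-generation counters data.frame;
#'   \code{bestIndividual}: lowest-cost member.
#' @export
setGeneric("population", function(object) standardGeneric("population"))

#' @rdname population
#' @export
setMethod("population", "GAState", function(object) object@population)

#' @rdname population
#' @export
setGeneric("generation", function(object) standardGeneric("generation"))

#' @rdname population
#' @export
setMethod("generation", "GAState", function(object) object@generation)

#' @rdname population
#' @export
setGeneric("campaignHistory",
           function(object) standardGeneric("campaignHistory"))

#' @rdname population
#' @export
setMethod("campaignHistory", "GAState", function(object) object@history)

#' @rdname population
#' @export
setGeneric("generationStats",
           function(object) standardGeneric("generationStats"))

#' @rdname population
#' @export
setMethod("generationStats", "GAState",
          function(object) object@generationStats)

#' @rdname population
#' @export
setGeneric("bestIndividual",
           function(object) standardGeneric("bestIndividual"))

#' @rdname population
#' @export
setMethod("bestIndividual", "GAState", function(object) {
  costs <- vapply(object@population, function(x) x@cost, numeric(1))
  object@population[[which.min(costs)]]
})
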
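# Built-in fitness family and the fitness-function contract used by the
# GA and Local engines.  Every fitness updates an Individual in place
# (functionally: returns the updated copy): cost, property record and pose
# payload.  Any failure poisons only that individual (cost = Inf).

#' Fitness specification constructor
#'
#' @param name fitness family: \code{"cost"} (desirability composite of
#'   score, qed and sa_score), \code{"cost_only_score"} (raw score),
#'   \code{"cost_multi_receptor"},
#'   \code{"cost_multi_receptor_only_score"}, or \code{"custom"}.
#' @param desirabilities named list of \linkS4class{DesirabilityParams};
#'   defaults to \code{\link{defaultDesirabilities}} for the families that
#'   use them.  Multi-receptor specs may add per-receptor entries named
#'   \code{vina_score_1}, \code{vina_score_2}, ...; missing entries fall
#'   back to the default score desirability (mirrored for anti-targets).
#' @param receptors list of receptor specs (each a list with
#'   \code{backend}, optional \code{receptor} path, \code{box},
#'   \code{direction} = \code{"minimize"}/\code{"maximize"}, and backend
#'   options).  A single surrogate on-target receptor is assumed when
#'   empty.
#' @param constraintType \code{NA}, \code{"score_only"} or
#'   \code{"local_only"}: route scoring through constrained conformer
#'   generation against \code{reference}.
#' @param reference reference structure (SDF/MOL path or mol block with 3D
#'   coordinates) for constrained scoring.
#' @param custom user fitness function for \code{name = "custom"}.
#' @return A \linkS4class{FitnessSpec}.
#' @export
fitnessSpec <- function(name = "cost", desirabilities = NULL,
                        receptors = list(), constraintType = NA_character_,
                        reference = NA_character_, custom = NULL) {
  if (is.null(desirabilities)) desirabilities <- defaultDesirabilities()
  if (grepl("multi_receptor", name) && length(receptors) < 2)
    stop("multi-receptor fitness requires >= 2 receptors", call. = FALSE)
  if (!length(receptors))
    receptors <- list(list(backend = "surrogate", direction = "minimize"))
  new("FitnessSpec", name = name, desirabilities = desirabilities,
      receptors = receptors, constraintType = constraintType,
      reference = reference, custom = custom)
}

# Score one individual against one receptor spec, honoring the
# constrained-conformation mode when configured.
.score_receptor <- function(ind, spec, receptor) {
  if (!is.na(spec@constraintType)) {
    constrainedScore(ind, reference = spec@reference,
                     protein = receptor$receptor,
                     mode = spec@constraintType, backend = receptor)
  } else {
    scorerBackend(ind, receptor)
  }
}

#' Evaluate an individual under a fitness specification
#'
#' Dispatches to the built-in fitness families.  For the desirability
#' families the cost is \eqn{1 - D} with \eqn{D} the weighted geometric
#' mean of the per-property desirabilities, so cost lies in [0, 1] and 0
#' means every property sits at (or beyond) its target.  Scoring, QED or
#' synthetic-accessibility failures are caught: the individual comes back
#' with \code{cost = Inf} and a warning names its SMILES.
#'
#' @param ind an \linkS4class{Individual}.
#' @param spec a \linkS4class{FitnessSpec}.
#' @return the updated \linkS4class{Individual}.
#' @export
evaluateFitness <- function(ind, spec) {
  res <- tryCatch(.evaluate_fitness_inner(ind, spec), error = function(e) {
    warning("evaluation failed for ", sQuote(ind@smiles), ": ",
            conditionMessage(e), call. = FALSE)
    ind@cost <- Inf
    ind
  })
  res
}

.evaluate_fitness_inner <- function(ind, spec) {
  switch(spec@name,
         cost = .fit_cost(ind, spec),
         cost_only_score = .fit_cost_only_score(ind, spec),
         cost_multi_receptor = .fit_multi(ind, spec, only_score = FALSE),
         cost_multi_receptor_only_score = .fit_multi(ind, spec,
                                                     only_score = TRUE),
         custom = {
           if (!is.function(spec@custom))
             stop("custom fitness spec carries no function")
           spec@custom(ind)
         })
}

.fit_cost <- function(ind, spec) {
  des <- spec@desirabilities
  sc <- .score_receptor(ind, spec, spec@receptors[[1]])
  q <- computeQED(ind)
  sa <- computeSAScore(ind)
  d <- c(applyDesirability(sc$score, des$vina_score),
         applyDesirability(q, des$qed),
         applyDesirability(sa, des$sa_score))
  w <- c(des$vina_score@w, des$qed@w, des$sa_score@w)
  ind@cost <- 1 - weightedGeometricMean(d, w)
  ind@props <- c(score = sc$score, qed = q, sa_score = sa)
  ind@pdbqt <- sc$pose
  ind
}

.fit_cost_only_score <- function(ind, spec) {
  sc <- .score_receptor(ind, spec, spec@receptors[[1]])
  ind@cost <- sc$score
  ind@props <- c(score = sc$score)
  ind@pdbqt <- sc$pose
  ind
}

# Desirability for receptor k: explicit vina_score_k entry when present,
# else the default score desirability for on-targets, or its mirrored
# larger-the-best counterpart for anti-targets.
.receptor_desirability <- function(des, k, direction) {
  key <- paste0("vina_score_", k)
  if (!is.null(des[[key]])) return(des[[key]])
  base <- des$vina_score
  if (is.null(base)) base <- defaultDesirabilities()$vina_score
  if (identical(direction, "maximize")) {
    desirabilityParams("larger_the_best", l = base@t, t = base@u,
                       r = base@r, w = base@w)
  } else base
}

.fit_multi <- function(ind, spec, only_score = FALSE) {
  des <- spec@desirabilities
  d <- numeric(0); w <- numeric(0)
  poses <- character(0)
  scores <- numeric(0)
  for (k in seq_along(spec@receptors)) {
    rc <- spec@receptors[[k]]
    dirn <- if (is.null(rc$direction)) "minimize" else rc$direction
    sc <- .score_receptor(ind, spec, rc)
    scores[k] <- sc$score
    poses[k] <- sc$pose
    dp <- .receptor_desirability(des, k, dirn)
    d <- c(d, applyDesirability(sc$score, dp))
    w <- c(w, dp@w)
  }
  names(scores) <- paste0("score_", seq_along(scores))
  if (!only_score) {
    q <- computeQED(ind)
    sa <- computeSAScore(ind)
    qd <- if (is.null(des$qed)) defaultDesirabilities()$qed else des$qed
    sd <- if (is.null(des$sa_score)) defaultDesirabilities()$sa_score else
      des$sa_score
    d <- c(d, applyDesirability(q, qd), applyDesirability(sa, sd))
    w <- c(w, qd@w, sd@w)
    extra <- c(qed = q, sa_score = sa)
  } else extra <- numeric(0)
  ind@cost <- 1 - weightedGeometricMean(d, w)
  ind@props <- c(scores, extra)
  ind@pdbqt <- poses[1]
  ind
}

#' Evaluate a list of individuals
#'
#' Batch evaluation used by the engines.  QED/synthetic-accessibility
#' values for all candidates are prefetched in one descriptor-helper call;
#' scoring then runs serially or, when \code{njobs > 1}, across forked
#' workers (evaluation is the only parallel section; the caller owns all
#' state, and results are independent of \code{njobs}).
#'
#' @param individuals list of \linkS4class{Individual}.
#' @param spec a \linkS4class{FitnessSpec}.
#' @param njobs integer worker count.
#' @return list of evaluated individuals, in input order.
#' @export
evaluatePopulation <- function(individuals, spec, njobs = 1L) {
  if (!length(individuals)) return(individuals)
  if (spec@name %in% c("cost", "cost_multi_receptor")) {
    try(prefetchDescriptors(vapply(individuals, function(x) x@smiles,
                                   character(1))), silent = TRUE)
  }
  if (njobs > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(individuals, evaluateFitness, spec = spec,
                       mc.cores = njobs)
  } else {
    lapply(individuals, evaluateFitness, spec = spec)
  }
}

#' Validate a user fitness callable against the engine contract
#'
#' The contract: the callable's first parameter is an
#' \linkS4class{Individual}; it returns an \linkS4class{Individual} with a
#' numeric cost set (finite or \code{Inf}); and it is serializable so it
#' can ship to worker processes and into checkpoints.  The check performs
#' a serialization round trip and a dry run on a probe molecule (methane)
#' and reports violations rather than erroring.
#'
#' @param fn a function, or path to an R file whose last expression (or a
#'   function named \code{fitness}) is the callable.
#' @return character vector of violations; empty when the contract holds.
#' @export
validateFitnessCallable <- function(fn) {
  violations <- character(0)
  if (is.character(fn)) {
    if (!file.exists(fn)) return("not a function or readable file")
    env <- new.env(parent = globalenv())
    last <- try(source(fn, local = env)$value, silent = TRUE)
    if (inherits(last, "try-error"))
      return(paste("cannot source fitness file:", fn))
    fn <- if (is.function(env$fitness)) env$fitness else last
  }
  if (!is.function(fn)) return("not a function")
  if (length(formals(fn)) < 1)
    violations <- c(violations, "must accept an Individual as first argument")
  ser <- try(suppressWarnings(serialize(fn, NULL)), silent = TRUE)
  if (inherits(ser, "try-error"))
    violations <- c(violations, "not serializable")
  probe <- makeIndividual("C", idx = -1L)
  out <- try(suppressWarnings(fn(probe)), silent = TRUE)
  if (inherits(out, "try-error")) {
    violations <- c(violations, "dry run on a probe Individual errors")
  } else if (!is(out, "Individual")) {
    violations <- c(violations, "does not return Individual")
  } else if (!is.numeric(out@cost) || length(out@cost) != 1 ||
             is.na(out@cost)) {
    violations <- c(violations, "returned Individual has no numeric cost")
  }
  violations
}
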
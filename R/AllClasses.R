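#' @import methods
NULL

#' Candidate molecule in an optimization campaign
#'
#' An \code{Individual} bundles one candidate: its mol block (connection
#' table, optionally with a 3D conformer), an integer identifier, the
#' canonical SMILES string that defines its identity, an opaque docked-pose
#' payload and a scalar cost (lower is better; \code{Inf} marks an
#' unevaluated or failed candidate).  Two individuals are considered the
#' same molecule exactly when their canonical SMILES strings are equal.
#'
#' @slot mol character scalar, V2000 mol block of the molecule.
#' @slot idx integer identifier, unique within a campaign.
#' @slot smiles canonical SMILES without explicit hydrogens; set at
#'   construction and never mutated.
#' @slot pdbqt opaque text payload for a docked pose (placeholder until a
#'   scoring backend provides one).
#' @slot cost numeric fitness, lower is better; \code{Inf} = unevaluated.
#' @slot props named numeric vector of property values recorded during
#'   fitness evaluation (e.g. \code{score}, \code{qed}, \code{sa_score}).
#' @exportClass Individual
setClass("Individual",
         representation(mol = "character", idx = "integer",
                        smiles = "character", pdbqt = "character",
                        cost = "numeric", props = "numeric"),
         prototype(mol = "", idx = 0L, smiles = "", pdbqt = "",
                   cost = Inf, props = numeric(0)))

setValidity("Individual", function(object) {
  msg <- character(0)
  if (length(object@smiles) != 1 || !nzchar(object@smiles))
    msg <- c(msg, "smiles must be a non-empty character scalar")
  if (length(object@cost) != 1)
    msg <- c(msg, "cost must be a numeric scalar")
  if (length(object@idx) != 1)
    msg <- c(msg, "idx must be an integer scalar")
  if (length(msg)) msg else TRUE
})

#' Morgan fingerprint
#'
#' Fixed-length binary fingerprint from iterative circular-neighborhood
#' hashing (ECFP-style), radius 2 and 2048 bits by default.
#'
#' @slot bits logical vector of length \code{nbits}.
#' @slot radius integer neighborhood radius.
#' @slot nbits integer fingerprint length.
#' @exportClass Fingerprint
setClass("Fingerprint",
         representation(bits = "logical", radius = "integer",
                        nbits = "integer"))

setValidity("Fingerprint", function(object) {
  if (length(object@bits) != object@nbits)
    return("bit vector length must equal nbits")
  if (object@radius < 0L) return("radius must be >= 0")
  TRUE
})

#' Desirability transform parameters
#'
#' Parameters of one Derringer--Suich desirability transform.  The three
#' shapes are \code{"larger_the_best"} (needs \code{l < t}),
#' \code{"smaller_the_best"} (needs \code{t < u}) and
#' \code{"nominal_the_best"} (needs \code{l < t < u}, with separate rising
#' and falling exponents \code{r1}, \code{r2}).
#'
#' @slot shape one of the three shape names above.
#' @slot l,u,t lower limit, upper limit, target (unused limits are NA).
#' @slot r,r1,r2 positive exponents; \code{r} for the monotone shapes.
#' @slot w non-negative aggregation weight.
#' @exportClass DesirabilityParams
setClass("DesirabilityParams",
         representation(shape = "character", l = "numeric", u = "numeric",
                        t = "numeric", r = "numeric", r1 = "numeric",
                        r2 = "numeric", w = "numeric"),
         prototype(l = NA_real_, u = NA_real_, r = 1, r1 = 1, r2 = 1, w = 1))

setValidity("DesirabilityParams", function(object) {
  sh <- object@shape
  if (!sh %in% c("larger_the_best", "smaller_the_best", "nominal_the_best"))
    return("unknown desirability shape")
  if (object@w < 0) return("weight w must be >= 0")
  if (sh == "larger_the_best") {
    if (is.na(object@l) || !(object@l < object@t))
      return("larger_the_best requires l < t")
    if (object@r <= 0) return("exponent r must be > 0")
  } else if (sh == "smaller_the_best") {
    if (is.na(object@u) || !(object@t < object@u))
      return("smaller_the_best requires t < u")
    if (object@r <= 0) return("exponent r must be > 0")
  } else {
    if (is.na(object@l) || is.na(object@u) ||
        !(object@l < object@t && object@t < object@u))
      return("nominal_the_best requires l < t < u")
    if (object@r1 <= 0 || object@r2 <= 0) return("r1, r2 must be > 0")
  }
  TRUE
})

#' Staged structure-generation controls
#'
#' Controls for the fragment-replacement mutator: the heavy-atom size range
#' of the replaced fragment (\code{minSize}..\code{maxSize}, 0 meaning
#' hydrogen positions), the allowed change in heavy-atom count
#' (\code{minInc}..\code{maxInc}, may be negative), a context radius kept
#' for compatibility with external fragment libraries, and a set of
#' protected atom indices that must never be removed or replaced.
#'
#' @slot radius integer context radius (forwarded to external generators;
#'   the built-in mutator replaces by size and increment only).
#' @slot minSize,maxSize integer heavy-atom size bounds of replaced sites.
#' @slot minInc,maxInc integer bounds on the heavy-atom count change.
#' @slot protected integer indices of heavy atoms never altered.
#' @slot maxChildren integer cap on children returned per call.
#' @exportClass MutationParams
setClass("MutationParams",
         representation(radius = "integer", minSize = "integer",
                        maxSize = "integer", minInc = "integer",
                        maxInc = "integer", protected = "integer",
                        maxChildren = "integer"),
         prototype(radius = 3L, minSize = 0L, maxSize = 0L, minInc = 1L,
                   maxInc = 6L, protected = integer(0), maxChildren = 50L))

setValidity("MutationParams", function(object) {
  if (object@minSize > object@maxSize) return("minSize must be <= maxSize")
  if (object@minInc > object@maxInc) return("minInc must be <= maxInc")
  if (object@radius < 0L) return("radius must be >= 0")
  if (object@minSize < 0L) return("minSize must be >= 0")
  if (object@maxChildren < 1L) return("maxChildren must be >= 1")
  TRUE
})

#' Table of attachable fragments
#'
#' A fragment table drives the built-in mutator.  Each row holds a fragment
#' SMILES with exactly one attachment point written as a terminal \code{*}
#' dummy atom (e.g. \code{*C} for methyl, \code{*c1ccccc1} for phenyl), its
#' heavy-atom count (the dummy does not count) and an optional maximum
#' synthetic-accessibility annotation.
#'
#' @slot table data.frame with columns \code{fragment_smiles},
#'   \code{heavy_atoms} and optionally \code{max_sa}.
#' @exportClass FragmentTable
setClass("FragmentTable", representation(table = "data.frame"))

setValidity("FragmentTable", function(object) {
  tb <- object@table
  need <- c("fragment_smiles", "heavy_atoms")
  if (!all(need %in% colnames(tb)))
    return("table needs columns fragment_smiles, heavy_atoms")
  if (nrow(tb) == 0) return("fragment table must not be empty")
  TRUE
})

#' Docking box specification
#'
#' Search-volume specification handed to a docking backend: a center and
#' box edge lengths in Angstrom, plus the engine's exhaustiveness setting.
#'
#' @slot center numeric length-3 center (x, y, z) in Angstrom.
#' @slot dimensions numeric length-3 box edges in Angstrom, all > 0.
#' @slot exhaustiveness integer >= 1 search effort (default 9).
#' @exportClass DockingBox
setClass("DockingBox",
         representation(center = "numeric", dimensions = "numeric",
                        exhaustiveness = "integer"),
         prototype(center = c(0, 0, 0), dimensions = c(20, 20, 20),
                   exhaustiveness = 9L))

setValidity("DockingBox", function(object) {
  if (length(object@center) != 3) return("center must have length 3")
  if (length(object@dimensions) != 3 || any(object@dimensions <= 0))
    return("dimensions must be 3 positive lengths")
  if (object@exhaustiveness < 1L) return("exhaustiveness must be >= 1")
  TRUE
})

#' Fitness-function specification
#'
#' Selects one of the built-in fitness families and carries everything the
#' evaluation needs: the per-property desirability transforms, the ordered
#' receptor list (scoring backend, receptor file, docking box, direction)
#' and an optional constrained-conformation mode.
#'
#' @slot name one of \code{"cost"}, \code{"cost_only_score"},
#'   \code{"cost_multi_receptor"}, \code{"cost_multi_receptor_only_score"},
#'   \code{"custom"}.
#' @slot desirabilities named list of \linkS4class{DesirabilityParams}
#'   keyed by property (\code{vina_score}, \code{qed}, \code{sa_score};
#'   multi-receptor specs use \code{vina_score_1}, \code{vina_score_2}, ...).
#' @slot receptors list of receptor specs, each a list with elements
#'   \code{backend}, \code{receptor}, \code{box}, \code{direction}
#'   (\code{"minimize"} for on-targets, \code{"maximize"} for anti-targets).
#' @slot constraintType \code{NA}, \code{"score_only"} or
#'   \code{"local_only"}; when set, scoring goes through constrained
#'   conformer generation against \code{reference}.
#' @slot reference character path (SDF/MOL with 3D coordinates) or mol
#'   block of the reference core for constrained scoring; \code{NA} when
#'   unused.
#' @slot custom function or NULL; user fitness callable for
#'   \code{name = "custom"}.
#' @exportClass FitnessSpec
setClass("FitnessSpec",
         representation(name = "character", desirabilities = "list",
                        receptors = "list", constraintType = "character",
                        reference = "character", custom = "ANY"),
         prototype(name = "cost", desirabilities = list(),
                   receptors = list(), constraintType = NA_character_,
                   reference = NA_character_, custom = NULL))

setValidity("FitnessSpec", function(object) {
  ok <- c("cost", "cost_only_score", "cost_multi_receptor",
          "cost_multi_receptor_only_score", "custom")
  if (!object@name %in% ok)
    return(paste("unknown fitness name:", object@name))
  for (rc in object@receptors) {
    if (!is.null(rc$direction) &&
        !rc$direction %in% c("minimize", "maximize"))
      return("receptor direction must be 'minimize' or 'maximize'")
  }
  if (!is.na(object@constraintType) &&
      !object@constraintType %in% c("score_only", "local_only"))
    return("constraintType must be score_only or local_only")
  TRUE
})

#' Constrained conformer set
#'
#' Conformers of a candidate whose core atoms are held at a 3D reference,
#' with per-conformer bookkeeping: the candidate-to-reference atom map, the
#' core RMSD achieved, whether the conformer came from the rigid-alignment
#' fallback rather than constrained embedding, and protein-clash flags.
#' The surviving set is the conformers whose clash flag is \code{FALSE}.
#'
#' @slot smiles canonical SMILES of the candidate.
#' @slot conformers list of numeric n x 3 heavy-atom coordinate matrices.
#' @slot mapping integer vector, candidate atom index for each reference
#'   atom (injective).
#' @slot clashFlags logical per conformer.
#' @slot coreRmsd numeric per conformer, Angstrom.
#' @slot fallback logical per conformer (TRUE = aligned, not embedded).
#' @exportClass ConformerSet
setClass("ConformerSet",
         representation(smiles = "character", conformers = "list",
                        mapping = "integer", clashFlags = "logical",
                        coreRmsd = "numeric", fallback = "logical"))

setValidity("ConformerSet", function(object) {
  nc <- length(object@conformers)
  if (length(object@clashFlags) != nc || length(object@coreRmsd) != nc ||
      length(object@fallback) != nc)
    return("per-conformer slots must have one entry per conformer")
  if (any(object@coreRmsd < 0, na.rm = TRUE)) return("coreRmsd must be >= 0")
  if (anyDuplicated(object@mapping)) return("mapping must be injective")
  TRUE
})

#' Free-energy record for relative-to-absolute conversion
#'
#' Inputs of the RBFE-to-ABFE arithmetic: the relative binding free energy
#' of molecule i, the relative and absolute values of the campaign's
#' representative molecule, and the statistical error of each (all in
#' kcal/mol).
#'
#' @slot ddgI,ddgR,dgR numeric free energies (kcal/mol).
#' @slot errDdgI,errDdgR,errDgR non-negative errors (kcal/mol).
#' @exportClass FreeEnergyRecord
setClass("FreeEnergyRecord",
         representation(ddgI = "numeric", ddgR = "numeric", dgR = "numeric",
                        errDdgI = "numeric", errDdgR = "numeric",
                        errDgR = "numeric"),
         prototype(errDdgI = 0, errDdgR = 0, errDgR = 0))

setValidity("FreeEnergyRecord", function(object) {
  errs <- c(object@errDdgI, object@errDdgR, object@errDgR)
  if (any(!is.finite(c(object@ddgI, object@ddgR, object@dgR))))
    return("free energies must be finite")
  if (any(errs < 0)) return("errors must be >= 0")
  TRUE
})

#' Genetic-algorithm state
#'
#' The complete, serializable state of a campaign: the current population,
#' generation counter, selection and offspring parameters, fitness and
#' mutation configuration, the set of all SMILES ever generated, and
#' append-only histories.  Saving and reloading a \code{GAState} and
#' continuing the run reproduces an uninterrupted run under the same seed.
#'
#' @slot population list of \linkS4class{Individual}; unique SMILES.
#' @slot generation integer generation counter (0 = initialized).
#' @slot popsize integer target population size.
#' @slot pc numeric proportion of children per generation, in (0, 1].
#' @slot beta numeric Boltzmann selection pressure, >= 0.
#' @slot maxiter integer default number of generations per \code{runGA} call.
#' @slot fitness \linkS4class{FitnessSpec}.
#' @slot mutation \linkS4class{MutationParams}.
#' @slot fragments \linkS4class{FragmentTable}.
#' @slot seedSmiles canonical SMILES of the seed molecule(s).
#' @slot rngSeed integer master seed; all per-generation randomness is
#'   derived deterministically from it and the generation number.
#' @slot seenSmiles character, every SMILES ever generated in the campaign.
#' @slot history data.frame candidate log (generation, idx, smiles, cost,
#'   score, qed, sa_score, accepted).
#' @slot popHistory data.frame population snapshot after each generation.
#' @slot generationStats data.frame per-generation counters (generated,
#'   accepted, acceptance rate, best/mean cost).
#' @slot njobs integer parallel evaluation width.
#' @slot deffnm character output file prefix.
#' @slot idxCounter integer next free individual identifier.
#' @exportClass GAState
setClass("GAState",
         representation(population = "list", generation = "integer",
                        popsize = "integer", pc = "numeric",
                        beta = "numeric", maxiter = "integer",
                        fitness = "FitnessSpec", mutation = "MutationParams",
                        fragments = "FragmentTable", seedSmiles = "character",
                        rngSeed = "integer", seenSmiles = "character",
                        history = "data.frame", popHistory = "data.frame",
                        generationStats = "data.frame", njobs = "integer",
                        deffnm = "character", idxCounter = "integer"),
         prototype(generation = 0L, popsize = 20L, pc = 0.5, beta = 1,
                   maxiter = 10L, rngSeed = 1L, seenSmiles = character(0),
                   njobs = 1L, deffnm = "moldesirer", idxCounter = 0L))

setValidity("GAState", function(object) {
  if (object@popsize < 1L) return("popsize must be >= 1")
  if (object@pc <= 0 || object@pc > 1) return("pc must be in (0, 1]")
  if (object@beta < 0) return("beta must be >= 0")
  if (object@generation < 0L) return("generation must be >= 0")
  smi <- vapply(object@population, function(x) x@smiles, character(1))
  if (anyDuplicated(smi))
    return("population members must have unique SMILES")
  TRUE
})

#' Multi-stage run plan
#'
#' An ordered list of named runs parsed from a YAML configuration.  The
#' first run carries the full initialization (seed molecule, fitness,
#' fragment table); later runs only override mutable attributes such as
#' \code{beta}, \code{maxiter} or the mutation parameters.
#'
#' @slot runs named list; each element a list of validated run settings.
#' @exportClass RunPlan
setClass("RunPlan", representation(runs = "list"))

# ---- show methods ----------------------------------------------------------

setMethod("show", "Individual", function(object) {
  cost <- if (is.finite(object@cost)) sprintf("%.4f", object@cost) else "Inf"
  cat("Individual #", object@idx, "  ", object@smiles, "\n",
      "  cost: ", cost,
      if (length(object@props))
        paste0("  [", paste(names(object@props),
                            sprintf("%.3f", object@props), sep = "=",
                            collapse = ", "), "]") else "",
      "\n", sep = "")
})

setMethod("show", "Fingerprint", function(object) {
  cat("Morgan fingerprint: radius", object@radius, "|", object@nbits,
      "bits |", sum(object@bits), "set\n")
})

setMethod("show", "FragmentTable", function(object) {
  cat("FragmentTable with", nrow(object@table), "fragments; heavy atoms",
      min(object@table$heavy_atoms), "-", max(object@table$heavy_atoms), "\n")
})

setMethod("show", "GAState", function(object) {
  cat("GAState: generation", object@generation, "| population",
      length(object@population), "/", object@popsize,
      "| pc", object@pc, "| beta", object@beta, "\n")
  costs <- vapply(object@population, function(x) x@cost, numeric(1))
  if (length(costs) && any(is.finite(costs)))
    cat("  best cost:", sprintf("%.4f", min(costs)),
        "| mean cost:", sprintf("%.4f", mean(costs[is.finite(costs)])), "\n")
  cat("  molecules generated so far:", length(object@seenSmiles), "\n")
})

setMethod("show", "ConformerSet", function(object) {
  cat("ConformerSet:", length(object@conformers), "conformers (",
      sum(!object@clashFlags), "surviving ) for", object@smiles, "\n")
})

setMethod("show", "FitnessSpec", function(object) {
  cat("FitnessSpec:", object@name,
      if (!is.na(object@constraintType))
        paste0("[", object@constraintType, "]") else "", "\n")
  if (length(object@receptors))
    cat("  receptors:", length(object@receptors), "\n")
})
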
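# Deterministic fixtures: toy fragment tables, toy receptors, and the
# staged campaign plan.  Everything here is pure given its seed, so tests
# and examples need no downloads.

.FRAGMENT_POOL <- c(
  "*C", "*CC", "*CCC", "*C(C)C", "*CCCC", "*O", "*OC", "*OCC", "*N",
  "*NC", "*N(C)C", "*F", "*Cl", "*Br", "*C=O", "*C(=O)C", "*C(=O)O",
  "*C(=O)N", "*C#N", "*S", "*SC", "*c1ccccc1", "*c1ccncc1", "*c1ccco1",
  "*c1cccs1", "*C(F)(F)F", "*CO", "*CN", "*CCO", "*CCN")

#' Build a deterministic toy fragment table
#'
#' Samples \code{nFragments} simple substituents (alkyl, hydroxyl, amino,
#' halogen, carbonyl, phenyl, small heteroaryl, ...) from a fixed pool,
#' keeping only fragments of at most \code{maxHeavy} heavy atoms.  The
#' same seed always yields the same table.
#'
#' @param seed integer seed.
#' @param nFragments number of fragments (>= 1; capped at the pool size).
#' @param maxHeavy largest fragment size in heavy atoms (default 6).
#' @param path optional TSV output path; when given, the table is also
#'   written (tab-separated, \code{fragment_smiles} and
#'   \code{heavy_atoms}).
#' @return A \linkS4class{FragmentTable}.
#' @export
buildToyFragmentTable <- function(seed = 1L, nFragments = 12L,
                                  maxHeavy = 6L, path = NULL) {
  stopifnot(nFragments >= 1)
  tab <- fragmentTable(.FRAGMENT_POOL)
  tab <- tab@table[tab@table$heavy_atoms <= maxHeavy, ]
  set.seed(seed)
  n <- min(nFragments, nrow(tab))
  tab <- tab[sort(sample.int(nrow(tab), n)), ]
  rownames(tab) <- NULL
  ft <- new("FragmentTable", table = tab)
  if (!is.null(path)) writeFragmentTable(ft, path)
  ft
}

#' Build a toy receptor as protein heavy-atom coordinates
#'
#' Two deterministic pseudo-receptors made of carbon pseudo-atoms, enough
#' chemistry for clash-filter work:
#' \describe{
#'   \item{cavity}{a spherical shell of atoms (radius 8, grid spacing
#'     about 1.5) leaving an empty pocket at the origin;}
#'   \item{wall}{a flat plane of atoms at x = 0 (y, z grid from -10 to
#'     10, spacing 1).}
#' }
#'
#' @param kind \code{"cavity"} or \code{"wall"}.
#' @param path optional PDB output path.
#' @return numeric m x 3 coordinate matrix (Angstrom); written as a PDB
#'   file too when \code{path} is given.
#' @export
buildToyReceptor <- function(kind = c("cavity", "wall"), path = NULL) {
  kind <- match.arg(kind)
  if (kind == "wall") {
    g <- seq(-10, 10, by = 1)
    coords <- as.matrix(expand.grid(x = 0, y = g, z = g))
  } else {
    # golden-spiral points on a sphere of radius 8
    n <- 350L
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)
    theta <- pi * (1 + sqrt(5)) * i
    coords <- 8 * cbind(x = sin(phi) * cos(theta),
                        y = sin(phi) * sin(theta), z = cos(phi))
  }
  rownames(coords) <- NULL
  if (!is.null(path)) .write_pseudo_pdb(coords, path)
  coords
}

.write_pseudo_pdb <- function(coords, path) {
  lines <- vapply(seq_len(nrow(coords)), function(i) {
    sprintf("ATOM  %5d  C   UNK A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, i, coords[i, 1], coords[i, 2], coords[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Staged campaign plan mirroring the lead-optimization schedule
#'
#' A four-stage plan reproducing the canonical mutation schedule — pure
#' growth, growth with limited substitution, pure mutation, and point
#' mutations — with parameter tuples (minSize, maxSize, minInc, maxInc)
#' of (0,0,1,6), (0,2,-2,4), (1,8,-5,3) and (0,1,-1,1), all at context
#' radius 3.  Generation counts are scaled down from the published
#' 20/25/40/15 schedule by \code{generationsPerStage / 100}.
#'
#' @param popsize population size for every stage.
#' @param generationsPerStage total generations across the four stages
#'   (split proportionally to 20/25/40/15; each stage gets at least 1).
#' @param seedMol seed molecule SMILES.
#' @param fragmentTablePath path to a fragment-table TSV (the plan
#'   references it; build one with \code{\link{buildToyFragmentTable}}).
#' @param seed master seed.
#' @return A \linkS4class{RunPlan} with runs \code{01_grow},
#'   \code{02_allow_grow}, \code{03_pure_mutate}, \code{04_local_stage}.
#' @export
stagedCampaignConfig <- function(popsize = 20L, generationsPerStage = 8L,
                                 seedMol = "C", fragmentTablePath,
                                 seed = 1L) {
  stopifnot(popsize >= 1, generationsPerStage >= 4)
  stages <- data.frame(
    name = c("01_grow", "02_allow_grow", "03_pure_mutate",
             "04_local_stage"),
    min_size = c(0L, 0L, 1L, 0L), max_size = c(0L, 2L, 8L, 1L),
    min_inc = c(1L, -2L, -5L, -1L), max_inc = c(6L, 4L, 3L, 1L),
    weight = c(20, 25, 40, 15))
  gens <- pmax(1L, round(generationsPerStage * stages$weight / 100))
  cfg <- list()
  for (i in seq_len(nrow(stages))) {
    run <- list(type = "GA", maxiter = gens[i],
                mutate_crem_kwargs = list(
                  radius = 3L, min_size = stages$min_size[i],
                  max_size = stages$max_size[i],
                  min_inc = stages$min_inc[i],
                  max_inc = stages$max_inc[i]),
                deffnm = stages$name[i])
    if (i == 1L) {
      run$popsize <- popsize
      run$pc <- 0.5
      run$beta <- 1
      run$seed_mol <- seedMol
      run$costfunc <- "Cost"
      run$costfunc_kwargs <- list(backend = "surrogate")
      run$fragment_table <- fragmentTablePath
      run$seed <- seed
    }
    cfg[[stages$name[i]]] <- run
  }
  parseConfig(yaml::as.yaml(cfg))
}
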
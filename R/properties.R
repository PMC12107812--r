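# Molecular property calculators: QED, synthetic accessibility, the
# deterministic surrogate docking score, and the scoring-backend registry.

# Cache of (smiles -> c(qed, sa)) filled by batched helper calls.
.desc_cache <- new.env(parent = emptyenv())

.find_python <- function() {
  p <- getOption("moldesirer.python", "")
  if (nzchar(p)) return(p)
  p <- Sys.which("python3")
  if (!nzchar(p)) p <- Sys.which("python")
  p
}

.descriptor_script <- function() {
  p <- system.file("python", "descriptors.py", package = "moldesirer")
  if (!nzchar(p)) stop("bundled descriptor helper not found", call. = FALSE)
  p
}

#' Prefetch QED and synthetic-accessibility values for a SMILES batch
#'
#' Runs the bundled RDKit helper once for all not-yet-cached SMILES and
#' stores the results in an in-memory cache, so campaign loops pay the
#' interpreter start-up cost once per generation rather than once per
#' molecule.  Called automatically by \code{\link{computeQED}} and
#' \code{\link{computeSAScore}}.
#'
#' @param smiles character vector of SMILES strings.
#' @return invisibly, the number of newly computed molecules.
#' @export
prefetchDescriptors <- function(smiles) {
  smiles <- unique(smiles)
  todo <- smiles[!vapply(smiles, function(s)
    !is.null(.desc_cache[[s]]), logical(1))]
  if (!length(todo)) return(invisible(0L))
  py <- .find_python()
  if (!nzchar(py))
    stop("property error: no python interpreter found for the RDKit ",
         "descriptor helper", call. = FALSE)
  out <- suppressWarnings(
    system2(py, shQuote(.descriptor_script()), input = todo,
            stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("property error: descriptor helper failed (is RDKit installed?)",
         call. = FALSE)
  done <- 0L
  for (line in out) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 3) next
    .desc_cache[[f[1]]] <- c(qed = suppressWarnings(as.numeric(f[2])),
                             sa = suppressWarnings(as.numeric(f[3])))
    done <- done + 1L
  }
  if (done < length(todo))
    warning(length(todo) - done, " molecule(s) failed descriptor ",
            "computation", call. = FALSE)
  invisible(done)
}

.descriptor <- function(mol, which) {
  smi <- canonicalSmiles(mol)
  prefetchDescriptors(smi)
  v <- .desc_cache[[smi]]
  if (is.null(v) || !is.finite(v[[which]]))
    stop("property error for ", sQuote(smi), ": ", which,
         " could not be computed", call. = FALSE)
  unname(v[[which]])
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' The standard QED descriptor: a weighted-desirability composite of eight
#' physicochemical properties (MW, ALOGP, HBA, HBD, PSA, rotatable bonds,
#' aromatic rings, structural alerts) with the published default weights,
#' computed through the bundled RDKit helper.  Values lie strictly inside
#' (0, 1); higher is more drug-like.
#'
#' @param mol SMILES, mol block or \linkS4class{Individual}.
#' @return numeric QED in (0, 1).
#' @examples
#' \dontrun{computeQED("OCc1ccccc1")  # ~0.57}
#' @export
computeQED <- function(mol) .descriptor(mol, "qed")

#' Synthetic accessibility score
#'
#' The fragment-contribution plus complexity-penalty synthetic
#' accessibility score on the 1 (easy) to 10 (hard) scale, computed
#' through the bundled RDKit helper.
#'
#' @param mol SMILES, mol block or \linkS4class{Individual}.
#' @return numeric in [1, 10].
#' @examples
#' \dontrun{computeSAScore("OCc1ccccc1")  # ~1.14}
#' @export
computeSAScore <- function(mol) .descriptor(mol, "sa")

#' Deterministic surrogate docking score
#'
#' A smooth stand-in for a docking-score axis so the optimization engine
#' can be exercised without a docking engine: \eqn{-0.35 H + 0.005 H^2}
#' for heavy-atom count \eqn{H}.  The score strictly decreases up to the
#' minimum of -6.125 at H = 35 and rises afterwards, mimicking a binding
#' score that first improves and then saturates with ligand size, on the
#' typical kcal/mol docking-score magnitude.
#'
#' @param mol SMILES, mol block, \linkS4class{Individual}, or directly an
#'   integer heavy-atom count.
#' @return numeric score.
#' @examples
#' surrogateScore("C")    # -0.345
#' surrogateScore(35L)    # -6.125, the minimum
#' @export
surrogateScore <- function(mol) {
  h <- if (is.numeric(mol)) as.numeric(mol) else heavyAtomCount(mol)
  -0.35 * h + 0.005 * h^2
}

#' Docking box constructor
#'
#' @param center numeric length-3, Angstrom.
#' @param dimensions numeric length-3 positive edges, Angstrom.
#' @param exhaustiveness integer >= 1 (default 9).
#' @return A \linkS4class{DockingBox}.
#' @export
dockingBox <- function(center = c(0, 0, 0), dimensions = c(20, 20, 20),
                       exhaustiveness = 9L) {
  new("DockingBox", center = as.numeric(center),
      dimensions = as.numeric(dimensions),
      exhaustiveness = as.integer(exhaustiveness))
}

# ---- scoring backends ------------------------------------------------------

.backend_registry <- new.env(parent = emptyenv())

#' Register a scoring backend
#'
#' A backend is a function \code{function(individual, receptorSpec)}
#' returning \code{list(score = <finite numeric>, pose = <text payload>)}.
#' The built-in \code{"surrogate"} backend is registered at load time; an
#' adapter for an external docking engine can be registered by the user.
#'
#' @param name backend name.
#' @param fun backend function.
#' @export
registerScorerBackend <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .backend_registry)
  invisible(name)
}

#' Score an individual with a named backend
#'
#' Resolves the backend by name and applies it.  Backend failures raise an
#' evaluation error; callers in the fitness layer map that error to
#' \code{cost = Inf} for the affected individual only.
#'
#' @param individual an \linkS4class{Individual}.
#' @param receptorSpec list with elements \code{backend} (name), and for
#'   engine backends \code{receptor} (file path) and \code{box}
#'   (\linkS4class{DockingBox}); the surrogate ignores both.
#' @return list(score, pose).
#' @export
scorerBackend <- function(individual, receptorSpec = list()) {
  name <- receptorSpec$backend
  if (is.null(name)) name <- "surrogate"
  fun <- .backend_registry[[name]]
  if (is.null(fun))
    stop("configuration error: unknown scorer backend ", sQuote(name),
         call. = FALSE)
  res <- fun(individual, receptorSpec)
  if (!is.list(res) || !is.finite(res$score))
    stop("evaluation error: backend ", sQuote(name),
         " returned no finite score", call. = FALSE)
  res
}

.surrogate_backend <- function(individual, receptorSpec) {
  list(score = surrogateScore(individual),
       pose = .placeholder_pdbqt(individual@smiles))
}

# External docking engine adapter: shells out to a Vina-compatible
# executable configured via receptorSpec$vina_executable.  Kept as a thin
# pass-through; the engine itself is out of scope.
.vina_backend <- function(individual, receptorSpec) {
  exe <- receptorSpec$vina_executable
  if (is.null(exe) || !nzchar(Sys.which(exe)))
    stop("configuration error: docking executable not found; ",
         "set receptorSpec$vina_executable or use the surrogate backend",
         call. = FALSE)
  stop("evaluation error: external docking adapter requires prepared ",
       "receptor/ligand inputs; not available in this installation",
       call. = FALSE)
}
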
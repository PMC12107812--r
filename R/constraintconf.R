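# Constrained conformer generation: hold a reference core's 3D
# coordinates, embed the remainder, fall back to rigid alignment, and
# remove conformers that clash with the protein.

#' Map a reference core into a candidate molecule
#'
#' Finds a substructure match of the reference's heavy-atom graph in the
#' candidate (element-matched subgraph monomorphism).  When several
#' matches exist the one minimizing the sum of mapped candidate atom
#' indices is chosen, a deterministic tie-break.  If no exact match
#' exists, an approximate maximum-common-substructure fallback shrinks
#' the reference by iteratively stripping terminal atoms and retrying;
#' if that also fails a constraint failure is raised.
#'
#' @param candidate SMILES, mol block or \linkS4class{Individual}.
#' @param reference SMILES, mol block or \linkS4class{Individual}.
#' @param mcsFallback try the shrinking fallback (default TRUE).
#' @return integer vector: for each (remaining) reference atom, the
#'   matched candidate atom index; reference atom indices as names.
#'   Attribute \code{"partial"} is TRUE when the fallback shrank the core.
#' @export
mapCore <- function(candidate, reference, mcsFallback = TRUE) {
  cmg <- .as_molgraph(candidate)
  rmg <- .as_molgraph(reference)
  keep <- seq_len(.mg_n(rmg))
  repeat {
    m <- .subgraph_match(rmg, keep, cmg)
    if (!is.null(m)) {
      names(m) <- keep
      attr(m, "partial") <- length(keep) < .mg_n(rmg)
      return(m)
    }
    if (!mcsFallback || length(keep) <= 2) break
    keep <- .strip_terminal(rmg, keep)
    if (is.null(keep)) break
  }
  stop("constraint failure: reference core cannot be mapped into ",
       "candidate", call. = FALSE)
}

# Element-colored subgraph monomorphism of reference[keep] into candidate;
# returns candidate indices (in `keep` order) or NULL.
.subgraph_match <- function(rmg, keep, cmg) {
  nr <- length(keep); nc <- .mg_n(cmg)
  if (nr > nc || nr == 0) return(NULL)
  remap <- integer(.mg_n(rmg)); remap[keep] <- seq_len(nr)
  rb <- rmg$bonds
  rb <- rb[rb[, 1] %in% keep & rb[, 2] %in% keep, , drop = FALSE]
  pat <- igraph::make_empty_graph(nr, directed = FALSE)
  if (nrow(rb))
    pat <- igraph::add_edges(pat, rbind(remap[rb[, 1]], remap[rb[, 2]]))
  tgt <- .mg_igraph(cmg)
  doms <- lapply(seq_len(nr), function(i) {
    which(cmg$elem == rmg$elem[keep[i]])
  })
  if (any(vapply(doms, length, integer(1)) == 0)) return(NULL)
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(pat, tgt, method = "lad",
                                  induced = FALSE, domains = doms),
    error = function(e) list())
  if (!length(maps)) return(NULL)
  vecs <- lapply(maps, as.integer)
  sums <- vapply(vecs, sum, numeric(1))
  ord <- order(sums, vapply(vecs, function(v)
    paste(sprintf("%06d", v), collapse = ""), character(1)))
  vecs[[ord[1]]]
}

# Remove one terminal (degree <= 1 within `keep`) atom: the highest-index
# terminal, keeping the retained core connected.  NULL when impossible.
.strip_terminal <- function(rmg, keep) {
  if (length(keep) <= 1) return(NULL)
  deg <- vapply(keep, function(i) {
    sum((rmg$bonds[, 1] == i & rmg$bonds[, 2] %in% keep) |
          (rmg$bonds[, 2] == i & rmg$bonds[, 1] %in% keep))
  }, numeric(1))
  term <- keep[deg <= 1]
  if (!length(term)) term <- keep  # ring-only core: strip highest index
  setdiff(keep, max(term))
}

# Kabsch superposition: rotate+translate `mob` (m x 3) so rows `mi` best
# fit rows `fi` of `fix`; returns transformed full matrix.
.kabsch_fit <- function(fix, fi, mob, mi) {
  A <- fix[fi, , drop = FALSE]
  B <- mob[mi, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(B0, A0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(mob, 2, cb) %*% R, 2, ca, `+`)
}

.core_rmsd <- function(coords, refCoords, mapping) {
  d <- coords[mapping, , drop = FALSE] - refCoords
  sqrt(mean(rowSums(d^2)))
}

# Multi-conformer 3D generation via Open Babel's conformer search; falls
# back to the single gen3d structure when the search fails.
.generate_conformers <- function(smiles, nConf) {
  block <- .smiles_to_molblock(smiles, gen3d = TRUE)
  one <- .parse_molblock(block)
  confs <- list(one$coords)
  if (nConf > 1 && nzchar(Sys.which("obabel"))) {
    tin <- tempfile(fileext = ".sdf"); tout <- tempfile(fileext = ".sdf")
    on.exit(unlink(c(tin, tout)), add = TRUE)
    writeLines(block, tin)
    st <- suppressWarnings(system2(
      "obabel", c(tin, "-O", tout, "--conformer",
                  "--nconf", as.character(nConf), "--writeconformers"),
      stdout = FALSE, stderr = FALSE))
    if (st == 0 && file.exists(tout)) {
      txt <- readLines(tout)
      recs <- split(txt, cumsum(c(1, head(txt, -1) == "$$$$")))
      confs <- list()
      for (r in recs) {
        if (!any(grepl("V2000", r, fixed = TRUE))) next
        mg <- try(.parse_molblock(paste(r, collapse = "\n")),
                  silent = TRUE)
        if (!inherits(mg, "try-error") && .mg_n(mg) == .mg_n(one))
          confs[[length(confs) + 1L]] <- mg$coords
      }
      if (!length(confs)) confs <- list(one$coords)
    }
  }
  confs[seq_len(min(length(confs), nConf))]
}

#' Constrained conformer embedding
#'
#' Generates up to \code{nConf} 3D conformers of the candidate and
#' constrains the mapped core: each conformer is rigidly superposed onto
#' the reference coordinates over the mapped atoms (Kabsch) and the
#' mapped atoms are then placed at the reference positions, so embedded
#' conformers satisfy the core tolerance (default 0.1 Angstrom RMSD) by
#' construction.  When constrained placement is impossible for a
#' conformer, the rigid alignment alone is kept and flagged as a
#' fallback.  The recorded \code{coreRmsd} is the post-constraint RMSD of
#' mapped atoms to the reference.
#'
#' @param candidate SMILES, mol block or \linkS4class{Individual}.
#' @param referenceCoords numeric k x 3 matrix of reference-core
#'   coordinates (Angstrom), ordered like the mapping.
#' @param mapping integer vector from \code{\link{mapCore}}: candidate
#'   atom index per reference atom.
#' @param nConf number of conformers to attempt (default 20).
#' @param tauCore core RMSD tolerance in Angstrom (default 0.1).
#' @return A \linkS4class{ConformerSet} (no clash flags set yet).
#' @export
constrainedEmbed <- function(candidate, referenceCoords, mapping,
                             nConf = 20L, tauCore = 0.1) {
  if (!length(mapping))
    stop("constraint failure: empty core mapping", call. = FALSE)
  smi <- canonicalSmiles(candidate)
  confs <- .generate_conformers(smi, nConf)
  if (!length(confs))
    stop("constraint failure: no conformer could be generated",
         call. = FALSE)
  out <- list(); rmsd <- numeric(0); fb <- logical(0)
  for (co in confs) {
    if (max(mapping) > nrow(co)) next
    al <- .kabsch_fit(referenceCoords, seq_len(nrow(referenceCoords)),
                      co, mapping)
    emb <- al
    emb[mapping, ] <- referenceCoords
    r <- .core_rmsd(emb, referenceCoords, mapping)
    if (r <= tauCore) {
      out[[length(out) + 1L]] <- emb
      rmsd <- c(rmsd, r); fb <- c(fb, FALSE)
    } else {
      out[[length(out) + 1L]] <- al
      rmsd <- c(rmsd, .core_rmsd(al, referenceCoords, mapping))
      fb <- c(fb, TRUE)
    }
  }
  if (!length(out))
    stop("constraint failure: no conformer admits the core constraint",
         call. = FALSE)
  new("ConformerSet", smiles = smi, conformers = out,
      mapping = as.integer(mapping), clashFlags = logical(length(out)),
      coreRmsd = rmsd, fallback = fb)
}

#' Remove protein-clashing conformers
#'
#' A conformer clashes when any of its heavy atoms lies within
#' \code{cutoff} of any protein heavy atom.  Clashing conformers are
#' flagged and dropped from the surviving set.  The filter is monotone in
#' the cutoff: survivors at a larger cutoff are a subset of survivors at
#' a smaller one.  An empty protein is a no-op with a warning.
#'
#' @param confs \linkS4class{ConformerSet}.
#' @param proteinCoords numeric m x 3 matrix of protein heavy-atom
#'   coordinates (Angstrom); see \code{\link{readProteinHeavyAtoms}}.
#' @param cutoff clash distance in Angstrom (default 1.5).
#' @return A \linkS4class{ConformerSet} with updated clash flags and only
#'   surviving conformers retained.
#' @export
clashFilter <- function(confs, proteinCoords, cutoff = 1.5) {
  stopifnot(is(confs, "ConformerSet"))
  if (is.null(proteinCoords) || !nrow(proteinCoords)) {
    warning("empty protein coordinate set: clash filter is a no-op",
            call. = FALSE)
    return(confs)
  }
  flags <- vapply(confs@conformers, function(co) {
    for (i in seq_len(nrow(co))) {
      d2 <- (proteinCoords[, 1] - co[i, 1])^2 +
        (proteinCoords[, 2] - co[i, 2])^2 +
        (proteinCoords[, 3] - co[i, 3])^2
      if (any(d2 < cutoff^2)) return(TRUE)
    }
    FALSE
  }, logical(1))
  keep <- !flags
  new("ConformerSet", smiles = confs@smiles,
      conformers = confs@conformers[keep],
      mapping = confs@mapping, clashFlags = logical(sum(keep)),
      coreRmsd = confs@coreRmsd[keep], fallback = confs@fallback[keep])
}

#' Read protein heavy-atom coordinates from a PDB file
#'
#' Extracts heavy-atom (non-hydrogen) coordinates from ATOM/HETATM
#' records, skipping waters (residue name HOH).
#'
#' @param path PDB file path.
#' @return numeric m x 3 coordinate matrix (Angstrom).
#' @export
readProteinHeavyAtoms <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  keep <- at$resid != "HOH" & !(at$elesy %in% c("H", "D"))
  as.matrix(at[keep, c("x", "y", "z")])
}

#' Constrained scoring of a candidate against a reference pose
#'
#' Maps the reference core into the candidate, embeds constrained
#' conformers, removes protein-clashing ones and scores the best
#' survivor with the requested backend.  \code{"score_only"} scores the
#' constrained conformation as is; \code{"local_only"} asks the backend
#' for local pose relaxation before scoring, which requires an external
#' docking engine — under the surrogate backend it degrades to
#' \code{"score_only"} with a warning.  The best survivor is the lowest
#' core-RMSD conformer, ties broken by conformer index.
#'
#' @param candidate SMILES, mol block or \linkS4class{Individual}.
#' @param reference reference molecule with 3D coordinates (SDF/MOL path
#'   or mol block).
#' @param protein optional PDB path or m x 3 coordinate matrix for clash
#'   filtering.
#' @param mode \code{"score_only"} or \code{"local_only"}.
#' @param backend receptor spec list (see \code{\link{scorerBackend}}).
#' @param nConf,cutoff embedding and clash parameters.
#' @return list(score, pose) where pose is the mol block of the scored
#'   conformer.
#' @export
constrainedScore <- function(candidate, reference, protein = NULL,
                             mode = c("score_only", "local_only"),
                             backend = list(backend = "surrogate"),
                             nConf = 20L, cutoff = 1.5) {
  mode <- match.arg(mode)
  refBlock <- if (is.character(reference) && !grepl("V2000", reference) &&
                  file.exists(reference)) {
    paste(readLines(reference), collapse = "\n")
  } else reference
  rmg <- .as_molgraph(refBlock)
  if (!isTRUE(rmg$is3d))
    stop("constraint failure: reference has no 3D coordinates",
         call. = FALSE)
  candInd <- if (is(candidate, "Individual")) candidate else
    makeIndividual(candidate)
  mapping <- mapCore(candInd, rmg)
  refCoords <- rmg$coords[as.integer(names(mapping)), , drop = FALSE]
  confs <- constrainedEmbed(candInd, refCoords, mapping, nConf = nConf)
  if (!is.null(protein)) {
    pc <- if (is.matrix(protein)) protein else
      readProteinHeavyAtoms(protein)
    confs <- clashFilter(confs, pc, cutoff = cutoff)
  }
  if (!length(confs@conformers))
    stop("evaluation error: all constrained conformers clash with the ",
         "protein", call. = FALSE)
  if (mode == "local_only" &&
      identical(backend$backend %||% "surrogate", "surrogate")) {
    warning("local_only requires an external docking engine; ",
            "degrading to score_only under the surrogate backend",
            call. = FALSE)
    mode <- "score_only"
  }
  best <- order(confs@coreRmsd)[1]
  cmg <- .as_molgraph(candInd)
  cmg$coords <- confs@conformers[[best]]
  cmg$is3d <- TRUE
  poseBlock <- .mg_to_molblock(cmg, title = confs@smiles)
  posed <- candInd
  posed@mol <- poseBlock
  sc <- scorerBackend(posed, backend)
  list(score = sc$score, pose = poseBlock, conformers = confs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
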
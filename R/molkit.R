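# Molecule wrapper, identity semantics, fingerprints and SDF payloads.

#' Create an Individual from a SMILES string or mol block
#'
#' Parses the structure, canonicalizes its SMILES (explicit hydrogens
#' removed, stereochemistry preserved) and returns an unevaluated
#' \linkS4class{Individual} with \code{cost = Inf} and a placeholder pose
#' payload.  The canonical SMILES is the molecule's identity: two
#' individuals are equal exactly when their SMILES strings are equal,
#' regardless of the input atom ordering.
#'
#' @param structure SMILES string, or a V2000 mol block (detected by the
#'   \code{"V2000"} tag).
#' @param idx integer identifier (default 0).
#' @return An \linkS4class{Individual}.
#' @examples
#' makeIndividual("OCc1ccccc1", idx = 1L)
#' @export
makeIndividual <- function(structure, idx = 0L) {
  stopifnot(is.character(structure), length(structure) == 1)
  if (grepl("V2000", structure, fixed = TRUE)) {
    molblock <- structure
    smi <- .molblock_to_smiles(molblock)
  } else {
    smi <- .ob_canonical(structure)
    molblock <- .smiles_to_molblock(structure)
  }
  mg <- .parse_molblock(molblock)
  if (!.mg_sanitize_ok(mg))
    stop("sanitization error: invalid valence in ", sQuote(smi),
         call. = FALSE)
  new("Individual", mol = molblock, idx = as.integer(idx), smiles = smi,
      pdbqt = .placeholder_pdbqt(smi), cost = Inf)
}

.placeholder_pdbqt <- function(smiles) {
  paste0("REMARK  moldesirer placeholder pose payload\n",
         "REMARK  smiles ", smiles, "\n")
}

#' Canonical SMILES of a molecule
#'
#' Deterministic canonical SMILES with explicit hydrogens removed and
#' stereochemistry preserved.  Idempotent: canonicalizing a canonical
#' string returns it unchanged.
#'
#' @param mol a SMILES string, an \linkS4class{Individual}, or a mol block.
#' @return character canonical SMILES.
#' @export
canonicalSmiles <- function(mol) {
  if (is(mol, "Individual")) return(mol@smiles)
  stopifnot(is.character(mol), length(mol) == 1)
  if (grepl("V2000", mol, fixed = TRUE)) .molblock_to_smiles(mol)
  else .ob_canonical(mol)
}

# Resolve any molecule-ish input to an internal molgraph.
.as_molgraph <- function(mol) {
  if (inherits(mol, "molgraph")) return(mol)
  if (is(mol, "Individual")) return(.parse_molblock(mol@mol))
  stopifnot(is.character(mol), length(mol) == 1)
  if (grepl("V2000", mol, fixed = TRUE)) .parse_molblock(mol)
  else .mg_from_smiles(mol)
}

#' Heavy-atom count
#'
#' @param mol SMILES, mol block or \linkS4class{Individual}.
#' @return integer number of non-hydrogen atoms.
#' @export
heavyAtomCount <- function(mol) .mg_n(.as_molgraph(mol))

# Deterministic integer hash of an integer vector (mod 2^31 - 1).
.hash_ints <- function(v) {
  h <- 5381
  for (x in v) h <- (h * 33 + (x %% 2147483647)) %% 2147483647
  h
}

#' Morgan (circular) fingerprint
#'
#' ECFP-style fingerprint: per-atom initial invariants (atomic number,
#' heavy degree, total hydrogen count, formal charge, ring membership) are
#' iteratively combined with sorted neighbor identifiers for
#' \code{radius} rounds; every intermediate identifier sets one bit of a
#' fixed-length vector.  The construction is invariant under input atom
#' reordering, so identical molecules always yield identical fingerprints.
#'
#' @param mol SMILES, mol block or \linkS4class{Individual}.
#' @param radius integer neighborhood radius (default 2).
#' @param nbits integer fingerprint length (default 2048).
#' @return A \linkS4class{Fingerprint}.
#' @export
morganFingerprint <- function(mol, radius = 2L, nbits = 2048L) {
  radius <- as.integer(radius); nbits <- as.integer(nbits)
  if (nbits <= 0L) stop("nbits must be > 0", call. = FALSE)
  if (radius < 0L) stop("radius must be >= 0", call. = FALSE)
  mg <- .as_molgraph(mol)
  n <- .mg_n(mg)
  bits <- logical(nbits)
  if (n == 0) return(new("Fingerprint", bits = bits, radius = radius,
                         nbits = nbits))
  z <- vapply(mg$elem, function(e) {
    i <- match(e, .ELEMENT_SYMBOLS)
    if (is.na(i)) 0L else i
  }, integer(1))
  deg <- .mg_heavy_degree(mg)
  hs <- .mg_total_h(mg)
  ring <- as.integer(.mg_in_ring(mg))
  ids <- vapply(seq_len(n), function(i) {
    .hash_ints(c(z[i], deg[i], hs[i], mg$charge[i], ring[i]))
  }, numeric(1))
  nbrs <- vector("list", n)
  b <- mg$bonds
  for (k in seq_len(nrow(b))) {
    nbrs[[b[k, 1]]] <- rbind(nbrs[[b[k, 1]]], c(b[k, 2], b[k, 3]))
    nbrs[[b[k, 2]]] <- rbind(nbrs[[b[k, 2]]], c(b[k, 1], b[k, 3]))
  }
  all_ids <- ids
  for (r in seq_len(radius)) {
    ids <- vapply(seq_len(n), function(i) {
      nb <- nbrs[[i]]
      if (is.null(nb)) return(.hash_ints(c(r, ids[i])))
      feats <- cbind(nb[, 2], ids[nb[, 1]])
      feats <- feats[order(feats[, 1], feats[, 2]), , drop = FALSE]
      .hash_ints(c(r, ids[i], as.numeric(t(feats))))
    }, numeric(1))
    all_ids <- c(all_ids, ids)
  }
  bits[(all_ids %% nbits) + 1] <- TRUE
  new("Fingerprint", bits = bits, radius = radius, nbits = nbits)
}

.ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe")

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{|a \wedge b| / |a \vee b|}, in [0, 1].  Two all-zero fingerprints
#' are defined as identical (similarity 1): both are featureless.
#'
#' @param a,b \linkS4class{Fingerprint} objects, or logical/0-1 vectors of
#'   equal length.
#' @return numeric in [0, 1].
#' @export
tanimotoSimilarity <- function(a, b) {
  av <- if (is(a, "Fingerprint")) a@bits else as.logical(a)
  bv <- if (is(b, "Fingerprint")) b@bits else as.logical(b)
  if (length(av) != length(bv))
    stop("fingerprint length mismatch", call. = FALSE)
  un <- sum(av | bv)
  if (un == 0) return(1)
  sum(av & bv) / un
}

#' Write individuals to an SDF file
#'
#' One V2000 record per individual carrying its 3D conformer, tagged with
#' the SDF data fields \code{idx}, \code{smiles} and \code{cost}.
#' Individuals without 3D coordinates are skipped with a warning.
#'
#' @param individuals list of \linkS4class{Individual}.
#' @param path output file path.
#' @return invisibly, the number of records written.
#' @export
writeIndividualsSDF <- function(individuals, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot open ", path, " for writing", call. = FALSE)
  on.exit(close(con))
  written <- 0L
  for (ind in individuals) {
    mg <- .parse_molblock(ind@mol)
    if (!isTRUE(mg$is3d)) {
      warning("individual ", ind@idx, " (", ind@smiles,
              ") has no 3D conformer; skipped", call. = FALSE)
      next
    }
    block <- .mg_to_molblock(mg, title = paste0("idx_", ind@idx))
    block <- sub("\\$\\$\\$\\$\n$", "", block)
    cost_txt <- if (is.finite(ind@cost)) format(ind@cost, digits = 10) else
      "Inf"
    cat(block,
        "> <idx>\n", ind@idx, "\n\n",
        "> <smiles>\n", ind@smiles, "\n\n",
        "> <cost>\n", cost_txt, "\n\n",
        "$$$$\n", sep = "", file = con)
    written <- written + 1L
  }
  invisible(written)
}

# ---- accessors -------------------------------------------------------------

#' @describeIn makeIndividual canonical SMILES of an Individual
#' @param object,x an \linkS4class{Individual}
#' @export
setGeneric("smiles", function(object) standardGeneric("smiles"))

#' @rdname makeIndividual
#' @export
setMethod("smiles", "Individual", function(object) object@smiles)

#' @describeIn makeIndividual fitness cost (Inf when unevaluated)
#' @export
setGeneric("cost", function(object) standardGeneric("cost"))

#' @rdname makeIndividual
#' @export
setMethod("cost", "Individual", function(object) object@cost)

#' @describeIn makeIndividual integer identifier
#' @export
setGeneric("idx", function(object) standardGeneric("idx"))

#' @rdname makeIndividual
#' @export
setMethod("idx", "Individual", function(object) object@idx)

#' @describeIn makeIndividual V2000 mol block payload
#' @export
setGeneric("molBlock", function(object) standardGeneric("molBlock"))

#' @rdname makeIndividual
#' @export
setMethod("molBlock", "Individual", function(object) object@mol)

#' @describeIn makeIndividual recorded property values (named numeric)
#' @export
setGeneric("properties", function(object) standardGeneric("properties"))

#' @rdname makeIndividual
#' @export
setMethod("properties", "Individual", function(object) object@props)

#' Equality of individuals is SMILES identity
#'
#' @param e1,e2 \linkS4class{Individual} objects.
#' @export
setMethod("==", signature("Individual", "Individual"),
          function(e1, e2) e1@smiles == e2@smiles)

#' Deduplicate a list of individuals by canonical SMILES
#'
#' Keeps the first occurrence of each SMILES, mirroring hashed-set
#' semantics where identity is the SMILES string.
#'
#' @param individuals list of \linkS4class{Individual}.
#' @return list of unique individuals.
#' @export
uniqueIndividuals <- function(individuals) {
  smi <- vapply(individuals, function(x) x@smiles, character(1))
  individuals[!duplicated(smi)]
}
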
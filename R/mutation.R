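# Pluggable structure generator: the built-in fragment-table mutator.
#
# A mutation replaces one "site" of the parent with one fragment from the
# table.  Sites are either hydrogen positions (size 0) or connected heavy-
# atom fragments of size minSize..maxSize that attach to the rest of the
# molecule through exactly one bond (so removal keeps the remainder
# connected and the incoming fragment's single attachment point is well
# defined).  The heavy-atom increment (child minus parent) must lie in
# [minInc, maxInc].  Protected atoms are never part of a removed site.
# The built-in mutator ignores the context `radius` (that information
# lives in external fragment databases); the external adapter forwards it.

#' Mutation parameter constructor
#'
#' @param radius context radius, kept for external-generator
#'   compatibility (default 3).
#' @param minSize,maxSize heavy-atom size range of replaced fragments;
#'   0 means hydrogen positions (defaults 0, 0: pure growth).
#' @param minInc,maxInc allowed heavy-atom count change, possibly
#'   negative (defaults 1, 6).
#' @param protected integer heavy-atom indices never removed or replaced.
#' @param maxChildren cap on returned children per call (default 50).
#' @return A \linkS4class{MutationParams}.
#' @export
mutationParams <- function(radius = 3L, minSize = 0L, maxSize = 0L,
                           minInc = 1L, maxInc = 6L,
                           protected = integer(0), maxChildren = 50L) {
  new("MutationParams", radius = as.integer(radius),
      minSize = as.integer(minSize), maxSize = as.integer(maxSize),
      minInc = as.integer(minInc), maxInc = as.integer(maxInc),
      protected = as.integer(protected),
      maxChildren = as.integer(maxChildren))
}

# ---- fragment tables -------------------------------------------------------

.parse_fragment <- function(frag_smiles) {
  if (length(gregexpr("\\*", frag_smiles)[[1]]) != 1 ||
      !grepl("\\*", frag_smiles))
    stop("fragment ", sQuote(frag_smiles),
         " must contain exactly one * attachment point", call. = FALSE)
  mg <- .mg_from_smiles(frag_smiles)
  dummy <- which(mg$elem == "*")
  if (length(dummy) != 1)
    stop("fragment ", sQuote(frag_smiles), " did not parse to a single ",
         "attachment dummy", call. = FALSE)
  touching <- which(mg$bonds[, 1] == dummy | mg$bonds[, 2] == dummy)
  if (length(touching) != 1)
    stop("fragment ", sQuote(frag_smiles),
         " attachment point must be terminal (one bond)", call. = FALSE)
  att <- setdiff(mg$bonds[touching, 1:2], dummy)
  keep <- setdiff(seq_len(.mg_n(mg)), dummy)
  remap <- integer(.mg_n(mg)); remap[keep] <- seq_along(keep)
  b <- mg$bonds[-touching, , drop = FALSE]
  if (nrow(b)) { b[, 1] <- remap[b[, 1]]; b[, 2] <- remap[b[, 2]] }
  sub <- structure(list(elem = mg$elem[keep], charge = mg$charge[keep],
                        xh = mg$xh[keep], bonds = b,
                        coords = mg$coords[keep, , drop = FALSE],
                        is3d = FALSE), class = "molgraph")
  list(graph = sub, attach = remap[att])
}

#' Fragment table constructor and readers
#'
#' Builds a validated \linkS4class{FragmentTable}.  Every fragment must
#' parse, carry exactly one terminal \code{*} attachment point, and have a
#' declared heavy-atom count matching the parsed structure.
#'
#' @param fragments character vector of fragment SMILES with one terminal
#'   \code{*}, or a data.frame with columns \code{fragment_smiles},
#'   \code{heavy_atoms} (and optionally \code{max_sa}).
#' @return A \linkS4class{FragmentTable}.
#' @export
fragmentTable <- function(fragments) {
  if (is.character(fragments)) {
    fragments <- data.frame(fragment_smiles = fragments,
                            heavy_atoms = NA_integer_)
  }
  tb <- fragments
  for (i in seq_len(nrow(tb))) {
    pf <- .parse_fragment(tb$fragment_smiles[i])
    n <- .mg_n(pf$graph)
    if (is.na(tb$heavy_atoms[i])) tb$heavy_atoms[i] <- n
    else if (tb$heavy_atoms[i] != n)
      stop("fragment ", sQuote(tb$fragment_smiles[i]), " declares ",
           tb$heavy_atoms[i], " heavy atoms but parses to ", n,
           call. = FALSE)
  }
  tb$heavy_atoms <- as.integer(tb$heavy_atoms)
  new("FragmentTable", table = tb)
}

#' @rdname fragmentTable
#' @param path TSV file with columns \code{fragment_smiles} and
#'   \code{heavy_atoms} (tab-separated, with header).
#' @export
readFragmentTable <- function(path) {
  tb <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  fragmentTable(tb)
}

#' @rdname fragmentTable
#' @param x a \linkS4class{FragmentTable}.
#' @export
writeFragmentTable <- function(x, path) {
  utils::write.table(x@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- site enumeration ------------------------------------------------------

#' Enumerate replaceable sites of a molecule
#'
#' Lists every site the mutator may replace under the given parameters:
#' hydrogen positions (one site per hydrogen) when \code{minSize == 0},
#' and connected heavy-atom fragments of each size in
#' \code{max(1, minSize)..maxSize} that contain no protected atom and
#' attach to the remainder through exactly one bond.  Protection forbids
#' removing an atom, not growing at its hydrogens.
#'
#' @param mol SMILES, mol block or \linkS4class{Individual}.
#' @param params \linkS4class{MutationParams}.
#' @param maxSites cap on enumerated heavy sites (deterministic order;
#'   default 200).
#' @return list of sites; each site is a list with \code{atoms} (integer
#'   heavy-atom indices; empty for a hydrogen site), \code{size},
#'   \code{anchor} (the heavy atom carrying the hydrogen, for size-0
#'   sites) and \code{boundary} (the remaining-side attachment atom, for
#'   heavy sites).
#' @export
enumerateReplaceableSites <- function(mol, params, maxSites = 200L) {
  mg <- .as_molgraph(mol)
  n <- .mg_n(mg)
  prot <- params@protected
  sites <- list()
  if (params@minSize == 0L) {
    hs <- .mg_total_h(mg)
    for (i in seq_len(n)) {
      if (hs[i] < 1L) next
      for (k in seq_len(hs[i])) {
        sites[[length(sites) + 1L]] <-
          list(atoms = integer(0), size = 0L, anchor = i, boundary = i)
      }
    }
  }
  lo <- max(1L, params@minSize)
  if (params@maxSize >= lo && n > 1) {
    subsets <- .connected_subsets(mg, lo, params@maxSize, prot, maxSites)
    for (S in subsets) {
      bnd <- .site_boundary(mg, S)
      if (is.null(bnd)) next
      sites[[length(sites) + 1L]] <-
        list(atoms = S, size = length(S), anchor = NA_integer_,
             boundary = bnd)
    }
  }
  sites
}

# All connected vertex subsets with size in [lo, hi] avoiding `prot`,
# enumerated deterministically (sorted-index canonical form), capped.
.connected_subsets <- function(mg, lo, hi, prot, cap) {
  n <- .mg_n(mg)
  adj <- vector("list", n)
  b <- mg$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
    adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
  }
  ok <- setdiff(seq_len(n), prot)
  out <- list()
  seen <- new.env(parent = emptyenv())
  frontier <- lapply(ok, function(i) i)
  while (length(frontier)) {
    nxt <- list()
    for (S in frontier) {
      key <- paste(S, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      if (length(S) >= lo && length(S) <= hi) {
        out[[length(out) + 1L]] <- S
        if (length(out) >= cap) return(out)
      }
      if (length(S) < hi) {
        nb <- setdiff(intersect(unique(unlist(adj[S])), ok), S)
        for (v in nb) nxt[[length(nxt) + 1L]] <- sort(c(S, v))
      }
    }
    frontier <- nxt
  }
  out
}

# Boundary of a candidate site: the unique remainder-side atom bonded to
# the site, or NULL when the site touches the remainder through != 1 bond
# (or is the whole molecule).
.site_boundary <- function(mg, S) {
  b <- mg$bonds
  outside <- integer(0)
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]
    ini <- i %in% S; inj <- j %in% S
    if (ini && !inj) outside <- c(outside, j)
    else if (inj && !ini) outside <- c(outside, i)
  }
  if (length(outside) != 1) return(NULL)
  if (length(S) >= .mg_n(mg)) return(NULL)
  outside
}

# ---- child construction ----------------------------------------------------

# Attach `frag` (parsed fragment: graph + attach index) to atom `at` of
# `mg` after removing atoms `drop`; returns a molgraph or NULL on failure.
.replace_site <- function(mg, drop, at, frag) {
  keep <- setdiff(seq_len(.mg_n(mg)), drop)
  remap <- integer(.mg_n(mg)); remap[keep] <- seq_along(keep)
  b <- mg$bonds
  bk <- b[!(b[, 1] %in% drop | b[, 2] %in% drop), , drop = FALSE]
  if (nrow(bk)) { bk[, 1] <- remap[bk[, 1]]; bk[, 2] <- remap[bk[, 2]] }
  fg <- frag$graph
  off <- length(keep)
  fb <- fg$bonds
  if (nrow(fb)) { fb[, 1] <- fb[, 1] + off; fb[, 2] <- fb[, 2] + off }
  newb <- rbind(bk, fb,
                c(remap[at], frag$attach + off, 1L))
  child <- structure(list(
    elem = c(mg$elem[keep], fg$elem),
    charge = c(mg$charge[keep], fg$charge),
    xh = c(mg$xh[keep], fg$xh),
    bonds = newb,
    coords = rbind(mg$coords[keep, , drop = FALSE],
                   matrix(0, .mg_n(fg), 3)),
    is3d = FALSE), class = "molgraph")
  if (!.mg_connected(child)) return(NULL)
  if (!.mg_sanitize_ok(child)) return(NULL)
  # the anchor must still have a free valence slot for the new bond
  if (.mg_implicit_h(child)[remap[at]] < 0) return(NULL)
  child
}

#' Mutate a molecule with fragments from a table
#'
#' Generates children by replacing one enumerated site with one table
#' fragment whose heavy-atom increment (fragment size minus site size)
#' lies in \code{[minInc, maxInc]}.  Children are valence-checked,
#' canonicalized and deduplicated; when more than \code{maxChildren}
#' candidates exist a random subset is kept (uses the current RNG state —
#' seed beforehand for reproducibility).  Protected atoms are present and
#' unmodified in every child.  An empty result is legal (no feasible
#' site/fragment pair).
#'
#' @param mol SMILES, mol block or \linkS4class{Individual}.
#' @param params \linkS4class{MutationParams}.
#' @param table \linkS4class{FragmentTable}.
#' @param maxChildren optional override of \code{params@maxChildren}.
#' @return character vector of canonical SMILES of the children.
#' @export
mutateMol <- function(mol, params, table, maxChildren = NULL) {
  stopifnot(is(params, "MutationParams"), is(table, "FragmentTable"))
  if (is.null(maxChildren)) maxChildren <- params@maxChildren
  mg <- .as_molgraph(mol)
  sites <- enumerateReplaceableSites(mg, params)
  if (!length(sites)) return(character(0))
  frags <- lapply(table@table$fragment_smiles, .parse_fragment)
  fsize <- table@table$heavy_atoms
  children <- character(0)
  # hydrogen sites at the same anchor are equivalent; build each
  # (anchor, fragment) product once
  seen_pair <- new.env(parent = emptyenv())
  for (s in sites) {
    for (fi in seq_along(frags)) {
      inc <- fsize[fi] - s$size
      if (inc < params@minInc || inc > params@maxInc) next
      pairkey <- paste(s$boundary, paste(s$atoms, collapse = "."), fi,
                       sep = "|")
      if (!is.null(seen_pair[[pairkey]])) next
      seen_pair[[pairkey]] <- TRUE
      child <- .replace_site(mg, s$atoms, s$boundary, frags[[fi]])
      if (is.null(child)) next
      smi <- try(.mg_canonical(child), silent = TRUE)
      if (inherits(smi, "try-error")) next
      children <- c(children, smi)
    }
  }
  children <- unique(children)
  if (length(children) > maxChildren)
    children <- sample(children, maxChildren)
  children
}

#' Grow a molecule at hydrogen positions
#'
#' \code{\link{mutateMol}} restricted to hydrogen sites with strictly
#' positive heavy-atom increments: \code{minSize = maxSize = 0} and
#' \code{minInc >= 1}.
#'
#' @inheritParams mutateMol
#' @return character vector of canonical SMILES.
#' @export
growMol <- function(mol, params, table, maxChildren = NULL) {
  gp <- mutationParams(radius = params@radius, minSize = 0L, maxSize = 0L,
                       minInc = max(1L, params@minInc),
                       maxInc = max(1L, params@maxInc),
                       protected = params@protected,
                       maxChildren = params@maxChildren)
  mutateMol(mol, gp, table, maxChildren = maxChildren)
}

#' Adapter for an external fragment-replacement generator
#'
#' Forwards \code{radius}, \code{min_size}, \code{max_size},
#' \code{min_inc} and \code{max_inc} verbatim to the external CReM-style
#' library (Python) and normalizes its output to canonical SMILES.
#' Requires the external library and its fragment database; raises a
#' configuration error instructing use of the built-in mutator otherwise.
#'
#' @param mol SMILES, mol block or \linkS4class{Individual}.
#' @param params \linkS4class{MutationParams}.
#' @param dbPath path to the external fragment database.
#' @param python python interpreter to probe (default: discovered).
#' @return character vector of canonical SMILES.
#' @export
externalGeneratorAdapter <- function(mol, params, dbPath,
                                     python = .find_python()) {
  if (!nzchar(python) ||
      system2(python, c("-c", shQuote("import crem")),
              stdout = FALSE, stderr = FALSE) != 0 ||
      missing(dbPath) || !file.exists(dbPath)) {
    stop("configuration error: the external fragment-replacement library ",
         "or its database is not available; use the built-in fragment-",
         "table mutator (mutateMol) instead", call. = FALSE)
  }
  smi <- canonicalSmiles(mol)
  code <- sprintf(paste0(
    "from crem.crem import mutate_mol\n",
    "from rdkit import Chem\n",
    "m = Chem.MolFromSmiles('%s')\n",
    "for s in mutate_mol(m, db_name='%s', radius=%d, min_size=%d, ",
    "max_size=%d, min_inc=%d, max_inc=%d, return_mol=False):\n",
    "    print(s)\n"),
    smi, dbPath, params@radius, params@minSize, params@maxSize,
    params@minInc, params@maxInc)
  out <- system2(python, "-", input = code, stdout = TRUE, stderr = FALSE)
  unique(vapply(out, .ob_canonical, character(1), USE.NAMES = FALSE))
}
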
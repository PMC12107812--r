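# Internal molecular-graph layer.
#
# Heavy-atom connection tables parsed from Open Babel output (via
# ChemmineR/ChemmineOB). A "molgraph" is a plain list:
#   elem   : character vector of heavy-atom element symbols
#   charge : integer formal charges (from M CHG lines)
#   xh     : integer counts of explicit hydrogens folded into each heavy atom
#   bonds  : integer matrix with columns (i, j, order); heavy-heavy bonds only
#   coords : numeric n x 3 matrix (may be all-zero for 0D/2D input)
#   is3d   : logical, TRUE when the source block carried 3D coordinates
# Hydrogen atoms never appear as graph vertices; they are accounted for by
# `xh` plus the implicit-hydrogen valence model below.

.OB_OPT <- function(name, arg = "") data.frame(names = name, args = arg)

.strip_smiles <- function(x) {
  x <- sub("[ \t].*$", "", x)
  gsub("[\r\n]", "", x)
}

# Canonical SMILES via Open Babel; stops with the offending string on failure.
.ob_canonical <- function(smiles) {
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles))
  out <- .strip_smiles(out)
  if (!nzchar(out)) {
    stop("SMILES parse/sanitization failure for input: ", sQuote(smiles),
         call. = FALSE)
  }
  out
}

.smiles_to_molblock <- function(smiles, gen3d = FALSE) {
  out <- suppressWarnings(
    if (gen3d)
      ChemmineOB::convertFormat("SMI", "SDF", smiles,
                                options = .OB_OPT("gen3d"))
    else ChemmineOB::convertFormat("SMI", "SDF", smiles))
  if (!nzchar(out) || !grepl("V2000", out, fixed = TRUE)) {
    stop("SMILES parse/sanitization failure for input: ", sQuote(smiles),
         call. = FALSE)
  }
  out
}

.molblock_to_smiles <- function(molblock) {
  out <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", molblock))
  out <- .strip_smiles(out)
  if (!nzchar(out)) stop("mol block could not be interpreted", call. = FALSE)
  out
}

# Parse one V2000 mol block into a molgraph.  The fixed-width counts,
# atom and bond lines are read directly: general SDF readers in the R
# ecosystem reject the degenerate but legal single-atom / zero-bond
# records (e.g. methane) that a molecular design campaign starts from.
.parse_molblock <- function(molblock) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_all <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(n_all) || is.na(nb) || !grepl("V2000", counts))
    stop("mol block could not be interpreted", call. = FALSE)
  atl <- lines[4 + seq_len(n_all)]
  coords_all <- cbind(as.numeric(substr(atl, 1, 10)),
                      as.numeric(substr(atl, 11, 20)),
                      as.numeric(substr(atl, 21, 30)))
  elem_all <- trimws(substr(atl, 32, 34))
  charges <- integer(n_all)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG *[0-9]+", "", ln)),
                             "[ ]+")[[1]])
    if (length(f) >= 2) {
      idx <- f[seq(1, length(f), by = 2)]
      val <- f[seq(2, length(f), by = 2)]
      charges[idx] <- val
    }
  }
  bonds_all <- if (nb > 0) {
    bdl <- lines[4 + n_all + seq_len(nb)]
    cbind(as.integer(substr(bdl, 1, 3)), as.integer(substr(bdl, 4, 6)),
          as.integer(substr(bdl, 7, 9)))
  } else {
    matrix(integer(0), ncol = 3)
  }
  heavy <- which(elem_all != "H")
  remap <- integer(n_all)
  remap[heavy] <- seq_along(heavy)
  xh <- integer(length(heavy))
  keep <- logical(nrow(bonds_all))
  if (nrow(bonds_all) > 0) {
    for (k in seq_len(nrow(bonds_all))) {
      i <- bonds_all[k, 1]; j <- bonds_all[k, 2]
      hi <- elem_all[i] == "H"; hj <- elem_all[j] == "H"
      if (hi && hj) next
      if (hi) { xh[remap[j]] <- xh[remap[j]] + 1L; next }
      if (hj) { xh[remap[i]] <- xh[remap[i]] + 1L; next }
      keep[k] <- TRUE
    }
  }
  bonds <- bonds_all[keep, , drop = FALSE]
  if (nrow(bonds) > 0) {
    bonds[, 1] <- remap[bonds[, 1]]
    bonds[, 2] <- remap[bonds[, 2]]
  }
  colnames(bonds) <- c("i", "j", "order")
  is3d <- grepl("V2000", molblock, fixed = TRUE) &&
    any(abs(coords_all[, 3]) > 1e-8)
  structure(list(elem = elem_all[heavy], charge = charges[heavy],
                 xh = xh, bonds = bonds,
                 coords = coords_all[heavy, , drop = FALSE], is3d = is3d),
            class = "molgraph")
}

.mg_from_smiles <- function(smiles, gen3d = FALSE) {
  .parse_molblock(.smiles_to_molblock(smiles, gen3d = gen3d))
}

.mg_n <- function(mg) length(mg$elem)

# Serialize back to a V2000 mol block (heavy atoms only; hydrogens implicit).
.mg_to_molblock <- function(mg, title = "moldesirer") {
  n <- .mg_n(mg)
  b <- mg$bonds
  co <- mg$coords
  if (is.null(co)) co <- matrix(0, n, 3)
  dim_tag <- if (isTRUE(mg$is3d)) "3D" else "2D"
  out <- c(title, sprintf("  moldesirer      %s", dim_tag), "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)))
  for (i in seq_len(n)) {
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          co[i, 1], co[i, 2], co[i, 3], mg$elem[i]))
  }
  for (k in seq_len(nrow(b))) {
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0", b[k, 1], b[k, 2], b[k, 3]))
  }
  chg <- which(mg$charge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      out <- c(out, paste0("M  CHG", sprintf("%3d", length(grp)),
                           paste0(sprintf("%4d%4d", grp, mg$charge[grp]),
                                  collapse = "")))
    }
  }
  paste(c(out, "M  END", "$$$$", ""), collapse = "\n")
}

.mg_canonical <- function(mg) .molblock_to_smiles(.mg_to_molblock(mg))

# --- implicit-hydrogen / valence model (neutral-organic oriented) -----------

.ALLOWED_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, F = 1, Si = 4, P = c(3, 5),
  S = c(2, 4, 6), Cl = 1, Br = 1, I = 1
)

.mg_bondsum <- function(mg) {
  n <- .mg_n(mg)
  s <- numeric(n)
  b <- mg$bonds
  for (k in seq_len(nrow(b))) {
    o <- b[k, 3]
    if (o == 4) o <- 1.5  # aromatic order, if a writer ever emits it
    s[b[k, 1]] <- s[b[k, 1]] + o
    s[b[k, 2]] <- s[b[k, 2]] + o
  }
  s + mg$xh
}

# Implicit hydrogens per heavy atom.  Allowed valences shift with the formal
# charge (N+ -> 4, O- -> 1, ...); unknown elements contribute no hydrogens.
.mg_implicit_h <- function(mg) {
  bs <- ceiling(.mg_bondsum(mg))
  vapply(seq_len(.mg_n(mg)), function(i) {
    av <- .ALLOWED_VALENCE[[mg$elem[i]]]
    if (is.null(av)) return(0L)
    av <- av + mg$charge[i]
    ok <- av[av >= bs[i]]
    if (!length(ok)) return(0L)
    as.integer(min(ok) - bs[i])
  }, integer(1))
}

.mg_total_h <- function(mg) .mg_implicit_h(mg) + mg$xh

.mg_heavy_degree <- function(mg) {
  n <- .mg_n(mg)
  d <- integer(n)
  b <- mg$bonds
  for (k in seq_len(nrow(b))) {
    d[b[k, 1]] <- d[b[k, 1]] + 1L
    d[b[k, 2]] <- d[b[k, 2]] + 1L
  }
  d
}

# Valence sanity: every atom's bond-order sum must fit an allowed valence.
.mg_sanitize_ok <- function(mg) {
  bs <- ceiling(.mg_bondsum(mg))
  all(vapply(seq_len(.mg_n(mg)), function(i) {
    av <- .ALLOWED_VALENCE[[mg$elem[i]]]
    if (is.null(av)) return(TRUE)
    bs[i] <= max(av + mg$charge[i])
  }, logical(1)))
}

.mg_igraph <- function(mg) {
  igraph::graph_from_data_frame(
    d = if (nrow(mg$bonds)) data.frame(from = mg$bonds[, 1],
                                       to = mg$bonds[, 2]) else
      data.frame(from = integer(0), to = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(.mg_n(mg))))
}

# Atom-in-ring flags: an atom is in a ring iff it has an incident non-bridge
# edge (igraph::bridges on the heavy-atom graph).
.mg_in_ring <- function(mg) {
  n <- .mg_n(mg)
  flag <- logical(n)
  if (nrow(mg$bonds) == 0) return(flag)
  g <- .mg_igraph(mg)
  br <- igraph::bridges(g)
  cyc <- setdiff(seq_len(igraph::ecount(g)), as.integer(br))
  for (e in cyc) {
    ends <- as.integer(igraph::ends(g, e))
    flag[ends] <- TRUE
  }
  flag
}

.mg_connected <- function(mg) {
  if (.mg_n(mg) <= 1) return(TRUE)
  igraph::is_connected(.mg_igraph(mg))
}
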
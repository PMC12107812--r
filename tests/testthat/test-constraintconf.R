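test_that("core mapping finds substructure matches deterministically", {
  # identity: a molecule maps onto itself
  m <- mapCore("c1ccccc1", "c1ccccc1")
  expect_length(m, 6L)
  expect_false(attr(m, "partial"))
  # benzene core inside ethylbenzene: a six-atom ring mapping
  m2 <- mapCore("CCc1ccccc1", "c1ccccc1")
  expect_length(m2, 6L)
  cand <- moldesirer:::.mg_from_smiles("CCc1ccccc1")
  expect_true(all(cand$elem[m2] == "C"))
  expect_true(all(m2 >= 3))  # the ethyl carbons are atoms 1-2
  # repeated calls give the same (tie-broken) mapping
  expect_identical(as.integer(mapCore("CCc1ccccc1", "c1ccccc1")),
                   as.integer(m2))
  # impossible core
  expect_error(mapCore("C", "c1ccccc1", mcsFallback = FALSE),
               "constraint failure")
  # partial fallback: shrink until something matches
  m3 <- mapCore("CCCC", "CCCO")
  expect_true(attr(m3, "partial"))
  expect_gte(length(m3), 2L)
})

test_that("constrained embedding pins the core to the reference", {
  ref <- moldesirer:::.mg_from_smiles("c1ccccc1", gen3d = TRUE)
  # identity candidate: zero core RMSD
  m <- mapCore("c1ccccc1", "c1ccccc1")
  cs <- constrainedEmbed("c1ccccc1", ref$coords, m, nConf = 3L)
  expect_true(all(cs@coreRmsd <= 0.1))
  # grown analog (toluene = reference + methyl): all embedded conformers
  # within the core tolerance
  m2 <- mapCore("Cc1ccccc1", "c1ccccc1")
  cs2 <- constrainedEmbed("Cc1ccccc1", ref$coords, m2, nConf = 5L)
  expect_gte(length(cs2@conformers), 1L)
  for (i in seq_along(cs2@conformers)) {
    if (!cs2@fallback[i]) {
      d <- cs2@conformers[[i]][cs2@mapping, ] - ref$coords
      expect_lte(sqrt(mean(rowSums(d^2))), 0.1)
    }
  }
  expect_error(constrainedEmbed("CC", ref$coords, integer(0)),
               "empty core mapping")
})

test_that("the clash filter removes exactly the violating conformers", {
  # synthetic two-conformer set around a known geometry
  mkset <- function(confs) {
    new("ConformerSet", smiles = "CC", conformers = confs,
        mapping = 1:2, clashFlags = logical(length(confs)),
        coreRmsd = numeric(length(confs)),
        fallback = logical(length(confs)))
  }
  atomAt <- function(x) rbind(c(x, 0, 0), c(x + 1.5, 0, 0))
  protein <- matrix(c(0, 0, 0), 1, 3)
  # boundary cases at cutoff 1.5: 1.4 removed, 1.6 kept
  cs <- mkset(list(atomAt(1.4), atomAt(1.6)))
  kept <- clashFilter(cs, protein, cutoff = 1.5)
  expect_length(kept@conformers, 1L)
  expect_equal(kept@conformers[[1]][1, 1], 1.6)
  # an exact overlap is always removed
  cs2 <- mkset(list(rbind(c(0, 0, 0), c(1.5, 0, 0))))
  expect_length(clashFilter(cs2, protein)@conformers, 0L)
  # protein far away: everything survives
  far <- matrix(c(100, 100, 100), 1, 3)
  expect_length(clashFilter(cs, far)@conformers, 2L)
  # monotone in cutoff: survivors shrink as the cutoff grows
  cs3 <- mkset(lapply(seq(0.5, 5, by = 0.5), atomAt))
  surv <- function(cut) {
    vapply(clashFilter(cs3, protein, cutoff = cut)@conformers,
           function(co) co[1, 1], numeric(1))
  }
  s1 <- surv(1.0); s2 <- surv(2.0); s3 <- surv(3.5)
  expect_true(all(s2 %in% s1))
  expect_true(all(s3 %in% s2))
  # empty protein: warned no-op
  expect_warning(out <- clashFilter(cs, matrix(numeric(0), 0, 3)),
                 "no-op")
  expect_length(out@conformers, 2L)
})

test_that("wall and cavity toy receptors behave as constructed", {
  wall <- buildToyReceptor("wall")
  expect_true(all(wall[, 1] == 0))
  # any conformer with an atom within 1.5 A of the plane is removed
  mkset <- function(confs) {
    new("ConformerSet", smiles = "C", conformers = confs, mapping = 1L,
        clashFlags = logical(length(confs)),
        coreRmsd = numeric(length(confs)),
        fallback = logical(length(confs)))
  }
  near <- matrix(c(1.0, 0.2, 0.3), 1, 3)
  farx <- matrix(c(5, 0.2, 0.3), 1, 3)
  kept <- clashFilter(mkset(list(near, farx)), wall, cutoff = 1.5)
  expect_length(kept@conformers, 1L)
  expect_equal(kept@conformers[[1]][1, 1], 5)
  # cavity: a ligand at the pocket center survives
  cav <- buildToyReceptor("cavity")
  center <- matrix(c(0.3, -0.2, 0.1), 1, 3)
  expect_length(clashFilter(mkset(list(center)), cav)@conformers, 1L)
  # PDB round trip preserves coordinates
  tf <- tempfile(fileext = ".pdb")
  buildToyReceptor("wall", path = tf)
  back <- readProteinHeavyAtoms(tf)
  expect_equal(nrow(back), nrow(wall))
  expect_equal(unname(back), unname(wall), tolerance = 1e-3)
})

test_that("constrained scoring follows the mode contract", {
  refBlock <- moldesirer:::.mg_to_molblock(
    moldesirer:::.mg_from_smiles("c1ccccc1", gen3d = TRUE))
  # surrogate, score_only: the (conformation-independent) surrogate score
  sc <- constrainedScore("Cc1ccccc1", refBlock, mode = "score_only",
                         nConf = 3L)
  expect_equal(sc$score, surrogateScore("Cc1ccccc1"))
  expect_true(grepl("V2000", sc$pose))
  # local_only degrades to score_only under the surrogate, with warning
  expect_warning(
    sc2 <- constrainedScore("Cc1ccccc1", refBlock, mode = "local_only",
                            nConf = 3L),
    "degrading to score_only")
  expect_equal(sc2$score, sc$score)
  # an enveloping protein removes every conformer -> evaluation error
  everywhere <- as.matrix(expand.grid(x = seq(-6, 6, 1.2),
                                      y = seq(-6, 6, 1.2),
                                      z = seq(-6, 6, 1.2)))
  expect_error(
    constrainedScore("Cc1ccccc1", refBlock, protein = everywhere,
                     mode = "score_only", nConf = 3L),
    "clash")
})
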
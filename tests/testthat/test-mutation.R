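test_that("site enumeration counts hydrogens and removable fragments", {
  # methane: one carbon with four hydrogens -> four size-0 sites
  expect_length(enumerateReplaceableSites(
    "C", mutationParams(minSize = 0L, maxSize = 0L)), 4L)
  # ethane: two single-carbon terminal sites
  expect_length(enumerateReplaceableSites(
    "CC", mutationParams(minSize = 1L, maxSize = 1L)), 2L)
  # full protection of the ring leaves nothing replaceable
  expect_length(enumerateReplaceableSites(
    "c1ccccc1", mutationParams(minSize = 1L, maxSize = 2L,
                               protected = 1:6)), 0L)
  # ring atoms are never single-bond-removable sites
  expect_length(enumerateReplaceableSites(
    "C1CC1", mutationParams(minSize = 1L, maxSize = 1L)), 0L)
})

test_that("mutation of methane with a grow table is exactly {ethane, propane}", {
  tab <- fragmentTable(c("*C", "*CC"))
  p <- mutationParams(minSize = 0L, maxSize = 0L, minInc = 1L,
                      maxInc = 6L)
  kids <- mutateMol("C", p, tab)
  expect_setequal(kids, c("CC", "CCC"))
  # increment bound: the largest fragment adds 2 heavy atoms
  p3 <- mutationParams(minSize = 0L, maxSize = 0L, minInc = 3L,
                       maxInc = 6L)
  expect_length(mutateMol("C", p3, tab), 0L)
  # whole scaffold protected under mutate-only parameters
  pm <- mutationParams(minSize = 1L, maxSize = 3L, minInc = -1L,
                       maxInc = 1L, protected = 1:3)
  expect_length(mutateMol("CCO", pm, tab), 0L)
})

test_that("children respect increments, sanitize and protected atoms", {
  tab <- toy_table()
  sizes <- tab@table$heavy_atoms
  parents <- c("CCO", "CCCCC", "c1ccccc1C", "CC(C)CO")
  p <- mutationParams(minSize = 0L, maxSize = 2L, minInc = -2L,
                      maxInc = 4L)
  for (par in parents) {
    set.seed(3)
    kids <- mutateMol(par, p, tab)
    h0 <- heavyAtomCount(par)
    for (k in kids) {
      inc <- heavyAtomCount(k) - h0
      expect_gte(inc, -2L); expect_lte(inc, 4L)
      # every child must reparse (valence-valid canonical SMILES)
      expect_silent(makeIndividual(k))
    }
  }
  # protecting the aromatic ring keeps it intact in every child
  pr <- mutationParams(minSize = 1L, maxSize = 2L, minInc = -2L,
                       maxInc = 4L, protected = 1:6)
  set.seed(3)
  kids <- mutateMol("c1ccccc1CCO", pr, tab)
  n_aromatic_c <- function(s)
    sum(strsplit(gsub("Cl", "", s), "")[[1]] == "c")
  for (k in kids) expect_gte(n_aromatic_c(k), 6)
})

test_that("mutation is deterministic under a fixed seed", {
  tab <- toy_table()
  p <- mutationParams(minSize = 0L, maxSize = 1L, minInc = -1L,
                      maxInc = 4L, maxChildren = 5L)
  set.seed(17); a <- mutateMol("CCCO", p, tab)
  set.seed(17); b <- mutateMol("CCCO", p, tab)
  expect_identical(a, b)
})

test_that("grow is mutate restricted to hydrogen sites with growth", {
  tab <- fragmentTable(c("*C"))
  p <- mutationParams(minInc = 1L, maxInc = 2L)
  expect_true("CC" %in% growMol("C", p, tab))
  # grow children are a subset of the size-0 mutation children
  tab2 <- toy_table()
  g <- growMol("CCO", mutationParams(minInc = 1L, maxInc = 6L), tab2)
  m <- mutateMol("CCO", mutationParams(minSize = 0L, maxSize = 0L,
                                       minInc = 1L, maxInc = 6L), tab2)
  expect_true(all(g %in% m))
})

test_that("fragment tables validate their rows and round-trip as TSV", {
  expect_error(fragmentTable(c("CC")), "attachment point")
  expect_error(fragmentTable(c("*C*")), "attachment point")
  expect_error(fragmentTable(data.frame(fragment_smiles = "*CC",
                                        heavy_atoms = 5L)),
               "parses to")
  tab <- toy_table()
  tf <- tempfile(fileext = ".tsv")
  writeFragmentTable(tab, tf)
  back <- readFragmentTable(tf)
  expect_identical(back@table$fragment_smiles, tab@table$fragment_smiles)
  expect_identical(back@table$heavy_atoms, tab@table$heavy_atoms)
})

test_that("the external-generator adapter reports a configuration error", {
  expect_error(
    externalGeneratorAdapter("CC", mutationParams(),
                             dbPath = tempfile("missing_db")),
    "configuration error")
})
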
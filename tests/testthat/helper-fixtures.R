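# Shared fixtures: everything is generated in code, deterministically.

toy_table <- function(seed = 7L, n = 10L) {
  buildToyFragmentTable(seed = seed, nFragments = n)
}

surrogate_spec <- function() fitnessSpec("cost_only_score")

cost_spec <- function() fitnessSpec("cost")

# A fixed set of small, valid, chemically diverse molecules.
diverse_smiles <- function() {
  c("C", "CC", "CCO", "CCC", "c1ccccc1", "CCN", "CCCl", "C1CCCCC1",
    "CC(C)O", "CCCC", "c1ccncc1", "CC=O", "OCc1ccccc1", "CC(=O)O",
    "c1ccco1", "CCS")
}

# Inject descriptor values into the in-memory cache so fitness
# arithmetic can be tested at exact, hand-computable property values.
fake_descriptors <- function(smiles, qed, sa) {
  smi <- canonicalSmiles(smiles)
  assign(smi, c(qed = qed, sa = sa), envir = moldesirer:::.desc_cache)
  smi
}

# Scoring backend that returns a fixed score regardless of structure.
register_fixed_backend <- function(name, score) {
  registerScorerBackend(name, function(individual, receptorSpec) {
    list(score = score, pose = "REMARK fixed backend pose\n")
  })
  list(backend = name)
}

# The N3 peptidomimetic inhibitor (verified reconstruction, see extdata).
n3_smiles <- function() {
  f <- system.file("extdata", "n3_inhibitor.smi", package = "moldesirer")
  strsplit(readLines(f)[1], "\t")[[1]][1]
}

seed_fragment_smiles <- function() {
  f <- system.file("extdata", "seed_fragment.smi", package = "moldesirer")
  strsplit(readLines(f)[1], "\t")[[1]][1]
}
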
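# Post-hoc campaign analytics: similarity distributions, population
# evolution summaries, chemical-space projection, and relative-to-
# absolute binding free energy conversion.

.as_fingerprints <- function(mols, radius = 2L, nbits = 2048L) {
  lapply(mols, function(m) {
    if (is(m, "Fingerprint")) m else morganFingerprint(m, radius, nbits)
  })
}

#' Intra-set pairwise Tanimoto similarities
#'
#' All n(n-1)/2 unordered-pair Tanimoto similarities on Morgan(2, 2048)
#' fingerprints of the molecules in one campaign.  With
#' \code{summarize = TRUE} a 300-bin histogram and a Gaussian kernel
#' density estimate (rule-of-thumb bandwidth) are attached as attributes
#' \code{"histogram"} and \code{"density"}.
#'
#' @param mols list of molecules (SMILES, \linkS4class{Individual} or
#'   precomputed \linkS4class{Fingerprint}), length >= 2.
#' @param summarize attach histogram/density summaries.
#' @return numeric vector of similarities in [0, 1].
#' @export
intraSimilarity <- function(mols, summarize = FALSE) {
  if (length(mols) < 2)
    stop("parameter error: need at least 2 molecules", call. = FALSE)
  fps <- .as_fingerprints(mols)
  n <- length(fps)
  vals <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      k <- k + 1L
      vals[k] <- tanimotoSimilarity(fps[[i]], fps[[j]])
    }
  }
  if (summarize) vals <- .attach_summary(vals)
  vals
}

#' Inter-set pairwise Tanimoto similarities
#'
#' Every molecule of one campaign compared with every molecule of the
#' other: all |A| x |B| cross-pair similarities.
#'
#' @param A,B non-empty lists of molecules (as in
#'   \code{\link{intraSimilarity}}).
#' @param summarize attach histogram/density summaries.
#' @return numeric vector of length |A| * |B|.
#' @export
interSimilarity <- function(A, B, summarize = FALSE) {
  if (!length(A) || !length(B))
    stop("parameter error: both sets must be non-empty", call. = FALSE)
  fa <- .as_fingerprints(A)
  fb <- .as_fingerprints(B)
  vals <- as.numeric(vapply(fa, function(x)
    vapply(fb, function(y) tanimotoSimilarity(x, y), numeric(1)),
    numeric(length(fb))))
  if (summarize) vals <- .attach_summary(vals)
  vals
}

.attach_summary <- function(vals) {
  attr(vals, "histogram") <- graphics::hist(
    vals, breaks = seq(0, 1, length.out = 301), plot = FALSE)
  attr(vals, "density") <- stats::density(vals, kernel = "gaussian")
  vals
}

#' Per-generation evolution summary of a campaign
#'
#' For each generation: minimum / median / maximum of cost, score, qed
#' and sa_score over the population snapshot, the heavy-atom count
#' spread, and the generation's acceptance rate (accepted children over
#' generated children).
#'
#' @param history a \linkS4class{GAState}, or its population-history
#'   data.frame (one row per population member per generation).
#' @param stats optional per-generation counters data.frame (taken from
#'   the state when one is supplied).
#' @return data.frame, one row per generation.
#' @export
evolutionSummary <- function(history, stats = NULL) {
  if (is(history, "GAState")) {
    stats <- history@generationStats
    history <- history@popHistory
  }
  if (!is.data.frame(history) || !nrow(history))
    stop("parameter error: empty history", call. = FALSE)
  gens <- sort(unique(history$generation))
  heavy <- vapply(history$smiles, heavyAtomCount, integer(1))
  rows <- lapply(gens, function(g) {
    h <- history[history$generation == g, ]
    hv <- heavy[history$generation == g]
    data.frame(
      generation = g,
      min_cost = min(h$cost), median_cost = stats::median(h$cost),
      max_cost = max(h$cost),
      min_score = suppressWarnings(min(h$score, na.rm = TRUE)),
      median_score = stats::median(h$score, na.rm = TRUE),
      max_score = suppressWarnings(max(h$score, na.rm = TRUE)),
      min_qed = suppressWarnings(min(h$qed, na.rm = TRUE)),
      median_qed = stats::median(h$qed, na.rm = TRUE),
      max_qed = suppressWarnings(max(h$qed, na.rm = TRUE)),
      min_sa = suppressWarnings(min(h$sa_score, na.rm = TRUE)),
      median_sa = stats::median(h$sa_score, na.rm = TRUE),
      max_sa = suppressWarnings(max(h$sa_score, na.rm = TRUE)),
      min_heavy = min(hv), median_heavy = stats::median(hv),
      max_heavy = max(hv),
      acceptance_rate = if (!is.null(stats) &&
                            g %in% stats$generation)
        stats$acceptance_rate[stats$generation == g] else NA_real_)
  })
  do.call(rbind, rows)
}

#' Project fingerprints into a 2D chemical-space map
#'
#' PCA reduces the binary fingerprint matrix to \code{nComponents}
#' principal components (reporting the cumulative explained-variance
#' fraction), and a seeded exact t-SNE embeds the component scores in two
#' dimensions.  The nonlinear map is qualitative by nature; duplicated
#' fingerprints map to identical component scores.
#'
#' @param fingerprints list of \linkS4class{Fingerprint} or a numeric
#'   matrix (rows = molecules).
#' @param nComponents number of principal components kept (default 50,
#'   capped at the available rank).
#' @param perplexity t-SNE perplexity (default 30, capped for small n).
#' @param seed integer seed for the embedding.
#' @return list with \code{coordinates} (n x 2), \code{varianceFraction}
#'   (cumulative fraction of variance in the kept components) and
#'   \code{scores} (the n x nComponents PC scores).
#' @export
projectChemicalSpace <- function(fingerprints, nComponents = 50L,
                                 perplexity = 30, seed = 1L) {
  X <- if (is.matrix(fingerprints)) fingerprints else
    do.call(rbind, lapply(fingerprints, function(f) as.numeric(f@bits)))
  if (nrow(X) < nComponents + 1)
    stop("parameter error: need more samples than components",
         call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  vf <- sum(pc$sdev[seq_len(k)]^2) / sum(pc$sdev^2)
  perp <- min(perplexity, floor((nrow(X) - 1) / 3))
  coords <- .tsne_exact(scores, perplexity = max(2, perp), seed = seed)
  list(coordinates = coords, varianceFraction = vf, scores = scores)
}

#' Free-energy record constructor
#'
#' @param ddgI relative binding free energy of molecule i (kcal/mol).
#' @param dgR absolute binding free energy of the representative
#'   molecule.
#' @param ddgR relative binding free energy of the representative.
#' @param errDdgI,errDgR,errDdgR non-negative statistical errors.
#' @return A \linkS4class{FreeEnergyRecord}.
#' @export
freeEnergyRecord <- function(ddgI, dgR, ddgR, errDdgI = 0, errDgR = 0,
                             errDdgR = 0) {
  if (any(c(errDdgI, errDgR, errDdgR) < 0))
    stop("parameter error: errors must be >= 0", call. = FALSE)
  new("FreeEnergyRecord", ddgI = ddgI, ddgR = ddgR, dgR = dgR,
      errDdgI = errDdgI, errDdgR = errDdgR, errDgR = errDgR)
}

#' Convert relative to absolute binding free energy
#'
#' \deqn{\Delta G_i = \Delta\Delta G_i + \Delta G_r - \Delta\Delta G_r}
#' with errors propagated in quadrature:
#' \deqn{\delta = \sqrt{\delta^2(\Delta\Delta G_i) +
#'   \delta^2(\Delta G_r) + \delta^2(\Delta\Delta G_r)}.}
#' When molecule i is the representative itself the result is exactly
#' \eqn{\Delta G_r}.
#'
#' @param rec a \linkS4class{FreeEnergyRecord}.
#' @return named numeric: \code{dg} and \code{err} (kcal/mol).
#' @export
rbfeToAbfe <- function(rec) {
  stopifnot(is(rec, "FreeEnergyRecord"))
  c(dg = rec@ddgI + rec@dgR - rec@ddgR,
    err = sqrt(rec@errDdgI^2 + rec@errDgR^2 + rec@errDdgR^2))
}
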
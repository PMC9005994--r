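# Synthetic benchmark generator: balanced 41-nt segment sets with a
# planted, class-dependent positional nucleotide bias.  The signal is
# positional (not motif based) so the one-hot / chemical-property /
# window-composition features provably carry it, giving selection
# methods a known ground-truth relevant column set.

#' Default biased positions for the planted signal
#'
#' Six positions flanking the center cytosine of a 41-nt segment.
#'
#' @return Integer vector of positions.
#' @export
defaultBiasedPositions <- function() c(16L, 18L, 20L, 22L, 24L, 26L)

#' Simulate a labeled set of candidate m5C segments
#'
#' Both classes draw each non-center position i.i.d. from the background
#' distribution; in positives, every biased position is instead drawn
#' from the mixture `(1 - effect) * background + effect * point mass` on
#' its designated nucleotide.  The center is always C in both classes,
#' so `effect = 0` makes the classes identically distributed and
#' `effect = 1` fixes each biased position in all positives.
#'
#' @param nPos,nNeg Positive / negative counts (>= 1).
#' @param effect Mixture weight of the planted bias, in [0, 1].
#' @param biasedPositions Positions carrying the bias (never the center).
#' @param biasedNucleotides Designated nucleotide per biased position
#'   (recycled; default cycles G, A, U).
#' @param flank Flank width (default 20, i.e. 41-nt segments).
#' @param background Named nucleotide probabilities (default uniform).
#' @param seed Seed; the same spec and seed give byte-identical output.
#' @return A labeled [SegmentSet-class].  `metadata(...)$signal` records
#'   the biased positions, their designated nucleotides and the planted
#'   one-hot feature columns.
#' @export
simulateSegments <- function(nPos, nNeg, effect = 0.5,
                             biasedPositions = defaultBiasedPositions(),
                             biasedNucleotides = c("G", "A", "U"),
                             flank = 20L,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, U = 0.25),
                             seed = 1L) {
  if (nPos < 1L || nNeg < 1L) stop("nPos and nNeg must be >= 1")
  if (effect < 0 || effect > 1) stop("effect must be in [0, 1]")
  flank <- as.integer(flank)
  L <- 2L * flank + 1L
  center <- flank + 1L
  if (any(biasedPositions == center))
    stop("biased positions must differ from the center position")
  if (any(biasedPositions < 1L | biasedPositions > L))
    stop("biased positions must lie in [1, ", L, "]")
  bg <- background[.NT] / sum(background)
  nts <- rep_len(biasedNucleotides, length(biasedPositions))
  set.seed(as.integer(seed))
  drawClass <- function(n, biased) {
    m <- matrix("", n, L)
    for (p in seq_len(L)) {
      if (p == center) {
        m[, p] <- "C"
      } else if (biased && p %in% biasedPositions) {
        nt <- nts[match(p, biasedPositions)]
        pr <- (1 - effect) * bg
        pr[nt] <- pr[nt] + effect
        m[, p] <- sample(.NT, n, replace = TRUE, prob = pr)
      } else {
        m[, p] <- sample(.NT, n, replace = TRUE, prob = bg)
      }
    }
    apply(m, 1, paste0, collapse = "")
  }
  seqs <- c(drawClass(nPos, TRUE), drawClass(nNeg, FALSE))
  ids <- c(sprintf("pos_%d", seq_len(nPos)),
           sprintf("neg_%d", seq_len(nNeg)))
  ss <- SegmentSet(seqs, ids = ids,
                   label = c(rep(1L, nPos), rep(0L, nNeg)))
  metadata(ss)$signal <- list(
    positions = as.integer(biasedPositions),
    nucleotides = nts,
    plantedColumns = plantedFeatureNames(biasedPositions, nts),
    effect = effect, seed = as.integer(seed))
  ss
}

#' Ground-truth relevant feature columns of a planted simulation
#'
#' The most directly informative single columns of the planted signal:
#' the one-hot indicator of the designated nucleotide at each biased
#' position.
#'
#' @param positions Biased positions.
#' @param nucleotides Designated nucleotide per position (recycled).
#' @return Character vector of one-hot feature-column names.
#' @export
plantedFeatureNames <- function(positions,
                                nucleotides = c("G", "A", "U")) {
  nts <- rep_len(nucleotides, length(positions))
  paste0("BIN_p", as.integer(positions), "_", nts)
}
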
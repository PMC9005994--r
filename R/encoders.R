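# Sequence feature encoders.
#
# All encoders operate on a SegmentSet (or a character vector of equal
# widths) and return a plain numeric matrix, one row per segment, with
# canonical column names.  encodeSegments() concatenates the families
# into the canonical 808-column representation.

# letter matrix (n x L) from a SegmentSet / character vector
.letterMatrix <- function(x) {
  if (is(x, "SegmentSet")) {
    m <- as.matrix(x@sequences)
    rownames(m) <- names(x)
    return(m)
  }
  s <- .normalizeSeq(as.character(x))
  L <- unique(nchar(s))
  if (length(L) != 1) stop("sequences must have equal length")
  m <- matrix(unlist(strsplit(s, ""), use.names = FALSE),
              nrow = length(s), ncol = L, byrow = TRUE)
  rownames(m) <- names(s)
  m
}

# list of n x L 0/1 indicator matrices, one per nucleotide
.indicators <- function(lm) {
  lapply(stats::setNames(.NT, .NT), function(nt) (lm == nt) + 0)
}

#' Enhanced nucleic acid composition (ENAC)
#'
#' A window of size `window` slides 5' to 3' over each segment; for every
#' window the frequency of each nucleotide (count / window size) is
#' recorded.  For 41-nt segments and the default window of 5 this yields
#' 4 x 37 = 148 features.
#'
#' @param x [SegmentSet-class] or character vector of equal-width
#'   sequences.
#' @param window Sliding-window size (default 5).
#' @return Numeric matrix with columns `ENAC_win<j>_<nt>` in window-major
#'   order, nucleotides ordered A, C, G, U.
#' @export
encodeENAC <- function(x, window = 5L) {
  lm <- .letterMatrix(x)
  L <- ncol(lm)
  window <- as.integer(window)
  if (window < 1L || window > L) stop("window must be in [1, ", L, "]")
  nw <- L - window + 1L
  # banded L x nw matrix summing each window's columns
  W <- matrix(0, L, nw)
  for (j in seq_len(nw)) W[j:(j + window - 1L), j] <- 1
  ind <- .indicators(lm)
  out <- matrix(0, nrow(lm), 4L * nw)
  for (t in seq_along(.NT))
    out[, seq(t, by = 4L, length.out = nw)] <- (ind[[t]] %*% W) / window
  colnames(out) <- paste0("ENAC_win", rep(seq_len(nw), each = 4L), "_",
                          rep(.NT, nw))
  rownames(out) <- rownames(lm)
  out
}

#' Composition of k-spaced nucleic acid pairs (CKSNAP)
#'
#' For each gap k = 0..`maxGap`, the frequency of every ordered
#' nucleotide pair separated by exactly k positions, normalized by the
#' number of such pairs (L - k - 1).  96 features for the default
#' `maxGap` of 5.
#'
#' @param x [SegmentSet-class] or character vector.
#' @param maxGap Largest gap k (default 5).
#' @return Numeric matrix with columns `CKSNAP_k<k>_<XY>`, pairs in
#'   lexicographic A, C, G, U order within each k block.
#' @export
encodeCKSNAP <- function(x, maxGap = 5L) {
  lm <- .letterMatrix(x)
  L <- ncol(lm)
  maxGap <- as.integer(maxGap)
  if (maxGap > L - 2L) stop("maxGap must be <= L - 2")
  ind <- .indicators(lm)
  blocks <- vector("list", maxGap + 1L)
  for (k in 0:maxGap) {
    ntot <- L - k - 1L
    li <- seq_len(ntot)
    ri <- li + k + 1L
    blk <- matrix(0, nrow(lm), 16L)
    cc <- 0L
    for (a in .NT) for (b in .NT) {
      cc <- cc + 1L
      blk[, cc] <- rowSums(ind[[a]][, li, drop = FALSE] *
                           ind[[b]][, ri, drop = FALSE]) / ntot
    }
    colnames(blk) <- paste0("CKSNAP_k", k, "_",
                            rep(.NT, each = 4L), rep(.NT, 4L))
    blocks[[k + 1L]] <- blk
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- rownames(lm)
  out
}

#' Accumulated nucleotide frequency (ANF / nucleotide density)
#'
#' The value at position i is the frequency of the nucleotide found at i
#' among positions 1..i (its running prefix density).  One feature per
#' position.
#'
#' @param x [SegmentSet-class] or character vector (any equal length).
#' @return Numeric matrix with columns `ANF_p<i>`; values in (0, 1].
#' @export
encodeANF <- function(x) {
  lm <- .letterMatrix(x)
  L <- ncol(lm)
  U <- upper.tri(matrix(0, L, L), diag = TRUE) + 0  # prefix-sum operator
  out <- matrix(0, nrow(lm), L)
  for (nt in .NT) {
    I <- (lm == nt) + 0
    out <- out + I * (I %*% U)
  }
  out <- sweep(out, 2, seq_len(L), "/")
  colnames(out) <- paste0("ANF_p", seq_len(L))
  rownames(out) <- rownames(lm)
  out
}

.NCP_CODE <- rbind(A = c(1, 1, 1), C = c(0, 1, 0),
                   U = c(1, 0, 0), G = c(0, 0, 1))

#' Nucleotide chemical property encoding (NCP)
#'
#' Each nucleotide maps to a 3-bit code derived from its chemical
#' property classes: A = (1,1,1), C = (0,1,0), U = (1,0,0), G = (0,0,1).
#' Position-major concatenation gives 3L features (123 for 41-nt
#' segments).
#'
#' @param x [SegmentSet-class] or character vector.
#' @return 0/1 matrix with columns `NCP_p<i>_b<1..3>`.
#' @export
encodeNCP <- function(x) {
  lm <- .letterMatrix(x)
  L <- ncol(lm)
  out <- matrix(0, nrow(lm), 3L * L)
  for (i in seq_len(L))
    out[, (3L * i - 2L):(3L * i)] <- .NCP_CODE[lm[, i], , drop = FALSE]
  colnames(out) <- paste0("NCP_p", rep(seq_len(L), each = 3L), "_b",
                          rep(1:3, L))
  rownames(out) <- rownames(lm)
  out
}

#' One-hot (binary) encoding
#'
#' A = (1,0,0,0), C = (0,1,0,0), G = (0,0,1,0), U = (0,0,0,1) per
#' position, position-major; 4L features (164 for 41-nt segments).
#'
#' @param x [SegmentSet-class] or character vector.
#' @return 0/1 matrix with columns `BIN_p<i>_<nt>`.
#' @export
encodeBinary <- function(x) {
  lm <- .letterMatrix(x)
  L <- ncol(lm)
  ind <- .indicators(lm)
  out <- matrix(0, nrow(lm), 4L * L)
  for (t in seq_along(.NT))
    out[, seq(t, by = 4L, length.out = L)] <- ind[[t]]
  colnames(out) <- paste0("BIN_p", rep(seq_len(L), each = 4L), "_",
                          rep(.NT, L))
  rownames(out) <- rownames(lm)
  out
}

#' Standardized RNA dinucleotide physicochemical property table
#'
#' Six structural step parameters (Roll, Rise, Shift, Twist, Slide, Tilt)
#' for the 16 RNA dinucleotides, z-standardized per index across the 16
#' dinucleotides as the pseudo-dinucleotide framework requires.
#'
#' @param path TSV with an `index` column and one column per dinucleotide
#'   (defaults to the table shipped with the package).
#' @param standardize Standardize each index row to mean 0, unit variance
#'   (default TRUE).
#' @return Numeric matrix, indices x 16 dinucleotides.
#' @export
rnaDinucProperties <- function(path = system.file("extdata",
                                 "rna_dinucleotide_properties.tsv",
                                 package = "m5Cpredict"),
                               standardize = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$index
  dinucs <- paste0(rep(.NT, each = 4L), rep(.NT, 4L))
  if (!all(dinucs %in% colnames(m)))
    stop("property table is missing dinucleotides: ",
         paste(setdiff(dinucs, colnames(m)), collapse = ", "))
  m <- m[, dinucs, drop = FALSE]
  if (standardize)
    m <- t(scale(t(m)))[, , drop = FALSE]
  m
}

#' Series-correlation pseudo dinucleotide composition (SCPseDNC)
#'
#' The first 16 components are the normalized dinucleotide frequencies;
#' components 17..16+lambda*Lambda are weighted tiered correlation
#' factors theta, one per (tier m = 1..lambda, property index), where the
#' tier-m factor for a property is the average over the sequence of the
#' product of that property's values at dinucleotides m steps apart.
#' All components share one denominator, so the vector sums to 1.
#'
#' @param x [SegmentSet-class] or character vector.
#' @param lambda Highest correlation tier (default 20; must satisfy
#'   lambda < L - 2).
#' @param w Weight of the correlation components, in (0, 1] (default 0.9).
#' @param properties Standardized property matrix from
#'   [rnaDinucProperties()] (indices x 16 dinucleotides).
#' @return Numeric matrix with columns `SCPDNC_1..SCPDNC_<16+lambda*nI>`;
#'   rows sum to 1.
#' @export
encodeSCPseDNC <- function(x, lambda = 20L, w = 0.9,
                           properties = rnaDinucProperties()) {
  lm <- .letterMatrix(x)
  L <- ncol(lm)
  lambda <- as.integer(lambda)
  if (lambda >= L - 2L) stop("lambda must be < L - 2")
  if (w <= 0 || w > 1) stop("w must be in (0, 1]")
  nI <- nrow(properties)
  dinucs <- paste0(rep(.NT, each = 4L), rep(.NT, 4L))
  if (!all(dinucs %in% colnames(properties)))
    stop("property table is missing dinucleotides")
  P <- properties[, dinucs, drop = FALSE]
  n <- nrow(lm)
  # dinucleotide index (1..16) at each of the L-1 steps
  code <- matrix(match(lm, .NT), n, L)
  dv <- 4L * (code[, -L, drop = FALSE] - 1L) + code[, -1L, drop = FALSE]
  out <- matrix(0, n, 16L + lambda * nI)
  for (r in seq_len(n)) {
    f <- tabulate(dv[r, ], nbins = 16L) / (L - 1L)
    th <- numeric(lambda * nI)
    for (m in seq_len(lambda)) {
      i <- seq_len(L - m - 2L)
      J <- P[, dv[r, i], drop = FALSE] * P[, dv[r, i + m], drop = FALSE]
      th[((m - 1L) * nI + 1L):(m * nI)] <- rowMeans(J)
    }
    out[r, ] <- c(f, w * th) / (sum(f) + w * sum(th))
  }
  colnames(out) <- paste0("SCPDNC_", seq_len(ncol(out)))
  rownames(out) <- rownames(lm)
  out
}

#' Encode a segment set into the canonical feature representation
#'
#' Runs the configured encoders and concatenates their outputs in the
#' fixed block order ENAC, CKSNAP, ANF, NCP, BIN, SCPDNC, W2V.  With all
#' seven families and default parameters on 41-nt segments this is the
#' canonical 808-column representation
#' (148 + 96 + 41 + 123 + 164 + 136 + 100).
#'
#' @param x A [SegmentSet-class].
#' @param model A trained [Word2VecModel-class]; required when the W2V
#'   block is included.
#' @param blocks Which feature families to compute, in canonical order.
#' @param enacWindow,cksnapMaxGap,pseLambda,pseWeight Encoder parameters.
#' @param properties Property table for the SCPDNC block.
#' @return A [FeatureMatrix-class] with labels copied from `x`.
#' @export
encodeSegments <- function(x, model = NULL,
                           blocks = c("ENAC", "CKSNAP", "ANF", "NCP",
                                      "BIN", "SCPDNC", "W2V"),
                           enacWindow = 5L, cksnapMaxGap = 5L,
                           pseLambda = 20L, pseWeight = 0.9,
                           properties = rnaDinucProperties()) {
  canonical <- c("ENAC", "CKSNAP", "ANF", "NCP", "BIN", "SCPDNC", "W2V")
  blocks <- canonical[canonical %in% blocks]
  if ("W2V" %in% blocks && is.null(model))
    stop("a trained Word2VecModel is required for the W2V block")
  parts <- list()
  for (b in blocks) {
    parts[[b]] <- switch(b,
      ENAC = encodeENAC(x, window = enacWindow),
      CKSNAP = encodeCKSNAP(x, maxGap = cksnapMaxGap),
      ANF = encodeANF(x),
      NCP = encodeNCP(x),
      BIN = encodeBinary(x),
      SCPDNC = encodeSCPseDNC(x, lambda = pseLambda, w = pseWeight,
                              properties = properties),
      W2V = encodeWord2Vec(x, model))
  }
  values <- do.call(cbind, parts)
  FeatureMatrix(values,
                blocks = rep(blocks, vapply(parts, ncol, 0L)),
                label = segmentLabels(x))
}
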
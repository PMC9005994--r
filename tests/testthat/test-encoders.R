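polyC <- strrep("C", 41)

test_that("window composition encoder handles degenerate segments", {
  e <- encodeENAC(polyC)
  expect_equal(ncol(e), 148L)
  # every window block is (0, 1, 0, 0): all C
  expect_equal(as.numeric(e), rep(c(0, 1, 0, 0), 37))
  expect_error(encodeENAC(polyC, window = 42), "window")
})

test_that("k-spaced pair encoder handles degenerate segments", {
  e <- encodeCKSNAP(polyC)
  expect_equal(ncol(e), 96L)
  m <- matrix(as.numeric(e), nrow = 16)
  expect_equal(m[6, ], rep(1, 6))        # C*C is the 6th pair
  expect_equal(colSums(m), rep(1, 6))
})

test_that("nucleotide density of a homopolymer is all ones", {
  expect_equal(as.numeric(encodeANF(strrep("A", 10))), rep(1, 10))
})

test_that("chemical-property and one-hot codes follow the letter maps", {
  seg <- paste0(strrep("G", 20), "C", strrep("G", 20))
  n <- encodeNCP(seg)
  expect_equal(ncol(n), 123L)
  expect_equal(as.numeric(n[, 1:3]), c(0, 0, 1))      # G
  expect_equal(as.numeric(n[, 61:63]), c(0, 1, 0))    # center C
  b <- encodeBinary(seg)
  expect_equal(ncol(b), 164L)
  expect_equal(as.numeric(b[, 81:84]), c(0, 1, 0, 0)) # center C one-hot
  # codes for all four letters
  expect_equal(as.numeric(encodeNCP("ACUG")),
               c(1, 1, 1, 0, 1, 0, 1, 0, 0, 0, 0, 1))
  expect_equal(as.numeric(encodeBinary("ACGU")),
               c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1))
})

test_that("pseudo dinucleotide components match direct evaluation on a toy", {
  # 6-nt toy, lambda = 2, one property index
  toy <- "AACGAU"
  P <- matrix(seq(-1.5, 1.5, length.out = 16), nrow = 1)
  colnames(P) <- as.vector(t(outer(NTS, NTS, paste0)))
  rownames(P) <- "toy"
  got <- encodeSCPseDNC(toy, lambda = 2, w = 0.5, properties = P)
  expect_equal(ncol(got), 16 + 2)
  exp <- oracle_scpsednc(toy, lambda = 2, w = 0.5, P = P)
  expect_equal(as.numeric(got), as.numeric(exp), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-12)
})

test_that("the shipped property table is standardized per index", {
  P <- rnaDinucProperties()
  expect_equal(dim(P), c(6L, 16L))
  expect_true(all(abs(rowMeans(P)) < 1e-9))
  expect_true(all(abs(apply(P, 1, var) - 1) < 1e-9))
  badP <- P[, -1]
  expect_error(encodeSCPseDNC(polyC, properties = badP), "missing")
})

test_that("embedding training is deterministic and vocabulary-faithful", {
  ss <- randomSegmentSet(25, seed = 7)
  m1 <- trainEmbedding(ss, dim = 16, epochs = 3, seed = 11)
  m2 <- trainEmbedding(ss, dim = 16, epochs = 3, seed = 11)
  expect_identical(tokenVectors(m1), tokenVectors(m2))
  expect_equal(ncol(tokenVectors(m1)), 16L)
  # disjoint corpora give disjoint vocabularies
  a <- trainEmbedding(SegmentSet(paste0(strrep("A", 20), "C",
                                        strrep("A", 20))),
                      dim = 4, epochs = 1)
  g <- trainEmbedding(SegmentSet(paste0(strrep("G", 20), "C",
                                        strrep("G", 20))),
                      dim = 4, epochs = 1)
  common <- intersect(rownames(tokenVectors(a)), rownames(tokenVectors(g)))
  # the only shared tokens could come from the common center C context
  expect_true(all(grepl("C", common)))
})

test_that("segment embedding is the mean of its token vectors", {
  ss <- randomSegmentSet(20, seed = 13)
  mod <- trainEmbedding(ss, dim = 8, epochs = 2, seed = 3)
  seg <- as.character(ss)[1]
  toks <- substring(seg, 1:39, 3:41)
  W <- tokenVectors(mod)
  manual <- colMeans(W[toks, , drop = FALSE])
  got <- encodeWord2Vec(seg, mod)
  expect_equal(as.numeric(got), as.numeric(manual), tolerance = 1e-12)
  # out-of-vocabulary tokens contribute zero vectors
  small <- trainEmbedding(SegmentSet(paste0(strrep("A", 20), "C",
                                            strrep("A", 20))),
                          dim = 4, epochs = 1)
  v <- encodeWord2Vec(strrep("G", 41), small)
  expect_equal(as.numeric(v), rep(0, 4))
})

test_that("full encoding has the canonical block structure", {
  ss <- randomSegmentSet(3, seed = 21)
  emb <- trainEmbedding(ss, dim = 100, epochs = 2, seed = 2)
  fm <- encodeSegments(ss, model = emb)
  expect_s4_class(fm, "FeatureMatrix")
  expect_equal(dim(featureValues(fm)), c(3L, 808L))
  expect_equal(lengths(blockMap(fm)),
               c(ENAC = 148L, CKSNAP = 96L, ANF = 41L, NCP = 123L,
                 BIN = 164L, SCPDNC = 136L, W2V = 100L))
  # repeated calls are byte-identical given fixed inputs
  fm2 <- encodeSegments(ss, model = emb)
  expect_identical(featureValues(fm), featureValues(fm2))
  # dropping the embedding block
  fm708 <- encodeSegments(ss, blocks = setdiff(names(blockMap(fm)),
                                               "W2V"))
  expect_equal(nrow(fm708), 708L)
  expect_error(encodeSegments(ss), "Word2VecModel")
})

test_that("feature matrices round-trip through CSV", {
  ss <- simulateSegments(5, 5, seed = 3)
  fm <- encodeSegments(ss, blocks = c("ANF", "BIN"))
  p <- tempfile(fileext = ".csv")
  writeFeatureCSV(fm, p)
  back <- readFeatureCSV(p)
  expect_equal(featureValues(back), featureValues(fm), tolerance = 1e-12)
  expect_identical(segmentLabels(back), segmentLabels(fm))
  expect_identical(names(blockMap(back)), names(blockMap(fm)))
})
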
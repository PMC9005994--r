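# Independent naive-loop oracles used to validate the vectorized
# encoders and curve computations.  These deliberately re-derive every
# quantity from the written definitions with plain loops and share no
# code with the package implementation.

NTS <- c("A", "C", "G", "U")

# random valid segment: fixed width, center C
randomSegment <- function(L = 41L) {
  s <- sample(NTS, L, replace = TRUE)
  s[(L + 1L) %/% 2L] <- "C"
  paste0(s, collapse = "")
}

randomSegmentSet <- function(n, L = 41L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  SegmentSet(vapply(seq_len(n), function(i) randomSegment(L), ""),
             ids = paste0("r", seq_len(n)))
}

oracle_enac <- function(seq, S = 5L) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  out <- c()
  for (j in 1:(L - S + 1)) {
    win <- ch[j:(j + S - 1)]
    for (nt in NTS) out <- c(out, sum(win == nt) / S)
  }
  out
}

oracle_cksnap <- function(seq, maxGap = 5L) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  out <- c()
  for (k in 0:maxGap) {
    ntotal <- L - k - 1
    for (a in NTS) for (b in NTS) {
      cnt <- 0
      for (i in 1:ntotal) if (ch[i] == a && ch[i + k + 1] == b)
        cnt <- cnt + 1
      out <- c(out, cnt / ntotal)
    }
  }
  out
}

oracle_anf <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  vapply(seq_along(ch), function(i) sum(ch[1:i] == ch[i]) / i, 0)
}

oracle_ncp <- function(seq) {
  map <- list(A = c(1, 1, 1), C = c(0, 1, 0), U = c(1, 0, 0),
              G = c(0, 0, 1))
  unlist(lapply(strsplit(seq, "")[[1]], function(n) map[[n]]))
}

oracle_bin <- function(seq) {
  map <- list(A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0),
              U = c(0, 0, 0, 1))
  unlist(lapply(strsplit(seq, "")[[1]], function(n) map[[n]]))
}

oracle_scpsednc <- function(seq, lambda, w, P) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  dn <- paste0(ch[-L], ch[-1])
  dinucs <- as.vector(t(outer(NTS, NTS, paste0)))
  f <- vapply(dinucs, function(d) sum(dn == d), 0) / (L - 1)
  # tier-major ordering: all indices of tier m, then tier m + 1, ...
  th <- c()
  for (m in 1:lambda) for (s in seq_len(nrow(P))) {
    vals <- vapply(1:(L - m - 2), function(i)
      P[s, dn[i]] * P[s, dn[i + m]], 0)
    th <- c(th, mean(vals))
  }
  c(f, w * th) / (sum(f) + w * sum(th))
}

# AUROC as the Mann-Whitney pair statistic, O(n^2)
oracle_auroc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# AUPRC by exhaustive enumeration of distinct-score thresholds,
# step-wise summation
oracle_auprc <- function(y, s) {
  cuts <- sort(unique(s), decreasing = TRUE)
  prevR <- 0
  area <- 0
  for (t in cuts) {
    pred <- s >= t
    tp <- sum(pred & y == 1)
    r <- tp / sum(y == 1)
    p <- tp / sum(pred)
    area <- area + (r - prevR) * p
    prevR <- r
  }
  area
}

# ---- brute-force Shapley attribution for an xgboost stump ensemble ---
# f_S(x): expectation of the ensemble when only features in S are known,
# propagating cover weights down unknown splits (the path-dependent
# convention).  Exact for depth-1 trees.
stumpTable <- function(bst) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = bst))
  trees <- split(dt, dt$Tree)
  lapply(trees, function(tr) {
    root <- tr[tr$Node == 0, ]
    if (is.na(root$Feature) || root$Feature == "Leaf")
      return(list(leafOnly = TRUE, value = root$Gain))
    yes <- tr[tr$ID == root$Yes, ]
    no <- tr[tr$ID == root$No, ]
    list(leafOnly = FALSE, feature = root$Feature, split = root$Split,
         vYes = yes$Gain, vNo = no$Gain,
         cYes = yes$Cover, cNo = no$Cover)
  })
}

stump_fS <- function(stumps, x, S) {
  tot <- 0
  for (st in stumps) {
    if (isTRUE(st$leafOnly)) { tot <- tot + st$value; next }
    if (st$feature %in% S) {
      tot <- tot + if (x[[st$feature]] < st$split) st$vYes else st$vNo
    } else {
      tot <- tot + (st$cYes * st$vYes + st$cNo * st$vNo) /
        (st$cYes + st$cNo)
    }
  }
  tot
}

bruteShapley <- function(bst, x, features) {
  stumps <- stumpTable(bst)
  nF <- length(features)
  phi <- setNames(numeric(nF), features)
  for (i in features) {
    rest <- setdiff(features, i)
    for (sz in 0:length(rest)) {
      subs <- if (sz == 0) list(character(0)) else
        combn(rest, sz, simplify = FALSE)
      wgt <- factorial(sz) * factorial(nF - sz - 1) / factorial(nF)
      for (S in subs)
        phi[i] <- phi[i] + wgt * (stump_fS(stumps, x, c(S, i)) -
                                  stump_fS(stumps, x, S))
    }
  }
  phi
}
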
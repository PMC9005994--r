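# Stage seeds are all derived from one top-level run seed so a single
# integer reproduces the whole pipeline.  Kept well below 2^31.
.STAGE_OFFSETS <- c(simulate = 11L, embedding = 23L, ranking = 37L,
                    folds = 53L, tuning = 71L, model = 89L, split = 101L)

#' Derive a stage seed from a top-level run seed
#'
#' @param seed Integer top-level seed.
#' @param stage One of `r paste(names(.STAGE_OFFSETS), collapse = ", ")`.
#' @return An integer seed, deterministic in `(seed, stage)`.
#' @export
deriveSeed <- function(seed, stage = names(.STAGE_OFFSETS)) {
  stage <- match.arg(stage)
  seed <- as.integer(seed)
  as.integer((as.numeric(seed) * 7919 + .STAGE_OFFSETS[[stage]]) %% 2147483629)
}

# normalize raw sequence text: uppercase, DNA T -> RNA U
.normalizeSeq <- function(x) {
  chartr("t", "U", chartr("T", "U", toupper(x)))
}

.assertBinaryLabels <- function(y) {
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("labels must be binary 0/1 without NA")
  y
}

.assertFiniteMatrix <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!all(is.finite(X))) stop("feature matrix contains non-finite values")
  X
}
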
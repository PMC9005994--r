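#' Construct a SegmentSet
#'
#' @param sequences Character vector or [Biostrings::RNAStringSet] of
#'   equal-width odd-length sequences with a center C.  `T` is converted to
#'   `U` and lowercase is uppercased before validation.
#' @param ids Segment identifiers (defaults to names of `sequences`).
#' @param centerOffset 1-based position of the center C in the source
#'   sequence (`NA` when unknown).
#' @param label Optional 0/1 labels.
#' @param speciesTag Optional single character tag.
#' @return A [SegmentSet-class] object.
#' @examples
#' s <- paste0(strrep("A", 20), "C", strrep("G", 20))
#' ss <- SegmentSet(setNames(s, "seg1"), label = 1L)
#' ss
#' @export
SegmentSet <- function(sequences, ids = names(sequences),
                       centerOffset = NA_integer_, label = NA_integer_,
                       speciesTag = NA_character_) {
  if (is(sequences, "XStringSet")) sequences <- as.character(sequences)
  sequences <- .normalizeSeq(as.character(sequences))
  n <- length(sequences)
  if (is.null(ids)) ids <- if (n) paste0("seg", seq_len(n)) else character()
  rss <- Biostrings::RNAStringSet(sequences)
  names(rss) <- ids
  new("SegmentSet",
      sequences = rss,
      centerOffset = rep_len(as.integer(centerOffset), n),
      label = rep_len(as.integer(label), n),
      speciesTag = as.character(speciesTag)[1])
}

#' @describeIn SegmentSet Number of segments.
#' @param x,object A `SegmentSet`.
#' @export
setMethod("length", "SegmentSet", function(x) length(x@sequences))

#' @describeIn SegmentSet Segment identifiers.
#' @export
setMethod("names", "SegmentSet", function(x) names(x@sequences))

#' @describeIn SegmentSet Segment sequences as a character vector.
#' @export
setMethod("as.character", "SegmentSet",
          function(x) as.character(x@sequences))

#' @describeIn SegmentSet 0/1 labels (NA when unlabeled).
#' @export
setMethod("segmentLabels", "SegmentSet", function(x) x@label)

#' @describeIn SegmentSet Replace labels.
#' @param value Replacement labels.
#' @export
setReplaceMethod("segmentLabels", "SegmentSet", function(x, value) {
  x@label <- rep_len(as.integer(value), length(x))
  validObject(x)
  x
})

#' @describeIn SegmentSet 1-based center positions in the source sequences.
#' @export
setMethod("centerOffset", "SegmentSet", function(x) x@centerOffset)

#' @describeIn SegmentSet Species tag of the set.
#' @export
setMethod("speciesTag", "SegmentSet", function(x) x@speciesTag)

#' @describeIn SegmentSet Subset segments.
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "SegmentSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x))
  initialize(x,
             sequences = x@sequences[i],
             centerOffset = x@centerOffset[i],
             label = x@label[i])
})

#' @describeIn SegmentSet Display a summary.
#' @export
setMethod("show", "SegmentSet", function(object) {
  n <- length(object)
  w <- if (n) Biostrings::width(object@sequences)[1] else NA_integer_
  nlab <- sum(!is.na(object@label))
  cat("SegmentSet with", n, "segments of width", w, "\n")
  if (!is.na(object@speciesTag)) cat("  species:", object@speciesTag, "\n")
  if (nlab)
    cat("  labeled:", nlab, "(", sum(object@label == 1L, na.rm = TRUE),
        "positive /", sum(object@label == 0L, na.rm = TRUE), "negative )\n")
  if (n) {
    k <- min(n, 3L)
    for (ii in seq_len(k))
      cat("  ", names(object)[ii], ": ",
          as.character(object@sequences[[ii]]), "\n", sep = "")
    if (n > k) cat("  ...\n")
  }
})

#' Read candidate m5C segments from a FASTA file
#'
#' Each record is expected to be a single segment of width `2*flank+1`
#' with a cytosine at the center.  `T` is converted to `U` and lowercase
#' accepted.  Records that fail validation (wrong length, non-C center,
#' ambiguity codes) are rejected individually and collected in a report
#' available as `metadata(result)$rejected`; they never abort the read.
#'
#' @param path FASTA file path.
#' @param flank Flanking length each side of the center (default 20,
#'   giving 41-nt segments).
#' @param rejectFile Optional path; when given, the rejection report is
#'   written there as tab-separated `id<TAB>reason`.
#' @return A [SegmentSet-class]; rejected records in
#'   `metadata(...)$rejected` (data.frame with columns id, reason).
#' @export
readSegmentFasta <- function(path, flank = 20L, rejectFile = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e)))
  L <- 2L * as.integer(flank) + 1L
  ids <- sub("\\s.*$", "", names(raw))
  seqs <- .normalizeSeq(as.character(raw))
  keep <- logical(length(seqs))
  reason <- character(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    if (nchar(s) != L) {
      reason[i] <- paste0("length != ", L)
    } else if (!grepl(sprintf("^[ACGU]{%d}$", L), s)) {
      reason[i] <- "non-ACGU character"
    } else if (substr(s, flank + 1L, flank + 1L) != "C") {
      reason[i] <- "center nucleotide is not C"
    } else keep[i] <- TRUE
  }
  rejected <- data.frame(id = ids[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (anyDuplicated(ids[keep]))
    stop("duplicate segment ids in FASTA: ",
         paste(unique(ids[keep][duplicated(ids[keep])]), collapse = ", "))
  ss <- SegmentSet(seqs[keep], ids = ids[keep])
  metadata(ss)$rejected <- rejected
  if (!is.null(rejectFile))
    utils::write.table(rejected, rejectFile, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  ss
}

#' Write a SegmentSet to FASTA
#'
#' @param x A [SegmentSet-class].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeSegmentFasta <- function(x, path) {
  stopifnot(is(x, "SegmentSet"))
  Biostrings::writeXStringSet(x@sequences, path)
  invisible(path)
}

#' Extract all candidate cytosine windows from longer sequences
#'
#' Slides over each input sequence and emits one segment per cytosine
#' whose full `flank`-nt context on both sides lies inside the sequence.
#' Cytosines closer than `flank` to either end are skipped (no padding:
#' every downstream encoder assumes the fixed window width).
#'
#' @param seqs Named character vector, [Biostrings::RNAStringSet], or a
#'   single unnamed sequence.  `T` is converted to `U`.
#' @param flank Flank width each side of the candidate C (default 20).
#' @return A [SegmentSet-class] with ids `<seqid>_<position>` and
#'   `centerOffset` giving the 1-based position of each candidate C.
#' @examples
#' extractCandidates(c(tx1 = "AAAACAAAAA"), flank = 2)
#' @export
extractCandidates <- function(seqs, flank = 20L) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  nm <- names(seqs)
  seqs <- .normalizeSeq(as.character(seqs))
  names(seqs) <- if (is.null(nm)) paste0("seq", seq_along(seqs)) else nm
  flank <- as.integer(flank)
  L <- 2L * flank + 1L
  short <- nchar(seqs) < L
  if (any(short))
    stop("sequence(s) shorter than ", L, " nt: ",
         paste(names(seqs)[short], collapse = ", "))
  out_seq <- character(); out_id <- character(); out_off <- integer()
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    n <- nchar(s)
    pos <- gregexpr("C", s, fixed = TRUE)[[1]]
    pos <- pos[pos > 0]
    pos <- pos[pos > flank & pos <= n - flank]
    if (length(pos)) {
      out_seq <- c(out_seq, substring(s, pos - flank, pos + flank))
      out_id <- c(out_id, paste0(names(seqs)[i], "_", pos))
      out_off <- c(out_off, pos)
    }
  }
  SegmentSet(out_seq, ids = out_id, centerOffset = out_off)
}

#' Write a labeled fixture (FASTA plus label table)
#'
#' @param x A labeled [SegmentSet-class].
#' @param fastaPath Output FASTA path.
#' @param labelPath Output TSV path (columns id, label).
#' @return Invisibly, a list with both paths.
#' @export
writeFixture <- function(x, fastaPath, labelPath) {
  writeSegmentFasta(x, fastaPath)
  utils::write.table(
    data.frame(id = names(x), label = segmentLabels(x)),
    labelPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fastaPath, labels = labelPath))
}

#' Read a labeled fixture written by [writeFixture()]
#'
#' @param fastaPath FASTA of 41-nt segments.
#' @param labelPath TSV with columns id, label.
#' @param flank Flank width (default 20).
#' @return A labeled [SegmentSet-class].
#' @export
readFixture <- function(fastaPath, labelPath, flank = 20L) {
  ss <- readSegmentFasta(fastaPath, flank = flank)
  lab <- utils::read.delim(labelPath, stringsAsFactors = FALSE)
  m <- match(names(ss), lab$id)
  segmentLabels(ss) <- lab$label[m]
  ss
}
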
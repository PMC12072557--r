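#' Scoring scheme for local alignment
#'
#' Affine gap scoring: a gap of length `L` costs `gapOpen + L * gapExtend`.
#' Defaults are conventional nucleotide settings (+1/-1, open -2, extend -1).
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0); also used for any column involving `N`.
#' @param gapOpen,gapExtend gap penalties (<= 0).
#' @return named list of the four parameters.
#' @export
scoringScheme <- function(match = 1, mismatch = -1, gapOpen = -2,
                          gapExtend = -1) {
  if (!(match > 0)) stop("match score must be > 0")
  if (!(mismatch < 0)) stop("mismatch score must be < 0")
  if (gapOpen > 0 || gapExtend > 0) stop("gap penalties must be <= 0")
  list(match = match, mismatch = mismatch, gapOpen = gapOpen,
       gapExtend = gapExtend)
}

checkAlnSeq <- function(x, what) {
  if (is(x, "CodingSequence")) x <- seqString(x)
  x <- toupper(as.character(x))
  if (length(x) != 1L || !nzchar(x)) stop(what, " must be a non-empty sequence")
  if (grepl("[^ACGTN]", x)) stop(what, " contains characters outside {A,C,G,T,N}")
  x
}

#' Affine-gap Smith-Waterman local alignment
#'
#' Optimal local alignment under affine gap scoring (Gotoh's three-state
#' recursion) with deterministic traceback; ties are resolved preferring
#' diagonal over up over left moves.  `N` never scores as a match and never
#' counts as identical.  Percent identity is computed over all alignment
#' columns, gap columns included (the \dQuote{n of m nt} convention of sink
#' reports counts a span, not just matches).
#'
#' @param a,b sequences over `{A,C,G,T,N}` (strings or `CodingSequence`s).
#' @param scoring a [scoringScheme()].
#' @return a [LocalAlignmentResult]; when no cell scores positive, the result
#'   has score 0 and an empty alignment.
#' @examples
#' smithWaterman("ACGT", "ACGT")
#' @export
smithWaterman <- function(a, b, scoring = scoringScheme()) {
  a <- checkAlnSeq(a, "a"); b <- checkAlnSeq(b, "b")
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  go <- scoring$gapOpen; ge <- scoring$gapExtend
  NEG <- -Inf
  M <- matrix(0, n + 1L, m + 1L)        # best ending in (mis)match at (i,j)
  X <- matrix(NEG, n + 1L, m + 1L)      # gap in b (consuming a)
  Y <- matrix(NEG, n + 1L, m + 1L)      # gap in a (consuming b)
  M[1L, ] <- NEG; M[, 1L] <- NEG; M[1L, 1L] <- 0
  subScore <- function(x, y)
    if (x == y && x != "N") scoring$match else scoring$mismatch
  for (i in seq_len(n) + 1L) {
    ai <- av[i - 1L]
    for (j in seq_len(m) + 1L) {
      s <- subScore(ai, bv[j - 1L])
      M[i, j] <- s + max(0, M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                         Y[i - 1L, j - 1L])
      X[i, j] <- max(M[i - 1L, j] + go + ge, X[i - 1L, j] + ge)
      Y[i, j] <- max(M[i, j - 1L] + go + ge, Y[i, j - 1L] + ge)
    }
  }
  best <- max(M)
  if (best <= 0) {
    return(new("LocalAlignmentResult", score = 0,
               aSpan = c(NA_integer_, NA_integer_),
               bSpan = c(NA_integer_, NA_integer_),
               alignedColumns = 0L, identicalColumns = 0L,
               percentIdentity = 0, alignmentA = "", alignmentB = ""))
  }
  hit <- which(M == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE][1L, ]
  i <- unname(hit[1L]); j <- unname(hit[2L])
  aEnd <- i - 1L; bEnd <- j - 1L
  alnA <- character(); alnB <- character()
  state <- "M"
  repeat {
    if (state == "M") {
      s <- subScore(av[i - 1L], bv[j - 1L])
      alnA <- c(av[i - 1L], alnA); alnB <- c(bv[j - 1L], alnB)
      prev <- M[i, j] - s
      i <- i - 1L; j <- j - 1L
      if (prev <= 1e-9) break         # zero cell: local alignment start
      ## move tie order: diagonal > up > left
      if (M[i, j] >= prev - 1e-9) state <- "M"
      else if (X[i, j] >= prev - 1e-9) state <- "X"
      else state <- "Y"
    } else if (state == "X") {
      alnA <- c(av[i - 1L], alnA); alnB <- c("-", alnB)
      opened <- M[i - 1L, j] + go + ge
      extended <- X[i - 1L, j] + ge
      i <- i - 1L
      state <- if (opened >= extended - 1e-9) "M" else "X"
    } else {
      alnA <- c("-", alnA); alnB <- c(bv[j - 1L], alnB)
      opened <- M[i, j - 1L] + go + ge
      extended <- Y[i, j - 1L] + ge
      j <- j - 1L
      state <- if (opened >= extended - 1e-9) "M" else "Y"
    }
  }
  ## after the loop, (i, j) is the matrix cell preceding the alignment;
  ## matrix row r corresponds to sequence position r - 1
  aStart <- i; bStart <- j
  ident <- sum(alnA == alnB & alnA != "-" & alnA != "N")
  cols <- length(alnA)
  new("LocalAlignmentResult", score = best,
      aSpan = c(aStart, aEnd), bSpan = c(bStart, bEnd),
      alignedColumns = as.integer(cols), identicalColumns = as.integer(ident),
      percentIdentity = 100 * ident / cols,
      alignmentA = paste(alnA, collapse = ""),
      alignmentB = paste(alnB, collapse = ""))
}

#' Scan a transcript for a miRNA sink site
#'
#' Aligns the miRNA against the reverse complement of the transcript (the
#' strand a miRNA would base-pair with) and maps the aligned transcript span
#' back to forward-strand coordinates.  A transcript carrying a perfectly
#' complementary window yields 100% identity over the miRNA length.
#'
#' @param mirna miRNA sequence.
#' @param transcript transcript sequence (forward strand).
#' @param scoring a [scoringScheme()].
#' @return list with `alignment` (a [LocalAlignmentResult] against the
#'   reverse complement) and `transcriptSpan` (1-based inclusive
#'   forward-strand coordinates of the aligned window, `NA` if empty).
#' @export
sinkScan <- function(mirna, transcript, scoring = scoringScheme()) {
  mirna <- checkAlnSeq(mirna, "mirna")
  transcript <- checkAlnSeq(transcript, "transcript")
  rc <- revcomp(transcript)
  res <- smithWaterman(mirna, rc, scoring)
  L <- nchar(transcript)
  span <- if (res@alignedColumns == 0L) c(NA_integer_, NA_integer_)
          else unname(c(L - res@bSpan[2L] + 1L, L - res@bSpan[1L] + 1L))
  list(alignment = res, transcriptSpan = span)
}

#' All-pairs local-alignment identity report
#'
#' Runs [smithWaterman()] for every query x target pair and tabulates percent
#' identity in the \dQuote{X% (n of m nt)} shape used for miRNA sink
#' comparisons.
#'
#' @param queries,targets named character vectors (or lists of
#'   `CodingSequence`s) of sequences.
#' @param scoring a [scoringScheme()].
#' @param revcompTargets align against reverse-complemented targets
#'   (sink-scan orientation).
#' @return data.frame with `query`, `target`, `score`, `percent_identity`,
#'   `identical`, `aligned`, `label`.
#' @export
pairwiseIdentityReport <- function(queries, targets, scoring = scoringScheme(),
                                   revcompTargets = FALSE) {
  asNamed <- function(x, what) {
    if (is.list(x) && all(vapply(x, is, logical(1L), "CodingSequence"))) {
      v <- vapply(x, seqString, character(1L))
      names(v) <- vapply(x, seqId, character(1L))
      return(v)
    }
    v <- vapply(x, as.character, character(1L))
    if (is.null(names(v)) || any(!nzchar(names(v))))
      names(v) <- paste0(what, seq_along(v))
    v
  }
  q <- asNamed(queries, "query"); t <- asNamed(targets, "target")
  rows <- vector("list", length(q) * length(t))
  k <- 0L
  for (qi in seq_along(q)) for (ti in seq_along(t)) {
    tt <- if (revcompTargets) revcomp(t[ti]) else t[ti]
    r <- smithWaterman(q[qi], tt, scoring)
    k <- k + 1L
    rows[[k]] <- data.frame(query = names(q)[qi], target = names(t)[ti],
                            score = r@score,
                            percent_identity = r@percentIdentity,
                            identical = r@identicalColumns,
                            aligned = r@alignedColumns,
                            label = identityLabel(r),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
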
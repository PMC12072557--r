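#' Read and write tissue expression matrices (TPM) as TSV
#'
#' On-disk layout: tab-delimited, first header row `gene` followed by sample
#' ids, second header row `tissue` followed by the tissue label of each
#' sample, then one row per gene of non-negative TPM values.
#'
#' @param path TSV file.
#' @return `readExpressionTsv`: a
#'   [SummarizedExperiment::SummarizedExperiment] with assay `"tpm"` and a
#'   `tissue` column in `colData`.
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @export
readExpressionTsv <- function(path) {
  if (!file.exists(path)) stop("expression TSV not found: ", path)
  lines <- readLines(path, n = 2L)
  h1 <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  h2 <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (h1[1L] != "gene" || h2[1L] != "tissue")
    stop("expected header rows starting with 'gene' and 'tissue' in ", path)
  if (length(h1) != length(h2))
    stop("sample and tissue header rows differ in length in ", path)
  df <- utils::read.delim(path, skip = 2L, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  genes <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (ncol(vals) != length(h1) - 1L)
    stop("data columns do not match header in ", path)
  dimnames(vals) <- list(genes, h1[-1L])
  if (any(vals < 0)) stop("negative expression values in ", path)
  if (any(!nzchar(h2[-1L]))) stop("empty tissue labels in ", path)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = vals),
    colData = S4Vectors::DataFrame(tissue = h2[-1L], row.names = h1[-1L]))
}

#' @param se a `SummarizedExperiment` with assay `tpm` and `colData$tissue`.
#' @rdname readExpressionTsv
#' @export
writeExpressionTsv <- function(se, path) {
  vals <- SummarizedExperiment::assay(se, "tpm")
  tissue <- SummarizedExperiment::colData(se)$tissue
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(vals)), collapse = "\t"), con)
  writeLines(paste(c("tissue", tissue), collapse = "\t"), con)
  utils::write.table(data.frame(rownames(vals), vals, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Collapse an expression matrix to per-tissue means
#'
#' Averages samples within each tissue (one value per tissue, matching
#' one-point-per-tissue correlation plots) after dropping excluded tissues
#' (e.g. cultured-cell pseudo-tissues).
#'
#' @param se a `SummarizedExperiment` from [readExpressionTsv()] /
#'   [simulateExpression()], or a genes x samples matrix plus `tissues`.
#' @param exclude tissue labels to drop; unknown labels warn and are ignored.
#' @param tissues tissue label per column when `se` is a plain matrix.
#' @return genes x tissues matrix of mean TPM.
#' @export
aggregateByTissue <- function(se, exclude = character(), tissues = NULL) {
  if (is(se, "SummarizedExperiment")) {
    vals <- SummarizedExperiment::assay(se, "tpm")
    tissues <- as.character(SummarizedExperiment::colData(se)$tissue)
  } else {
    vals <- as.matrix(se)
    if (is.null(tissues)) stop("'tissues' required for a plain matrix")
  }
  unknown <- setdiff(exclude, tissues)
  if (length(unknown))
    warning("excluded tissue(s) not present: ", paste(unknown, collapse = ", "))
  keep <- !(tissues %in% exclude)
  if (!any(keep)) stop("all tissues excluded: empty result")
  vals <- vals[, keep, drop = FALSE]
  tissues <- tissues[keep]
  levs <- unique(tissues)
  out <- vapply(levs, function(tl)
    rowMeans(vals[, tissues == tl, drop = FALSE]), numeric(nrow(vals)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                       dimnames = list(rownames(vals), levs))
  out
}

permutationsOf <- function(n) {
  ## n! x n matrix of all permutations of 1..n (insertion construction)
  p <- matrix(1L, 1L, 1L)
  if (n == 1L) return(p)
  for (k in 2L:n) {
    old <- p
    blocks <- lapply(seq_len(k), function(pos) {
      left <- old[, seq_len(pos - 1L), drop = FALSE]
      right <- if (pos <= k - 1L) old[, pos:(k - 1L), drop = FALSE]
      cbind(left, k, right)
    })
    p <- do.call(rbind, blocks)
  }
  unname(p)
}

#' Spearman rank correlation with exact or t-approximate p-value
#'
#' Computes rho on mid-ranks.  Two-sided p-value: for `n < 10` by exhaustive
#' enumeration of all `n!` rank permutations (exact, valid with ties); for
#' `n >= 10` by the t approximation `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @param method `"auto"` (size-based switch), `"exact"`, or `"approx"`.
#' @return list with `r`, `p`, `n`, `method`.
#' @examples
#' spearmanCor(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearmanCor <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need n >= 3 points")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant vector: Spearman rho undefined")
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (method == "auto") method <- if (n < 10L) "exact" else "approx"
  if (method == "exact") {
    if (n > 9L) stop("exact permutation p limited to n <= 9")
    perms <- permutationsOf(n)
    ## rho is affine in S = sum_i rx[perm[i]] * ry[i] for fixed rank multisets
    rxp <- matrix(rx[perms], nrow(perms), n)
    S <- as.vector(rxp %*% ry)
    mx <- mean(rx); my <- mean(ry)
    denom <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
    rPerm <- (S - n * mx * my) / denom
    p <- mean(abs(rPerm) >= abs(r) - 1e-12)
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  list(r = r, p = p, n = n, method = method)
}

#' Screen all gene pairs for expression correlation
#'
#' Spearman correlation for every unordered pair of the requested genes
#' across tissue-level expression values, with raw and
#' Benjamini-Hochberg-adjusted p-values and significance flags.
#'
#' @param m genes x tissues matrix (e.g. from [aggregateByTissue()]) or a
#'   `SummarizedExperiment` (then collapsed by tissue first).
#' @param genes gene ids to screen (default: all rows).
#' @param alpha significance threshold on the raw p (default 0.05).
#' @param trendAlpha trend threshold (default 0.1): pairs with
#'   `alpha <= p < trendAlpha` are flagged `"trend"`.
#' @param exclude tissue labels to drop when `m` is a `SummarizedExperiment`.
#' @return data.frame with `gene_a`, `gene_b`, `r`, `p`, `p_bh`, `n`, `flag`.
#' @export
correlationScreen <- function(m, genes = NULL, alpha = 0.05, trendAlpha = 0.1,
                              exclude = character()) {
  if (is(m, "SummarizedExperiment")) m <- aggregateByTissue(m, exclude)
  m <- as.matrix(m)
  if (is.null(genes)) genes <- rownames(m)
  miss <- setdiff(genes, rownames(m))
  if (length(miss)) stop("gene(s) not present: ", paste(miss, collapse = ", "))
  if (length(genes) < 2L) stop("need at least two genes")
  pairs <- utils::combn(genes, 2L)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    ga <- pairs[1L, k]; gb <- pairs[2L, k]
    sc <- spearmanCor(m[ga, ], m[gb, ])
    rows[[k]] <- data.frame(gene_a = ga, gene_b = gb, r = sc$r, p = sc$p,
                            n = sc$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$flag <- ifelse(out$p < alpha, "significant",
                     ifelse(out$p < trendAlpha, "trend", "none"))
  out[, c("gene_a", "gene_b", "r", "p", "p_bh", "n", "flag")]
}
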
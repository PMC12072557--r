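## Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
## caller's RNG afterwards.  All generators take explicit seeds; none leaks
## global state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(apply(expand.grid(DNA_BASES4, DNA_BASES4, DNA_BASES4),
                              1L, paste, collapse = ""), STOP_CODONS)

#' Simulate a random root coding sequence
#'
#' Random CDS starting with ATG, ending with a stop codon, with no internal
#' stop codons.  `lengthCodons = 559` mirrors the scale of the GDH precursor
#' (558 residues plus stop).
#'
#' @param lengthCodons total codon count including start and stop (>= 2).
#' @param seed integer seed; a fixed seed gives identical output.
#' @return a [CodingSequence].
#' @export
simulateRootCds <- function(lengthCodons, seed = 1L) {
  lengthCodons <- as.integer(lengthCodons)
  if (lengthCodons < 2L) stop("need at least 2 codons (start + stop)")
  codons <- withSeed(seed, {
    mid <- if (lengthCodons > 2L)
      sample(SENSE_CODONS, lengthCodons - 2L, replace = TRUE) else character()
    c("ATG", mid, sample(STOP_CODONS, 1L))
  })
  CodingSequence(sprintf("root_cds_%d", seed), paste(codons, collapse = ""),
                 isCds = TRUE, source = "simulateRootCds")
}

#' Evolve a coding sequence along a tree under K2P
#'
#' Sites evolve independently; on each branch the new base is drawn from the
#' K2P transition probabilities [k2pProb()] for that branch length
#' (substitutions/site).  True internal-node sequences are retained so
#' ancestral-reconstruction accuracy can be scored against ground truth.
#'
#' @param root root [CodingSequence].
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @param kappa transition/transversion rate ratio.
#' @param seed integer seed.
#' @return list with `leaves` and `internals` (named character vectors of
#'   sequences; internal names are node labels or `node<k>`, the root being
#'   node `ntip+1`).
#' @export
evolveOnTree <- function(root, tree, kappa = 2, seed = 1L) {
  stopifnot(is(root, "CodingSequence"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label) && all(nzchar(tree$node.label)))
                tree$node.label else paste0("node", (ntip + 1L):nnode))
  seqIdx <- vector("list", nnode)
  rootChars <- match(strsplit(seqString(root), "")[[1L]], DNA_BASES4)
  if (anyNA(rootChars)) stop("root sequence must be over {A,C,G,T}")
  rootNode <- ntip + 1L
  seqIdx[[rootNode]] <- rootChars
  po <- ape::reorder.phylo(tree, "postorder")
  edgeOrder <- rev(seq_len(nrow(po$edge)))   # pre-order: parent before child
  withSeed(seed, {
    for (k in edgeOrder) {
      par <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
      P <- k2pProb(po$edge.length[k], kappa)
      cur <- seqIdx[[par]]
      nw <- integer(length(cur))
      u <- stats::runif(length(cur))
      for (b in 1:4) {
        idx <- which(cur == b)
        if (!length(idx)) next
        cp <- cumsum(P[b, ])
        nw[idx] <- findInterval(u[idx], cp, left.open = TRUE) + 1L
      }
      seqIdx[[ch]] <- nw
    }
  })
  toSeq <- function(v) paste(DNA_BASES4[v], collapse = "")
  leaves <- vapply(seq_len(ntip), function(i) toSeq(seqIdx[[i]]), character(1L))
  names(leaves) <- labels[seq_len(ntip)]
  internals <- vapply((ntip + 1L):nnode, function(i) toSeq(seqIdx[[i]]),
                      character(1L))
  names(internals) <- labels[(ntip + 1L):nnode]
  list(leaves = leaves, internals = internals)
}

#' Superimpose post-mortem deamination damage on a sequence
#'
#' Each `A`/`T` site is independently flipped to `G`/`C` with probability
#' `ts1Rate` (adenine-deamination class) and each `C`/`G` site to `T`/`A`
#' with probability `ts2Rate` (cytosine-deamination class).  Every simulated
#' event is a transition that [classifyTransition()] maps back to its own
#' class deterministically.  Damage is applied to terminal (sampled)
#' sequences only, reflecting its post-mortem origin.
#'
#' @param cds a [CodingSequence].
#' @param ts1Rate,ts2Rate per-site damage probabilities in `[0, 1)`... 1 is
#'   accepted for forced-damage tests.
#' @param seed integer seed.
#' @return list with `cds` (damaged copy) and `truth` (data.frame of
#'   `cds_pos`, `ref_base`, `alt_base`, `type`).
#' @export
applyDamage <- function(cds, ts1Rate, ts2Rate, seed = 1L) {
  stopifnot(is(cds, "CodingSequence"))
  if (ts1Rate < 0 || ts1Rate > 1 || ts2Rate < 0 || ts2Rate > 1)
    stop("rates must be in [0, 1]")
  chars <- strsplit(seqString(cds), "")[[1L]]
  u <- withSeed(seed, stats::runif(length(chars)))
  ts1Map <- c(A = "G", T = "C")
  ts2Map <- c(C = "T", G = "A")
  hit1 <- chars %in% names(ts1Map) & u < ts1Rate
  hit2 <- chars %in% names(ts2Map) & u < ts2Rate
  pos <- sort(c(which(hit1), which(hit2)))
  truth <- data.frame(cds_pos = pos, ref_base = chars[pos],
                      alt_base = ifelse(chars[pos] %in% names(ts1Map),
                                        ts1Map[chars[pos]], ts2Map[chars[pos]]),
                      type = ifelse(chars[pos] %in% names(ts1Map), "TS1", "TS2"),
                      stringsAsFactors = FALSE)
  chars[pos] <- truth$alt_base
  list(cds = CodingSequence(paste0(seqId(cds), "_damaged"),
                            paste(chars, collapse = ""), isCds = isCds(cds),
                            source = sprintf("applyDamage(ts1=%g, ts2=%g, seed=%d)",
                                             ts1Rate, ts2Rate, as.integer(seed))),
       truth = truth)
}

#' Simulate a tissue expression matrix with a target Spearman structure
#'
#' Gaussian-copula draws: latent multivariate normals with Pearson
#' correlation `2 sin(pi rho / 6)` (so the Spearman correlation of the copula
#' matches the target) are transformed to log-normal TPM-like values.
#' Empirical Spearman correlations fall within about 0.15 of the target for
#' `nTissues >= 30`.
#'
#' @param nTissues number of tissues.
#' @param rho target Spearman correlation matrix among genes (symmetric,
#'   positive semidefinite, unit diagonal); gene names taken from its
#'   dimnames.
#' @param seed integer seed.
#' @param nReplicates samples per tissue (independent draws sharing the
#'   tissue label).
#' @param meanlog,sdlog log-normal marginal parameters.
#' @return a `SummarizedExperiment` with assay `tpm` and `colData$tissue`.
#' @export
simulateExpression <- function(nTissues, rho, seed = 1L, nReplicates = 1L,
                               meanlog = 2, sdlog = 1) {
  rho <- as.matrix(rho)
  g <- nrow(rho)
  if (g != ncol(rho) || max(abs(rho - t(rho))) > 1e-8)
    stop("rho must be a symmetric matrix")
  if (any(abs(diag(rho) - 1) > 1e-8)) stop("rho must have unit diagonal")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("rho must be positive semidefinite")
  genes <- rownames(rho)
  if (is.null(genes)) genes <- paste0("gene", seq_len(g))
  pearson <- 2 * sin(pi * rho / 6)
  diag(pearson) <- 1
  ## guard against tiny PSD violations from the transform
  ev2 <- eigen(pearson, symmetric = TRUE)
  ev2$values[ev2$values < 0] <- 0
  pearson <- ev2$vectors %*% diag(ev2$values, g) %*% t(ev2$vectors)
  nSamp <- as.integer(nTissues) * as.integer(nReplicates)
  z <- withSeed(seed, MASS::mvrnorm(nSamp, mu = rep(0, g), Sigma = pearson))
  vals <- t(stats::qlnorm(stats::pnorm(z), meanlog = meanlog, sdlog = sdlog))
  tissue <- rep(sprintf("Tissue%02d", seq_len(nTissues)),
                each = as.integer(nReplicates))
  dimnames(vals) <- list(genes,
                         sprintf("S%03d", seq_len(nSamp)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = vals),
    colData = S4Vectors::DataFrame(tissue = tissue, row.names = colnames(vals)))
}

#' Simulate a transcript with an embedded miRNA sink site
#'
#' Generates a random miRNA and a random transcript carrying one perfectly
#' complementary window (the reverse complement of the miRNA), recording the
#' ground-truth forward-strand coordinates of the embedded site.
#'
#' @param seed integer seed.
#' @param mirnaLength miRNA length (default 22 nt).
#' @param transcriptLength transcript length.
#' @param siteStart start of the embedded site (default: random).
#' @return list with `mirna`, `transcript`, `siteStart`, `siteEnd`.
#' @export
simulateMirnaTarget <- function(seed = 1L, mirnaLength = 22L,
                                transcriptLength = 500L, siteStart = NULL) {
  stopifnot(mirnaLength >= 5L, transcriptLength >= mirnaLength)
  withSeed(seed, {
    mirna <- paste(sample(DNA_BASES4, mirnaLength, replace = TRUE),
                   collapse = "")
    tx <- sample(DNA_BASES4, transcriptLength, replace = TRUE)
    if (is.null(siteStart))
      siteStart <- sample.int(transcriptLength - mirnaLength + 1L, 1L)
    site <- strsplit(revcomp(mirna), "")[[1L]]
    tx[siteStart:(siteStart + mirnaLength - 1L)] <- site
    list(mirna = mirna, transcript = paste(tx, collapse = ""),
         siteStart = as.integer(siteStart),
         siteEnd = as.integer(siteStart + mirnaLength - 1L))
  })
}
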
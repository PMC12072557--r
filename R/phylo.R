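## Alignments are passed around as named character vectors of equal-length
## strings over {A,C,G,T,N} (pre-aligned CDSs; no MSA is performed here).

alnToMatrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- toupper(aln)
  } else if (is.list(aln) && all(vapply(aln, is, logical(1L), "CodingSequence"))) {
    seqs <- vapply(aln, seqString, character(1L))
    names(seqs) <- vapply(aln, seqId, character(1L))
    return(alnToMatrix(seqs))
  } else {
    aln <- vapply(aln, as.character, character(1L))
    lens <- nchar(aln)
    if (length(unique(lens)) != 1L)
      stop("alignment rows have unequal lengths")
    m <- do.call(rbind, strsplit(toupper(aln), ""))
    rownames(m) <- names(aln)
  }
  if (nrow(m) < 2L) stop("alignment needs >= 2 rows")
  if (is.null(rownames(m)) || any(!nzchar(rownames(m))))
    stop("alignment rows must be named")
  bad <- setdiff(unique(as.vector(m)), DNA_ALPHABET5)
  if (length(bad))
    stop("alignment contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ","))
  m
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` and `Q` the
#' transition and transversion proportions over the sites where both
#' sequences carry an unambiguous base (pairwise deletion of `N`).
#'
#' @param a,b equal-length sequences (strings or `CodingSequence`s).
#' @return distance in substitutions/site, with attributes `P`, `Q`, `n_sites`.
#'   Saturated pairs (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) are an error.
#' @examples
#' k2pDistance("ACGTACGTAC", "ACGTACGTAC")  # 0
#' @export
k2pDistance <- function(a, b) {
  if (is(a, "CodingSequence")) a <- seqString(a)
  if (is(b, "CodingSequence")) b <- seqString(b)
  if (nchar(a) != nchar(b)) stop("sequences have different lengths")
  x <- strsplit(toupper(a), "")[[1L]]
  y <- strsplit(toupper(b), "")[[1L]]
  ok <- x %in% DNA_BASES4 & y %in% DNA_BASES4
  n <- sum(ok)
  if (n == 0L) stop("no unambiguous sites in common")
  x <- x[ok]; y <- y[ok]
  diff <- x != y
  pair <- paste0(x[diff], y[diff])
  ts <- pair %in% c("AG", "GA", "CT", "TC")
  P <- sum(ts) / n
  Q <- sum(!ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance undefined (saturation): 1-2P-Q = ", signif(w1, 3),
         ", 1-2Q = ", signif(w2, 3))
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  structure(d, P = P, Q = Q, n_sites = n)
}

#' @param aln alignment (named character vector, character matrix, or list of
#'   `CodingSequence`s).
#' @rdname k2pDistance
#' @export
k2pDistanceMatrix <- function(aln) {
  m <- alnToMatrix(aln)
  n <- nrow(m)
  seqs <- apply(m, 1L, paste, collapse = "")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- as.numeric(k2pDistance(seqs[i], seqs[j]))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q criterion; consistent on
#' additive distances (recovers the generating topology and branch lengths
#' exactly).  Negative estimated branch lengths are clamped to zero.  The
#' returned tree is unrooted (stored with a basal trifurcation).
#'
#' @param D symmetric distance matrix with zero diagonal and >= 3 labelled taxa.
#' @return an unrooted `ape::phylo` tree.
#' @export
njTree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("need >= 3 taxa")
  if (is.null(rownames(D))) stop("distance matrix must carry taxon labels")
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal")
  labels <- rownames(D)
  if (any(grepl("[(),:;]", labels)))
    stop("taxon labels may not contain newick metacharacters")
  nodes <- labels          # newick fragment per active cluster
  repeat {
    k <- length(nodes)
    if (k == 3L) break
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1L, ]
    i <- min(ij); j <- max(ij)
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    newNode <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], li, nodes[j], lj)
    dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
                c(dNew[keep], 0))
    nodes <- c(nodes[keep], newNode)
    D <- D2
  }
  ## three-point closed form for the final join
  la <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  lb <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  lc <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[1], la, nodes[2], lb, nodes[3], lc)
  ape::read.tree(text = nwk)
}

## canonical keys for the non-trivial bipartitions (internal edges) of a tree
treeBipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  refTip <- sort(tree$tip.label)[1L]
  keys <- character(); nodeIds <- integer()
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  for (v in internal) {
    tips <- tipsBelow(tree, v)
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    side <- if (refTip %in% tips) setdiff(tree$tip.label, tips) else tips
    if (length(side) < 2L || length(side) > ntip - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodeIds <- c(nodeIds, v)
  }
  data.frame(node = nodeIds, key = keys, stringsAsFactors = FALSE)
}

tipsBelow <- function(tree, node) {
  ntip <- length(tree$tip.label)
  stack <- node; tips <- integer()
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= ntip) tips <- c(tips, v)
    else stack <- c(stack, tree$edge[tree$edge[, 1L] == v, 2L])
  }
  tree$tip.label[tips]
}

#' Nonparametric bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ tree
#' for each replicate, and reports the percentage of replicates containing
#' each internal bipartition of the tree built from the full alignment.
#' Replicate `r` uses `seed + r`, so runs are reproducible for a fixed seed.
#'
#' @param aln alignment (see [k2pDistanceMatrix()]).
#' @param nReps number of bootstrap replicates (>= 1).
#' @param seed integer base seed.
#' @return the full-alignment NJ tree with supports (in `[0,100]`) written to
#'   `node.label` and a `supports` attribute (data.frame of bipartition keys).
#'   An alignment with no variable sites yields a `degenerate = TRUE`
#'   attribute and a warning.
#' @export
bootstrapSupport <- function(aln, nReps, seed = 1L) {
  stopifnot(nReps >= 1L)
  m <- alnToMatrix(aln)
  S <- ncol(m)
  variable <- any(apply(m, 2L, function(col) {
    b <- unique(col[col %in% DNA_BASES4]); length(b) > 1L
  }))
  tree <- njTree(k2pDistanceMatrix(m))
  bip <- treeBipartitions(tree)
  hits <- setNames(numeric(nrow(bip)), bip$key)
  done <- 0L
  for (r in seq_len(nReps)) {
    cols <- withSeed(seed + r, sample.int(S, S, replace = TRUE))
    bt <- tryCatch(njTree(k2pDistanceMatrix(m[, cols, drop = FALSE])),
                   error = function(e) NULL)
    if (is.null(bt)) next   # e.g. saturated replicate
    done <- done + 1L
    bk <- treeBipartitions(bt)$key
    hits[bip$key %in% bk] <- hits[bip$key %in% bk] + 1
  }
  support <- if (done > 0L) 100 * hits / done else hits * NA_real_
  ntip <- length(tree$tip.label)
  lab <- rep("", tree$Nnode)
  lab[bip$node - ntip] <- sprintf("%g", round(support, 1))
  tree$node.label <- lab
  attr(tree, "supports") <- data.frame(bipartition = bip$key,
                                       support = unname(support),
                                       stringsAsFactors = FALSE)
  attr(tree, "n_replicates_used") <- done
  if (!variable) {
    warning("alignment has no variable sites: topology is arbitrary (degenerate)")
    attr(tree, "degenerate") <- TRUE
  }
  tree
}

#' K2P transition-probability matrix
#'
#' Probability matrix `P(t)` of the Kimura 2-parameter model with
#' transition/transversion rate ratio `kappa` and equal base frequencies,
#' normalized so branch lengths are in expected substitutions per site.
#' Base order `A,C,G,T`.  Rows sum to 1 and `P(0)` is the identity.
#'
#' @param t branch length (substitutions/site, >= 0).
#' @param kappa transition/transversion rate ratio (> 0).
#' @return 4x4 matrix with dimnames `A,C,G,T`.
#' @export
k2pProb <- function(t, kappa) {
  if (t < 0) stop("branch length must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  same <- 0.25 + 0.25 * e1 + 0.5 * e2
  ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  tv <- 0.25 - 0.25 * e1
  P <- matrix(tv, 4L, 4L, dimnames = list(DNA_BASES4, DNA_BASES4))
  diag(P) <- same
  P["A", "G"] <- P["G", "A"] <- P["C", "T"] <- P["T", "C"] <- ts
  P
}

## tip partial-likelihood matrices (4 x S); N (or any ambiguity) = all ones
tipPartials <- function(m) {
  S <- ncol(m)
  lapply(seq_len(nrow(m)), function(i) {
    L <- matrix(0, 4L, S, dimnames = list(DNA_BASES4, NULL))
    for (b in DNA_BASES4) L[b, m[i, ] == b] <- 1
    L[, !(m[i, ] %in% DNA_BASES4)] <- 1
    L
  })
}

## inside (Felsenstein) pass; returns per-node partials, per-edge child
## contributions P(t) %*% L_child, and per-site log scaling at each node
insidePass <- function(tree, m, kappa) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  S <- ncol(m)
  ord <- match(tree$tip.label, rownames(m))
  if (anyNA(ord)) stop("alignment rows do not match tree tip labels")
  tp <- tipPartials(m[ord, , drop = FALSE])
  partial <- vector("list", nnode)
  logScale <- matrix(0, nnode, S)
  for (i in seq_len(ntip)) partial[[i]] <- tp[[i]]
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  po <- ape::reorder.phylo(tree, "postorder")
  edgeDown <- vector("list", nrow(po$edge))
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    P <- k2pProb(po$edge.length[k], kappa)
    edgeDown[[k]] <- P %*% partial[[ch]]
    if (is.null(partial[[par]])) {
      partial[[par]] <- edgeDown[[k]]
      logScale[par, ] <- logScale[ch, ]
    } else {
      partial[[par]] <- partial[[par]] * edgeDown[[k]]
      logScale[par, ] <- logScale[par, ] + logScale[ch, ]
    }
    if (max(which(po$edge[, 1L] == par)) == k) {
      ## all children of `par` folded in: rescale
      sc <- apply(partial[[par]], 2L, max)
      sc[sc == 0] <- 1
      partial[[par]] <- sweep(partial[[par]], 2L, sc, "/")
      logScale[par, ] <- logScale[par, ] + log(sc)
    }
  }
  root <- po$edge[nrow(po$edge), 1L]
  list(partial = partial, logScale = logScale, root = root, po = po,
       edgeDown = edgeDown)
}

#' Log-likelihood of an alignment on a tree under K2P (pruning algorithm)
#'
#' Felsenstein's post-order pruning with K2P transition probabilities, uniform
#' 1/4 root frequencies and per-site rescaling.  `N` is treated as fully
#' missing (partial vector of ones).
#'
#' @param tree an `ape::phylo` with non-negative branch lengths (rooted or
#'   unrooted).
#' @param aln alignment whose row names match the tip labels.
#' @param kappa transition/transversion rate ratio.
#' @return total log-likelihood (numeric scalar).
#' @export
pruningLoglik <- function(tree, aln, kappa = 2) {
  m <- alnToMatrix(aln)
  ins <- insidePass(tree, m, kappa)
  site <- log(colSums(ins$partial[[ins$root]] * 0.25)) + ins$logScale[ins$root, ]
  sum(site)
}

#' Root a tree on a named outgroup leaf
#'
#' Roots the tree on the edge leading to `outgroup`, placing the root at the
#' midpoint of that edge.
#'
#' @param tree an `ape::phylo`.
#' @param outgroup tip label to root on.
#' @return a rooted `ape::phylo`.
#' @export
rootAtOutgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  r <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ## split the outgroup edge at its midpoint
  tipId <- which(r$tip.label == outgroup)
  rootId <- length(r$tip.label) + 1L
  eOut <- which(r$edge[, 1L] == rootId & r$edge[, 2L] == tipId)
  eIn <- which(r$edge[, 1L] == rootId & r$edge[, 2L] != tipId)
  if (length(eOut) == 1L && length(eIn) == 1L) {
    tot <- r$edge.length[eOut] + r$edge.length[eIn]
    r$edge.length[eOut] <- tot / 2
    r$edge.length[eIn] <- tot / 2
  }
  r
}

#' Marginal maximum-likelihood ancestral sequence reconstruction
#'
#' For every internal node and site, combines the inside (subtree) and outside
#' (rest-of-tree) partial likelihoods under K2P into the marginal posterior
#' over `{A,C,G,T}`, integrating over the states of all other nodes.  The
#' reported state is the posterior argmax; exact ties are broken
#' alphabetically and flagged.
#'
#' @param tree a rooted `ape::phylo` (root on an outgroup via
#'   [rootAtOutgroup()]); an unrooted tree is an error.
#' @param aln alignment whose row names match the tip labels.
#' @param kappa transition/transversion rate ratio.
#' @return list with `states` (named character vector of internal-node
#'   sequences; the root is node `ntip+1`), `posterior` (list of 4 x S
#'   matrices per internal node), `ties` (logical matrix nodes x sites) and
#'   `loglik`.
#' @export
ancestralStates <- function(tree, aln, kappa = 2) {
  if (!ape::is.rooted(tree))
    stop("tree must be rooted (use rootAtOutgroup())")
  m <- alnToMatrix(aln)
  S <- ncol(m)
  ntip <- length(tree$tip.label)
  ins <- insidePass(tree, m, kappa)
  po <- ins$po
  nnode <- ntip + tree$Nnode
  outside <- vector("list", nnode)
  outside[[ins$root]] <- matrix(0.25, 4L, S, dimnames = list(DNA_BASES4, NULL))
  ## pre-order: walk edges in reverse postorder; P is symmetric so the same
  ## matrix propagates messages both ways
  for (k in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    sibEdges <- setdiff(which(po$edge[, 1L] == par), k)
    msg <- outside[[par]]
    for (sk in sibEdges) msg <- msg * ins$edgeDown[[sk]]
    P <- k2pProb(po$edge.length[k], kappa)
    out <- P %*% msg
    sc <- apply(out, 2L, max); sc[sc == 0] <- 1
    outside[[ch]] <- sweep(out, 2L, sc, "/")
  }
  internals <- (ntip + 1L):nnode
  labels <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label)))
    tree$node.label else paste0("node", internals)
  states <- character(length(internals))
  posterior <- vector("list", length(internals))
  ties <- matrix(FALSE, length(internals), S)
  for (i in seq_along(internals)) {
    v <- internals[i]
    post <- ins$partial[[v]] * outside[[v]]
    post <- sweep(post, 2L, colSums(post), "/")
    posterior[[i]] <- post
    idx <- apply(post, 2L, which.max)
    mx <- post[cbind(idx, seq_len(S))]
    nmax <- colSums(abs(sweep(post, 2L, mx, "-")) < 1e-12)
    ties[i, ] <- nmax > 1L
    states[i] <- paste(DNA_BASES4[idx], collapse = "")
  }
  names(states) <- labels
  names(posterior) <- labels
  rownames(ties) <- labels
  list(states = states, posterior = posterior, ties = ties,
       loglik = sum(log(colSums(ins$partial[[ins$root]] * 0.25)) +
                      ins$logScale[ins$root, ]))
}

#' Maximum-likelihood estimate of the K2P kappa on a fixed tree
#'
#' Maximizes [pruningLoglik()] over `kappa` by bounded one-dimensional search
#' (tolerance 1e-4).  An alignment with no variable sites returns the default
#' `kappa = 2` with a warning; an estimate at the upper search bound (e.g. no
#' transversions observed) is flagged via the `boundary` attribute and a
#' warning.
#'
#' @param aln alignment.
#' @param tree tree with branch lengths.
#' @param interval search interval for kappa.
#' @return estimated kappa with attributes `loglik` and `boundary`.
#' @export
estimateKappa <- function(aln, tree, interval = c(0.05, 100)) {
  m <- alnToMatrix(aln)
  variable <- any(apply(m, 2L, function(col) {
    b <- unique(col[col %in% DNA_BASES4]); length(b) > 1L
  }))
  if (!variable) {
    warning("alignment has no variable sites; returning default kappa = 2")
    return(structure(2, loglik = pruningLoglik(tree, m, 2), boundary = FALSE))
  }
  opt <- stats::optimize(function(k) pruningLoglik(tree, m, k),
                         interval = interval, maximum = TRUE, tol = 1e-4)
  boundary <- opt$maximum > 0.98 * interval[2L]
  if (boundary)
    warning("kappa estimate at the upper search bound (no transversion signal?)")
  structure(opt$maximum, loglik = opt$objective, boundary = boundary)
}
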
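## Independent oracles used by the tests.  Everything here is deliberately
## written with different algorithms from the package implementation.

oracleBases <- c("A", "C", "G", "T")

## ---- alignment oracles -----------------------------------------------------

oracleSubScore <- function(x, y, sc)
  if (x == y && x != "N") sc$match else sc$mismatch

## exhaustive enumeration of every gapped global alignment (affine scoring
## read off the alignment itself); exponential, for very short strings only
enumGlobalScore <- function(a, b, sc) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, oracleSubScore(av[i], bv[j], sc) + rec(i + 1L, j + 1L, "M"))
    if (i <= n) {
      open <- if (last == "X") 0 else sc$gapOpen
      best <- max(best, open + sc$gapExtend + rec(i + 1L, j, "X"))
    }
    if (j <= m) {
      open <- if (last == "Y") 0 else sc$gapOpen
      best <- max(best, open + sc$gapExtend + rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(1L, 1L, "S")
}

## iterative global Gotoh (needleman-wunsch with affine gaps)
globalAffineScore <- function(a, b, sc) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  if (n == 0L && m == 0L) return(0)
  NEG <- -Inf
  M <- matrix(NEG, n + 1L, m + 1L); X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n) + 1L) X[i, 1L] <- sc$gapOpen + (i - 1L) * sc$gapExtend
  for (j in seq_len(m) + 1L) Y[1L, j] <- sc$gapOpen + (j - 1L) * sc$gapExtend
  for (i in seq_len(n) + 1L) for (j in seq_len(m) + 1L) {
    s <- oracleSubScore(av[i - 1L], bv[j - 1L], sc)
    M[i, j] <- s + max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
    X[i, j] <- max(M[i - 1L, j] + sc$gapOpen + sc$gapExtend,
                   X[i - 1L, j] + sc$gapExtend)
    Y[i, j] <- max(M[i, j - 1L] + sc$gapOpen + sc$gapExtend,
                   Y[i, j - 1L] + sc$gapExtend)
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

## best local score = max over all substring pairs of the global score
oracleLocalScore <- function(a, b, sc) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  best <- 0
  for (i1 in seq_len(n)) for (i2 in i1:n)
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      s <- globalAffineScore(paste(av[i1:i2], collapse = ""),
                             paste(bv[j1:j2], collapse = ""), sc)
      if (s > best) best <- s
    }
  best
}

randomSeq <- function(len, alphabet = oracleBases)
  paste(sample(alphabet, len, replace = TRUE), collapse = "")

## ---- K2P / tree oracles ----------------------------------------------------

## transition-probability matrix by actual matrix exponentiation of the
## normalized K2P rate matrix (eigen decomposition), independent of the
## closed form used in the package
oracleK2pProb <- function(t, kappa) {
  beta <- 1 / (kappa + 2); alpha <- kappa * beta
  Q <- matrix(beta, 4L, 4L, dimnames = list(oracleBases, oracleBases))
  Q["A", "G"] <- Q["G", "A"] <- Q["C", "T"] <- Q["T", "C"] <- alpha
  diag(Q) <- 0; diag(Q) <- -rowSums(Q)
  e <- eigen(Q)
  P <- e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors)
  dimnames(P) <- dimnames(Q)
  P
}

## brute-force tree likelihood: explicit sum over every assignment of states
## to internal nodes (and to tips carrying N)
enumSiteLik <- function(tree, states, kappa) {
  ## states: character vector indexed by node id (tips filled, internals NA)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  allowed <- lapply(seq_len(nnode), function(v) {
    if (v <= ntip && states[v] %in% oracleBases) states[v] else oracleBases
  })
  free <- which(vapply(allowed, length, integer(1L)) > 1L)
  Pm <- lapply(seq_len(nrow(tree$edge)),
               function(k) oracleK2pProb(tree$edge.length[k], kappa))
  root <- ntip + 1L
  grid <- do.call(expand.grid, c(allowed[free], stringsAsFactors = FALSE))
  tot <- 0
  assign <- vapply(allowed, `[`, character(1L), 1L)
  for (g in seq_len(max(nrow(grid), 1L))) {
    if (length(free)) assign[free] <- unlist(grid[g, ], use.names = FALSE)
    lik <- 0.25
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
      lik <- lik * Pm[[k]][assign[p], assign[ch]]
    }
    tot <- tot + lik
  }
  tot
}

enumTreeLoglik <- function(tree, alnMat, kappa) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  total <- 0
  for (s in seq_len(ncol(alnMat))) {
    states <- rep(NA_character_, nnode)
    states[seq_len(ntip)] <- alnMat[tree$tip.label, s]
    total <- total + log(enumSiteLik(tree, states, kappa))
  }
  total
}

## brute-force marginal posterior at one internal node for one site
enumAncPosterior <- function(tree, alnMat, kappa, node, site) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- rep(NA_character_, nnode)
  states[seq_len(ntip)] <- alnMat[tree$tip.label, site]
  lik <- vapply(oracleBases, function(b) {
    ## clamp the node by pruning the state space: enumerate with node fixed
    allowedStates <- states
    enumSiteLikClamped(tree, allowedStates, kappa, node, b)
  }, numeric(1L))
  lik / sum(lik)
}

enumSiteLikClamped <- function(tree, states, kappa, clampNode, clampState) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  allowed <- lapply(seq_len(nnode), function(v) {
    if (v == clampNode) clampState
    else if (v <= ntip && states[v] %in% oracleBases) states[v]
    else oracleBases
  })
  free <- which(vapply(allowed, length, integer(1L)) > 1L)
  Pm <- lapply(seq_len(nrow(tree$edge)),
               function(k) oracleK2pProb(tree$edge.length[k], kappa))
  grid <- do.call(expand.grid, c(allowed[free], stringsAsFactors = FALSE))
  tot <- 0
  assign <- vapply(allowed, `[`, character(1L), 1L)
  for (g in seq_len(max(nrow(grid), 1L))) {
    if (length(free)) assign[free] <- unlist(grid[g, ], use.names = FALSE)
    lik <- 0.25
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
      lik <- lik * Pm[[k]][assign[p], assign[ch]]
    }
    tot <- tot + lik
  }
  tot
}

## least-squares fit of a 4-taxon distance matrix to each quartet topology;
## returns the split of the best (zero-residual for additive input) fit
quartetLeastSquares <- function(D) {
  taxa <- rownames(D)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))   # partner of taxon 1
  pairsIdx <- t(combn(4, 2))
  fits <- lapply(splits, function(sp) {
    ## edges: e1..e4 terminal, e5 internal; path matrix rows = taxon pairs
    inSame <- function(i, j) (i %in% sp) == (j %in% sp)
    A <- t(apply(pairsIdx, 1L, function(ij) {
      v <- numeric(5L); v[ij[1L]] <- 1; v[ij[2L]] <- 1
      if (!inSame(ij[1L], ij[2L])) v[5L] <- 1
      v
    }))
    d <- apply(pairsIdx, 1L, function(ij) D[ij[1L], ij[2L]])
    fit <- qr.solve(crossprod(A), crossprod(A, d))
    resid <- sum((A %*% fit - d)^2)
    list(split = sp, resid = resid, lengths = as.numeric(fit))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "resid"))]]
  sideA <- sort(taxa[best$split]); sideB <- sort(setdiff(taxa, sideA))
  list(split = paste(paste(sideA, collapse = ","), paste(sideB, collapse = ","),
                     sep = "|"),
       resid = best$resid, lengths = best$lengths)
}

## canonical split string of the single internal edge of a 4-taxon tree
njQuartetSplit <- function(tree) {
  bp <- paleogdh:::treeBipartitions(tree)
  stopifnot(nrow(bp) == 1L)
  side <- strsplit(bp$key, "|", fixed = TRUE)[[1L]]
  other <- sort(setdiff(tree$tip.label, side))
  paste(paste(sort(side), collapse = ","), paste(other, collapse = ","),
        sep = "|")
  ## note: ordering of the two sides may differ from quartetLeastSquares;
  ## compare with splitsEqual()
}

splitsEqual <- function(s1, s2) {
  p1 <- sort(strsplit(s1, "|", fixed = TRUE)[[1L]])
  p2 <- sort(strsplit(s2, "|", fixed = TRUE)[[1L]])
  identical(p1, p2)
}

randomAdditiveTree <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, rooted = FALSE,
                   tip.label = paste0("t", seq_len(ntaxa)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  tr
}

## ---- permutation oracle ----------------------------------------------------

## recursive permutation enumeration (distinct construction from the package)
oraclePerms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1L))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- oraclePerms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

oracleSpearmanExactP <- function(x, y) {
  robs <- stats::cor(x, y, method = "spearman")
  perms <- oraclePerms(seq_along(y))
  rp <- apply(perms, 1L, function(p) stats::cor(x, y[p], method = "spearman"))
  mean(abs(rp) >= abs(robs) - 1e-12)
}
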
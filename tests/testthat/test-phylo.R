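test_that("K2P distance closed form, saturation, and ape cross-check", {
  expect_equal(as.numeric(k2pDistance("ACGTACGTAC", "ACGTACGTAC")), 0)
  # direct evaluation of the closed form at P=0.1, Q=0.05 (20 sites)
  a <- paste(rep("A", 20), collapse = "")
  bv <- rep("A", 20); bv[1:2] <- "G"; bv[3] <- "C"   # 2 transitions, 1 transversion
  b <- paste(bv, collapse = "")
  d <- k2pDistance(a, b)
  expect_equal(attr(d, "P"), 0.1)
  expect_equal(attr(d, "Q"), 0.05)
  expect_equal(as.numeric(d), -0.5 * log(0.75) - 0.25 * log(0.9))
  # saturation: Q = 0.5
  sat_b <- paste(c(rep("C", 10), rep("A", 10)), collapse = "")
  expect_error(k2pDistance(a, sat_b), "saturation")
  # N sites excluded pairwise
  dn <- k2pDistance("ANAAA", "AGAAA")
  expect_equal(attr(dn, "n_sites"), 4L)
  expect_equal(attr(dn, "P"), 0)
  # cross-check against ape::dist.dna(model = "K80") on random pairs
  set.seed(31)
  for (i in 1:5) {
    root <- simulateRootCds(200, seed = i)
    tr <- ape::read.tree(text = "(x:0.06,y:0.09);")
    ev <- evolveOnTree(root, tr, kappa = 3, seed = i)
    m <- rbind(x = strsplit(ev$leaves[["x"]], "")[[1L]],
               y = strsplit(ev$leaves[["y"]], "")[[1L]])
    dApe <- as.numeric(ape::dist.dna(ape::as.DNAbin(tolower(m)), model = "K80"))
    expect_equal(as.numeric(k2pDistance(ev$leaves[["x"]], ev$leaves[["y"]])),
                 dApe, tolerance = 1e-10)
  }
})

test_that("K2P reduces to Jukes-Cantor when transitions are one third of changes", {
  for (p in seq(0.03, 0.6, by = 0.03)) {
    P <- p / 3; Q <- 2 * p / 3
    dK <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    dJC <- -0.75 * log(1 - 4 * p / 3)
    expect_equal(dK, dJC, tolerance = 1e-12)
  }
})

test_that("K2P probability matrix rows sum to 1, P(0)=I, matches matrix exponential", {
  for (kappa in c(0.5, 1, 2, 8)) for (t in c(0, 0.01, 0.2, 1, 5)) {
    P <- k2pProb(t, kappa)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(P >= 0))
    expect_equal(P, oracleK2pProb(t, kappa), tolerance = 1e-10)
  }
  expect_equal(unname(k2pProb(0, 2)), diag(4), tolerance = 1e-12)
  expect_error(k2pProb(-1, 2), ">= 0")
  expect_error(k2pProb(1, 0), "> 0")
})

test_that("NJ reconstructs a known additive quartet exactly", {
  ## tree ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tree <- njTree(D)
  ls <- quartetLeastSquares(D)
  expect_lt(ls$resid, 1e-20)
  expect_true(splitsEqual(njQuartetSplit(tree), ls$split))
  expect_true(splitsEqual(ls$split, "A,B|C,D"))
  # exact branch lengths (terminal 1,2,3,4 and internal 1)
  expect_equal(sort(tree$edge.length), c(1, 1, 2, 3, 4), tolerance = 1e-9)
  # recovered distances are exactly additive
  expect_equal(as.matrix(ape::cophenetic.phylo(tree))[rownames(D), rownames(D)],
               D, tolerance = 1e-9)
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2,
                             dimnames = list(c("a", "b"), c("a", "b")))), "taxa")
  Dbad <- D; Dbad[1, 2] <- 99
  expect_error(njTree(Dbad), "symmetric")
})

test_that("NJ solves the 3-taxon closed form and ultrametric quartets", {
  D <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(D)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2L])], tr$tip.label)
  expect_equal(unname(len["a"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(len["b"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(len["c"]), (0.5 + 0.6 - 0.3) / 2)
  # ultrametric quartet
  Du <- matrix(c(0, 2, 6, 6,
                 2, 0, 6, 6,
                 6, 6, 0, 2,
                 6, 6, 2, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_true(splitsEqual(njQuartetSplit(njTree(Du)), "A,B|C,D"))
})

test_that("NJ recovers random additive trees of 5-7 taxa (vs ape::nj too)", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(5:7, 1L)
    tr <- randomAdditiveTree(n)
    D <- ape::cophenetic.phylo(tr)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    mine <- njTree(D)
    expect_equal(phangorn::RF.dist(mine, tr), 0)
    expect_equal(phangorn::RF.dist(mine, ape::nj(as.dist(D))), 0)
    expect_equal(sort(mine$edge.length), sort(tr$edge.length), tolerance = 1e-8)
  }
})

test_that("pruning log-likelihood matches hand computation and brute force", {
  ## two leaves joined by total length t, same base at the single site
  t <- 0.3; kappa <- 2
  tree <- ape::read.tree(text = sprintf("(x:%f,y:%f);", t / 2, t / 2))
  llSame <- pruningLoglik(tree, c(x = "A", y = "A"), kappa)
  P <- oracleK2pProb(t, kappa)
  expect_equal(llSame, log(0.25 * P["A", "A"]), tolerance = 1e-10)
  llDiff <- pruningLoglik(tree, c(x = "A", y = "G"), kappa)
  expect_equal(llDiff, log(0.25 * P["A", "G"]), tolerance = 1e-10)

  ## zero-length star tree with identical leaves: log(1/4) per site
  star <- ape::read.tree(text = "(a:0,b:0,c:0);")
  expect_equal(pruningLoglik(star, c(a = "ACGT", b = "ACGT", c = "ACGT"), 2),
               4 * log(0.25), tolerance = 1e-12)

  ## random small trees vs exhaustive enumeration over internal states
  set.seed(23)
  for (i in 1:12) {
    n <- sample(4:5, 1L)
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.6)
    S <- 6L
    m <- matrix(sample(c(oracleBases, "N"), n * S, replace = TRUE,
                       prob = c(rep(0.23, 4), 0.08)), n, S,
                dimnames = list(paste0("t", 1:n), NULL))
    kappa <- runif(1, 0.5, 6)
    expect_equal(pruningLoglik(tr, m, kappa), enumTreeLoglik(tr, m, kappa),
                 tolerance = 1e-8)
  }
  expect_error(pruningLoglik(ape::read.tree(text = "(a:-1,b:1);"),
                             c(a = "A", b = "A"), 2), "negative")
})

test_that("ancestral reconstruction is the brute-force marginal posterior", {
  set.seed(29)
  for (i in 1:6) {
    tr <- ape::rtree(4, tip.label = paste0("t", 1:4))
    tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.5)
    S <- 4L
    m <- matrix(sample(oracleBases, 4L * S, replace = TRUE), 4L, S,
                dimnames = list(paste0("t", 1:4), NULL))
    kappa <- runif(1, 0.8, 4)
    anc <- ancestralStates(tr, m, kappa)
    ntip <- 4L
    for (v in (ntip + 1L):(ntip + tr$Nnode)) for (s in seq_len(S)) {
      oracle <- enumAncPosterior(tr, m, kappa, v, s)
      expect_equal(unname(anc$posterior[[v - ntip]][, s]), unname(oracle),
                   tolerance = 1e-8)
    }
    # posteriors sum to one everywhere
    for (pp in anc$posterior)
      expect_equal(unname(colSums(pp)), rep(1, S), tolerance = 1e-12)
  }
})

test_that("ancestral reconstruction handles forced and degenerate cases", {
  tr <- ape::read.tree(text = "((a:0.01,b:0.01):0.01,(c:0.01,d:0.01):0.01);")
  aln <- c(a = "A", b = "A", c = "A", d = "A")
  anc <- ancestralStates(tr, aln, 2)
  expect_true(all(substr(anc$states, 1, 1) == "A"))
  expect_true(all(vapply(anc$posterior, function(p) p["A", 1L], 1) >= 0.99))
  # zero-length branches force the shared state exactly
  tr0 <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  anc0 <- ancestralStates(tr0, c(a = "G", b = "G", c = "G", d = "G"), 2)
  expect_true(all(anc0$states == "G"))
  # symmetric tie broken alphabetically and flagged
  trt <- ape::read.tree(text = "(a:0.1,b:0.1);")
  anct <- ancestralStates(trt, c(a = "A", b = "G"), 2)
  expect_true(anct$ties[1L, 1L])
  expect_equal(anct$states[[1L]], "A")
  # unrooted input refused
  unr <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_error(ancestralStates(unr, c(a = "A", b = "A", c = "A"), 2), "rooted")
})

test_that("pruning likelihood agrees with phangorn::pml under K80", {
  skip_if_not_installed("phangorn")
  set.seed(37)
  root <- simulateRootCds(120, seed = 5)
  tr <- ape::rtree(5, tip.label = paste0("t", 1:5))
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.4)
  ev <- evolveOnTree(root, tr, kappa = 3, seed = 6)
  m <- do.call(rbind, strsplit(ev$leaves, ""))
  pd <- phangorn::phyDat(m, type = "DNA")
  fit <- phangorn::pml(ape::unroot(tr), pd, bf = rep(0.25, 4),
                       Q = c(1, 3, 1, 1, 3, 1), k = 1)
  expect_equal(pruningLoglik(tr, ev$leaves, kappa = 3), as.numeric(fit$logLik),
               tolerance = 1e-6)
})

test_that("bootstrap support finds a clean bipartition and is reproducible", {
  set.seed(41)
  S <- 400L
  base <- sample(oracleBases, S, replace = TRUE)
  diag1 <- sample(seq_len(S), 120L)
  mk <- function(flip) {
    v <- base
    v[diag1] <- if (flip) chartr("AGCT", "GATC", v[diag1]) else v[diag1]
    paste(v, collapse = "")
  }
  noise <- function(s, k, seed) {  # a little within-clade variation
    set.seed(seed); v <- strsplit(s, "")[[1L]]
    i <- sample(seq_len(S), k)
    v[i] <- chartr("AGCT", "GATC", v[i]); paste(v, collapse = "")
  }
  aln <- c(a1 = mk(FALSE), a2 = noise(mk(FALSE), 4L, 1),
           b1 = mk(TRUE), b2 = noise(mk(TRUE), 4L, 2))
  bt <- bootstrapSupport(aln, nReps = 100, seed = 99)
  sup <- attr(bt, "supports")
  expect_equal(nrow(sup), 1L)
  expect_gte(sup$support, 99)     # ~100% for 120 diagnostic sites
  # reproducibility and n=1 dichotomy
  bt2 <- bootstrapSupport(aln, nReps = 100, seed = 99)
  expect_equal(attr(bt2, "supports")$support, sup$support)
  bt1 <- bootstrapSupport(aln, nReps = 1, seed = 3)
  expect_true(all(attr(bt1, "supports")$support %in% c(0, 100)))
  # identical sequences -> degenerate flag
  expect_warning(
    btd <- bootstrapSupport(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
                              c = "ACGTACGTAC", d = "ACGTACGTAC"),
                            nReps = 5, seed = 1),
    "degenerate")
  expect_true(attr(btd, "degenerate"))
})

test_that("kappa estimation recovers simulated values and flags edge cases", {
  tr <- ape::read.tree(
    text = "((a:0.05,b:0.08):0.04,(c:0.06,d:0.05):0.05,o:0.12);")
  root <- simulateRootCds(1000, seed = 8)
  ev <- evolveOnTree(root, rootAtOutgroup(tr, "o"), kappa = 4, seed = 9)
  k <- estimateKappa(ev$leaves, tr)
  expect_gt(as.numeric(k), 2.6)
  expect_lt(as.numeric(k), 6)
  ev1 <- evolveOnTree(root, rootAtOutgroup(tr, "o"), kappa = 1, seed = 10)
  k1 <- estimateKappa(ev1$leaves, tr)
  expect_gt(as.numeric(k1), 0.6)
  expect_lt(as.numeric(k1), 1.6)
  # no variation -> default 2 with warning
  expect_warning(k2 <- estimateKappa(c(a = "ACGT", b = "ACGT", c = "ACGT"),
                                     ape::read.tree(text = "(a:.1,b:.1,c:.1);")),
                 "default kappa")
  expect_equal(as.numeric(k2), 2)
  # transitions only -> estimate pinned at the upper bound, flagged
  expect_warning(kb <- estimateKappa(
    c(a = "AAAAAAAAAA", b = "GGGGGAAAAA", c = "AAAAAAAAAG"),
    ape::read.tree(text = "(a:.1,b:.1,c:.1);")), "upper")
  expect_true(attr(kb, "boundary"))
})

test_that("outgroup rooting splits the outgroup edge at its midpoint", {
  tr <- njTree(matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3, 3,
                      dimnames = list(c("a", "b", "o"), c("a", "b", "o"))))
  r <- rootAtOutgroup(tr, "o")
  expect_true(ape::is.rooted(r))
  rootId <- length(r$tip.label) + 1L
  kids <- r$edge.length[r$edge[, 1L] == rootId]
  expect_equal(kids[1L], kids[2L])             # midpoint rooting
  expect_error(rootAtOutgroup(tr, "zz"), "not a tip")
})
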
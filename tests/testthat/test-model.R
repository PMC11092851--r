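ns <- asNamespace("synergraph")
groupSoftmax <- ns$groupSoftmax
hgForward <- ns$hgForward
hgIndex <- ns$hgIndex
subjForward <- ns$subjForward
makeModelStruct <- ns$makeModelStruct
initSynergyParams <- ns$initSynergyParams
modelForward <- ns$modelForward
lossGrad <- ns$lossGrad
flattenParams <- ns$flattenParams
unflattenParams <- ns$unflattenParams
bceLoss <- ns$bceLoss

test_that("segment softmax: singleton, symmetry, hand value, shift invariance", {
  expect_equal(groupSoftmax(0.7, 1L, 1L), 1)
  expect_equal(groupSoftmax(c(3, 3, 3), c(1L, 1L, 1L), 1L), rep(1 / 3, 3))
  expect_equal(groupSoftmax(c(log(2), 0), c(1L, 1L), 1L), c(2 / 3, 1 / 3))
  z <- rnorm(6)
  g <- c(1L, 1L, 2L, 2L, 2L, 1L)
  expect_equal(groupSoftmax(z + 5, g, 2L), groupSoftmax(z, g, 2L))
  ## weights sum to one per group
  w <- groupSoftmax(z, g, 2L)
  expect_equal(as.vector(tapply(w, g, sum)), c(1, 1), tolerance = 1e-12)
})

test_that("message-passing layer equals the brute-force loop implementation", {
  set.seed(5)
  for (i in 1:20) {
    nV <- sample(2:8, 1); nE <- sample(2:8, 1); d <- sample(2:5, 1)
    M <- randomIncidence(nV, nE)
    hg <- IncidenceHypergraph(M)
    E <- matrix(rnorm(nV * d), nV, d)
    W <- matrix(rnorm(d * 2 * d), d, 2 * d)
    C <- rnorm(d)
    fwd <- hgForward(hgIndex(hg), E, W, C, K = 2)
    HE0 <- t(apply(t(M) / colSums(M), 1, function(w) colSums(w * E)))
    b1 <- bruteLayer(M, E, HE0, W, C)
    b2 <- bruteLayer(M, b1$HV, b1$HE, W, C)
    expect_lt(max(abs(fwd$HV - b2$HV)), 1e-10)
    expect_lt(max(abs(fwd$HE - b2$HE)), 1e-10)
  }
})

test_that("disconnected components do not influence each other", {
  M <- matrix(0, 4, 4)
  M[1:2, 1:2] <- matrix(c(1, 1, 1, 0), 2, 2)
  M[3:4, 3:4] <- matrix(c(1, 0, 1, 1), 2, 2)
  dimnames(M) <- list(paste0("n", 1:4), paste0("e", 1:4))
  hg <- IncidenceHypergraph(M)
  set.seed(6)
  E <- matrix(rnorm(4 * 3), 4, 3)
  W <- matrix(rnorm(3 * 6), 3, 6)
  C <- rnorm(3)
  base <- hgForward(hgIndex(hg), E, W, C, K = 2)
  E2 <- E
  E2[3:4, ] <- rnorm(6)  # perturb only component B
  pert <- hgForward(hgIndex(hg), E2, W, C, K = 2)
  expect_equal(base$HV[1:2, ], pert$HV[1:2, ])
  expect_false(isTRUE(all.equal(base$HV[3:4, ], pert$HV[3:4, ])))
})

test_that("node permutation permutes layer outputs identically", {
  set.seed(8)
  M <- randomIncidence(6, 5)
  d <- 3
  E <- matrix(rnorm(6 * d), 6, d)
  W <- matrix(rnorm(d * 2 * d), d, 2 * d)
  C <- rnorm(d)
  hg <- IncidenceHypergraph(M)
  out <- hgForward(hgIndex(hg), E, W, C, K = 1)
  perm <- sample(6)
  hgP <- IncidenceHypergraph(M[perm, ])
  outP <- hgForward(hgIndex(hgP), E[perm, ], W, C, K = 1)
  expect_equal(outP$HV, out$HV[perm, ])
  expect_equal(outP$HE, out$HE)
})

test_that("subgraph attention equals brute force; degenerate cases behave", {
  set.seed(9)
  for (i in 1:20) {
    nV <- sample(3:10, 1); d <- sample(2:5, 1)
    HV <- matrix(abs(rnorm(nV * d)), nV, d)
    b <- rnorm(d)
    f <- rnorm(nV) * rbinom(nV, 1, 0.7)
    if (all(f == 0)) f[1] <- 1
    bp <- list(pj = rep(1L, sum(f != 0)), pi = which(f != 0),
               val = f[f != 0])
    got <- subjForward(HV, b, bp, 1L)
    expect_lt(max(abs(got$h[1, ] - bruteSubgraph(f, HV, b))), 1e-10)
  }
  ## singleton support: weight exactly one
  HV <- matrix(rnorm(6), 3, 2)
  got <- subjForward(HV, rnorm(2), list(pj = 1L, pi = 2L, val = 1.3), 1L)
  expect_equal(got$a, 1)
  ## zero bias: uniform weights over the support
  got0 <- subjForward(HV, c(0, 0),
                      list(pj = c(1L, 1L, 1L), pi = 1:3, val = c(1, 2, 3)), 1L)
  expect_equal(got0$a, rep(1 / 3, 3))
  ## empty subgraph rejected at pair construction
  F0 <- matrix(0, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  F0[1, 1] <- 1
  expect_error(ns$makePairs(F0), "empty subgraph")
})

test_that("analytic gradients match central differences in train and eval modes", {
  setup <- tinyModelSetup(n = 2, seed = 42)
  config <- synergyConfig(embedDim = 4, hidden = 5, nLayers = 2,
                          dropoutSub = 0, dropoutFnn = 0, seed = 3)
  struct <- makeModelStruct(setup$features, setup$cellHg, setup$drugHg, config)
  init <- initSynergyParams(5, 6, 3, config)
  S <- 1:2
  y <- setup$features$labels[S]
  for (train in c(TRUE, FALSE)) {
    lg <- lossGrad(init$params, init$buffers, struct, S, train = train)
    ga <- flattenParams(lg$grads)
    th <- flattenParams(init$params)
    lossAt <- function(v) {
      fwd <- modelForward(unflattenParams(v, init$params), init$buffers,
                          struct, S, train = train)
      bceLoss(fwd$logit, y)
    }
    h <- 1e-5
    gn <- vapply(seq_along(th), function(i) {
      e <- th; e[i] <- e[i] + h; lp <- lossAt(e)
      e[i] <- e[i] - 2 * h; lm <- lossAt(e)
      (lp - lm) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(ga - gn) / pmax(1e-6, abs(ga) + abs(gn))), 1e-4)
  }
})

test_that("training is reproducible, respects zero epochs, rejects one-class folds", {
  setup <- tinyModelSetup(n = 12, seed = 21)
  config <- synergyConfig(embedDim = 3, hidden = 4, epochs = 3,
                          batchSize = 6, seed = 5)
  m1 <- trainSynergyModel(setup$features, setup$cellHg, setup$drugHg, config,
                          trainIdx = 1:8, valIdx = 9:12)
  m2 <- trainSynergyModel(setup$features, setup$cellHg, setup$drugHg, config,
                          trainIdx = 1:8, valIdx = 9:12)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_identical(m1@params, m2@params)

  cfg0 <- synergyConfig(embedDim = 3, hidden = 4, epochs = 0, seed = 5)
  m0 <- trainSynergyModel(setup$features, setup$cellHg, setup$drugHg, cfg0)
  init <- initSynergyParams(5, 6, 3, cfg0)
  expect_equal(m0@params, init$params)
  expect_equal(nrow(trainingHistory(m0)), 0L)

  oneClass <- setup$features
  oneClass$labels <- rep(1, 12)
  expect_error(trainSynergyModel(oneClass, setup$cellHg, setup$drugHg, config),
               "single class")
})

test_that("evaluation-mode prediction is deterministic and finite", {
  setup <- tinyModelSetup(n = 8, seed = 31)
  config <- synergyConfig(embedDim = 3, hidden = 4, epochs = 2,
                          batchSize = 4, seed = 2)
  m <- trainSynergyModel(setup$features, setup$cellHg, setup$drugHg, config)
  p1 <- predictSynergy(m, setup$features)
  p2 <- predictSynergy(m, setup$features)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1) & p1 > 0 & p1 < 1))
})

test_that("subject attention rows sum to one over each support", {
  setup <- tinyModelSetup(n = 6, seed = 11)
  config <- synergyConfig(embedDim = 3, hidden = 4, epochs = 1,
                          batchSize = 6, seed = 2)
  m <- trainSynergyModel(setup$features, setup$cellHg, setup$drugHg, config)
  for (which in c("cell", "drug")) {
    a <- subjectAttention(m, setup$features, which)
    expect_equal(unname(rowSums(a)), rep(1, 6), tolerance = 1e-9)
    f <- featureValues(setup$features[[which]])
    expect_true(all(a[f == 0] == 0))
  }
})

test_that("scaling subject features sharpens attention monotonically in the score", {
  ## with fixed positive node scores u = b' hV, multiplying F by a
  ## positive constant scales all scores: the argmax node's weight rises
  set.seed(13)
  HV <- matrix(abs(rnorm(12)), 4, 3)
  b <- abs(rnorm(3))
  f <- c(0.5, 2, 0, 1)
  bp <- list(pj = rep(1L, 3), pi = c(1L, 2L, 4L), val = f[c(1, 2, 4)])
  a1 <- subjForward(HV, b, bp, 1L)$a
  bp2 <- bp; bp2$val <- 3 * bp$val
  a2 <- subjForward(HV, b, bp2, 1L)$a
  top <- which.max(f[c(1, 2, 4)] * (HV %*% b)[c(1, 2, 4)])
  expect_gt(a2[top], a1[top])
})
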
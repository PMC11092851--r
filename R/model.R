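## ---------------------------------------------------------------------
## Sub-hypergraph attention network: forward and analytic backward passes.
## Message passing operates on the sparse incidence pair list (node index
## g, edge index p per incidence); softmaxes are segment softmaxes over
## those pairs, and all segment sums go through rowsum().
## ---------------------------------------------------------------------

#' Model configuration
#'
#' Hyperparameters of the sub-hypergraph attention synergy model. The
#' defaults follow the tuned values this package adopts: embedding /
#' hidden dimension 200, dropout 0.2 on the subgraph attention output
#' and 0.3 inside the feed-forward head, k-mer size 9, two
#' message-passing layers, Adam with a cosine learning-rate schedule.
#'
#' @param embedDim node-embedding dimension of the hypergraph encoder.
#' @param hidden width of the two feed-forward hidden layers.
#' @param nLayers number of dual-attention message-passing layers.
#' @param dropoutSub dropout rate on the subgraph embeddings.
#' @param dropoutFnn dropout rate after each feed-forward layer.
#' @param kmer SMILES k-mer window length.
#' @param lr base Adam learning rate (cosine-annealed over epochs).
#' @param weightDecay L2 penalty added to weight gradients (not applied
#'   to biases or batch-norm parameters).
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param seed seed governing initialisation, shuffling and dropout.
#' @return named list of settings.
#' @export
synergyConfig <- function(embedDim = 200, hidden = 200, nLayers = 2,
                          dropoutSub = 0.2, dropoutFnn = 0.3, kmer = 9,
                          lr = 1e-3, weightDecay = 0, epochs = 50,
                          batchSize = 128, seed = 1) {
  stopifnot(embedDim > 0, hidden > 0, nLayers >= 1,
            dropoutSub >= 0, dropoutSub < 1, dropoutFnn >= 0, dropoutFnn < 1)
  list(embedDim = embedDim, hidden = hidden, nLayers = nLayers,
       dropoutSub = dropoutSub, dropoutFnn = dropoutFnn, kmer = kmer,
       lr = lr, weightDecay = weightDecay, epochs = epochs,
       batchSize = batchSize, seed = seed)
}

## incidence pair-list view of a hypergraph
hgIndex <- function(hg) {
  tri <- Matrix::summary(incidence(hg))
  list(g = tri$i, p = tri$j, nV = nrow(incidence(hg)),
       nE = ncol(incidence(hg)),
       deg = rowsumVec(rep(1, length(tri$i)), tri$j, ncol(incidence(hg))))
}

## subject-node pair-list view of a feature matrix; subjects with empty
## support (all-zero rows) are an error: they have no sub-hypergraph.
makePairs <- function(F) {
  nz <- which(F != 0, arr.ind = TRUE)
  if (any(rowSums(F != 0) == 0))
    stopf("empty subgraph: %d subject(s) have all-zero feature rows",
          sum(rowSums(F != 0) == 0))
  o <- order(nz[, 1L])
  j <- nz[o, 1L]; i <- nz[o, 2L]
  list(i = i, val = F[cbind(j, i)],
       bySubject = split(seq_along(j), factor(j, levels = seq_len(nrow(F)))))
}

batchPairs <- function(pairs, S) {
  sel <- pairs$bySubject[S]
  idx <- unlist(sel, use.names = FALSE)
  list(pj = rep(seq_along(S), lengths(sel)), pi = pairs$i[idx],
       val = pairs$val[idx])
}

## ---- hypergraph encoder --------------------------------------------

## K layers of dual attention. Initial node states are the embedding
## table; initial hyperedge states are means of their incident nodes.
hgForward <- function(hgi, E, W, C, K) {
  d <- ncol(E)
  HV <- E
  HE <- rowsumMat(E[hgi$g, , drop = FALSE], hgi$p, hgi$nE) / hgi$deg
  layers <- vector("list", K)
  for (k in seq_len(K)) {
    Xv <- HV[hgi$g, , drop = FALSE]
    Xe <- HE[hgi$p, , drop = FALSE]
    A <- cbind(Xv, Xe) %*% t(W)
    S <- tanh(A)
    z <- drop(S %*% C)
    aE <- groupSoftmax(z, hgi$p, hgi$nE)
    aV <- groupSoftmax(z, hgi$g, hgi$nV)
    preE <- rowsumMat(aE * Xv, hgi$p, hgi$nE)
    preV <- rowsumMat(aV * Xe, hgi$g, hgi$nV)
    layers[[k]] <- list(HVin = HV, HEin = HE, S = S, aE = aE, aV = aV,
                        preE = preE, preV = preV)
    HV <- pmax(preV, 0)
    HE <- pmax(preE, 0)
  }
  list(HV = HV, HE = HE, layers = layers)
}

hgBackward <- function(hgi, W, C, fwd, dHV_out) {
  K <- length(fwd$layers)
  d <- length(C)
  dW <- matrix(0, d, 2 * d)
  dC <- numeric(d)
  dHV <- dHV_out
  dHE <- matrix(0, hgi$nE, d)
  for (k in rev(seq_len(K))) {
    lc <- fwd$layers[[k]]
    Xv <- lc$HVin[hgi$g, , drop = FALSE]
    Xe <- lc$HEin[hgi$p, , drop = FALSE]
    dpreV <- dHV * (lc$preV > 0)
    dpreE <- dHE * (lc$preE > 0)
    daV <- rowSums(dpreV[hgi$g, , drop = FALSE] * Xe)
    daE <- rowSums(dpreE[hgi$p, , drop = FALSE] * Xv)
    sV <- rowsumVec(lc$aV * daV, hgi$g, hgi$nV)
    sE <- rowsumVec(lc$aE * daE, hgi$p, hgi$nE)
    dz <- lc$aV * (daV - sV[hgi$g]) + lc$aE * (daE - sE[hgi$p])
    dS <- outer(dz, C)
    dA <- dS * (1 - lc$S^2)
    dC <- dC + drop(crossprod(lc$S, dz))
    dW <- dW + crossprod(dA, cbind(Xv, Xe))
    dX <- dA %*% W
    dHV <- rowsumMat(dX[, 1:d, drop = FALSE] +
                       lc$aE * dpreE[hgi$p, , drop = FALSE], hgi$g, hgi$nV)
    dHE <- rowsumMat(dX[, (d + 1):(2 * d), drop = FALSE] +
                       lc$aV * dpreV[hgi$g, , drop = FALSE], hgi$p, hgi$nE)
  }
  ## through the mean-pooled initial hyperedge states into the table
  dE <- dHV + rowsumMat(dHE[hgi$p, , drop = FALSE] / hgi$deg[hgi$p],
                        hgi$g, hgi$nV)
  list(dE = dE, dW = dW, dC = dC)
}

## ---- subgraph attention --------------------------------------------

## attention over a subject's support: score_i = F_ji * (b' hV_i),
## softmax within the subject, ReLU of the weighted node sum.
subjForward <- function(HV, b, bp, nSub) {
  u <- drop(HV %*% b)
  w <- bp$val * u[bp$pi]
  a <- groupSoftmax(w, bp$pj, nSub)
  pre <- rowsumMat(a * HV[bp$pi, , drop = FALSE], bp$pj, nSub)
  list(h = pmax(pre, 0), a = a, pre = pre)
}

subjBackward <- function(HV, b, bp, nSub, cache, dh) {
  dpre <- dh * (cache$pre > 0)
  da <- rowSums(dpre[bp$pj, , drop = FALSE] * HV[bp$pi, , drop = FALSE])
  sj <- rowsumVec(cache$a * da, bp$pj, nSub)
  dw <- cache$a * (da - sj[bp$pj])
  duPair <- bp$val * dw
  duNode <- rowsumVec(duPair, bp$pi, nrow(HV))
  dHV <- rowsumMat(cache$a * dpre[bp$pj, , drop = FALSE], bp$pi, nrow(HV)) +
    outer(duNode, b)
  db <- drop(crossprod(HV, duNode))
  list(dHV = dHV, db = db)
}

## ---- feed-forward head ---------------------------------------------

elu <- function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1)
eluGrad <- function(z, h) ifelse(z > 0, 1, h + 1)

bnEps <- 1e-5

fnnForward <- function(p, buffers, x, train) {
  if (train) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
  } else {
    mu <- buffers$mean
    v <- buffers$var
  }
  sdv <- sqrt(v + bnEps)
  xhat <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  yBN <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  z1 <- sweep(yBN %*% t(p$W1), 2, p$b1, "+")
  h1 <- elu(z1)
  z2 <- sweep(h1 %*% t(p$W2), 2, p$b2, "+")
  h2 <- elu(z2)
  logit <- drop(h2 %*% p$w3) + p$b3
  list(logit = logit, cache = list(x = x, xhat = xhat, sdv = sdv, yBN = yBN,
                                   z1 = z1, h1 = h1, z2 = z2, h2 = h2,
                                   mu = mu, v = v, train = train))
}

## dropout inside the head is applied by the caller on h1/h2 via masks;
## to keep the cache exact we fold masks in here instead
fnnForwardDrop <- function(p, buffers, x, train, m1 = NULL, m2 = NULL) {
  f <- fnnForward(p, buffers, x, train)
  cache <- f$cache
  h1d <- if (is.null(m1)) cache$h1 else cache$h1 * m1
  z2 <- sweep(h1d %*% t(p$W2), 2, p$b2, "+")
  h2 <- elu(z2)
  h2d <- if (is.null(m2)) h2 else h2 * m2
  logit <- drop(h2d %*% p$w3) + p$b3
  cache$h1d <- h1d; cache$z2 <- z2; cache$h2 <- h2; cache$h2d <- h2d
  cache$m1 <- m1; cache$m2 <- m2
  list(logit = logit, cache = cache)
}

fnnBackward <- function(p, cache, dlogit) {
  n <- length(dlogit)
  dw3 <- drop(crossprod(cache$h2d, dlogit))
  db3 <- sum(dlogit)
  dh2d <- outer(dlogit, p$w3)
  dh2 <- if (is.null(cache$m2)) dh2d else dh2d * cache$m2
  dz2 <- dh2 * eluGrad(cache$z2, cache$h2)
  dW2 <- crossprod(dz2, cache$h1d)
  db2 <- colSums(dz2)
  dh1d <- dz2 %*% p$W2
  dh1 <- if (is.null(cache$m1)) dh1d else dh1d * cache$m1
  dz1 <- dh1 * eluGrad(cache$z1, cache$h1)
  dW1 <- crossprod(dz1, cache$yBN)
  db1 <- colSums(dz1)
  dyBN <- dz1 %*% p$W1
  dgamma <- colSums(dyBN * cache$xhat)
  dbeta <- colSums(dyBN)
  dxhat <- sweep(dyBN, 2, p$gamma, "*")
  if (cache$train) {
    mean1 <- colMeans(dxhat)
    mean2 <- colMeans(dxhat * cache$xhat)
    dx <- sweep(sweep(dxhat, 2, mean1, "-") -
                  sweep(cache$xhat, 2, mean2, "*"), 2, cache$sdv, "/")
  } else {
    dx <- sweep(dxhat, 2, cache$sdv, "/")
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta, W1 = dW1, b1 = db1,
                             W2 = dW2, b2 = db2, w3 = dw3, b3 = db3))
}

## ---- parameter plumbing --------------------------------------------

initSynergyParams <- function(nVcell, nVdrug, covDim, config, seed = config$seed) {
  d <- config$embedDim
  h <- config$hidden
  D <- 2 * d + covDim
  withSeed(seed, {
    glorot <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / (nr + nc))),
                                      nr, nc)
    params <- list(
      cell = list(E = matrix(rnorm(nVcell * d, 0, 0.1), nVcell, d),
                  W = glorot(d, 2 * d), c = rnorm(d, 0, 0.1),
                  b = rnorm(d, 0, 0.1)),
      drug = list(E = matrix(rnorm(nVdrug * d, 0, 0.1), nVdrug, d),
                  W = glorot(d, 2 * d), c = rnorm(d, 0, 0.1),
                  b = rnorm(d, 0, 0.1)),
      fnn = list(gamma = rep(1, D), beta = rep(0, D),
                 W1 = glorot(h, D), b1 = rep(0, h),
                 W2 = glorot(h, h), b2 = rep(0, h),
                 w3 = rnorm(h, 0, sqrt(1 / h)), b3 = 0))
    list(params = params,
         buffers = list(mean = rep(0, D), var = rep(1, D)))
  })
}

flattenParams <- function(p) unlist(p, use.names = FALSE)

unflattenParams <- function(v, skel) {
  pos <- 0L
  walk <- function(s) {
    if (is.list(s)) return(lapply(s, walk))
    n <- length(s)
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(s))) dim(out) <- dim(s)
    out
  }
  walk(skel)
}

## ---- full model forward / backward ---------------------------------

## struct: list(cellIdx, drugIdx, cellPairs, drugPairs, cov, labels, K)
makeModelStruct <- function(features, cellHg, drugHg, config) {
  list(cellIdx = hgIndex(cellHg), drugIdx = hgIndex(drugHg),
       cellPairs = makePairs(featureValues(features$cell)),
       drugPairs = makePairs(featureValues(features$drug)),
       cov = features$cov, labels = features$labels, K = config$nLayers)
}

modelForward <- function(params, buffers, struct, S, train = FALSE,
                         masks = NULL) {
  fc <- hgForward(struct$cellIdx, params$cell$E, params$cell$W,
                  params$cell$c, struct$K)
  fd <- hgForward(struct$drugIdx, params$drug$E, params$drug$W,
                  params$drug$c, struct$K)
  bpc <- batchPairs(struct$cellPairs, S)
  bpd <- batchPairs(struct$drugPairs, S)
  sc <- subjForward(fc$HV, params$cell$b, bpc, length(S))
  sd <- subjForward(fd$HV, params$drug$b, bpd, length(S))
  hc <- if (is.null(masks$subC)) sc$h else sc$h * masks$subC
  hd <- if (is.null(masks$subD)) sd$h else sd$h * masks$subD
  x <- cbind(hc, hd, struct$cov[S, , drop = FALSE])
  ff <- fnnForwardDrop(params$fnn, buffers, x, train,
                       masks$fnn1, masks$fnn2)
  list(logit = ff$logit,
       cache = list(fc = fc, fd = fd, bpc = bpc, bpd = bpd, sc = sc, sd = sd,
                    ff = ff$cache, masks = masks, S = S),
       batchStats = list(mean = ff$cache$mu, var = ff$cache$v))
}

modelBackward <- function(params, struct, cache, dlogit) {
  d <- ncol(params$cell$E)
  fb <- fnnBackward(params$fnn, cache$ff, dlogit)
  dhc <- fb$dx[, 1:d, drop = FALSE]
  dhd <- fb$dx[, (d + 1):(2 * d), drop = FALSE]
  if (!is.null(cache$masks$subC)) dhc <- dhc * cache$masks$subC
  if (!is.null(cache$masks$subD)) dhd <- dhd * cache$masks$subD
  n <- length(cache$S)
  sbC <- subjBackward(cache$fc$HV, params$cell$b, cache$bpc, n, cache$sc, dhc)
  sbD <- subjBackward(cache$fd$HV, params$drug$b, cache$bpd, n, cache$sd, dhd)
  hbC <- hgBackward(struct$cellIdx, params$cell$W, params$cell$c,
                    cache$fc, sbC$dHV)
  hbD <- hgBackward(struct$drugIdx, params$drug$W, params$drug$c,
                    cache$fd, sbD$dHV)
  list(cell = list(E = hbC$dE, W = hbC$dW, c = hbC$dC, b = sbC$db),
       drug = list(E = hbD$dE, W = hbD$dW, c = hbD$dC, b = sbD$db),
       fnn = fb$grads)
}

## mean BCE-with-logits loss and its gradient
bceLoss <- function(logit, y) {
  mean(pmax(logit, 0) - logit * y + log1p(exp(-abs(logit))))
}

bceGrad <- function(logit, y) (plogis(logit) - y) / length(y)

## one loss + gradient evaluation on subjects S
lossGrad <- function(params, buffers, struct, S, train = FALSE, masks = NULL) {
  fwd <- modelForward(params, buffers, struct, S, train, masks)
  y <- struct$labels[S]
  loss <- bceLoss(fwd$logit, y)
  grads <- modelBackward(params, struct, fwd$cache, bceGrad(fwd$logit, y))
  list(loss = loss, grads = grads, logit = fwd$logit,
       batchStats = fwd$batchStats)
}

applyWeightDecay <- function(grads, params, wd) {
  if (wd == 0) return(grads)
  for (blk in c("cell", "drug")) for (nm in c("E", "W", "c", "b"))
    grads[[blk]][[nm]] <- grads[[blk]][[nm]] + wd * params[[blk]][[nm]]
  for (nm in c("W1", "W2", "w3"))
    grads$fnn[[nm]] <- grads$fnn[[nm]] + wd * params$fnn[[nm]]
  grads
}

#' Train the sub-hypergraph attention synergy model
#'
#' Minimises sigmoid binary cross-entropy on the synergy labels with
#' Adam under a cosine learning-rate schedule, using minibatches,
#' batch-norm on the concatenated input, and dropout on the subgraph
#' embeddings and feed-forward layers. All randomness (initialisation,
#' shuffling, dropout) derives from `config$seed`, so identical calls
#' give bitwise-identical histories. When validation indices are given,
#' per-epoch validation AUPRC/AUROC are logged and the
#' best-validation-AUPRC checkpoint is returned; otherwise the final
#' parameters are.
#'
#' @param features feature bundle from [buildSampleFeatures()].
#' @param cellHg,drugHg the hypergraphs the features were built on.
#' @param config a [synergyConfig()].
#' @param trainIdx,valIdx integer sample indices; default trains on all
#'   samples with no validation split.
#' @param vocab optional covariate vocabulary to store with the model.
#' @param verbose print per-epoch progress.
#' @return a [HypergraphSynergyModel-class].
#' @export
trainSynergyModel <- function(features, cellHg, drugHg,
                              config = synergyConfig(),
                              trainIdx = NULL, valIdx = NULL,
                              vocab = list(), verbose = FALSE) {
  struct <- makeModelStruct(features, cellHg, drugHg, config)
  n <- length(struct$labels)
  trainIdx <- trainIdx %||% seq_len(n)
  yTr <- struct$labels[trainIdx]
  if (length(unique(yTr)) < 2L)
    stopf("training fold contains a single class")

  init <- initSynergyParams(struct$cellIdx$nV, struct$drugIdx$nV,
                            ncol(struct$cov), config)
  params <- init$params
  buffers <- init$buffers
  skel <- params
  theta <- flattenParams(params)
  mAdam <- vAdam <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  history <- list()
  best <- list(params = params, buffers = buffers, metric = -Inf)

  d <- config$embedDim; h <- config$hidden
  momentum <- 0.1

  withSeed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$lr * 0.5 * (1 + cos(pi * (epoch - 1) / max(config$epochs, 1)))
      perm <- sample(trainIdx)
      batches <- split(perm, ceiling(seq_along(perm) / config$batchSize))
      epochLoss <- 0
      for (S in batches) {
        nb <- length(S)
        masks <- list()
        if (config$dropoutSub > 0) {
          keep <- 1 - config$dropoutSub
          masks$subC <- matrix(rbinom(nb * d, 1, keep) / keep, nb, d)
          masks$subD <- matrix(rbinom(nb * d, 1, keep) / keep, nb, d)
        }
        if (config$dropoutFnn > 0) {
          keep <- 1 - config$dropoutFnn
          masks$fnn1 <- matrix(rbinom(nb * h, 1, keep) / keep, nb, h)
          masks$fnn2 <- matrix(rbinom(nb * h, 1, keep) / keep, nb, h)
        }
        lg <- lossGrad(params, buffers, struct, S, train = TRUE, masks = masks)
        grads <- applyWeightDecay(lg$grads, params, config$weightDecay)
        g <- flattenParams(grads)
        t <- t + 1L
        mAdam <- b1 * mAdam + (1 - b1) * g
        vAdam <- b2 * vAdam + (1 - b2) * g^2
        mhat <- mAdam / (1 - b1^t)
        vhat <- vAdam / (1 - b2^t)
        theta <- flattenParams(params) - lr * mhat / (sqrt(vhat) + eps)
        params <- unflattenParams(theta, skel)
        buffers$mean <- (1 - momentum) * buffers$mean +
          momentum * lg$batchStats$mean
        buffers$var <- (1 - momentum) * buffers$var +
          momentum * lg$batchStats$var
        epochLoss <- epochLoss + lg$loss * nb
      }
      row <- data.frame(epoch = epoch, lr = lr,
                        train_loss = epochLoss / length(trainIdx),
                        val_auprc = NA_real_, val_auroc = NA_real_)
      if (!is.null(valIdx) && length(valIdx)) {
        fwd <- modelForward(params, buffers, struct, valIdx, train = FALSE)
        sc <- plogis(fwd$logit)
        yv <- struct$labels[valIdx]
        if (any(yv == 1)) row$val_auprc <- auprc(sc, yv)
        if (any(yv == 1) && any(yv == 0)) row$val_auroc <- auroc(sc, yv)
        if (!is.na(row$val_auprc) && row$val_auprc > best$metric)
          best <- list(params = params, buffers = buffers,
                       metric = row$val_auprc)
      }
      history[[epoch]] <- row
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val AUPRC %s", epoch,
                        row$train_loss,
                        ifelse(is.na(row$val_auprc), "-",
                               sprintf("%.3f", row$val_auprc))))
    }
  })

  if (is.null(valIdx) || best$metric == -Inf)
    best <- list(params = params, buffers = buffers)
  hist <- if (length(history)) do.call(rbind, history) else
    data.frame(epoch = integer(0), lr = numeric(0), train_loss = numeric(0),
               val_auprc = numeric(0), val_auroc = numeric(0))
  new("HypergraphSynergyModel", params = best$params, buffers = best$buffers,
      config = config, vocab = vocab, history = hist,
      cellHg = cellHg, drugHg = drugHg)
}

#' Predict synergy probabilities
#'
#' Runs the trained model in evaluation mode (running batch-norm
#' statistics, no dropout) on a feature bundle built against the same
#' hypergraphs the model was trained on, returning per-sample synergy
#' probabilities. Evaluation mode is deterministic: repeated calls give
#' identical scores.
#'
#' @param model a [HypergraphSynergyModel-class].
#' @param features feature bundle from [buildSampleFeatures()].
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictSynergy <- function(model, features) {
  struct <- makeModelStruct(features, model@cellHg, model@drugHg,
                            modelConfig(model))
  fwd <- modelForward(model@params, model@buffers, struct,
                      seq_along(struct$labels), train = FALSE)
  plogis(fwd$logit)
}

#' Extract per-subject attention weights
#'
#' Runs the model in evaluation mode and returns the subgraph attention
#' weights over the requested hypergraph's nodes: a subjects x nodes
#' matrix whose rows sum to one over each subject's support and are zero
#' elsewhere. These are the weights the interpretation analysis
#' multiplies with the subject features (see [weightedSubgraph()]).
#'
#' @param model a [HypergraphSynergyModel-class].
#' @param features feature bundle from [buildSampleFeatures()].
#' @param which `"cell"` for the gene-set hypergraph or `"drug"` for
#'   the drug hypergraph.
#' @return dense subjects x nodes attention matrix.
#' @export
subjectAttention <- function(model, features, which = c("cell", "drug")) {
  which <- match.arg(which)
  struct <- makeModelStruct(features, model@cellHg, model@drugHg,
                            modelConfig(model))
  S <- seq_along(struct$labels)
  fwd <- modelForward(model@params, model@buffers, struct, S, train = FALSE)
  hg <- if (which == "cell") model@cellHg else model@drugHg
  bp <- if (which == "cell") fwd$cache$bpc else fwd$cache$bpd
  a <- if (which == "cell") fwd$cache$sc$a else fwd$cache$sd$a
  out <- matrix(0, length(S), length(nodeNames(hg)),
                dimnames = list(subjectIds(if (which == "cell")
                  features$cell else features$drug), nodeNames(hg)))
  out[cbind(bp$pj, bp$pi)] <- a
  out
}
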
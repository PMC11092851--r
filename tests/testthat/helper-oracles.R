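## Independent brute-force oracles: explicit loops, no shared code with
## the package implementations they check.

bruteAP <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  ap <- 0
  prevRec <- 0
  for (t in thr) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    prec <- tp / (tp + fp)
    rec <- tp / P
    ap <- ap + (rec - prevRec) * prec
    prevRec <- rec
  }
  ap
}

bruteAUROC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## U statistic by direct pair counting
bruteU <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  u
}

## exact two-sided Mann-Whitney p by enumeration of group assignments
bruteMWp <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  uObs <- bruteU(x, y)
  mid <- n * m / 2
  combs <- combn(n + m, n)
  hits <- 0
  for (k in seq_len(ncol(combs))) {
    xi <- pooled[combs[, k]]
    yi <- pooled[-combs[, k]]
    if (abs(bruteU(xi, yi) - mid) >= abs(uObs - mid) - 1e-9) hits <- hits + 1
  }
  hits / ncol(combs)
}

bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in seq(m, 1)) {
    running <- min(running, p[o[i]] * m / i)
    q[o[i]] <- min(running, 1)
  }
  q
}

## one dual-attention message-passing layer by explicit loops
bruteLayer <- function(M, HV, HE, W, C) {
  nV <- nrow(M); nE <- ncol(M); d <- ncol(HV)
  z <- matrix(NA_real_, nV, nE)
  for (g in seq_len(nV)) for (p in seq_len(nE)) if (M[g, p] == 1) {
    s <- tanh(as.vector(W %*% c(HV[g, ], HE[p, ])))
    z[g, p] <- sum(C * s)
  }
  HEk <- matrix(0, nE, d)
  for (p in seq_len(nE)) {
    nodes <- which(M[, p] == 1)
    w <- exp(z[nodes, p] - max(z[nodes, p]))
    w <- w / sum(w)
    acc <- rep(0, d)
    for (k in seq_along(nodes)) acc <- acc + w[k] * HV[nodes[k], ]
    HEk[p, ] <- pmax(acc, 0)
  }
  HVk <- matrix(0, nV, d)
  for (g in seq_len(nV)) {
    edges <- which(M[g, ] == 1)
    w <- exp(z[g, edges] - max(z[g, edges]))
    w <- w / sum(w)
    acc <- rep(0, d)
    for (k in seq_along(edges)) acc <- acc + w[k] * HE[edges[k], ]
    HVk[g, ] <- pmax(acc, 0)
  }
  list(HV = HVk, HE = HEk)
}

## subgraph attention embedding by explicit loops
bruteSubgraph <- function(fRow, HV, b) {
  sup <- which(fRow != 0)
  sc <- numeric(length(sup))
  for (k in seq_along(sup))
    sc[k] <- fRow[sup[k]] * sum(b * HV[sup[k], ])
  w <- exp(sc - max(sc))
  w <- w / sum(w)
  acc <- rep(0, ncol(HV))
  for (k in seq_along(sup)) acc <- acc + w[k] * HV[sup[k], ]
  pmax(acc, 0)
}

## random valid incidence matrix: no empty edge, no isolated node
randomIncidence <- function(nV, nE) {
  repeat {
    M <- matrix(rbinom(nV * nE, 1, 0.45), nV, nE)
    if (all(colSums(M) > 0) && all(rowSums(M) > 0)) break
  }
  dimnames(M) <- list(paste0("n", seq_len(nV)), paste0("e", seq_len(nE)))
  M
}
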
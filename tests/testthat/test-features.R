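test_that("ssGSEA matches the frozen independent reference within 1e-6", {
  fx <- referenceExprFixture()
  nes <- ssgsea(fx$expr, fx$gsc)
  expect_lt(max(abs(unname(nes) - unname(referenceNesExpected()))), 1e-6)
})

test_that("ssGSEA enrichment matches the hand-computed running sum on 4 genes", {
  expr <- matrix(c(4, 3, 2, 1, 1, 2, 3, 4), 4, 2,
                 dimnames = list(paste0("G", 1:4), c("s1", "s2")))
  gsc <- GeneSetCollection(list(TOP2 = c("G1", "G2")))
  ## sample 1, set = top-2 genes: positions (hit, hit, miss, miss);
  ## weighted in-set CDF steps 4^w/(4^w+3^w) then 1; out-of-set 0, 0, .5, 1
  w <- 0.25
  es1 <- 4^w / (4^w + 3^w) + 1 + 0.5 + 0
  ## sample 2 reversed: hits at the bottom
  es2 <- (0 - 0.5) + (0 - 1) + (2^w / (2^w + 1) - 1) + 0
  expected <- c(es1, es2) / (es1 - es2)
  nes <- ssgsea(expr, gsc)
  expect_equal(as.numeric(nes), expected, tolerance = 1e-12)
})

test_that("ssGSEA is invariant to gene-row permutation and drops non-overlapping sets", {
  fx <- referenceExprFixture()
  perm <- sample(nrow(fx$expr))
  expect_equal(ssgsea(fx$expr[perm, ], fx$gsc), ssgsea(fx$expr, fx$gsc))

  withAlien <- GeneSetCollection(c(geneSets(fx$gsc),
                                   list(ALIEN = c("ZZZ1", "ZZZ2"))))
  expect_warning(nes <- ssgsea(fx$expr, withAlien), "no usable overlap")
  expect_false("ALIEN" %in% colnames(nes))
})

test_that("gene-set hypergraph: sets are nodes, genes are hyperedges", {
  gsc <- GeneSetCollection(list(S1 = c("A", "B"), S2 = c("B", "C")))
  hg <- buildGenesetHypergraph(gsc)
  expect_equal(dim(hg), c(2L, 3L))
  expect_equal(as.numeric(incidence(hg)["S1", ]), c(1, 1, 0))
  expect_equal(as.numeric(incidence(hg)[, "B"]), c(1, 1))

  ## disjoint sets give block-diagonal incidence
  dj <- buildGenesetHypergraph(GeneSetCollection(
    list(S1 = c("A", "B"), S2 = c("C", "D"))))
  m <- incidence(dj)
  expect_equal(sum(m["S1", c("C", "D")]) + sum(m["S2", c("A", "B")]), 0)

  ## incidence column sums equal each gene's set-membership count
  set.seed(1)
  sets <- lapply(1:6, function(i) sample(LETTERS[1:12], sample(2:6, 1)))
  names(sets) <- paste0("S", 1:6)
  gsc2 <- GeneSetCollection(sets)
  hg2 <- buildGenesetHypergraph(gsc2)
  counts <- vapply(colnames(incidence(hg2)), function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))), numeric(1))
  expect_equal(Matrix::colSums(incidence(hg2)), counts)

  ## transposed orientation swaps the axes
  tr <- buildGenesetHypergraph(gsc, transpose = TRUE)
  expect_equal(dim(tr), c(3L, 2L))
})

test_that("k-mer tokenization slides a window and keeps short strings whole", {
  expect_equal(kmerTokenize("ABCD", 3), c("ABC", "BCD"))
  expect_equal(kmerTokenize("CCO", 9), "CCO")
  expect_error(kmerTokenize("", 3), "empty SMILES")

  ## token count before dedup is max(1, len - k + 1): brute force
  set.seed(2)
  for (i in 1:50) {
    len <- sample(1:20, 1)
    k <- sample(1:12, 1)
    s <- paste(sample(c("C", "c", "O", "N", "1", "(", ")"), len, TRUE),
               collapse = "")
    all_windows <- if (len < k) s else
      vapply(1:(len - k + 1), function(j) substr(s, j, j + k - 1), "")
    expect_equal(length(all_windows), max(1, len - k + 1))
    expect_setequal(kmerTokenize(s, k), unique(all_windows))
  }
})

test_that("drug hypergraph joins k-mer nodes and overlapping gene-set nodes", {
  drugs <- data.frame(name = c("d1", "d2", "d3"),
                      smiles = c("CCOC", "CCOC", "NNCC"),
                      stringsAsFactors = FALSE)
  drugs$genes <- list("G1", character(0), c("G9", "G4"))
  gsc <- GeneSetCollection(list(S1 = c("G1", "G2"), S2 = c("G3", "G4"),
                                S3 = c("G7", "G8")))
  hg <- buildDrugHypergraph(drugs, gsc, k = 3)
  m <- incidence(hg)
  expect_equal(as.numeric(m["set:S1", "d1"]), 1)
  expect_equal(as.numeric(m["set:S2", "d3"]), 1)
  expect_false("set:S3" %in% rownames(m))
  ## identical SMILES give identical token incidence columns
  tok <- grep("^kmer:", rownames(m))
  expect_equal(m[tok, "d1"], m[tok, "d2"])
  ## node count = |unique tokens| + |overlapping sets|
  uniqTok <- unique(c(kmerTokenize("CCOC", 3), kmerTokenize("NNCC", 3)))
  expect_equal(nrow(m), length(uniqTok) + 2L)
})

test_that("cell dose injection scales NES by the summed dose, linearly", {
  nes <- c(S1 = 0.5, S2 = -0.2)
  expect_equal(unname(doseInjectCell(nes, 2, 3)["S1"]), 2.5)
  expect_warning(z <- doseInjectCell(nes, 0, 0), "zero")
  expect_equal(unname(z), c(0, 0))
  expect_equal(doseInjectCell(nes, 4, 6), 2 * doseInjectCell(nes, 2, 3))
})

test_that("drug-pair dose injection adds shared-node contributions", {
  m <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2,
              dimnames = list(c("n1", "n2", "n3"), c("dA", "dB")))
  hg <- IncidenceHypergraph(m)
  f <- doseInjectDrugPair(hg, "dA", "dB", 2, 3)
  expect_equal(f, c(2, 3, 5))  # only-A, only-B, shared
  expect_error(doseInjectDrugPair(hg, "dA", "nope", 1, 1), "unknown drug")
})

test_that("one-hot covariates encode doses and phenotypes with unseen-zero blocks", {
  samples <- data.frame(dose_a = c(1, 10), dose_b = c(100, 10),
                        cell = c("c1", "c2"), stringsAsFactors = FALSE)
  meta <- data.frame(cell = c("c1", "c2"), tissue = c("lung", "breast"),
                     gender = c("F", "M"), age = c(34, 67),
                     stringsAsFactors = FALSE)
  vocab <- buildCovariateVocab(samples, meta)
  expect_equal(vocab$dose, c(1, 10, 100))
  enc <- encodeCovariates(samples, vocab, meta)
  expect_equal(ncol(enc), 2 * 3 + 2 + 2 + 2)
  expect_equal(unname(enc[2, 1:3]), c(0, 1, 0))     # dose_a = 10
  expect_equal(unname(enc[1, 4:6]), c(0, 0, 1))     # dose_b = 100

  unseen <- data.frame(dose_a = 55, dose_b = 10, cell = "c3",
                       stringsAsFactors = FALSE)
  encU <- encodeCovariates(unseen, vocab,
                           rbind(meta, data.frame(cell = "c3",
                                                  tissue = "kidney",
                                                  gender = "F", age = 101)))
  expect_equal(unname(encU[1, 1:3]), c(0, 0, 0))    # unseen dose
  expect_equal(sum(encU[1, 7:8]), 0)                # unseen tissue
})

test_that("feature bundle aligns axes and injects transformed doses", {
  gsc <- GeneSetCollection(list(S1 = c("A", "B"), S2 = c("B", "C")))
  cellHg <- buildGenesetHypergraph(gsc)
  drugs <- data.frame(name = c("d1", "d2"), smiles = c("CCOC", "NNCC"),
                      stringsAsFactors = FALSE)
  drugs$genes <- list("A", "C")
  drugHg <- buildDrugHypergraph(drugs, gsc, k = 3)
  nes <- matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2,
                dimnames = list(c("c1", "c2"), c("S1", "S2")))
  samples <- data.frame(drug_a = "d1", drug_b = "d2", cell = "c1",
                        dose_a = 9, dose_b = 99, label = 1L,
                        triplet = "d1||d2||c1", stringsAsFactors = FALSE)
  vocab <- buildCovariateVocab(samples)
  fb <- buildSampleFeatures(samples, nes, cellHg, drugHg, vocab)
  expect_equal(colnames(featureValues(fb$cell)), nodeNames(cellHg))
  ## (log10(10) + log10(100)) * NES
  expect_equal(unname(featureValues(fb$cell)[1, "S1"]), 3 * 0.5)
  ## drug feature: d1 token nodes get log10(10) = 1
  m <- featureValues(fb$drug)
  expect_equal(unname(m[1, "kmer:CCO"]), 1)
  expect_equal(unname(m[1, "kmer:NNC"]), 2)
  expect_equal(unname(m[1, "set:S1"]), 1)
})
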
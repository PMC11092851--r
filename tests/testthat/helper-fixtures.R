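## small deterministic fixtures shared across test files

tinySynergyCsv <- function(path, rows) {
  header <- paste(c("drug_a", "drug_b", "cell", "dose_a", "dose_b",
                    "inhibition", "bliss", "hsa", "loewe", "zip", "study"),
                  collapse = ",")
  writeLines(c(header, rows), path)
  path
}

## the 50-gene fixture whose NES values were frozen from an independent
## single-sample GSEA implementation (rank normalisation, weight 0.25)
referenceExprFixture <- function() {
  set.seed(7)
  genes <- sprintf("G%03d", 1:50)
  expr <- matrix(round(runif(50 * 4, 0, 12), 4), 50, 4,
                 dimnames = list(genes, paste0("S", 1:4)))
  sets <- list(A = genes[1:8], B = genes[c(5, 10, 15, 20, 25, 30)],
               C = genes[41:50], D = genes[seq(2, 40, 4)],
               E = genes[c(3, 7, 11, 44)])
  list(expr = expr, gsc = GeneSetCollection(sets))
}

referenceNesExpected <- function() {
  rbind(
    S1 = c(0.0678343692, -0.0038229586, 0.2739774107, -0.2765196115, -0.4221043803),
    S2 = c(0.1674431591, 0.1183354013, 0.0419055494, 0.3519629107, -0.2413438845),
    S3 = c(-0.1510638601, 0.0394663274, 0.0314803049, -0.1202104706, 0.2492547368),
    S4 = c(-0.0606087233, 0.1348801112, -0.0034055465, 0.5778956197, -0.1112068929))
}

## minimal feature bundle over random tiny hypergraphs, for model tests
tinyModelSetup <- function(n = 4, seed = 42, covDim = 3) {
  set.seed(seed)
  cellHg <- IncidenceHypergraph(randomIncidence(5, 7))
  drugHg <- IncidenceHypergraph(randomIncidence(6, 4))
  Fc <- matrix(rnorm(n * 5), n, 5,
               dimnames = list(paste0("s", 1:n), nodeNames(cellHg)))
  Fd <- matrix(rnorm(n * 6), n, 6,
               dimnames = list(paste0("s", 1:n), nodeNames(drugHg)))
  cov <- matrix(rnorm(n * covDim), n, covDim)
  labels <- rep_len(c(0, 1), n)
  features <- list(cell = SubjectFeatures(Fc, cellHg),
                   drug = SubjectFeatures(Fd, drugHg),
                   cov = cov, labels = labels,
                   triplet = paste0("t", rep_len(1:2, n)))
  list(cellHg = cellHg, drugHg = drugHg, features = features)
}
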
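baseRecord <- function(...) {
  r <- data.frame(drug_a = "A", drug_b = "B", cell = "c1",
                  dose_a = 1, dose_b = 1, inhibition = 20,
                  bliss = 15, hsa = 15, loewe = 15, zip = 15,
                  study = "s1", stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) r[[nm]] <- args[[nm]]
  r
}

toyDrugs <- function() {
  d <- data.frame(name = c("A", "B", "X-001", "lapatinib"),
                  smiles = c("CCO", "CCN", "c1ccccc1N", "c1ccccc1N"),
                  stringsAsFactors = FALSE)
  d$genes <- list("EGFR", "MYC", "ERBB2", "ERBB2")
  d
}

test_that("drugs sharing a SMILES unify to one canonical id", {
  rec <- rbind(baseRecord(drug_a = "X-001", drug_b = "A"),
               baseRecord(drug_a = "lapatinib", drug_b = "A"))
  out <- unifyDrugs(rec, toyDrugs())
  expect_equal(out$drug_b, c("X-001", "X-001"))  # canonical: min alias
  expect_equal(out$triplet[1], out$triplet[2])
})

test_that("unknown drugs are dropped and logged", {
  rec <- rbind(baseRecord(), baseRecord(drug_a = "mystery"))
  out <- unifyDrugs(rec, toyDrugs())
  expect_equal(nrow(out), 1L)
  rep <- parseReport(out)
  expect_equal(rep$dropped, 1L)
  expect_equal(rep$unresolved_drugs, "mystery")
})

test_that("pair order is canonical: (B,A) and (A,B) share a triplet key with doses swapped", {
  rec <- rbind(baseRecord(drug_a = "A", drug_b = "B", dose_a = 1, dose_b = 2),
               baseRecord(drug_a = "B", drug_b = "A", dose_a = 2, dose_b = 1))
  out <- unifyDrugs(rec, toyDrugs())
  expect_equal(out$triplet[1], out$triplet[2])
  expect_equal(out$dose_a, c(1, 1))
  expect_equal(out$dose_b, c(2, 2))
})

test_that("replicate averaging means the scores and merges study tags", {
  rec <- unifyDrugs(rbind(baseRecord(loewe = 8), baseRecord(loewe = 12)),
                    toyDrugs())
  out <- averageReplicates(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$loewe, 10)

  ## no replicates: identity (up to ordering)
  rec2 <- unifyDrugs(rbind(baseRecord(dose_a = 1), baseRecord(dose_a = 2)),
                     toyDrugs())
  expect_equal(nrow(averageReplicates(rec2)), 2L)

  ## three replicates of mixed studies: single record, manual means
  rec3 <- unifyDrugs(rbind(baseRecord(loewe = 6, bliss = 3, study = "s2"),
                           baseRecord(loewe = 12, bliss = 6, study = "s1"),
                           baseRecord(loewe = 18, bliss = 0, study = "s1")),
                     toyDrugs())
  out3 <- averageReplicates(rec3)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$loewe, (6 + 12 + 18) / 3)
  expect_equal(out3$bliss, 3)
  expect_equal(out3$study, "s1;s2")
})

test_that("additive filter removes records with all four scores inside [-10, 10]", {
  keepers <- filterAdditive(rbind(
    baseRecord(bliss = 5, hsa = 3, loewe = -2, zip = 8),    # all inside
    baseRecord(bliss = 5, hsa = 3, loewe = 15, zip = 8),    # loewe outside
    baseRecord(bliss = 10, hsa = 10, loewe = 10, zip = 10)  # closed boundary
  ))
  expect_equal(nrow(keepers), 1L)
  expect_equal(keepers$loewe, 15)
})

test_that("non-inhibitory filter needs full synergy agreement AND negative inhibition", {
  out <- filterNonInhibitory(rbind(
    baseRecord(bliss = 12, hsa = 14, loewe = 11, zip = 13, inhibition = -5),
    baseRecord(bliss = 12, hsa = 14, loewe = 11, zip = 13, inhibition = 20),
    baseRecord(bliss = 12, hsa = -14, loewe = 11, zip = 13, inhibition = -5)))
  expect_equal(nrow(out), 2L)
  expect_false(any(out$inhibition == -5 & out$hsa > 0))
})

test_that("binarization thresholds LOEWE at +/-10 and excludes the middle", {
  rec <- rbind(baseRecord(loewe = 15), baseRecord(loewe = -15),
               baseRecord(loewe = 9, bliss = 20))
  out <- binarizeLabels(rec)
  expect_equal(out$label, c(1L, 0L))
  expect_equal(parseReport(out)$dropped, 1L)
  expect_equal(parseReport(out)$reason, "loewe-indeterminate")
})

test_that("non-cancer screens are removed by study tag, case-insensitively", {
  rec <- rbind(baseRecord(study = "oneil"), baseRecord(study = "Malaria"),
               baseRecord(study = "s1;sars-cov-2"))
  expect_equal(filterNonCancer(rec)$study, "oneil")
})

test_that("worked five-record fixture curates to exactly two labelled samples", {
  fx <- workedPipelineFixture()
  res <- curateSamples(fx$records, fx$drugs)
  expect_equal(nrow(res$samples), 2L)
  expect_equal(sort(res$samples$label), c(0L, 1L))

  cnt <- res$report$counts
  expect_equal(unname(cnt["input"]), 5)
  expect_equal(unname(cnt["after_label_binarization"]), 2)
  ## counts monotone non-increasing
  expect_true(all(diff(cnt) <= 0))
  ## every removal attributed to exactly one rule
  expect_equal(sum(res$report$excluded), 5 - 2)
  expect_equal(unname(res$report$excluded[c("additive", "non_inhibitory",
                                            "loewe_indeterminate")]),
               c(1, 1, 1))
})

test_that("curation is idempotent and order-independent", {
  fx <- workedPipelineFixture()
  once <- curateSamples(fx$records, fx$drugs)$samples
  twice <- curateSamples(once, fx$drugs)$samples
  attr(once, "parse_report") <- attr(twice, "parse_report") <- NULL
  expect_equal(twice[names(once)], once)

  perm <- fx$records[c(4, 1, 5, 3, 2), ]
  permuted <- curateSamples(perm, fx$drugs)$samples
  o1 <- once[order(once$triplet, once$dose_a, once$dose_b), ]
  o2 <- permuted[order(permuted$triplet, permuted$dose_a, permuted$dose_b), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o2, o1, ignore_attr = "parse_report")
})

test_that("gene-set size filter keeps sizes within one sample SD of the mean", {
  gsc <- GeneSetCollection(list(
    A = paste0("G", 1:10), B = paste0("G", 1:20), C = paste0("G", 1:30),
    D = paste0("G", 1:40), E = paste0("G", 1:100)))
  ## sizes 10,20,30,40,100: mean 40, sample sd sqrt(1250) ~ 35.36
  out <- filterGeneSets(gsc)
  expect_equal(names(geneSets(out)), c("A", "B", "C", "D"))
  expect_equal(unname(attr(out, "size_bounds")),
               c(40 - sqrt(1250), 40 + sqrt(1250)))

  same <- GeneSetCollection(list(A = paste0("G", 1:5), B = paste0("H", 1:5),
                                 C = paste0("K", 1:5)))
  expect_equal(length(filterGeneSets(same)), 3L)

  two <- GeneSetCollection(list(A = paste0("G", 1:5), B = paste0("H", 1:5)))
  expect_equal(length(filterGeneSets(two)), 2L)
})
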
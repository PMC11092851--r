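#' Unify drug identities by SMILES
#'
#' Screens code the same compound under serial numbers, generic names or
#' chemical names. To avoid leakage across such aliases, every drug name
#' is resolved to its SMILES string and all names sharing one SMILES are
#' mapped to a single canonical id (the lexicographically smallest alias).
#' The drug pair is then ordered lexicographically by canonical id, with
#' the dose columns swapped alongside, so that (A, B) and (B, A) records
#' of the same measurement collapse onto one triplet key.
#'
#' Records whose drug name cannot be resolved are dropped and listed in
#' the attached [parseReport()].
#'
#' @param records synergy-record data.frame (see [readSynergyTable()]).
#' @param drugs drug table (see [readDrugTable()]).
#' @return records with canonical `drug_a`/`drug_b` (ordered), a
#'   `triplet` key column, and a parse report.
#' @export
unifyDrugs <- function(records, drugs) {
  smiles <- stats::setNames(drugs$smiles, drugs$name)
  ## canonical alias chosen in C-locale order for platform independence
  canon <- vapply(split(drugs$name, drugs$smiles), function(nms)
    sort(nms, method = "radix")[1L], character(1))
  idOf <- stats::setNames(canon[smiles], names(smiles))

  total <- nrow(records)
  known <- records$drug_a %in% names(idOf) & records$drug_b %in% names(idOf)
  unknown <- unique(c(records$drug_a[!records$drug_a %in% names(idOf)],
                      records$drug_b[!records$drug_b %in% names(idOf)]))
  rec <- records[known, , drop = FALSE]
  if (nrow(rec)) {
    a <- unname(idOf[rec$drug_a])
    b <- unname(idOf[rec$drug_b])
    ord <- sort(unique(c(a, b)), method = "radix")
    swap <- match(a, ord) > match(b, ord)
    rec$drug_a <- ifelse(swap, b, a)
    rec$drug_b <- ifelse(swap, a, b)
    da <- rec$dose_a
    rec$dose_a[swap] <- rec$dose_b[swap]
    rec$dose_b[swap] <- da[swap]
  }
  rec$triplet <- tripletKey(rec$drug_a, rec$drug_b, rec$cell)
  rownames(rec) <- NULL
  attr(rec, "parse_report") <- list(total = total, kept = nrow(rec),
                                    dropped = total - nrow(rec),
                                    unresolved_drugs = unknown)
  rec
}

#' Average experimental replicates
#'
#' Replicates are records with identical (canonical triplet, dose A,
#' dose B). Each replicate group collapses to one record whose percent
#' inhibition and four synergy scores are arithmetic means; study tags
#' are merged (unique, sorted, semicolon-separated).
#'
#' @param records unified synergy records (see [unifyDrugs()]).
#' @return one record per (triplet, dose pair).
#' @export
averageReplicates <- function(records) {
  if (nrow(records) == 0L) return(records)
  if (is.null(records$triplet))
    records$triplet <- tripletKey(records$drug_a, records$drug_b, records$cell)
  key <- paste(records$triplet, records$dose_a, records$dose_b, sep = "@")
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(i) {
    r <- records[i[1L], , drop = FALSE]
    for (col in c("inhibition", scoreColumns()))
      r[[col]] <- mean(records[[col]][i])
    r$study <- paste(sort(unique(records$study[i])), collapse = ";")
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$triplet, out$dose_a, out$dose_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove non-cancer screens
#'
#' Drops records whose study tag matches a configurable blacklist of
#' non-cancer screen tags (matching is case-insensitive on any
#' semicolon-separated component of the merged study tag).
#'
#' @param records synergy records.
#' @param blacklist character vector of study/disease tags to remove.
#' @return filtered records.
#' @export
filterNonCancer <- function(records, blacklist = c("malaria", "SARS-COV-2")) {
  if (nrow(records) == 0L || length(blacklist) == 0L) return(records)
  bl <- toupper(blacklist)
  hit <- vapply(strsplit(toupper(records$study), ";", fixed = TRUE),
                function(tags) any(tags %in% bl), logical(1))
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove additive samples
#'
#' A record is additive — neither synergistic nor antagonistic — when all
#' four synergy scores (BLISS, HSA/I, LOEWE, ZIP) lie within the closed
#' interval \[-10, 10\]. Such records are excluded: the classification
#' target is deviation from additivity.
#'
#' @param records synergy records.
#' @return records with additive rows removed.
#' @export
filterAdditive <- function(records) {
  if (nrow(records) == 0L) return(records)
  s <- as.matrix(records[, scoreColumns(), drop = FALSE])
  additive <- rowSums(s >= -10 & s <= 10) == 4L
  out <- records[!additive, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove non-inhibitory "synergy"
#'
#' Records in full agreement on synergy (all four scores above 10) that
#' nevertheless fail to kill cells (percent inhibition below 0 relative
#' to the untreated control) are artefacts outside the prediction target
#' and are excluded.
#'
#' @param records synergy records.
#' @return filtered records.
#' @export
filterNonInhibitory <- function(records) {
  if (nrow(records) == 0L) return(records)
  s <- as.matrix(records[, scoreColumns(), drop = FALSE])
  bad <- rowSums(s > 10) == 4L & records$inhibition < 0
  out <- records[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binarize LOEWE scores into synergy labels
#'
#' LOEWE > 10 labels a record synergistic (1); LOEWE < -10 antagonistic
#' (0). Records in between (possible when another score kept them past
#' the additive filter) carry no label and are excluded with reason
#' `loewe-indeterminate`.
#'
#' @param records post-filter synergy records.
#' @return labelled samples: records plus `label` and `triplet` columns,
#'   with a [parseReport()] counting indeterminate exclusions.
#' @export
binarizeLabels <- function(records) {
  total <- nrow(records)
  if (is.null(records$triplet) && total > 0L)
    records$triplet <- tripletKey(records$drug_a, records$drug_b, records$cell)
  keep <- records$loewe > 10 | records$loewe < -10
  out <- records[keep, , drop = FALSE]
  out$label <- as.integer(out$loewe > 10)
  rownames(out) <- NULL
  attr(out, "parse_report") <- list(total = total, kept = nrow(out),
                                    dropped = total - nrow(out),
                                    reason = "loewe-indeterminate")
  out
}

#' Full sample-curation pipeline
#'
#' Applies, in order: drug unification (canonical ids, pair ordering),
#' replicate averaging, the non-cancer study filter, the additive
#' exclusion, the non-inhibitory exclusion, and LOEWE label
#' binarization. Averaging precedes the score filters so that exclusions
#' act on replicate-mean scores. The pipeline is idempotent and
#' order-independent in its input records.
#'
#' @param records raw synergy records.
#' @param drugs drug table used for SMILES-based unification.
#' @param blacklist non-cancer study tags, see [filterNonCancer()].
#' @return list with `samples` (labelled data.frame) and `report`, a
#'   `CurationReport`: per-stage record counts (monotone non-increasing)
#'   and an exclusion log attributing every removal to one rule.
#' @export
#' @examples
#' fx <- workedPipelineFixture()
#' curateSamples(fx$records, fx$drugs)$report
curateSamples <- function(records, drugs,
                          blacklist = c("malaria", "SARS-COV-2")) {
  counts <- c(input = nrow(records))
  log <- list()

  uni <- unifyDrugs(records, drugs)
  rep0 <- parseReport(uni)
  if (rep0$dropped > 0L)
    log$unresolvable_drug <- rep0$dropped
  counts["after_drug_unification"] <- nrow(uni)

  avg <- averageReplicates(uni)
  log$replicate_collapsed <- nrow(uni) - nrow(avg)
  counts["after_replicate_averaging"] <- nrow(avg)

  canc <- filterNonCancer(avg, blacklist)
  log$non_cancer <- nrow(avg) - nrow(canc)
  counts["after_noncancer_filter"] <- nrow(canc)

  nadd <- filterAdditive(canc)
  log$additive <- nrow(canc) - nrow(nadd)
  counts["after_additive_filter"] <- nrow(nadd)

  ninh <- filterNonInhibitory(nadd)
  log$non_inhibitory <- nrow(nadd) - nrow(ninh)
  counts["after_noninhibitory_filter"] <- nrow(ninh)

  lab <- binarizeLabels(ninh)
  log$loewe_indeterminate <- nrow(ninh) - nrow(lab)
  counts["after_label_binarization"] <- nrow(lab)

  report <- structure(list(counts = counts, excluded = unlist(log)),
                      class = "CurationReport")
  list(samples = lab, report = report)
}

#' @export
print.CurationReport <- function(x, ...) {
  cat("Curation report\n  stage counts:\n")
  for (nm in names(x$counts))
    cat(sprintf("    %-28s %d\n", nm, x$counts[[nm]]))
  cat("  exclusions by rule:\n")
  for (nm in names(x$excluded))
    cat(sprintf("    %-28s %d\n", nm, x$excluded[[nm]]))
  invisible(x)
}

#' Filter gene sets by size
#'
#' Retains gene sets whose size lies within one standard deviation of
#' the mean set size (closed interval, sample standard deviation);
#' over-broad and near-empty sets are removed before hypergraph
#' construction.
#'
#' @param x a [GeneSetCollection-class] with at least two sets.
#' @return the filtered collection, with attribute `size_bounds`.
#' @export
#' @examples
#' gsc <- GeneSetCollection(list(
#'   A = paste0("G", 1:10), B = paste0("G", 1:20), C = paste0("G", 1:30),
#'   D = paste0("G", 1:40), E = paste0("G", 1:100)))
#' length(filterGeneSets(gsc))  # the size-100 outlier is removed
filterGeneSets <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  sizes <- setSizes(x)
  if (length(sizes) < 2L)
    stopf("need at least two gene sets to estimate the size distribution")
  m <- mean(sizes)
  s <- stats::sd(sizes)
  keep <- sizes >= m - s & sizes <= m + s
  if (!any(keep)) stopf("size filter removed every gene set")
  out <- GeneSetCollection(geneSets(x)[keep])
  attr(out, "size_bounds") <- c(lower = m - s, upper = m + s)
  out
}
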
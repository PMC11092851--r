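#' @importClassesFrom Matrix Matrix
NULL

#' Read and write GMT gene-set files
#'
#' `readGmt()` parses the tab-separated GMT dialect (one set per line:
#' name, description, then member genes). Gene symbols are upper-cased at
#' ingest because upstream sources mix capitalisation; duplicate genes
#' within a set are dropped keeping the first occurrence. A duplicated
#' set name or an empty set is a format error. `writeGmt()` is the
#' lossless inverse.
#'
#' @param path file path.
#' @param x a [GeneSetCollection-class].
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled `"na"` otherwise).
#' @return `readGmt()` a `GeneSetCollection`; `writeGmt()` the path,
#'   invisibly.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("S1\tdesc\tA\tB\tA", tf)
#' geneSets(readGmt(tf))
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("GMT file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stopf("duplicate gene-set name(s) in '%s': %s", path,
          paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- toupper(genes[nzchar(genes)])
    if (length(genes) == 0L)
      stopf("empty gene set '%s' in '%s'", f[[1L]], path)
    genes[!duplicated(genes)]
  })
  names(sets) <- nms
  GeneSetCollection(sets)
}

#' @rdname readGmt
#' @export
writeGmt <- function(x, path, descriptions = NULL) {
  stopifnot(is(x, "GeneSetCollection"))
  sets <- geneSets(x)
  desc <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sets), desc, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write expression matrices
#'
#' Tab-separated matrix with gene symbols in the first column and
#' cell-line ids as the header; values are expected on the log2(TPM+1)
#' scale. Duplicate gene rows and non-numeric cells are format errors
#' (the downstream enrichment is rank-based, so silent coercion would
#' corrupt ranks). Gene symbols are upper-cased at ingest.
#'
#' @param path file path.
#' @param x numeric matrix, genes in rows (rownames), cell lines in
#'   columns (colnames).
#' @return `readExpression()` a genes x cells numeric matrix.
#' @export
readExpression <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stopf("expression file '%s' has no sample columns", path)
  genes <- toupper(df[[1L]])
  if (anyDuplicated(genes))
    stopf("duplicate gene row(s) in '%s': %s", path,
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num))
    stopf("non-numeric expression value(s) in '%s'", path)
  dimnames(num) <- list(genes, colnames(df)[-1L])
  num
}

#' @rdname readExpression
#' @export
writeExpression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse reports
#'
#' Readers and curation steps attach a parse/curation report accounting
#' for every input row (`kept + dropped == total`).
#'
#' @param x an object returned by a reader.
#' @return a list with elements `total`, `kept`, `dropped` (and possibly
#'   a `reasons` table), or `NULL`.
#' @export
parseReport <- function(x) attr(x, "parse_report", exact = TRUE)

#' Read a dose-level combination-response table
#'
#' Comma-separated export with one row per (drug A, drug B, cell line,
#' dose A, dose B) measurement carrying the percent inhibition relative
#' to untreated control, the four synergy scores (BLISS, HSA/I, LOEWE,
#' ZIP) and a study tag. Rows missing any synergy score are dropped and
#' counted in the parse report; a missing mandatory column or a negative
#' dose is a format error. Column names in other export dialects can be
#' remapped with `colmap`.
#'
#' @param path file path.
#' @param colmap optional named character vector mapping canonical names
#'   (`drug_a`, `drug_b`, `cell`, `dose_a`, `dose_b`, `inhibition`,
#'   `bliss`, `hsa`, `loewe`, `zip`, `study`) to the file's column names.
#' @return data.frame of records with a [parseReport()] attribute.
#' @export
readSynergyTable <- function(path, colmap = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  want <- synergyColumns()
  if (!is.null(colmap)) {
    bad <- setdiff(names(colmap), want)
    if (length(bad)) stopf("unknown colmap target(s): %s", paste(bad, collapse = ", "))
    for (canon in names(colmap)) {
      if (!colmap[[canon]] %in% names(df))
        stopf("mapped column '%s' not in '%s'", colmap[[canon]], path)
      names(df)[names(df) == colmap[[canon]]] <- canon
    }
  }
  missing <- setdiff(want, names(df))
  if (length(missing))
    stopf("missing mandatory column(s) in '%s': %s", path,
          paste(missing, collapse = ", "))
  df <- df[, want, drop = FALSE]
  total <- nrow(df)
  if (total > 0L) {
    for (col in c("dose_a", "dose_b", "inhibition", scoreColumns()))
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (any(stats::complete.cases(df[, c("dose_a", "dose_b")]) &
            (df$dose_a < 0 | df$dose_b < 0)))
      stopf("negative dose in '%s'", path)
    keep <- stats::complete.cases(df[, scoreColumns(), drop = FALSE])
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "parse_report") <- list(total = total, kept = nrow(df),
                                   dropped = total - nrow(df))
  df
}

#' @rdname readSynergyTable
#' @param records data.frame of synergy records.
#' @export
writeSynergyTable <- function(records, path) {
  utils::write.csv(records[, intersect(c(synergyColumns(), "label", "triplet"),
                                       names(records)), drop = FALSE],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a drug table
#'
#' Comma-separated with columns `name`, `smiles` and `genes`
#' (semicolon-separated drug-associated gene symbols, possibly empty).
#' Gene symbols are upper-cased; an empty SMILES string is an error.
#'
#' @param path file path.
#' @return data.frame with columns `name`, `smiles` and list-column
#'   `genes`.
#' @export
readDrugTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  missing <- setdiff(c("name", "smiles", "genes"), names(df))
  if (length(missing))
    stopf("missing drug-table column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(df$name))
    stopf("duplicate drug name(s) in '%s'", path)
  if (any(!nzchar(df$smiles)))
    stopf("empty SMILES in '%s' for drug(s): %s", path,
          paste(df$name[!nzchar(df$smiles)], collapse = ", "))
  genes <- lapply(strsplit(df$genes, ";", fixed = TRUE), function(g) {
    g <- toupper(trimws(g[nzchar(trimws(g))]))
    unique(g)
  })
  out <- data.frame(name = df$name, smiles = df$smiles,
                    stringsAsFactors = FALSE)
  out$genes <- genes
  out
}

#' @rdname readDrugTable
#' @param drugs drug table as returned by `readDrugTable()`.
#' @export
writeDrugTable <- function(drugs, path) {
  df <- data.frame(name = drugs$name, smiles = drugs$smiles,
                   genes = vapply(drugs$genes, paste, character(1),
                                  collapse = ";"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an IC50 table
#'
#' Comma-separated with columns `drug`, `cell`, `ic50`: one half-maximal
#' inhibitory concentration per (drug, cell line), on the same
#' concentration scale as the tested doses. Duplicate (drug, cell) rows
#' or non-positive IC50 values are errors.
#'
#' @param path file path.
#' @return data.frame with columns `drug`, `cell`, `ic50`.
#' @export
readIc50Table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(c("drug", "cell", "ic50"), names(df))
  if (length(missing))
    stopf("missing IC50 column(s): %s", paste(missing, collapse = ", "))
  df$ic50 <- suppressWarnings(as.numeric(df$ic50))
  if (anyNA(df$ic50) || any(df$ic50 <= 0))
    stopf("IC50 values must be positive numbers")
  key <- paste(df$drug, df$cell, sep = "||")
  if (anyDuplicated(key))
    stopf("duplicate (drug, cell) IC50 row(s) in '%s'", path)
  df[, c("drug", "cell", "ic50")]
}

#' @rdname readIc50Table
#' @param ic50 IC50 table.
#' @export
writeIc50Table <- function(ic50, path) {
  utils::write.csv(ic50[, c("drug", "cell", "ic50")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

## IC50 lookup: named numeric vector keyed by drug||cell
ic50Lookup <- function(ic50) {
  stats::setNames(ic50$ic50, paste(ic50$drug, ic50$cell, sep = "||"))
}

#' Write a hypergraph as plain-text files
#'
#' Writes `<prefix>_nodes.txt`, `<prefix>_edges.txt` and
#' `<prefix>_incidence.tsv` (sparse node/edge index triplets, 1-based).
#'
#' @param hg an [IncidenceHypergraph-class].
#' @param prefix output path prefix.
#' @export
writeHypergraph <- function(hg, prefix) {
  m <- incidence(hg)
  writeLines(rownames(m), paste0(prefix, "_nodes.txt"))
  writeLines(colnames(m), paste0(prefix, "_edges.txt"))
  tri <- Matrix::summary(m)
  write.table(data.frame(node = tri$i, edge = tri$j, value = 1L),
              paste0(prefix, "_incidence.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
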
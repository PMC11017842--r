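#' Read a candidate gene set
#'
#' Reads a plain-text file with one gene symbol per line into a canonical
#' gene-set vector: symbols are whitespace-trimmed, upper-cased and must be
#' unique and non-empty. Blank lines and lines starting with `#` are skipped.
#'
#' @param path Path to a text file, one symbol per line.
#' @return Character vector of unique uppercase gene symbols, in file order.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("AR", "PIK3CA", "MET"), f)
#' read_gene_set(f)
read_gene_set <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  gene_set(x)
}

#' Construct a validated gene set
#'
#' @param genes Character vector of gene symbols.
#' @return Character vector of unique uppercase symbols, order preserved.
#' @export
gene_set <- function(genes) {
  if (length(genes) == 0) stop_input("gene set is empty")
  g <- canon_gene(genes)
  if (any(!nzchar(g))) stop_input("gene set contains empty symbols")
  if (anyDuplicated(g)) {
    stop_input("duplicate gene symbols: %s",
               paste(unique(g[duplicated(g)]), collapse = ", "))
  }
  g
}

evidence_cols <- c("mirna_id", "gene_id", "source_name",
                   "source_class", "direction", "confidence")

#' Read a miRNA-gene interaction evidence table
#'
#' The evidence table is a TSV with one row per (miRNA, gene, source)
#' assertion and columns `mirna_id`, `gene_id`, `source_name`,
#' `source_class` (`validated` or `predicted`), `direction` (`positive` or
#' `negative`) and `confidence` in \[0, 1\]. The `confidence` column may be
#' omitted, in which case every record gets confidence 1. Duplicate
#' (miRNA, gene, source) keys are an error so that downstream tallies are
#' reproducible.
#'
#' @param path Path to a TSV file.
#' @return A tibble with the six evidence columns, row order preserved.
#' @export
read_evidence_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- setdiff(evidence_cols, "confidence")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    stop_input("evidence table %s: malformed header, missing column(s) %s",
               path, paste(missing, collapse = ", "))
  }
  if (!"confidence" %in% names(tbl)) tbl$confidence <- "1"
  tbl <- dplyr::select(tbl, dplyr::all_of(evidence_cols))
  tbl$confidence <- suppressWarnings(as.numeric(tbl$confidence))
  validate_evidence(tbl, line_offset = 1L)
}

#' Validate an in-memory evidence table
#'
#' @param tbl A data frame with the evidence columns (see
#'   [read_evidence_table()]). A missing `confidence` column defaults to 1.
#' @param line_offset Internal: added to row indices in error messages so
#'   file readers can report 1-based file line numbers (header = line 1).
#' @return The validated table as a tibble.
#' @export
validate_evidence <- function(tbl, line_offset = 0L) {
  tbl <- tibble::as_tibble(tbl)
  if (!"confidence" %in% names(tbl)) tbl$confidence <- 1
  missing <- setdiff(evidence_cols, names(tbl))
  if (length(missing)) {
    stop_input("evidence table missing column(s): %s",
               paste(missing, collapse = ", "))
  }
  tbl <- dplyr::select(tbl, dplyr::all_of(evidence_cols))
  if (nrow(tbl) == 0) return(tbl)
  line <- function(i) i + line_offset
  bad <- which(is.na(tbl$confidence) | tbl$confidence < 0 | tbl$confidence > 1)
  if (length(bad)) {
    stop_input("confidence out of [0,1] at line %s",
               paste(line(bad), collapse = ", "))
  }
  bad <- which(!tbl$source_class %in% c("validated", "predicted"))
  if (length(bad)) {
    stop_input("unknown source_class %s at line %s",
               paste(unique(tbl$source_class[bad]), collapse = ", "),
               paste(line(bad), collapse = ", "))
  }
  bad <- which(!tbl$direction %in% c("positive", "negative"))
  if (length(bad)) {
    stop_input("unknown direction %s at line %s",
               paste(unique(tbl$direction[bad]), collapse = ", "),
               paste(line(bad), collapse = ", "))
  }
  key <- paste(canon_mirna_key(tbl$mirna_id), canon_gene(tbl$gene_id),
               tbl$source_name, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad)) {
    stop_input("duplicate (miRNA, gene, source) key at line %s",
               paste(line(bad), collapse = ", "))
  }
  tbl
}

#' Write an evidence table to TSV
#'
#' @param tbl Evidence tibble (validated on write).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(tbl, path) {
  tbl <- validate_evidence(tbl)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read sequences from FASTA, normalized to the RNA alphabet
#'
#' Wraps `Biostrings::readBStringSet()` and normalizes the result: sequences
#' are upper-cased and `T` is mapped to `U`, so that all downstream duplex
#' arithmetic runs on one alphabet. Duplicate record ids and empty records
#' are errors.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return Named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(ids))) stop_input("FASTA %s: record with empty id", path)
  if (anyDuplicated(ids)) {
    stop_input("FASTA %s: duplicate id(s) %s", path,
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(ss)
  names(seqs) <- ids
  normalize_rna(seqs, ids)
}

#' Write RNA sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop_input("sequences must be named")
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read gene-set annotations in GMT format
#'
#' Each GMT line is `term<TAB>description<TAB>gene1<TAB>gene2...`. Gene
#' symbols are canonicalized to uppercase and de-duplicated within a term.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (term -> genes), with term
#'   descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop_input("GMT %s: line %s has no member genes", path,
               paste(which(short), collapse = ", "))
  }
  terms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(terms)) {
    stop_input("GMT %s: duplicate term id(s) %s", path,
               paste(unique(terms[duplicated(terms)]), collapse = ", "))
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) unique(canon_gene(f[-(1:2)])))
  names(genes) <- terms
  attr(genes, "description") <- setNames(desc, terms)
  genes
}

#' Write gene-set annotations to GMT
#'
#' @param gmt Named list of character vectors; descriptions taken from
#'   `attr(gmt, "description")` (empty string when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gmt, path) {
  desc <- attr(gmt, "description") %||% setNames(rep("", length(gmt)), names(gmt))
  lines <- vapply(names(gmt), function(tm) {
    paste(c(tm, desc[[tm]] %||% "", gmt[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a replicate Ct table
#'
#' CSV with columns `sample_id`, `group`, `assay`, `ct`. Each (sample, assay)
#' pair may appear at most once.
#'
#' @param path Path to a CSV file.
#' @return Tibble with the four columns.
#' @export
read_ct_table <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    sample_id = "c", group = "c", assay = "c", ct = "d"), progress = FALSE)
  validate_ct(tbl)
}

validate_ct <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  need <- c("sample_id", "group", "assay", "ct")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    stop_input("Ct table missing column(s): %s", paste(missing, collapse = ", "))
  }
  if (any(is.na(tbl$ct) | tbl$ct <= 0)) stop_input("Ct values must be positive")
  key <- paste(tbl$sample_id, tbl$assay, sep = "\r")
  if (anyDuplicated(key)) {
    stop_input("duplicate (sample, assay) measurement(s): %s",
               paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  }
  tbl[, need]
}

#' Read per-cell DNA-content intensities
#'
#' CSV with columns `condition` and `intensity` (positive fluorescence
#' units, one row per event).
#'
#' @param path Path to a CSV file.
#' @return Tibble with columns `condition`, `intensity`.
#' @export
read_intensities <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    condition = "c", intensity = "d"), progress = FALSE)
  if (any(is.na(tbl$intensity) | tbl$intensity <= 0)) {
    stop_input("intensities must be positive")
  }
  tbl
}
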
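# On-disk formats: Matrix Market counts + label files, GMT gene sets,
# schema-validated TSV tables. Everything round-trips byte-faithfully.

#' Construct a count matrix container
#'
#' Bundles a sparse gene x cell integer count matrix with its ordered gene
#' and cell label vectors. This is the substrate every differential
#' expression stratum is drawn from.
#'
#' @param counts sparse (or dense) non-negative integer matrix, genes in
#'   rows, cells in columns.
#' @param genes character vector of gene symbols, one per row.
#' @param cells character vector of cell barcodes, one per column.
#' @return An object of class `count_matrix` with elements `counts`
#'   (a `dgCMatrix`), `genes`, and `cells`.
#' @export
count_matrix <- function(counts, genes, cells) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  # normalize representation: pattern (ngCMatrix) and symmetric/triangular
  # forms all become numeric general CsparseMatrix
  counts <- methods::as(methods::as(methods::as(
    counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(genes))
    stop_sexdim(sprintf("gene labels (%d) do not match matrix rows (%d)",
                        length(genes), nrow(counts)))
  if (ncol(counts) != length(cells))
    stop_sexdim(sprintf("cell labels (%d) do not match matrix columns (%d)",
                        length(cells), ncol(counts)))
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop_sexdim("counts must be non-negative integers")
  if (anyDuplicated(genes)) stop_sexdim("gene symbols must be unique")
  dimnames(counts) <- list(genes, cells)
  structure(list(counts = counts, genes = as.character(genes),
                 cells = as.character(cells)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %d non-zero entries\n",
              length(x$genes), length(x$cells), length(x$counts@x)))
  invisible(x)
}

#' Write a count matrix as Matrix Market plus label files
#'
#' @param x a `count_matrix`.
#' @param mtx_path,genes_path,cells_path output file paths; the matrix uses
#'   the Matrix Market coordinate format (1-based indices, the format's
#'   convention), labels are one symbol/barcode per line.
#' @return Invisibly, `x`.
#' @export
write_counts <- function(x, mtx_path, genes_path, cells_path) {
  stopifnot(inherits(x, "count_matrix"))
  Matrix::writeMM(x$counts, mtx_path)
  writeLines(x$genes, genes_path)
  writeLines(x$cells, cells_path)
  invisible(x)
}

#' Read a count matrix from Matrix Market plus label files
#'
#' Validates that the label files agree with the matrix header and errors
#' with both counts on mismatch.
#'
#' @inheritParams write_counts
#' @return A `count_matrix`.
#' @export
read_counts <- function(mtx_path, genes_path, cells_path) {
  m <- Matrix::readMM(mtx_path)
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  if (nrow(m) != length(genes))
    stop_sexdim(sprintf(
      "matrix header declares %d rows but gene file has %d lines",
      nrow(m), length(genes)))
  if (ncol(m) != length(cells))
    stop_sexdim(sprintf(
      "matrix header declares %d columns but cell file has %d lines",
      ncol(m), length(cells)))
  count_matrix(m, genes, cells)
}

#' Read a GMT gene-set collection
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a set are dropped with a warning; a duplicated
#' set name is an error.
#'
#' @param path GMT file path.
#' @return A named list of character vectors; the `description` attribute
#'   carries the second field of each line.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop_sexdim(sprintf("GMT line %d has fewer than 3 tab-separated fields",
                        bad[1]))
  nm <- vapply(fields, `[[`, "", 1L)
  dup <- which(duplicated(nm))
  if (length(dup))
    stop_sexdim(sprintf("duplicate gene-set name '%s' (line %d)",
                        nm[dup[1]], dup[1]))
  sets <- lapply(seq_along(fields), function(i) {
    members <- fields[[i]][-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': duplicate members removed", nm[i]),
              call. = FALSE)
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors; an optional `description`
#'   attribute supplies field 2 (defaults to the set name).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_sexdim("sets must have unique names")
  if (any(lengths(sets) == 0L)) stop_sexdim("sets must be non-empty")
  desc <- attr(sets, "description") %||% names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

# Column schemas for the tabular inputs. Each entry: required columns with
# target type, plus optional per-column allowed value sets.
.schemas <- list(
  edges = list(
    required = c(source = "character", target = "character",
                 sign = "character", mechanism = "character",
                 tissue = "character"),
    enums = list(sign = c("+", "-", "unknown"))
  ),
  lr_pairs = list(
    required = c(ligand = "character", receptor = "character"),
    enums = list()
  ),
  cell_meta = list(
    required = c(cell_id = "character", subject_id = "character",
                 cell_type = "character", condition = "character",
                 sex = "character", braak = "integer",
                 age = "numeric", mmse = "numeric"),
    enums = list(condition = c("AD", "HC"), sex = c("M", "F"))
  ),
  subject_meta = list(
    required = c(subject_id = "character", group = "character",
                 condition = "character", sex = "character",
                 braak = "integer", age = "numeric", mmse = "numeric"),
    enums = list(condition = c("AD", "HC"), sex = c("M", "F"))
  ),
  sample_meta = list(
    required = c(sample_id = "character", condition = "character",
                 sex = "character", age = "numeric"),
    enums = list(condition = c("AD", "HC"), sex = c("M", "F"))
  )
)

#' Read a schema-validated TSV table
#'
#' Shared reader for edge tables, ligand-receptor pairs, and the cell,
#' subject, and proteomics sample metadata. Required columns are coerced to
#' their declared types, enumerated columns are checked against the allowed
#' vocabulary, unknown columns pass through, and row order is preserved.
#' Lines starting with `#` (provenance headers) are skipped.
#'
#' @param path TSV path with a header row.
#' @param schema one of `"edges"`, `"lr_pairs"`, `"cell_meta"`,
#'   `"subject_meta"`, `"sample_meta"`.
#' @return A `data.frame`.
#' @export
read_table <- function(path, schema) {
  sc <- .schemas[[schema]]
  if (is.null(sc))
    stop_sexdim(sprintf("unknown schema '%s' (known: %s)", schema,
                        paste(names(.schemas), collapse = ", ")))
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, na.strings = "NA",
                   colClasses = NA, check.names = FALSE)
  missing <- setdiff(names(sc$required), names(df))
  if (length(missing))
    stop_sexdim(sprintf("missing required column(s): %s; found: %s",
                        paste(missing, collapse = ", "),
                        paste(names(df), collapse = ", ")))
  for (col in names(sc$required)) {
    df[[col]] <- switch(sc$required[[col]],
                        character = as.character(df[[col]]),
                        integer   = as.integer(df[[col]]),
                        numeric   = as.numeric(df[[col]]))
  }
  for (col in names(sc$enums)) {
    allowed <- sc$enums[[col]]
    bad <- setdiff(unique(df[[col]][!is.na(df[[col]])]), allowed)
    if (length(bad))
      stop_sexdim(sprintf("column '%s' has value(s) %s; allowed: %s", col,
                          paste(sQuote(bad), collapse = ", "),
                          paste(allowed, collapse = ", ")))
  }
  df
}

#' Write a results table as TSV with a provenance header
#'
#' Writes `# key: value` comment lines (tool version plus caller-supplied
#' provenance such as seed and parameters) followed by a tab-separated
#' table. Output is deterministic so repeated runs are diffable.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param provenance named list appended to the header.
#' @return Invisibly, `path`.
#' @export
write_result_table <- function(df, path, provenance = list()) {
  prov <- c(list(tool = paste0("sexdim ", as.character(packageVersion("sexdim")))),
            provenance)
  hdr <- sprintf("# %s: %s", names(prov),
                 vapply(prov, function(v) paste(format(v), collapse = " "), ""))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}
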
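#' Read a transcripts-by-samples expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds transcript IDs and
#' whose header row holds sample IDs. Row and column order are preserved.
#' Duplicate IDs and non-numeric cells are hard errors that name the
#' offending location.
#'
#' @param path path to the TSV file.
#' @return numeric matrix with transcript row names and sample column names.
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2L) stop("expression file needs an ID column plus samples")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate transcript ID: ", ids[duplicated(ids)][1L])
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample ID: ", samples[duplicated(samples)][1L])
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, samples))
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value at transcript '%s', sample '%s'",
                 ids[bad[1L]], samples[bad[2L]]))
  }
  .checkExprMatrix(vals)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpression()]; round-trips preserve values to full
#' double precision.
#'
#' @param expr numeric matrix or [AgingCohort-class].
#' @param path output path.
#' @export
writeExpression <- function(expr, path) {
  m <- exprValues(expr)
  df <- data.frame(transcript_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample cohort metadata from TSV
#'
#' First column must be `sample_id`; required columns are `age`, `sex`,
#' `rin`, `pmi`, `batch`, `intronic_mean`, `intronic_sd`.
#'
#' @param path path to the TSV file.
#' @return data.frame row-named by sample ID.
#' @export
readCohortMetadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "sample_id")
    stop("metadata file must start with a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ID: ", df$sample_id[duplicated(df$sample_id)][1L])
  missing <- setdiff(.REQUIRED_META, colnames(df))
  if (length(missing))
    stop("metadata columns missing: ", paste(missing, collapse = ", "))
  rownames(df) <- df$sample_id
  df[-1L]
}

#' Write cohort metadata as TSV
#' @param metadata data.frame row-named by sample ID (or an
#'   [AgingCohort-class], whose `colData` is written).
#' @param path output path.
#' @export
writeCohortMetadata <- function(metadata, path) {
  if (is(metadata, "SummarizedExperiment"))
    metadata <- as.data.frame(SummarizedExperiment::colData(metadata))
  df <- data.frame(sample_id = rownames(metadata), metadata,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript-to-gene annotation table
#'
#' Two-column TSV: transcript ID, gene symbol. Each transcript must map to
#' exactly one gene.
#'
#' @param path path to the TSV file.
#' @return named character vector, transcript ID -> gene symbol.
#' @export
readAnnotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  .annotationMap(df)
}

#' Write a transcript-to-gene annotation table
#' @param annotation named character vector (transcript -> gene).
#' @param path output path.
#' @export
writeAnnotation <- function(annotation, path) {
  write.table(data.frame(transcript_id = names(annotation),
                         gene_symbol = unname(annotation)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description,
#' then member gene symbols.
#'
#' @param path path to a `.gmt` file.
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short))
    stop("GMT line ", which(short)[1L], " has fewer than 3 fields")
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(members) <- vapply(fields, `[`, "", 1L)
  GeneSetCollection(members,
                    setNames = vapply(fields, `[`, "", 2L))
}

#' Write a GeneSetCollection (or marker list) in GMT format
#' @param sets a [GeneSetCollection-class] or named list of character vectors.
#' @param path output path.
#' @export
writeGMT <- function(sets, path) {
  if (is(sets, "GeneSetCollection")) {
    ids <- sets@setIds; nms <- sets@setNames; members <- sets@members
  } else {
    ids <- names(sets); nms <- ids; members <- sets
  }
  lines <- vapply(seq_along(ids), function(i)
    paste(c(ids[i], nms[i], members[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read cell-type marker sets from GMT
#'
#' Convenience wrapper around [readGMT()] returning a plain named list
#' (cell type -> marker gene symbols) validated so that no gene marks two
#' cell types.
#'
#' @param path path to a `.gmt` file of marker sets.
#' @return named list of character vectors.
#' @export
readMarkerSets <- function(path) {
  markerSets(geneSetMembers(readGMT(path)))
}

#' Validate cell-type marker sets
#'
#' @param markers named list: cell type -> character vector of marker gene
#'   symbols. Markers must be unique within a cell type and no gene may mark
#'   two cell types.
#' @return the validated list (duplicates within a type removed).
#' @export
markerSets <- function(markers) {
  if (is.null(names(markers)) || any(!nzchar(names(markers))))
    stop("marker sets must be a named list (cell type -> genes)")
  markers <- lapply(markers, function(g) unique(as.character(g)))
  all_genes <- unlist(markers, use.names = FALSE)
  if (anyDuplicated(all_genes))
    stop("gene marks more than one cell type: ",
         all_genes[duplicated(all_genes)][1L])
  markers
}
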
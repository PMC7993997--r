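#' Gene-by-library count matrix with library metadata
#'
#' The container for TE inference: an integer matrix (genes x libraries) plus
#' a metadata table with one row per library giving `library_id`, `condition`
#' (`reference` or `perturbed`), `assay` (`RNA` or `RPF`) and `replicate`.
#'
#' @param counts integer matrix with rownames = gene ids and colnames =
#'   library ids.
#' @param libraries data frame with columns `library_id`, `condition`,
#'   `assay`, `replicate`; row order defines column order.
#' @return a `count_matrix` object (list with elements `counts`, `libraries`).
#' @export
count_matrix <- function(counts, libraries) {
  libraries <- tibble::as_tibble(libraries)
  need <- c("library_id", "condition", "assay", "replicate")
  if (!all(need %in% names(libraries))) {
    stop("library metadata needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(libraries$library_id)) stop("duplicate library_id")
  trip <- paste(libraries$condition, libraries$assay, libraries$replicate)
  if (anyDuplicated(trip)) stop("duplicate (condition, assay, replicate) triple")
  if (!all(libraries$condition %in% c("reference", "perturbed"))) {
    stop("condition must be 'reference' or 'perturbed'")
  }
  if (!all(libraries$assay %in% c("RNA", "RPF"))) stop("assay must be 'RNA' or 'RPF'")
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts needs gene rownames")
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  }
  if (is.null(colnames(counts))) colnames(counts) <- libraries$library_id
  if (!setequal(colnames(counts), libraries$library_id)) {
    stop("matrix columns and library metadata disagree")
  }
  counts <- counts[, libraries$library_id, drop = FALSE]
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, libraries = libraries), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "libraries\n")
  print(x$libraries, ...)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix and its library metadata from TSV
#'
#' The matrix TSV has a `gene_id` column and one column per library; the
#' metadata TSV maps each library id to (condition, assay, replicate) and its
#' row order defines the column order of the result.
#'
#' @param path count-matrix TSV.
#' @param metadata_path library-metadata TSV.
#' @return a `count_matrix`.
#' @export
read_count_matrix <- function(path, metadata_path) {
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(
    library_id = readr::col_character(),
    condition = readr::col_character(),
    assay = readr::col_character(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  libs <- setdiff(names(tab), "gene_id")
  missing_meta <- setdiff(libs, meta$library_id)
  if (length(missing_meta)) {
    stop("libraries absent from metadata: ", paste(missing_meta, collapse = ", "))
  }
  m <- as.matrix(tab[, meta$library_id, drop = FALSE])
  if (any(m != floor(m))) stop("non-integer cell in count matrix ", path)
  rownames(m) <- tab$gene_id
  count_matrix(m, meta)
}

#' Write a count matrix and metadata to TSV
#' @param x a `count_matrix`.
#' @param path count-matrix TSV path.
#' @param metadata_path library-metadata TSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, metadata_path) {
  tab <- tibble::as_tibble(x$counts)
  tab <- cbind(tibble::tibble(gene_id = rownames(x$counts)), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  readr::write_tsv(x$libraries, metadata_path, progress = FALSE)
  invisible(path)
}

#' Select library ids by condition/assay
#' @param x a `count_matrix`.
#' @param condition,assay optional filters.
#' @return character vector of library ids, in metadata order.
#' @export
library_ids <- function(x, condition = NULL, assay = NULL) {
  keep <- rep(TRUE, nrow(x$libraries))
  if (!is.null(condition)) keep <- keep & x$libraries$condition %in% condition
  if (!is.null(assay)) keep <- keep & x$libraries$assay %in% assay
  x$libraries$library_id[keep]
}
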
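# Readers and containers for expression matrices, experiment manifests and
# gene sets.  All downstream modules consume the expression_collection
# assembled here.

#' Read a genes x arrays expression matrix from TSV
#'
#' The expected layout is a header row `gene_id<TAB>arr1<TAB>arr2...`
#' followed by one row per gene.  Cells are numeric; the token `NA` marks a
#' missing measurement and is kept as `NA` in the returned matrix (downstream
#' correlations use pairwise-complete observations).
#'
#' @param path Path to a UTF-8 TSV file.
#' @return A numeric matrix of class `expression_matrix` with gene ids as
#'   row names and array ids as column names.
#' @details Malformed input raises an error naming the offending line:
#'   duplicate gene or array ids, non-numeric cells, ragged rows, or an
#'   array column that is entirely missing.
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("expression matrix file must have a header and at least one gene row: ", path)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop("malformed header (line 1): expected 'gene_id' followed by array ids")
  }
  array_ids <- header[-1L]
  if (anyDuplicated(array_ids)) {
    stop("duplicate array id in header: ",
         paste(unique(array_ids[duplicated(array_ids)]), collapse = ", "))
  }
  n_arr <- length(array_ids)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  gene_ids <- character(length(body))
  values <- matrix(NA_real_, nrow = length(body), ncol = n_arr)
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_arr + 1L) {
      stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                   i + 1L, n_arr + 1L, length(row)))
    }
    gene_ids[i] <- row[[1L]]
    cells <- row[-1L]
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & cells != "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric cell '%s' at line %d, column %d",
                   cells[bad[1L]], i + 1L, bad[1L] + 1L))
    }
    values[i, ] <- num
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    stop("duplicate gene id: ", paste(unique(dup), collapse = ", "))
  }
  dimnames(values) <- list(gene_ids, array_ids)
  all_na <- colSums(!is.na(values)) == 0L
  if (any(all_na)) {
    stop("array column entirely missing: ",
         paste(array_ids[all_na], collapse = ", "))
  }
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: a write-then-read round trip
#' reproduces ids, ordering, the missing-value mask, and values to full
#' double precision.
#'
#' @param mat Numeric matrix with gene row names and array column names.
#' @param path Output path.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  for (i in seq_len(nrow(mat))) {
    cells <- ifelse(is.na(mat[i, ]), "NA", sprintf("%.17g", mat[i, ]))
    writeLines(paste(c(rownames(mat)[i], cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an array-to-experiment manifest from TSV
#'
#' Two columns: `array_id<TAB>experiment_id`.  Each array must map to
#' exactly one experiment and each experiment must own at least two arrays
#' (a single-array experiment cannot support correlation downstream).
#'
#' @param path Path to the manifest TSV.
#' @param header Logical; skip a header row if `TRUE`.
#' @return An object of class `experiment_map`: a data.frame with columns
#'   `array_id` and `experiment_id`, plus an `experiment_ids` attribute in
#'   first-appearance order.
#' @export
read_experiment_manifest <- function(path, header = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (header) lines <- lines[-1L]
  if (!length(lines)) stop("empty manifest: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("manifest line %d does not have exactly 2 fields",
                 bad[1L] + as.integer(header)))
  }
  array_id <- vapply(parts, `[[`, character(1L), 1L)
  experiment_id <- vapply(parts, `[[`, character(1L), 2L)
  experiment_map(array_id, experiment_id)
}

#' Construct an experiment map from parallel id vectors
#'
#' @param array_id Character vector of array ids.
#' @param experiment_id Character vector, same length, giving the owning
#'   experiment of each array.
#' @return An `experiment_map` object.
#' @export
experiment_map <- function(array_id, experiment_id) {
  stopifnot(length(array_id) == length(experiment_id))
  dup <- array_id[duplicated(array_id)]
  if (length(dup)) {
    stop("array listed more than once in manifest: ",
         paste(unique(dup), collapse = ", "))
  }
  counts <- table(experiment_id)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    stop("experiment with a single array (correlation undefined): ",
         paste(small, collapse = ", "))
  }
  out <- data.frame(array_id = array_id, experiment_id = experiment_id,
                    stringsAsFactors = FALSE)
  attr(out, "experiment_ids") <- unique(experiment_id)
  class(out) <- c("experiment_map", "data.frame")
  out
}

#' Write an experiment manifest as TSV
#' @param map An `experiment_map`.
#' @param path Output path.
#' @export
write_experiment_manifest <- function(map, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(map$array_id, map$experiment_id, sep = "\t"), con)
  invisible(path)
}

#' Experiment ids of an experiment map or collection, in first-appearance order
#' @param x An `experiment_map` or `expression_collection`.
#' @return Character vector of experiment ids.
#' @export
experiment_ids <- function(x) {
  if (inherits(x, "expression_collection")) x <- x$experiments
  attr(x, "experiment_ids")
}

#' Assemble an expression collection
#'
#' Binds an expression matrix to its array-to-experiment partition after
#' checking that the two refer to exactly the same arrays.  Array order is
#' taken from the matrix columns.
#'
#' @param matrix A genes x arrays numeric matrix with dimnames (e.g. from
#'   [read_expression_matrix()]).
#' @param experiments An `experiment_map`.
#' @return An `expression_collection`: a list with elements `matrix` and
#'   `experiments`.
#' @export
expression_collection <- function(matrix, experiments) {
  stopifnot(is.matrix(matrix), inherits(experiments, "experiment_map"))
  if (!setequal(colnames(matrix), experiments$array_id)) {
    stop("matrix arrays and manifest arrays differ")
  }
  structure(list(matrix = matrix, experiments = experiments),
            class = "expression_collection")
}

#' @export
print.expression_collection <- function(x, ...) {
  cat(sprintf("expression_collection: %d genes x %d arrays in %d experiments\n",
              nrow(x$matrix), ncol(x$matrix), length(experiment_ids(x))))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Each line is `set_name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a set are removed with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (gene-id sets).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", bad[1L]))
  }
  sets <- lapply(parts, function(p) {
    genes <- p[-c(1L, 2L)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate gene(s) in set '%s' removed", p[[1L]]),
              call. = FALSE)
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(sets)) {
    writeLines(paste(c(names(sets)[i], descriptions[i], sets[[i]]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Category/background gene partition
#'
#' @param category Character vector: genes of the functional category of
#'   interest.
#' @param background Character vector: background genes (annotated to other
#'   terms).  Any overlap with the category is removed from the background,
#'   so the two sets are always disjoint.
#' @return A `gene_partition` object.
#' @export
gene_partition <- function(category, background) {
  category <- unique(category)
  background <- setdiff(unique(background), category)
  if (length(category) < 3L) {
    stop("category must contain at least 3 genes, got ", length(category))
  }
  if (!length(background)) stop("background is empty")
  structure(list(category = category, background = background),
            class = "gene_partition")
}

#' Build the category/background partition for one term
#'
#' The category is the chosen set intersected with the collection's genes;
#' the background is the union of all *other* sets (intersected with the
#' collection) minus the category.  Genes annotated both to the term of
#' interest and elsewhere therefore appear only in the category.  Unannotated
#' genes are never part of the background.
#'
#' @param sets Named list of gene sets (see [read_gene_sets()]).
#' @param term Name of the set to use as the category of interest.
#' @param collection An `expression_collection`.
#' @param min_size Minimum category size after intersection with the
#'   collection.  The default of 25 genes keeps the two-sample t-test and
#'   the cross-validation folds adequately populated; lower it for small
#'   synthetic categories.
#' @return A `gene_partition`.
#' @export
make_partition <- function(sets, term, collection, min_size = 25L) {
  if (!term %in% names(sets)) stop("unknown term: ", term)
  genes <- rownames(collection$matrix)
  category <- intersect(sets[[term]], genes)
  if (length(category) < min_size) {
    stop(sprintf("category '%s' has %d genes in the collection, below min_size %d",
                 term, length(category), min_size))
  }
  others <- unlist(sets[setdiff(names(sets), term)], use.names = FALSE)
  background <- setdiff(intersect(unique(others), genes), category)
  if (!length(background)) stop("no background genes for term: ", term)
  gene_partition(category, background)
}
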
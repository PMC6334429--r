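#' Expression dataset objects
#'
#' An `expression_dataset` holds a samples x attributes numeric matrix
#' together with one categorical class label per sample. It is the search
#' universe for [gsp()]: attributes (genes, probes, transcripts) are the
#' candidate terminals, and the labels define the classification task whose
#' leave-one-out accuracy drives selection.
#'
#' Invariants enforced at construction: at least 2 samples, at least 1
#' attribute, unique attribute names, exactly one label per sample, and at
#' least 2 distinct classes. Labels are compared as exact strings after
#' whitespace trimming. Missing values are rejected unless
#' `impute_missing = TRUE`, in which case each attribute's median fills its
#' gaps.
#'
#' @param x A numeric matrix (samples in rows) or a data frame containing
#'   numeric attribute columns plus a label column.
#' @param labels Character or factor vector of class labels, one per sample.
#'   For the data-frame method, use `label_column` instead.
#' @param label_column Name of the column of `x` holding class labels.
#' @param impute_missing If `TRUE`, missing values are replaced by the
#'   attribute median instead of raising an error.
#'
#' @return An object of class `expression_dataset` with fields `matrix`
#'   (numeric, samples x attributes), `labels` (factor) and `class_names`.
#'
#' @examples
#' df <- data.frame(g1 = rnorm(6), g2 = rnorm(6),
#'                  class = rep(c("tumor", "normal"), 3))
#' ds <- as_expression_dataset(df, label_column = "class")
#' n_samples(ds)
#' attribute_names(ds)
#' @export
expression_dataset <- function(x, labels, impute_missing = FALSE) {
  m <- as.matrix(x)
  if (!is.numeric(m)) {
    bad <- which(!vapply(seq_len(ncol(m)), function(j) {
      all(!is.na(suppressWarnings(as.numeric(m[, j]))) | is.na(m[, j]))
    }, logical(1)))
    stop_input(sprintf(
      "expression matrix must be numeric; column(s) %s contain non-numeric values",
      paste(colnames(m)[bad] %||% bad, collapse = ", ")
    ))
  }
  if (nrow(m) < 2) stop_input("need at least 2 samples")
  if (ncol(m) < 1) stop_input("need at least 1 attribute")
  if (is.null(colnames(m))) colnames(m) <- paste0("a", seq_len(ncol(m)))
  if (anyDuplicated(colnames(m))) {
    dup <- unique(colnames(m)[duplicated(colnames(m))])
    stop_input(sprintf("duplicate attribute names: %s",
                       paste(head(dup, 5), collapse = ", ")))
  }
  if (length(labels) != nrow(m)) {
    stop_input(sprintf("%d labels for %d samples", length(labels), nrow(m)))
  }
  labels <- trimws(as.character(labels))
  if (anyNA(labels) || any(labels == "")) stop_input("empty or missing class labels")
  if (length(unique(labels)) < 2) {
    stop_input("need at least 2 distinct classes")
  }
  if (anyNA(m)) {
    if (!impute_missing) {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop_input(sprintf(
        "missing value at sample %d, attribute '%s' (use impute_missing = TRUE for median imputation)",
        idx[1], colnames(m)[idx[2]]
      ))
    }
    for (j in which(colSums(is.na(m)) > 0)) {
      med <- stats::median(m[, j], na.rm = TRUE)
      if (is.na(med)) stop_input(sprintf("attribute '%s' is entirely missing", colnames(m)[j]))
      m[is.na(m[, j]), j] <- med
    }
  }
  if (any(!is.finite(m))) stop_input("expression matrix contains non-finite values")
  labels <- factor(labels, levels = sort(unique(labels)))
  structure(
    list(matrix = m, labels = labels, class_names = levels(labels)),
    class = "expression_dataset"
  )
}

#' @rdname expression_dataset
#' @export
as_expression_dataset <- function(x, label_column = "class", impute_missing = FALSE) {
  if (inherits(x, "expression_dataset")) return(x)
  if (!is.data.frame(x)) stop_input("`x` must be a data frame or expression_dataset")
  if (!label_column %in% names(x)) {
    stop_input(sprintf("label column '%s' not found", label_column))
  }
  labels <- x[[label_column]]
  expr <- x[setdiff(names(x), label_column)]
  for (j in seq_along(expr)) {
    if (!is.numeric(expr[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(expr[[j]]))) & !is.na(expr[[j]]))
      stop_input(sprintf("non-numeric value in attribute '%s' at sample %d",
                         names(expr)[j], if (length(bad)) bad[1] else NA_integer_))
    }
  }
  expression_dataset(as.matrix(expr), labels, impute_missing = impute_missing)
}

#' @rdname expression_dataset
#' @export
n_samples <- function(x) nrow(x$matrix)

#' @rdname expression_dataset
#' @export
n_attributes <- function(x) ncol(x$matrix)

#' @rdname expression_dataset
#' @export
attribute_names <- function(x) colnames(x$matrix)

#' @rdname expression_dataset
#' @export
class_names <- function(x) x$class_names

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d samples x %d attributes, %d classes (%s)\n",
              n_samples(x), n_attributes(x), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' @export
as_tibble.expression_dataset <- function(x, ..., label_column = "class") {
  out <- as_tibble(as.data.frame(x$matrix))
  out[[label_column]] <- as.character(x$labels)
  out
}

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
}

#' Read an expression matrix from delimited text
#'
#' Reads a CSV/TSV file with a mandatory header row into an
#' [expression_dataset]. The matrix may be stored samples-in-rows (header =
#' attribute names, labels in a named column) or genes-in-rows (first column =
#' attribute names, header = sample identifiers, labels supplied through a
#' sidecar file with one label per line, aligned to the sample columns).
#'
#' @param path Path to the delimited text file.
#' @param label_column Name of the label column (samples-in-rows orientation).
#' @param labels_file Optional sidecar file holding one class label per line;
#'   required for `orientation = "genes"`.
#' @param orientation `"samples"` if samples index rows, `"genes"` if genes
#'   index rows (the matrix is transposed on load).
#' @param delim Field delimiter; inferred from the file extension when `NULL`
#'   (`.tsv`/`.tab`/`.txt` are tab, anything else comma).
#' @param impute_missing Passed to [expression_dataset()].
#'
#' @return An [expression_dataset].
#' @export
read_expression_matrix <- function(path, label_column = "class",
                                   labels_file = NULL,
                                   orientation = c("samples", "genes"),
                                   delim = NULL, impute_missing = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path, delim = infer_delim(path, delim),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (orientation == "genes") {
    if (is.null(labels_file)) {
      stop_input("orientation = 'genes' requires labels in a sidecar `labels_file`")
    }
    attr_names <- trimws(raw[[1]])
    m <- t(vapply(seq_len(nrow(raw)), function(i) {
      row <- unlist(raw[i, -1], use.names = FALSE)
      v <- suppressWarnings(as.numeric(row))
      bad <- which(is.na(v) & !is.na(row) & row != "NA" & row != "")
      if (length(bad)) {
        stop_input(sprintf("non-numeric value '%s' for attribute '%s', sample column %d",
                           row[bad[1]], attr_names[i], bad[1]))
      }
      v
    }, numeric(ncol(raw) - 1L)))
    rownames(m) <- attr_names
    m <- t(m)
    colnames(m) <- attr_names
    labels <- readr::read_lines(labels_file)
    labels <- labels[nzchar(trimws(labels))]
    expression_dataset(m, labels, impute_missing = impute_missing)
  } else {
    if (!is.null(labels_file)) {
      labels <- readr::read_lines(labels_file)
      labels <- labels[nzchar(trimws(labels))]
      df <- raw
    } else {
      if (!label_column %in% names(raw)) {
        stop_input(sprintf("label column '%s' not found in %s", label_column, path))
      }
      labels <- raw[[label_column]]
      df <- raw[setdiff(names(raw), label_column)]
    }
    for (j in seq_along(df)) {
      v <- suppressWarnings(as.numeric(df[[j]]))
      bad <- which(is.na(v) & !is.na(df[[j]]) & df[[j]] != "NA" & df[[j]] != "")
      if (length(bad)) {
        stop_input(sprintf("non-numeric value '%s' at sample %d, attribute '%s'",
                           df[[j]][bad[1]], bad[1], names(df)[j]))
      }
      df[[j]] <- v
    }
    expression_dataset(as.matrix(df), labels, impute_missing = impute_missing)
  }
}

#' Write an expression dataset to delimited text
#'
#' Inverse of [read_expression_matrix()] for the samples-in-rows orientation;
#' the label column is appended last. `read_expression_matrix()` on the
#' written file reproduces the dataset exactly.
#'
#' @param x An [expression_dataset].
#' @param path Output path; delimiter inferred from the extension.
#' @param label_column Name for the label column.
#' @param delim Optional delimiter override.
#' @export
write_expression_matrix <- function(x, path, label_column = "class", delim = NULL) {
  df <- as.data.frame(x$matrix)
  df[[label_column]] <- as.character(x$labels)
  readr::write_delim(df, path, delim = infer_delim(path, delim), progress = FALSE)
  invisible(path)
}

#' Write a selection report
#'
#' Writes a JSON report for a finished [gsp()] run (selected attribute names,
#' final LOOCV accuracy, subset size, generation count, seed and the effective
#' configuration) plus a plain-text list with one selected attribute per line.
#'
#' @param result A [gsp_result][gsp()] object.
#' @param dataset The [expression_dataset] the result was produced on.
#' @param path Path for the JSON report.
#' @param genes_path Path for the plain-text attribute list; defaults to the
#'   report path with a `_genes.txt` suffix.
#' @return Invisibly, the report path.
#' @export
write_selection_report <- function(result, dataset, path, genes_path = NULL) {
  stopifnot(inherits(result, "gsp_result"))
  if (is.null(genes_path)) {
    genes_path <- paste0(tools::file_path_sans_ext(path), "_genes.txt")
  }
  unknown <- setdiff(result$best_subset, attribute_names(dataset))
  if (length(unknown)) {
    stop_input(sprintf("result references attributes absent from dataset: %s",
                       paste(head(unknown, 5), collapse = ", ")))
  }
  report <- list(
    selected_attributes = as.list(result$best_subset),
    n_selected = length(result$best_subset),
    accuracy = result$best_accuracy,
    generations_run = result$generations_run,
    history_length = nrow(result$history),
    seed = result$seed,
    empty_selection = length(result$best_subset) == 0,
    dataset = list(n_samples = n_samples(dataset),
                   n_attributes = n_attributes(dataset),
                   classes = as.list(class_names(dataset))),
    config = config_as_list(result$config)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(result$best_subset, genes_path)
  invisible(path)
}
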
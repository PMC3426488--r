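#' Construct a prediction table
#'
#' A prediction table holds the categorical outputs of several standalone
#' subcellular-localization predictors on a common set of proteins, plus an
#' optional column of true (experimentally annotated) locations. It is the
#' central container of the package: contribution scoring, subset selection,
#' ensemble training and evaluation all consume it.
#'
#' Missing predictions are represented by the sentinel label \code{"NA"};
#' rows containing the sentinel are excluded from contribution scoring and
#' feature selection. Labels are matched case-sensitively after whitespace
#' trimming.
#'
#' @param predictions character matrix, proteins in rows and predictors in
#'   columns, cells are location labels. Column names become predictor names
#'   unless \code{predictor_names} is given.
#' @param protein_ids character vector of unique protein identifiers; defaults
#'   to rownames of \code{predictions} or \code{"p1"..."pN"}.
#' @param predictor_names character vector of unique predictor identifiers.
#' @param true_labels optional character vector of true locations, one per
#'   protein.
#' @return An object of class \code{prediction_table} with fields
#'   \code{protein_ids}, \code{predictor_names}, \code{predictions} (character
#'   matrix) and \code{true_labels} (character or \code{NULL}).
#' @examples
#' pt <- prediction_table(
#'   predictions = cbind(toolA = c("Nucleus", "Cytosol"),
#'                       toolB = c("Nucleus", "Nucleus")),
#'   true_labels = c("Nucleus", "Cytosol"))
#' pt
#' @export
prediction_table <- function(predictions, protein_ids = NULL,
                             predictor_names = NULL, true_labels = NULL) {
  predictions <- as.matrix(predictions)
  if (is.null(predictor_names)) predictor_names <- colnames(predictions)
  if (is.null(predictor_names))
    predictor_names <- paste0("predictor", seq_len(ncol(predictions)))
  if (is.null(protein_ids)) protein_ids <- rownames(predictions)
  if (is.null(protein_ids))
    protein_ids <- paste0("p", seq_len(nrow(predictions)))

  storage.mode(predictions) <- "character"
  predictions[] <- trimws(predictions)
  protein_ids <- trimws(as.character(protein_ids))
  predictor_names <- trimws(as.character(predictor_names))
  if (!is.null(true_labels)) true_labels <- trimws(as.character(true_labels))

  if (length(protein_ids) != nrow(predictions))
    stop("protein_ids length (", length(protein_ids),
         ") does not match number of rows (", nrow(predictions), ")")
  if (length(predictor_names) != ncol(predictions))
    stop("predictor_names length (", length(predictor_names),
         ") does not match number of columns (", ncol(predictions), ")")
  if (anyDuplicated(protein_ids))
    stop("duplicate protein id(s): ",
         paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "))
  if (anyDuplicated(predictor_names))
    stop("duplicate predictor name(s): ",
         paste(unique(predictor_names[duplicated(predictor_names)]),
               collapse = ", "))
  bad <- which(is.na(predictions) | predictions == "", arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("empty prediction cell at row '", protein_ids[bad[1, 1]],
         "', predictor '", predictor_names[bad[1, 2]],
         "' (use the sentinel label \"NA\" for missing predictions)")
  if (!is.null(true_labels)) {
    if (length(true_labels) != length(protein_ids))
      stop("true_labels length does not match number of proteins")
    if (any(is.na(true_labels) | true_labels == ""))
      stop("empty true label at row '",
           protein_ids[which(is.na(true_labels) | true_labels == "")[1]], "'")
  }
  dimnames(predictions) <- list(protein_ids, predictor_names)
  structure(
    list(protein_ids = protein_ids, predictor_names = predictor_names,
         predictions = predictions, true_labels = true_labels),
    class = "prediction_table")
}

#' @export
print.prediction_table <- function(x, ...) {
  cat("<prediction_table> ", length(x$protein_ids), " proteins x ",
      length(x$predictor_names), " predictors",
      if (is.null(x$true_labels)) " (no true labels)" else " (with true labels)",
      "\n", sep = "")
  cat("predictors: ", paste(x$predictor_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.prediction_table <- function(x) dim(x$predictions)

#' Number of proteins / predictors in a table
#' @param table a \code{prediction_table}.
#' @return integer count.
#' @export
n_proteins <- function(table) nrow(table$predictions)

#' @rdname n_proteins
#' @export
n_predictors <- function(table) ncol(table$predictions)

#' Subset a prediction table
#'
#' @param x a \code{prediction_table}.
#' @param i protein (row) index vector.
#' @param j predictor (column) index, name, or logical vector.
#' @param ... unused.
#' @return a \code{prediction_table} restricted to the selected proteins and
#'   predictors.
#' @export
`[.prediction_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$predictions))
  if (missing(j)) j <- seq_len(ncol(x$predictions))
  prediction_table(
    predictions = x$predictions[i, j, drop = FALSE],
    protein_ids = x$protein_ids[i],
    true_labels = if (!is.null(x$true_labels)) x$true_labels[i])
}

# rows usable for scoring/selection: no sentinel "NA" prediction and,
# when truth is present, no sentinel truth
complete_rows <- function(table) {
  ok <- rowSums(table$predictions == "NA") == 0
  if (!is.null(table$true_labels)) ok <- ok & table$true_labels != "NA"
  which(ok)
}

#' Read a prediction table from TSV
#'
#' The expected dialect is tab-delimited UTF-8 with a header row and no
#' quoting: column 1 is \code{protein_id}, an optional column
#' \code{true_label} holds the annotated location, and every remaining column
#' is one predictor. This is the exact inverse of
#' \code{\link{write_prediction_table}}.
#'
#' @param path path to a TSV file.
#' @param has_truth does the file carry a \code{true_label} column? Default
#'   auto-detects by header name.
#' @return a \code{\link{prediction_table}}.
#' @export
read_prediction_table <- function(path, has_truth = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1]])
  if (header[1] != "protein_id")
    stop("first column must be 'protein_id', found '", header[1], "'")
  nfield <- length(header)
  widths <- lengths(fields[-1])
  if (any(widths != nfield))
    stop("ragged row ", which(widths != nfield)[1] + 1L, ": expected ",
         nfield, " fields, found ", widths[widths != nfield][1])
  if (is.null(has_truth)) has_truth <- "true_label" %in% header
  if (has_truth && !"true_label" %in% header)
    stop("has_truth = TRUE but no 'true_label' column in header")
  body <- fields[-1]
  m <- if (length(body) == 0) {
    matrix(character(0), 0, nfield)
  } else {
    matrix(trimws(unlist(body)), nrow = length(body), ncol = nfield,
           byrow = TRUE)
  }
  truth_col <- if (has_truth) match("true_label", header) else NA_integer_
  pred_cols <- setdiff(seq_len(nfield), c(1L, truth_col))
  if (length(pred_cols) == 0) stop("no predictor columns in ", path)
  prediction_table(
    predictions = m[, pred_cols, drop = FALSE],
    protein_ids = m[, 1],
    predictor_names = header[pred_cols],
    true_labels = if (has_truth) m[, truth_col])
}

#' Write a prediction table to TSV
#'
#' @param table a \code{\link{prediction_table}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @seealso \code{\link{read_prediction_table}} for the dialect; the
#'   read-write pair is an exact (string-level) round trip.
#' @export
write_prediction_table <- function(table, path) {
  stopifnot(inherits(table, "prediction_table"))
  header <- c("protein_id",
              if (!is.null(table$true_labels)) "true_label",
              table$predictor_names)
  body <- cbind(table$protein_ids,
                if (!is.null(table$true_labels)) table$true_labels,
                table$predictions)
  lines <- c(paste(header, collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
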
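#' Unified location vocabulary
#'
#' Standalone localization predictors differ in the compartments they report.
#' To combine them the package maps every native label to a small unified
#' vocabulary; the default low-resolution scheme is Cytosol, Mitochondrion,
#' Nucleus, Secretory (the secretory pathway) and Others.
#'
#' @return character vector of the five default unified locations.
#' @export
unified_locations <- function() {
  c("Cytosol", "Mitochondrion", "Nucleus", "Secretory", "Others")
}

# compartments aggregated into the unified Secretory class
secretory_members <- function() {
  c("extracellular", "plasma membrane", "endoplasmic reticulum",
    "golgi apparatus", "lysosomal", "vacuolar")
}

#' Construct a location mapping
#'
#' A location mapping translates each predictor's native compartment labels
#' into a unified vocabulary. Entries are predictor-specific; the pseudo
#' predictor \code{"*"} holds generic rules applied when no predictor-specific
#' entry matches. An optional fallback label (used by the built-in mapping)
#' catches labels with no entry at all.
#'
#' @param entries data.frame with character columns \code{predictor},
#'   \code{native_label}, \code{unified_label}.
#' @param vocabulary unified label vocabulary; defaults to
#'   \code{\link{unified_locations}}.
#' @param fallback a unified label assigned to unmatched native labels, or
#'   \code{NA} (the default) to treat unmatched labels as an error.
#' @return an object of class \code{location_mapping}.
#' @export
location_mapping <- function(entries, vocabulary = unified_locations(),
                             fallback = NA_character_) {
  stopifnot(is.data.frame(entries),
            all(c("predictor", "native_label", "unified_label") %in%
                  names(entries)))
  entries <- data.frame(
    predictor = trimws(as.character(entries$predictor)),
    native_label = trimws(as.character(entries$native_label)),
    unified_label = trimws(as.character(entries$unified_label)),
    stringsAsFactors = FALSE)
  bad <- setdiff(unique(entries$unified_label), vocabulary)
  if (length(bad) > 0)
    stop("unified label(s) outside the vocabulary: ",
         paste(bad, collapse = ", "))
  key <- paste(entries$predictor, entries$native_label, sep = "\r")
  if (anyDuplicated(key)) {
    d <- entries[duplicated(key), , drop = FALSE]
    stop("native label mapped more than once: predictor '", d$predictor[1],
         "', label '", d$native_label[1], "'")
  }
  if (!is.na(fallback) && !fallback %in% vocabulary)
    stop("fallback label '", fallback, "' is not in the vocabulary")
  structure(list(entries = entries, vocabulary = vocabulary,
                 fallback = fallback),
            class = "location_mapping")
}

#' @export
print.location_mapping <- function(x, ...) {
  cat("<location_mapping> ", nrow(x$entries), " entries, vocabulary: ",
      paste(x$vocabulary, collapse = ", "), "\n", sep = "")
  if (!is.na(x$fallback)) cat("fallback label: ", x$fallback, "\n", sep = "")
  invisible(x)
}

#' Built-in location mapping
#'
#' Returns the package's default mapping to the five-class unified scheme.
#' It contains the published CELLO and WoLFPSORT translations (e.g. CELLO
#' \code{extra}, \code{plas}, \code{er}, \code{vacu}, \code{golgi},
#' \code{lyso} map to Secretory while \code{chlo}, \code{pero}, \code{cytos}
#' map to Others), plus the generic six-class secretory rule: extracellular,
#' plasma membrane, endoplasmic reticulum, golgi apparatus, lysosomal and
#' vacuolar compartments all collapse into Secretory. Unified labels map to
#' themselves, and any other label falls back to Others.
#'
#' @return a \code{\link{location_mapping}} with fallback \code{"Others"}.
#' @examples
#' m <- builtin_mappings()
#' query_mapping(m, "*", "lysosomal")     # "Secretory"
#' query_mapping(m, "WoLFPSORT", "cysk")  # "Others"
#' @export
builtin_mappings <- function() {
  cello_sec <- c("extra", "plas", "er", "vacu", "golgi", "lyso")
  cello_oth <- c("chlo", "pero", "cytos")
  wolf_sec <- c("E.R.", "extr", "plas", "golg", "lyso", "vacu")
  wolf_oth <- c("chlo", "cysk", "pero")
  vocab <- unified_locations()
  entries <- rbind(
    data.frame(predictor = "CELLO", native_label = cello_sec,
               unified_label = "Secretory"),
    data.frame(predictor = "CELLO", native_label = cello_oth,
               unified_label = "Others"),
    data.frame(predictor = "WoLFPSORT", native_label = wolf_sec,
               unified_label = "Secretory"),
    data.frame(predictor = "WoLFPSORT", native_label = wolf_oth,
               unified_label = "Others"),
    data.frame(predictor = "*", native_label = secretory_members(),
               unified_label = "Secretory"),
    data.frame(predictor = "*", native_label = vocab,
               unified_label = vocab))
  location_mapping(entries, vocabulary = vocab, fallback = "Others")
}

#' Look up the unified label for one native label
#'
#' Resolution order: predictor-specific entry, then generic (\code{"*"})
#' entry, then the mapping's fallback label; an error if none applies. The
#' sentinel label \code{"NA"} passes through unchanged.
#'
#' @param mapping a \code{\link{location_mapping}}.
#' @param predictor predictor name (\code{"*"} queries the generic rules).
#' @param label native label.
#' @return a unified label (length-1 character).
#' @export
query_mapping <- function(mapping, predictor, label) {
  stopifnot(inherits(mapping, "location_mapping"))
  label <- trimws(label)
  if (label == "NA") return("NA")
  e <- mapping$entries
  hit <- which(e$predictor == predictor & e$native_label == label)
  if (length(hit) == 0) hit <- which(e$predictor == "*" & e$native_label == label)
  if (length(hit) > 0) return(e$unified_label[hit[1]])
  if (!is.na(mapping$fallback)) return(mapping$fallback)
  stop("no mapping for label '", label, "' of predictor '", predictor, "'")
}

#' Map a prediction table onto the unified vocabulary
#'
#' Replaces every native label in the table (and the true labels, if present)
#' by its unified location. Dimensions and row order are unchanged. Mapping is
#' idempotent once all labels are unified, because unified labels map to
#' themselves under the generic rule.
#'
#' @param table a \code{\link{prediction_table}} with native labels.
#' @param mapping a \code{\link{location_mapping}}; defaults to
#'   \code{\link{builtin_mappings}}.
#' @param map_truth also map the \code{true_labels} column (default TRUE,
#'   using the generic rules).
#' @return a \code{\link{prediction_table}} over unified labels.
#' @export
map_locations <- function(table, mapping = builtin_mappings(),
                          map_truth = TRUE) {
  stopifnot(inherits(table, "prediction_table"))
  preds <- table$predictions
  for (j in seq_along(table$predictor_names)) {
    pn <- table$predictor_names[j]
    labs <- unique(preds[, j])
    lut <- vapply(labs, function(l) query_mapping(mapping, pn, l), character(1))
    preds[, j] <- lut[preds[, j]]
  }
  truth <- table$true_labels
  if (!is.null(truth) && map_truth) {
    labs <- unique(truth)
    lut <- vapply(labs, function(l) query_mapping(mapping, "*", l), character(1))
    truth <- unname(lut[truth])
  }
  prediction_table(preds, protein_ids = table$protein_ids,
                   predictor_names = table$predictor_names,
                   true_labels = truth)
}

#' Read a location mapping from TSV
#'
#' Expected columns: \code{predictor}, \code{native_label},
#' \code{unified_label}; predictor \code{"*"} denotes generic rules.
#'
#' @param path TSV file path.
#' @param vocabulary unified vocabulary (default the five-class scheme).
#' @param fallback fallback unified label, or \code{NA} for strict matching.
#' @return a \code{\link{location_mapping}}.
#' @export
read_location_mapping <- function(path, vocabulary = unified_locations(),
                                  fallback = NA_character_) {
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("predictor", "native_label", "unified_label")
  if (!all(need %in% names(df)))
    stop("mapping file must have columns: ", paste(need, collapse = ", "))
  location_mapping(df[need], vocabulary = vocabulary, fallback = fallback)
}
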
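#' Severity categories for carcinogenicity endpoints
#'
#' Rodent carcinogenicity endpoints are graded on an ordinal five-level scale
#' reflecting the stage of the carcinogenic process they represent:
#'
#' 1. preneoplastic lesion
#' 2. benign tumor(s)
#' 3. malignant tumor(s) in a single organ
#' 4. malignant (metastasizing) tumors in different organs
#' 5. tumor-bearing animals
#'
#' Only categories 2-5 enter relative-potency estimation; preneoplastic
#' lesions (category 1) are read and inventoried but excluded from fitting.
#'
#' @param code integer in 1..5
#' @return a `severity_category` object (integer code with a `label`)
#' @export
#' @examples
#' severity_category(2)
severity_category <- function(code) {
  code <- as.integer(code)
  if (length(code) != 1L || is.na(code) || code < 1L || code > 5L) {
    stop("severity code must be a single integer in 1..5", call. = FALSE)
  }
  structure(code, label = severity_labels()[code], class = "severity_category")
}

#' @rdname severity_category
#' @export
severity_labels <- function() {
  c("preneoplastic lesion",
    "benign tumor(s)",
    "malignant tumor(s) in a single organ",
    "malignant (metastasizing) tumors in different organs",
    "tumor-bearing animals")
}

#' @export
print.severity_category <- function(x, ...) {
  cat(sprintf("severity %d: %s\n", unclass(x), attr(x, "label")))
  invisible(x)
}

# canonical form used for lookup keys: trimmed, lower case, single spaces
normalize_lesion_term <- function(term) {
  term <- tolower(trimws(term))
  gsub("[[:space:]]+", " ", term)
}

#' Read a lesion-term severity lookup table
#'
#' The table maps pathology lesion terms (case- and whitespace-insensitive)
#' to severity categories 1-5. A CSV with columns `lesion_term` and
#' `severity` is expected.
#'
#' @param path path to a CSV file
#' @return a `severity_lookup`: named integer vector keyed by normalized term
#' @export
read_severity_lookup <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lesion_term", "severity")
  if (!all(need %in% names(df))) {
    stop("severity lookup must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sev <- as.integer(df$severity)
  if (anyNA(sev) || any(sev < 1L | sev > 5L)) {
    stop("severity lookup contains codes outside 1..5", call. = FALSE)
  }
  key <- normalize_lesion_term(df$lesion_term)
  if (anyDuplicated(key)) {
    stop("duplicate lesion terms in lookup: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(sev, key), class = "severity_lookup")
}

#' Default severity lookup shipped with the package
#'
#' A reconstruction of the category definitions covering common rodent
#' lesion terminology: hyperplasia/metaplasia-type changes map to category
#' 1, adenomas/papillomas/fibromas to 2, single-organ carcinomas and
#' sarcomas to 3, metastasizing or multi-organ malignancies to 4, and
#' whole-animal tumor-bearing endpoints to 5. It is a default, not a
#' validated pathology reference; supply your own table via
#' [read_severity_lookup()] for production analyses.
#'
#' @return a `severity_lookup`
#' @export
default_severity_lookup <- function() {
  read_severity_lookup(ccemix_extdata("severity_lookup_default.csv"))
}

#' Assign a severity category to a lesion term
#'
#' Matching is case- and whitespace-insensitive. An exact match on the
#' normalized term is tried first; failing that, the longest trailing
#' sequence of words with an entry in the lookup is used, so qualified terms
#' such as "hepatocellular adenoma" resolve through their head noun
#' ("adenoma"). Unknown terms are an error, never a silent default.
#'
#' @param lesion_term non-empty character scalar
#' @param lookup a `severity_lookup`; defaults to the packaged table
#' @return a `severity_category`
#' @export
#' @examples
#' assign_severity("hyperplasia")
#' assign_severity("Hepatocellular Adenoma")
assign_severity <- function(lesion_term, lookup = default_severity_lookup()) {
  if (!is.character(lesion_term) || length(lesion_term) != 1L ||
      is.na(lesion_term) || !nzchar(trimws(lesion_term))) {
    stop("lesion_term must be a non-empty string", call. = FALSE)
  }
  key <- normalize_lesion_term(lesion_term)
  if (key %in% names(lookup)) {
    return(severity_category(lookup[[key]]))
  }
  words <- strsplit(key, " ", fixed = TRUE)[[1]]
  # longest trailing word sequence known to the lookup
  if (length(words) > 1L) {
    for (i in seq_along(words)[-1]) {
      suffix <- paste(words[i:length(words)], collapse = " ")
      if (suffix %in% names(lookup)) {
        return(severity_category(lookup[[suffix]]))
      }
    }
  }
  stop(sprintf("unclassified lesion term: \"%s\"", lesion_term), call. = FALSE)
}

#' Path to a packaged example/fixture file
#'
#' @param file file name under the package's `extdata/` directory; empty to
#'   list available files
#' @return a file path (or a vector of available file names)
#' @export
ccemix_extdata <- function(file = "") {
  if (!nzchar(file)) {
    return(dir(system.file("extdata", package = "ccemix")))
  }
  path <- system.file("extdata", file, package = "ccemix")
  if (!nzchar(path)) stop("no packaged file named ", file, call. = FALSE)
  path
}
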
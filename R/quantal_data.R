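#' Construct a quantal carcinogenicity dataset
#'
#' One dataset is one incidence table for a single combination of compound,
#' tissue, sex, tumor type, exposure duration and study duration: the unit
#' at which dose-response curves are fitted. Doses must be strictly
#' increasing (the first may be a zero control) and incidences cannot
#' exceed group sizes.
#'
#' @param compound_id compound identifier (e.g. an abbreviation)
#' @param lesion_term pathology term for the endpoint
#' @param severity severity category code 1-5 (see [severity_category()])
#' @param tissue,sex,tumor_type study metadata
#' @param exposure_weeks,study_weeks exposure and total study duration, weeks
#' @param dose numeric vector of dose levels (consistent inhalation units
#'   within one analysis, e.g. mg/m3)
#' @param n_at_risk integer vector, animals at risk per dose group
#' @param n_affected integer vector, animals with the lesion per dose group
#' @param dose_unit unit label carried along and checked at joint fits
#' @return a `quantal_dataset`
#' @export
quantal_dataset <- function(compound_id, lesion_term, severity,
                            tissue, sex, tumor_type,
                            exposure_weeks, study_weeks,
                            dose, n_at_risk, n_affected,
                            dose_unit = "mg/m3") {
  dose <- as.numeric(dose)
  n_at_risk <- as.integer(n_at_risk)
  n_affected <- as.integer(n_affected)
  if (length(dose) != length(n_at_risk) || length(dose) != length(n_affected)) {
    stop("dose, n_at_risk and n_affected must have equal length", call. = FALSE)
  }
  if (any(dose < 0)) stop("doses must be non-negative", call. = FALSE)
  if (is.unsorted(dose, strictly = TRUE)) {
    stop("doses must be strictly increasing (duplicate or unordered dose)",
         call. = FALSE)
  }
  if (any(n_at_risk <= 0L)) stop("n_at_risk must be positive", call. = FALSE)
  if (any(n_affected < 0L) || any(n_affected > n_at_risk)) {
    stop("n_affected must satisfy 0 <= n_affected <= n_at_risk", call. = FALSE)
  }
  structure(list(
    compound_id = as.character(compound_id),
    lesion_term = as.character(lesion_term),
    severity = as.integer(severity_category(severity)),
    tissue = as.character(tissue),
    sex = as.character(sex),
    tumor_type = as.character(tumor_type),
    exposure_weeks = as.numeric(exposure_weeks),
    study_weeks = as.numeric(study_weeks),
    dose = dose,
    n_at_risk = n_at_risk,
    n_affected = n_affected,
    dose_unit = as.character(dose_unit)
  ), class = "quantal_dataset")
}

#' @export
print.quantal_dataset <- function(x, ...) {
  cat(sprintf("quantal dataset: %s | %s | %s | %s | %g wk exposure (severity %d)\n",
              x$compound_id, x$tissue, x$sex, x$tumor_type,
              x$exposure_weeks, x$severity))
  print(data.frame(dose = x$dose, n_at_risk = x$n_at_risk,
                   n_affected = x$n_affected))
  invisible(x)
}

# key identifying one dataset (grouping columns for the long CSV format)
dataset_key <- function(d) {
  paste(d$compound_id, d$tissue, d$sex, d$tumor_type,
        d$exposure_weeks, d$study_weeks, d$lesion_term, sep = "|")
}

quantal_columns <- c("compound_id", "lesion_term", "severity", "tissue",
                     "sex", "tumor_type", "exposure_weeks", "study_weeks",
                     "dose", "n_at_risk", "n_affected", "dose_unit")

#' Read quantal datasets from a long-format CSV
#'
#' One row per dose group; rows sharing (compound, tissue, sex, tumor type,
#' exposure duration, study duration, lesion term) form one dataset. If a
#' `severity` column is absent it is derived from `lesion_term` via the
#' lookup. Validation errors report the offending row number.
#'
#' @param path CSV path (header row, comma-delimited, UTF-8)
#' @param lookup severity lookup used when the file has no severity column
#' @return a list of [quantal_dataset()] objects (empty list for an empty
#'   file)
#' @export
read_quantal_datasets <- function(path, lookup = default_severity_lookup()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(list())
  if (!"dose_unit" %in% names(df)) df$dose_unit <- "mg/m3"
  if (!"severity" %in% names(df)) {
    df$severity <- vapply(df$lesion_term, function(t)
      unclass(assign_severity(t, lookup)), integer(1))
  }
  need <- setdiff(quantal_columns, names(df))
  if (length(need)) {
    stop("quantal CSV is missing columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  # +1 for the header line so messages match the file as seen in an editor
  df$.row <- seq_len(nrow(df)) + 1L
  bad <- which(df$n_affected > df$n_at_risk)
  if (length(bad)) {
    stop(sprintf("row %d: n_affected (%d) exceeds n_at_risk (%d)",
                 df$.row[bad[1]], df$n_affected[bad[1]], df$n_at_risk[bad[1]]),
         call. = FALSE)
  }
  key <- paste(df$compound_id, df$tissue, df$sex, df$tumor_type,
               df$exposure_weeks, df$study_weeks, df$lesion_term, sep = "|")
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$dose), , drop = FALSE]
    if (anyDuplicated(g$dose)) {
      dup <- g$.row[duplicated(g$dose)][1]
      stop(sprintf("row %d: duplicate dose %g within one dataset", dup,
                   g$dose[duplicated(g$dose)][1]), call. = FALSE)
    }
    if (length(unique(g$dose_unit)) > 1L) {
      stop(sprintf("row %d: mixed dose units within one dataset", g$.row[1]),
           call. = FALSE)
    }
    quantal_dataset(g$compound_id[1], g$lesion_term[1], g$severity[1],
                    g$tissue[1], g$sex[1], g$tumor_type[1],
                    g$exposure_weeks[1], g$study_weeks[1],
                    g$dose, g$n_at_risk, g$n_affected, g$dose_unit[1])
  })
  unname(out[order(names(out))])
}

#' Write quantal datasets to the long CSV format read by
#' [read_quantal_datasets()]
#'
#' @param datasets list of `quantal_dataset`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_quantal_datasets <- function(datasets, path) {
  rows <- lapply(datasets, function(d) {
    data.frame(compound_id = d$compound_id, lesion_term = d$lesion_term,
               severity = d$severity, tissue = d$tissue, sex = d$sex,
               tumor_type = d$tumor_type, exposure_weeks = d$exposure_weeks,
               study_weeks = d$study_weeks, dose = d$dose,
               n_at_risk = d$n_at_risk, n_affected = d$n_affected,
               dose_unit = d$dose_unit, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Filter datasets eligible for relative-potency analysis
#'
#' Keeps datasets with exposure duration strictly greater than
#' `min_exposure` weeks and severity category 2-5 (preneoplastic lesions
#' are excluded from potency fitting).
#'
#' @param datasets list of `quantal_dataset`
#' @param min_exposure minimum exposure duration in weeks (exclusive;
#'   default 96)
#' @return the eligible subset, contents untouched
#' @export
filter_eligible <- function(datasets, min_exposure = 96) {
  stopifnot(min_exposure > 0)
  keep <- vapply(datasets, function(d)
    d$exposure_weeks > min_exposure && d$severity >= 2L && d$severity <= 5L,
    logical(1))
  datasets[keep]
}

#' Inventory of datasets per compound and severity category
#'
#' @param datasets list of `quantal_dataset`
#' @return data.frame with counts of datasets and dose groups per
#'   compound x severity
#' @export
dataset_inventory <- function(datasets) {
  if (!length(datasets)) {
    return(data.frame(compound_id = character(), severity = integer(),
                      n_datasets = integer(), n_groups = integer()))
  }
  df <- data.frame(
    compound_id = vapply(datasets, `[[`, character(1), "compound_id"),
    severity = vapply(datasets, `[[`, integer(1), "severity"),
    n_groups = vapply(datasets, function(d) length(d$dose), integer(1)))
  agg <- stats::aggregate(n_groups ~ compound_id + severity, df,
                          function(v) c(n = length(v), g = sum(v)))
  out <- data.frame(compound_id = agg$compound_id, severity = agg$severity,
                    n_datasets = agg$n_groups[, "n"],
                    n_groups = agg$n_groups[, "g"])
  out[order(out$compound_id, out$severity), , drop = FALSE]
}
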
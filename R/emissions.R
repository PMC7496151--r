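#' A positive quantity carried as two-sided geometric confidence bounds
#'
#' The working representation for every uncertain input of the
#' probabilistic comparison: per-stick emissions of each product and
#' relative potency factors, each held as a (5%, 95%) bound pair at the
#' default 90% confidence level.
#'
#' @param lb,ub positive bounds, `lb <= ub`
#' @param confidence two-sided confidence level the bounds represent
#' @return a `bounded_quantity`
#' @export
bounded_quantity <- function(lb, ub, confidence = 0.90) {
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  if (length(lb) != 1L || length(ub) != 1L || is.na(lb) || is.na(ub)) {
    stop("lb and ub must be single numbers", call. = FALSE)
  }
  if (lb <= 0 || !is.finite(lb)) stop("lb must be positive and finite", call. = FALSE)
  if (ub < lb) stop("ub must be >= lb", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  structure(list(lb = lb, ub = ub, confidence = confidence),
            class = "bounded_quantity")
}

#' @export
print.bounded_quantity <- function(x, ...) {
  cat(sprintf("[%.4g, %.4g] (%.0f%% bounds)\n", x$lb, x$ub,
              100 * x$confidence))
  invisible(x)
}

#' Replicate emission measurements for one compound in one product
#'
#' @param compound_id,product_id identifiers
#' @param values positive replicate measurements (micrograms per stick)
#' @param regime smoking-regime label (e.g. "HCI"); products compared under
#'   different regimes trigger a warning downstream
#' @return an `emission_replicates`
#' @export
emission_replicates <- function(compound_id, product_id, values,
                                regime = "unspecified") {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("replicate values must all be positive", call. = FALSE)
  }
  structure(list(compound_id = as.character(compound_id),
                 product_id = as.character(product_id),
                 values = values, regime = as.character(regime)),
            class = "emission_replicates")
}

#' Geometric-mean confidence interval from replicate measurements
#'
#' Student-t interval for the mean of the natural-log values,
#' exponentiated: `exp(mean(log v) +/- t * sd(log v) / sqrt(n))` with
#' `t = qt(1 - (1-confidence)/2, n - 1)`. This is the standard confidence
#' interval for a geometric mean and matches multiplicative (lognormal)
#' measurement variation.
#'
#' @param replicates an [emission_replicates()] or a plain numeric vector
#'   of at least 2 positive values
#' @param confidence two-sided level (default 0.90)
#' @return a [bounded_quantity()]
#' @export
#' @examples
#' geometric_mean_ci(c(10, 12, 9, 11))
geometric_mean_ci <- function(replicates, confidence = 0.90) {
  v <- if (inherits(replicates, "emission_replicates")) replicates$values
       else as.numeric(replicates)
  if (length(v) < 2L) {
    stop("need at least 2 replicates for a confidence interval", call. = FALSE)
  }
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("replicate values must all be positive", call. = FALSE)
  }
  lv <- log(v)
  m <- mean(lv); s <- stats::sd(lv); n <- length(lv)
  tq <- stats::qt(1 - (1 - confidence) / 2, df = n - 1)
  half <- tq * s / sqrt(n)
  bounded_quantity(exp(m - half), exp(m + half), confidence)
}

#' Read replicate emission measurements from CSV
#'
#' Expects columns `compound`, `product`, `value` and optionally `regime`.
#' Values written as `"<x"` are below the detection limit `x` and are
#' substituted by `x * lod_factor` (default `1/sqrt(2)`) with a warning.
#'
#' @param path CSV path
#' @param lod_factor substitution multiplier applied to detection limits
#' @return list of [emission_replicates()], one per (compound, product)
#' @export
read_emission_replicates <- function(path, lod_factor = 1 / sqrt(2)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("compound", "product", "value")
  if (!all(need %in% names(df))) {
    stop("emission replicate CSV needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"regime" %in% names(df)) df$regime <- "unspecified"
  raw <- trimws(df$value)
  censored <- startsWith(raw, "<")
  vals <- suppressWarnings(as.numeric(sub("^<", "", raw)))
  if (anyNA(vals)) {
    stop("non-numeric emission value at row ", which(is.na(vals))[1] + 1L,
         call. = FALSE)
  }
  if (any(censored)) {
    vals[censored] <- vals[censored] * lod_factor
    warning(sum(censored), " value(s) below detection limit substituted at ",
            "limit * ", format(lod_factor, digits = 4), call. = FALSE)
  }
  df$value <- vals
  key <- paste(df$compound, df$product, sep = "|")
  out <- lapply(split(df, key), function(g) {
    if (length(unique(g$regime)) > 1L) {
      warning("mixed smoking regimes for ", g$compound[1], "/", g$product[1],
              call. = FALSE)
    }
    emission_replicates(g$compound[1], g$product[1], g$value, g$regime[1])
  })
  unname(out[order(names(out))])
}

#' Read a table of pre-computed emission bounds
#'
#' Expects columns `compound`, `product`, `lb`, `ub`: two-sided 90%
#' geometric-mean bounds in micrograms per stick. The packaged default
#' comparison table (`ccemix_extdata("emission_bounds_table.csv")`) holds
#' the heated-tobacco versus cigarette case-study values.
#'
#' @param path CSV path
#' @param confidence level the bounds represent (default 0.90)
#' @return named list of products; each product a named list of
#'   [bounded_quantity()] keyed by compound
#' @export
read_emission_bounds <- function(path, confidence = 0.90) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "product", "lb", "ub")
  if (!all(need %in% names(df))) {
    stop("emission bounds CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    bq <- tryCatch(bounded_quantity(df$lb[i], df$ub[i], confidence),
                   error = function(e)
                     stop("row ", i + 1L, " (", df$compound[i], ", ",
                          df$product[i], "): ", conditionMessage(e),
                          call. = FALSE))
    out[[df$product[i]]][[df$compound[i]]] <- bq
  }
  lapply(out, function(p) p[order(names(p))])
}

#' Scale emission bounds by a consumption factor
#'
#' Consumption differences between products (sticks consumed relative to
#' the comparison baseline) act as a simple multiplier on a product's
#' emission bounds.
#'
#' @param bounds a [bounded_quantity()] or a named list of them
#' @param factor positive scalar
#' @return object of the same shape with both bounds multiplied
#' @export
apply_consumption_factor <- function(bounds, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop("consumption factor must be a positive number", call. = FALSE)
  }
  if (inherits(bounds, "bounded_quantity")) {
    return(bounded_quantity(bounds$lb * factor, bounds$ub * factor,
                            bounds$confidence))
  }
  lapply(bounds, apply_consumption_factor, factor = factor)
}
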
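#' Packaged case-study inputs
#'
#' `case_study_rpfs()` returns the packaged relative-potency bounds
#' (relative to 1,3-butadiene) for the compounds with emission data, the
#' reference compound itself as a degenerate (1, 1) bound — a compound's
#' potency relative to itself is 1 by definition.
#' `case_study_emissions()` returns the packaged heated-tobacco-product
#' and cigarette per-stick emission bounds.
#'
#' @param emission_compounds_only keep only compounds present in the
#'   emission table (the set entering the CCE computation)
#' @return named list(s) of [bounded_quantity()]
#' @export
case_study_rpfs <- function(emission_compounds_only = TRUE) {
  df <- utils::read.csv(ccemix_extdata("rpf_bounds_table.csv"),
                        stringsAsFactors = FALSE)
  if (emission_compounds_only) df <- df[df$has_emission_data, , drop = FALSE]
  out <- lapply(seq_len(nrow(df)), function(i) {
    if (df$is_reference[i]) bounded_quantity(1, 1)
    else bounded_quantity(df$lb[i], df$ub[i])
  })
  names(out) <- df$compound
  out[order(names(out))]
}

#' @rdname case_study_rpfs
#' @export
case_study_emissions <- function() {
  read_emission_bounds(ccemix_extdata("emission_bounds_table.csv"))
}

#' Run the six-step comparison pipeline
#'
#' Executes severity classification, per-dataset BMD fitting,
#' critical-dataset selection, covariate RPF estimation with
#' severity-category combination, emission-interval computation,
#' probabilistic CCE evaluation and the health-impact translation, writing
#' per-step artifacts to `out_dir`. Two entry modes:
#'
#' * **bounds mode** (`rpf_bounds` + `emission_bounds` given): steps 1-4
#'   are skipped and pre-computed interval tables are used directly — the
#'   mode in which the packaged case study is reproducible.
#' * **full mode** (`quantal` + `emissions` given): raw incidence tables
#'   and replicate measurements are processed through all six steps.
#'
#' @param quantal path to a quantal dataset CSV (full mode)
#' @param emissions path to a replicate emissions CSV (full mode)
#' @param rpf_bounds path to an RPF bounds CSV with columns `compound`,
#'   `lb`, `ub` and optionally `is_reference` (bounds mode)
#' @param emission_bounds path to an emission bounds CSV (bounds mode)
#' @param severity_lookup optional path to a severity lookup CSV
#' @param reference_id reference compound (full mode)
#' @param baseline_product,alt_product product labels in the emission
#'   table; numerator and denominator of the CCE
#' @param bmr benchmark response for BMD reporting
#' @param min_exposure_weeks eligibility threshold (exclusive) for exposure
#'   duration
#' @param n_samples Monte-Carlo draws for the CCE
#' @param seed RNG seed, recorded in all outputs
#' @param consumption_factor sticks-consumed ratio applied to the
#'   alternative product's emissions
#' @param out_dir artifact directory (created if missing)
#' @return invisibly, a list with the CCE result, the health translation,
#'   the contribution table and the paths of all written artifacts
#' @export
run_pipeline <- function(quantal = NULL, emissions = NULL,
                         rpf_bounds = NULL, emission_bounds = NULL,
                         severity_lookup = NULL,
                         reference_id = "1,3-Butadiene",
                         baseline_product = "cigarette",
                         alt_product = "htp",
                         bmr = 0.10, min_exposure_weeks = 96,
                         n_samples = 1e6, seed = 1L,
                         consumption_factor = 1, out_dir = ".") {
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline aborted at %s: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  write_json <- function(x, file) {
    path <- file.path(out_dir, file)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    artifacts[[file]] <<- path
    path
  }
  write_table <- function(x, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(x, path, row.names = FALSE)
    artifacts[[file]] <<- path
    path
  }
  inputs <- Filter(Negate(is.null),
                   list(quantal = quantal, emissions = emissions,
                        rpf_bounds = rpf_bounds,
                        emission_bounds = emission_bounds,
                        severity_lookup = severity_lookup))
  provenance <- list(
    package = "ccemix",
    version = as.character(utils::packageVersion("ccemix")),
    seed = seed, n_samples = n_samples, bmr = bmr,
    consumption_factor = consumption_factor,
    input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p))))

  bounds_mode <- !is.null(rpf_bounds) && !is.null(emission_bounds)
  if (!bounds_mode && (is.null(quantal) || is.null(emissions))) {
    stop(paste("supply either rpf_bounds + emission_bounds (bounds mode)",
               "or quantal + emissions (full mode)"), call. = FALSE)
  }

  if (bounds_mode) {
    rpf_df <- step("step 3 (RPF bounds input)", {
      df <- utils::read.csv(rpf_bounds, stringsAsFactors = FALSE)
      if (!all(c("compound", "lb", "ub") %in% names(df))) {
        stop("RPF bounds CSV needs columns compound, lb, ub", call. = FALSE)
      }
      df
    })
    rpf_map <- lapply(seq_len(nrow(rpf_df)), function(i) {
      if (isTRUE(rpf_df$is_reference[i])) bounded_quantity(1, 1)
      else bounded_quantity(rpf_df$lb[i], rpf_df$ub[i])
    })
    names(rpf_map) <- rpf_df$compound
    em <- step("step 4 (emission bounds input)",
               read_emission_bounds(emission_bounds))
  } else {
    lookup <- step("step 1 (severity classification)", {
      if (is.null(severity_lookup)) default_severity_lookup()
      else read_severity_lookup(severity_lookup)
    })
    datasets <- step("step 1 (severity classification)",
                     read_quantal_datasets(quantal, lookup))
    write_table(dataset_inventory(datasets), "severity_inventory.csv")
    eligible <- filter_eligible(datasets, min_exposure_weeks)
    if (!length(eligible)) {
      stop("pipeline aborted at step 1 (severity classification): ",
           "no eligible datasets (severity 2-5, exposure > ",
           min_exposure_weeks, " weeks)", call. = FALSE)
    }
    sev_levels <- sort(unique(vapply(eligible, `[[`, integer(1), "severity")))
    per_sev <- list()
    bmd_rows <- list()
    for (s in sev_levels) {
      sub <- eligible[vapply(eligible, function(d) d$severity == s,
                             logical(1))]
      if (length(unique(vapply(sub, `[[`, character(1), "compound_id"))) < 2L)
        next
      crit <- step(sprintf("step 2 (BMD fits, severity %d)", s),
                   select_critical(sub, bmr = bmr))
      bmd_rows[[as.character(s)]] <-
        cbind(severity = s, attr(crit, "bmd_table"))
      cov <- step(sprintf("step 3 (RPF estimation, severity %d)", s),
                  fit_covariate(crit, reference_id, bmr = bmr))
      per_sev[[as.character(s)]] <- cov$rpf
    }
    if (!length(per_sev)) {
      stop("pipeline aborted at step 3 (RPF estimation): no severity ",
           "category has two or more compounds", call. = FALSE)
    }
    write_table(do.call(rbind, bmd_rows), "bmd_per_dataset.csv")
    all_rpf <- do.call(rbind, per_sev)
    write_table(all_rpf, "rpf_per_severity.csv")
    combined <- do.call(rbind, lapply(
      split(all_rpf, all_rpf$compound_id), combine_severity_rpfs))
    write_table(combined, "rpf_combined.csv")
    rpf_map <- lapply(seq_len(nrow(combined)), function(i) {
      if (combined$compound_id[i] == reference_id) bounded_quantity(1, 1)
      else bounded_quantity(combined$lb[i], combined$ub[i])
    })
    names(rpf_map) <- combined$compound_id

    reps <- step("step 4 (emission intervals)",
                 read_emission_replicates(emissions))
    em <- list()
    for (r in reps) {
      em[[r$product_id]][[r$compound_id]] <-
        step("step 4 (emission intervals)", geometric_mean_ci(r))
    }
  }

  cce <- step("step 5 (CCE computation)", {
    if (!baseline_product %in% names(em) || !alt_product %in% names(em)) {
      stop("emission table lacks product(s): ",
           paste(setdiff(c(baseline_product, alt_product), names(em)),
                 collapse = ", "), call. = FALSE)
    }
    e_cig <- em[[baseline_product]]
    e_alt <- apply_consumption_factor(em[[alt_product]], consumption_factor)
    shared <- Reduce(intersect, list(names(e_cig), names(e_alt),
                                     names(rpf_map)))
    if (!length(shared)) {
      stop("no compound has both RPF and emission data for both products",
           call. = FALSE)
    }
    sample_cce(e_cig[shared], e_alt[shared], rpf_map[shared],
               n = n_samples, seed = seed)
  })
  emission_rows <- do.call(rbind, lapply(names(em), function(p)
    data.frame(compound = names(em[[p]]), product = p,
               lb = vapply(em[[p]], `[[`, numeric(1), "lb"),
               ub = vapply(em[[p]], `[[`, numeric(1), "ub"),
               row.names = NULL)))
  write_table(emission_rows, "emission_bounds.csv")

  contrib <- contribution_report(cce)
  write_table(contrib, "contributions.csv")
  health <- step("step 6 (health translation)",
                 health_translation(cce$p05, cce$p95))
  write_json(c(provenance, list(
    p05 = unname(cce$p05), p50 = unname(cce$p50), p95 = unname(cce$p95),
    compounds = contrib$compound[order(contrib$compound)],
    health = list(h_lower = health$h_lower, h_upper = health$h_upper,
                  verdict = health$verdict))), "cce.json")

  invisible(list(cce = cce, health = health, contributions = contrib,
                 artifacts = artifacts))
}
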
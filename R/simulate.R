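#' Configuration for a synthetic product-comparison study
#'
#' Describes a complete synthetic study: tumor-incidence data generated
#' from parallel log-dose quantal exponential curves with known relative
#' potencies, and lognormal replicate emission measurements for two
#' products with known geometric means. Every downstream stage
#' (dose-response fitting, RPF estimation, emission intervals, CCE) can
#' then be validated against the configured truth.
#'
#' The default scenario mirrors the shape of a realistic product
#' comparison: eight compounds with true potencies spanning four orders of
#' magnitude around a reference compound, a 5% background tumor incidence,
#' steepness 1.2, four dose groups of 50 animals (the standard rodent
#' bioassay group size), and five emission replicates per compound and
#' product with a geometric SD of 1.3, the baseline product emitting
#' 10-fold more than the alternative.
#'
#' @param true_rpfs named positive vector of relative potencies; must be 1
#'   for `reference_id`
#' @param reference_id name of the reference compound
#' @param steepness shared shape parameter g of the quantal exponential
#'   curves
#' @param background background incidence, recycled over compounds
#' @param beta_ref dose-scale parameter of the reference compound; compound
#'   i responds with scale `beta_ref / rpf_i`
#' @param base_doses dose grid of the reference compound; compound i is
#'   dosed at `base_doses / rpf_i` so each compound's design spans its own
#'   response range
#' @param group_size animals per dose group
#' @param emission_gm data.frame (`compound`, `product`, `gm`): true
#'   geometric-mean emissions; defaults to a two-product layout
#' @param emission_gsd geometric standard deviation of replicates (>= 1)
#' @param n_replicates emission replicates per compound and product
#' @param seed RNG seed for data generation
#' @return a `simulation_config`
#' @export
simulation_config <- function(true_rpfs = NULL, reference_id = "ref",
                              steepness = 1.2, background = 0.05,
                              beta_ref = 100,
                              base_doses = c(0, 50, 100, 200),
                              group_size = 50,
                              emission_gm = NULL, emission_gsd = 1.3,
                              n_replicates = 5, seed = 1L) {
  if (is.null(true_rpfs)) {
    true_rpfs <- c(ref = 1, cmp01 = 0.01, cmp02 = 0.1, cmp03 = 0.5,
                   cmp04 = 2, cmp05 = 10, cmp06 = 50, cmp07 = 100)
  }
  if (is.null(names(true_rpfs)) || any(!nzchar(names(true_rpfs)))) {
    stop("true_rpfs must be a named vector", call. = FALSE)
  }
  if (!reference_id %in% names(true_rpfs)) {
    stop("reference_id must appear in true_rpfs", call. = FALSE)
  }
  if (abs(true_rpfs[[reference_id]] - 1) > 1e-12) {
    stop("the reference compound's true RPF must be 1", call. = FALSE)
  }
  if (any(true_rpfs <= 0)) stop("true RPFs must be positive", call. = FALSE)
  stopifnot(steepness > 0, beta_ref > 0, group_size >= 1,
            emission_gsd >= 1, n_replicates >= 1,
            background >= 0, background < 1)
  if (is.null(emission_gm)) {
    comps <- names(true_rpfs)
    emission_gm <- rbind(
      data.frame(compound = comps, product = "cigarette",
                 gm = 10^seq(2, -1, length.out = length(comps))),
      data.frame(compound = comps, product = "htp",
                 gm = 10^seq(2, -1, length.out = length(comps)) / 10))
  }
  stopifnot(all(c("compound", "product", "gm") %in% names(emission_gm)),
            all(emission_gm$gm > 0))
  structure(list(true_rpfs = true_rpfs, reference_id = reference_id,
                 steepness = steepness, background = background,
                 beta_ref = beta_ref, base_doses = sort(base_doses),
                 group_size = as.integer(group_size),
                 emission_gm = emission_gm, emission_gsd = emission_gsd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate binomial tumor-incidence datasets from parallel curves
#'
#' For compound i the incidence at dose d is drawn binomially from
#' `p(d) = c + (1 - c) * (1 - exp(-(rpf_i * d / beta_ref)^g))`, i.e. all
#' compounds share one curve on the potency-adjusted dose scale — the
#' dose-addition situation the estimation machinery assumes.
#'
#' @param config a [simulation_config()]
#' @return list of [quantal_dataset()], one per compound (severity 3)
#' @export
simulate_quantal <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, {
    lapply(names(config$true_rpfs), function(cp) {
      rpf <- config$true_rpfs[[cp]]
      d <- config$base_doses / rpf
      p <- quantal_response(d, config$background,
                            config$beta_ref / rpf, config$steepness)
      x <- stats::rbinom(length(d), config$group_size, p)
      quantal_dataset(cp, "carcinoma", 3, "lung", "male", "carcinoma",
                      104, 104, d, rep(config$group_size, length(d)), x)
    })
  })
}

#' Simulate lognormal emission replicates
#'
#' @param config a [simulation_config()]
#' @return list of [emission_replicates()], one per (compound, product)
#' @export
simulate_emissions <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  gm <- config$emission_gm
  sdlog <- log(config$emission_gsd)
  # offset the quantal stream so both generators can share one config seed
  .with_seed(config$seed + 10000L, {
    lapply(seq_len(nrow(gm)), function(i) {
      v <- if (sdlog == 0) rep(gm$gm[i], config$n_replicates)
           else stats::rlnorm(config$n_replicates, log(gm$gm[i]), sdlog)
      emission_replicates(gm$compound[i], gm$product[i], v, "simulated")
    })
  })
}

#' True change in cumulative exposure implied by a configuration
#'
#' Evaluates the potency-weighted emission ratio at the configured true
#' geometric means and true RPFs — the recovery target for full-pipeline
#' tests. Products are taken as "cigarette" (baseline, numerator) and
#' "htp" (alternative, denominator) unless the configuration's emission
#' table names exactly two other products, in which case the first sorted
#' name is the baseline.
#'
#' @param config a [simulation_config()]
#' @return the true CCE (scalar)
#' @export
end_to_end_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  gm <- config$emission_gm
  prods <- sort(unique(gm$product))
  if (all(c("cigarette", "htp") %in% prods)) {
    base <- "cigarette"; alt <- "htp"
  } else if (length(prods) == 2L) {
    base <- prods[1]; alt <- prods[2]
  } else {
    stop("emission table must describe exactly two products", call. = FALSE)
  }
  num <- den <- 0
  for (cp in intersect(names(config$true_rpfs), unique(gm$compound))) {
    eb <- gm$gm[gm$compound == cp & gm$product == base]
    ea <- gm$gm[gm$compound == cp & gm$product == alt]
    if (!length(eb) || !length(ea)) next
    num <- num + eb[1] * config$true_rpfs[[cp]]
    den <- den + ea[1] * config$true_rpfs[[cp]]
  }
  if (den == 0) stop("no compound has emissions for both products",
                     call. = FALSE)
  num / den
}
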
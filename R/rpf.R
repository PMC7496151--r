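#' Select the critical (lowest-BMD) dataset per compound
#'
#' Within one severity category each compound may have several datasets
#' (tissues, sexes, tumor types). The critical dataset is the one with the
#' smallest fitted BMD point estimate; ties are broken by the smaller BMDL
#' and then by lexicographic dataset key, so the choice is deterministic
#' under permutation of the input.
#'
#' @param datasets list of [quantal_dataset()], all of one severity
#'   category and one dose unit
#' @param bmr benchmark response used for the per-dataset fits
#' @return named list (by compound) of the selected datasets; the
#'   per-dataset BMD table is attached as attribute `"bmd_table"`
#' @export
select_critical <- function(datasets, bmr = 0.10) {
  if (!length(datasets)) stop("no datasets supplied", call. = FALSE)
  sev <- unique(vapply(datasets, `[[`, integer(1), "severity"))
  if (length(sev) > 1L) {
    stop("datasets span several severity categories: ",
         paste(sort(sev), collapse = ", "), call. = FALSE)
  }
  tab <- do.call(rbind, lapply(datasets, function(ds) {
    f <- tryCatch(fit_single(ds, bmr = bmr), error = function(e) NULL)
    data.frame(
      compound_id = ds$compound_id, key = dataset_key(ds),
      bmd = if (is.null(f)) NA_real_ else f$bmd$bmd,
      bmdl = if (is.null(f)) NA_real_ else f$bmd$bmdl,
      converged = !is.null(f) && f$fit$converged,
      stringsAsFactors = FALSE)
  }))
  chosen <- list()
  for (cp in sort(unique(tab$compound_id))) {
    sub <- tab[tab$compound_id == cp & tab$converged, , drop = FALSE]
    if (!nrow(sub)) {
      stop("no convergent dose-response fit for compound: ", cp,
           call. = FALSE)
    }
    sub <- sub[order(sub$bmd, sub$bmdl, sub$key), , drop = FALSE]
    idx <- match(sub$key[1], vapply(datasets, dataset_key, character(1)))
    chosen[[cp]] <- datasets[[idx]]
  }
  structure(chosen, bmd_table = tab)
}

# ---- joint (covariate) likelihood ------------------------------------------

# theta = (logit c_1..K, log g, log beta_ref, delta_2..K) with
# delta_i = log RPF_i and beta_i = beta_ref / RPF_i (reference is compound 1)
.nll_joint <- function(theta, D, N, X, ci, K) {
  cc <- stats::plogis(theta[seq_len(K)])[ci]
  g <- exp(theta[K + 1L])
  lbeta <- theta[K + 2L] - c(0, theta[K + 2L + seq_len(K - 1L)])
  beta <- exp(lbeta)[ci]
  p <- .clamp_p(cc + (1 - cc) * (1 - exp(-(D / beta)^g)))
  -sum(stats::dbinom(X, N, p, log = TRUE))
}

# analytic gradient of .nll_joint (chain rule through the logit/log links)
.nll_joint_grad <- function(theta, D, N, X, ci, K) {
  cc_k <- stats::plogis(theta[seq_len(K)])
  cc <- cc_k[ci]
  g <- exp(theta[K + 1L])
  delta <- c(0, theta[K + 2L + seq_len(K - 1L)])
  lbeta_k <- theta[K + 2L] - delta
  lbeta <- lbeta_k[ci]
  pos <- D > 0
  t <- numeric(length(D))
  t[pos] <- exp(g * (log(D[pos]) - lbeta[pos]))
  et <- exp(-t)
  er <- 1 - et
  p <- .clamp_p(cc + (1 - cc) * er)
  w <- -(X / p - (N - X) / (1 - p))          # d nll / d p
  u <- w * (1 - cc) * et                     # d nll / d t
  gt <- u * g * t                            # d nll / d log-scale shifts
  grad_lc <- vapply(seq_len(K), function(k)
    sum(w[ci == k] * (1 - er[ci == k])) * cc_k[k] * (1 - cc_k[k]),
    numeric(1))
  ld <- numeric(length(D))
  ld[pos] <- log(D[pos]) - lbeta[pos]
  grad_lg <- sum(gt * ld)
  grad_lbref <- -sum(gt)
  grad_delta <- vapply(2:K, function(k) sum(gt[ci == k]), numeric(1))
  c(grad_lc, grad_lg, grad_lbref, grad_delta)
}

#' Joint covariate fit: shared steepness, per-compound potency
#'
#' Fits all critical datasets simultaneously with one steepness parameter
#' `g` shared across compounds, a per-dataset background and a per-compound
#' dose scale `beta`. Under the shared steepness the curves are parallel on
#' log-dose, and the relative potency factor of compound *i* is the
#' horizontal shift `RPF_i = beta_ref / beta_i = BMD_ref / BMD_i`: a pure
#' ratio of dose scales, independent of the BMR. Two-sided
#' profile-likelihood intervals on each log RPF use a log-likelihood drop
#' of `qchisq(conf, 1)/2` (1.3528 at the default 90%).
#'
#' Weak datasets (no significant trend) borrow steepness from the others
#' and still yield an informative one-sided interval; an unbounded side is
#' coded `0` (lower) or `Inf` (upper).
#'
#' @param critical_datasets named list of [quantal_dataset()], one per
#'   compound and all of one severity category (see [select_critical()])
#' @param reference_id compound whose potency defines RPF = 1
#' @param bmr benchmark response; affects reported BMDs only, not RPFs
#' @param conf two-sided confidence level for the RPF intervals
#' @return a `covariate_fit`: list with `fit` (shared steepness, per-compound
#'   beta and BMD, per-dataset background, log-likelihood) and `rpf`
#'   (data.frame: compound_id, reference_id, severity, rpf, lb, ub)
#' @export
fit_covariate <- function(critical_datasets, reference_id, bmr = 0.10,
                          conf = 0.90) {
  ds <- critical_datasets
  comps <- vapply(ds, `[[`, character(1), "compound_id")
  if (anyDuplicated(comps)) {
    stop("expected one critical dataset per compound", call. = FALSE)
  }
  names(ds) <- comps
  if (length(ds) < 2L) stop("joint fit needs at least 2 compounds", call. = FALSE)
  if (!reference_id %in% comps) {
    stop("reference compound not among datasets: ", reference_id, call. = FALSE)
  }
  units <- unique(vapply(ds, `[[`, character(1), "dose_unit"))
  if (length(units) > 1L) {
    stop("datasets mix dose units (", paste(units, collapse = ", "),
         "); relative potencies require a single unit", call. = FALSE)
  }
  sev <- unique(vapply(ds, `[[`, integer(1), "severity"))
  if (length(sev) > 1L) {
    stop("datasets span several severity categories", call. = FALSE)
  }
  # reference first, others in sorted order (deterministic)
  ord <- c(reference_id, sort(setdiff(comps, reference_id)))
  ds <- ds[ord]
  K <- length(ds)
  D <- unlist(lapply(ds, `[[`, "dose"))
  N <- unlist(lapply(ds, `[[`, "n_at_risk"))
  X <- unlist(lapply(ds, `[[`, "n_affected"))
  ci <- rep(seq_len(K), vapply(ds, function(d) length(d$dose), integer(1)))

  # starts from per-dataset fits (point estimates only)
  singles <- lapply(ds, function(d)
    tryCatch(fit_single(d, bmr = bmr, ci = FALSE), error = function(e) NULL))
  lc0 <- vapply(seq_len(K), function(k) {
    if (!is.null(singles[[k]])) stats::qlogis(min(max(
      singles[[k]]$fit$background, 1e-4), 1 - 1e-4))
    else stats::qlogis((X[ci == k][1] + 0.5) / (N[ci == k][1] + 1))
  }, numeric(1))
  lB0 <- vapply(seq_len(K), function(k) {
    dk <- D[ci == k]
    if (!is.null(singles[[k]]) && is.finite(singles[[k]]$fit$beta) &&
        singles[[k]]$fit$beta < 1e6 * max(dk)) log(singles[[k]]$fit$beta)
    else log(max(dk))
  }, numeric(1))
  g_pool <- stats::median(vapply(singles, function(s)
    if (is.null(s)) NA_real_ else s$fit$steepness, numeric(1)), na.rm = TRUE)
  if (!is.finite(g_pool) || g_pool <= 0) g_pool <- 1
  starts <- lapply(c(g_pool, 0.5, 1, 2, 4), function(g0)
    c(lc0, log(g0), lB0[1], lB0[1] - lB0[-1]))

  run_bfgs <- function(start, maxit = 400) {
    tryCatch(stats::optim(start, .nll_joint, gr = .nll_joint_grad,
                          method = "BFGS", D = D, N = N, X = X, ci = ci,
                          K = K, control = list(maxit = maxit,
                                                reltol = 1e-12)),
             error = function(e) NULL)
  }
  best <- NULL
  for (s in starts) {
    res <- run_bfgs(s)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("joint fit failed from all starts", call. = FALSE)
  # simplex polish guards against BFGS stalling on a kink
  polish <- tryCatch(
    stats::optim(best$par, .nll_joint, method = "Nelder-Mead", D = D, N = N,
                 X = X, ci = ci, K = K,
                 control = list(maxit = 3000, reltol = 1e-10)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value < best$value) best <- polish
  final <- run_bfgs(best$par)
  if (!is.null(final) && final$value <= best$value) best <- final
  theta <- best$par
  nll_min <- best$value
  g <- exp(theta[K + 1L])
  lbeta <- theta[K + 2L] - c(0, theta[K + 2L + seq_len(K - 1L)])
  delta_hat <- c(0, theta[K + 2L + seq_len(K - 1L)])

  crit <- stats::qchisq(conf, 1) / 2
  target <- nll_min + crit
  # profile one delta_i: all other parameters re-optimised, warm-started
  profile_delta <- function(i) {
    free <- setdiff(seq_along(theta), K + 2L + i)  # drop delta_i slot
    warm <- theta[free]
    prof <- function(dval) {
      expand <- function(th) {
        full <- numeric(length(theta))
        full[free] <- th
        full[K + 2L + i] <- dval
        full
      }
      inner <- function(th) .nll_joint(expand(th), D, N, X, ci, K)
      inner_gr <- function(th)
        .nll_joint_grad(expand(th), D, N, X, ci, K)[free]
      res <- stats::optim(warm, inner, gr = inner_gr, method = "BFGS",
                          control = list(maxit = 200, reltol = 1e-12))
      warm <<- res$par
      res$value
    }
    lo <- .profile_bound(prof, delta_hat[i + 1L], target, -1,
                         limit_value = -Inf)
    warm <- theta[free]
    up <- .profile_bound(prof, delta_hat[i + 1L], target, +1,
                         limit_value = Inf)
    c(lo, up)
  }
  ci_mat <- if (K > 1L) vapply(seq_len(K - 1L), profile_delta, numeric(2))
  rpf <- data.frame(
    compound_id = ord,
    reference_id = reference_id,
    severity = sev,
    rpf = exp(delta_hat),
    lb = c(1, exp(ci_mat[1, ])),
    ub = c(1, exp(ci_mat[2, ])),
    stringsAsFactors = FALSE)
  rownames(rpf) <- NULL

  fit <- structure(list(
    background = stats::plogis(theta[seq_len(K)]),
    beta = stats::setNames(exp(lbeta), ord),
    bmd = stats::setNames(bmd_from_parameters(exp(lbeta), g, bmr), ord),
    steepness = g, bmr = bmr, log_lik = -nll_min,
    converged = best$convergence == 0,
    n_params = length(theta)), class = "model_fit")
  structure(list(fit = fit, rpf = rpf, conf = conf),
            class = "covariate_fit")
}

#' @export
print.covariate_fit <- function(x, ...) {
  cat(sprintf("covariate fit: %d compounds, shared g = %.4g, logLik = %.3f\n",
              length(x$fit$beta), x$fit$steepness, x$fit$log_lik))
  print(x$rpf, digits = 4)
  invisible(x)
}

#' Likelihood-ratio check of the parallel-curves assumption
#'
#' Compares the shared-steepness joint model against the unrestricted
#' alternative in which every compound has its own steepness (equivalent to
#' independent per-dataset fits). The likelihood-ratio statistic has
#' `n_compounds - 1` degrees of freedom under the null of parallelism. The
#' check is advisory: relative potencies are only well defined when the
#' curves are (approximately) parallel, but a rejection does not stop the
#' pipeline.
#'
#' @inheritParams fit_covariate
#' @return a `parallelism_check`: list with `lr`, `df`, `p_value`,
#'   `applicable`
#' @export
check_parallelism <- function(critical_datasets, reference_id, bmr = 0.10) {
  if (length(critical_datasets) < 2L) {
    return(structure(list(lr = NA_real_, df = 0L, p_value = NA_real_,
                          applicable = FALSE), class = "parallelism_check"))
  }
  joint <- fit_covariate(critical_datasets, reference_id, bmr = bmr)
  ll_free <- sum(vapply(critical_datasets, function(d)
    fit_single(d, bmr = bmr, ci = FALSE)$fit$log_lik, numeric(1)))
  lr <- max(0, 2 * (ll_free - joint$fit$log_lik))
  df <- length(critical_datasets) - 1L
  structure(list(lr = lr, df = df,
                 p_value = stats::pchisq(lr, df, lower.tail = FALSE),
                 applicable = TRUE), class = "parallelism_check")
}

#' @export
print.parallelism_check <- function(x, ...) {
  if (!x$applicable) {
    cat("parallelism check: not applicable (single compound)\n")
  } else {
    cat(sprintf("parallelism LR = %.3f on %d df, p = %.4f\n",
                x$lr, x$df, x$p_value))
  }
  invisible(x)
}

# 5%/95% (or other) quantile of an equal-weight lognormal mixture,
# solved on the mixture CDF
.mixture_quantile <- function(q, mu, sigma) {
  sigma <- pmax(sigma, 1e-12)
  cdf <- function(lx) mean(stats::pnorm((lx - mu) / sigma))
  lo <- min(mu - 10 * sigma); hi <- max(mu + 10 * sigma)
  exp(stats::uniroot(function(lx) cdf(lx) - q, lower = lo, upper = hi,
                     tol = 1e-10)$root)
}

#' Combine severity-specific RPF intervals into one interval per compound
#'
#' Each severity-specific 90% interval is interpreted as the 5th/95th
#' percentile pair of a lognormal (the same calibration used for the
#' probabilistic CCE computation); the combined interval is the 5th/95th
#' percentile pair of the equal-weight mixture of those lognormals,
#' computed from the analytic mixture CDF. A single input interval is
#' returned unchanged.
#'
#' @param per_severity data.frame of RPF rows for one compound (columns
#'   `compound_id`, `reference_id`, `lb`, `ub`; one row per severity
#'   category)
#' @param conf confidence level the bounds represent (default 0.90)
#' @return one-row data.frame with `severity = "combined"`
#' @export
combine_severity_rpfs <- function(per_severity, conf = 0.90) {
  stopifnot(is.data.frame(per_severity), nrow(per_severity) >= 1L)
  if (length(unique(per_severity$compound_id)) != 1L) {
    stop("combine_severity_rpfs expects rows for a single compound",
         call. = FALSE)
  }
  out <- data.frame(
    compound_id = per_severity$compound_id[1],
    reference_id = per_severity$reference_id[1],
    severity = "combined",
    rpf = NA_real_, lb = NA_real_, ub = NA_real_,
    stringsAsFactors = FALSE)
  if (nrow(per_severity) == 1L) {
    out$rpf <- if ("rpf" %in% names(per_severity)) per_severity$rpf[1] else
      sqrt(per_severity$lb[1] * per_severity$ub[1])
    out$lb <- per_severity$lb[1]
    out$ub <- per_severity$ub[1]
    return(out)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  mu <- (log(per_severity$lb) + log(per_severity$ub)) / 2
  sigma <- (log(per_severity$ub) - log(per_severity$lb)) / (2 * z)
  ql <- (1 - conf) / 2
  out$lb <- .mixture_quantile(ql, mu, sigma)
  out$ub <- .mixture_quantile(1 - ql, mu, sigma)
  out$rpf <- .mixture_quantile(0.5, mu, sigma)
  out
}
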
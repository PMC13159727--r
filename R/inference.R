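# derived sub-seeds stay below 2^31 and are decorrelated by a fixed multiplier
.derive_seed <- function(root, a, b = 0) {
  (root * 48271 + a * 16807 + b * 69621 + 1) %% 2147483647
}

.obs_fingerprint <- function(obs) {
  v <- as.vector(obs$counts)
  c(dims = paste(dim(obs$counts), collapse = "x"),
    total = sum(v), wsum = sum(v * seq_along(v)))
}

#' Composite log-likelihood of an observed SFS
#'
#' lnCL = sum over polymorphic cells of m_i * ln(max(p_i, p_min)), the
#' multinomial composite likelihood of SFS entry counts m against expected
#' cell probabilities p (natural log). Monomorphic corner cells are excluded.
#'
#' When \code{pairwise = TRUE} the statistic is instead summed over the 2D
#' marginal spectra of every unordered population pair (all marginal cells
#' included: every site is polymorphic in the full sample, so the pair
#' corner cells are legitimate, informative categories). The pairwise-2D
#' composite has far lower Monte-Carlo variance than the sparse
#' high-dimensional joint at desk scale, mirroring how model fit is
#' conventionally validated against 2D and 1D spectra.
#'
#' @param obs observed \code{sfs} (counts).
#' @param probs expected \code{sfs} of probabilities (as from
#'   \code{\link{expected_sfs_probs}}).
#' @param p_min probability floor for cells with observed sites but zero
#'   simulated mass; defaults to the floor recorded by
#'   \code{expected_sfs_probs}, else 1e-10.
#' @param pairwise sum the composite over all pairwise 2D marginals instead
#'   of the full joint spectrum.
#' @return scalar lnCL.
#' @export
composite_log_likelihood <- function(obs, probs, p_min = NULL,
                                     pairwise = FALSE) {
  if (!identical(unname(dim(obs$counts)), unname(dim(probs$counts))))
    stop("observed and expected SFS have different dimensions")
  if (!identical(obs$folded, probs$folded))
    stop("folded/unfolded mismatch between observed and expected SFS")
  if (is.null(p_min)) p_min <- attr(probs, "p_min")
  if (is.null(p_min)) p_min <- 1e-10
  stopifnot(p_min > 0)
  if (pairwise && length(obs$pops) >= 2) {
    pairs <- utils::combn(obs$pops, 2)
    tot <- 0
    for (k in seq_len(ncol(pairs))) {
      o <- marginalize_sfs(obs, pairs[, k])
      p <- marginalize_sfs(probs, pairs[, k])
      tot <- tot + sum(o$counts * log(pmax(p$counts, p_min)))
    }
    return(tot)
  }
  mask <- polymorphic_mask(obs)
  m <- obs$counts[mask]
  p <- pmax(probs$counts[mask], p_min)
  sum(m * log(p))
}

#' AIC from a fastsimcoal-style log10 likelihood
#'
#' The package's own AIC convention is natural-log: AIC = 2k - 2 lnCL. For
#' comparison with tools reporting log10 composite likelihoods, AIC =
#' 2k - 2 ln(10) log10L.
#'
#' @param k number of estimated parameters.
#' @param log10L composite likelihood in log10 units.
#' @return AIC value.
#' @export
aic_from_log10 <- function(k, log10L) 2 * k - 2 * log(10) * log10L

# Evaluate the composite log-likelihood of a named model at given parameters.
.lncl_at <- function(name, params, obs, n_sims, seed, mu, gen_time_years,
                     p_min = NULL, pairwise = FALSE) {
  demog <- build_named_model(name, params, n_samples = sample_sizes(obs),
                             mu = mu, gen_time_years = gen_time_years)
  probs <- expected_sfs_probs(demog, n_sims, seed, folded = obs$folded)
  composite_log_likelihood(obs, probs, p_min = p_min, pairwise = pairwise)
}

.default_param_order <- function(space) {
  p <- space$param
  c(p[startsWith(p, "T_")], p[startsWith(p, "N_")], p[startsWith(p, "a_")],
    p[startsWith(p, "m")])
}

.mid_start <- function(space) {
  setNames(ifelse(space$scale == "log", sqrt(space$lower * space$upper),
                  (space$lower + space$upper) / 2), space$param)
}

#' Fit a demographic model to an observed SFS by ECM composite likelihood
#'
#' Cycles of conditional one-parameter maximization: within a cycle each free
#' parameter in turn is maximized by a bounded Brent line search (on log
#' scale for log-scaled parameters) while the others are held fixed, with
#' common random numbers across all probes of the cycle so the search surface
#' is quasi-deterministic; by default fresh simulation streams are drawn each
#' cycle. Restarts rerun the whole search from perturbed starting points and
#' the best final lnCL wins.
#'
#' @param name model name (see \code{\link{build_named_model}}).
#' @param obs observed \code{sfs}.
#' @param space parameter space (default \code{\link{param_space}(name)}).
#' @param n_sims simulated genealogies per likelihood evaluation.
#' @param cycles number of ECM cycles.
#' @param seed integer root seed (all restarts/cycles derive from it).
#' @param fixed named vector of parameters to hold fixed (not counted in k).
#' @param init optional named starting values for the free parameters.
#' @param order parameter update order (default: divergence times oldest to
#'   youngest, then sizes, admixture fractions, migration).
#' @param n_restarts independent restarts (best-of-restarts reported).
#' @param crn_across_cycles reuse one simulation stream for every cycle
#'   (makes the lnCL trace exactly non-decreasing).
#' @param mu,gen_time_years passed to the model builder.
#' @param brent_tol relative tolerance of each line search.
#' @param pairwise use the pairwise-2D composite objective (see
#'   \code{\link{composite_log_likelihood}}).
#' @return object of class \code{fit_result}: \code{model}, \code{params},
#'   \code{free}, \code{lnCL}, \code{k}, \code{AIC}, \code{n_sims},
#'   \code{trace} (per-cycle lnCL), \code{seed}, \code{converged}.
#' @export
fit_model_ecm <- function(name, obs, space = param_space(name), n_sims = 2000,
                          cycles = 5, seed = 1, fixed = NULL, init = NULL,
                          order = NULL, n_restarts = 1,
                          crn_across_cycles = FALSE, mu = 1.36e-8,
                          gen_time_years = 10, brent_tol = 0.005,
                          pairwise = FALSE) {
  seed <- .seed_int(seed)
  fixed <- unlist(fixed)
  free_names <- setdiff(space$param, names(fixed))
  if (length(free_names) == 0) stop("no free parameters to fit")
  if (is.null(order)) order <- .default_param_order(space)
  order <- intersect(order, free_names)
  sp <- space[match(space$param, space$param), ]
  rownames(sp) <- sp$param
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    params <- as.list(.mid_start(space))
    for (nm in names(fixed)) params[[nm]] <- unname(fixed[[nm]])
    if (!is.null(init)) for (nm in names(init)) params[[nm]] <- unname(init[[nm]])
    if (rs > 1) {  # perturb free starts within bounds
      set.seed(.derive_seed(seed, 7000 + rs))
      for (nm in free_names) {
        lo <- sp[nm, "lower"]; hi <- sp[nm, "upper"]
        params[[nm]] <- if (sp[nm, "scale"] == "log")
          exp(runif(1, log(lo), log(hi))) else runif(1, lo, hi)
      }
    }
    trace <- numeric(0)
    cur_lncl <- -Inf
    for (cy in seq_len(cycles)) {
      cyc_seed <- if (crn_across_cycles) .derive_seed(seed, rs)
                  else .derive_seed(seed, rs, cy)
      eval_at <- function(plist)
        .lncl_at(name, plist, obs, n_sims, cyc_seed, mu, gen_time_years,
                 pairwise = pairwise)
      objective <- function(v, nm, logscale) {
        p2 <- params
        p2[[nm]] <- if (logscale) exp(v) else v
        ll <- tryCatch(eval_at(p2), error = function(e) NA_real_)
        if (!is.finite(ll)) return(1e18)
        -ll
      }
      cur_lncl <- eval_at(params)
      if (!is.finite(cur_lncl) && cy == 1)
        stop("non-finite composite likelihood at the starting point")
      for (nm in order) {
        logscale <- sp[nm, "scale"] == "log"
        lo <- sp[nm, "lower"]; hi <- sp[nm, "upper"]
        iv <- if (logscale) log(c(lo, hi)) else c(lo, hi)
        opt <- optimize(objective, interval = iv, nm = nm,
                        logscale = logscale, tol = brent_tol * diff(iv))
        cand <- if (logscale) exp(opt$minimum) else opt$minimum
        if (-opt$objective > cur_lncl) {  # keep only genuine improvements
          params[[nm]] <- cand
          cur_lncl <- -opt$objective
        }
      }
      trace <- c(trace, cur_lncl)
    }
    if (is.null(best) || cur_lncl > best$lnCL) {
      k <- length(free_names)
      best <- structure(list(
        model = name,
        params = unlist(params)[space$param],
        free = free_names,
        lnCL = cur_lncl, k = k, AIC = 2 * k - 2 * cur_lncl,
        n_sims = n_sims, cycles = cycles, trace = trace,
        seed = seed, restart = rs,
        converged = length(trace) >= 2 &&
          abs(trace[length(trace)] - trace[length(trace) - 1]) <
            0.001 * abs(trace[length(trace)]) + 1e-9,
        obs_fingerprint = .obs_fingerprint(obs)), class = "fit_result")
    }
  }
  best
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:", x$model, "| lnCL =", format(x$lnCL), "| k =", x$k,
      "| AIC =", format(x$AIC), "\n")
  print(round(x$params, 5))
  invisible(x)
}

#' Rank fitted models by AIC
#'
#' Selects the best lnCL per model name (best-of-restarts when several fits
#' of the same model are supplied), then sorts ascending by AIC. All fits
#' must be of the same observed SFS.
#'
#' @param fits list of \code{fit_result} objects (>= 2).
#' @return data.frame with columns \code{model}, \code{k}, \code{lnCL},
#'   \code{AIC}, \code{delta_AIC}, sorted by AIC.
#' @export
compare_models <- function(fits) {
  if (!is.list(fits) || length(fits) < 2 || inherits(fits, "fit_result"))
    stop("need a list of at least two fit_result objects")
  stopifnot(all(vapply(fits, inherits, logical(1), "fit_result")))
  fps <- lapply(fits, function(f) f$obs_fingerprint)
  if (!all(vapply(fps, identical, logical(1), fps[[1]])))
    stop("fits were computed on different observed data")
  models <- vapply(fits, function(f) f$model, character(1))
  best <- lapply(split(seq_along(fits), models), function(ix) {
    lls <- vapply(fits[ix], function(f) f$lnCL, numeric(1))
    fits[[ix[which.max(lls)]]]
  })
  df <- data.frame(model = vapply(best, function(f) f$model, character(1)),
                   k = vapply(best, function(f) f$k, numeric(1)),
                   lnCL = vapply(best, function(f) f$lnCL, numeric(1)),
                   AIC = vapply(best, function(f) f$AIC, numeric(1)))
  df <- df[order(df$AIC), ]
  df$delta_AIC <- df$AIC - df$AIC[1]
  rownames(df) <- NULL
  df
}

#' Profile composite likelihood over one parameter
#'
#' Evaluates lnCL along a grid of one parameter with all other parameters
#' held fixed, using common random numbers across grid points (the same
#' simulation stream for every point) so the profile is smooth in the
#' parameter.
#'
#' @param name model name.
#' @param obs observed \code{sfs}.
#' @param param name of the profiled parameter.
#' @param grid numeric grid of values (within bounds).
#' @param fixed named vector of every other model parameter.
#' @param n_sims simulated genealogies per grid point.
#' @param seed integer seed (shared by all grid points).
#' @param mu,gen_time_years passed to the model builder.
#' @param pairwise use the pairwise-2D composite (see
#'   \code{\link{composite_log_likelihood}}).
#' @return list with \code{profile} (data.frame value/lnCL), \code{argmax},
#'   \code{lnCL_max}.
#' @export
profile_likelihood <- function(name, obs, param, grid, fixed, n_sims = 5000,
                               seed = 1, mu = 1.36e-8, gen_time_years = 10,
                               pairwise = FALSE) {
  if (length(grid) == 0) stop("empty grid")
  seed <- .seed_int(seed)
  space <- param_space(name)
  stopifnot(param %in% space$param)
  lo <- space$lower[space$param == param]
  hi <- space$upper[space$param == param]
  if (any(grid < lo | grid > hi)) stop("grid outside parameter bounds")
  lncl <- vapply(grid, function(v) {
    p <- as.list(unlist(fixed))
    p[[param]] <- v
    .lncl_at(name, p, obs, n_sims, seed, mu, gen_time_years,
             pairwise = pairwise)
  }, numeric(1))
  i <- which.max(lncl)
  list(profile = data.frame(value = grid, lnCL = lncl),
       argmax = grid[i], lnCL_max = lncl[i], param = param)
}

#' Parametric-bootstrap confidence intervals for a fitted model
#'
#' Simulates \code{n_boot} SNP-panel SFS datasets at the point estimate,
#' refits each at reduced settings (same free parameters, fewer cycles), and
#' returns percentile intervals.
#'
#' @param fit a converged \code{fit_result}.
#' @param n_boot number of bootstrap replicates.
#' @param level interval level (default 0.95).
#' @param seed integer root seed.
#' @param n_snps segregating sites per replicate (default: polymorphic mass
#'   of the fitted data).
#' @param n_sims,cycles refit settings.
#' @param pairwise use the pairwise-2D composite objective in refits.
#' @param max_fail_rate abort if more than this fraction of refits error.
#' @return object of class \code{bootstrap_ci}: per-parameter \code{lower},
#'   \code{upper}, point \code{estimate}, \code{n_boot}, \code{seeds}.
#' @export
parametric_bootstrap_ci <- function(fit, n_boot, level = 0.95, seed = 1,
                                    n_snps = NULL, n_sims = 1000, cycles = 2,
                                    max_fail_rate = 0.20, pairwise = FALSE) {
  stopifnot(inherits(fit, "fit_result"), n_boot >= 2)
  seed <- .seed_int(seed)
  space <- param_space(fit$model)
  fixed <- fit$params[setdiff(names(fit$params), fit$free)]
  n_hap <- as.integer(strsplit(fit$obs_fingerprint[["dims"]], "x")[[1]]) - 1L
  if (is.null(n_snps)) n_snps <- max(100, round(as.numeric(
    fit$obs_fingerprint[["total"]])))
  est <- matrix(NA_real_, n_boot, length(fit$free),
                dimnames = list(NULL, fit$free))
  seeds <- numeric(n_boot)
  fails <- 0L
  for (b in seq_len(n_boot)) {
    seeds[b] <- .derive_seed(seed, 900 + b)
    res <- tryCatch({
      demog <- build_named_model(fit$model, fit$params, n_samples = n_hap)
      ob <- simulate_snp_sfs(demog, n_snps,
                             n_genealogies = max(500, n_snps %/% 10),
                             seed = seeds[b])
      rf <- fit_model_ecm(fit$model, ob, space = space, n_sims = n_sims,
                          cycles = cycles, seed = .derive_seed(seed, b),
                          fixed = fixed, init = fit$params[fit$free],
                          pairwise = pairwise)
      rf$params[fit$free]
    }, error = function(e) NULL)
    if (is.null(res)) fails <- fails + 1L else est[b, ] <- res
  }
  if (fails / n_boot > max_fail_rate)
    stop("bootstrap refit failure rate ", fails, "/", n_boot,
         " exceeds ", max_fail_rate)
  alpha <- (1 - level) / 2
  lower <- apply(est, 2, quantile, probs = alpha, na.rm = TRUE)
  upper <- apply(est, 2, quantile, probs = 1 - alpha, na.rm = TRUE)
  structure(list(estimate = fit$params[fit$free], lower = lower,
                 upper = upper, level = level, n_boot = n_boot,
                 n_failed = fails, seeds = seeds), class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%d%% parametric bootstrap CIs (%d replicates, %d failed):\n",
              round(100 * x$level), x$n_boot, x$n_failed))
  df <- data.frame(estimate = x$estimate, lower = x$lower, upper = x$upper)
  print(round(df, 5))
  invisible(x)
}
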
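#' Fit a longitudinal latent variable model to item responses
#'
#' The main fitting interface: combines trial data, a structural model
#' specification and a calibrated item bank, and maximizes the marginal
#' likelihood with the requested engine. Item slopes and intercepts stay
#' fixed at their banked values throughout, which identifies the latent
#' metric; the free parameters are the latent means (intercepts under a
#' latent regression), the covariance block, regression coefficients,
#' item-specific residual slopes, and the site variance.
#'
#' @param data a [trial_data()].
#' @param spec a `proirt_spec` from [growth_spec()], [two_tier_spec()] or
#'   [latent_difference_spec()], possibly extended by [add_site_level()] and
#'   [attach_regression()].
#' @param bank an [item_bank()].
#' @param engine `"baem"` (Bock-Aitkin EM with two-tier dimension reduction;
#'   see [fit_baem()]) or `"mhrm"` (Metropolis-Hastings Robbins-Monro;
#'   see [fit_mhrm()]).
#' @param start optional `proirt_params` starting values.
#' @param seed seed for the MH-RM engine (ignored by BAEM, which is
#'   deterministic).
#' @param control a [proirt_control()].
#' @param config an [mhrm_control()] (MH-RM only).
#' @return an object of class `proirt_fit` with methods `print`, `summary`,
#'   `coef`, `vcov`, `logLik`, `simulate` and `plot`.
#' @examples
#' des <- default_trial_design(seed = 1)
#' sim <- simulate_trial(des)
#' \donttest{
#' fit <- proirt(sim$data, des$spec, des$bank, engine = "mhrm", seed = 1)
#' summary(fit)
#' }
#' @export
proirt <- function(data, spec, bank, engine = c("baem", "mhrm"),
                   start = NULL, seed = 1,
                   control = proirt_control(), config = mhrm_control()) {
  engine <- match.arg(engine)
  if (engine == "baem")
    fit_baem(data, spec, bank, start = start, control = control)
  else
    fit_mhrm(data, spec, bank, start = start, seed = seed,
             config = config, control = control)
}

#' @export
print.proirt_fit <- function(x, digits = 3, ...) {
  cat("Longitudinal IRT model (", x$spec$parameterization,
      if (!is.null(x$spec$site)) "+ site intercept", "), engine:", x$engine, "\n")
  cat("  ", x$n_cases, "subjects,", x$n_free, "free parameters;",
      x$convergence$status, "after", x$convergence$iterations,
      if (x$engine == "BAEM") "EM iterations" else "cycles", "\n")
  if (is.finite(x$minus2LL)) {
    ic <- information_criteria(x$minus2LL, x$n_free, x$n_cases)
    cat(sprintf("  -2 log-likelihood: %.2f  AIC: %.2f  BIC: %.2f\n",
                x$minus2LL, ic["AIC"], ic["BIC"]))
  } else {
    cat("  marginal log-likelihood not computed by this engine;",
        "see mc_marginal_loglik()\n")
  }
  tab <- cbind(Est = x$estimate,
               SE = if (!is.null(x$se)) x$se else rep(NA_real_, x$n_free))
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.proirt_fit <- function(object, ...) object$estimate

#' @export
vcov.proirt_fit <- function(object, ...) object$vcov

#' @export
logLik.proirt_fit <- function(object, ...) {
  if (!is.finite(object$minus2LL))
    stop("the MH-RM engine does not produce the marginal log-likelihood; ",
         "use mc_marginal_loglik()", call. = FALSE)
  structure(-object$minus2LL / 2, df = object$n_free, nobs = object$n_cases,
            class = "logLik")
}

#' @export
summary.proirt_fit <- function(object, ...) {
  est <- object$estimate
  se <- object$se %||% rep(NA_real_, length(est))
  z <- est / se
  tab <- cbind(Est = est, SE = se, z = z,
               `p` = 2 * stats::pnorm(-abs(z)))
  G <- n_general(object$spec)
  corr <- if (all(diag(object$params$Sigma) > 0))
    cov_to_corr(object$params$Sigma) else NULL
  iccv <- if (!is.null(object$spec$site))
    icc(object$params$site_var, object$params$Sigma[1, 1]) else NULL
  out <- list(engine = object$engine, spec = object$spec, table = tab,
              corr = corr, icc = iccv, minus2LL = object$minus2LL,
              n_free = object$n_free, n_cases = object$n_cases,
              convergence = object$convergence)
  class(out) <- "summary.proirt_fit"
  out
}

#' @export
print.summary.proirt_fit <- function(x, digits = 3, ...) {
  cat("Longitudinal IRT model (", x$spec$parameterization, "), engine:",
      x$engine, "--", x$convergence$status, "\n\n")
  stats::printCoefmat(x$table, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE, na.print = "-")
  if (!is.null(x$corr) && nrow(x$corr) > 1) {
    cat("\nLatent correlations (standardized covariance block):\n")
    print(round(x$corr, 2))
  }
  if (!is.null(x$icc))
    cat(sprintf("\nIntraclass correlation (site / site + baseline): %.2f\n",
                x$icc))
  if (is.finite(x$minus2LL)) {
    ic <- information_criteria(x$minus2LL, x$n_free, x$n_cases)
    cat(sprintf("\n-2LL = %.2f, AIC = %.2f, BIC = %.2f (N = %d, k = %d)\n",
                x$minus2LL, ic["AIC"], ic["BIC"], x$n_cases, x$n_free))
  }
  invisible(x)
}

#' Simulate item responses from a fitted model
#'
#' Draws new responses from the fitted parameters while preserving the
#' design: the same subjects, sites, covariates, and the same missingness
#' pattern. Used for parametric-bootstrap style checks and the
#' limited-information fit machinery.
#'
#' @param object a `proirt_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a [trial_data()] if `nsim = 1`, else a list of them.
#' @export
simulate.proirt_fit <- function(object, nsim = 1, seed = 1, ...) {
  set.seed(seed)
  spec <- object$spec; bank <- object$bank; params <- object$params
  data <- object$data
  n <- nrow(data$Y); K <- data$K; T <- data$T
  G <- n_general(spec)
  rs <- spec_rows(spec, bank)
  covs <- spec_covariates(spec)
  X <- covariate_matrix(data, covs)
  site_of <- if (!is.null(spec$site)) as.integer(factor(data$site)) else NULL
  perm <- match(bank_ids(bank), data$item_ids)
  colmap <- as.vector(vapply(seq_len(T), function(t) (t - 1L) * K + perm,
                             integer(K)))
  miss <- is.na(data$Y[, colmap, drop = FALSE])
  sload <- if (spec$specific_free) params$s[rs$rows$item] else rs$rows$sload
  sl <- if (!is.null(spec$site)) spec$site$loadings else rep(0, T)
  ch <- chol(params$Sigma)
  out <- vector("list", nsim)
  for (ii in seq_len(nsim)) {
    Mu <- matrix(rep(params$mu, each = n), ncol = G)
    if (length(covs)) Mu <- Mu + X %*% t(params$B)
    Th <- Mu + matrix(stats::rnorm(n * G), n, G) %*% ch
    thc <- if (!is.null(site_of))
      stats::rnorm(max(site_of), 0, sqrt(params$site_var)) else NULL
    Xi <- matrix(stats::rnorm(n * rs$n_groups), n, rs$n_groups)
    eta <- Th %*% t(spec$A)
    Y <- matrix(NA_integer_, n, K * T)
    for (r in seq_len(nrow(rs$rows))) {
      t <- rs$rows$occ[r]
      lp <- rs$rows$a[r] * (eta[, t] + if (!is.null(thc)) sl[t] * thc[site_of] else 0) +
        sload[r] * Xi[, rs$rows$group[r]]
      cum <- vapply(seq_len(rs$rows$ncat[r] - 1L), function(cc)
        stats::plogis(rs$intercepts[r, cc] + lp), numeric(n))
      Y[, r] <- rowSums(stats::runif(n) < cum)
    }
    Y[miss] <- NA_integer_
    out[[ii]] <- trial_data(Y, subject = data$subject, site = data$site,
                            covariates = data$covariates,
                            item_ids = bank_ids(bank), T = T,
                            category_base = data$category_base)
  }
  if (nsim == 1) out[[1]] else out
}

#' Plot estimated latent trajectories
#'
#' Plots the model-implied mean of the occasion composite (the latent outcome
#' on the banked metric) against occasion, with pointwise Wald intervals when
#' standard errors are available; for specs with a treatment regression, one
#' line per arm.
#'
#' @param x a `proirt_fit`.
#' @param level confidence level for the intervals.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the matrix of plotted occasion means.
#' @export
plot.proirt_fit <- function(x, level = 0.95, ...) {
  spec <- x$spec
  G <- n_general(spec)
  covs <- spec_covariates(spec)
  pats <- if (length(covs)) rbind(0, diag(length(covs))) else matrix(0, 1, 0)
  mns <- apply(pats, 1, function(xx)
    drop(spec$A %*% (x$params$mu + if (length(covs)) x$params$B %*% xx else 0)))
  mns <- matrix(mns, nrow = spec$T)
  labs <- if (length(covs)) c("reference", covs) else "sample"
  graphics::matplot(seq_len(spec$T), mns, type = "b", pch = 19, lty = 1,
                    xlab = "Occasion", ylab = "Latent mean (eta)",
                    xaxt = "n", ...)
  graphics::axis(1, at = seq_len(spec$T))
  graphics::legend("topright", legend = labs, col = seq_len(ncol(mns)),
                   lty = 1, bty = "n")
  invisible(mns)
}
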
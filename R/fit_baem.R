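#' Control settings for model fitting
#'
#' Quadrature and convergence settings shared by the likelihood engine and
#' the Bock-Aitkin EM fitter.
#'
#' @param quadpts points per dimension for general and specific factors
#'   (rectangular grid over `qrange`).
#' @param qrange grid range.
#' @param site_quadpts points for the site factor (its own outer grid).
#' @param tol EM convergence tolerance on the maximum absolute parameter
#'   change.
#' @param max_iter maximum EM iterations.
#' @param se compute standard errors after convergence.
#' @param richardson_h base step factor for Richardson-extrapolated
#'   differentiation of the score (scaled by `1 + |v|` per parameter).
#' @param verbose print per-iteration log-likelihood and maximum change.
#' @return a list of class `proirt_control`.
#' @export
proirt_control <- function(quadpts = 21, qrange = c(-5, 5), site_quadpts = 11,
                           tol = 1e-4, max_iter = 2000, se = TRUE,
                           richardson_h = 1e-3, verbose = FALSE) {
  structure(list(quadpts = as.integer(quadpts), qrange = qrange,
                 site_quadpts = as.integer(site_quadpts), tol = tol,
                 max_iter = as.integer(max_iter), se = se,
                 richardson_h = richardson_h, verbose = verbose),
            class = "proirt_control")
}

## ---- M-step pieces ---------------------------------------------------------

# restricted GLS update of Gamma = [mu | B] (G x q) over its free pattern
update_gamma <- function(Zz, Cs, Omega, Fpat) {
  G <- nrow(Fpat); q <- ncol(Fpat)
  A <- kronecker(Zz, Omega)
  f <- as.vector(Fpat)
  b <- as.vector(Omega %*% Cs)
  x <- numeric(G * q)
  x[f] <- solve(A[f, f, drop = FALSE], b[f])
  matrix(x, G, q)
}

# expected complete-data cross-products for the structural normal part
struct_moments <- function(eng, es) {
  list(Em = es$Em, E2 = es$E2, Z = cbind(1, eng$Xstruct),
       n = if (eng$struct_level == "unit") eng$n_units else eng$n_clusters)
}

# expected complete-data log-likelihood contribution of item k's specific
# slope, from the E-step count tables (posterior mass over composite value d,
# specific node q, observed category c)
q_specific <- function(s, k, eng, tables, w_vals) {
  rows_k <- which(eng$rows$rows$item == k)
  tot <- 0
  for (r in rows_k) {
    tb <- tables[[r]]
    if (!length(tb) || sum(tb) == 0) next
    t <- eng$rows$rows$occ[r]
    D <- length(w_vals[[t]]); Q <- length(eng$xq)
    ncat <- eng$rows$rows$ncat[r]
    lp <- outer(eng$rows$rows$a[r] * w_vals[[t]], s * eng$xq, "+")
    dim(tb) <- c(D, Q, ncat)
    for (cc in 0:(ncat - 1L)) {
      tbc <- tb[, , cc + 1L]
      if (!any(tbc > 0)) next
      p <- grm_prob(lp, eng$rows$intercepts[r, ], ncat, cc)
      tot <- tot + sum(tbc * log(p))
    }
  }
  tot
}

# derivative of q_specific in s (used for the analytic marginal score)
dq_specific <- function(s, k, eng, tables, w_vals) {
  rows_k <- which(eng$rows$rows$item == k)
  tot <- 0
  for (r in rows_k) {
    tb <- tables[[r]]
    if (!length(tb) || sum(tb) == 0) next
    t <- eng$rows$rows$occ[r]
    D <- length(w_vals[[t]]); Q <- length(eng$xq)
    ncat <- eng$rows$rows$ncat[r]
    ints <- eng$rows$intercepts[r, ]
    lp <- outer(eng$rows$rows$a[r] * w_vals[[t]], s * eng$xq, "+")
    XQ <- matrix(eng$xq, D, Q, byrow = TRUE)
    dim(tb) <- c(D, Q, ncat)
    for (cc in 0:(ncat - 1L)) {
      tbc <- tb[, , cc + 1L]
      if (!any(tbc > 0)) next
      Flo <- if (cc == 0) 1 else stats::plogis(ints[cc] + lp)
      Fhi <- if (cc == ncat - 1L) 0 else stats::plogis(ints[cc + 1L] + lp)
      flo <- Flo * (1 - Flo)
      fhi <- Fhi * (1 - Fhi)
      p <- pmax(Flo - Fhi, 1e-300)
      tot <- tot + sum(tbc * XQ * (flo - fhi) / p)
    }
  }
  tot
}

m_step <- function(eng, es, params) {
  spec <- eng$spec
  G <- n_general(spec)
  sm <- struct_moments(eng, es)
  Fpat <- regression_pattern(spec)
  Zz <- crossprod(sm$Z)
  Cs <- t(sm$Em) %*% sm$Z
  Om <- chol2inv(chol(params$Sigma))
  Gam <- update_gamma(Zz, Cs, Om, Fpat)
  Ssum <- matrix(colSums(sm$E2), G, G)
  Sig <- (Ssum - Cs %*% t(Gam) - Gam %*% t(Cs) + Gam %*% Zz %*% t(Gam)) / sm$n
  Sig <- (Sig + t(Sig)) / 2
  if (spec$cov_struct == "diagonal") Sig <- diag(diag(Sig), G)

  new <- params
  new$mu[] <- Gam[, 1]
  if (ncol(Fpat) > 1) new$B[] <- Gam[, -1, drop = FALSE]
  new$Sigma[] <- Sig

  if (spec$specific_free) {
    for (k in seq_len(eng$K)) {
      opt <- stats::optimize(q_specific, interval = c(0, 8), maximum = TRUE,
                             k = k, eng = eng, tables = es$tables,
                             w_vals = es$w_vals, tol = 1e-6)
      # guard: keep the old value unless the expected likelihood improves
      if (opt$objective >= q_specific(params$s[k], k, eng, es$tables, es$w_vals))
        new$s[k] <- opt$maximum
    }
  }

  if (eng$site) {
    mC <- if (!is.null(eng$Xsite_cl)) {
      beta <- solve(crossprod(eng$Xsite_cl),
                    crossprod(eng$Xsite_cl, es$site_Em))
      new$site_beta[] <- drop(beta)
      drop(eng$Xsite_cl %*% beta)
    } else rep(0, eng$n_clusters)
    new$site_var <- max(mean(es$site_E2 - 2 * mC * es$site_Em + mC^2), 1e-8)
  }
  new
}

## ---- Bock-Aitkin EM --------------------------------------------------------

#' Fit a model by Bock-Aitkin EM
#'
#' Marginal maximum likelihood with fixed banked item parameters: the E-step
#' computes posterior expectations on the dimension-reduced quadrature grid;
#' the M-step updates latent means, covariance blocks and regression
#' coefficients in closed form (restricted GLS) and maximizes each free
#' specific slope exactly in one dimension, so the marginal log-likelihood is
#' non-decreasing across iterations. Standard errors use Richardson
#' extrapolation of the analytic marginal score (see [se_richardson()]).
#'
#' @param data a [trial_data()].
#' @param spec a `proirt_spec`.
#' @param bank an [item_bank()].
#' @param start optional `proirt_params` starting values.
#' @param control a [proirt_control()].
#' @return a `proirt_fit` object.
#' @export
fit_baem <- function(data, spec, bank, start = NULL,
                     control = proirt_control()) {
  eng <- make_engine(data, spec, bank, control)
  params <- start %||% default_start(spec, bank)
  v <- pack_params(params, spec, bank)
  trace <- numeric(0)
  status <- "not converged"
  iter <- 0L
  max_change <- NA_real_
  want_tab <- spec$specific_free
  want_post <- TRUE
  want_cl <- eng$site
  while (iter < control$max_iter) {
    iter <- iter + 1L
    es <- engine_estep(eng, params, want_post = want_post,
                       want_tables = want_tab, want_cluster_post = want_cl)
    trace <- c(trace, es$loglik)
    params_new <- m_step(eng, es, params)
    v_new <- pack_params(params_new, spec, bank)
    max_change <- max(abs(v_new - v))
    if (control$verbose)
      message(sprintf("iter %4d  logL %.6f  max change %.2e",
                      iter, es$loglik, max_change))
    params <- params_new
    v <- v_new
    if (max_change < control$tol) { status <- "converged"; break }
  }
  final <- engine_estep(eng, params)
  trace <- c(trace, final$loglik)
  if (control$max_iter == 0L) status <- "start values (max_iter = 0)"

  fit <- new_proirt_fit(
    engine = "BAEM", params = params, spec = spec, bank = bank, data = data,
    minus2LL = -2 * final$loglik,
    n_free = n_free_params(spec, eng$K), n_cases = eng$n_subjects,
    convergence = list(iterations = iter, max_change = max_change,
                       status = status, loglik_trace = trace),
    control = control)
  if (isTRUE(control$se) && status == "converged") {
    se <- try(se_richardson(data, spec, bank, params, control = control),
              silent = TRUE)
    if (!inherits(se, "try-error")) {
      fit$se <- se$se
      fit$vcov <- se$vcov
    } else {
      warning("standard-error computation failed: ", attr(se, "condition")$message)
    }
  }
  fit
}

new_proirt_fit <- function(engine, params, spec, bank, data, minus2LL,
                           n_free, n_cases, convergence, control, ...) {
  structure(list(engine = engine, params = params,
                 estimate = pack_params(params, spec, bank),
                 se = NULL, vcov = NULL,
                 spec = spec, bank = bank, data = data,
                 minus2LL = minus2LL, n_free = n_free, n_cases = n_cases,
                 convergence = convergence, control = control, ...),
            class = "proirt_fit")
}

## ---- analytic marginal score (Fisher's identity) ---------------------------

# gradient of the marginal log-likelihood, assembled from one E-step
fisher_score <- function(eng, params) {
  spec <- eng$spec
  G <- n_general(spec)
  es <- engine_estep(eng, params, want_post = TRUE,
                     want_tables = spec$specific_free,
                     want_cluster_post = eng$site)
  sm <- struct_moments(eng, es)
  Fpat <- regression_pattern(spec)
  Gam <- unname(cbind(params$mu, params$B))
  Om <- chol2inv(chol(params$Sigma))
  Zz <- crossprod(sm$Z)
  Cs <- t(sm$Em) %*% sm$Z
  Sgam <- Om %*% (Cs - Gam %*% Zz)          # G x q score matrix
  g <- unname(Sgam[, 1])                    # means
  # covariance block
  Ssum <- matrix(colSums(sm$E2), G, G)
  M <- Ssum - Cs %*% t(Gam) - Gam %*% t(Cs) + Gam %*% Zz %*% t(Gam)
  Dm <- 0.5 * (Om %*% M %*% Om - sm$n * Om)
  if (spec$cov_struct == "full") {
    vp <- vech_pairs(G)
    gs <- Dm[vp]
    off <- vp[, 1] != vp[, 2]
    gs[off] <- 2 * gs[off]
    g <- c(g, gs)
  } else {
    g <- c(g, diag(Dm))
  }
  # regression coefficients, in spec$regression order
  for (fac in names(spec$regression)) {
    gi <- match(fac, spec$gen_names)
    ci <- match(spec$regression[[fac]], colnames(Fpat))
    g <- c(g, Sgam[gi, ci])
  }
  # specific slopes
  if (spec$specific_free)
    g <- c(g, vapply(seq_len(eng$K), function(k)
      dq_specific(params$s[k], k, eng, es$tables, es$w_vals), numeric(1)))
  # site variance and site regression
  if (eng$site) {
    mC <- if (!is.null(eng$Xsite_cl) && !is.null(params$site_beta))
      drop(eng$Xsite_cl %*% params$site_beta) else rep(0, eng$n_clusters)
    essq <- es$site_E2 - 2 * mC * es$site_Em + mC^2
    g <- c(g, sum(essq) / (2 * params$site_var^2) -
             eng$n_clusters / (2 * params$site_var))
    if (!is.null(eng$Xsite_cl))
      g <- c(g, drop(crossprod(eng$Xsite_cl, es$site_Em - mC)) / params$site_var)
  }
  stats::setNames(g, param_names(spec, eng$bank))
}

## ---- Richardson standard errors --------------------------------------------

# Richardson-extrapolated Hessian of a function with gradient `gfun`:
# central differences at steps h and h/2 combined as (4 D(h/2) - D(h)) / 3
richardson_hessian <- function(gfun, v0, h0 = 1e-3) {
  p <- length(v0)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- h0 * (1 + abs(v0[j]))
    dcol <- function(hh) {
      vp <- v0; vp[j] <- v0[j] + hh
      vm <- v0; vm[j] <- v0[j] - hh
      (gfun(vp) - gfun(vm)) / (2 * hh)
    }
    H[, j] <- (4 * dcol(h / 2) - dcol(h)) / 3
  }
  (H + t(H)) / 2
}

#' Richardson-extrapolation standard errors
#'
#' Observed-information standard errors at a stationary point: each column of
#' the Hessian is obtained by Richardson-extrapolated central differences of
#' the analytic marginal score (Fisher's identity evaluated through the
#' E-step), combining steps `h` and `h/2` as `(4 D(h/2) - D(h)) / 3` with
#' `h = h0 (1 + |v|)` per parameter. Parameters whose information row cannot
#' be inverted are flagged with `NA` standard errors.
#'
#' @inheritParams fit_baem
#' @param params_hat fitted `proirt_params` (a stationary point).
#' @param h0 base step size.
#' @return list with `se` (named vector), `vcov`, and `info`.
#' @export
se_richardson <- function(data, spec, bank, params_hat,
                          control = proirt_control(), h0 = control$richardson_h) {
  eng <- make_engine(data, spec, bank, control)
  v0 <- pack_params(params_hat, spec, bank)
  gfun <- function(v) fisher_score(eng, unpack_params(v, spec, bank))
  info <- -richardson_hessian(gfun, v0, h0)
  dimnames(info) <- list(names(v0), names(v0))
  vc <- try(solve(info), silent = TRUE)
  if (inherits(vc, "try-error")) {
    ev <- eigen(info, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-10
    vc <- ev$vectors[, pos, drop = FALSE] %*%
      diag(1 / ev$values[pos], sum(pos)) %*% t(ev$vectors[, pos, drop = FALSE])
    dimnames(vc) <- dimnames(info)
    warning("information matrix is singular; standard errors use a ",
            "generalized inverse and may be missing for some parameters")
  }
  se <- sqrt(pmax(diag(vc), 0))
  se[diag(vc) <= 0] <- NA_real_
  list(se = stats::setNames(se, names(v0)), vcov = vc, info = info)
}
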
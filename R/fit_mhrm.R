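#' Control settings for MH-RM estimation
#'
#' Tuning of the Metropolis-Hastings Robbins-Monro stochastic approximation:
#' burn-in (proposal tuning only), a constant-gain stage, and a decaying-gain
#' stage with gain `(1/j)^gain_exponent`. Convergence is declared after
#' `window` consecutive cycles whose maximum Robbins-Monro update is below
#' `tol`. All randomness flows from the `seed` passed to [fit_mhrm()].
#'
#' @param n_burnin cycles of latent sampling with proposal auto-tuning and no
#'   parameter updates.
#' @param n_stage1 constant-gain (gain 1) cycles; these apply the
#'   complete-data maximum-likelihood map to the imputed latents (stochastic
#'   EM), which keeps every iterate inside the parameter space and moves the
#'   chain into the vicinity of the solution before the Newton-type
#'   Robbins-Monro recursion starts.
#' @param n_stage2 maximum decaying-gain Robbins-Monro cycles.
#' @param gain_exponent exponent of the stage-2 gain sequence; must lie in
#'   (0.5, 1] so the sequence sums to infinity with summable squares.
#' @param proposal_scale initial random-walk standard deviation (auto-tuned
#'   during burn-in toward acceptance rates inside `accept_range`).
#' @param accept_range acceptance-rate band outside which proposals are
#'   re-tuned during burn-in.
#' @param tol,window,window_size Robbins-Monro convergence rule: stage 2
#'   stops once `window` successive non-overlapping windows of `window_size`
#'   cycles each have a mean absolute parameter update below `tol` in every
#'   coordinate (averaging over a window removes the Monte-Carlo noise floor
#'   of single-cycle updates).
#' @param max_step per-cycle cap on any single parameter update.
#' @param se_cycles,se_thin extra cycles at the solution for the recursive
#'   (Louis-identity) standard errors, and Metropolis sweeps per retained
#'   cycle (thinning reduces the noise of the score-covariance term).
#' @param keep_trace keep the per-cycle parameter trace in the fit object.
#' @return a list of class `mhrm_control`.
#' @export
mhrm_control <- function(n_burnin = 200, n_stage1 = 200, n_stage2 = 2000,
                         gain_exponent = 0.75, proposal_scale = 1,
                         accept_range = c(0.15, 0.6),
                         tol = 1e-3, window = 3, window_size = 50,
                         max_step = 0.25,
                         se_cycles = 1500, se_thin = 3, keep_trace = FALSE) {
  stopifnot(gain_exponent > 0.5, gain_exponent <= 1)
  structure(list(n_burnin = n_burnin, n_stage1 = n_stage1,
                 n_stage2 = n_stage2, gain_exponent = gain_exponent,
                 proposal_scale = proposal_scale, accept_range = accept_range,
                 tol = tol, window = window, window_size = window_size,
                 max_step = max_step,
                 se_cycles = se_cycles, se_thin = se_thin,
                 keep_trace = keep_trace),
            class = "mhrm_control")
}

## ---- static state for the sampler ------------------------------------------

mh_setup <- function(data, spec, bank) {
  if (spec$level == "block")
    stop("fit_mhrm works with the single-level parameterizations; ",
         "use fit_baem for the block (multilevel growth) form", call. = FALSE)
  rs <- spec_rows(spec, bank)
  K <- length(bank$items); T <- spec$T; n <- nrow(data$Y)
  perm <- match(bank_ids(bank), data$item_ids)
  if (anyNA(perm)) stop("data/bank item mismatch", call. = FALSE)
  colmap <- as.vector(vapply(seq_len(T), function(t) (t - 1L) * data$K + perm,
                             integer(K)))
  Y <- data$Y[, colmap, drop = FALSE]
  R <- nrow(rs$rows)
  # cumulative intercepts bracketing the observed category (+-Inf boundaries)
  CLO <- CHI <- matrix(NA_real_, n, R)
  for (r in seq_len(R)) {
    y <- Y[, r]
    nc <- rs$rows$ncat[r]
    lo <- ifelse(y == 0L, Inf, rs$intercepts[r, pmax(y, 1L)])
    hi <- ifelse(y == nc - 1L, -Inf, rs$intercepts[r, pmin(y + 1L, nc - 1L)])
    CLO[, r] <- ifelse(is.na(y), NA, lo)
    CHI[, r] <- ifelse(is.na(y), NA, hi)
  }
  site <- !is.null(spec$site)
  site_of <- if (site) as.integer(factor(data$site)) else NULL
  # direction of the site/structural translation ridge: shifting a site's
  # intercept by c and its subjects' general factors by -c * wdir leaves all
  # occasion composites (hence the likelihood) unchanged
  wdir <- NULL
  if (site) {
    wd <- qr.solve(spec$A, spec$site$loadings)
    if (max(abs(spec$A %*% wd - spec$site$loadings)) < 1e-8) wdir <- wd
  }
  covs <- spec_covariates(spec)
  X <- covariate_matrix(data, covs)
  Xsite <- NULL
  if (site && length(spec$site_regression %||% character())) {
    Xs <- covariate_matrix(data, spec$site_regression)
    first <- match(seq_len(max(site_of)), site_of)
    Xsite <- Xs[first, , drop = FALSE]
  }
  list(spec = spec, bank = bank, rs = rs, n = n, K = K, T = T, R = R,
       G = n_general(spec), nG = rs$n_groups,
       CLO = CLO, CHI = CHI, miss = is.na(Y),
       a = rs$rows$a, occ = rs$rows$occ, grp = rs$rows$group,
       site = site, site_of = site_of, n_sites = if (site) max(site_of) else 0L,
       wdir = wdir, X = X, Xsite = Xsite)
}

# log P(observed category) for row r at linear-predictor vector lp (length n);
# 0 for missing responses
row_logp <- function(st, r, lp) {
  p <- stats::plogis(st$CLO[, r] + lp) - stats::plogis(st$CHI[, r] + lp)
  out <- log(pmax(p, 1e-300))
  out[st$miss[, r]] <- 0
  out
}

# occasion composites given latents: n x T
mh_hrow <- function(st, Th, thc) {
  H <- Th %*% t(st$spec$A)
  if (st$site) H <- H + tcrossprod(thc[st$site_of], st$spec$site$loadings)
  H
}

# total conditional log-likelihood per subject (n-vector)
mh_cond_ll <- function(st, Th, Xi, thc, sload) {
  H <- mh_hrow(st, Th, thc)
  ll <- numeric(st$n)
  for (r in seq_len(st$R))
    ll <- ll + row_logp(st, r, st$a[r] * H[, st$occ[r]] + sload[r] * Xi[, st$grp[r]])
  ll
}

## ---- one Metropolis sweep (componentwise, vectorized over subjects) --------

mh_sweep <- function(st, lat, params, scales) {
  spec <- st$spec
  sload <- if (spec$specific_free) params$s[st$rs$rows$item] else st$rs$rows$sload
  Mu <- matrix(rep(params$mu, each = st$n), ncol = st$G)
  if (ncol(st$X)) Mu <- Mu + st$X %*% t(params$B)
  Om <- chol2inv(chol(params$Sigma))
  acc <- c(theta = 0, xi = 0, site = 0)
  ntries <- c(theta = 0, xi = 0, site = 0)

  H <- mh_hrow(st, lat$Th, lat$thc)
  # general factors, one coordinate at a time
  for (g in seq_len(st$G)) {
    prop <- lat$Th[, g] + scales$theta[g] * stats::rnorm(st$n)
    occs <- which(spec$A[, g] != 0)
    dll <- numeric(st$n)
    dH <- outer(prop - lat$Th[, g], spec$A[, g])    # n x T
    for (t in occs) for (r in which(st$occ == t)) {
      lp0 <- st$a[r] * H[, t] + sload[r] * lat$Xi[, st$grp[r]]
      dll <- dll + row_logp(st, r, lp0 + st$a[r] * dH[, t]) - row_logp(st, r, lp0)
    }
    d0 <- lat$Th - Mu
    d1 <- d0; d1[, g] <- prop - Mu[, g]
    dpr <- -0.5 * (rowSums((d1 %*% Om) * d1) - rowSums((d0 %*% Om) * d0))
    ok <- log(stats::runif(st$n)) < dll + dpr
    lat$Th[ok, g] <- prop[ok]
    H[ok, ] <- H[ok, , drop = FALSE] + dH[ok, , drop = FALSE]
    acc["theta"] <- acc["theta"] + sum(ok); ntries["theta"] <- ntries["theta"] + st$n
  }
  # specific factors, one group at a time
  for (gp in seq_len(st$nG)) {
    prop <- lat$Xi[, gp] + scales$xi[gp] * stats::rnorm(st$n)
    dll <- numeric(st$n)
    for (r in which(st$grp == gp)) {
      lp0 <- st$a[r] * H[, st$occ[r]] + sload[r] * lat$Xi[, gp]
      lp1 <- st$a[r] * H[, st$occ[r]] + sload[r] * prop
      dll <- dll + row_logp(st, r, lp1) - row_logp(st, r, lp0)
    }
    dpr <- -0.5 * (prop^2 - lat$Xi[, gp]^2)
    ok <- log(stats::runif(st$n)) < dll + dpr
    lat$Xi[ok, gp] <- prop[ok]
    acc["xi"] <- acc["xi"] + sum(ok); ntries["xi"] <- ntries["xi"] + st$n
  }
  # site intercepts, one per cluster
  if (st$site) {
    prop <- lat$thc + scales$site * stats::rnorm(st$n_sites)
    dstep <- (prop - lat$thc)[st$site_of]
    dll_subj <- numeric(st$n)
    for (t in seq_len(st$T)) {
      l <- spec$site$loadings[t]
      if (l == 0) next
      for (r in which(st$occ == t)) {
        lp0 <- st$a[r] * H[, t] + sload[r] * lat$Xi[, st$grp[r]]
        dll_subj <- dll_subj + row_logp(st, r, lp0 + st$a[r] * l * dstep) -
          row_logp(st, r, lp0)
      }
    }
    dll <- as.vector(rowsum(dll_subj, st$site_of))
    mS <- if (!is.null(st$Xsite) && !is.null(params$site_beta))
      drop(st$Xsite %*% params$site_beta) else 0
    dpr <- -0.5 * ((prop - mS)^2 - (lat$thc - mS)^2) / params$site_var
    ok <- log(stats::runif(st$n_sites)) < dll + dpr
    lat$thc[ok] <- prop[ok]
    acc["site"] <- acc["site"] + sum(ok); ntries["site"] <- ntries["site"] + st$n_sites

    # likelihood-preserving translation along the site/structural ridge:
    # thc_i -> thc_i + c_i, Th_j -> Th_j - c_i * wdir for the site's subjects;
    # the acceptance ratio involves only the latent priors
    if (!is.null(st$wdir)) {
      ci <- scales$site * stats::rnorm(st$n_sites)
      csub <- ci[st$site_of]
      d0 <- lat$Th - Mu
      Omw <- drop(Om %*% st$wdir)
      t1 <- drop(d0 %*% Omw)
      wOw <- sum(st$wdir * Omw)
      dsub <- csub * t1 - 0.5 * csub^2 * wOw          # from Th -= c * wdir
      dpr_sub <- as.vector(rowsum(dsub, st$site_of))
      mS2 <- if (!is.null(st$Xsite) && !is.null(params$site_beta))
        drop(st$Xsite %*% params$site_beta) else 0
      dpr_site <- -0.5 * ((lat$thc + ci - mS2)^2 - (lat$thc - mS2)^2) /
        params$site_var
      ok2 <- log(stats::runif(st$n_sites)) < dpr_sub + dpr_site
      if (any(ok2)) {
        lat$thc[ok2] <- lat$thc[ok2] + ci[ok2]
        shift <- ifelse(ok2[st$site_of], csub, 0)
        lat$Th <- lat$Th - outer(shift, st$wdir)
      }
    }
  }
  lat$accept <- acc / pmax(ntries, 1)
  lat
}

## ---- complete-data score and information -----------------------------------

# duplication matrix: vec(S) = D vech(S), vech in column-major lower order
dup_matrix <- function(G) {
  vp <- vech_pairs(G)
  D <- matrix(0, G * G, nrow(vp))
  for (k in seq_len(nrow(vp))) {
    i <- vp[k, 1]; j <- vp[k, 2]
    D[i + G * (j - 1), k] <- 1
    D[j + G * (i - 1), k] <- 1
  }
  D
}

# complete-data log-likelihood (for verification and step control)
cd_loglik <- function(st, lat, params) {
  spec <- st$spec
  sload <- if (spec$specific_free) params$s[st$rs$rows$item] else st$rs$rows$sload
  ll <- sum(mh_cond_ll(st, lat$Th, lat$Xi, lat$thc, sload))
  Mu <- matrix(rep(params$mu, each = st$n), ncol = st$G)
  if (ncol(st$X)) Mu <- Mu + st$X %*% t(params$B)
  d <- lat$Th - Mu
  Om <- chol2inv(chol(params$Sigma))
  ll <- ll - 0.5 * st$n * determinant(params$Sigma)$modulus -
    0.5 * sum((d %*% Om) * d)
  ll <- ll - 0.5 * sum(lat$Xi^2)
  if (st$site) {
    mS <- if (!is.null(st$Xsite) && !is.null(params$site_beta))
      drop(st$Xsite %*% params$site_beta) else 0
    ll <- ll - 0.5 * st$n_sites * log(params$site_var) -
      0.5 * sum((lat$thc - mS)^2) / params$site_var
  }
  as.numeric(ll)
}

# score and observed information of the free specific slopes given latents
cd_s_block <- function(st, lat, params) {
  sload <- params$s[st$rs$rows$item]
  H <- mh_hrow(st, lat$Th, lat$thc)
  s_s <- numeric(st$K); i_s <- numeric(st$K)
  for (r in seq_len(st$R)) {
    k <- st$rs$rows$item[r]
    xi <- lat$Xi[, st$grp[r]]
    lp <- st$a[r] * H[, st$occ[r]] + sload[r] * xi
    Flo <- stats::plogis(st$CLO[, r] + lp)
    Fhi <- stats::plogis(st$CHI[, r] + lp)
    p <- pmax(Flo - Fhi, 1e-300)
    flo <- Flo * (1 - Flo); fhi <- Fhi * (1 - Fhi)
    dflo <- flo * (1 - 2 * Flo); dfhi <- fhi * (1 - 2 * Fhi)
    u1 <- (flo - fhi) / p
    u2 <- (dflo - dfhi) / p - u1^2
    ok <- !st$miss[, r]
    s_s[k] <- s_s[k] + sum((xi * u1)[ok])
    i_s[k] <- i_s[k] - sum((xi^2 * u2)[ok])
  }
  list(score = s_s, info = i_s)
}

# complete-data maximum-likelihood map given imputed latents (stage-1 update):
# restricted GLS for [mu | B], sample covariance for Sigma, damped Newton for
# the specific slopes, closed form for the site block
cd_mle <- function(st, lat, params) {
  spec <- st$spec
  G <- st$G; n <- st$n
  Fpat <- regression_pattern(spec)
  Z <- cbind(1, st$X)
  Om <- chol2inv(chol(params$Sigma))
  Zz <- crossprod(Z)
  Cs <- crossprod(lat$Th, Z)                 # G x q
  Gam <- update_gamma(Zz, Cs, Om, Fpat)
  Sig <- (crossprod(lat$Th) - Cs %*% t(Gam) - Gam %*% t(Cs) +
            Gam %*% Zz %*% t(Gam)) / n
  Sig <- (Sig + t(Sig)) / 2
  if (spec$cov_struct == "diagonal") Sig <- diag(diag(Sig), G)
  diag(Sig) <- pmax(diag(Sig), 1e-6)
  new <- params
  new$mu[] <- Gam[, 1]
  if (ncol(Fpat) > 1) new$B[] <- Gam[, -1, drop = FALSE]
  new$Sigma[] <- Sig
  if (spec$specific_free) {
    sb <- cd_s_block(st, lat, new)
    step <- ifelse(sb$info > 1e-8, sb$score / sb$info, 0)
    new$s[] <- pmin(pmax(new$s + pmin(pmax(step, -0.5), 0.5), -8), 8)
  }
  if (st$site) {
    if (!is.null(st$Xsite) && !is.null(params$site_beta)) {
      beta <- solve(crossprod(st$Xsite), crossprod(st$Xsite, lat$thc))
      new$site_beta[] <- drop(beta)
      mS <- drop(st$Xsite %*% beta)
    } else mS <- 0
    new$site_var <- max(mean((lat$thc - mS)^2), 1e-6)
  }
  new
}

# analytic complete-data score and observed information at the imputed data,
# in pack_params() order
cd_score_info <- function(st, lat, params) {
  spec <- st$spec
  G <- st$G
  n <- st$n
  Fpat <- regression_pattern(spec)
  q <- ncol(Fpat)
  Z <- cbind(1, st$X)
  Om <- chol2inv(chol(params$Sigma))
  Mu <- Z %*% t(cbind(params$mu, params$B))
  d <- lat$Th - Mu                       # n x G
  dOm <- d %*% Om
  # --- structural normal block (vecGamma, covariance params) ---------------
  SG <- crossprod(Z, dOm)                # q x G : score for Gamma' (z x g)
  M <- crossprod(d)                      # sum dd'
  Zz <- crossprod(Z)
  # index of free Gamma entries in pack order: means then betas
  gsel <- seq_len(G)                     # (g, col 1) -> vec index g
  for (fac in names(spec$regression)) {
    gi <- match(fac, spec$gen_names)
    ci <- match(spec$regression[[fac]], colnames(Fpat))
    gsel <- c(gsel, gi + G * (ci - 1L))
  }
  vecSG <- as.vector(t(SG))              # vec over (g fastest, then z)
  s_gamma <- vecSG[gsel]
  I_gamma_full <- kronecker(Zz, Om)      # (Gq x Gq), vec(Gamma) col-major
  if (spec$cov_struct == "full") {
    Dm <- dup_matrix(G)
    Svec <- 0.5 * as.vector(Om %*% M %*% Om - n * Om)
    s_cov <- drop(crossprod(Dm, Svec))
    OMO <- Om %*% M %*% Om
    Ivec <- 0.5 * (kronecker(Om, OMO) + kronecker(OMO, Om) -
                     n * kronecker(Om, Om))
    I_cov <- crossprod(Dm, Ivec %*% Dm)
    # cross Gamma x vech(Sigma): rows over vec(Gamma), cols vec(Sigma)
    W <- crossprod(Z, dOm)               # q x G
    Hfull <- matrix(0, G * q, G * G)
    for (i in seq_len(q))
      Hfull[(i - 1) * G + seq_len(G), ] <- -kronecker(matrix(W[i, ], 1), Om)
    I_gc_full <- -Hfull %*% Dm           # information = -Hessian
    ncov <- G * (G + 1) / 2
  } else {
    sig <- diag(params$Sigma)
    s_cov <- -n / (2 * sig) + diag(M) / (2 * sig^2)
    I_cov <- diag(diag(M) / sig^3 - n / (2 * sig^2), G)
    # cross (Gamma entries of factor g) x sigma_g^2
    W <- crossprod(Z, dOm)               # q x G ; dOm col g = d_g / sig_g
    I_gc_full <- matrix(0, G * q, G)
    for (i in seq_len(q)) for (g in seq_len(G))
      I_gc_full[(i - 1) * G + g, g] <- W[i, g] / sig[g]
    ncov <- G
  }
  sel <- gsel
  I_gamma <- I_gamma_full[sel, sel, drop = FALSE]
  I_gc <- I_gc_full[sel, , drop = FALSE]

  npar_head <- length(gsel) + ncov
  # pack order: means, cov, betas -- reorder (means | betas) block
  ord_head <- c(seq_len(G),                                   # means
                length(gsel) + seq_len(ncov),                 # cov block
                if (length(gsel) > G) G + seq_len(length(gsel) - G))
  s_head <- c(s_gamma, s_cov)[ord_head]
  I_head <- rbind(cbind(I_gamma, I_gc), cbind(t(I_gc), I_cov))
  I_head <- I_head[ord_head, ord_head, drop = FALSE]

  s <- s_head
  Iblocks <- list(I_head)

  # --- specific slopes -------------------------------------------------------
  if (spec$specific_free) {
    sb <- cd_s_block(st, lat, params)
    s <- c(s, sb$score)
    Iblocks <- c(Iblocks, list(diag(sb$info, st$K)))
  }
  # --- site block ------------------------------------------------------------
  if (st$site) {
    mS <- if (!is.null(st$Xsite) && !is.null(params$site_beta))
      drop(st$Xsite %*% params$site_beta) else rep(0, st$n_sites)
    dc <- lat$thc - mS
    sv <- params$site_var
    s_sv <- -st$n_sites / (2 * sv) + sum(dc^2) / (2 * sv^2)
    i_sv <- sum(dc^2) / sv^3 - st$n_sites / (2 * sv^2)
    if (!is.null(st$Xsite) && !is.null(params$site_beta)) {
      s_sb <- drop(crossprod(st$Xsite, dc)) / sv
      i_sb <- crossprod(st$Xsite) / sv
      i_cross <- drop(crossprod(st$Xsite, dc)) / sv^2
      Ib <- rbind(c(i_sv, i_cross), cbind(i_cross, i_sb))
      s <- c(s, s_sv, s_sb)
      Iblocks <- c(Iblocks, list(Ib))
    } else {
      s <- c(s, s_sv)
      Iblocks <- c(Iblocks, list(matrix(i_sv, 1, 1)))
    }
  }
  p <- length(s)
  I <- matrix(0, p, p)
  at <- 0
  for (B in Iblocks) {
    idx <- at + seq_len(nrow(B))
    I[idx, idx] <- B
    at <- at + nrow(B)
  }
  list(s = stats::setNames(s, param_names(spec, st$bank)), I = I)
}

## ---- MH-RM driver -----------------------------------------------------------

#' Fit a model by Metropolis-Hastings Robbins-Monro
#'
#' Stochastic marginal maximum likelihood for single-level specs (optionally
#' with a site factor): each cycle (1) imputes all latent variables by
#' componentwise random-walk Metropolis sweeps, (2) evaluates the analytic
#' complete-data score and observed information, and (3) applies a
#' Robbins-Monro update with a recursively averaged curvature matrix.
#' Proposal scales are auto-tuned during burn-in only. Given the same seed
#' and configuration the result is bitwise reproducible. Standard errors use
#' the Louis identity accumulated recursively over extra cycles at the
#' solution ([se_recursive()]); the marginal log-likelihood is not a
#' by-product and can be estimated with [mc_marginal_loglik()].
#'
#' @inheritParams fit_baem
#' @param seed integer seed governing all randomness.
#' @param config an [mhrm_control()] list.
#' @return a `proirt_fit` object (with `minus2LL = NA`).
#' @export
fit_mhrm <- function(data, spec, bank, start = NULL, seed = 1,
                     config = mhrm_control(), control = proirt_control()) {
  set.seed(seed)
  st <- mh_setup(data, spec, bank)
  params <- start %||% default_start(spec, bank)
  v <- pack_params(params, spec, bank)
  p <- length(v)
  # latent initialization at prior means
  Mu <- matrix(rep(params$mu, each = st$n), ncol = st$G)
  if (ncol(st$X)) Mu <- Mu + st$X %*% t(params$B)
  lat <- list(Th = Mu, Xi = matrix(0, st$n, st$nG),
              thc = if (st$site) rep(0, st$n_sites) else numeric(0))
  scales <- list(theta = rep(config$proposal_scale, st$G),
                 xi = rep(config$proposal_scale, st$nG),
                 site = config$proposal_scale)

  # burn-in with proposal tuning
  accw <- c(theta = 0, xi = 0, site = 0); naccw <- 0
  for (it in seq_len(config$n_burnin)) {
    lat <- mh_sweep(st, lat, params, scales)
    accw <- accw + lat$accept; naccw <- naccw + 1
    if (it %% 20 == 0) {
      rate <- accw / naccw
      tune <- function(sc, r) {
        if (r < config$accept_range[1]) sc * 0.7
        else if (r > config$accept_range[2]) sc * 1.4
        else sc
      }
      scales$theta[] <- tune(scales$theta, rate["theta"])
      scales$xi[] <- tune(scales$xi, rate["xi"])
      if (st$site) scales$site <- tune(scales$site, rate["site"])
      accw[] <- 0; naccw <- 0
    }
  }

  Gamma <- NULL
  trace <- if (config$keep_trace) matrix(NA_real_, 0, p) else NULL
  nconv <- 0L
  status <- "not converged"
  cycles <- 0L

  # stage 1: stochastic EM -- complete-data ML map on the imputed latents,
  # with the curvature matrix accumulated as a running average for stage 2
  for (j in seq_len(config$n_stage1)) {
    cycles <- cycles + 1L
    lat <- mh_sweep(st, lat, params, scales)
    params <- cd_mle(st, lat, params)
    v <- pack_params(params, spec, bank)
    if (any(!is.finite(v)) || max(abs(v)) > 1e6)
      stop("MH-RM diverged in stage 1 (parameter norm exploded)", call. = FALSE)
    si <- cd_score_info(st, lat, params)
    if (is.null(Gamma)) Gamma <- si$I + diag(1e-6, p)
    else Gamma <- Gamma + (si$I - Gamma) / j
    if (config$keep_trace) trace <- rbind(trace, v)
  }

  # stage 2: Robbins-Monro with decaying gain and recursive curvature
  dvsum <- numeric(p)
  for (j in seq_len(config$n_stage2)) {
    cycles <- cycles + 1L
    lat <- mh_sweep(st, lat, params, scales)
    si <- cd_score_info(st, lat, params)
    gain <- (1 / j)^config$gain_exponent
    if (is.null(Gamma)) Gamma <- si$I + diag(1e-6, p)
    else Gamma <- Gamma + gain * (si$I - Gamma)
    step <- try(solve(Gamma + diag(1e-8, p), si$s), silent = TRUE)
    if (inherits(step, "try-error"))
      step <- si$s / pmax(diag(Gamma), 1)
    dv <- gain * pmin(pmax(step, -config$max_step), config$max_step)
    okp <- FALSE
    for (half in 1:30) {
      vn <- v + dv
      pn <- try(unpack_params(vn, spec, bank), silent = TRUE)
      okp <- !inherits(pn, "try-error") &&
        !inherits(try(chol(pn$Sigma), silent = TRUE), "try-error") &&
        (is.null(pn$site_var) || pn$site_var > 1e-6)
      if (okp) break
      dv <- dv / 2
    }
    if (!okp) stop("MH-RM diverged: no valid step found", call. = FALSE)
    if (any(!is.finite(vn)) || max(abs(vn)) > 1e6)
      stop("MH-RM diverged (parameter norm exploded); check the model or ",
           "lower the proposal scale", call. = FALSE)
    v <- vn; params <- pn
    if (config$keep_trace) trace <- rbind(trace, v)
    dvsum <- dvsum + dv
    if (j %% config$window_size == 0) {
      if (max(abs(dvsum)) / config$window_size < config$tol)
        nconv <- nconv + 1L
      else nconv <- 0L
      dvsum[] <- 0
      if (nconv >= config$window) { status <- "converged"; break }
    }
  }
  if (status != "converged") status <- "not converged (stage-2 limit)"

  fit <- new_proirt_fit(
    engine = "MHRM", params = params, spec = spec, bank = bank, data = data,
    minus2LL = NA_real_,
    n_free = p, n_cases = st$n,
    convergence = list(iterations = cycles, max_change = NA_real_,
                       status = status, loglik_trace = numeric(0)),
    control = control)
  fit$seed <- seed
  fit$config <- config
  fit$mh_scales <- scales
  if (config$keep_trace) fit$trace <- trace

  if (config$se_cycles > 0) {
    ser <- se_recursive_run(st, lat, params, scales, config$se_cycles,
                            thin = config$se_thin %||% 3L)
    fit$se <- ser$se
    fit$vcov <- ser$vcov
  }
  fit
}

# Louis-identity information accumulated over extra cycles at fixed params
se_recursive_run <- function(st, lat, params, scales, n_cycles, thin = 2L) {
  p <- length(pack_params(params, st$spec, st$bank))
  A <- matrix(0, p, p)
  b <- numeric(p)
  for (j in seq_len(n_cycles)) {
    for (s in seq_len(thin)) lat <- mh_sweep(st, lat, params, scales)
    si <- cd_score_info(st, lat, params)
    A <- A + ((si$I - tcrossprod(si$s)) - A) / j
    b <- b + (si$s - b) / j
  }
  info <- A + tcrossprod(b)
  nm <- param_names(st$spec, st$bank)
  dimnames(info) <- list(nm, nm)
  vc <- try(solve(info), silent = TRUE)
  if (inherits(vc, "try-error")) {
    ev <- eigen(info, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-10
    vc <- ev$vectors[, pos, drop = FALSE] %*%
      diag(1 / ev$values[pos], sum(pos)) %*% t(ev$vectors[, pos, drop = FALSE])
    dimnames(vc) <- dimnames(info)
    warning("recursive information not positive definite; generalized inverse used")
  }
  se <- sqrt(pmax(diag(vc), 0))
  se[diag(vc) <= 0] <- NA_real_
  list(se = stats::setNames(se, nm), vcov = vc, info = info)
}

#' Recursive standard errors of an MH-RM fit
#'
#' Re-runs latent imputation cycles at the fitted parameters and accumulates
#' the Louis-identity observed information recursively: the running average
#' of (complete-data information minus score outer product) plus the outer
#' product of the running average score.
#'
#' @param fit a `proirt_fit` from [fit_mhrm()].
#' @param n_cycles number of imputation cycles.
#' @param seed seed for the imputation chain.
#' @param thin Metropolis sweeps per retained cycle.
#' @return list with `se`, `vcov`, `info`.
#' @export
se_recursive <- function(fit, n_cycles = 1500, seed = fit$seed %||% 1,
                         thin = 3L) {
  stopifnot(inherits(fit, "proirt_fit"), fit$engine == "MHRM")
  set.seed(seed + 1L)
  st <- mh_setup(fit$data, fit$spec, fit$bank)
  Mu <- matrix(rep(fit$params$mu, each = st$n), ncol = st$G)
  if (ncol(st$X)) Mu <- Mu + st$X %*% t(fit$params$B)
  lat <- list(Th = Mu, Xi = matrix(0, st$n, st$nG),
              thc = if (st$site) rep(0, st$n_sites) else numeric(0))
  scales <- fit$mh_scales %||% list(theta = rep(1, st$G), xi = rep(1, st$nG),
                                    site = 1)
  for (i in 1:50) lat <- mh_sweep(st, lat, fit$params, scales)  # re-burn
  se_recursive_run(st, lat, fit$params, scales, n_cycles, thin = thin)
}

## ---- Monte-Carlo marginal log-likelihood ------------------------------------

#' Monte-Carlo marginal log-likelihood (Chib-Jeliazkov)
#'
#' Estimates `-2 log L` at fixed parameters when quadrature is impractical,
#' using the posterior-ordinate identity per subject: `log L_j = log f(y_j |
#' z*) + log p(z*) - log pi(z* | y_j)`, with the posterior ordinate at the
#' posterior mean `z*` estimated from Metropolis accept ratios of a joint
#' random-walk kernel (numerator over posterior draws, denominator over fresh
#' proposals from `z*`). For specs with a site factor the site intercept is
#' integrated on its quadrature grid, with the per-subject ordinates
#' estimated at each site node. The 95% confidence interval comes from 10
#' batch means over the sampling cycles.
#'
#' @param data,spec,bank,params model pieces as in [marginal_loglik()];
#'   `params` should be converged estimates (a [fit_mhrm()] result's
#'   `$params`).
#' @param n_samples Monte-Carlo draws per subject (default 250).
#' @param seed integer seed.
#' @param n_burnin chain burn-in per subject.
#' @param thin Metropolis sweeps per retained draw (reduces autocorrelation
#'   of the ordinate estimate).
#' @param control quadrature settings (used for the site grid).
#' @return list with `minus2LL`, `ci` (two-sided 95%), `se`, `batches`.
#' @export
mc_marginal_loglik <- function(data, spec, bank, params, n_samples = 250,
                               seed = 1, n_burnin = 100, thin = 3,
                               control = proirt_control()) {
  if (n_samples < 20) stop("need at least 2 batches of 10 samples", call. = FALSE)
  set.seed(seed)
  st <- mh_setup(data, spec, bank)
  sload <- if (spec$specific_free) params$s[st$rs$rows$item] else st$rs$rows$sload
  Mu <- matrix(rep(params$mu, each = st$n), ncol = st$G)
  if (ncol(st$X)) Mu <- Mu + st$X %*% t(params$B)
  Om <- chol2inv(chol(params$Sigma))
  ldetS <- as.numeric(determinant(params$Sigma)$modulus)
  d <- st$G + st$nG

  site_nodes <- 0; site_w <- 1
  if (st$site) {
    sg <- quadrature_grid(control$site_quadpts, control$qrange)
    site_nodes <- sg$nodes * sqrt(params$site_var)
    site_w <- sg$weights
  }

  # log target: conditional likelihood + latent prior, vectorized (n x d states)
  logpost <- function(Z, thc_val) {
    Th <- Z[, seq_len(st$G), drop = FALSE]
    Xi <- Z[, st$G + seq_len(st$nG), drop = FALSE]
    thc <- rep(thc_val, st$n_sites)
    ll <- mh_cond_ll(st, Th, Xi, if (st$site) thc else numeric(0), sload)
    dd <- Th - Mu
    ll - 0.5 * rowSums((dd %*% Om) * dd) - 0.5 * ldetS -
      0.5 * rowSums(Xi^2) - 0.5 * d * log(2 * pi)
  }

  nb <- 10L
  bs <- n_samples %/% nb
  loglik_site <- matrix(0, st$n, length(site_nodes))   # per subject per node
  batch_site <- array(0, c(st$n, length(site_nodes), nb))
  for (m in seq_along(site_nodes)) {
    sc <- 2.4 / sqrt(d)
    Z <- cbind(Mu, matrix(0, st$n, st$nG))
    lp <- logpost(Z, site_nodes[m])
    # burn-in with light tuning
    accr <- 0
    for (it in seq_len(n_burnin)) {
      Zp <- Z + sc * matrix(stats::rnorm(st$n * d), st$n, d)
      lpp <- logpost(Zp, site_nodes[m])
      ok <- log(stats::runif(st$n)) < lpp - lp
      Z[ok, ] <- Zp[ok, ]; lp[ok] <- lpp[ok]
      accr <- accr + mean(ok)
      if (it %% 25 == 0) {
        r <- accr / 25; accr <- 0
        if (r < 0.15) sc <- sc * 0.7 else if (r > 0.5) sc <- sc * 1.3
      }
    }
    draws <- array(0, c(st$n, d, n_samples))
    lps <- matrix(0, st$n, n_samples)
    for (it in seq_len(n_samples)) {
      for (s in seq_len(thin)) {
        Zp <- Z + sc * matrix(stats::rnorm(st$n * d), st$n, d)
        lpp <- logpost(Zp, site_nodes[m])
        ok <- log(stats::runif(st$n)) < lpp - lp
        Z[ok, ] <- Zp[ok, ]; lp[ok] <- lpp[ok]
      }
      draws[, , it] <- Z
      lps[, it] <- lp
    }
    # the ordinate point z* comes from the first half of the draws; the
    # ordinate itself is estimated from the second half, so the two are
    # (nearly) independent and q(z* | z) is not evaluated at a point chosen
    # from the same draws it weights
    nh <- n_samples %/% 2L
    zstar <- apply(draws[, , seq_len(nh), drop = FALSE], c(1, 2), mean)
    lpz <- logpost(zstar, site_nodes[m])
    use <- (nh + 1L):n_samples
    # numerator: E_post[ alpha(z -> z*) q(z* | z) ]; denominator: E_q[ alpha(z* -> z) ]
    num <- den <- matrix(0, st$n, length(use))
    for (ii in seq_along(use)) {
      it <- use[ii]
      dz <- zstar - draws[, , it]
      lq <- -0.5 * rowSums(dz^2) / sc^2 - d * log(sc) - 0.5 * d * log(2 * pi)
      num[, ii] <- exp(pmin(lpz - lps[, it], 0) + lq)
      Zp <- zstar + sc * matrix(stats::rnorm(st$n * d), st$n, d)
      lpp <- logpost(Zp, site_nodes[m])
      den[, ii] <- exp(pmin(lpp - lpz, 0))
    }
    # point estimate from all retained draws; batches give the CI spread
    ord <- rowMeans(num) / pmax(rowMeans(den), 1e-300)
    loglik_site[, m] <- lpz - log(pmax(ord, 1e-300))
    bs2 <- length(use) %/% nb
    for (b in seq_len(nb)) {
      idx <- (b - 1L) * bs2 + seq_len(bs2)
      ordb <- rowMeans(num[, idx, drop = FALSE]) /
        pmax(rowMeans(den[, idx, drop = FALSE]), 1e-300)
      batch_site[, m, b] <- lpz - log(pmax(ordb, 1e-300))
    }
  }
  # combine site nodes (outer quadrature), then across subjects/sites
  combine <- function(lls) {
    if (st$site) {
      # site likelihood: integrate product over its subjects per node
      tot <- 0
      for (cl in seq_len(st$n_sites)) {
        idx <- which(st$site_of == cl)
        lsum <- colSums(lls[idx, , drop = FALSE])
        mx <- max(lsum + log(site_w))
        tot <- tot + mx + log(sum(exp(lsum + log(site_w) - mx)))
      }
      tot
    } else sum(lls[, 1])
  }
  total_b <- vapply(seq_len(nb), function(b)
    combine(matrix(batch_site[, , b], st$n, length(site_nodes))), numeric(1))
  m2 <- -2 * combine(loglik_site)
  sem <- 2 * stats::sd(total_b) / sqrt(nb)
  ci <- m2 + c(-1, 1) * stats::qt(0.975, nb - 1) * sem
  list(minus2LL = m2, ci = ci, se = sem, batches = -2 * total_b,
       n_samples = n_samples)
}
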
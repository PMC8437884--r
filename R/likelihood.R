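#' Quadrature grid
#'
#' Equally spaced rectangular quadrature abscissae on the standardized latent
#' metric with weights proportional to the standard-normal density,
#' normalized to sum to one. Each latent dimension uses these nodes scaled by
#' its current standard deviation (and shifted by its model-implied mean), so
#' the grid always spans `range` prior standard deviations; correlation
#' between dimensions enters through the joint node weights.
#'
#' @param n number of points.
#' @param range interval covered by the grid, in standard-deviation units.
#' @return list with `nodes`, `weights`, `n_points`, `range`.
#' @export
quadrature_grid <- function(n = 21, range = c(-5, 5)) {
  stopifnot(n >= 2, length(range) == 2, range[1] < range[2])
  nodes <- seq(range[1], range[2], length.out = n)
  w <- stats::dnorm(nodes)
  structure(list(nodes = nodes, weights = w / sum(w), n_points = n,
                 range = range), class = "quadrature_grid")
}

# tensor grid over G dimensions: matrix (n^G x G), first dimension fastest
tensor_nodes <- function(nodes, G) {
  if (G == 0) return(matrix(0, 1, 0))
  as.matrix(do.call(expand.grid, rep(list(nodes), G)))
}

# normalized multivariate-normal weights of rows of Theta for each row of Mu
# returns n x Ng matrix with rows summing to 1
mvn_weights <- function(Theta, Mu, Sigma) {
  G <- ncol(Theta)
  if (G == 0) return(matrix(1, nrow(Mu), 1))
  ch <- tryCatch(chol(Sigma),
                 error = function(e) chol(Sigma + diag(1e-8, G)))
  Om <- chol2inv(ch)
  TOm <- Theta %*% Om
  qf0 <- rowSums(TOm * Theta)
  cst <- rowSums((Mu %*% Om) * Mu)
  LW <- -0.5 * (outer(qf0, cst, "+") - 2 * (TOm %*% t(Mu)))   # Ng x n
  LW <- sweep(LW, 2, apply(LW, 2, max))
  W <- exp(LW)
  t(W) / colSums(W)
}

cor_from_cov <- function(S) {
  sds <- sqrt(pmax(diag(S), 1e-12))
  S / tcrossprod(sds)
}

## ---- engine construction ---------------------------------------------------

# Static per-fit structures shared by likelihood, EM and scoring calls.
make_engine <- function(data, spec, bank, control = proirt_control()) {
  stopifnot(inherits(data, "trial_data"), inherits(spec, "proirt_spec"),
            inherits(bank, "item_bank"))
  K <- length(bank$items); T <- spec$T
  if (data$T != T) stop("data has ", data$T, " occasions, spec expects ", T,
                        call. = FALSE)
  perm <- match(bank_ids(bank), data$item_ids)
  if (anyNA(perm))
    stop("data is missing items: ",
         paste(setdiff(bank_ids(bank), data$item_ids), collapse = ", "),
         call. = FALSE)
  rs <- spec_rows(spec, bank)
  n <- nrow(data$Y)
  colmap <- as.vector(vapply(seq_len(T), function(t) (t - 1L) * data$K + perm,
                             integer(K)))
  Y <- data$Y[, colmap, drop = FALSE]
  maxcat <- rep(bank_ncat(bank), T)
  if (any(sweep(Y, 2, maxcat, ">=") , na.rm = TRUE))
    stop("response categories out of range", call. = FALSE)

  level <- spec$level
  site <- !is.null(spec$site)
  if (site && is.null(data$site))
    stop("spec has a site factor but data has no site ids", call. = FALSE)

  if (level == "block") {
    n_units <- n * T
    unit_subject <- rep(seq_len(n), each = T)
    unit_occ <- rep(seq_len(T), times = n)
    struct_level <- "cluster"
    Gu <- 0L
    ucl <- unit_subject
  } else {
    n_units <- n
    unit_subject <- seq_len(n)
    unit_occ <- NULL
    struct_level <- "unit"
    Gu <- n_general(spec)
    ucl <- if (site) as.integer(factor(data$site)) else seq_len(n)
  }
  unit_order <- order(ucl)
  ucl_sorted <- ucl[unit_order]
  nC <- length(unique(ucl_sorted))
  cluster_ptr <- c(0L, cumsum(as.integer(
    table(factor(ucl_sorted, levels = unique(ucl_sorted))))))

  # observation lists per unit, grouped within unit
  ob <- vector("list", n_units)
  for (uu in seq_len(n_units)) {
    u <- unit_order[uu]
    j <- unit_subject[u]
    rows_u <- if (level == "block") which(rs$rows$occ == unit_occ[u])
              else seq_len(nrow(rs$rows))
    y <- Y[j, rows_u]
    keep <- !is.na(y)
    r <- rows_u[keep]
    o <- order(rs$rows$group[r], rs$rows$occ[r])
    ob[[uu]] <- list(row = r[o] - 1L, cat = as.integer(y[keep][o]))
  }
  obs_row <- unlist(lapply(ob, `[[`, "row"), use.names = FALSE) %||% integer(0)
  obs_cat <- unlist(lapply(ob, `[[`, "cat"), use.names = FALSE) %||% integer(0)
  unit_ptr <- c(0L, cumsum(vapply(ob, function(z) length(z$row), integer(1))))

  # grids on the standardized metric
  gg <- quadrature_grid(control$quadpts, control$qrange)
  Theta <- tensor_nodes(gg$nodes, Gu)
  if (struct_level == "cluster") {
    Gc <- n_general(spec)
    Thc <- tensor_nodes(gg$nodes, Gc)
  } else if (site) {
    sg <- quadrature_grid(control$site_quadpts, control$qrange)
    Gc <- 1L
    Thc <- matrix(sg$nodes, ncol = 1)
    attr(Thc, "weights") <- sg$weights
  } else {
    Gc <- 0L
    Thc <- matrix(0, 1, 0)
  }

  # integration space for the structural factors
  G <- n_general(spec)
  gen_space <- if (G == T && abs(det(spec$A)) > 1e-10) "eta" else "theta"
  Ainv <- if (gen_space == "eta") solve(spec$A) else NULL

  # covariate patterns (offsets folded into the composite lattice)
  covs <- spec_covariates(spec)
  X <- covariate_matrix(data, covs)                   # subjects x ncov
  subj_of_unit <- unit_subject[unit_order]
  Xsub <- X[subj_of_unit, , drop = FALSE]             # per unit, sorted order
  sitecovs <- if (site) spec$site_regression %||% character() else character()
  Xsite_sub <- if (length(sitecovs))
    covariate_matrix(data, sitecovs)[subj_of_unit, , drop = FALSE]
  else matrix(0, n_units, 0)
  pkey <- apply(cbind(Xsub, Xsite_sub), 1, paste, collapse = "\r")
  upat <- match(pkey, unique(pkey))
  first <- match(unique(pkey), pkey)
  Xpat <- Xsub[first, , drop = FALSE]
  Xsite_pat <- Xsite_sub[first, , drop = FALSE]
  if (length(sitecovs)) {
    ok <- vapply(seq_len(ncol(Xsite_sub)), function(jc)
      all(tapply(Xsite_sub[, jc], ucl_sorted, function(v) length(unique(v)) == 1L)),
      logical(1))
    if (!all(ok)) stop("site-level covariates must be constant within site",
                       call. = FALSE)
  }

  # structural-design rows (one per structural entity)
  if (struct_level == "cluster") {
    cl_first_unit <- match(unique(ucl_sorted), ucl_sorted)
    Xstruct <- Xsub[cl_first_unit, , drop = FALSE]
  } else {
    Xstruct <- Xsub
  }
  Xsite_cl <- if (length(sitecovs)) {
    cl_first_unit <- match(unique(ucl_sorted), ucl_sorted)
    Xsite_sub[cl_first_unit, , drop = FALSE]
  } else NULL

  list(spec = spec, bank = bank, rows = rs, K = K, T = T,
       n_subjects = n, n_units = n_units, n_clusters = nC,
       struct_level = struct_level, site = site,
       gen_space = gen_space, Ainv = Ainv,
       subj_of_unit = subj_of_unit,
       obs_row = obs_row, obs_cat = obs_cat,
       unit_ptr = unit_ptr, cluster_ptr = cluster_ptr,
       unit_pattern = upat - 1L, n_patterns = length(first),
       Xpat = Xpat, Xsite_pat = Xsite_pat,
       Theta = Theta, Thc = Thc, Ng = nrow(Theta), Ncl = nrow(Thc),
       Gu = Gu, Gc = Gc,
       xq = gg$nodes, wq = gg$weights,
       Xstruct = Xstruct, Xsite_cl = Xsite_cl,
       control = control)
}

# current specific loading per row given params
row_sload <- function(eng, params) {
  rs <- eng$rows
  if (eng$spec$specific_free) params$s[rs$rows$item] else rs$rows$sload
}

# per-call grid pieces: composite values/indices, weights, transforms
engine_grids <- function(eng, params) {
  spec <- eng$spec
  G <- n_general(spec)
  T <- eng$T
  # structural scaling
  if (eng$gen_space == "eta") {
    Se <- spec$A %*% params$Sigma %*% t(spec$A)
    sds <- sqrt(pmax(diag(Se), 1e-12))
    Rm <- cor_from_cov(Se)
  } else {
    sds <- sqrt(pmax(diag(params$Sigma), 1e-12))
    Rm <- cor_from_cov(params$Sigma)
  }
  if (eng$struct_level == "unit") {
    Vu <- if (eng$gen_space == "eta") {
      sweep(eng$Theta, 2, sds, "*")                 # eta_t = o_t + sd_t z_t
    } else {
      sweep(eng$Theta, 2, sds, "*") %*% t(spec$A)
    }
    pw_unit <- mvn_weights(eng$Theta, matrix(0, 1, eng$Gu), Rm)
    if (eng$site) {
      sdc <- sqrt(max(params$site_var, 1e-12))
      Vc <- (sdc * eng$Thc[, 1]) %o% spec$site$loadings
      pw_cluster <- matrix(attr(eng$Thc, "weights"), 1)
    } else {
      sdc <- NULL
      Vc <- matrix(0, 1, T)
      pw_cluster <- matrix(1, 1, 1)
    }
  } else {
    # block parameterization: structural factors at cluster level
    Vu <- matrix(0, 1, T)
    pw_unit <- matrix(1, 1, 1)
    sdc <- NULL
    Vc <- sweep(eng$Thc, 2, sds, "*") %*% t(spec$A)
    pw_cluster <- mvn_weights(eng$Thc, matrix(0, 1, eng$Gc), Rm)
  }
  # per-pattern composite offsets
  MuP <- matrix(rep(params$mu, each = eng$n_patterns), ncol = G)
  if (ncol(eng$Xpat)) MuP <- MuP + eng$Xpat %*% t(params$B)
  offP <- MuP %*% t(spec$A)                          # patterns x T
  if (eng$site && !is.null(params$site_beta) && ncol(eng$Xsite_pat))
    offP <- offP + (eng$Xsite_pat %*% params$site_beta) %o% spec$site$loadings
  w_vals <- vector("list", T); w_idx <- vector("list", T)
  for (t in seq_len(T)) {
    cmb <- outer(as.vector(outer(Vc[, t], offP[, t], "+")), Vu[, t], "+")
    key <- round(cmb, 12)
    vals <- sort(unique(as.vector(key)))
    w_vals[[t]] <- vals
    w_idx[[t]] <- matrix(match(key, vals) - 1L, nrow(cmb), ncol(cmb))
  }
  list(sds = sds, Rm = Rm, sdc = sdc, MuP = MuP,
       pw_unit = pw_unit, pw_cluster = pw_cluster,
       w_vals = w_vals, w_idx = w_idx)
}

# one E-step / likelihood evaluation, with moments on the structural scale
engine_estep <- function(eng, params, want_post = FALSE, want_tables = FALSE,
                         want_cluster_post = FALSE) {
  spec <- eng$spec
  gr <- engine_grids(eng, params)
  want_z <- want_post && eng$struct_level == "unit"
  want_cl <- (want_cluster_post || want_post) && eng$Gc > 0
  res <- eng_estep(eng$obs_row, eng$obs_cat, eng$unit_ptr, eng$cluster_ptr,
                   eng$unit_pattern, eng$n_patterns,
                   eng$rows$rows$a, row_sload(eng, params),
                   eng$rows$rows$group - 1L, eng$rows$rows$occ - 1L,
                   eng$rows$intercepts, eng$rows$rows$ncat,
                   eng$rows$n_groups,
                   eng$Theta, gr$pw_unit, gr$w_idx, gr$w_vals,
                   gr$pw_cluster, eng$Thc, eng$xq, eng$wq,
                   want_z, want_tables, want_cl)
  out <- list(loglik = sum(res$ll), ll = res$ll, tables = res$tables,
              w_vals = gr$w_vals, grids = gr)
  G <- n_general(spec)
  if (want_post) {
    # structural moments on the theta scale, one row per structural entity
    if (eng$struct_level == "unit") {
      Ez <- res$Egen; Ez2 <- res$Egen2
      Mu_ent <- gr$MuP[eng$unit_pattern + 1L, , drop = FALSE]
    } else {
      Ez <- res$Ecl; Ez2 <- res$Ecl2
      pat_cl <- eng$unit_pattern[eng$cluster_ptr[seq_len(eng$n_clusters)] + 1L]
      Mu_ent <- gr$MuP[pat_cl + 1L, , drop = FALSE]
    }
    N <- nrow(Ez)
    D <- diag(gr$sds, G)
    Em <- matrix(0, N, G); E2 <- matrix(0, N, G * G)
    for (j in seq_len(N)) {
      mz <- Ez[j, ]; Sz <- matrix(Ez2[j, ], G, G)
      if (eng$gen_space == "eta" && eng$struct_level == "unit") {
        o <- drop(spec$A %*% Mu_ent[j, ])
        Eh <- o + gr$sds * mz
        Eh2 <- tcrossprod(o) + tcrossprod(o, gr$sds * mz) +
          tcrossprod(gr$sds * mz, o) + D %*% Sz %*% D
        Em[j, ] <- drop(eng$Ainv %*% Eh)
        E2[j, ] <- eng$Ainv %*% Eh2 %*% t(eng$Ainv)
      } else {
        o <- Mu_ent[j, ]
        Em[j, ] <- o + gr$sds * mz
        E2[j, ] <- tcrossprod(o) + tcrossprod(o, gr$sds * mz) +
          tcrossprod(gr$sds * mz, o) + D %*% Sz %*% D
      }
    }
    out$Em <- Em; out$E2 <- E2
  }
  if (want_cluster_post && eng$site) {
    mC <- if (!is.null(eng$Xsite_cl) && !is.null(params$site_beta))
      drop(eng$Xsite_cl %*% params$site_beta) else rep(0, eng$n_clusters)
    out$site_Em <- mC + gr$sdc * res$Ecl[, 1]
    out$site_E2 <- mC^2 + 2 * mC * gr$sdc * res$Ecl[, 1] +
      gr$sdc^2 * res$Ecl2[, 1]
  }
  out
}

## ---- public likelihood API -------------------------------------------------

#' Marginal log-likelihood of a model
#'
#' Integrates the latent variables out of the item-response likelihood. The
#' default method exploits the two-tier structure: general factors are
#' integrated jointly, specific factors one at a time conditionally on the
#' generals, and the site factor (when present) on an outer grid, so the
#' maximal joint integral has dimension [integration_dimension()]. The
#' `"naive"` method integrates all latent dimensions on one full tensor grid
#' and exists as a brute-force cross-check for small models.
#'
#' @param data a [trial_data()] object.
#' @param spec a `proirt_spec`.
#' @param bank an [item_bank()].
#' @param params a `proirt_params` set; defaults to [default_start()].
#' @param control a [proirt_control()] list (quadrature settings).
#' @param method `"reduced"` (default) or `"naive"`.
#' @return total marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(data, spec, bank, params = default_start(spec, bank),
                            control = proirt_control(),
                            method = c("reduced", "naive")) {
  method <- match.arg(method)
  if (method == "reduced") {
    eng <- make_engine(data, spec, bank, control)
    engine_estep(eng, params)$loglik
  } else {
    naive_loglik(data, spec, bank, params, control)
  }
}

# full-tensor quadrature over all latent dimensions (single-level specs only)
naive_loglik <- function(data, spec, bank, params, control = proirt_control()) {
  if (spec$level != "single" || !is.null(spec$site))
    stop("the naive method supports single-level specs without site factors",
         call. = FALSE)
  eng <- make_engine(data, spec, bank, control)
  rs <- eng$rows
  G <- eng$Gu; nG <- rs$n_groups
  dims <- G + nG
  npts <- control$quadpts
  if (npts^dims > 2e7)
    stop("naive quadrature over ", dims, " dimensions at ", npts,
         " points is too large", call. = FALSE)
  gr <- engine_grids(eng, params)
  gg <- quadrature_grid(npts, control$qrange)
  TH <- tensor_nodes(gg$nodes, dims)
  Zg <- TH[, seq_len(G), drop = FALSE]
  # same standardized construction as the reduced method
  comp <- if (eng$gen_space == "eta") sweep(Zg, 2, gr$sds, "*")
          else sweep(Zg, 2, gr$sds, "*") %*% t(spec$A)      # rows x T
  wgen <- mvn_weights(tensor_nodes(gg$nodes, G), matrix(0, 1, G), gr$Rm)
  gen_idx <- ((seq_len(nrow(TH)) - 1L) %% npts^G) + 1L
  w <- wgen[1, gen_idx]
  for (d in seq_len(nG))
    w <- w * gg$weights[tensor_col(nrow(TH), npts, G + d)]
  sload <- row_sload(eng, params)
  offP <- gr$MuP %*% t(spec$A)
  ll <- 0
  for (uu in seq_len(eng$n_units)) {
    cond <- rep(1, nrow(TH))
    if (eng$unit_ptr[uu + 1L] > eng$unit_ptr[uu]) {
      for (o in (eng$unit_ptr[uu] + 1L):(eng$unit_ptr[uu + 1L])) {
        r <- eng$obs_row[o] + 1L; cat <- eng$obs_cat[o]
        t <- rs$rows$occ[r]
        eta <- offP[eng$unit_pattern[uu] + 1L, t] + comp[gen_idx, t]
        xi <- TH[, G + rs$rows$group[r]]
        lp <- rs$rows$a[r] * eta + sload[r] * xi
        cond <- cond * grm_prob(lp, eng$rows$intercepts[r, ], rs$rows$ncat[r], cat)
      }
    }
    ll <- ll + log(sum(w * cond))
  }
  ll
}

# category probability at linear predictor lp (vectorized over lp)
grm_prob <- function(lp, intercepts, ncat, cat) {
  lo <- if (cat == 0) 1 else stats::plogis(intercepts[cat] + lp)
  hi <- if (cat == ncat - 1) 0 else stats::plogis(intercepts[cat + 1] + lp)
  pmax(lo - hi, 1e-300)
}

# 1-based position of each tensor row along dimension d
tensor_col <- function(npts_total, n, d) {
  ((seq_len(npts_total) - 1L) %/% n^(d - 1L)) %% n + 1L
}

#' Conditional log-likelihood of one subject's responses
#'
#' Log-likelihood of a subject's observed responses given fixed values of all
#' latent variables (item responses are conditionally independent given the
#' latents).
#'
#' @param y responses for one subject: vector of length `K * T`
#'   (occasion-major in bank item order, 0-based categories, `NA` missing).
#' @param spec,bank,params model pieces as in [marginal_loglik()].
#' @param theta values of the general (structural) factors.
#' @param xi values of the specific factors (one per group: items, or
#'   occasions for the growth spec).
#' @param theta_site site factor value (default 0).
#' @return scalar log-likelihood; 0 when all responses are missing.
#' @export
conditional_loglik <- function(y, spec, bank, params = default_start(spec, bank),
                               theta, xi, theta_site = 0) {
  rs <- spec_rows(spec, bank)
  G <- n_general(spec)
  if (length(theta) != G) stop("'theta' must have length ", G, call. = FALSE)
  if (length(xi) != rs$n_groups)
    stop("'xi' must have length ", rs$n_groups, call. = FALSE)
  sload <- if (spec$specific_free) params$s[rs$rows$item] else rs$rows$sload
  sl <- if (!is.null(spec$site)) spec$site$loadings else rep(0, spec$T)
  ll <- 0
  for (r in seq_len(nrow(rs$rows))) {
    if (r > length(y) || is.na(y[r])) next
    t <- rs$rows$occ[r]
    eta <- sum(spec$A[t, ] * theta) + sl[t] * theta_site
    lp <- rs$rows$a[r] * eta + sload[r] * xi[rs$rows$group[r]]
    ll <- ll + log(grm_prob(lp, rs$intercepts[r, ], rs$rows$ncat[r], y[r]))
  }
  as.numeric(ll)
}

#' Posterior moments of the structural latent variables
#'
#' Quadrature-weighted posterior means and covariances of the structural
#' (general) factors for every subject given their observed responses and
#' covariates, plus the posterior mean/variance of the site factor per
#' cluster when the spec has one. Subjects with no observed responses get
#' their prior moments back.
#'
#' @inheritParams marginal_loglik
#' @return list with `mean` (subjects x G), `cov` (G x G x subjects array),
#'   and optionally `site` (data.frame per cluster).
#' @export
posterior_moments <- function(data, spec, bank,
                              params = default_start(spec, bank),
                              control = proirt_control()) {
  eng <- make_engine(data, spec, bank, control)
  es <- engine_estep(eng, params, want_post = TRUE,
                     want_cluster_post = eng$Gc > 0)
  G <- n_general(spec)
  n <- eng$n_subjects
  if (eng$struct_level == "unit") {
    ord <- order(eng$subj_of_unit)
    Em <- es$Em[ord, , drop = FALSE]; E2 <- es$E2[ord, , drop = FALSE]
  } else {
    # clusters are subjects, contiguous in original subject order
    Em <- es$Em; E2 <- es$E2
  }
  covs <- array(0, c(G, G, n))
  for (j in seq_len(n))
    covs[, , j] <- matrix(E2[j, ], G, G) - tcrossprod(Em[j, ])
  out <- list(mean = `colnames<-`(Em, spec$gen_names), cov = covs)
  if (eng$site)
    out$site <- data.frame(mean = es$site_Em, var = es$site_E2 - es$site_Em^2)
  out
}
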
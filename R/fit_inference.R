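#' Information criteria from a deviance
#'
#' `AIC = -2LL + 2k` and `BIC = -2LL + k log(N)`, with `N` the number of
#' unique subjects (a subject missing at baseline but observed later still
#' counts once).
#'
#' @param minus2LL deviance (-2 log-likelihood).
#' @param n_free number of free parameters.
#' @param n_cases number of unique subjects.
#' @return named vector with `AIC` and `BIC`.
#' @export
information_criteria <- function(minus2LL, n_free, n_cases) {
  stopifnot(n_free >= 0, n_cases >= 1)
  c(AIC = minus2LL + 2 * n_free, BIC = minus2LL + n_free * log(n_cases))
}

#' Wald test of a linear hypothesis
#'
#' `W = (L v - h)' (L V L')^{-1} (L v - h)` compared to a chi-square with
#' `rank(L)` degrees of freedom. When `L V L'` is singular a generalized
#' inverse is used and the degrees of freedom are reduced to the rank of
#' `L V L'`, with a warning.
#'
#' @param estimates coefficient vector (or a `proirt_fit`).
#' @param vcov error covariance of the estimates (taken from the fit when
#'   `estimates` is a fit).
#' @param L contrast matrix (rows = constraints); a vector is treated as one
#'   row. Columns may be named to select coefficients.
#' @param h hypothesized values (default zeros).
#' @return object of class `wald_test` with `W`, `df`, `p_value`, `L`, `h`.
#' @export
wald_test <- function(estimates, vcov = NULL, L, h = NULL) {
  if (inherits(estimates, "proirt_fit")) {
    vcov <- vcov %||% estimates$vcov
    estimates <- estimates$estimate
  }
  if (is.null(vcov)) stop("no covariance matrix available", call. = FALSE)
  if (is.vector(L)) L <- matrix(L, nrow = 1)
  if (!is.null(colnames(L))) {
    full <- matrix(0, nrow(L), length(estimates),
                   dimnames = list(NULL, names(estimates)))
    full[, colnames(L)] <- L
    L <- full
  }
  if (ncol(L) != length(estimates))
    stop("contrast matrix has ", ncol(L), " columns; expected ",
         length(estimates), call. = FALSE)
  h <- h %||% rep(0, nrow(L))
  delta <- drop(L %*% estimates) - h
  V <- L %*% vcov %*% t(L)
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  tolv <- max(ev$values) * 1e-10
  rank <- sum(ev$values > tolv)
  if (rank < nrow(L))
    warning("L V L' is singular; using a generalized inverse with df = ", rank)
  Vi <- ev$vectors[, seq_len(rank), drop = FALSE] %*%
    diag(1 / ev$values[seq_len(rank)], rank) %*%
    t(ev$vectors[, seq_len(rank), drop = FALSE])
  W <- max(drop(t(delta) %*% Vi %*% delta), 0)
  structure(list(W = W, df = rank, p_value = stats::pchisq(W, rank,
                                                           lower.tail = FALSE),
                 L = L, h = h),
            class = "wald_test")
}

#' @export
print.wald_test <- function(x, ...) {
  cat(sprintf("Wald chi-square test: W = %.4f, df = %d, p = %.4g\n",
              x$W, x$df, x$p_value))
  invisible(x)
}

#' Standardize a covariance matrix to correlations
#'
#' Thin validated wrapper around [stats::cov2cor()] used when reporting
#' latent covariance blocks as correlations.
#'
#' @param V positive-definite covariance matrix.
#' @return correlation matrix.
#' @export
cov_to_corr <- function(V) {
  V <- as.matrix(V)
  if (any(diag(V) <= 0))
    stop("covariance matrix has non-positive diagonal entries", call. = FALSE)
  stats::cov2cor(V)
}

#' Intraclass correlation from variance components
#'
#' Between-cluster variance over total variance.
#'
#' @param site_var between-site variance.
#' @param within_var within-site (subject-level) variance.
#' @return scalar ICC.
#' @export
icc <- function(site_var, within_var) {
  stopifnot(site_var >= 0, within_var >= 0)
  if (site_var + within_var <= 0)
    stop("total variance must be positive", call. = FALSE)
  site_var / (site_var + within_var)
}

## ---- limited-information fit: M2 and RMSEA ----------------------------------

#' Limited-information model fit: M2 statistic and RMSEA
#'
#' Computes the M2 statistic from first- and second-order marginal residuals:
#' observed minus model-implied probabilities of univariate category events
#' and bivariate category pairs across all item-by-occasion variables, with
#' the standard reduced weight matrix
#' `C2 = Xi^-1 - Xi^-1 D (D' Xi^-1 D)^-1 D' Xi^-1` (`Xi` the model-implied
#' covariance of the margin indicators, `D` the Jacobian of the margins in
#' the free parameters). `df = n_margins - n_free`;
#' `RMSEA = sqrt(max(M2 - df, 0) / (df * n))`.
#'
#' Margins are computed over complete cases. The model-implied `Xi` needs
#' joint probabilities of up to four variables, so cost grows with the square
#' of the number of margins; `max_margins` guards against infeasible
#' requests. Applies to single-level unconditional models (no site factor, no
#' latent regression).
#'
#' @param fit a `proirt_fit`, or supply `data`, `spec`, `bank`, `params`.
#' @param data,spec,bank,params used when `fit` is missing.
#' @param control quadrature settings for the margin integrals.
#' @param max_margins safety cap on the number of first- plus second-order
#'   margins.
#' @return object of class `m2_fit`: `M2`, `df`, `p_value`, `RMSEA`,
#'   `n_margins`, `n` (complete cases).
#' @export
m2_rmsea <- function(fit = NULL, data = fit$data, spec = fit$spec,
                     bank = fit$bank, params = fit$params,
                     control = proirt_control(), max_margins = 1200) {
  stopifnot(inherits(spec, "proirt_spec"))
  if (!is.null(spec$site) || length(spec$regression))
    stop("M2 applies to single-level unconditional models", call. = FALSE)
  if (spec$level != "single")
    stop("use the single-level parameterization for M2", call. = FALSE)
  eng <- make_engine(data, spec, bank, control)
  rs <- eng$rows
  R <- nrow(rs$rows)
  ncat <- rs$rows$ncat
  # margin bookkeeping: univariate then bivariate
  margins <- list()
  for (r in seq_len(R)) for (cc in seq_len(ncat[r] - 1L))
    margins[[length(margins) + 1L]] <- list(rows = r, cats = cc)
  for (r1 in seq_len(R - 1L)) for (r2 in (r1 + 1L):R)
    for (c1 in seq_len(ncat[r1] - 1L)) for (c2 in seq_len(ncat[r2] - 1L))
      margins[[length(margins) + 1L]] <- list(rows = c(r1, r2),
                                              cats = c(c1, c2))
  m <- length(margins)
  nfree <- n_free_params(spec, eng$K)
  if (m > max_margins)
    stop("M2 would use ", m, " margins (cap ", max_margins, "); reduce the ",
         "number of items/occasions or raise 'max_margins'", call. = FALSE)
  if (m <= nfree) stop("degrees of freedom would be non-positive", call. = FALSE)

  # observed margins over complete cases (bank row order)
  perm <- match(bank_ids(bank), data$item_ids)
  colmap <- as.vector(vapply(seq_len(eng$T), function(t)
    (t - 1L) * data$K + perm, integer(eng$K)))
  Y <- data$Y[, colmap, drop = FALSE]
  cc_rows <- stats::complete.cases(Y)
  n <- sum(cc_rows)
  if (n < 10) stop("too few complete cases for M2", call. = FALSE)
  Yc <- Y[cc_rows, , drop = FALSE]
  ehat <- vapply(margins, function(mg) {
    ok <- rep(TRUE, n)
    for (i in seq_along(mg$rows)) ok <- ok & (Yc[, mg$rows[i]] == mg$cats[i])
    mean(ok)
  }, numeric(1))

  model_margins <- function(params) {
    pr <- margin_prob_machinery(eng, params)
    vapply(margins, function(mg) pr$joint(mg$rows, mg$cats), numeric(1))
  }
  pim <- model_margins(params)

  # model-implied covariance of the margin indicators
  pr <- margin_prob_machinery(eng, params)
  Xi <- matrix(0, m, m)
  for (a in seq_len(m)) {
    mga <- margins[[a]]
    for (b in a:m) {
      mgb <- margins[[b]]
      rows <- c(mga$rows, mgb$rows)
      cats <- c(mga$cats, mgb$cats)
      shared <- intersect(mga$rows, mgb$rows)
      conflict <- FALSE
      if (length(shared)) {
        for (r in shared)
          if (mga$cats[match(r, mga$rows)] != mgb$cats[match(r, mgb$rows)])
            conflict <- TRUE
        keep <- !duplicated(rows)
        rows <- rows[keep]; cats <- cats[keep]
      }
      pab <- if (conflict) 0 else pr$joint(rows, cats)
      Xi[a, b] <- Xi[b, a] <- pab - pim[a] * pim[b]
    }
  }

  # Jacobian of the margins in the free parameters (central differences)
  v0 <- pack_params(params, spec, bank)
  Dm <- matrix(0, m, length(v0))
  for (j in seq_along(v0)) {
    h <- 1e-4 * (1 + abs(v0[j]))
    vp <- v0; vp[j] <- vp[j] + h
    vm <- v0; vm[j] <- vm[j] - h
    Dm[, j] <- (model_margins(unpack_params(vp, spec, bank)) -
                  model_margins(unpack_params(vm, spec, bank))) / (2 * h)
  }

  XiI <- solve(Xi + diag(1e-12, m))
  A <- t(Dm) %*% XiI %*% Dm
  C2 <- XiI - XiI %*% Dm %*% solve(A, t(Dm) %*% XiI)
  e <- ehat - pim
  M2 <- max(n * drop(t(e) %*% C2 %*% e), 0)
  df <- m - length(v0)
  rmsea <- sqrt(max(M2 - df, 0) / (df * n))
  structure(list(M2 = M2, df = df,
                 p_value = stats::pchisq(M2, df, lower.tail = FALSE),
                 RMSEA = rmsea, n_margins = m, n = n),
            class = "m2_fit")
}

#' @export
print.m2_fit <- function(x, ...) {
  cat(sprintf("M2 = %.3f on %d df (p = %.3g), RMSEA = %.4f  [%d margins, n = %d]\n",
              x$M2, x$df, x$p_value, x$RMSEA, x$n_margins, x$n))
  invisible(x)
}

# model-implied joint probabilities of small sets of item-by-occasion rows,
# integrating general factors on the standardized grid and each specific
# factor inside its group; singleton and pair lookups are cached per call
margin_prob_machinery <- function(eng, params) {
  spec <- eng$spec
  gr <- engine_grids(eng, params)
  Ng <- eng$Ng
  Q <- length(eng$xq)
  # occasion composites including the (single) offset pattern
  comp <- vapply(seq_len(eng$T), function(t)
    gr$w_vals[[t]][gr$w_idx[[t]][1, ] + 1L], numeric(Ng))   # Ng x T
  w <- gr$pw_unit[1, ]
  sload <- row_sload(eng, params)
  rs <- eng$rows
  # per-row category curves given the specific node: list of Ng x Q x C
  pfull <- lapply(seq_len(nrow(rs$rows)), function(r) {
    lp <- outer(rs$rows$a[r] * comp[, rs$rows$occ[r]], sload[r] * eng$xq, "+")
    vapply(0:(rs$rows$ncat[r] - 1L), function(cc)
      grm_prob(lp, rs$intercepts[r, ], rs$rows$ncat[r], cc),
      matrix(0, Ng, Q))
  })
  # xi-marginalized singleton curves: Ng x C per row
  pbar <- lapply(pfull, function(P)
    apply(P, 3, function(M) drop(M %*% eng$wq)))
  cache <- new.env(parent = emptyenv())
  group_vec <- function(sel, cats) {
    # joint curve over the grid for rows `sel` (same group) at categories cats
    if (length(sel) == 1L) return(pbar[[sel]][, cats + 1L])
    key <- paste(c(sel, cats), collapse = ".")
    if (!is.null(cache[[key]])) return(cache[[key]])
    M <- pfull[[sel[1]]][, , cats[1] + 1L]
    for (i in 2:length(sel)) M <- M * pfull[[sel[i]]][, , cats[i] + 1L]
    out <- drop(M %*% eng$wq)
    cache[[key]] <- out
    out
  }
  joint <- function(rows, cats) {
    val <- w
    for (g in unique(rs$rows$group[rows])) {
      pick <- rs$rows$group[rows] == g
      val <- val * group_vec(rows[pick], cats[pick])
    }
    sum(val)
  }
  list(joint = joint)
}
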
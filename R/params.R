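#' Structural parameter sets
#'
#' A `proirt_params` object holds the free structural parameters of a model
#' spec in named views: latent means (or reference-cell intercepts when a
#' regression is attached), the general-factor covariance matrix, latent
#' regression coefficients, free specific slopes, and the site variance.
#' `pack_params()` / `unpack_params()` map to and from the flat named vector
#' used by the optimizers and standard-error machinery; the mapping is an
#' exact round trip.
#'
#' @param spec a `proirt_spec`.
#' @param bank an [item_bank()].
#' @return `default_start()` returns neutral starting values: means 0,
#'   variances 1, covariances 0, regression coefficients 0, specific slopes
#'   at their bank initialization, site variance 1.
#' @name proirt_params
NULL

#' @rdname proirt_params
#' @export
default_start <- function(spec, bank) {
  G <- n_general(spec)
  covs <- spec_covariates(spec)
  p <- list(
    mu = stats::setNames(rep(0, G), spec$gen_names),
    Sigma = diag(G),
    B = matrix(0, G, length(covs),
               dimnames = list(spec$gen_names, covs)),
    s = if (spec$specific_free) bank_s(bank) else NULL,
    site_var = if (!is.null(spec$site)) 1 else NULL,
    site_beta = if (!is.null(spec$site) && length(spec$site_regression))
      stats::setNames(rep(0, length(spec$site_regression)),
                      spec$site_regression) else NULL
  )
  dimnames(p$Sigma) <- list(spec$gen_names, spec$gen_names)
  if (!is.null(p$s)) names(p$s) <- bank_ids(bank)
  class(p) <- "proirt_params"
  p
}

# lower-triangle (vech) index pairs in column-major order
vech_pairs <- function(G) {
  idx <- which(lower.tri(diag(G), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

#' @rdname proirt_params
#' @export
param_names <- function(spec, bank = NULL) {
  G <- n_general(spec)
  nm <- paste0("mean.", spec$gen_names)
  if (spec$cov_struct == "full") {
    vp <- vech_pairs(G)
    nm <- c(nm, apply(vp, 1, function(ij) {
      if (ij[1] == ij[2]) paste0("var.", spec$gen_names[ij[1]])
      else paste0("cov.", spec$gen_names[ij[2]], ".", spec$gen_names[ij[1]])
    }))
  } else {
    nm <- c(nm, paste0("var.", spec$gen_names))
  }
  for (g in names(spec$regression))
    nm <- c(nm, paste0("beta.", g, ".", spec$regression[[g]]))
  if (spec$specific_free) {
    ids <- if (!is.null(bank)) bank_ids(bank) else paste0("item", seq_len(spec$K))
    nm <- c(nm, paste0("s.", ids))
  }
  if (!is.null(spec$site)) {
    nm <- c(nm, "var.site")
    if (length(spec$site_regression))
      nm <- c(nm, paste0("beta.site.", spec$site_regression))
  }
  nm
}

#' @rdname proirt_params
#' @param params a `proirt_params` object.
#' @export
pack_params <- function(params, spec, bank = NULL) {
  G <- n_general(spec)
  v <- unname(params$mu)
  if (spec$cov_struct == "full") {
    vp <- vech_pairs(G)
    v <- c(v, params$Sigma[vp])
  } else {
    v <- c(v, diag(params$Sigma))
  }
  for (g in names(spec$regression))
    v <- c(v, params$B[g, spec$regression[[g]]])
  if (spec$specific_free) v <- c(v, unname(params$s))
  if (!is.null(spec$site)) {
    v <- c(v, params$site_var)
    if (length(spec$site_regression)) v <- c(v, unname(params$site_beta))
  }
  stats::setNames(v, param_names(spec, bank))
}

#' @rdname proirt_params
#' @param v flat named parameter vector as produced by `pack_params()`.
#' @export
unpack_params <- function(v, spec, bank) {
  G <- n_general(spec)
  p <- default_start(spec, bank)
  i <- 0L
  take <- function(n) {
    out <- v[i + seq_len(n)]; i <<- i + n; out
  }
  p$mu[] <- take(G)
  if (spec$cov_struct == "full") {
    vp <- vech_pairs(G)
    vals <- take(nrow(vp))
    S <- matrix(0, G, G)
    S[vp] <- vals
    S[vp[, c(2, 1), drop = FALSE]] <- vals
    p$Sigma[] <- S
  } else {
    p$Sigma[] <- diag(take(G), G)
  }
  for (g in names(spec$regression))
    p$B[g, spec$regression[[g]]] <- take(length(spec$regression[[g]]))
  if (spec$specific_free) p$s[] <- take(spec$K %||% length(bank$items))
  if (!is.null(spec$site)) {
    p$site_var <- unname(take(1L))
    if (length(spec$site_regression)) p$site_beta[] <- take(length(spec$site_regression))
  }
  if (i != length(v))
    stop("parameter vector has length ", length(v), ", expected ", i,
         call. = FALSE)
  p
}

#' @export
print.proirt_params <- function(x, ...) {
  cat("proirt parameter set\n")
  cat("  means:", paste(sprintf("%s=%.3f", names(x$mu), x$mu), collapse = ", "), "\n")
  cat("  covariance:\n")
  print(round(x$Sigma, 4))
  if (!is.null(x$B) && ncol(x$B)) { cat("  regression coefficients:\n"); print(round(x$B, 4)) }
  if (!is.null(x$s))
    cat("  specific slopes:", paste(sprintf("%.3f", x$s), collapse = ", "), "\n")
  if (!is.null(x$site_var)) cat("  site variance:", round(x$site_var, 4), "\n")
  invisible(x)
}
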
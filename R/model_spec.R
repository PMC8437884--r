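#' Latent structural model specifications
#'
#' Constructors for the three longitudinal latent structures supported by the
#' package. All three share the same measurement model: item-by-occasion
#' responses follow the graded model with banked slopes/intercepts, and the
#' occasion composite `eta_t` is a linear combination of structural latent
#' factors given by an occasion-composition matrix.
#'
#' * `growth_spec()` - latent growth curve: `eta_t = theta_0 + x(t) theta_1 +
#'   eps_t` with free means, variances and covariance for Intercept and Slope
#'   and occasion-specific residual factors fixed at N(0, 1). With
#'   `level = "block"` the same model is reparameterized as a multilevel
#'   model: Intercept and Slope become level-2 (subject-level) factors and a
#'   single level-1 residual factor absorbs the occasion residuals; the two
#'   parameterizations have identical free parameters and likelihood.
#' * `two_tier_spec()` - one general factor per occasion with free means and
#'   a free unstructured covariance matrix, plus one specific factor per item
#'   (loading `s_k`, constrained equal over occasions) capturing residual
#'   dependence of repeated administrations.
#' * `latent_difference_spec()` - cumulative loading pattern so that factor
#'   `t >= 2` is the latent change from occasion `t - 1` to `t`; difference
#'   factors are uncorrelated (diagonal covariance) with free means and
#'   variances; specific item factors as in the two-tier model.
#'
#' @param T number of occasions (>= 2 except where noted).
#' @param time_codes numeric basis for the growth slope, default `0:(T-1)`.
#' @param K number of items administered at each occasion.
#' @param level `"single"` (wide, one row per subject) or `"block"`
#'   (multilevel reparameterization, subjects as level-2 clusters).
#' @return An object of class `proirt_spec`.
#' @name model_specs
NULL

new_spec <- function(parameterization, K, T, time_codes = NULL,
                     A, gen_names, cov_struct, specific, specific_free,
                     level = "single") {
  structure(list(
    parameterization = parameterization,
    K = K, T = T, time_codes = time_codes,
    A = A, gen_names = gen_names,
    cov_struct = cov_struct,
    specific = specific, specific_free = specific_free,
    level = level,
    site = NULL, regression = list(), site_regression = NULL
  ), class = "proirt_spec")
}

#' @rdname model_specs
#' @export
growth_spec <- function(T, time_codes = seq_len(T) - 1, level = "single") {
  if (T < 2) stop("a growth model needs at least 2 occasions", call. = FALSE)
  if (length(time_codes) != T) stop("'time_codes' must have length T", call. = FALSE)
  level <- match.arg(level, c("single", "block"))
  A <- cbind(Intercept = rep(1, T), Slope = as.numeric(time_codes))
  new_spec("growth", K = NULL, T = T, time_codes = as.numeric(time_codes),
           A = A, gen_names = c("Intercept", "Slope"),
           cov_struct = "full", specific = "occasion", specific_free = FALSE,
           level = level)
}

#' @rdname model_specs
#' @export
two_tier_spec <- function(K, T) {
  if (K < 1 || T < 1) stop("need K >= 1 items and T >= 1 occasions", call. = FALSE)
  A <- diag(T)
  nm <- occasion_names(T)
  dimnames(A) <- list(NULL, nm)
  new_spec("two_tier", K = as.integer(K), T = as.integer(T),
           A = A, gen_names = nm,
           cov_struct = "full", specific = "item", specific_free = TRUE)
}

#' @rdname model_specs
#' @export
latent_difference_spec <- function(K, T) {
  if (K < 1 || T < 1) stop("need K >= 1 items and T >= 1 occasions", call. = FALSE)
  A <- matrix(0, T, T)
  A[lower.tri(A, diag = TRUE)] <- 1  # occasion t composes differences 1..t
  nm <- occasion_names(T)
  colnames(A) <- nm
  new_spec("latent_difference", K = as.integer(K), T = as.integer(T),
           A = A, gen_names = nm,
           cov_struct = "diagonal", specific = "item", specific_free = TRUE)
}

occasion_names <- function(T) {
  if (T == 1) return("Baseline")
  c("Baseline", paste0("Follow-up ", seq_len(T - 1)))
}

#' Add a site-level random intercept
#'
#' Adds a single level-2 factor with mean zero and a free variance, loaded by
#' every occasion composite (or by the supplied 0/1 pattern). Under the
#' cumulative latent-difference pattern, unit loadings are equivalent to a
#' site-level shift of the baseline factor.
#'
#' @param spec a `proirt_spec`.
#' @param loadings numeric vector of length `T` (typically 0/1) giving the
#'   loading of each occasion composite on the site factor.
#' @return the modified spec.
#' @export
add_site_level <- function(spec, loadings = rep(1, spec$T)) {
  stopifnot(inherits(spec, "proirt_spec"))
  if (!is.null(spec$site))
    stop("spec already has a site-level factor", call. = FALSE)
  if (spec$level == "block")
    stop("site factors are not supported in the block (multilevel growth) ",
         "parameterization; use level = \"single\"", call. = FALSE)
  if (length(loadings) != spec$T)
    stop("'loadings' must have length T = ", spec$T, call. = FALSE)
  spec$site <- list(loadings = as.numeric(loadings))
  spec
}

#' Regress latent factors on covariates
#'
#' Turns the mean of a structural factor into a reference-cell intercept and
#' adds one free regression coefficient per covariate. Covariates are looked
#' up by name in the trial data at fit time. Use `factor = "site"` to regress
#' the site random intercept on site-level covariates.
#'
#' @param spec a `proirt_spec`.
#' @param factor general factor name (e.g. `"Follow-up 1"`), factor index, or
#'   `"site"`.
#' @param covariates character vector of covariate names.
#' @return the modified spec.
#' @export
attach_regression <- function(spec, factor, covariates) {
  stopifnot(inherits(spec, "proirt_spec"), is.character(covariates),
            length(covariates) >= 1L)
  if (identical(factor, "site")) {
    if (is.null(spec$site)) stop("add a site level first", call. = FALSE)
    spec$site_regression <- union(spec$site_regression %||% character(), covariates)
    return(spec)
  }
  if (is.numeric(factor)) factor <- spec$gen_names[factor]
  if (!factor %in% spec$gen_names)
    stop("unknown factor '", factor, "'; available: ",
         paste(spec$gen_names, collapse = ", "), call. = FALSE)
  old <- spec$regression[[factor]] %||% character()
  spec$regression[[factor]] <- union(old, covariates)
  spec
}

## ---- derived structure -----------------------------------------------------

# Number of general (structural) factors
n_general <- function(spec) ncol(spec$A)

# All covariate names used anywhere in the spec, in stable order
spec_covariates <- function(spec) {
  unique(unlist(spec$regression, use.names = FALSE))
}

# Free-pattern matrix for [mu | B]: G x (1 + n_cov); col 1 = intercept/mean
regression_pattern <- function(spec) {
  covs <- spec_covariates(spec)
  G <- n_general(spec)
  F <- matrix(FALSE, G, 1L + length(covs),
              dimnames = list(spec$gen_names, c("(mean)", covs)))
  F[, 1L] <- TRUE
  for (g in names(spec$regression))
    F[g, spec$regression[[g]]] <- TRUE
  F
}

#' Number of free parameters of a specification
#'
#' Counts latent means, free covariance elements, regression coefficients,
#' free specific slopes, and the site variance.
#'
#' @param spec a `proirt_spec`.
#' @param K number of items; taken from the spec when it carries one.
#' @return integer count.
#' @export
n_free_params <- function(spec, K = spec$K) {
  G <- n_general(spec)
  n <- G                                             # means / intercepts
  n <- n + switch(spec$cov_struct, full = G * (G + 1L) / 2L, diagonal = G)
  n <- n + sum(lengths(spec$regression))
  if (spec$specific_free) {
    if (is.null(K)) stop("K (number of items) required", call. = FALSE)
    n <- n + K
  }
  if (!is.null(spec$site)) n <- n + 1L + length(spec$site_regression %||% character())
  as.integer(n)
}

#' Joint integration dimension after two-tier dimension reduction
#'
#' The maximum dimension of any joint numerical integral the likelihood
#' engine performs: all general factors at the structural level jointly, plus
#' one dimension for the specific factors (integrated one at a time,
#' conditionally on the generals), plus the site factor when present. For the
#' longitudinal two-tier model with 3 occasion factors and 8 item factors
#' this is 4 rather than 11.
#'
#' @param spec a `proirt_spec`.
#' @return integer dimension.
#' @export
integration_dimension <- function(spec) {
  G <- n_general(spec)
  d <- G + 1L                       # generals jointly + specifics one at a time
  if (!is.null(spec$site)) d <- d + 1L
  as.integer(d)
}

#' Full factor loading pattern of a specification
#'
#' Expands the spec against an item bank into the (items x occasions) by
#' (general + specific factors) loading matrix, with banked general loadings
#' and the current specific slopes. Mainly for inspection and testing.
#'
#' @param spec a `proirt_spec`.
#' @param bank an [item_bank()].
#' @return numeric matrix with row names `t{t}_{item_id}`.
#' @export
loading_pattern <- function(spec, bank) {
  rs <- spec_rows(spec, bank)
  G <- n_general(spec)
  nG <- rs$n_groups
  L <- matrix(0, nrow(rs$rows), G + nG)
  rn <- character(nrow(rs$rows))
  for (r in seq_len(nrow(rs$rows))) {
    t <- rs$rows$occ[r]; k <- rs$rows$item[r]
    L[r, seq_len(G)] <- rs$rows$a[r] * spec$A[t, ]
    L[r, G + rs$rows$group[r]] <- rs$rows$sload[r]
    rn[r] <- paste0("t", t, "_", rs$rows$id[r])
  }
  gcols <- if (rs$n_groups == spec$T && spec$specific == "occasion")
    paste0("occ", seq_len(nG), "_resid") else paste0("spec_", bank_ids(bank))
  dimnames(L) <- list(rn, c(spec$gen_names, gcols))
  L
}

# Row-level expansion of a spec against a bank. Rows ordered occasion-major:
# t1_item1 .. t1_itemK, t2_item1, ...
# Returns: rows data.frame(item, occ, id, a, ncat, group, sload, sfree),
#          intercepts matrix (row x maxc), n_groups.
spec_rows <- function(spec, bank) {
  K <- length(bank$items)
  if (!is.null(spec$K) && spec$K != K)
    stop("spec expects K = ", spec$K, " items but bank has ", K, call. = FALSE)
  T <- spec$T
  item <- rep(seq_len(K), times = T)
  occ <- rep(seq_len(T), each = K)
  a <- bank_slopes(bank)[item]
  ncat <- bank_ncat(bank)[item]
  if (spec$specific == "item") {
    group <- item
    sload <- bank_s(bank)[item]       # starting values; free during fitting
    sfree <- rep(spec$specific_free, K * T)
  } else {
    group <- occ
    sload <- a                        # residual factor entered through eta
    sfree <- rep(FALSE, K * T)
  }
  list(rows = data.frame(item = item, occ = occ,
                         id = bank_ids(bank)[item],
                         a = a, ncat = ncat, group = group,
                         sload = sload, sfree = sfree,
                         stringsAsFactors = FALSE),
       intercepts = bank_intercepts(bank)[item, , drop = FALSE],
       n_groups = if (spec$specific == "item") K else T)
}

#' @export
print.proirt_spec <- function(x, ...) {
  cat("proirt model specification:", x$parameterization,
      if (x$level == "block") "(multilevel/block parameterization)", "\n")
  cat("  occasions:", x$T,
      if (!is.null(x$time_codes)) paste0("(time codes ",
                                         paste(x$time_codes, collapse = ", "), ")"),
      "\n")
  cat("  general factors:", paste(x$gen_names, collapse = ", "),
      sprintf("[%s covariance]", x$cov_struct), "\n")
  cat("  specific factors:",
      if (x$specific == "item") "one per item (free slopes, equal over occasions)"
      else "one per occasion (fixed N(0,1) residuals)", "\n")
  if (!is.null(x$site))
    cat("  site factor: loadings (", paste(x$site$loadings, collapse = ", "),
        "), free variance\n")
  for (g in names(x$regression))
    cat("  regression:", g, "~", paste(x$regression[[g]], collapse = " + "), "\n")
  if (!is.null(x$site_regression))
    cat("  site regression: ~", paste(x$site_regression, collapse = " + "), "\n")
  cat("  integration dimension after reduction:", integration_dimension(x), "\n")
  invisible(x)
}
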
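#' EAP scores from response patterns
#'
#' Expected a posteriori scores for a single administration of the bank's
#' items under the plain unidimensional graded model (the item-specific
#' residual-dependence factors belong to the longitudinal measurement model
#' and are excluded from scoring, matching how calibrated banks are scored at
#' a single visit).
#'
#' @param responses integer vector (one pattern) or matrix (patterns x items)
#'   of 0-based categories; `NA` for missing.
#' @param bank an [item_bank()].
#' @param prior_mean,prior_sd prior on theta (standard normal by default).
#' @param quadpts,qrange scoring quadrature (finer than fitting: 1-D is cheap).
#' @return data.frame with `theta` (EAP), `sd` (posterior SD), `t_score`,
#'   and `all_missing`.
#' @export
eap_score <- function(responses, bank, prior_mean = 0, prior_sd = 1,
                      quadpts = 49, qrange = c(-6, 6)) {
  stopifnot(inherits(bank, "item_bank"))
  if (is.vector(responses)) responses <- matrix(responses, nrow = 1)
  K <- length(bank$items)
  if (ncol(responses) != K)
    stop("'responses' must have one column per bank item (", K, ")",
         call. = FALSE)
  nodes <- prior_mean + prior_sd * seq(qrange[1], qrange[2], length.out = quadpts)
  w <- stats::dnorm(nodes, prior_mean, prior_sd)
  w <- w / sum(w)
  # per-item category probability curves
  P <- lapply(seq_len(K), function(k) {
    it <- bank$items[[k]]
    vapply(0:(it$n_categories - 1L), function(cc)
      category_prob(it, nodes, 0, cc), numeric(quadpts))
  })
  n <- nrow(responses)
  theta <- sdv <- numeric(n)
  allmiss <- logical(n)
  for (i in seq_len(n)) {
    lik <- rep(1, quadpts)
    obs <- FALSE
    for (k in seq_len(K)) {
      y <- responses[i, k]
      if (is.na(y)) next
      if (y < 0 || y >= bank$items[[k]]$n_categories)
        stop("response out of range for item ", bank_ids(bank)[k], call. = FALSE)
      lik <- lik * P[[k]][, y + 1L]
      obs <- TRUE
    }
    post <- w * lik
    post <- post / sum(post)
    theta[i] <- sum(post * nodes)
    sdv[i] <- sqrt(max(sum(post * nodes^2) - theta[i]^2, 0))
    allmiss[i] <- !obs
  }
  data.frame(theta = theta, sd = sdv,
             t_score = round(t_score(theta, bank), 1),
             all_missing = allmiss)
}

#' Summed-score to EAP conversion table
#'
#' Builds the model-implied distribution of the summed score given theta by
#' the Lord-Wingersky recursion (one item at a time over the quadrature
#' grid), then reports the posterior EAP, posterior SD and T-score for every
#' attainable summed score. Requires complete response patterns, which is the
#' standard proviso for summed-score scoring.
#'
#' @inheritParams eap_score
#' @param category_base summed scores are reported on this category coding
#'   (banked instruments conventionally code categories from 1, so an 8-item
#'   5-category form spans 8 to 40).
#' @return data.frame of class `conversion_table` with columns
#'   `sum`, `theta`, `sd`, `t_score`.
#' @export
summed_score_table <- function(bank, prior_mean = 0, prior_sd = 1,
                               quadpts = 49, qrange = c(-6, 6),
                               category_base = 1L) {
  stopifnot(inherits(bank, "item_bank"))
  nodes <- prior_mean + prior_sd * seq(qrange[1], qrange[2], length.out = quadpts)
  w <- stats::dnorm(nodes, prior_mean, prior_sd)
  w <- w / sum(w)
  # Lord-Wingersky: L[s+1, ] = P(sum = s | theta), built item by item
  L <- matrix(0, 1, quadpts)
  L[1, ] <- 1
  for (it in bank$items) {
    C <- it$n_categories
    newL <- matrix(0, nrow(L) + C - 1L, quadpts)
    for (cc in 0:(C - 1L)) {
      p <- category_prob(it, nodes, 0, cc)
      newL[cc + seq_len(nrow(L)), ] <-
        newL[cc + seq_len(nrow(L)), , drop = FALSE] +
        L * matrix(p, nrow(L), quadpts, byrow = TRUE)
    }
    L <- newL
  }
  sums <- seq_len(nrow(L)) - 1L
  theta <- sdv <- numeric(nrow(L))
  for (s in seq_along(sums)) {
    post <- w * L[s, ]
    post <- post / sum(post)
    theta[s] <- sum(post * nodes)
    sdv[s] <- sqrt(max(sum(post * nodes^2) - theta[s]^2, 0))
  }
  out <- data.frame(sum = sums + length(bank$items) * category_base,
                    theta = theta, sd = sdv,
                    t_score = round(t_score(theta, bank), 1))
  class(out) <- c("conversion_table", "data.frame")
  out
}

#' @export
print.conversion_table <- function(x, ...) {
  cat("Summed-score to EAP conversion table (", nrow(x), "rows )\n")
  print.data.frame(x, row.names = FALSE, digits = 4, ...)
  invisible(x)
}

#' Transform theta to the bank's reporting T metric
#'
#' `T = mean_T + sd_T * theta`, i.e. `50 + 10 * theta` on the conventional
#' metric for calibrated patient-reported-outcome banks.
#'
#' @param theta latent score(s).
#' @param bank optional [item_bank()] supplying the metric (default 50/10).
#' @return numeric T-score(s), full precision (round for reporting).
#' @export
t_score <- function(theta, bank = NULL) {
  m <- if (is.null(bank)) 50 else bank$mean_T
  s <- if (is.null(bank)) 10 else bank$sd_T
  m + s * theta
}

#' Write a conversion table as delimited text
#'
#' @param table a [summed_score_table()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_conversion_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
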
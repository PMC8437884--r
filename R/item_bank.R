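#' Calibrated graded-response item
#'
#' Constructs a single item of the logistic graded response model with
#' parameters taken from a calibrated item bank. The banked slope and
#' category intercepts are treated as fixed during all model fitting; the
#' only item-level free parameter is the specific slope `s` on the
#' item-specific residual-dependence factor that arises when the same item
#' is administered repeatedly.
#'
#' The cumulative response curves use the intercept convention
#' `logit P(Y >= c) = c_star[c] + a_star * eta + s * xi`, so intercepts must
#' be strictly decreasing in `c`.
#'
#' @param item_id character scalar, unique within a bank.
#' @param a_star banked slope (discrimination), positive.
#' @param c_star numeric vector of banked category intercepts, strictly
#'   decreasing; the item has `length(c_star) + 1` ordered categories.
#' @param s specific slope on the item's residual-dependence factor;
#'   non-negative. Starting value when freely estimated.
#' @return An object of class `graded_item`.
#' @seealso [item_bank()], [cumulative_prob()], [category_prob()]
#' @export
graded_item <- function(item_id, a_star, c_star, s = 1) {
  stopifnot(is.character(item_id), length(item_id) == 1L, nzchar(item_id))
  a_star <- as.numeric(a_star)
  c_star <- as.numeric(c_star)
  s <- as.numeric(s)
  if (length(a_star) != 1L || !is.finite(a_star) || a_star <= 0)
    stop("'a_star' must be a single positive number", call. = FALSE)
  if (length(c_star) < 1L || anyNA(c_star))
    stop("'c_star' must contain at least one finite intercept", call. = FALSE)
  if (length(c_star) > 1L && any(diff(c_star) >= 0))
    stop("intercepts must be strictly decreasing (item '", item_id, "')",
         call. = FALSE)
  if (length(s) != 1L || !is.finite(s) || s < 0)
    stop("'s' must be a single non-negative number", call. = FALSE)
  structure(
    list(item_id = item_id, a_star = a_star, c_star = c_star, s = s,
         n_categories = length(c_star) + 1L),
    class = "graded_item"
  )
}

#' Item bank of calibrated graded-response items
#'
#' Bundles calibrated items together with the reporting metric. Scores are
#' reported on a T metric with population mean 50 and standard deviation 10
#' by default, the convention used for calibrated patient-reported-outcome
#' banks.
#'
#' @param items list of [graded_item()] objects with unique ids.
#' @param mean_T,sd_T reporting metric of the bank.
#' @return An object of class `item_bank`.
#' @export
item_bank <- function(items, mean_T = 50, sd_T = 10) {
  if (inherits(items, "graded_item")) items <- list(items)
  stopifnot(length(items) >= 1L)
  ok <- vapply(items, inherits, logical(1), "graded_item")
  if (!all(ok)) stop("all elements of 'items' must be graded_item objects",
                     call. = FALSE)
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids)) stop("duplicate item ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "),
                               call. = FALSE)
  names(items) <- ids
  structure(list(items = items, mean_T = mean_T, sd_T = sd_T),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat("Item bank:", length(x$items), "graded items, T metric (",
      x$mean_T, ",", x$sd_T, ")\n")
  df <- data.frame(
    item_id = vapply(x$items, `[[`, character(1), "item_id"),
    categories = vapply(x$items, `[[`, integer(1), "n_categories"),
    a_star = vapply(x$items, `[[`, numeric(1), "a_star"),
    s = vapply(x$items, `[[`, numeric(1), "s"),
    row.names = NULL
  )
  print(df, ...)
  invisible(x)
}

#' @export
length.item_bank <- function(x) length(x$items)

#' Cumulative category probability of a graded item
#'
#' `P(Y >= c | eta, xi)` under the logistic graded response model with an
#' item-specific residual-dependence factor:
#' `plogis(c_star[c] + a_star * eta + s * xi)` for interior categories,
#' with the boundary conventions `P(Y >= 0) = 1` and
#' `P(Y >= n_categories) = 0`.
#'
#' @param item a [graded_item()].
#' @param eta latent trait value(s) on the occasion composite.
#' @param xi item-specific factor value(s); ignored when `s = 0`.
#' @param c integer category, `0 <= c <= n_categories`.
#' @return probability, vectorized over `eta`/`xi`.
#' @export
cumulative_prob <- function(item, eta, xi = 0, c) {
  stopifnot(inherits(item, "graded_item"))
  if (length(c) != 1L || c != round(c) || c < 0 || c > item$n_categories)
    stop("category 'c' must be an integer in [0, ", item$n_categories, "]",
         call. = FALSE)
  n <- max(length(eta), length(xi))
  if (c == 0) return(rep(1, n))
  if (c == item$n_categories) return(rep(0, n))
  stats::plogis(item$c_star[c] + item$a_star * eta + item$s * xi)
}

#' Category probability of a graded item
#'
#' `P(Y = c | eta, xi)` as the difference of two adjacent cumulative
#' probabilities. Categories are coded `0 ... n_categories - 1`.
#'
#' @inheritParams cumulative_prob
#' @return probability, vectorized over `eta`/`xi`.
#' @export
category_prob <- function(item, eta, xi = 0, c) {
  stopifnot(inherits(item, "graded_item"))
  if (length(c) != 1L || c != round(c) || c < 0 || c > item$n_categories - 1L)
    stop("category 'c' must be an integer in [0, ", item$n_categories - 1L, "]",
         call. = FALSE)
  cumulative_prob(item, eta, xi, c) - cumulative_prob(item, eta, xi, c + 1L)
}

## ---- bank file I/O ---------------------------------------------------------

#' Read an item bank from a delimited text file
#'
#' The file is comma-separated with a small `#`-prefixed header declaring the
#' conventions, e.g.
#'
#' ```
#' # parameterization: intercept
#' # category_base: 1
#' item_id,n_categories,slope,intercept_1,...,intercept_4,specific_slope_init
#' ```
#'
#' `parameterization` may be `intercept` (the native convention,
#' `logit = c + a*eta`) or `difficulty` (`logit = a*(eta - b)`, converted on
#' read via `c = -a*b`). `category_base` declares how categories are coded in
#' accompanying data files (banks themselves carry no responses); it is
#' stored on the bank for readers of response files.
#'
#' @param path file path.
#' @return an [item_bank()] with attribute `category_base`.
#' @export
read_item_bank <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_key <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", m[1]))
  }
  parameterization <- get_key("parameterization", "intercept")
  if (!parameterization %in% c("intercept", "difficulty"))
    stop("unknown parameterization '", parameterization, "' in ", path,
         call. = FALSE)
  category_base <- as.integer(get_key("category_base", "1"))
  mean_T <- as.numeric(get_key("mean_T", "50"))
  sd_T <- as.numeric(get_key("sd_T", "10"))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  need <- c("item_id", "n_categories", "slope")
  if (!all(need %in% names(df)))
    stop("bank file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  items <- lapply(seq_len(nrow(df)), function(i) {
    ncat <- as.integer(df$n_categories[i])
    cols <- paste0("intercept_", seq_len(ncat - 1L))
    if (!all(cols %in% names(df)))
      stop("bank file missing intercept columns for item '",
           df$item_id[i], "'", call. = FALSE)
    cc <- as.numeric(df[i, cols])
    a <- as.numeric(df$slope[i])
    if (parameterization == "difficulty") {
      # b parameters are increasing in c; convert and flip to intercepts
      cc <- -a * cc
    }
    s0 <- if ("specific_slope_init" %in% names(df))
      as.numeric(df$specific_slope_init[i]) else 1
    graded_item(as.character(df$item_id[i]), a, cc, s = s0)
  })
  bank <- item_bank(items, mean_T = mean_T, sd_T = sd_T)
  attr(bank, "category_base") <- category_base
  bank
}

#' Write an item bank to a delimited text file
#'
#' Writes the native (`intercept`) parameterization so that
#' `read_item_bank(write_item_bank(bank, path))` round-trips exactly.
#'
#' @param bank an [item_bank()].
#' @param path file path.
#' @param category_base category coding declared for accompanying data files.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path, category_base = NULL) {
  stopifnot(inherits(bank, "item_bank"))
  if (is.null(category_base))
    category_base <- attr(bank, "category_base") %||% 1L
  maxc <- max(vapply(bank$items, `[[`, integer(1), "n_categories")) - 1L
  rows <- lapply(bank$items, function(it) {
    cc <- rep(NA_real_, maxc)
    cc[seq_along(it$c_star)] <- it$c_star
    c(list(item_id = it$item_id, n_categories = it$n_categories,
           slope = it$a_star),
      stats::setNames(as.list(cc), paste0("intercept_", seq_len(maxc))),
      list(specific_slope_init = it$s))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# parameterization: intercept",
               paste0("# category_base: ", category_base),
               paste0("# mean_T: ", bank$mean_T),
               paste0("# sd_T: ", bank$sd_T)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convenience accessors used throughout the package
bank_slopes <- function(bank) vapply(bank$items, `[[`, numeric(1), "a_star")
bank_ncat <- function(bank) vapply(bank$items, `[[`, integer(1), "n_categories")
bank_ids <- function(bank) vapply(bank$items, `[[`, character(1), "item_id")
bank_s <- function(bank) vapply(bank$items, `[[`, numeric(1), "s")
# intercept matrix padded with NA, rows = items
bank_intercepts <- function(bank) {
  maxc <- max(bank_ncat(bank)) - 1L
  out <- matrix(NA_real_, nrow = length(bank$items), ncol = maxc)
  for (i in seq_along(bank$items))
    out[i, seq_along(bank$items[[i]]$c_star)] <- bank$items[[i]]$c_star
  out
}
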
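#' Longitudinal item-response trial data
#'
#' Canonical container for item responses collected at repeated visits in a
#' multisite trial. Internally responses are held in a wide integer matrix
#' with one row per subject and `K * T` columns ordered occasion-major
#' (`t1_item1 ... t1_itemK, t2_item1, ...`), categories coded `0 ...
#' C_k - 1`, and `NA` for missing responses. A subject absent at an occasion
#' simply has `NA` in all of that occasion's columns; the likelihood
#' marginalizes over observed responses only.
#'
#' @param responses integer matrix (subjects x `K * T`), categories already
#'   0-based. Column order occasion-major.
#' @param subject vector of unique subject identifiers.
#' @param site vector of site identifiers (same length as `subject`); may be
#'   `NULL` for single-site data.
#' @param covariates data.frame of subject-level covariates (e.g. a treatment
#'   dummy), or `NULL`.
#' @param item_ids character vector of `K` item names.
#' @param T number of occasions.
#' @param category_base how categories are coded in external files (1 by
#'   convention for banked instruments); internal coding is always 0-based.
#' @return An object of class `trial_data`.
#' @export
trial_data <- function(responses, subject, site = NULL, covariates = NULL,
                       item_ids, T, category_base = 1L) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  K <- length(item_ids)
  if (ncol(responses) != K * T)
    stop("'responses' must have K * T = ", K * T, " columns", call. = FALSE)
  n <- nrow(responses)
  if (length(subject) != n) stop("'subject' length mismatch", call. = FALSE)
  if (anyDuplicated(subject)) stop("duplicate subject ids", call. = FALSE)
  if (!is.null(site) && length(site) != n)
    stop("'site' length mismatch", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("'covariates' row mismatch", call. = FALSE)
  }
  if (any(responses < 0L, na.rm = TRUE))
    stop("internal categories must be >= 0; check 'category_base'", call. = FALSE)
  colnames(responses) <- wide_colnames(item_ids, T)
  structure(list(Y = responses, subject = subject, site = site,
                 covariates = covariates, item_ids = item_ids,
                 K = K, T = as.integer(T),
                 category_base = as.integer(category_base)),
            class = "trial_data")
}

wide_colnames <- function(item_ids, T)
  as.vector(vapply(seq_len(T), function(t) paste0("t", t, "_", item_ids),
                   character(length(item_ids))))

#' @export
print.trial_data <- function(x, ...) {
  cat("Longitudinal trial data:", nrow(x$Y), "subjects,",
      x$K, "items x", x$T, "occasions")
  if (!is.null(x$site)) cat(",", length(unique(x$site)), "sites")
  cat("\n")
  per_occ <- vapply(seq_len(x$T), function(t)
    sum(rowSums(!is.na(x$Y[, (t - 1) * x$K + seq_len(x$K), drop = FALSE])) > 0),
    integer(1))
  cat("  subjects observed per occasion:", paste(per_occ, collapse = ", "), "\n")
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trial_data <- function(x) dim(x$Y)

## ---- layout conversion -----------------------------------------------------

#' Convert trial data to a wide data frame
#'
#' One row per subject with `t{t}_{item}` response columns on the external
#' (1-based by default) category coding.
#'
#' @param data a [trial_data()] object.
#' @return data.frame.
#' @export
as_wide <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  df <- data.frame(subject = data$subject, stringsAsFactors = FALSE)
  if (!is.null(data$site)) df$site <- data$site
  if (!is.null(data$covariates)) df <- cbind(df, data$covariates)
  Y <- data$Y + data$category_base
  cbind(df, as.data.frame(Y))
}

#' Convert trial data to a block data frame
#'
#' One row per subject-by-occasion with plain `item` columns; occasions at
#' which a subject has no observed responses are retained as all-missing rows
#' (structural missingness).
#'
#' @param data a [trial_data()] object.
#' @return data.frame with columns subject, site, occasion, covariates, items.
#' @export
as_block <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  n <- nrow(data$Y); K <- data$K; T <- data$T
  idx <- rep(seq_len(n), each = T)
  occ <- rep(seq_len(T), times = n)
  resp <- matrix(NA_integer_, n * T, K, dimnames = list(NULL, data$item_ids))
  for (t in seq_len(T))
    resp[occ == t, ] <- data$Y[, (t - 1) * K + seq_len(K), drop = FALSE]
  df <- data.frame(subject = data$subject[idx], stringsAsFactors = FALSE)
  if (!is.null(data$site)) df$site <- data$site[idx]
  df$occasion <- occ
  if (!is.null(data$covariates))
    df <- cbind(df, data$covariates[idx, , drop = FALSE], row.names = NULL)
  cbind(df, as.data.frame(resp + data$category_base))
}

## ---- file I/O --------------------------------------------------------------

#' Read longitudinal trial data from delimited text
#'
#' `read_trial_wide()` expects one row per subject with `t{t}_{item}` columns
#' (e.g. `t1_item1 ... t3_item8`); `read_trial_block()` expects one row per
#' subject-by-occasion with a `occasion` column and one column per item.
#' A `subject` column is required; `site` and any other columns are treated
#' as site id and subject-level covariates respectively. Missing responses
#' are empty fields (or `NA`). Category coding of the file defaults to
#' 1-based and may be declared in a `# category_base:` header line.
#'
#' @param path file path.
#' @param category_base category coding used in the file; overrides any
#'   header declaration when supplied.
#' @return a [trial_data()] object.
#' @export
read_trial_wide <- function(path, category_base = NULL) {
  lines <- readLines(path)
  category_base <- category_base %||% header_base(lines)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  if (!"subject" %in% names(df)) stop("no 'subject' column", call. = FALSE)
  rcols <- grep("^t[0-9]+_", names(df), value = TRUE)
  if (!length(rcols)) stop("no t{t}_{item} response columns found", call. = FALSE)
  tt <- as.integer(sub("^t([0-9]+)_.*$", "\\1", rcols))
  ids <- sub("^t[0-9]+_", "", rcols)
  T <- max(tt)
  item_ids <- unique(ids[tt == 1L])
  for (t in seq_len(T))
    if (!setequal(ids[tt == t], item_ids))
      stop("occasion ", t, " does not have the same items as occasion 1",
           call. = FALSE)
  want <- wide_colnames(item_ids, T)
  if (!all(want %in% names(df)))
    stop("missing response columns: ",
         paste(setdiff(want, names(df)), collapse = ", "), call. = FALSE)
  Y <- as.matrix(df[, want])
  storage.mode(Y) <- "integer"
  Y <- Y - category_base
  other <- setdiff(names(df), c("subject", "site", want))
  trial_data(Y, subject = df$subject,
             site = if ("site" %in% names(df)) df$site else NULL,
             covariates = if (length(other)) df[, other, drop = FALSE] else NULL,
             item_ids = item_ids, T = T, category_base = category_base)
}

#' @rdname read_trial_wide
#' @export
read_trial_block <- function(path, category_base = NULL) {
  lines <- readLines(path)
  category_base <- category_base %||% header_base(lines)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  need <- c("subject", "occasion")
  if (!all(need %in% names(df)))
    stop("block files need columns ", paste(need, collapse = ", "), call. = FALSE)
  meta <- intersect(c("subject", "site", "occasion"), names(df))
  covnames <- setdiff(names(df), meta)
  # item columns: those that are integer-valued responses; covariates are the
  # columns constant within subject. Distinguish by constancy across occasions.
  subj <- unique(df$subject)
  is_cov <- vapply(covnames, function(cn) {
    all(tapply(df[[cn]], df$subject, function(v) length(unique(v[!is.na(v)])) <= 1L))
  }, logical(1))
  # a column constant within every subject could still be an item; treat
  # columns with any within-subject variation as items, and let an explicit
  # 'cov_' prefix or non-numeric type force covariate status
  force_cov <- grepl("^cov_", covnames) |
    !vapply(covnames, function(cn) is.numeric(df[[cn]]), logical(1))
  item_ids <- covnames[!(is_cov | force_cov)]
  covnames <- setdiff(covnames, item_ids)
  if (!length(item_ids)) stop("no item columns detected", call. = FALSE)
  T <- max(df$occasion)
  if (anyDuplicated(df[, c("subject", "occasion")]))
    stop("duplicate (subject, occasion) rows", call. = FALSE)
  K <- length(item_ids)
  Y <- matrix(NA_integer_, length(subj), K * T)
  si <- match(df$subject, subj)
  for (r in seq_len(nrow(df))) {
    t <- df$occasion[r]
    Y[si[r], (t - 1) * K + seq_len(K)] <-
      as.integer(unlist(df[r, item_ids])) - category_base
  }
  first <- match(subj, df$subject)
  covs <- if (length(covnames)) {
    cv <- df[, covnames, drop = FALSE]
    # take each subject's first non-missing value
    out <- cv[first, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else NULL
  trial_data(Y, subject = subj,
             site = if ("site" %in% names(df)) df$site[first] else NULL,
             covariates = covs, item_ids = item_ids, T = T,
             category_base = category_base)
}

header_base <- function(lines) {
  m <- grep("^#\\s*category_base\\s*:", lines, value = TRUE)
  if (length(m)) as.integer(trimws(sub("^#\\s*category_base\\s*:", "", m[1])))
  else 1L
}

#' Write trial data as delimited text
#'
#' @param data a [trial_data()] object.
#' @param path file path.
#' @param layout `"wide"` or `"block"`.
#' @return `path`, invisibly.
#' @export
write_trial <- function(data, path, layout = c("wide", "block")) {
  layout <- match.arg(layout)
  df <- if (layout == "wide") as_wide(data) else as_block(data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# category_base: ", data$category_base), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Covariate design matrix for the spec's covariates, with validation
covariate_matrix <- function(data, covs) {
  if (!length(covs)) return(matrix(0, nrow(data$Y), 0))
  if (is.null(data$covariates) || !all(covs %in% names(data$covariates)))
    stop("covariates not found in data: ",
         paste(setdiff(covs, names(data$covariates)), collapse = ", "),
         call. = FALSE)
  X <- as.matrix(data$covariates[, covs, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing covariate values are not supported", call. = FALSE)
  X
}
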
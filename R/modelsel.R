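# Regression model comparison: ordinary least squares fits of strain
# measures on kinematic predictors, exhaustive or canonical model
# enumeration, and selection by maximum F-statistic, maximum adjusted R^2,
# or best two-variable model.
#
# The overall F is the model-vs-intercept statistic, consistent with
#   F = (R^2 / k) / ((1 - R^2) / (n - k - 1)),
# and adjusted R^2 uses the (n - 1)/(n - k - 1) penalty. Coefficients are on
# the raw predictor scales (no standardization) and significance is judged
# two-sided at p < 0.05 with no multiple-testing correction.

#' Specify one regression model
#'
#' @param response `"csdm15"` or `"mps"`.
#' @param predictors Nonempty character vector of unique predictor names
#'   drawn from [kinematic_predictors()].
#' @param model_no Optional canonical model number.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(response = c("csdm15", "mps"), predictors,
                       model_no = NA_integer_) {
  response <- match.arg(response)
  if (length(predictors) == 0L) stop("predictor subset must be nonempty")
  if (anyDuplicated(predictors)) stop("predictors must be unique")
  unknown <- setdiff(predictors, kinematic_predictors())
  if (length(unknown)) stop("unknown candidate name: ",
                            paste(unknown, collapse = ", "))
  structure(list(response = response, predictors = as.character(predictors),
                 model_no = model_no), class = "model_spec")
}

#' Fit one linear regression model by least squares
#'
#' QR-based ordinary least squares with the summary statistics used for
#' model comparison: coefficients with two-sided p-values,
#' `R^2 = 1 - SSE/SST`, `adjusted R^2 = 1 - (1 - R^2)(n-1)/(n-k-1)`,
#' `F = (R^2/k) / ((1-R^2)/(n-k-1))` with coefficient p-values from
#' t-statistics on `n - k - 1` degrees of freedom.
#'
#' @param spec A [model_spec()].
#' @param data Data frame containing the response and predictor columns.
#' @return Object of class `model_fit`: `spec`, `n`, `k`, `coefficients`
#'   (named, including `(Intercept)`), `se`, `t`, `p`, `significant`
#'   (p < 0.05 per coefficient, intercept excluded), `r2`, `adj_r2`, `f`,
#'   `f_p`.
#' @export
fit_ols <- function(spec, data) {
  if (!inherits(spec, "model_spec")) stop("spec must be a model_spec")
  miss <- setdiff(c(spec$response, spec$predictors), names(data))
  if (length(miss)) stop("columns absent from data: ", paste(miss, collapse = ", "))
  y <- as.numeric(data[[spec$response]])
  Xp <- as.matrix(data[spec$predictors])
  storage.mode(Xp) <- "double"
  n <- length(y)
  k <- ncol(Xp)
  if (n <= k + 1L) stop("need n > k + 1 observations to fit ", k, " predictors")
  novar <- spec$predictors[apply(Xp, 2, function(x) max(x) - min(x)) == 0]
  if (length(novar)) stop("constant (zero-variance) predictor: ",
                          paste(novar, collapse = ", "))
  X <- cbind(`(Intercept)` = 1, Xp)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  res <- y - as.numeric(X %*% beta)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  df <- n - k - 1L
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df
  f <- (r2 / k) / ((1 - r2) / df)
  sigma2 <- sse / df
  piv <- qrx$pivot
  xtxinv_p <- chol2inv(qr.R(qrx))
  xtxinv <- matrix(NA_real_, ncol(X), ncol(X))
  xtxinv[piv, piv] <- xtxinv_p
  se <- sqrt(diag(xtxinv) * sigma2)
  names(se) <- colnames(X)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  structure(list(spec = spec, n = n, k = k,
                 coefficients = beta, se = se, t = tval, p = pval,
                 significant = pval[-1] < 0.05,
                 r2 = r2, adj_r2 = adj_r2, f = f,
                 f_p = stats::pf(f, k, df, lower.tail = FALSE)),
            class = "model_fit")
}

#' Enumerate candidate regression models
#'
#' `canonical37` reproduces the fixed set of 37 predictor subsets used in
#' the laboratory study's model-comparison tables (shipped as a
#' version-controlled fixture; see [canonical_models()]). `all_subsets`
#' enumerates every subset of the candidates up to `max_k` predictors, in
#' deterministic order (by size, then combination order).
#'
#' @param response Response the specs are built for.
#' @param mode `"canonical37"` or `"all_subsets"`.
#' @param candidates Candidate predictor names (subset of
#'   [kinematic_predictors()]).
#' @param max_k Maximum subset size for `all_subsets`.
#' @return List of [model_spec()] objects, numbered consecutively
#'   (`canonical37` keeps the canonical numbering).
#' @export
enumerate_models <- function(response = c("csdm15", "mps"),
                             mode = c("canonical37", "all_subsets"),
                             candidates = kinematic_predictors(),
                             max_k = 2) {
  response <- match.arg(response)
  mode <- match.arg(mode)
  unknown <- setdiff(candidates, kinematic_predictors())
  if (length(unknown)) stop("unknown candidate name: ",
                            paste(unknown, collapse = ", "))
  if (mode == "canonical37") {
    tab <- canonical_models()
    return(lapply(seq_len(nrow(tab)), function(i) {
      model_spec(response, strsplit(tab$predictors[i], ";", fixed = TRUE)[[1]],
                 model_no = tab$model_no[i])
    }))
  }
  specs <- list()
  no <- 0L
  for (k in seq_len(min(max_k, length(candidates)))) {
    combs <- utils::combn(candidates, k, simplify = FALSE)
    for (cb in combs) {
      no <- no + 1L
      specs[[no]] <- model_spec(response, cb, model_no = no)
    }
  }
  specs
}

#' The canonical 37-model comparison table
#'
#' The fixed enumeration of predictor subsets used in the study's
#' model-comparison tables: 7 single-predictor models, 13 two-variable, 8
#' three-variable, 8 four-variable and 1 five-variable model, together with
#' the adjusted R^2 and F values the study reported for each response.
#'
#' @return Data frame with `model_no`, `k`, `predictors`
#'   (semicolon-separated), `adj_r2_csdm15`, `f_csdm15`, `adj_r2_mps`,
#'   `f_mps`.
#' @export
canonical_models <- function() {
  path <- system.file("extdata", "canonical_models.csv", package = "headkin")
  if (path == "") stop("canonical model fixture not found")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fit a set of model specs on one data group
#'
#' Specs that are infeasible for the group (n <= k + 1) are skipped with a
#' warning and recorded in the ledger's `skipped` field.
#'
#' @param data Data frame of one group's records.
#' @param specs List of [model_spec()]s.
#' @param group Group label stored in the ledger (`all`, `front`, `back`,
#'   `side`, ...).
#' @return Object of class `model_ledger`: `fits` (list of `model_fit`),
#'   `table` (one row per fit: `model_no`, `k`, `predictors`, `r2`,
#'   `adj_r2`, `f`, `n`, `group`, `p_flags`), `skipped`, `group`,
#'   `response`.
#' @export
fit_ledger <- function(data, specs, group = "all") {
  if (length(specs) == 0L) stop("no model specs supplied")
  fits <- list()
  skipped <- integer(0)
  rows <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (nrow(data) <= length(sp$predictors) + 1L) {
      warning(sprintf("group '%s': skipping model %s (n = %d too small for k = %d)",
                      group, sp$model_no, nrow(data), length(sp$predictors)))
      skipped <- c(skipped, sp$model_no)
      next
    }
    fit <- fit_ols(sp, data)
    fits[[length(fits) + 1L]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(
      model_no = sp$model_no, k = fit$k,
      predictors = paste(sp$predictors, collapse = ";"),
      r2 = fit$r2, adj_r2 = fit$adj_r2, f = fit$f, n = fit$n,
      group = group,
      p_flags = paste(ifelse(fit$significant, "*", "-"), collapse = ""),
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model_no = integer(0), k = integer(0), predictors = character(0),
               r2 = numeric(0), adj_r2 = numeric(0), f = numeric(0),
               n = integer(0), group = character(0), p_flags = character(0))
  structure(list(fits = fits, table = tab, skipped = skipped, group = group,
                 response = if (length(specs)) specs[[1]]$response else NA),
            class = "model_ledger")
}

#' Select the best model in a ledger under one criterion
#'
#' `max_f` maximizes the overall F-statistic, `max_adj_r2` the adjusted
#' R^2; `best_two_variable` maximizes F among the two-predictor fits. Ties
#' are broken deterministically: fewer predictors first, then lexicographic
#' predictor names.
#'
#' @param ledger A `model_ledger`.
#' @param criterion One of `max_f`, `max_adj_r2`, `best_two_variable`.
#' @return The selected `model_fit`.
#' @export
select_best <- function(ledger,
                        criterion = c("max_f", "max_adj_r2", "best_two_variable")) {
  criterion <- match.arg(criterion)
  tab <- ledger$table
  fits <- ledger$fits
  if (nrow(tab) == 0L) stop("empty ledger")
  keep <- seq_len(nrow(tab))
  if (criterion == "best_two_variable") {
    keep <- which(tab$k == 2L)
    if (length(keep) == 0L) stop("no two-predictor fits in ledger")
  }
  value <- if (criterion == "max_adj_r2") tab$adj_r2 else tab$f
  sorted_pred <- vapply(fits, function(f)
    paste(sort(f$spec$predictors), collapse = ";"), character(1))
  ord <- order(-value[keep], tab$k[keep], sorted_pred[keep])
  fits[[keep[ord[1]]]]
}

#' Fit ledgers for all impacts and for each impact location separately
#'
#' @param data Data frame of all records (must carry `location` when
#'   per-location groups are requested).
#' @param specs List of [model_spec()]s (see [enumerate_models()]).
#' @param groups Character vector of groups; `"all"` pools every record.
#' @return Named list of `model_ledger`s.
#' @export
stratified_ledger <- function(data, specs,
                              groups = c("all", "front", "back", "side")) {
  out <- list()
  for (g in groups) {
    sub <- if (g == "all") data else data[data$location == g, , drop = FALSE]
    out[[g]] <- fit_ledger(sub, specs, group = g)
  }
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model %s: %s ~ %s\n", x$spec$model_no, x$spec$response,
              paste(x$spec$predictors, collapse = " + ")))
  cat(sprintf("  n = %d, k = %d, R2 = %.4f, adj R2 = %.4f, F = %.1f\n",
              x$n, x$k, x$r2, x$adj_r2, x$f))
  invisible(x)
}
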
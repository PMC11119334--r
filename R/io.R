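#' Read a regression dataset from a delimited text file
#'
#' Reads a CSV or TSV file with a header row, takes `response` as the
#' response column and `covariates` (default: all remaining numeric
#' columns) as the design matrix. Rows containing non-finite values are
#' dropped with a warning. With `intercept = TRUE` a constant column named
#' `"(Intercept)"` is prepended. With `standardize = TRUE` covariates are
#' z-scored (the attributes `center`/`scale` record the transformation so
#' coefficients can be mapped back).
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @param response response column name.
#' @param covariates covariate column names (default all other columns).
#' @param intercept prepend a constant column.
#' @param standardize z-score the (non-constant) covariates.
#' @return list with `x` (matrix), `y` (vector) and `dropped` (number of
#'   removed rows).
#' @export
read_dataset <- function(path, response, covariates = NULL,
                         intercept = FALSE, standardize = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (!nrow(df)) stop("dataset is empty: ", path)
  if (!response %in% names(df))
    stop("response column '", response, "' not found")
  if (is.null(covariates)) covariates <- setdiff(names(df), response)
  missing_cols <- setdiff(covariates, names(df))
  if (length(missing_cols))
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "))
  cols <- df[, c(response, covariates), drop = FALSE]
  bad_type <- names(cols)[!vapply(cols, is.numeric, logical(1))]
  if (length(bad_type))
    stop("non-numeric column(s): ", paste(bad_type, collapse = ", "))
  keep <- stats::complete.cases(cols) &
    apply(cols, 1, function(r) all(is.finite(r)))
  dropped <- sum(!keep)
  if (dropped) warning(dropped, " row(s) with non-finite values dropped")
  cols <- cols[keep, , drop = FALSE]
  if (!nrow(cols)) stop("no complete rows in ", path)
  y <- cols[[response]]
  x <- as.matrix(cols[, covariates, drop = FALSE])
  center <- NULL; scl <- NULL
  if (standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    x <- scale(x, center = center, scale = scl)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
  }
  if (intercept) x <- cbind(`(Intercept)` = 1, x)
  out <- list(x = x, y = y, dropped = dropped)
  if (standardize) { out$center <- center; out$scale <- scl }
  out
}

#' Serialize and restore a selection result
#'
#' `write_fit()` stores the selected model — per-component proportions,
#' coefficients, scales and shapes, the selected penalties, MBIC, degrees
#' of freedom and convergence information — as JSON with full double
#' precision, so `read_fit()` reproduces the parameter state exactly.
#'
#' @param result an [epmix_select()] (or [epmix_fit()]) object.
#' @param path output JSON path.
#' @return `write_fit` returns `path` invisibly; `read_fit` returns a list
#'   with the restored [mixture_theta()] under `$theta` plus the stored
#'   metadata.
#' @export
write_fit <- function(result, path) {
  if (inherits(result, "epmix_select")) {
    fit <- result$best_fit
    meta <- list(lambda1 = unname(result$best_lambda[1]),
                 lambda2 = unname(result$best_lambda[2]),
                 mbic = result$mbic, df = result$df,
                 mbic_surface = result$mbic_surface)
  } else if (inherits(result, "epmix_fit")) {
    fit <- result
    meta <- list(lambda1 = fit$cfg$lambda1, lambda2 = fit$cfg$lambda2)
  } else stop("'result' must be an epmix_select or epmix_fit object")
  payload <- c(list(
    m_hat = fit$m_hat,
    pi = fit$theta$pi,
    beta = fit$theta$beta,
    sigma = fit$theta$sigma,
    p = fit$theta$p,
    fixed_p = if (is.null(fit$control$fixed_p)) NULL else fit$control$fixed_p,
    loglik = fit$loglik,
    converged = fit$converged,
    n_iter = fit$n_iter), meta)
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = I(17),
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- matrix(obj$beta, nrow = obj$m_hat, byrow = FALSE)
  # rowmajor serialization: jsonlite returns the matrix directly
  if (is.matrix(obj$beta)) beta <- obj$beta
  obj$theta <- mixture_theta(obj$pi, beta, obj$sigma, obj$p)
  obj
}
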
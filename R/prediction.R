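# L1-penalized marker-effect model: LASSO with the penalty chosen by
# 10-fold cross-validation, fitted on genotype codes in {-1, 0, 1}.

new_prediction_model <- function(intercept, coefficients, lambda, n_train) {
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 lambda = unname(lambda),
                 markers = names(coefficients),
                 n_train = n_train),
            class = "prediction_model")
}

#' Fit the L1-penalized marker-effect model
#'
#' Fits `y = mu + X beta + e` with a LASSO penalty on `beta` (intercept
#' unpenalized), selecting the penalty `lambda` that minimizes the mean
#' cross-validated squared error over the standard decreasing lambda path.
#' Predictors are used on the raw `{-1, 0, 1}` code scale (no
#' standardization: all codes share a common unit). Fold assignment is
#' randomized from the session RNG and therefore reproducible under
#' `set.seed()`.
#'
#' Zero coefficients are retained, so the model always carries one
#' coefficient per training marker. A constant response (or all-constant
#' predictors) yields an intercept-only model with a warning.
#'
#' @param X n x m numeric matrix of genotype codes, columns named by
#'   marker id.
#' @param y numeric response of length n (phenotypes).
#' @param n_folds number of cross-validation folds (default 10; must be
#'   between 3 and n).
#' @return A `prediction_model` with elements `intercept`, `coefficients`
#'   (named, zeros retained), `lambda`, `markers`, `n_train`.
#' @examples
#' set.seed(1)
#' X <- matrix(sample(c(-1L, 0L, 1L), 600, TRUE), 100, 6,
#'             dimnames = list(NULL, paste0("m", 1:6)))
#' y <- 2 * X[, 1] + rnorm(100, 0, 0.1)
#' fit_prediction_model(X, y)
#' @export
fit_prediction_model <- function(X, y, n_folds = 10) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || anyNA(y)) stop("missing values in training data")
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n_folds < 3 || n_folds > n)
    stop("n_folds must be between 3 and the number of observations")
  markers <- colnames(X) %||% sprintf("m%d", seq_len(ncol(X)))
  if (anyDuplicated(markers)) stop("duplicate marker ids in training data")
  colnames(X) <- markers
  col_var <- apply(X, 2, var)
  if (var(y) == 0 || all(col_var == 0)) {
    warning("degenerate training data (constant response or predictors); ",
            "returning intercept-only model")
    return(new_prediction_model(mean(y),
                                setNames(rep(0, ncol(X)), markers),
                                NA_real_, n))
  }
  if (ncol(X) < 2)
    stop("at least two markers are required to fit the penalized model")
  cvfit <- glmnet::cv.glmnet(X, y, nfolds = n_folds, standardize = FALSE)
  b <- as.numeric(coef(cvfit, s = "lambda.min"))
  new_prediction_model(b[1], setNames(b[-1], markers), cvfit$lambda.min, n)
}

#' Prediction values from a fitted marker model
#'
#' `PV_i = mu + sum_j beta_j x_ij`. Columns of `codes` are matched to the
#' model's markers by id; extra columns are ignored, missing markers are an
#' error.
#'
#' @param object a `prediction_model`.
#' @param codes matrix (or single row vector) of genotype codes with
#'   columns named by marker id; unnamed matrices must match the model's
#'   marker count and order.
#' @param ... ignored.
#' @return Numeric vector of prediction values.
#' @export
predict.prediction_model <- function(object, codes, ...) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1,
                                           dimnames = list(NULL, names(codes)))
  codes <- as.matrix(codes)
  if (is.null(colnames(codes))) {
    if (ncol(codes) != length(object$markers))
      stop("unnamed code matrix does not match the model's marker count")
    colnames(codes) <- object$markers
  }
  m <- match(object$markers, colnames(codes))
  if (anyNA(m))
    stop("codes are missing model markers: ",
         paste(object$markers[is.na(m)], collapse = ", "))
  storage.mode(codes) <- "double"
  drop(object$intercept +
         codes[, m, drop = FALSE] %*% object$coefficients)
}

#' Write / read a prediction model
#'
#' Text format: a header line `#intercept <value> lambda <value>` followed
#' by tab-separated `marker_id  coefficient` rows. The round trip is
#' lossless (values written with full precision).
#'
#' @param model a `prediction_model`.
#' @param path file path.
#' @return `read_model` returns a `prediction_model`; `write_model`
#'   returns the path invisibly.
#' @export
write_model <- function(model, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#intercept %s lambda %s",
                     format(model$intercept, digits = 17),
                     format(model$lambda, digits = 17)), con)
  writeLines("marker_id\tcoefficient", con)
  if (length(model$coefficients))
    writeLines(sprintf("%s\t%s", model$markers,
                       vapply(model$coefficients, format, "", digits = 17)),
               con)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#intercept"))
    stop("line 1: expected '#intercept <value> lambda <value>' header in ",
         path)
  head_parts <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (length(head_parts) != 4 || head_parts[3] != "lambda")
    stop("line 1: malformed model header in ", path)
  intercept <- suppressWarnings(as.numeric(head_parts[2]))
  lambda <- suppressWarnings(as.numeric(head_parts[4]))
  if (is.na(intercept)) stop("line 1: non-numeric intercept in ", path)
  if (length(lines) < 2 || !identical(trimws(lines[2]),
                                      "marker_id\tcoefficient"))
    stop("line 2: expected 'marker_id\tcoefficient' column header in ", path)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  coefs <- numeric(0)
  ids <- character(0)
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(parts[2]))
    if (length(parts) != 2 || is.na(val))
      stop(sprintf("line %d: malformed coefficient row in %s", i + 2, path))
    ids[i] <- parts[1]
    coefs[i] <- val
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop(sprintf("line %d: duplicate marker id '%s' in %s",
                 which(ids == dup)[2] + 2, dup, path))
  }
  new_prediction_model(intercept, setNames(coefs, ids), lambda, NA_integer_)
}

#' @exportS3Method base::print
print.prediction_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(paste0("prediction_model: intercept %.4g, %d markers ",
                     "(%d nonzero), lambda %s, n_train %s\n"),
              x$intercept, length(x$coefficients), nz,
              format(x$lambda, digits = 4), format(x$n_train)))
  invisible(x)
}
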
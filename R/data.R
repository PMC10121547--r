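#' Assemble a dataset for location-scale regression
#'
#' Packages a numeric response and predictor matrix into the container used by
#' the fitting routines: an intercept column is prepended and, by default,
#' each predictor is divided by its sample standard deviation so that all
#' coefficients live on a comparable scale (a prerequisite for penalizing them
#' equally). The scaling factors are recorded so estimates can be mapped back
#' to the original units; see [coef.sic_fit()].
#'
#' @param y numeric response vector, length n.
#' @param x numeric matrix (or data frame) of predictors, n rows, without an
#'   intercept column.
#' @param scale logical; divide each predictor by its sample SD (default TRUE).
#' @param center logical; subtract predictor means first (default FALSE;
#'   affects only the interpretation of the intercepts).
#' @return An object of class `"mpr_data"`: a list with `y`, `X` (n x (p+1)
#'   design including the leading intercept column), `scale_factors` (length
#'   p), `centers` (length p) and `var_names`.
#' @examples
#' d <- mpr_data(rnorm(20), matrix(rnorm(40), 20, 2))
#' apply(d$X[, -1], 2, sd)  # 1 1
#' @export
mpr_data <- function(y, x, scale = TRUE, center = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(x) != n)
    stop("'y' and 'x' must have the same number of rows", call. = FALSE)
  if (anyNA(y) || anyNA(x)) {
    bad <- which(!stats::complete.cases(cbind(y, x)))
    stop("missing values in rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(y)) || !all(is.finite(x)))
    stop("non-finite values in the data", call. = FALSE)
  p <- ncol(x)
  var_names <- colnames(x)
  if (is.null(var_names)) var_names <- paste0("x", seq_len(p))
  centers <- if (center && p > 0) colMeans(x) else rep(0, p)
  if (p > 0) x <- sweep(x, 2L, centers, "-")
  if (p > 0) {
    s <- apply(x, 2L, stats::sd)
    if (any(s == 0))
      stop("constant predictor column(s): ",
           paste(var_names[s == 0], collapse = ", "), call. = FALSE)
  } else {
    s <- numeric(0)
  }
  if (scale && p > 0) x <- sweep(x, 2L, s, "/") else s <- rep(1, p)
  X <- cbind(1, x)
  colnames(X) <- c("(intercept)", var_names)
  if (qr(X)$rank < ncol(X))
    stop("singular design: X does not have full column rank", call. = FALSE)
  structure(
    list(y = y, X = X, scale_factors = s, centers = centers,
         var_names = var_names),
    class = "mpr_data")
}

#' @export
print.mpr_data <- function(x, ...) {
  cat(sprintf("mpr_data: n = %d observations, p = %d predictors\n",
              length(x$y), length(x$var_names)))
  invisible(x)
}

#' Read a CSV file into an `mpr_data` object
#'
#' Reads a headed CSV with one response column and numeric predictors,
#' prepends an intercept and scales predictors to unit sample variance
#' (recording the factors used).
#'
#' @param path path to a CSV file with a header row.
#' @param response_column name of the response column.
#' @param scale,center passed to [mpr_data()].
#' @return An `"mpr_data"` object.
#' @export
read_dataset <- function(path, response_column, scale = TRUE, center = FALSE) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (!response_column %in% names(df))
    stop(sprintf("response column '%s' not found in %s", response_column,
                 path), call. = FALSE)
  not_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(not_num))
    stop("non-numeric column(s): ", paste(not_num, collapse = ", "),
         call. = FALSE)
  y <- df[[response_column]]
  x <- as.matrix(df[setdiff(names(df), response_column)])
  d <- mpr_data(y, x, scale = scale, center = center)
  d$response_name <- response_column
  d
}

# Undo predictor scaling for a coefficient vector (intercept first): a
# coefficient of a scaled predictor x/s corresponds to coef/s on the raw scale.
unscale_coef <- function(coef, scale_factors, centers = NULL) {
  out <- coef
  if (length(coef) > 1L)
    out[-1L] <- coef[-1L] / scale_factors
  if (!is.null(centers) && any(centers != 0))
    out[1L] <- out[1L] - sum(out[-1L] * centers)
  out
}
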
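#' Construct a spatial count dataset
#'
#' Bundles a non-negative integer count response, a matrix of predictors on
#' their raw scale, and planar coordinates for each observation location.
#' This is the input container for every fitting routine in the package.
#'
#' The intercept is never stored in \code{X}; fitting functions prepend it
#' internally, so \code{ncol(X)} is always the number of substantive
#' predictors \code{k}.
#'
#' @param y non-negative integer-valued counts, length n.
#' @param X numeric predictor matrix (or data frame) with n rows and k
#'   columns, raw scale, no intercept column.
#' @param coords two-column matrix of planar coordinates \code{(u, v)} per
#'   location. Coordinates are treated as planar: distances are Euclidean in
#'   the units given (for longitude/latitude inputs this is Euclidean on
#'   degrees; no great-circle correction is applied).
#' @param predictor_names optional character vector of length k; defaults to
#'   the column names of \code{X} or \code{x1..xk}.
#' @param location_labels optional character vector of length n; defaults to
#'   \code{loc_1..loc_n}.
#' @return An object of class \code{spatial_count_dataset}: a list with
#'   elements \code{y}, \code{X}, \code{coords}, \code{predictor_names},
#'   \code{location_labels}, \code{n}, \code{k}.
#' @examples
#' ds <- spatial_count_dataset(c(1, 2, 3), cbind(x1 = c(0.1, 0.5, 0.9)),
#'                             coords = cbind(0:2, 0:2))
#' ds$n; ds$k
#' @export
spatial_count_dataset <- function(y, X, coords, predictor_names = NULL,
                                  location_labels = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(y)
  k <- ncol(X)

  if (anyNA(y) || anyNA(X) || anyNA(coords))
    stop("spatial_count_dataset: missing values are not allowed in y, X or coords")
  if (!all(is.finite(y)) || !all(is.finite(X)) || !all(is.finite(coords)))
    stop("spatial_count_dataset: non-finite values in y, X or coords")
  bad <- which(y < 0 | y != round(y))
  if (length(bad))
    stop(sprintf("spatial_count_dataset: response must be non-negative integers; offending row(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  if (nrow(X) != n)
    stop("spatial_count_dataset: nrow(X) must equal length(y)")
  if (nrow(coords) != n || ncol(coords) != 2L)
    stop("spatial_count_dataset: coords must be an n x 2 matrix of (u, v) pairs")
  if (n < k + 2L)
    stop(sprintf("spatial_count_dataset: need at least k + 2 = %d observations to fit intercept, %d slope(s) and a dispersion parameter; got n = %d",
                 k + 2L, k, n))

  if (is.null(predictor_names)) {
    predictor_names <- colnames(X)
    if (is.null(predictor_names)) predictor_names <- paste0("x", seq_len(k))
  }
  if (length(predictor_names) != k)
    stop("spatial_count_dataset: predictor_names must have length k")
  colnames(X) <- predictor_names
  if (is.null(location_labels)) location_labels <- paste0("loc_", seq_len(n))
  if (length(location_labels) != n)
    stop("spatial_count_dataset: location_labels must have length n")
  colnames(coords) <- c("u", "v")

  if (anyDuplicated(coords))
    warning("spatial_count_dataset: duplicated coordinates found; off-diagonal zero distances are permitted but local fits at those points share data")

  structure(list(y = y, X = X, coords = coords,
                 predictor_names = predictor_names,
                 location_labels = location_labels,
                 n = n, k = k),
            class = "spatial_count_dataset")
}

#' @export
print.spatial_count_dataset <- function(x, ...) {
  cat(sprintf("Spatial count dataset: n = %d locations, k = %d predictor(s)\n", x$n, x$k))
  cat("  predictors:", paste(x$predictor_names, collapse = ", "), "\n")
  cat(sprintf("  response: min %g, max %g, mean %.3f, variance %.3f\n",
              min(x$y), max(x$y), mean(x$y), stats::var(x$y)))
  invisible(x)
}

#' Read a spatial count dataset from a delimited text file
#'
#' @param path path to a delimited file with a header row.
#' @param response name of the count response column.
#' @param predictors character vector of predictor column names.
#' @param coords length-2 character vector naming the (u, v) coordinate
#'   columns.
#' @param labels optional name of a location-label column.
#' @param delim field delimiter, default comma.
#' @return A \code{\link{spatial_count_dataset}}; row order is preserved and
#'   predictors are kept on their raw scale.
#' @export
read_spatial_counts <- function(path, response, predictors, coords = c("u", "v"),
                                labels = NULL, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim, dec = ".",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  need <- c(response, predictors, coords, labels)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("read_spatial_counts: column(s) not found in '%s': %s",
                 path, paste(missing_cols, collapse = ", ")))
  yraw <- df[[response]]
  if (anyNA(yraw))
    stop(sprintf("read_spatial_counts: missing value in response column '%s' at row(s) %s",
                 response, paste(which(is.na(yraw)), collapse = ", ")))
  ynum <- suppressWarnings(as.numeric(yraw))
  bad <- which(is.na(ynum) | ynum < 0 | ynum != round(ynum))
  if (length(bad))
    stop(sprintf("read_spatial_counts: response column '%s' must contain non-negative integers; offending row(s): %s",
                 response, paste(utils::head(bad, 5L), collapse = ", ")))
  Xdf <- df[predictors]
  if (anyNA(Xdf))
    stop("read_spatial_counts: missing value(s) in predictor columns")
  spatial_count_dataset(ynum, as.matrix(Xdf),
                        as.matrix(df[coords]),
                        predictor_names = predictors,
                        location_labels = if (is.null(labels)) NULL else as.character(df[[labels]]))
}

#' Write a spatial count dataset to CSV
#'
#' Column order is: label, response \code{y}, predictors, coordinates
#' \code{u}, \code{v}; re-reading with \code{\link{read_spatial_counts}}
#' reproduces the dataset for finite-decimal inputs.
#'
#' @param ds a \code{\link{spatial_count_dataset}}.
#' @param path output path.
#' @export
write_spatial_counts <- function(ds, path) {
  df <- data.frame(label = ds$location_labels, y = ds$y,
                   as.data.frame(ds$X), u = ds$coords[, 1], v = ds$coords[, 2],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pairwise Euclidean distance matrix between observation locations
#'
#' @param x a \code{\link{spatial_count_dataset}} or a two-column coordinate
#'   matrix.
#' @return Symmetric n x n matrix with zero diagonal,
#'   \code{d[i, j] = sqrt((u_i - u_j)^2 + (v_i - v_j)^2)}.
#' @examples
#' distance_matrix(cbind(c(0, 3), c(0, 4)))[1, 2]  # 5
#' @export
distance_matrix <- function(x) {
  coords <- if (inherits(x, "spatial_count_dataset")) x$coords else as.matrix(x)
  if (ncol(coords) != 2L) stop("distance_matrix: coordinates must have two columns")
  d <- as.matrix(stats::dist(coords, method = "euclidean"))
  dimnames(d) <- NULL
  d
}
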
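#' Fixed-effect incidence for the combined year-location-trial factor
#'
#' One column per observed (year, location, trial) combination, cell-means
#' coding: every plot carries exactly one 1, so the matrix is full column
#' rank and no reference-level constraint is needed.
#'
#' @param plots plot table (or subset).
#' @return list with sparse incidence \code{X} (plots x levels) and
#'   \code{levels}, the level labels in column order.
#' @export
build_fixed_ylt <- function(plots) {
  f <- factor(paste(plots$year, plots$location, plots$trial, sep = ":"))
  X <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                            dims = c(length(f), nlevels(f)),
                            dimnames = list(NULL, levels(f)))
  list(X = X, levels = levels(f))
}

#' Line (genetic effect) incidence
#'
#' Maps plots to the full label set of a relationship matrix so that lines
#' without records (e.g. a validation set) still receive breeding values
#' through the covariance structure.
#'
#' @param plots plot table.
#' @param line_ids label set (typically \code{rownames(G)}).
#' @return sparse plots x lines incidence; each row has exactly one 1.
#' @export
build_line_incidence <- function(plots, line_ids) {
  j <- match(plots$line, line_ids)
  if (anyNA(j))
    stop("lines absent from the relationship matrix: ",
         paste(utils::head(unique(plots$line[is.na(j)]), 5), collapse = ", "))
  Matrix::sparseMatrix(i = seq_len(nrow(plots)), j = j, x = 1,
                       dims = c(nrow(plots), length(line_ids)),
                       dimnames = list(NULL, line_ids))
}

#' Row/column spatial incidence for single-plot (F5-style) trials
#'
#' Fits the plot's field column (x) and row (y) as factor levels nested
#' within (year, location, trial); the two incidences share one spatial
#' variance. This is the n = 2 spatial structure.
#'
#' @param plots plot table subset carrying coordinates.
#' @return list with \code{Z_x}, \code{Z_y} (sparse incidences) and
#'   \code{Z}, their column-wise concatenation.
#' @export
build_spatial_f5 <- function(plots) {
  if (anyNA(plots$x) || anyNA(plots$y))
    stop("plot(s) without coordinates: ",
         paste(utils::head(plots$plot_id[is.na(plots$x) | is.na(plots$y)], 5),
               collapse = ", "))
  key <- paste(plots$year, plots$location, plots$trial, sep = ":")
  fx <- factor(paste(key, plots$x, sep = ":x"))
  fy <- factor(paste(key, plots$y, sep = ":y"))
  mk <- function(f) Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f),
                                         x = 1, dims = c(length(f), nlevels(f)),
                                         dimnames = list(NULL, levels(f)))
  Zx <- mk(fx); Zy <- mk(fy)
  list(Z_x = Zx, Z_y = Zy, Z = cbind(Zx, Zy))
}

#' Moving-average spatial incidence for replicated (F6-style) trials
#'
#' Spatial levels are the occupied grid positions within each (year,
#' location, trial). A plot at (x, y) carries a 1 for its own position and
#' for each of its eight Moore neighbours that exists in the same trial grid
#' (edge plots simply have fewer), so a plot's spatial effect is the sum
#' of up to 9 iid position effects. This is the n = 9 structure.
#'
#' @param plots plot table subset carrying coordinates.
#' @param normalize divide each row by its neighbour count so the row sums
#'   to 1 (off by default; the unnormalised sum is the fitted form).
#' @return sparse plots x positions incidence with row sums <= 9.
#' @export
build_spatial_f6 <- function(plots, normalize = FALSE) {
  if (anyNA(plots$x) || anyNA(plots$y))
    stop("plot(s) without coordinates: ",
         paste(utils::head(plots$plot_id[is.na(plots$x) | is.na(plots$y)], 5),
               collapse = ", "))
  key <- paste(plots$year, plots$location, plots$trial, sep = ":")
  pos <- paste(key, plots$x, plots$y, sep = ":")
  lev <- sort(unique(pos))
  pidx <- stats::setNames(seq_along(lev), lev)
  off <- expand.grid(dx = -1:1, dy = -1:1)
  ii <- integer(0); jj <- integer(0)
  for (k in seq_len(nrow(off))) {
    nb <- paste(key, plots$x + off$dx[k], plots$y + off$dy[k], sep = ":")
    hit <- nb %in% lev
    ii <- c(ii, which(hit))
    jj <- c(jj, pidx[nb[hit]])
  }
  Z <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(nrow(plots), length(lev)),
                            dimnames = list(NULL, lev))
  if (normalize) Z <- Matrix::Diagonal(x = 1 / Matrix::rowSums(Z)) %*% Z
  Z
}
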
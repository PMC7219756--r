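#' Per-marker allele frequencies and call rates
#'
#' The frequency \code{p} of the counted (second) allele at marker j is the
#' sum of non-missing counts divided by twice the number of non-missing
#' lines. MAF is \code{min(p, 1-p)}.
#'
#' @param g genotype matrix (0/1/2 counts, NA missing).
#' @return list with per-marker data.frame \code{markers} (marker, p, maf,
#'   call_rate) and per-line data.frame \code{lines} (line, missing_frac).
#' @export
allele_frequencies <- function(g) {
  nonmiss <- colSums(!is.na(g))
  if (any(nonmiss == 0))
    stop("marker(s) with zero non-missing calls: ",
         paste(utils::head(colnames(g)[nonmiss == 0], 5), collapse = ", "))
  p <- colSums(g, na.rm = TRUE) / (2 * nonmiss)
  list(
    markers = data.frame(marker = colnames(g), p = p, maf = pmin(p, 1 - p),
                         call_rate = nonmiss / nrow(g), row.names = NULL),
    lines = data.frame(line = rownames(g), missing_frac = rowMeans(is.na(g)),
                       row.names = NULL)
  )
}

#' Marker and line quality control
#'
#' Removes lines whose fraction of missing calls exceeds
#' \code{line_missing_max}, then recomputes allele frequencies on the
#' surviving lines and removes markers with MAF below \code{maf_min}
#' (lines first, then markers, so marginal marker frequencies reflect the
#' retained lines).
#'
#' @param g genotype matrix.
#' @param maf_min minor-allele frequency threshold; markers with MAF strictly
#'   below it are dropped.
#' @param line_missing_max per-line missing fraction; lines strictly above it
#'   are dropped.
#' @return filtered genotype matrix.
#' @export
qc_filter <- function(g, maf_min = 0.01, line_missing_max = 0.02) {
  keep_l <- rowMeans(is.na(g)) <= line_missing_max
  if (sum(keep_l) < 2) stop("fewer than 2 lines survive the missingness filter")
  g2 <- g[keep_l, , drop = FALSE]
  nonmiss <- colSums(!is.na(g2))
  p <- ifelse(nonmiss > 0, colSums(g2, na.rm = TRUE) / (2 * nonmiss), 0)
  keep_m <- nonmiss > 0 & pmin(p, 1 - p) >= maf_min
  if (!any(keep_m)) stop("no markers survive the MAF filter")
  genotype_matrix(unclass(g2)[, keep_m, drop = FALSE])
}

#' Mean imputation of missing genotype calls
#'
#' Replaces each missing call by the marker's mean count over non-missing
#' lines, so imputed markers keep their column means and contribute zero to
#' the centred marker matrix.
#'
#' @param g genotype matrix (post-QC).
#' @return real-valued matrix without missing values (line/marker dimnames
#'   preserved; no longer constrained to \{0,1,2\}).
#' @export
mean_impute <- function(g) {
  m <- unclass(g)
  mu <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx) > 0) m[idx] <- mu[idx[, 2]]
  m
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' \code{G = ZZ' / (2 * sum(p_j (1 - p_j)))} where \code{Z} is the matrix of
#' allele counts column-centred by twice the allele frequency
#' (\code{Z = M - 2p}). Frequencies default to those of the supplied matrix;
#' pass \code{p} to centre by frequencies computed before imputation.
#'
#' @param m numeric line-by-marker matrix without missing values (e.g. from
#'   [mean_impute()]).
#' @param p optional vector of allele frequencies per marker.
#' @return symmetric matrix of class \code{"relmat"} with
#'   \code{attr(,"kind") == "genomic"}.
#' @export
build_G <- function(m, p = NULL) {
  m <- unclass(as.matrix(m))
  if (anyNA(m)) stop("genotype matrix still has missing values; impute first")
  if (nrow(m) < 2) stop("need at least 2 lines")
  if (is.null(p)) p <- colMeans(m) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: zero VanRaden denominator")
  z <- sweep(m, 2, 2 * p, "-")
  G <- tcrossprod(z) / denom
  G <- (G + t(G)) / 2
  structure(G, kind = "genomic", bend = 0, class = c("relmat", "matrix", "array"))
}

# one round of self-fertilisation: F' = (1 + F) / 2
self_f <- function(f, cycles) {
  for (k in seq_len(cycles)) f <- (1 + f) / 2
  f
}

#' Pedigree numerator relationship matrix under repeated selfing
#'
#' Tabular method extended for recorded self-fertilisation. Individuals are
#' processed in topological order; for j with parents s and d,
#' \code{a_ij = 0.5 (a_is + a_id)} for earlier i, and the inbreeding
#' coefficient at the cross, \code{F = 0.5 a_sd}, is advanced through each
#' recorded selfing cycle by \code{F' = 0.5 (1 + F)} before setting
#' \code{a_jj = 1 + F}. Founders (and unknown parents) are treated as
#' unrelated lines carrying \code{founder_selfing} cycles of selfing, i.e.
#' \code{F = 1 - 0.5^founder_selfing}; a founder record with its own
#' \code{selfing_cycles} overrides the default.
#'
#' @param ped pedigree (see [pedigree()]).
#' @param founder_selfing selfing cycles assumed for parental lines without
#'   recorded parents (default 9).
#' @return symmetric matrix of class \code{"relmat"},
#'   \code{attr(,"kind") == "pedigree"}, rows/cols in pedigree order.
#' @export
build_A_selfed <- function(ped, founder_selfing = 9) {
  n <- nrow(ped)
  ids <- ped$id
  idx <- stats::setNames(seq_len(n), ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    s <- ped$parent1[j]; d <- ped$parent2[j]
    si <- if (is.na(s)) NA_integer_ else idx[[s]]
    di <- if (is.na(d)) NA_integer_ else idx[[d]]
    if (is.na(si) && is.na(di)) {
      cycles <- if (is.na(ped$selfing_cycles[j])) founder_selfing else ped$selfing_cycles[j]
      A[j, j] <- 1 + (1 - 0.5^cycles)
      next
    }
    # single known parent: the unknown one is an unrelated fully-selfed founder
    for (i in seq_len(j - 1)) {
      as_ <- if (is.na(si)) 0 else A[i, si]
      ad_ <- if (is.na(di)) 0 else A[i, di]
      A[i, j] <- A[j, i] <- 0.5 * (as_ + ad_)
    }
    f_cross <- if (is.na(si) || is.na(di)) 0 else 0.5 * A[si, di]
    A[j, j] <- 1 + self_f(f_cross, ped$selfing_cycles[j])
  }
  structure(A, kind = "pedigree", bend = 0, class = c("relmat", "matrix", "array"))
}

#' Mean diagonal element of a relationship matrix
#'
#' The scaling factor \code{d(G)} entering the phenotypic variance of line
#' means and the heritability of line means.
#'
#' @param G square matrix.
#' @return scalar mean of the diagonal.
#' @export
mean_diagonal <- function(G) {
  if (nrow(G) != ncol(G)) stop("matrix is not square")
  mean(diag(as.matrix(G)))
}

#' Principal coordinate analysis of a relationship matrix
#'
#' Double-centres the relationship (similarity) matrix and eigendecomposes
#' it; this equals classical metric scaling of the induced squared distances
#' \code{d_ij^2 = G_ii + G_jj - 2 G_ij}. Variance-explained shares are taken
#' over the positive eigenvalues only.
#'
#' @param G relationship matrix.
#' @param n_axes number of coordinate axes requested.
#' @return list with \code{coordinates} (lines x axes, scaled by sqrt of the
#'   eigenvalue), \code{eigenvalues}, and \code{variance_explained}
#'   (fraction of the positive-eigenvalue total per returned axis).
#' @export
pcoa <- function(G, n_axes = 2) {
  G <- as.matrix(G)
  if (max(abs(G - t(G))) > 1e-8) stop("relationship matrix is not symmetric")
  n <- nrow(G)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% G %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(e$values, 0) * 1e-12)
  if (length(pos) == 0) stop("relationship matrix has no positive spectrum")
  if (n_axes > length(pos)) {
    warning("only ", length(pos), " positive axes available; truncating")
    n_axes <- length(pos)
  }
  ax <- seq_len(n_axes)
  coords <- sweep(e$vectors[, ax, drop = FALSE], 2, sqrt(e$values[ax]), "*")
  rownames(coords) <- rownames(G)
  colnames(coords) <- paste0("Axis", ax)
  list(coordinates = coords, eigenvalues = e$values,
       variance_explained = e$values[ax] / sum(e$values[pos]))
}

#' Condition a relationship matrix to be positive definite
#'
#' If the smallest eigenvalue is below \code{epsilon}, adds
#' \code{(epsilon - lambda_min)} to the diagonal ("bending"), recorded in the
#' \code{"bend"} attribute. REML needs invertible covariance structures;
#' genomic matrices from fewer markers than lines, or with duplicated lines,
#' are singular without this.
#'
#' @param G relationship matrix.
#' @param epsilon eigenvalue floor (default 1e-6).
#' @return conditioned matrix of class \code{"relmat"}.
#' @export
condition_pd <- function(G, epsilon = 1e-6) {
  M <- as.matrix(G)
  if (max(abs(M - t(M))) > 1e-8) stop("matrix is not symmetric")
  lmin <- min(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  bend <- 0
  if (lmin < epsilon) {
    bend <- epsilon - lmin
    M <- M + diag(bend, nrow(M))
  }
  structure(M, kind = attr(G, "kind", exact = TRUE) %||% "genomic", bend = bend,
            class = c("relmat", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
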
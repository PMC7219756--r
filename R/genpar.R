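#' Phenotypic variance and heritability of line means
#'
#' The phenotypic variance of a line mean is
#' \deqn{\sigma_p^2 = d(G)\,\sigma_g^2 + n_s \sigma_s^2 / r_1 + \sigma_e^2 / r_2}
#' and heritability is \eqn{h^2 = d(G)\sigma_g^2 / \sigma_p^2}, where
#' \code{d_G} is the mean diagonal of the genomic relationship matrix,
#' \code{n_s} the spatial neighbourhood size (2 for row/column, 9 for the
#' moving average) and \code{r_1}, \code{r_2} the replicate counts of the
#' spatial and residual effects per line. Plot heritability uses
#' \code{r1 = r2 = 1}; with a single plot per line the two coincide.
#'
#' @param sigma_g2,sigma_e2,sigma_s2 variance components (genomic, residual,
#'   spatial; spatial defaults to 0).
#' @param d_G mean diagonal of G ([mean_diagonal()]).
#' @param n_s spatial neighbourhood size.
#' @param r1,r2 replicate counts (>= 1) for the spatial and residual terms.
#' @return list with \code{sigma_p2}, \code{h2}, and the inputs.
#' @export
line_heritability <- function(sigma_g2, sigma_e2, sigma_s2 = 0, d_G = 1,
                              n_s = 0, r1 = 1, r2 = 1) {
  stopifnot(r1 >= 1, r2 >= 1, sigma_g2 >= 0, sigma_e2 >= 0, sigma_s2 >= 0)
  sigma_p2 <- d_G * sigma_g2 + n_s * sigma_s2 / r1 + sigma_e2 / r2
  if (sigma_p2 <= 0) stop("phenotypic variance is zero")
  list(sigma_p2 = sigma_p2, h2 = d_G * sigma_g2 / sigma_p2, d_G = d_G,
       n_s = n_s, r1 = r1, r2 = r2)
}

#' Heritability summary of a GBLUP fit
#'
#' Computes plot heritability (single-plot basis, \code{r = 1}) and
#' line-mean heritability per trait from the fitted variance components.
#' Replicate counts default to the mean number of plots per line in the
#' fitted data (used for both the spatial and residual terms); override with
#' \code{r1}/\code{r2}.
#'
#' @param object a [gblup()] fit.
#' @param r1,r2 optional explicit replicate counts (recycled across traits).
#' @param ... unused.
#' @return data.frame with one row per trait: variance components,
#'   \code{d_G}, \code{n_s}, replicate counts, \code{sigma_p2_line},
#'   \code{h2_plot}, \code{h2_line}.
#' @export
heritability <- function(object, r1 = NULL, r2 = NULL, ...) {
  stopifnot(inherits(object, "gblup"))
  dG <- mean_diagonal(object$G)
  vc <- vc_by_trait(object)
  rows <- lapply(seq_along(object$traits), function(i) {
    g <- object$traits[i]
    sub <- object$plots[object$plots$generation == g, ]
    r_mean <- mean(table(sub$line))
    r1i <- if (is.null(r1)) r_mean else rep_len(r1, i)[i]
    r2i <- if (is.null(r2)) r_mean else rep_len(r2, i)[i]
    v <- vc[[g]]
    ns <- unname(object$n_s[g])
    plot_h <- line_heritability(v["sigma_g2"], v["sigma_e2"], v["sigma_s2"],
                                dG, ns, 1, 1)
    line_h <- line_heritability(v["sigma_g2"], v["sigma_e2"], v["sigma_s2"],
                                dG, ns, r1i, r2i)
    data.frame(trait = g, sigma_g2 = unname(v["sigma_g2"]),
               sigma_a2 = unname(v["sigma_a2"]),
               sigma_s2 = unname(v["sigma_s2"]),
               sigma_e2 = unname(v["sigma_e2"]), d_G = dG, n_s = ns,
               r1 = r1i, r2 = r2i, sigma_p2_line = line_h$sigma_p2,
               h2_plot = plot_h$h2, h2_line = line_h$h2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genetic correlation between the two traits
#'
#' \code{H[1,2] / sqrt(H[1,1] * H[2,2])} from a 2x2 genetic (co)variance
#' matrix, or from the genomic \code{H} block of a bivariate [gblup()] fit.
#'
#' @param x 2x2 matrix or a bivariate \code{"gblup"} object.
#' @return scalar genetic correlation.
#' @export
genetic_correlation <- function(x) {
  if (inherits(x, "gblup")) {
    if (length(x$traits) != 2) stop("fit is not bivariate")
    th <- theta_of(x)
    H <- matrix(c(th[["genomic_v1"]], th[["genomic_cov"]],
                  th[["genomic_cov"]], th[["genomic_v2"]]), 2)
    return(genetic_correlation(H))
  }
  H <- as.matrix(x)
  stopifnot(nrow(H) == 2, ncol(H) == 2)
  if (H[1, 1] <= 0 || H[2, 2] <= 0) stop("zero genetic variance on the diagonal")
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) stop("H is not positive semidefinite")
  H[1, 2] / sqrt(H[1, 1] * H[2, 2])
}
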
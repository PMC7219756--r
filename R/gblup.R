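#' Fit a GBLUP mixed model to field-trial yield records
#'
#' Single-trait or bivariate genomic evaluation of breeding-line yield.
#' Fixed effects are the combined year-location-trial (YLT) factor; genetic
#' effects carry the genomic relationship matrix \code{G} (and optionally an
#' additive effect with the pedigree matrix \code{A} as a second random
#' term); spatial random effects use field coordinates — row/column factors
#' for single-plot F5 trials (n = 2) and a 9-plot moving-average
#' neighbourhood for replicated F6 trials (n = 9). Variance components are
#' estimated by AI-REML ([reml_fit()]).
#'
#' With two generations the model is bivariate: genetic effects follow
#' \code{N(0, H x G)} with an unstructured 2x2 \code{H}, and the residual
#' covariance between the traits is structurally zero (they are never
#' observed on the same plot).
#'
#' @param plots plot table ([read_plots()] / [plot_table()]).
#' @param G genomic relationship matrix over line labels; must cover every
#'   fitted line (use [condition_pd()] first if near-singular).
#' @param A optional pedigree relationship matrix for an additional additive
#'   term.
#' @param generation \code{"F6"}, \code{"F5"}, or \code{c("F5", "F6")} for
#'   the bivariate model (order defines trait 1 and trait 2).
#' @param spatial fit the spatial random term(s); the form follows each
#'   trait's generation.
#' @param include_checks keep replicated check entries in the data (they
#'   receive genetic effects like any line).
#' @param init,max_iter,tol,verbose passed to [reml_fit()].
#' @return object of class \code{"gblup"}; see [predict.gblup()],
#'   [heritability()], [genetic_correlation()].
#' @examples
#' sim <- simulate_study(sim_config(n_sets = 2, lines_per_set = 30,
#'                                  n_markers = 200, seed = 1))
#' G <- condition_pd(build_G(mean_impute(qc_filter(sim$genotypes))))
#' fit <- gblup(sim$plots, G, generation = "F6")
#' summary(fit)
#' @export
gblup <- function(plots, G, A = NULL, generation = "F6", spatial = FALSE,
                  include_checks = TRUE, init = NULL, max_iter = 200,
                  tol = 1e-8, verbose = FALSE) {
  stopifnot(length(generation) %in% 1:2, all(generation %in% c("F5", "F6")))
  cl <- match.call()
  plots <- as.data.frame(plots)
  plots <- plots[!is.na(plots$yield) & plots$generation %in% generation, ,
                 drop = FALSE]
  if (!include_checks) plots <- plots[!plots$is_check, , drop = FALSE]
  if (nrow(plots) == 0) stop("no usable yield records")
  gl <- rownames(G)
  drop_l <- setdiff(unique(plots$line), gl)
  if (length(drop_l) > 0) {
    message("dropping ", length(drop_l),
            " line(s) without entries in the relationship matrix")
    plots <- plots[plots$line %in% gl, , drop = FALSE]
    if (nrow(plots) == 0) stop("no plots left after dropping ungenotyped lines")
  }
  sub <- lapply(generation, function(g) plots[plots$generation == g, , drop = FALSE])
  names(sub) <- generation
  for (g in generation)
    if (nrow(sub[[g]]) == 0) stop("no records for generation ", g)

  part <- lapply(sub, function(s) {
    zs <- NULL; ns <- 0
    if (spatial) {
      if (s$generation[1] == "F5") { zs <- build_spatial_f5(s)$Z; ns <- 2 }
      else { zs <- build_spatial_f6(s); ns <- 9 }
    }
    list(y = s$yield, X = build_fixed_ylt(s), Zg = build_line_incidence(s, gl),
         Za = if (!is.null(A)) build_line_incidence(s, rownames(A)),
         Zs = zs, n_s = ns, n = nrow(s))
  })

  zpad <- function(Z, n) {
    if (is.null(Z)) return(NULL)
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n, ncol(Z)), dimnames = list(NULL, colnames(Z)))
  }
  if (length(generation) == 1) {
    p1 <- part[[1]]
    terms <- list(rterm(p1$Zg, G, "genomic"))
    if (!is.null(A)) terms <- c(terms, list(rterm(p1$Za, A, "pedigree")))
    if (spatial) terms <- c(terms, list(rterm(p1$Zs, NULL, "spatial")))
    model <- reml_model(p1$y, as.matrix(p1$X$X), terms,
                        resid = factor(rep(generation, p1$n)))
  } else {
    p1 <- part[[1]]; p2 <- part[[2]]
    X <- rbind(cbind(as.matrix(p1$X$X), matrix(0, p1$n, ncol(p2$X$X))),
               cbind(matrix(0, p2$n, ncol(p1$X$X)), as.matrix(p2$X$X)))
    colnames(X) <- c(paste0(generation[1], ":", p1$X$levels),
                     paste0(generation[2], ":", p2$X$levels))
    terms <- list(cterm(rbind(p1$Zg, zpad(p2$Zg, p2$n)),
                        rbind(zpad(p1$Zg, p1$n), p2$Zg), G, "genomic"))
    if (!is.null(A))
      terms <- c(terms, list(cterm(rbind(p1$Za, zpad(p2$Za, p2$n)),
                                   rbind(zpad(p1$Za, p1$n), p2$Za), A,
                                   "pedigree")))
    if (spatial) {
      terms <- c(terms,
                 list(rterm(rbind(p1$Zs, zpad(p1$Zs, p2$n)), NULL,
                            paste0("spatial_", generation[1])),
                      rterm(rbind(zpad(p2$Zs, p1$n), p2$Zs), NULL,
                            paste0("spatial_", generation[2]))))
    }
    model <- reml_model(c(p1$y, p2$y), X, terms,
                        resid = factor(rep(generation, c(p1$n, p2$n)),
                                       levels = generation))
  }

  fit <- reml_fit(model, init = init, max_iter = max_iter, tol = tol,
                  verbose = verbose)
  ebv <- fit$u$genomic
  if (is.null(dim(ebv))) ebv <- matrix(ebv, ncol = 1, dimnames = list(names(ebv), generation))
  else colnames(ebv) <- generation
  structure(list(fit = fit, traits = generation, spatial = spatial,
                 n_s = stats::setNames(vapply(part, `[[`, 0, "n_s"), generation),
                 G = G, A = A, plots = plots, line_ids = gl, ebv = ebv,
                 call = cl),
            class = "gblup")
}

theta_of <- function(object) object$fit$theta

# per-trait (sigma_g2, sigma_e2, sigma_s2) from the parameter vector
vc_by_trait <- function(object) {
  th <- theta_of(object)
  out <- list()
  for (i in seq_along(object$traits)) {
    g <- object$traits[i]
    sg <- if (length(object$traits) == 1) th[["genomic"]]
          else th[[paste0("genomic_v", i)]]
    sa <- if (is.null(object$A)) 0
          else if (length(object$traits) == 1) th[["pedigree"]]
          else th[[paste0("pedigree_v", i)]]
    ss <- if (!object$spatial) 0
          else if (length(object$traits) == 1) th[["spatial"]]
          else th[[paste0("spatial_", g)]]
    out[[g]] <- c(sigma_g2 = unname(sg), sigma_a2 = unname(sa),
                  sigma_s2 = unname(ss), sigma_e2 = th[[paste0("resid_", g)]])
  }
  out
}

#' @export
print.gblup <- function(x, ...) {
  cat("GBLUP", if (length(x$traits) == 2) "bivariate" else "single-trait",
      "fit:", paste(x$traits, collapse = " + "),
      if (!is.null(x$A)) "| pedigree term" else "",
      if (x$spatial) "| spatial term" else "", "\n")
  cat(sprintf("%d plots, %d lines in G; logL = %.4f (%s, %d iterations)\n",
              nrow(x$plots), nrow(x$G), x$fit$logLik,
              if (x$fit$converged) "converged" else "NOT converged",
              x$fit$iterations))
  print(x$fit$vc, digits = 4)
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  h <- heritability(object)
  rg <- if (length(object$traits) == 2) genetic_correlation(object) else NA_real_
  structure(list(object = object, herit = h, cor_g = rg),
            class = "summary.gblup")
}

#' @export
print.summary.gblup <- function(x, ...) {
  print(x$object)
  cat("\nHeritability of plot and line means:\n")
  print(x$herit, digits = 3)
  if (!is.na(x$cor_g))
    cat(sprintf("\nGenetic correlation between %s and %s: %.3f\n",
                x$object$traits[1], x$object$traits[2], x$cor_g))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$fit$b

#' @export
logLik.gblup <- function(object, ...) {
  structure(object$fit$logLik, df = length(object$fit$theta),
            nobs = nrow(object$plots), class = "logLik")
}

#' @export
fitted.gblup <- function(object, ...) object$fit$fitted

#' @export
residuals.gblup <- function(object, ...) object$fit$residuals

#' Genomic estimated breeding values
#'
#' Returns EBVs for any set of lines covered by the relationship matrix,
#' including lines without own records (predicted through \code{G}).
#'
#' @param object a [gblup()] fit.
#' @param lines line ids (default: all lines in \code{G}).
#' @param trait which trait's EBV (default: the last, i.e. the prediction
#'   target in a bivariate fit).
#' @param type \code{"genomic"} (default) or \code{"total"}, the sum of the
#'   genomic and pedigree-based additive EBV when a pedigree term was fitted.
#' @param ... unused.
#' @return named numeric vector.
#' @export
predict.gblup <- function(object, lines = NULL, trait = NULL,
                          type = c("genomic", "total"), ...) {
  type <- match.arg(type)
  if (is.null(trait)) trait <- object$traits[length(object$traits)]
  if (!trait %in% object$traits) stop("trait must be one of: ",
                                      paste(object$traits, collapse = ", "))
  g <- object$ebv[, trait]
  if (type == "total" && !is.null(object$A)) {
    a <- object$fit$u$pedigree
    if (!is.null(dim(a))) a <- a[, which(object$traits == trait)]
    g <- g + a[match(names(g), names(a))]
  }
  if (is.null(lines)) return(g)
  miss <- setdiff(lines, names(g))
  if (length(miss) > 0)
    stop("lines not in the relationship matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  g[lines]
}

#' Simulate responses from a fitted GBLUP model
#'
#' Draws new yield vectors at the estimated fixed effects and variance
#' components (fresh genetic, spatial and residual effects each replicate).
#'
#' @param object a [gblup()] fit.
#' @param nsim number of replicate response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with \code{nsim} columns, rows matching the fitted
#'   plot records.
#' @export
simulate.gblup <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  model <- object$fit$model
  th <- theta_of(object)
  mu <- as.numeric(model$X %*% object$fit$b)
  out <- matrix(0, model$n, nsim)
  for (s in seq_len(nsim)) {
    y <- mu
    k <- 1
    for (tinfo in model$info) {
      tm <- tinfo$term
      if (tm$type == "var") {
        y <- y + sqrt(th[k]) * as.numeric(tinfo$W %*% stats::rnorm(ncol(tinfo$W)))
        k <- k + 1
      } else {
        H <- matrix(c(th[k], th[k + 1], th[k + 1], th[k + 2]), 2)
        Uh <- psd_sqrt(H)
        z <- matrix(stats::rnorm(2 * ncol(tinfo$W1)), ncol = 2)
        gz <- z %*% t(Uh)
        y <- y + as.numeric(tinfo$W1 %*% gz[, 1]) + as.numeric(tinfo$W2 %*% gz[, 2])
        k <- k + 3
      }
    }
    for (gname in names(model$resid_groups)) {
      rows <- model$resid_groups[[gname]]
      y[rows] <- y[rows] + stats::rnorm(length(rows),
                                        sd = sqrt(th[[paste0("resid_", gname)]]))
    }
    out[, s] <- y
  }
  colnames(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out)
}

#' @export
plot.gblup <- function(x, trait = NULL, ...) {
  if (is.null(trait)) trait <- x$traits[length(x$traits)]
  sub <- x$plots[x$plots$generation == trait, ]
  ym <- tapply(sub$yield, sub$line, mean)
  g <- predict(x, trait = trait)
  common <- intersect(names(ym), names(g))
  graphics::plot(g[common], ym[common],
                 xlab = sprintf("EBV (%s)", trait),
                 ylab = sprintf("observed line-mean yield (%s)", trait),
                 main = "GBLUP fit", ...)
  graphics::abline(stats::lm(ym[common] ~ g[common]), col = 2)
  invisible(x)
}
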
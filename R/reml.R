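# REML engine for linear mixed models whose covariance is linear in the
# parameters: V(theta) = sum_k theta_k C_k (+ per-group residual diagonals).
# Variance terms contribute C = W W' with W = Z chol(K)'; a two-trait
# covariance block contributes three parameters (v1, cov, v2) with
# C_cov = W1 W2' + W2 W1'. All C_k are symmetric, so traces against the REML
# projection P need only elementwise products: tr(P C) = sum(P * C).

# matrix square root of a PSD covariance: Cholesky when possible,
# eigen-based otherwise (small negative eigenvalues truncated)
psd_sqrt <- function(K) {
  K <- as.matrix(K)
  attributes(K) <- attributes(K)[c("dim", "dimnames")]  # drop S3 classes
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (!is.null(ch)) return(t(ch))
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(ev), length(ev))
}

#' Random term with a single variance
#'
#' @param Z incidence matrix (observations x levels), dense or sparse.
#' @param K covariance structure among levels (relationship matrix), or
#'   \code{NULL} for identity.
#' @param name parameter name (e.g. \code{"genomic"}, \code{"spatial"}).
#' @return term object for [reml_model()].
#' @export
rterm <- function(Z, K = NULL, name = "u") {
  L <- if (is.null(K)) NULL else psd_sqrt(as.matrix(K))
  list(type = "var", Z = Z, L = L, name = name,
       labels = colnames(Z) %||% colnames(K))
}

#' Correlated two-trait random term
#'
#' Effects \code{[u1; u2] ~ N(0, H x K)} (Kronecker) with an unstructured
#' 2x2 \code{H}; \code{Z1} maps observations to levels for trait 1 (zero
#' rows elsewhere) and \code{Z2} for trait 2. Adds three parameters:
#' \code{<name>_v1}, \code{<name>_cov}, \code{<name>_v2}.
#'
#' @param Z1,Z2 incidence matrices over the same level set.
#' @param K shared covariance structure among levels (or NULL for identity).
#' @param name parameter name stem.
#' @return term object for [reml_model()].
#' @export
cterm <- function(Z1, Z2, K = NULL, name = "g") {
  if (ncol(Z1) != ncol(Z2)) stop("Z1 and Z2 must share the same level set")
  L <- if (is.null(K)) NULL else psd_sqrt(as.matrix(K))
  list(type = "cov", Z1 = Z1, Z2 = Z2, L = L, name = name,
       labels = colnames(Z1) %||% colnames(K))
}

#' Assemble a REML model
#'
#' @param y response vector.
#' @param X fixed-effect design matrix; aliased columns are dropped.
#' @param terms list of [rterm()] / [cterm()] objects.
#' @param resid factor splitting records into residual groups with separate
#'   variances (e.g. trait); \code{NULL} for a single residual variance.
#'   Residual covariances across groups are structurally zero.
#' @return object of class \code{"reml_model"}.
#' @export
reml_model <- function(y, X, terms = list(), resid = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("nrow(X) != length(y)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, sort(keep), drop = FALSE]
  }
  if (is.null(resid)) resid <- factor(rep("all", n))
  resid <- droplevels(as.factor(resid))
  ridx <- split(seq_len(n), resid)

  pars <- list(); C <- list(); info <- list()
  for (tm in terms) {
    if (tm$type == "var") {
      W <- as.matrix(if (is.null(tm$L)) tm$Z else tm$Z %*% tm$L)
      C[[length(C) + 1]] <- tcrossprod(W)
      pars[[length(pars) + 1]] <- list(name = tm$name, kind = "var",
                                       q = ncol(W), rows = which(rowSums(abs(W)) > 0))
      info[[length(info) + 1]] <- list(term = tm, W = W)
    } else {
      W1 <- as.matrix(if (is.null(tm$L)) tm$Z1 else tm$Z1 %*% tm$L)
      W2 <- as.matrix(if (is.null(tm$L)) tm$Z2 else tm$Z2 %*% tm$L)
      C[[length(C) + 1]] <- tcrossprod(W1)
      pars[[length(pars) + 1]] <- list(name = paste0(tm$name, "_v1"), kind = "var",
                                       q = ncol(W1), rows = which(rowSums(abs(W1)) > 0))
      C12 <- W1 %*% t(W2)
      C[[length(C) + 1]] <- C12 + t(C12)
      pars[[length(pars) + 1]] <- list(name = paste0(tm$name, "_cov"), kind = "cov",
                                       q = ncol(W1))
      C[[length(C) + 1]] <- tcrossprod(W2)
      pars[[length(pars) + 1]] <- list(name = paste0(tm$name, "_v2"), kind = "var",
                                       q = ncol(W2), rows = which(rowSums(abs(W2)) > 0))
      info[[length(info) + 1]] <- list(term = tm, W1 = W1, W2 = W2)
    }
  }
  for (g in names(ridx)) {
    C[[length(C) + 1]] <- NULL  # residual handled diagonally
    pars[[length(pars) + 1]] <- list(name = paste0("resid_", g), kind = "resid",
                                     q = length(ridx[[g]]), rows = ridx[[g]])
  }
  names(C) <- vapply(pars[seq_along(C)], `[[`, "", "name")
  # cov parameters are constrained against their flanking variances: the
  # 2x2 block [v1 cov; cov v2] must stay PSD
  covcon <- list()
  k <- 1
  nm <- vapply(pars, `[[`, "", "name")
  while (k <= length(pars)) {
    if (pars[[k]]$kind == "cov")
      covcon[[length(covcon) + 1]] <- c(v1 = k - 1L, cov = k, v2 = k + 1L)
    k <- k + 1
  }
  structure(list(y = y, X = X, n = n, p = ncol(X), terms = terms, info = info,
                 C = C, pars = pars, par_names = nm, covcon = covcon,
                 resid_groups = ridx, logdetXtX = determinant(crossprod(X))$modulus[1]),
            class = "reml_model")
}

# V(theta), dense symmetric
build_V <- function(model, theta) {
  V <- matrix(0, model$n, model$n)
  for (k in seq_along(model$pars)) {
    p <- model$pars[[k]]
    if (p$kind == "resid") {
      d <- diag(V)
      d[p$rows] <- d[p$rows] + theta[k]
      diag(V) <- d
    } else {
      V <- V + theta[k] * model$C[[p$name]]
    }
  }
  V
}

#' Restricted log-likelihood
#'
#' \code{logL = -0.5 (log|V| + log|X'V^-1 X| - log|X'X| + y'Py + (n-p) log 2pi)}.
#' The \code{log|X'X|} normalisation makes the value invariant to the choice
#' of (full-rank) fixed-effect parameterisation.
#'
#' @param model a [reml_model()].
#' @param theta named or positional parameter vector (order
#'   \code{model$par_names}).
#' @return scalar restricted log-likelihood.
#' @export
restricted_loglik <- function(model, theta) {
  theta <- theta_order(model, theta)
  V <- build_V(model, theta)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    lmin <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf("V is singular at these parameters (lambda_min = %.3e)", lmin))
  }
  Viy <- backsolve(ch, forwardsolve(t(ch), model$y))
  ViX <- backsolve(ch, forwardsolve(t(ch), model$X))
  XtViX <- crossprod(model$X, ViX)
  chx <- chol(XtViX)
  beta <- backsolve(chx, forwardsolve(t(chx), crossprod(ViX, model$y)))
  yPy <- sum(model$y * Viy) - sum(crossprod(model$X, Viy) * beta)
  ld_V <- 2 * sum(log(diag(ch)))
  ld_X <- 2 * sum(log(diag(chx)))
  -0.5 * (ld_V + ld_X - model$logdetXtX + yPy +
            (model$n - model$p) * log(2 * pi))
}

theta_order <- function(model, theta) {
  if (!is.null(names(theta)) && all(model$par_names %in% names(theta)))
    theta <- theta[model$par_names]
  if (length(theta) != length(model$pars))
    stop("theta must have ", length(model$pars), " parameters (",
         paste(model$par_names, collapse = ", "), ")")
  as.numeric(theta)
}

theta_feasible <- function(model, theta, floor) {
  kinds <- vapply(model$pars, `[[`, "", "kind")
  if (any(theta[kinds != "cov"] < floor * (1 - 1e-9))) return(FALSE)
  for (cc in model$covcon) {
    if (theta[cc["cov"]]^2 > theta[cc["v1"]] * theta[cc["v2"]] * (1 - 1e-10))
      return(FALSE)
  }
  TRUE
}

project_feasible <- function(model, theta, floor) {
  kinds <- vapply(model$pars, `[[`, "", "kind")
  theta[kinds != "cov"] <- pmax(theta[kinds != "cov"], floor)
  for (cc in model$covcon) {
    bound <- sqrt(theta[cc["v1"]] * theta[cc["v2"]]) * (1 - 1e-8)
    theta[cc["cov"]] <- max(min(theta[cc["cov"]], bound), -bound)
  }
  theta
}

# one evaluation of the REML internals at theta; returns NULL if V not PD
reml_eval <- function(model, theta) {
  V <- build_V(model, theta)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  n <- model$n
  Vinv <- chol2inv(ch)
  ViX <- Vinv %*% model$X
  XtViX <- crossprod(model$X, ViX)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(NULL)
  XtViX_inv <- chol2inv(chx)
  P <- Vinv - ViX %*% XtViX_inv %*% t(ViX)
  P <- (P + t(P)) / 2
  Py <- drop(P %*% model$y)
  yPy <- sum(model$y * Py)
  logL <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) -
                    model$logdetXtX + yPy + (n - model$p) * log(2 * pi))
  list(P = P, Py = Py, Vinv = Vinv, XtViX_inv = XtViX_inv, ViX = ViX,
       logL = logL)
}

# one EM iteration. Scalar variances use the standard projected update
# theta + theta^2 (y'PCPy - tr(PC)) / q; a two-trait covariance block H is
# updated jointly as E[v'v | y] / q for the whitened effects v (true EM, so
# the restricted likelihood cannot decrease).
em_step <- function(model, theta, ev, d) {
  prop <- theta
  yPCPy <- colSums(d$tk * ev$Py)
  k <- 1
  for (tinfo in model$info) {
    tm <- tinfo$term
    if (tm$type == "var") {
      prop[k] <- theta[k] +
        theta[k]^2 * (yPCPy[k] - d$trPC[k]) / ncol(tinfo$W)
      k <- k + 1
    } else {
      q <- ncol(tinfo$W1)
      w1 <- drop(crossprod(tinfo$W1, ev$Py))
      w2 <- drop(crossprod(tinfo$W2, ev$Py))
      H <- matrix(c(theta[k], theta[k + 1], theta[k + 1], theta[k + 2]), 2)
      vhat <- cbind(H[1, 1] * w1 + H[1, 2] * w2,
                    H[2, 1] * w1 + H[2, 2] * w2)
      PW1 <- ev$P %*% tinfo$W1
      PW2 <- ev$P %*% tinfo$W2
      trM <- matrix(c(sum(tinfo$W1 * PW1), sum(tinfo$W2 * PW1),
                      sum(tinfo$W1 * PW2), sum(tinfo$W2 * PW2)), 2)
      Hn <- matrix(0, 2, 2)
      for (i in 1:2) for (j in i:2) {
        trCV <- q * H[i, j] - sum(outer(H[i, ], H[j, ]) * trM)
        Hn[i, j] <- Hn[j, i] <- (sum(vhat[, i] * vhat[, j]) + trCV) / q
      }
      prop[k] <- Hn[1, 1]; prop[k + 1] <- Hn[1, 2]; prop[k + 2] <- Hn[2, 2]
      k <- k + 3
    }
  }
  while (k <= length(theta)) {  # residual groups
    prop[k] <- theta[k] +
      theta[k]^2 * (yPCPy[k] - d$trPC[k]) / model$pars[[k]]$q
    k <- k + 1
  }
  prop
}

# score vector and AI matrix at an evaluated point
reml_derivs <- function(model, ev) {
  K <- length(model$pars)
  tk <- matrix(0, model$n, K)
  trPC <- numeric(K)
  dP <- diag(ev$P)
  for (k in seq_len(K)) {
    p <- model$pars[[k]]
    if (p$kind == "resid") {
      trPC[k] <- sum(dP[p$rows])
      v <- numeric(model$n); v[p$rows] <- ev$Py[p$rows]
      tk[, k] <- v
    } else {
      Ck <- model$C[[p$name]]
      trPC[k] <- sum(ev$P * Ck)
      tk[, k] <- Ck %*% ev$Py
    }
  }
  score <- -0.5 * (trPC - colSums(tk * ev$Py))
  AI <- 0.5 * crossprod(tk, ev$P %*% tk)
  list(score = score, AI = (AI + t(AI)) / 2, trPC = trPC, tk = tk)
}

#' Fit variance components by average-information REML
#'
#' AI updates with step-halving; when the AI system is singular or every
#' halved step stays infeasible or decreases the restricted likelihood, an
#' EM-style update (feasibility-projected) is substituted. Variance
#' parameters are floored at \code{1e-8} times the phenotypic variance;
#' two-trait covariance blocks are kept positive semidefinite. Convergence
#' is declared when the largest relative parameter change drops below
#' \code{tol}.
#'
#' @param model a [reml_model()].
#' @param init optional named initial parameter vector. Default: half the
#'   residual phenotypic variance split equally among the random variance
#'   terms, half to the residual(s); covariances start at half the bound.
#' @param max_iter,tol iteration cap and relative-change tolerance.
#' @param verbose print the likelihood path.
#' @return object of class \code{"reml_fit"}: \code{theta} (named),
#'   \code{vc} table with asymptotic SEs, \code{logLik}, \code{converged},
#'   \code{iterations}, and the BLUP solutions from [blup_solve()] at the
#'   final parameters (\code{b}, \code{u}).
#' @export
reml_fit <- function(model, init = NULL, max_iter = 200, tol = 1e-8,
                     verbose = FALSE) {
  kinds <- vapply(model$pars, `[[`, "", "kind")
  K <- length(model$pars)
  # phenotypic variance after fixed effects, overall and per residual group
  r0 <- stats::lm.fit(model$X, model$y)$residuals
  var0 <- max(stats::var(r0), .Machine$double.eps)
  floor_ <- 1e-8 * var0
  if (is.null(init)) {
    n_rand <- sum(kinds == "var")
    theta <- numeric(K)
    for (k in seq_len(K)) {
      p <- model$pars[[k]]
      if (p$kind == "resid") {
        theta[k] <- 0.5 * max(stats::var(r0[p$rows]), floor_)
      } else if (p$kind == "var") {
        v <- if (length(p$rows) > 1) stats::var(r0[p$rows]) else var0
        theta[k] <- 0.5 * max(v, floor_, na.rm = TRUE) / max(n_rand, 1)
      }
    }
    for (cc in model$covcon)
      theta[cc["cov"]] <- 0.5 * sqrt(theta[cc["v1"]] * theta[cc["v2"]])
  } else {
    theta <- theta_order(model, init)
  }
  theta <- project_feasible(model, theta, floor_)

  ev <- reml_eval(model, theta)
  if (is.null(ev)) stop("initial covariance matrix is singular")
  converged <- FALSE; it <- 0; delta_rel <- NA_real_
  AI <- NULL; no_improve <- 0; best_logL <- -Inf
  while (it < max_iter) {
    it <- it + 1
    d <- reml_derivs(model, ev)
    AI <- d$AI
    step <- tryCatch(solve(AI, d$score), error = function(e) NULL)
    if (is.null(step)) {
      # near-singular average information (confounded terms, boundary
      # degeneracy): retry with a Levenberg-style ridge
      for (r in c(1e-8, 1e-6, 1e-4, 1e-2)) {
        ridge <- r * mean(abs(diag(AI))) + 1e-300
        step <- tryCatch(solve(AI + diag(ridge, K), d$score),
                         error = function(e) NULL)
        if (!is.null(step)) break
      }
    }
    used_em <- FALSE
    cand <- NULL; ev_new <- NULL
    if (!is.null(step) && all(is.finite(step))) {
      lam <- 1
      for (h in 1:15) {
        prop <- theta + lam * step
        # parameters pinned at the floor with negative score stay pinned
        pin <- kinds != "cov" & theta <= floor_ * (1 + 1e-6) & d$score < 0
        prop[pin] <- floor_
        prop <- project_feasible(model, prop, floor_)
        if (theta_feasible(model, prop, floor_)) {
          ev_try <- reml_eval(model, prop)
          if (!is.null(ev_try) && is.finite(ev_try$logL) &&
              ev_try$logL >= ev$logL - 1e-6) {
            cand <- prop; ev_new <- ev_try
            break
          }
        }
        lam <- lam / 2
      }
    }
    if (is.null(cand)) {
      used_em <- TRUE
      prop <- project_feasible(model, em_step(model, theta, ev, d), floor_)
      ev_try <- reml_eval(model, prop)
      if (is.null(ev_try)) break  # cannot improve further
      cand <- prop; ev_new <- ev_try
    }
    delta_rel <- sqrt(sum((cand - theta)^2) / max(sum(theta^2), floor_^2))
    if (verbose)
      message(sprintf("iter %3d logL %.8f rel-change %.2e%s", it,
                      ev_new$logL, delta_rel, if (used_em) " [EM]" else ""))
    theta <- cand; ev <- ev_new
    if (delta_rel < tol) { converged <- TRUE; break }
    # stop once the restricted likelihood is stationary: boundary-pinned
    # parameters can keep exchanging tiny amounts forever
    if (ev$logL > best_logL + 1e-9 * max(1, abs(ev$logL))) {
      best_logL <- ev$logL; no_improve <- 0
    } else {
      no_improve <- no_improve + 1
      if (no_improve >= 5) { converged <- TRUE; break }
    }
  }

  se <- rep(NA_real_, K)
  if (!is.null(AI)) {
    AIi <- tryCatch(solve(AI), error = function(e) NULL)
    if (!is.null(AIi)) se <- sqrt(pmax(diag(AIi), 0))
  }
  names(theta) <- model$par_names
  sol <- blup_solve(model, theta, ev = ev)
  structure(list(theta = theta,
                 vc = data.frame(component = model$par_names,
                                 kind = kinds, estimate = theta, se = se,
                                 row.names = NULL),
                 logLik = ev$logL, converged = converged, iterations = it,
                 delta = delta_rel, floor = floor_, AI = AI,
                 b = sol$b, u = sol$u, fitted = sol$fitted,
                 residuals = sol$residuals, model = model),
            class = "reml_fit")
}

#' BLUP solutions at given variance parameters
#'
#' Generalised least squares for the fixed effects,
#' \code{b = (X'V^-1 X)^-1 X'V^-1 y}, and conditional means for every random
#' term, \code{u = Cov(u, y) P y}; equivalent to solving Henderson's mixed
#' model equations at the same parameters.
#'
#' @param model a [reml_model()].
#' @param theta parameter vector.
#' @param ev internal; a pre-computed evaluation.
#' @return list with \code{b} (named by X columns), \code{u} (per term; a
#'   vector for [rterm()]s, a levels x 2 matrix for [cterm()]s),
#'   \code{fitted} (\code{Xb + sum Zu}) and conditional \code{residuals}.
#' @export
blup_solve <- function(model, theta, ev = NULL) {
  theta <- theta_order(model, theta)
  if (is.null(ev)) ev <- reml_eval(model, theta)
  if (is.null(ev)) stop("covariance matrix singular at theta")
  b <- drop(ev$XtViX_inv %*% crossprod(ev$ViX, model$y))
  names(b) <- colnames(model$X)
  u <- list(); fit_rand <- numeric(model$n)
  k <- 1
  for (tinfo in model$info) {
    tm <- tinfo$term
    if (tm$type == "var") {
      w <- drop(crossprod(tinfo$W, ev$Py))
      uh <- theta[k] * (if (is.null(tm$L)) w else as.numeric(tm$L %*% w))
      names(uh) <- tm$labels
      u[[tm$name]] <- uh
      fit_rand <- fit_rand + as.numeric(tm$Z %*% uh)
      k <- k + 1
    } else {
      w1 <- drop(crossprod(tinfo$W1, ev$Py))
      w2 <- drop(crossprod(tinfo$W2, ev$Py))
      h11 <- theta[k]; h12 <- theta[k + 1]; h22 <- theta[k + 2]
      backL <- function(v) if (is.null(tm$L)) v else as.numeric(tm$L %*% v)
      u1 <- backL(h11 * w1 + h12 * w2)
      u2 <- backL(h12 * w1 + h22 * w2)
      U <- cbind(trait1 = u1, trait2 = u2)
      rownames(U) <- tm$labels
      u[[tm$name]] <- U
      fit_rand <- fit_rand + as.numeric(tm$Z1 %*% u1) + as.numeric(tm$Z2 %*% u2)
      k <- k + 3
    }
  }
  fitted <- drop(model$X %*% b) + fit_rand
  list(b = b, u = u, fitted = fitted, residuals = model$y - fitted)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit:", if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations; logL =", format(x$logLik, digits = 8),
      "\n")
  print(x$vc, digits = 4)
  invisible(x)
}
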
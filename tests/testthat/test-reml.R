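# balanced one-way toy: q groups, n per group, random group effect
oneway_data <- function(q = 5, n = 4, mu = 10, vu = 2, ve = 1, seed = 1) {
  set.seed(seed)
  grp <- factor(rep(seq_len(q), each = n))
  y <- mu + rep(rnorm(q, 0, sqrt(vu)), each = n) + rnorm(q * n, 0, sqrt(ve))
  Z <- stats::model.matrix(~ 0 + grp)
  list(y = y, X = matrix(1, q * n, 1), Z = Z, grp = grp, q = q, n = n)
}

test_that("restricted likelihood equals its dense textbook evaluation", {
  d <- oneway_data(4, 1, seed = 2)  # n = 4 observations total
  mod <- reml_model(d$y, d$X, list(rterm(d$Z, NULL, "grp")))
  for (vc in list(c(1, 1), c(0.3, 2.2), c(5, 0.01))) {
    expect_equal(restricted_loglik(mod, vc),
                 dense_reml_loglik(d$y, d$X, list(d$Z), list(NULL),
                                   vc[1], vc[2]),
                 tolerance = 1e-10)
  }
})

test_that("vanishing genetic variance recovers the fixed-model likelihood", {
  d <- oneway_data(3, 4, seed = 3)
  mod <- reml_model(d$y, d$X, list(rterm(d$Z, NULL, "grp")))
  lim <- restricted_loglik(mod, c(1e-14, 1.3))
  fixed_only <- dense_reml_loglik(d$y, d$X, list(), list(), numeric(0), 1.3)
  expect_equal(lim, fixed_only, tolerance = 1e-6)
})

test_that("likelihood is higher at the truth than at a distant point", {
  hits <- 0
  for (s in 1:200) {
    d <- oneway_data(6, 3, vu = 1.5, ve = 0.8, seed = 1000 + s)
    mod <- reml_model(d$y, d$X, list(rterm(d$Z, NULL, "grp")))
    hits <- hits + (restricted_loglik(mod, c(1.5, 0.8)) >
                      restricted_loglik(mod, c(15, 8)))
  }
  expect_gte(hits / 200, 0.95)
})

test_that("REML on balanced one-way data matches the ANOVA closed form", {
  d <- oneway_data(5, 4, vu = 2, ve = 1, seed = 4)
  fit <- reml_fit(reml_model(d$y, d$X, list(rterm(d$Z, NULL, "grp"))))
  expect_true(fit$converged)
  av <- anova(stats::aov(d$y ~ d$grp))
  mse <- av[["Mean Sq"]][2]
  msb <- av[["Mean Sq"]][1]
  expect_equal(unname(fit$theta["resid_all"]), mse, tolerance = 1e-6)
  expect_equal(unname(fit$theta["grp"]), (msb - mse) / d$n, tolerance = 1e-6)
})

test_that("REML matches direct maximization on a 12-observation toy", {
  set.seed(5)
  K <- crossprod(matrix(rnorm(36), 6)) / 6 + diag(6) * 0.5
  dimnames(K) <- list(paste0("l", 1:6), paste0("l", 1:6))
  Z <- stats::model.matrix(~ 0 + factor(rep(1:6, each = 2)))
  X <- cbind(1, rep(c(0, 1), 6))
  y <- as.numeric(X %*% c(5, 1) + Z %*% t(chol(K)) %*% rnorm(6) + rnorm(12, 0, 0.7))
  mod <- reml_model(y, X, list(rterm(Z, K, "gen")))
  fit <- reml_fit(mod)
  # independent route: Nelder-Mead on log variances
  obj <- function(lv) -restricted_loglik(mod, exp(lv))
  opt <- stats::optim(log(c(0.5, 0.5)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(unname(fit$theta), unname(exp(opt$par)), tolerance = 1e-4)
  expect_equal(fit$logLik, -opt$value, tolerance = 1e-8)
})

test_that("null genetic variance is recovered as negligible", {
  # under sigma_u^2 = 0 the unconstrained REML estimate is negative about
  # half the time (then floored) and a small positive value otherwise
  at_floor <- 0; negligible <- 0
  for (s in 1:100) {
    set.seed(2000 + s)
    y <- rnorm(40, 8, 1)
    Z <- stats::model.matrix(~ 0 + factor(rep(1:10, each = 4)))
    fit <- reml_fit(reml_model(y, matrix(1, 40, 1),
                               list(rterm(Z, NULL, "grp"))))
    at_floor <- at_floor + (fit$theta["grp"] <= 10 * fit$floor)
    negligible <- negligible +
      (fit$theta["grp"] <= 0.3 * sum(fit$theta))
  }
  expect_gte(at_floor, 35)
  expect_gte(negligible, 90)
})

test_that("restricted likelihood is invariant to the fixed-effect coding", {
  set.seed(6)
  f <- factor(rep(1:3, each = 5))
  y <- rnorm(15, as.numeric(f))
  Z <- stats::model.matrix(~ 0 + factor(rep(1:5, 3)))
  X_cell <- stats::model.matrix(~ 0 + f)
  X_ref <- stats::model.matrix(~ f)
  m1 <- reml_model(y, X_cell, list(rterm(Z, NULL, "u")))
  m2 <- reml_model(y, X_ref, list(rterm(Z, NULL, "u")))
  for (vc in list(c(0.5, 1), c(2, 0.2)))
    expect_equal(restricted_loglik(m1, vc), restricted_loglik(m2, vc),
                 tolerance = 1e-8)
  f1 <- reml_fit(m1); f2 <- reml_fit(m2)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-6)
})

test_that("estimates are invariant to row permutation of the data", {
  sim <- small_sim(seed = 12, n_sets = 2, lines_per_set = 15, n_markers = 100)
  G <- build_G_pipeline(sim)
  f6 <- sim$plots[sim$plots$generation == "F6", ]
  fit1 <- gblup(f6, G)
  set.seed(7)
  fit2 <- gblup(f6[sample(nrow(f6)), ], G)
  expect_equal(fit1$fit$theta, fit2$fit$theta, tolerance = 1e-8)
  expect_equal(fit1$fit$logLik, fit2$fit$logLik, tolerance = 1e-8)
})

test_that("BLUP solutions satisfy the mixed model equations and GLS", {
  set.seed(8)
  q <- 5
  K <- crossprod(matrix(rnorm(q * q), q)) / q + diag(q) * 0.3
  dimnames(K) <- list(paste0("l", 1:q), paste0("l", 1:q))
  Z <- stats::model.matrix(~ 0 + factor(rep(1:q, 3)))
  X <- cbind(1, rnorm(15))
  y <- as.numeric(X %*% c(3, 0.5) + Z %*% t(chol(K)) %*% rnorm(q) + rnorm(15))
  mod <- reml_model(y, X, list(rterm(Z, K, "gen")))
  vc <- c(gen = 0.8, resid_all = 1.2)
  sol <- blup_solve(mod, vc)

  # dense GLS for fixed effects, conditional mean for the random effect
  V <- vc[1] * Z %*% K %*% t(Z) + diag(vc[2], 15)
  Vi <- solve(V)
  b_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  expect_equal(unname(sol$b), as.numeric(b_gls), tolerance = 1e-8)
  u_cond <- vc[1] * K %*% t(Z) %*% Vi %*% (y - X %*% b_gls)
  expect_equal(unname(sol$u$gen), as.numeric(u_cond), tolerance = 1e-8)

  # Henderson MME residual norm
  lam <- vc[2] / vc[1]
  C <- rbind(cbind(t(X) %*% X, t(X) %*% Z),
             cbind(t(Z) %*% X, t(Z) %*% Z + solve(K) * lam))
  rhs <- c(t(X) %*% y, t(Z) %*% y)
  resid <- C %*% c(sol$b, sol$u$gen) - rhs
  expect_lt(max(abs(resid)), 1e-8)

  # shrinkage limit: overwhelming residual variance flattens the BLUPs
  sol0 <- blup_solve(mod, c(1e-10, 1e6))
  expect_lt(max(abs(sol0$u$gen)), 1e-6)
})

test_that("a diagonal bivariate model reproduces the two univariate fits", {
  sim <- small_sim(seed = 13, n_sets = 2, lines_per_set = 15, n_markers = 150)
  G <- build_G_pipeline(sim)
  p <- as.data.frame(sim$plots)
  p <- p[p$line %in% rownames(G), ]
  fits <- lapply(c("F5", "F6"), function(g) gblup(p, G, generation = g))

  # stacked model with two independent genetic terms (no covariance)
  f5 <- p[p$generation == "F5", ]; f6 <- p[p$generation == "F6", ]
  X5 <- as.matrix(build_fixed_ylt(f5)$X); X6 <- as.matrix(build_fixed_ylt(f6)$X)
  X <- rbind(cbind(X5, matrix(0, nrow(f5), ncol(X6))),
             cbind(matrix(0, nrow(f6), ncol(X5)), X6))
  Z5 <- build_line_incidence(f5, rownames(G))
  Z6 <- build_line_incidence(f6, rownames(G))
  pad <- function(Z, n, top) {
    zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(n, ncol(Z)))
    if (top) rbind(Z, zero) else rbind(zero, Z)
  }
  mod <- reml_model(c(f5$yield, f6$yield), X,
                    list(rterm(pad(Z5, nrow(f6), TRUE), G, "g5"),
                         rterm(pad(Z6, nrow(f5), FALSE), G, "g6")),
                    resid = factor(rep(c("F5", "F6"),
                                       c(nrow(f5), nrow(f6))),
                                   levels = c("F5", "F6")))
  fit <- reml_fit(mod)
  expect_equal(unname(fit$theta["g5"]),
               unname(fits[[1]]$fit$theta["genomic"]), tolerance = 1e-4)
  expect_equal(unname(fit$theta["g6"]),
               unname(fits[[2]]$fit$theta["genomic"]), tolerance = 1e-4)
  expect_equal(unname(fit$theta["resid_F5"]),
               unname(fits[[1]]$fit$theta["resid_F5"]), tolerance = 1e-4)
  expect_equal(unname(fit$theta["resid_F6"]),
               unname(fits[[2]]$fit$theta["resid_F6"]), tolerance = 1e-4)
})

test_that("bivariate fits recover a known genetic correlation", {
  # H = [[1, .7], [.7, 1]], identity level covariance, sigma_e = 1
  rg_hat <- numeric(20)
  for (s in 1:20) {
    set.seed(300 + s)
    q <- 400
    # kinship-like level covariance (a plain identity with one record per
    # level would confound the genetic and residual variances)
    K <- tcrossprod(matrix(rnorm(q * 50), q)) / 50 * 0.5 + diag(q) * 0.5
    Lk <- t(chol(K))
    H <- matrix(c(1, 0.7, 0.7, 1), 2)
    U <- (Lk %*% matrix(rnorm(2 * q), q)) %*% chol(H)
    y1 <- U[, 1] + rnorm(q)
    y2 <- U[, 2] + rnorm(q)
    Z <- Matrix::Diagonal(q)
    zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0), dims = c(q, q))
    mod <- reml_model(c(y1, y2), kronecker(diag(2), matrix(1, q, 1)),
                      list(cterm(rbind(Z, zero), rbind(zero, Z), K, "g")),
                      resid = factor(rep(1:2, each = q)))
    fit <- reml_fit(mod, tol = 1e-6)
    rg_hat[s] <- fit$theta["g_cov"] /
      sqrt(fit$theta["g_v1"] * fit$theta["g_v2"])
  }
  expect_lt(abs(mean(rg_hat) - 0.7), 0.1)
})

test_that("identical traits drive the genetic correlation to the boundary", {
  sim <- small_sim(seed = 14, n_sets = 2, lines_per_set = 15, n_markers = 150)
  G <- build_G_pipeline(sim)
  p <- as.data.frame(sim$plots)
  f6 <- p[p$generation == "F6" & p$line %in% rownames(G), ]
  copy <- f6
  copy$generation <- "F5"
  copy$plot_id <- paste0(copy$plot_id, "c")
  copy$year <- copy$year + 100  # separate YLT levels for the duplicate trait
  fit <- gblup(rbind(copy, f6), G, generation = c("F5", "F6"))
  expect_gt(genetic_correlation(fit), 0.98)
})

test_that("trait-2 EBVs of trait-1-only lines flow through the F5 records", {
  sim <- small_sim(seed = 15, n_sets = 3, lines_per_set = 15, n_markers = 150)
  G <- build_G_pipeline(sim)
  p <- as.data.frame(sim$plots)
  p <- p[p$line %in% rownames(G), ]
  val_lines <- unique(p$line[p$set == 3 & !p$is_check])
  train <- p[!(p$generation == "F6" & p$set == 3), ]
  fit <- gblup(train, G, generation = c("F5", "F6"))
  ebv_full <- predict(fit, trait = "F6")[val_lines]
  # drop the validation lines' F5 records as well
  train2 <- train[!(train$line %in% val_lines & train$generation == "F5"), ]
  fit2 <- gblup(train2, G, generation = c("F5", "F6"))
  ebv_cut <- predict(fit2, trait = "F6")[val_lines]
  expect_true(all(is.finite(ebv_full)) && all(is.finite(ebv_cut)))
  expect_gt(max(abs(ebv_full - ebv_cut)), 1e-6)
})
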
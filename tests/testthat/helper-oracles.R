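# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths.

# Gene-dropping Monte Carlo estimate of numerator relationships under
# selfing: founders receive unique allele labels; each selfing round
# resamples an individual's two alleles from its own pair. Returns the
# estimated relationship matrix plus binomial-style MC standard errors.
gene_drop_A <- function(ped, founder_selfing = 9, n_rep = 1e5) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  al1 <- matrix(0L, n_rep, n)
  al2 <- matrix(0L, n_rep, n)
  next_allele <- 0L
  for (j in seq_len(n)) {
    s <- ped$parent1[j]; d <- ped$parent2[j]
    if (is.na(s) && is.na(d)) {
      a <- matrix(rep(c(next_allele + 1L, next_allele + 2L), each = n_rep), n_rep)
      next_allele <- next_allele + 2L
      cycles <- if (is.na(ped$selfing_cycles[j])) founder_selfing else ped$selfing_cycles[j]
    } else {
      pick <- function(pi) {
        u <- runif(n_rep) < 0.5
        ifelse(u, al1[, pi], al2[, pi])
      }
      a <- cbind(pick(idx[[s]]), pick(idx[[d]]))
      cycles <- ped$selfing_cycles[j]
    }
    for (r in seq_len(cycles)) {
      u1 <- runif(n_rep) < 0.5
      u2 <- runif(n_rep) < 0.5
      new1 <- ifelse(u1, a[, 1], a[, 2])
      new2 <- ifelse(u2, a[, 1], a[, 2])
      a <- cbind(new1, new2)
    }
    al1[, j] <- a[, 1]; al2[, j] <- a[, 2]
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  SE <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) {
      f <- mean(al1[, i] == al2[, i])
      A[i, i] <- 1 + f
      SE[i, i] <- sqrt(f * (1 - f) / n_rep)
    } else {
      # kinship: average IBD over the four allele pairings
      k <- (
        (al1[, i] == al1[, j]) + (al1[, i] == al2[, j]) +
          (al2[, i] == al1[, j]) + (al2[, i] == al2[, j])) / 4
      A[i, j] <- A[j, i] <- 2 * mean(k)
      SE[i, j] <- SE[j, i] <- 2 * sd(k) / sqrt(n_rep)
    }
  }
  list(A = A, SE = SE)
}

# Dense textbook evaluation of the restricted log-likelihood for
# V = sum theta_k Z_k K_k Z_k' + sigma_e^2 I (univariate), normalised the
# same way as the package (|X'X| term, Gaussian constant).
dense_reml_loglik <- function(y, X, Zs, Ks, vars, ve) {
  n <- length(y)
  V <- diag(ve, n)
  for (k in seq_along(Zs)) {
    K <- if (is.null(Ks[[k]])) diag(ncol(Zs[[k]])) else as.matrix(Ks[[k]])
    V <- V + vars[k] * (as.matrix(Zs[[k]]) %*% K %*% t(as.matrix(Zs[[k]])))
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus -
                       determinant(t(X) %*% X)$modulus +
                       t(y) %*% P %*% y + (n - qr(X)$rank) * log(2 * pi)))
}

# small default study used by several test files
small_sim <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_sets = 4, lines_per_set = 24, n_markers = 300, n_founders = 12,
         years = 1, locations = 1, replicates = 2, trial_lines = 12,
         n_checks = 3, seed = seed),
    list(...))
  simulate_study(do.call(sim_config, args))
}

build_G_pipeline <- function(sim, maf = 0.01, linemiss = 0.02) {
  condition_pd(build_G(mean_impute(qc_filter(sim$genotypes, maf, linemiss))))
}
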
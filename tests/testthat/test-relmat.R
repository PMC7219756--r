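test_that("allele frequencies follow the counting definition", {
  g <- genotype_matrix(matrix(c(0, 2, 2, 1, 1, NA), 3, 2,
                              dimnames = list(c("a", "b", "c"), c("m1", "m2"))))
  af <- allele_frequencies(g)
  expect_equal(af$markers$p, c(4 / 6, 2 / 4))
  expect_equal(af$markers$maf, c(1 / 3, 1 / 2))
  expect_equal(af$lines$missing_frac, c(0, 0, 0.5))

  # brute-force loop on a random masked matrix
  set.seed(21)
  m <- matrix(sample(0:2, 40 * 25, replace = TRUE), 40, 25,
              dimnames = list(paste0("l", 1:40), paste0("m", 1:25)))
  m[sample(length(m), 60)] <- NA
  af2 <- allele_frequencies(genotype_matrix(m))
  for (j in 1:25) {
    tot <- 0; nn <- 0
    for (i in 1:40) if (!is.na(m[i, j])) { tot <- tot + m[i, j]; nn <- nn + 1 }
    expect_equal(af2$markers$p[j], tot / (2 * nn))
  }

  zero <- m; zero[, 3] <- NA
  expect_error(allele_frequencies(genotype_matrix(zero)), "zero non-missing")
})

test_that("QC filtering removes lines first, then low-MAF markers", {
  m <- matrix(c(0, 0, 0, 0, 2,   # MAF 0.2 -> kept
                1, 1, 1, 1, 1,   # p = 0.5 -> kept
                0, 0, 0, 0, 0),  # monomorphic -> dropped
              5, 3, dimnames = list(paste0("l", 1:5), paste0("m", 1:3)))
  out <- qc_filter(genotype_matrix(m), maf_min = 0.01, line_missing_max = 0.02)
  expect_equal(colnames(out), c("m1", "m2"))

  # brute-force refilter on a random matrix with missingness
  set.seed(31)
  m2 <- matrix(sample(0:2, 50 * 200, replace = TRUE, prob = c(0.8, 0.05, 0.15)),
               50, 200, dimnames = list(paste0("l", 1:50), paste0("m", 1:200)))
  m2[sample(length(m2), 500)] <- NA
  got <- qc_filter(genotype_matrix(m2), maf_min = 0.05, line_missing_max = 0.06)
  keep_lines <- rownames(m2)[sapply(seq_len(nrow(m2)), function(i)
    mean(is.na(m2[i, ])) <= 0.06)]
  keep_markers <- colnames(m2)[sapply(seq_len(ncol(m2)), function(j) {
    v <- m2[keep_lines, j]; v <- v[!is.na(v)]
    if (length(v) == 0) return(FALSE)
    p <- sum(v) / (2 * length(v))
    min(p, 1 - p) >= 0.05
  })]
  expect_identical(rownames(got), keep_lines)
  expect_identical(colnames(got), keep_markers)
  af <- allele_frequencies(got)
  expect_true(all(af$markers$maf >= 0.05))
})

test_that("mean imputation preserves marker means and known cells", {
  g <- genotype_matrix(matrix(c(0, 2, NA, 1, 1, 1), 3, 2,
                              dimnames = list(letters[1:3], c("m1", "m2"))))
  imp <- mean_impute(g)
  expect_equal(unname(imp["c", "m1"]), 1.0)
  expect_false(anyNA(imp))

  nofill <- genotype_matrix(matrix(c(0, 2, 1, 1), 2, 2,
                                   dimnames = list(c("a", "b"), c("m1", "m2"))))
  expect_equal(mean_impute(nofill), unclass(nofill))

  set.seed(41)
  m <- matrix(sample(0:2, 30 * 50, replace = TRUE), 30, 50,
              dimnames = list(paste0("l", 1:30), paste0("m", 1:50)))
  masked <- m; masked[sample(length(m), 100)] <- NA
  imp2 <- mean_impute(genotype_matrix(masked))
  expect_equal(colMeans(imp2), colMeans(masked, na.rm = TRUE), tolerance = 1e-12)
})

test_that("VanRaden G matches forced examples and the naive double loop", {
  m <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "m1"))
  G <- build_G(m)
  expect_equal(unclass(G), matrix(c(2, -2, -2, 2), 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))),
               ignore_attr = TRUE)

  # identical genotype rows give identical relationship rows
  m2 <- matrix(sample(0:2, 3 * 40, replace = TRUE), 3, 40,
               dimnames = list(c("a", "b", "c"), paste0("m", 1:40)))
  m2["b", ] <- m2["a", ]
  G2 <- build_G(m2)
  expect_equal(G2["a", ], G2["b", ])
  expect_equal(G2["a", "a"], G2["a", "b"])

  set.seed(51)
  m3 <- matrix(sample(0:2, 20 * 100, replace = TRUE), 20, 100,
               dimnames = list(paste0("l", 1:20), paste0("m", 1:100)))
  G3 <- build_G(m3)
  p <- colMeans(m3) / 2
  denom <- 2 * sum(p * (1 - p))
  for (i in c(1, 7, 20)) for (j in c(1, 13, 20)) {
    acc <- 0
    for (k in 1:100) acc <- acc + (m3[i, k] - 2 * p[k]) * (m3[j, k] - 2 * p[k])
    expect_equal(G3[i, j], unname(acc / denom), tolerance = 1e-10)
  }
  # centred marker columns make G doubly centred
  expect_lt(abs(sum(G3)), 1e-8)

  expect_error(build_G(matrix(2, 3, 2, dimnames = list(1:3, 1:2))),
               "monomorphic")
})

test_that("selfed-pedigree A matches closed forms and stays in range", {
  ped <- pedigree(data.frame(
    id = c("P1", "P2", "X1", "X2"),
    parent1 = c(NA, NA, "P1", "P1"),
    parent2 = c(NA, NA, "P2", "P2"),
    selfing_cycles = c(9, 9, 0, 4)))
  A <- build_A_selfed(ped)
  expect_identical(A["P1", "P1"], 1.998046875)
  expect_identical(A["X1", "X1"], 1)                   # F1 of unrelated founders
  expect_equal(A["X1", "P1"], 0.5 * 1.998046875)       # 0.999023...
  expect_equal(A["X2", "X2"], 1 + (1 - 0.5^4))         # 4 SSD selfings
  expect_equal(A["X1", "X2"], 0.5 * (A["X1", "P1"] + A["X1", "P2"]))

  # range and PSD invariants on a generated pedigree
  sim <- small_sim(seed = 8, n_sets = 2, lines_per_set = 12, n_markers = 20)
  A2 <- build_A_selfed(sim$pedigree)
  expect_true(all(A2 >= 0 & A2 <= 2 + 1e-12))
  expect_true(all(diag(A2) >= 1 & diag(A2) <= 2))
  expect_gte(min(eigen(unclass(A2), symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_lt(max(abs(A2 - t(A2))), 1e-12)
})

test_that("A matches gene-dropping IBD probabilities on an SSD pedigree", {
  # three generations: founders -> cross+SSD -> cross of two SSD lines
  ped <- pedigree(data.frame(
    id = c("F1", "F2", "F3", "L1", "L2", "L3", "C1", "C2"),
    parent1 = c(NA, NA, NA, "F1", "F1", "F2", "L1", "L1"),
    parent2 = c(NA, NA, NA, "F2", "F2", "F3", "L3", "L2"),
    selfing_cycles = c(9, 9, 9, 4, 4, 4, 2, 2)))
  A <- build_A_selfed(ped)
  set.seed(99)
  gd <- gene_drop_A(ped, n_rep = 2e4)
  tol <- 3 * pmax(gd$SE, 1e-4)
  expect_true(all(abs(A - gd$A) <= tol))
})

test_that("PCoA recovers axis shares consistent with an independent solver", {
  G <- matrix(c(2, -2, -2, 2), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- pcoa(G, n_axes = 1)
  expect_equal(p$variance_explained, 1)
  expect_equal(abs(p$coordinates[, 1]), c(a = sqrt(2), b = sqrt(2)))

  set.seed(61)
  m <- matrix(sample(0:2, 30 * 80, replace = TRUE), 30, 80,
              dimnames = list(paste0("l", 1:30), paste0("m", 1:80)))
  G2 <- build_G(m)
  res <- pcoa(G2, n_axes = 4)
  # independent route: SVD of the double-centred matrix
  n <- nrow(G2); J <- diag(n) - 1 / n
  sv <- svd(J %*% unclass(G2) %*% J)$d
  pos <- sv[sv > max(sv) * 1e-12]
  expect_equal(res$variance_explained, (pos / sum(pos))[1:4], tolerance = 1e-8)

  expect_warning(pcoa(G, n_axes = 5), "truncating")
})

test_that("mean diagonal and PD conditioning behave", {
  expect_equal(mean_diagonal(diag(5)), 1)
  expect_equal(mean_diagonal(matrix(c(2, -2, -2, 2), 2)), 2)
  set.seed(71)
  M <- crossprod(matrix(rnorm(36), 6))
  acc <- 0; for (i in 1:6) acc <- acc + M[i, i]
  expect_equal(mean_diagonal(M), acc / 6)

  pd <- diag(3) + 0.1
  expect_equal(unclass(condition_pd(pd)), pd, ignore_attr = TRUE)
  expect_equal(attr(condition_pd(pd), "bend"), 0)

  m <- matrix(sample(0:2, 3 * 30, replace = TRUE), 3, 30,
              dimnames = list(letters[1:3], paste0("m", 1:30)))
  m[2, ] <- m[1, ]  # duplicated line -> singular G
  Gs <- build_G(m)
  Gc <- condition_pd(Gs, 1e-6)
  expect_gt(attr(Gc, "bend"), 0)
  ev <- eigen(unclass(Gc), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-6 - 1e-10)
})
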
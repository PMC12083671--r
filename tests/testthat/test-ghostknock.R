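test_that("equicorrelated s follows min((M+1)/M * lambda_min, 1) and is PSD", {
  expect_equal(solve_s(regularize_ld(diag(1, 3), shrinkage = 0), M = 1),
               rep(1, 3))
  ld05 <- regularize_ld(matrix(c(1, 0.5, 0.5, 1), 2), shrinkage = 0)
  expect_equal(solve_s(ld05, M = 1), c(1, 1))     # min(2 * 0.5, 1) = 1
  ld09 <- regularize_ld(matrix(c(1, 0.9, 0.9, 1), 2), shrinkage = 0)
  s5 <- solve_s(ld09, M = 5)
  expect_equal(s5, rep(6 / 5 * 0.1, 2), tolerance = 1e-10)
  # joint covariance PSD by the independent full-matrix oracle
  for (M in c(1, 5)) {
    for (seed in 1:3) {
      Sigma <- regularize_ld(random_corr(8, seed = seed))$R
      s <- solve_s(regularize_ld(Sigma, shrinkage = 0), M = M)
      ev <- eigen(joint_covariance(Sigma, s, M), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gte(min(ev), -1e-8)
    }
  }
})

test_that("ldet s stays feasible and beats nothing on log-det only", {
  Sigma <- regularize_ld(random_corr(6, seed = 4))$R
  ld <- regularize_ld(Sigma, shrinkage = 0)
  s <- solve_s(ld, M = 5, method = "ldet")
  expect_true(all(s >= 0 & s <= 1))
  ev <- eigen(joint_covariance(Sigma, s, 5), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("conditional parameters reproduce the closed-form (P, V)", {
  # Sigma = I, s = 1: knockoffs are independent standard normals
  ldI <- regularize_ld(diag(1, 3), shrinkage = 0)
  mI <- conditional_params(ldI, rep(1, 3), M = 2)
  expect_equal(mI$P1, matrix(0, 3, 3))
  expect_equal(knockoff_V(mI), diag(1, 6), tolerance = 1e-10)

  # s = 0: P stacks identities, V = 0, knockoffs equal originals
  ld <- regularize_ld(matrix(c(1, 0.5, 0.5, 1), 2), shrinkage = 0)
  m0 <- conditional_params(ld, c(0, 0), M = 3)
  expect_equal(m0$P1, diag(1, 2))
  expect_equal(knockoff_V(m0), matrix(0, 6, 6), tolerance = 1e-12)
  expect_equal(sample_knockoff_z(c(1.2, -0.7), m0, seed = 1),
               matrix(c(1.2, -0.7), 2, 3), tolerance = 1e-12,
               ignore_attr = TRUE)

  # 2x2 hand inversion: Sigma^{-1} = [[1,-r],[-r,1]] / (1 - r^2)
  r <- 0.5
  Sinv <- matrix(c(1, -r, -r, 1), 2) / (1 - r^2)
  m1 <- conditional_params(ld, c(1, 1), M = 1)
  expect_equal(m1$P1, diag(1, 2) - Sinv, tolerance = 1e-10)
  expect_equal(knockoff_V(m1), 2 * diag(1, 2) - Sinv, tolerance = 1e-10)
})

test_that("V factor reproduces V = I_M x D + J_M x (D - D Sinv D)", {
  Sigma <- regularize_ld(random_corr(5, seed = 9))$R
  ld <- regularize_ld(Sigma, shrinkage = 0)
  for (M in c(1, 2, 5)) {
    s <- solve_s(ld, M = M)
    m <- conditional_params(ld, s, M = M)
    D <- diag(s, 5)
    C <- D - D %*% solve(Sigma) %*% D
    V_direct <- kronecker(diag(1, M), D) + kronecker(matrix(1, M, M), C)
    expect_equal(knockoff_V(m), V_direct, tolerance = 1e-8)
  }
})

test_that("knockoff sampling is deterministic and has the right moments", {
  Sigma <- regularize_ld(matrix(c(1, 0.4, 0.4, 1), 2), shrinkage = 0)
  s <- solve_s(Sigma, M = 3)
  m <- conditional_params(Sigma, s, M = 3)
  z <- c(2, -1)
  expect_identical(sample_knockoff_z(z, m, seed = 7),
                   sample_knockoff_z(z, m, seed = 7))

  # Sigma = I, s = 1: many draws of E have mean 0 and identity covariance.
  # knockoff_genotype_copies on zero rows draws the same noise law row-wise.
  ldI <- regularize_ld(diag(1, 2), shrinkage = 0)
  mI <- conditional_params(ldI, c(1, 1), M = 2)
  n <- 1e5
  copies <- knockoff_genotype_copies(matrix(0, n, 2), mI, seed = 11)
  E <- cbind(copies[[1]], copies[[2]])
  se_mean <- 3 / sqrt(n)
  expect_true(all(abs(colMeans(E)) < se_mean))
  expect_equal(stats::cor(E), diag(1, 4), tolerance = 0.02)
})

test_that("joint second moments match (Sigma, Sigma - D) exchangeability", {
  Sigma <- regularize_ld(random_corr(4, seed = 5))$R
  ld <- regularize_ld(Sigma, shrinkage = 0)
  M <- 3
  s <- solve_s(ld, M = M)
  model <- conditional_params(ld, s, M = M)
  n <- 2e4
  set.seed(3)
  Z <- matrix(rnorm(n * 4), n, 4) %*% chol(Sigma)   # null draws ~ N(0, Sigma)
  copies <- knockoff_genotype_copies(Z, model, seed = 13)
  D <- diag(s, 4)
  tol <- 0.05
  for (mi in seq_len(M)) {
    expect_equal(crossprod(copies[[mi]]) / n, Sigma, tolerance = tol,
                 ignore_attr = TRUE)
    expect_equal(crossprod(copies[[mi]], Z) / n, Sigma - D, tolerance = tol,
                 ignore_attr = TRUE)
  }
  expect_equal(crossprod(copies[[1]], copies[[2]]) / n, Sigma - D,
               tolerance = tol, ignore_attr = TRUE)
})

test_that("importance statistics implement the (kappa, tau, W) definitions", {
  st <- importance_and_W(3, matrix(c(1, -2), 1))
  expect_equal(st$T_orig, 9)
  expect_equal(as.vector(st$T_knock), c(1, 4))
  expect_equal(st$kappa, 0L)
  expect_equal(st$W, 6.5)                  # 9 - median(1, 4) = 9 - 2.5
  expect_equal(st$tau, 6.5)

  st2 <- importance_and_W(1, matrix(c(2, 0), 1))
  expect_equal(st2$W, 0)                   # T = 1 < max T_m = 4
  expect_equal(st2$kappa, 1L)
  expect_equal(st2$tau, 4 - 0.5)           # max 4 minus median of (1, 0)

  st3 <- importance_and_W(sqrt(5), matrix(sqrt(2), 1))
  expect_equal(st3$W, 3)                   # single-knockoff positive part
})

test_that("W is never negative and ties with tau on kappa = 0", {
  set.seed(21)
  for (M in c(1, 2, 5)) {
    z <- rnorm(50)
    zk <- matrix(rnorm(50 * M), 50, M)
    st <- importance_and_W(z, zk)
    expect_true(all(st$W >= 0))
    expect_equal(st$W[st$kappa == 0], st$tau[st$kappa == 0])
    expect_true(all(st$W[st$kappa > 0] == 0))
  }
})

test_that("the multiple-knockoff threshold matches its FDP estimate", {
  one <- structure(list(kappa = 0L, tau = 5, W = 5, M = 5),
                   class = "knockoff_stats")
  expect_true(select_fdr(one, 0.2)$selected)     # (1/5)/1 = 0.2 <= 0.2
  expect_false(select_fdr(one, 0.1)$selected)    # 0.2 > 0.1

  none <- structure(list(kappa = c(1L, 2L), tau = c(0, 0), W = c(0, 0),
                         M = 5), class = "knockoff_stats")
  expect_equal(sum(select_fdr(none, 0.2)$selected), 0)
  expect_error(select_fdr(one, 1.5), "q")
})

test_that("selection is monotone in the target FDR level", {
  set.seed(33)
  z <- c(rnorm(80), rnorm(20, mean = 4))
  zk <- matrix(rnorm(100 * 5), 100, 5)
  st <- importance_and_W(z, zk)
  prev <- rep(FALSE, 100)
  for (q in c(0.01, 0.05, 0.1, 0.2, 0.5)) {
    sel <- select_fdr(st, q)$selected
    expect_true(all(which(prev) %in% which(sel)))   # selection only grows
    prev <- sel
  }
})

test_that("ghostknockoff runs per block and returns a tidy table", {
  Sigma <- regularize_ld(random_corr(12, seed = 6))$R
  ld <- regularize_ld(Sigma, variants = paste0("v", 1:12))
  z <- c(rnorm(10), 5, 6)
  blocks <- list(1:6, 7:12)
  st <- ghostknockoff(z, ld, M = 5, q = 0.2, blocks = blocks, seed = 2)
  expect_named(st$table,
               c("variant_id", "Z", "T", "W", "kappa", "tau", "selected"))
  expect_equal(st$table$T, z^2)
  st_again <- ghostknockoff(z, ld, M = 5, q = 0.2, blocks = blocks, seed = 2)
  expect_identical(st$table, st_again$table)
})
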
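# Independent textbook oracles implemented inline: ordinary least-squares
# score test and logistic IRLS score test, written directly from the
# efficient-score formulas on dense matrices.
ols_score_oracle <- function(y, X, g) {
  b <- solve(crossprod(X), crossprod(X, y))
  r <- y - X %*% b
  sig2 <- sum(r^2) / length(y)
  gp <- g - X %*% solve(crossprod(X), crossprod(X, g))
  sum(gp * r) / sqrt(sig2 * sum(gp^2))
}

logistic_score_oracle <- function(y, X, g) {
  fit <- glm.fit(X, y, family = binomial())
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  U <- sum(g * (y - mu))
  v <- sum(w * g^2) -
    t(g * w) %*% X %*% solve(crossprod(X, X * w)) %*% crossprod(X, g * w)
  U / sqrt(as.numeric(v))
}

test_that("with identity kinship the LMM score test is the OLS score test", {
  set.seed(101)
  n <- 200
  X <- cbind(1, matrix(rnorm(n * 4), n, 4))
  y <- rnorm(n)
  G <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
  fit <- fit_null_lmm(y, X, NULL)
  z_pkg <- lmm_score_test(fit, G)$z
  z_ora <- apply(G, 2, function(g) ols_score_oracle(y, X, g))
  expect_equal(z_pkg, z_ora, tolerance = 1e-8)
  # identical through the fixed-effect interface too
  expect_equal(fixed_effect_test(y, X, G, "linear", "score")$z, z_ora,
               tolerance = 1e-8)
})

test_that("an exact linear fit drives both variance components to zero", {
  set.seed(5)
  n <- 120
  X <- cbind(1, rnorm(n))
  alpha <- c(2, -1)
  y <- as.vector(X %*% alpha)
  kb <- kinship_blocks(printed_phi(), n / 10)
  fit <- fit_null_lmm(y, X, kb)
  expect_lt(fit$theta_hat + fit$sigma2_hat, 1e-12)
  expect_equal(fit$alpha_hat, alpha, tolerance = 1e-6)
})

test_that("the LMM recovers the variance component on gene-dropped families", {
  kb <- toy_families(400, seed = 50)$kinship
  th <- vapply(1:10, function(r) {
    gd <- toy_families(400, seed = 50)
    ph <- simulate_phenotypes(gd$G, numeric(ncol(gd$G)),
                              phenotype_spec("quantitative", theta = 4),
                              kb, seed = 300 + r)
    fit_null_lmm(ph$y, ph$X, kb)$theta_hat
  }, numeric(1))
  expect_lt(abs(median(th) - 4), 0.5)
  expect_true(all(th > 0))
})

test_that("mixed and plain score tests stay calibrated under the null, and
           the plain test is anti-conservative under relatedness", {
  gd <- toy_families(500, seed = 60)
  kb <- gd$kinship
  alpha_mix <- c()
  alpha_naive <- c()
  for (r in 1:3) {
    ph <- simulate_phenotypes(gd$G, numeric(ncol(gd$G)),
                              phenotype_spec("quantitative", theta = 6),
                              kb, seed = 400 + r)
    fit <- fit_null_lmm(ph$y, ph$X, kb)
    alpha_mix <- c(alpha_mix, lmm_score_test(fit, gd$G)$p < 0.05)
    alpha_naive <- c(alpha_naive,
                     fixed_effect_test(ph$y, ph$X, gd$G, "linear",
                                       "score")$p < 0.05)
  }
  # mixed test: type-I error near nominal (3 SE band)
  m <- length(alpha_mix)
  expect_lt(abs(mean(alpha_mix) - 0.05), 3 * sqrt(0.05 * 0.95 / m))
  # naive test inflates under theta = 6 relatedness
  expect_gt(mean(alpha_naive), mean(alpha_mix))
})

test_that("constant dosage yields (p = 1, direction = +1) with a warning", {
  set.seed(8)
  y <- rnorm(50)
  X <- cbind(1, rnorm(50))
  fit <- fit_null_lmm(y, X, NULL)
  expect_warning(res <- lmm_score_test(fit, rep(2, 50)), "monomorphic")
  expect_equal(res$p, 1)
  expect_equal(res$direction, 1)
})

test_that("direction equals the sign of the genotype-residual correlation", {
  set.seed(17)
  n <- 150
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  G <- matrix(rbinom(n * 8, 2, 0.4), n, 8)
  fit <- fit_null_lmm(y, X, NULL)
  res <- lmm_score_test(fit, G)
  r0 <- resid(lm(y ~ X - 1))
  expect_equal(res$direction,
               as.numeric(sign(cor(G, r0))[, 1]))
})

test_that("PQL with theta = 0 reduces to ordinary logistic regression", {
  set.seed(23)
  n <- 400
  X <- cbind(1, rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + 0.5 * X[, 2]))
  G <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
  kb <- kinship_blocks(diag(1, 10), n / 10)
  fit <- fit_null_logistic_mixed(y, X, kb, theta_fixed = 0)
  expect_equal(fit$theta_hat, 0)
  g0 <- glm(y ~ X[, 2], family = binomial())
  expect_equal(unname(fit$alpha_hat), unname(coef(g0)), tolerance = 1e-6)
  z_pkg <- glmm_score_test(fit, G)$z
  z_ora <- apply(G, 2, function(g) logistic_score_oracle(y, X, g))
  expect_equal(z_pkg, z_ora, tolerance = 1e-6)
  # exact equality for the dedicated fixed-effect score test
  expect_equal(fixed_effect_test(y, X, G, "logistic", "score")$z, z_ora,
               tolerance = 1e-8)
})

test_that("PQL estimates a positive, monotone variance component", {
  gd <- toy_families(300, seed = 70)
  kb <- gd$kinship
  th <- sapply(c(1, 7), function(theta_true) {
    vapply(1:5, function(r) {
      ph <- simulate_phenotypes(gd$G, numeric(ncol(gd$G)),
                                phenotype_spec("dichotomous",
                                               theta = theta_true),
                                kb, seed = 500 + 10 * theta_true + r)
      fit_null_logistic_mixed(ph$y, ph$X, kb)$theta_hat
    }, numeric(1))
  })
  expect_true(all(th > 0))
  # attenuated (PQL) but increasing in the true component
  expect_gt(median(th[, 2]), median(th[, 1]))
})

test_that("degenerate binary phenotypes raise separation errors", {
  X <- cbind(1, rnorm(40))
  kb <- kinship_blocks(printed_phi(), 4)
  expect_error(fit_null_logistic_mixed(rep(0, 40), X, kb), "separation")
  # perfectly separating dosage in the fixed-effect fit
  y <- rep(c(0, 1), each = 20)
  g <- rep(c(0, 2), each = 20)
  expect_error(fixed_effect_test(y, X, g, "logistic", "wald"), "separation")
})

test_that("score, Wald and LRT agree asymptotically on linear data", {
  set.seed(31)
  n <- 1e4
  X <- cbind(1, rnorm(n))
  g <- rbinom(n, 2, 0.3)
  y <- 0.04 * g + rnorm(n)
  zs <- sapply(c("score", "wald", "lrt"), function(m) {
    fixed_effect_test(y, X, g, "linear", m)$z
  })
  expect_lt(max(dist(abs(zs))), 0.05)
  # orthogonal-by-construction dosage: score p ~ 1
  r <- resid(lm(y ~ X - 1))
  g_orth <- rnorm(n)
  g_orth <- g_orth -
    cbind(X, r) %*% solve(crossprod(cbind(X, r)), crossprod(cbind(X, r), g_orth))
  expect_gt(fixed_effect_test(y, X, g_orth, "linear", "score")$p, 0.999)
})

test_that("null p-values are uniform for the fixed-effect tests", {
  set.seed(41)
  n <- 2000
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  G <- matrix(rbinom(n * 300, 2, runif(300, 0.05, 0.5)), n, 300,
              byrow = TRUE)
  for (m in c("score", "wald", "lrt")) {
    p <- fixed_effect_test(y, X, G, "linear", m)$p
    expect_gt(ks.test(p, "punif")$p.value, 0.01)
  }
})

test_that("assoc_sumstats wraps tests into a summary-statistic table", {
  gd <- toy_families(50, seed = 80)
  ph <- simulate_phenotypes(gd$G, numeric(ncol(gd$G)),
                            phenotype_spec("quantitative", theta = 2),
                            gd$kinship, seed = 90)
  tab <- assoc_sumstats(ph$y, ph$X, gd$G, test = "mixed_score",
                        family = "linear", Phi = gd$kinship)
  expect_s3_class(tab, "sumstat_table")
  expect_equal(nrow(tab), ncol(gd$G))
  expect_equal(tab$p, 2 * pnorm(-abs(tab$z)), tolerance = 1e-12)
})
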
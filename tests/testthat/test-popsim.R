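test_that("haplotype pools hit their target frequencies and LD regime", {
  pool0 <- generate_haplotype_pool(p = 50, n_hap = 1e4, ld_decay = 0,
                                   seed = 1)
  R0 <- cor(pool0$H)
  adj0 <- R0[cbind(1:(ncol(R0) - 1), 2:ncol(R0))]
  expect_lt(max(abs(adj0)), 0.05)          # independence limit

  expect_true(all(pool0$H %in% c(0L, 1L)))
  emp <- colMeans(pool0$H)
  expect_lt(max(abs(emp - pool0$maf)), 0.02)
  expect_true(all(pmin(emp, 1 - emp) >= 0.01))   # MAF filter

  # determinism and LD ordering
  expect_identical(generate_haplotype_pool(p = 30, n_hap = 200, seed = 3)$H,
                   generate_haplotype_pool(p = 30, n_hap = 200, seed = 3)$H)
  pool9 <- generate_haplotype_pool(p = 50, n_hap = 1e4, ld_decay = 0.97,
                                   seed = 1)
  R9 <- cor(pool9$H)
  adj9 <- R9[cbind(1:(ncol(R9) - 1), 2:ncol(R9))]
  expect_gt(mean(abs(adj9)), mean(abs(adj0)))
})

test_that("unrelated genotypes are HWE dosages from the pool", {
  pool <- toy_pool()
  G <- sample_unrelated_genotypes(pool, 1e4, seed = 2)
  expect_true(all(G %in% 0:2))
  expect_lt(max(abs(colMeans(G) - 2 * colMeans(pool$H))), 0.03)
})

test_that("the pedigree recursion reproduces the printed 10x10 matrix", {
  Phi <- relationship_from_pedigree()
  expect_equal(unname(Phi), printed_phi())
  # named relative pairs
  expect_equal(Phi[3, 7], 0.5)             # parent-offspring
  expect_equal(Phi[3, 4], 0.5)             # full siblings
  expect_equal(Phi[7, 9], 0.125)           # first cousins
  expect_equal(Phi[4, 7], 0.25)            # avuncular
  expect_equal(Phi[1, 7], 0.25)            # grandparent-grandchild
  # founders only -> identity
  founders <- data.frame(id = 1:4, father = 0L, mother = 0L)
  expect_equal(unname(relationship_from_pedigree(founders)), diag(1, 4))
  # out-of-order (cyclic-like) pedigree is rejected
  bad <- data.frame(id = 1:2, father = c(2L, 0L), mother = c(0L, 0L))
  expect_error(relationship_from_pedigree(bad), "order")
})

test_that("gene dropping matches the relationship matrix in expectation", {
  pool <- toy_pool()
  nf <- 4000
  gd <- gene_drop_families(pool, nf, seed = 11)
  expect_true(all(gd$G %in% 0:2))
  # dosage correlation between relative pairs ~ Phi entries
  pairs <- list(c(3, 7, 0.5), c(7, 8, 0.5), c(7, 9, 0.125), c(1, 2, 0))
  js <- which(colMeans(pool$H) > 0.2)[1:5] # common sites: stable correlation
  for (pr in pairs) {
    obs <- mean(vapply(js, function(j) {
      a <- gd$G[gd$member == pr[1], j]
      b <- gd$G[gd$member == pr[2], j]
      cor(a, b)
    }, numeric(1)))
    expect_lt(abs(obs - pr[3]), 0.03)
  }
})

test_that("causal effects explain exactly `a` under the coefficient rule", {
  pool <- toy_pool()
  G <- sample_unrelated_genotypes(pool, 2000, seed = 4)
  beta <- causal_effects(G, n_causal = 10, a = 1, seed = 5)
  causal <- which(beta != 0)
  expect_equal(length(causal), 10)
  v <- apply(G[, causal], 2, var)
  expect_equal(sum(beta[causal]^2 * v), 1, tolerance = 1e-12)
  expect_equal(sum(beta < 0), 5)           # half protective
  expect_equal(sum(beta > 0), 5)
  # dichotomous default a = 2.5 via phenotype_spec
  expect_equal(phenotype_spec("dichotomous")$a, 2.5)
  expect_equal(phenotype_spec("quantitative")$a, 1)
})

test_that("quantitative phenotype variance follows the bookkeeping", {
  pool <- toy_pool()
  G <- sample_unrelated_genotypes(pool, 1e5, seed = 6)[, 1:5]
  ph <- simulate_phenotypes(G, numeric(5),
                            phenotype_spec("quantitative", theta = 0),
                            seed = 7)
  expect_equal(var(ph$y), 9, tolerance = 0.15)    # Var(X1) + Var(eps) = 1 + 8

  # mixed: residual shrinks to 8 - theta; sibling covariance ~ theta / 2
  nf <- 3000
  gd <- gene_drop_families(pool, nf, seed = 8)
  kb <- kinship_blocks(relationship_from_pedigree(), nf)
  ph7 <- simulate_phenotypes(gd$G, numeric(ncol(gd$G)),
                             phenotype_spec("quantitative", theta = 7),
                             kb, seed = 9)
  y7 <- ph7$y
  sib_cov <- cov(y7[gd$member == 7], y7[gd$member == 8])
  expect_lt(abs(sib_cov - 3.5), 0.4)
  expect_equal(var(y7), 9, tolerance = 0.2)       # total variance invariant
  expect_error(simulate_phenotypes(gd$G, numeric(ncol(gd$G)),
                                   phenotype_spec("quantitative",
                                                  theta = 9)),
               "total_var")
})

test_that("intercept calibration hits the target prevalence", {
  expect_equal(calibrate_intercept(rep(0, 10), 0.1), qlogis(0.1),
               tolerance = 1e-5)
  set.seed(10)
  eta <- rnorm(1e5, sd = 2)
  expect_lt(abs(calibrate_intercept(eta, 0.5)), 0.02)  # symmetric eta
  b0 <- calibrate_intercept(eta, 0.1)
  y <- rbinom(1e5, 1, plogis(b0 + eta))
  expect_lt(abs(mean(y) - 0.1), 0.005)
  expect_error(calibrate_intercept(eta, 1.2), "prevalence")
})

test_that("dichotomous phenotypes have ~10% prevalence", {
  pool <- toy_pool()
  G <- sample_unrelated_genotypes(pool, 1e5, seed = 12)
  beta <- causal_effects(G, n_causal = 10, a = 2.5, seed = 13)
  ph <- simulate_phenotypes(G, beta, phenotype_spec("dichotomous"),
                            seed = 14)
  expect_lt(abs(mean(ph$y) - 0.10), 0.005)
})

test_that("ascertainment schemes implement their definitions", {
  gd <- toy_families(400, seed = 15)
  ph <- simulate_phenotypes(gd$G,
                            causal_effects(gd$G, a = 2.5, seed = 16),
                            phenotype_spec("dichotomous", theta = 4),
                            gd$kinship, seed = 17)
  y <- ph$y
  fam <- gd$family

  selC <- sample_scheme("C", fam, y, n_controls = 300, seed = 18)
  case_fams <- unique(fam[y == 1])
  expect_true(all(which(y == 1 & fam %in% case_fams) %in% selC))
  expect_true(all(y[selC] == 1 | !(fam[selC] %in% case_fams)))

  selB <- sample_scheme("B", fam, y, n_case_families = 50,
                        n_control_families = 50, seed = 19)
  expect_equal(length(selB), 10 * 100)     # whole families included

  expect_warning(selA <- sample_scheme("A", fam, y, n_cases = 1e6,
                                       n_controls = 100, seed = 20),
                 "clamped")
  expect_equal(sum(y[selA] == 1), sum(y == 1))   # all cases taken
  expect_error(sample_scheme("C", fam, rep(0, length(y))), "case famil")
})

test_that("the K statistic counts concordant within-family pairs", {
  # toy: one family with (case, case, control): 3 pairs, 1 concordant
  fam <- c(1, 1, 1, 2, 2, 2)
  y <- c(1, 1, 0, 1, 1, 0)
  expect_equal(relatedness_K(1:6, fam, y), 1 / 3)
  # scheme C-style selection: concordance is exactly 1
  gd <- toy_families(400, seed = 15)
  ph <- simulate_phenotypes(gd$G,
                            causal_effects(gd$G, a = 2.5, seed = 16),
                            phenotype_spec("dichotomous", theta = 4),
                            gd$kinship, seed = 17)
  selC <- sample_scheme("C", gd$family, ph$y, n_controls = 300, seed = 21)
  expect_equal(relatedness_K(selC, gd$family, ph$y), 1)
  # singleton selections are a warning, K reported 0
  expect_warning(k0 <- relatedness_K(c(1, 4), fam, y), "K reported")
  expect_equal(k0, 0)
})
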
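# Shared fixtures, built in code. Heavier objects are created once per test
# run and memoized in this environment.
.fixtures <- new.env(parent = emptyenv())

# A random well-conditioned correlation matrix via a factor model.
random_corr <- function(p, k = 3, seed = 1) {
  set.seed(seed)
  L <- matrix(rnorm(p * k), p, k)
  S <- tcrossprod(L) + diag(runif(p, 0.5, 1.5), p)
  d <- sqrt(diag(S))
  S / (d %o% d)
}

# Small haplotype pool shared across popsim/bench tests.
toy_pool <- function() {
  if (is.null(.fixtures$pool)) {
    .fixtures$pool <- generate_haplotype_pool(p = 120, n_hap = 1000,
                                              ld_decay = 0.97, seed = 42)
  }
  .fixtures$pool
}

# Foundation family data (genotypes + kinship blocks) shared across tests.
toy_families <- function(n_families = 300, seed = 7) {
  key <- paste0("fam_", n_families, "_", seed)
  if (is.null(.fixtures[[key]])) {
    gd <- gene_drop_families(toy_pool(), n_families, seed = seed)
    gd$kinship <- kinship_blocks(relationship_from_pedigree(), n_families)
    .fixtures[[key]] <- gd
  }
  .fixtures[[key]]
}

# The kinship matrix as printed for the default three-generation pedigree.
printed_phi <- function() {
  matrix(c(
    1, 0, 0.5, 0.5, 0, 0, 0.25, 0.25, 0.25, 0.25,
    0, 1, 0.5, 0.5, 0, 0, 0.25, 0.25, 0.25, 0.25,
    0.5, 0.5, 1, 0.5, 0, 0, 0.5, 0.5, 0.25, 0.25,
    0.5, 0.5, 0.5, 1, 0, 0, 0.25, 0.25, 0.5, 0.5,
    0, 0, 0, 0, 1, 0, 0.5, 0.5, 0, 0,
    0, 0, 0, 0, 0, 1, 0, 0, 0.5, 0.5,
    0.25, 0.25, 0.5, 0.25, 0.5, 0, 1, 0.5, 0.125, 0.125,
    0.25, 0.25, 0.5, 0.25, 0.5, 0, 0.5, 1, 0.125, 0.125,
    0.25, 0.25, 0.25, 0.5, 0, 0.5, 0.125, 0.125, 1, 0.5,
    0.25, 0.25, 0.25, 0.5, 0, 0.5, 0.125, 0.125, 0.5, 1
  ), 10, 10, byrow = TRUE)
}

# Full joint covariance of (Z, Ztilde^1..M) implied by (Sigma, s): an
# independent construction used as the oracle for the knockoff model.
joint_covariance <- function(Sigma, s, M) {
  p <- nrow(Sigma)
  D <- diag(s, p)
  J <- matrix(1, M + 1, M + 1)
  kronecker(diag(1, M + 1), D) + kronecker(J, Sigma - D)
}
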
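# Synthetic-data engine: haplotype pool, pedigree gene dropping, kinship,
# mixed-model phenotypes, case-control ascertainment schemes and the K
# relatedness statistic.

#' Generate a synthetic haplotype pool with block-correlated LD
#'
#' Haplotypes are produced by thresholding a stationary first-order
#' autoregressive latent Gaussian process: for haplotype h, the latent
#' series follows `x_j = rho x_{j-1} + sqrt(1-rho^2) e_j` with
#' `rho = ld_decay`, and the allele at site j is `1{x_j < qnorm(maf_j)}`,
#' so each column hits its target allele frequency while neighboring sites
#' are positively correlated. Columns whose empirical minor-allele frequency
#' falls below 0.01 are dropped (the usual MAF filter before association
#' testing).
#'
#' @param p number of variant sites before the MAF filter.
#' @param n_hap number of haplotypes in the pool.
#' @param maf_dist function of one argument `m` returning `m` target allele
#'   frequencies; the default draws log-uniform frequencies in
#'   \[0.005, 0.5\], giving a rare-skewed site-frequency spectrum.
#' @param ld_decay latent AR(1) coefficient in \[0, 1); 0 gives independent
#'   sites, values near 1 give long runs of tightly linked variants. The
#'   default 0.97 is chosen so that, after the attenuation from thresholding
#'   the latent process to binary alleles, roughly one variant in five joins
#'   a multi-variant cluster at the |r| = 0.75 pruning cutoff.
#' @param seed integer seed.
#' @return an object of class `haplotype_pool`: list with `H` (n_hap x p'
#'   binary matrix after filtering), `maf` (target frequencies of retained
#'   columns), `ld_decay`, `variants` (identifiers `s1, s2, ...` by original
#'   site index).
#' @export
generate_haplotype_pool <- function(p = 1000, n_hap = 10000,
                                    maf_dist = NULL, ld_decay = 0.97,
                                    seed = 1) {
  stopifnot(p >= 1, n_hap >= 1, ld_decay >= 0, ld_decay < 1)
  if (is.null(maf_dist)) {
    maf_dist <- function(m) 10^stats::runif(m, log10(0.005), log10(0.5))
  }
  set.seed(seed)
  maf <- maf_dist(p)
  X <- matrix(stats::rnorm(n_hap * p), n_hap, p)
  if (ld_decay > 0 && p > 1) {
    rho <- ld_decay
    sd_innov <- sqrt(1 - rho^2)
    for (j in 2:p) X[, j] <- rho * X[, j - 1] + sd_innov * X[, j]
  }
  H <- matrix(0L, n_hap, p)
  thr <- stats::qnorm(maf)
  for (j in seq_len(p)) H[, j] <- as.integer(X[, j] < thr[j])
  freq <- colMeans(H)
  keep <- pmin(freq, 1 - freq) >= 0.01
  structure(list(H = H[, keep, drop = FALSE], maf = maf[keep],
                 ld_decay = ld_decay,
                 variants = paste0("s", which(keep))),
            class = "haplotype_pool")
}

#' LD (correlation) matrix of a haplotype pool
#'
#' Pearson correlation between allele indicators across pool haplotypes;
#' under random mating this equals the genotype-dosage correlation, so the
#' pool acts as the external LD reference panel.
#'
#' @param pool a `haplotype_pool`.
#' @param shrinkage passed to [regularize_ld()].
#' @return an `ld_matrix`.
#' @export
pool_ld <- function(pool, shrinkage = "auto") {
  R <- stats::cor(pool$H)
  regularize_ld(R, shrinkage = shrinkage, variants = pool$variants)
}

#' Sample unrelated genotypes from a haplotype pool
#'
#' Each individual is the sum of two haplotypes drawn uniformly with
#' replacement, giving dosages in \{0, 1, 2\}.
#'
#' @param pool a `haplotype_pool`.
#' @param n number of individuals.
#' @param seed integer seed.
#' @return n x p integer dosage matrix.
#' @export
sample_unrelated_genotypes <- function(pool, n, seed = 1) {
  set.seed(seed)
  n_hap <- nrow(pool$H)
  i1 <- sample.int(n_hap, n, replace = TRUE)
  i2 <- sample.int(n_hap, n, replace = TRUE)
  pool$H[i1, , drop = FALSE] + pool$H[i2, , drop = FALSE]
}

#' The default three-generation, ten-member pedigree
#'
#' Members 1 and 2 are founding grandparents; 3 and 4 are their children
#' (full siblings); 5 and 6 are unrelated married-in second-generation
#' parents; 7 and 8 are children of the 3 x 5 couple and 9 and 10 of the
#' 4 x 6 couple. Father/mother id 0 marks a founder.
#'
#' @return data.frame with columns `id`, `father`, `mother`, `generation`.
#' @export
default_pedigree <- function() {
  data.frame(
    id = 1:10,
    father = c(0L, 0L, 1L, 1L, 0L, 0L, 3L, 3L, 4L, 4L),
    mother = c(0L, 0L, 2L, 2L, 0L, 0L, 5L, 5L, 6L, 6L),
    generation = c(1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L)
  )
}

#' Read a pedigree file
#'
#' Four whitespace- or tab-delimited columns: family, id, father, mother
#' (0 = founder). Only the structure of the first family is used when a
#' single pedigree is expected.
#'
#' @param path file path.
#' @return data.frame with `family`, `id`, `father`, `mother`.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE,
                           col.names = c("family", "id", "father", "mother"))
  ped
}

.check_pedigree <- function(ped) {
  ids <- ped$id
  if (anyDuplicated(ids)) stop("duplicate pedigree ids")
  for (k in seq_len(nrow(ped))) {
    for (par in c(ped$father[k], ped$mother[k])) {
      if (par != 0) {
        pk <- match(par, ids)
        if (is.na(pk)) stop("unknown parent id ", par)
        if (pk >= k) stop("pedigree not in parents-before-children order ",
                          "(or cyclic)")
      }
    }
  }
  invisible(ped)
}

#' Additive relationship matrix from a pedigree
#'
#' Standard recursion over members listed parents-first: founders are
#' mutually unrelated with diagonal 1; for a non-founder j,
#' `Phi[i, j] = (Phi[i, father(j)] + Phi[i, mother(j)]) / 2` and
#' `Phi[j, j] = 1 + Phi[father(j), mother(j)] / 2`. For non-inbred pedigrees
#' the diagonal is exactly 1 (parent-offspring and full-sibling entries 0.5,
#' avuncular 0.25, first cousins 0.125).
#'
#' @param ped data.frame with `id`, `father`, `mother` (0 = founder),
#'   parents listed before children.
#' @return symmetric positive semidefinite relationship matrix.
#' @export
relationship_from_pedigree <- function(ped = default_pedigree()) {
  .check_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$id
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    f <- match(ped$father[j], ids)
    m <- match(ped$mother[j], ids)
    if (ped$father[j] == 0 || ped$mother[j] == 0) {
      A[j, j] <- 1
    } else {
      if (j > 1) {
        for (i in seq_len(j - 1)) {
          A[i, j] <- A[j, i] <- (A[i, f] + A[i, m]) / 2
        }
      }
      A[j, j] <- 1 + A[f, m] / 2
    }
    # founders: off-diagonals stay 0 (matrix initialized to 0)
  }
  dimnames(A) <- list(ids, ids)
  A
}

#' Block-replicated kinship for a set of identical families
#'
#' Wraps one within-family relationship matrix plus a family count; the
#' mixed-model fitters exploit this structure (one small eigendecomposition
#' instead of an n x n one). Rows of the corresponding phenotype/genotype
#' data must be family-major: family 1 members first, then family 2, etc.
#'
#' @param block k x k within-family relationship matrix.
#' @param n_families number of families.
#' @return object of class `kinship_blocks`.
#' @export
kinship_blocks <- function(block, n_families) {
  block <- as.matrix(block)
  stopifnot(nrow(block) == ncol(block), n_families >= 1)
  structure(list(block = block, n_families = n_families,
                 n = nrow(block) * n_families),
            class = "kinship_blocks")
}

#' Gene-drop genotypes for replicated pedigree families
#'
#' Founders receive two haplotypes drawn uniformly from the pool; every
#' non-founder inherits one entire haplotype from each parent, chosen
#' uniformly and independently (zero recombination, appropriate for a short
#' region). Because transmission is whole-haplotype, each carried haplotype
#' is a pool row, and the drop is vectorized across families.
#'
#' @param pool a `haplotype_pool`.
#' @param n_families number of families.
#' @param ped pedigree (default [default_pedigree()]).
#' @param seed integer seed.
#' @return list with `G` (n_families * k x p dosage matrix, family-major
#'   row order), `family` (family index per row), `member` (pedigree member
#'   per row).
#' @export
gene_drop_families <- function(pool, n_families, ped = default_pedigree(),
                               seed = 1) {
  .check_pedigree(ped)
  set.seed(seed)
  k <- nrow(ped)
  n_hap <- nrow(pool$H)
  ids <- ped$id
  # hap index carried by each member: two matrices n_families x k
  hap1 <- matrix(0L, n_families, k)
  hap2 <- matrix(0L, n_families, k)
  for (j in seq_len(k)) {
    if (ped$father[j] == 0 || ped$mother[j] == 0) {
      hap1[, j] <- sample.int(n_hap, n_families, replace = TRUE)
      hap2[, j] <- sample.int(n_hap, n_families, replace = TRUE)
    } else {
      f <- match(ped$father[j], ids)
      m <- match(ped$mother[j], ids)
      from_f1 <- stats::runif(n_families) < 0.5
      from_m1 <- stats::runif(n_families) < 0.5
      hap1[, j] <- ifelse(from_f1, hap1[, f], hap2[, f])
      hap2[, j] <- ifelse(from_m1, hap1[, m], hap2[, m])
    }
  }
  # family-major row order: family f occupies rows (f-1)*k + 1:k
  idx1 <- as.vector(t(hap1))
  idx2 <- as.vector(t(hap2))
  G <- pool$H[idx1, , drop = FALSE] + pool$H[idx2, , drop = FALSE]
  list(G = G,
       family = rep(seq_len(n_families), each = k),
       member = rep(ids, n_families))
}

#' Draw sparse causal effects among candidate variants
#'
#' Selects `n_causal` causal variants uniformly among `candidates`
#' (monomorphic candidates are excluded) and sets
#' `|beta_j| = sqrt(a / (n_causal * Var(G_j)))`, so the total variance
#' explained by the causal variants is `a` when they are uncorrelated.
#' Exactly `floor(n_causal / 2)` effects are protective (negative), the rest
#' risk-increasing, with signs assigned at random.
#'
#' @param G dosage matrix.
#' @param n_causal number of causal variants (default 10).
#' @param a variance explained by causal variants (1 for quantitative,
#'   2.5 for dichotomous traits).
#' @param candidates column indices eligible to be causal (default all).
#' @param seed integer seed.
#' @return numeric vector of length `ncol(G)`; nonzero at causal sites.
#' @export
causal_effects <- function(G, n_causal = 10, a = 1, candidates = NULL,
                           seed = 1) {
  set.seed(seed)
  p <- ncol(G)
  if (is.null(candidates)) candidates <- seq_len(p)
  v <- apply(G[, candidates, drop = FALSE], 2, stats::var)
  candidates <- candidates[v > 0]
  v <- v[v > 0]
  if (length(candidates) < n_causal) stop("not enough polymorphic candidates")
  pick <- sample(seq_along(candidates), n_causal)
  causal <- candidates[pick]
  beta <- numeric(p)
  beta[causal] <- sqrt(a / (n_causal * v[pick]))
  n_neg <- floor(n_causal / 2)
  neg <- sample(causal, n_neg)
  beta[neg] <- -beta[neg]
  beta
}

#' Specification of a simulated phenotype model
#'
#' @param trait `"quantitative"` or `"dichotomous"`.
#' @param theta variance component of the family random effect
#'   (`b ~ N(0, theta * Phi)`); 0 gives the fixed-effect model.
#' @param prevalence target case fraction for dichotomous traits
#'   (default 0.10).
#' @param total_var for quantitative traits, the constant
#'   `Var(b) + Var(eps)` (default 8), so the residual variance is
#'   `total_var - theta` and power is comparable across theta.
#' @param a variance explained by causal variants; default 1 for
#'   quantitative and 2.5 for dichotomous traits.
#' @return list of class `phenotype_spec`.
#' @export
phenotype_spec <- function(trait = c("quantitative", "dichotomous"),
                           theta = 0, prevalence = 0.1, total_var = 8,
                           a = NULL) {
  trait <- match.arg(trait)
  if (is.null(a)) a <- if (trait == "quantitative") 1 else 2.5
  if (trait == "quantitative" && theta > total_var) {
    stop("theta exceeds total_var: residual variance would be negative")
  }
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  structure(list(trait = trait, theta = theta, prevalence = prevalence,
                 total_var = total_var, a = a),
            class = "phenotype_spec")
}

#' Calibrate the logistic intercept to a target prevalence
#'
#' Solves `mean(plogis(beta0 + eta)) == prevalence` over the supplied
#' Monte-Carlo sample of the non-intercept linear predictor `eta`, by
#' bisection to 1e-6.
#'
#' @param eta numeric sample of the linear predictor (>= 1e4 draws
#'   recommended).
#' @param prevalence target case fraction in (0, 1).
#' @return the intercept `beta0`.
#' @export
calibrate_intercept <- function(eta, prevalence = 0.1) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  f <- function(b0) mean(stats::plogis(b0 + eta)) - prevalence
  lo <- -50
  hi <- 50
  if (f(lo) > 0 || f(hi) < 0) stop("prevalence not bracketed")
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate phenotypes under the (mixed) generative model
#'
#' Quantitative: `y = X1 + G beta + b + eps` with `b ~ N(0, theta * Phi)`
#' per family and `eps ~ N(0, total_var - theta)`. Dichotomous:
#' `logit(pi) = beta0 + X1 + G beta + b` for the mixed model (plus an
#' independent `N(0,1)` latent covariate term instead of `b` for the
#' fixed-effect model), with `beta0` calibrated to the target prevalence by
#' [calibrate_intercept()]. `X1 ~ N(0, 1)` is generated internally.
#'
#' @param G dosage matrix (rows family-major when `Phi_blocks` is given).
#' @param beta effect vector from [causal_effects()].
#' @param spec a `phenotype_spec`.
#' @param Phi_blocks a `kinship_blocks` (required when `theta > 0`).
#' @param seed integer seed.
#' @return list with `y`, `X` (intercept + X1 covariate matrix), `eta`
#'   (linear predictor without intercept), and `beta0` (dichotomous only).
#' @export
simulate_phenotypes <- function(G, beta, spec, Phi_blocks = NULL, seed = 1) {
  stopifnot(inherits(spec, "phenotype_spec"))
  set.seed(seed)
  n <- nrow(G)
  X1 <- stats::rnorm(n)
  gb <- as.vector(G %*% beta)
  b <- 0
  if (spec$theta > 0) {
    if (is.null(Phi_blocks)) stop("theta > 0 requires Phi_blocks")
    stopifnot(inherits(Phi_blocks, "kinship_blocks"),
              Phi_blocks$n == n)
    k <- nrow(Phi_blocks$block)
    L <- chol(spec$theta * Phi_blocks$block +
                diag(1e-10, k))              # guard exact singularity
    Bm <- t(L) %*% matrix(stats::rnorm(n), k, Phi_blocks$n_families)
    b <- as.vector(Bm)                       # family-major, matches rows
  }
  X <- cbind(`(Intercept)` = 1, X1 = X1)
  if (spec$trait == "quantitative") {
    eps <- stats::rnorm(n, sd = sqrt(spec$total_var - spec$theta))
    y <- X1 + gb + b + eps
    return(list(y = y, X = X, eta = X1 + gb + b, beta0 = NULL))
  }
  eta <- X1 + gb + b
  if (spec$theta == 0) eta <- eta + stats::rnorm(n)  # latent N(0,1) term
  beta0 <- calibrate_intercept(eta, spec$prevalence)
  y <- stats::rbinom(n, 1, stats::plogis(beta0 + eta))
  list(y = y, X = X, eta = eta, beta0 = beta0)
}

#' Case-control ascertainment schemes on family data
#'
#' Scheme A samples cases and controls individually at random. Scheme B
#' samples whole families: case families (at least one case) and control
#' families (no cases), including every member of a sampled family.
#' Scheme C takes every case belonging to a case family and samples
#' controls only from control families. Quotas exceeding availability are
#' clamped with a warning.
#'
#' @param scheme `"A"`, `"B"`, or `"C"`.
#' @param family family index per individual.
#' @param y binary phenotype per individual.
#' @param n_cases,n_controls individual quotas (schemes A and C).
#' @param n_case_families,n_control_families family quotas (scheme B).
#' @param seed integer seed.
#' @return integer vector of selected row indices.
#' @export
sample_scheme <- function(scheme = c("A", "B", "C"), family, y,
                          n_cases = 5000, n_controls = 5000,
                          n_case_families = 500, n_control_families = 500,
                          seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(length(family) == length(y), all(y %in% c(0, 1)))
  set.seed(seed)
  cases_by_fam <- tapply(y, family, sum)
  case_fams <- as.integer(names(cases_by_fam)[cases_by_fam >= 1])
  control_fams <- as.integer(names(cases_by_fam)[cases_by_fam == 0])
  if (length(case_fams) == 0) stop("no case families in the foundation data")
  clamp <- function(q, avail, what) {
    if (q > avail) {
      warning("quota of ", q, " ", what, " clamped to ", avail)
      avail
    } else q
  }
  if (scheme == "A") {
    cases <- which(y == 1)
    controls <- which(y == 0)
    nc <- clamp(n_cases, length(cases), "cases")
    nk <- clamp(n_controls, length(controls), "controls")
    return(sort(c(sample(cases, nc), sample(controls, nk))))
  }
  if (scheme == "B") {
    ncf <- clamp(n_case_families, length(case_fams), "case families")
    nkf <- clamp(n_control_families, length(control_fams), "control families")
    fams <- c(sample(case_fams, ncf), sample(control_fams, nkf))
    return(which(family %in% fams))
  }
  # scheme C: all cases from case families + controls from control families
  cases <- which(y == 1 & family %in% case_fams)
  ctrl_pool <- which(y == 0 & family %in% control_fams)
  nk <- clamp(n_controls, length(ctrl_pool), "controls")
  sort(c(cases, sample(ctrl_pool, nk)))
}

#' Within-family case-status concordance statistic K
#'
#' For every family with at least two selected members, the fraction of
#' same-family selected pairs sharing case/control status; K is the mean of
#' these fractions over families contributing at least one pair (families
#' with fewer than two selected members carry no pairs and are excluded).
#' Scheme C ascertainment yields K = 1 by construction.
#'
#' @param selection integer indices of ascertained individuals.
#' @param family family index per individual (full data).
#' @param y binary phenotype per individual (full data).
#' @return K in \[0, 1\]; 0 with a warning when no family has a pair.
#' @export
relatedness_K <- function(selection, family, y) {
  stopifnot(length(selection) > 0)
  fam_s <- family[selection]
  y_s <- y[selection]
  conc <- c()
  for (f in unique(fam_s)) {
    yf <- y_s[fam_s == f]
    m <- length(yf)
    if (m < 2) next
    n1 <- sum(yf == 1)
    n0 <- m - n1
    same <- choose(n1, 2) + choose(n0, 2)
    conc <- c(conc, same / choose(m, 2))
  }
  if (length(conc) == 0) {
    warning("no family with >= 2 selected members; K reported as 0")
    return(0)
  }
  mean(conc)
}
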
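# Overlap-aware meta-analysis of per-study Z-scores: study-correlation
# estimation from null-ish LD-pruned variants, power-maximizing nonnegative
# weights from a small quadratic program, and masked combination with
# per-variant normalization preserving unit null variance.

#' Estimate the between-study correlation matrix from Z-scores
#'
#' Sample overlap between studies induces correlation between their null
#' Z-scores. `Cor.S[i, j]` is estimated as the Pearson correlation of
#' `(Z_i, Z_j)` over LD-pruned representative variants that look null in
#' both studies (`|Z| < 1.96`), so the correlation reflects shared samples
#' rather than LD or signal. The estimate is projected to the nearest PSD
#' matrix by eigenvalue clipping and renormalized to unit diagonal.
#'
#' @param Z variants x studies matrix of Z-scores (NA where unobserved),
#'   e.g. from [harmonize_studies()].
#' @param representatives optional row subset (indices or logical) of
#'   LD-pruned cluster representatives; default all rows.
#' @param min_shared minimum usable variants per study pair (default 200).
#' @return L x L correlation matrix `Cor.S`.
#' @export
estimate_study_correlation <- function(Z, representatives = NULL,
                                       min_shared = 200) {
  Z <- as.matrix(Z)
  if (!is.null(representatives)) Z <- Z[representatives, , drop = FALSE]
  L <- ncol(Z)
  CorS <- diag(1, L)
  if (L > 1) {
    for (i in 1:(L - 1)) {
      for (j in (i + 1):L) {
        ok <- !is.na(Z[, i]) & !is.na(Z[, j]) &
          abs(Z[, i]) < 1.96 & abs(Z[, j]) < 1.96
        if (sum(ok) < min_shared) {
          stop("fewer than ", min_shared, " usable variants for study pair (",
               i, ", ", j, ")")
        }
        CorS[i, j] <- CorS[j, i] <- stats::cor(Z[ok, i], Z[ok, j])
      }
    }
  }
  e <- eigen(CorS, symmetric = TRUE)
  if (min(e$values) < 0) {
    CorS <- e$vectors %*% diag(pmax(e$values, 0), L) %*% t(e$vectors)
    d <- sqrt(diag(CorS))
    CorS <- CorS / (d %o% d)
  }
  diag(CorS) <- 1
  (CorS + t(CorS)) / 2
}

#' Power-maximizing nonnegative meta-analysis weights
#'
#' Solves the quadratic program
#' `minimize w' Cor.S w  subject to  sum_l w_l sqrt(n_l) = 1, w >= 0`
#' by active-set iteration on the nonnegativity constraints (closed-form
#' equality-constrained solve on each active set, via the pseudo-inverse so
#' a singular `Cor.S` yields the minimum-norm optimum). For a single study
#' this returns `1 / sqrt(n_1)`; for two independent equal-n studies,
#' `w_1 = w_2 = 1 / (2 sqrt(n))`.
#'
#' @param CorS L x L PSD study-correlation matrix.
#' @param n per-study sample sizes (positive).
#' @return weight vector `w` of length L with KKT residual below 1e-8.
#' @export
optimal_weights <- function(CorS, n) {
  CorS <- as.matrix(CorS)
  L <- nrow(CorS)
  stopifnot(length(n) == L)
  if (all(n <= 0)) stop("all sample sizes are zero: constraint infeasible")
  a <- sqrt(pmax(n, 0))
  free <- a > 0
  for (iter in 1:(2 * L + 2)) {
    Af <- CorS[free, free, drop = FALSE]
    af <- a[free]
    Ainv_a <- MASS::ginv(Af) %*% af
    denom <- as.numeric(crossprod(af, Ainv_a))
    if (denom <= 0) stop("degenerate constraint: cannot normalize weights")
    wf <- as.vector(Ainv_a) / denom
    w <- numeric(L)
    w[free] <- wf
    if (any(wf < -1e-10)) {
      # drop the most negative weight from the free set and re-solve
      drop_idx <- which(free)[which.min(wf)]
      free[drop_idx] <- FALSE
      if (!any(free)) stop("active-set iteration emptied the free set")
      next
    }
    w[w < 0] <- 0
    # KKT: reduced gradient 2(Aw - mu a) must be >= 0 on the active set
    mu <- 2 * as.numeric(crossprod(w, CorS %*% w))   # from a'w = 1
    grad <- 2 * (CorS %*% w) - mu * a
    viol <- which(!free & a > 0 & grad < -1e-8)
    if (length(viol) == 0) return(w)
    free[viol[1]] <- TRUE
  }
  stop("active-set QP did not converge")
}

#' Combine per-study Z-scores into meta-analysis Z-scores
#'
#' `Z_j = h_j * sum_l w_l c_lj Z_lj` with the per-variant normalization
#' `h_j = (sum_{s,t} w_s w_t c_sj c_tj Cor.S_st)^{-1/2}`, where `c_lj` is 1
#' when study l observed variant j. Under the null, with unit-variance
#' per-study Z, `Var(Z_j) = 1` for any observation pattern; a variant
#' observed in a single study passes through unchanged.
#'
#' @param Z variants x studies matrix (NA where unobserved).
#' @param w weights from [optimal_weights()].
#' @param CorS study-correlation matrix.
#' @return list with `z` (meta Z per variant, NA when observed nowhere),
#'   `h` (normalizers), and `n_obs` (studies observing each variant).
#' @export
combine_z <- function(Z, w, CorS) {
  Z <- as.matrix(Z)
  L <- ncol(Z)
  stopifnot(length(w) == L, nrow(CorS) == L)
  mask <- 1 * !is.na(Z)
  Z0 <- Z
  Z0[is.na(Z0)] <- 0
  num <- as.vector(Z0 %*% w)
  A <- diag(w, L) %*% CorS %*% diag(w, L)
  denom <- rowSums((mask %*% A) * mask)
  n_obs <- rowSums(mask)
  none <- n_obs == 0
  if (any(none)) message(sum(none), " variant(s) observed in no study: excluded")
  h <- ifelse(none | denom <= 0, NA_real_, 1 / sqrt(denom))
  list(z = h * num, h = h, n_obs = n_obs)
}

#' Overlap-aware meta-analysis of several summary-statistic tables
#'
#' Harmonizes studies onto one variant list, estimates (or accepts) the
#' study-correlation matrix, solves for the optimal weights, and combines
#' the Z-scores. The result feeds directly into [ghostknockoff()].
#'
#' @param tables list of `sumstat_table`s.
#' @param CorS optional user-supplied study-correlation matrix (skips
#'   estimation).
#' @param representatives optional variant subset used for correlation
#'   estimation (see [estimate_study_correlation()]).
#' @param n per-study sample sizes; default taken from the tables.
#' @return list with `table` (meta `sumstat_table`), `weights`, `CorS`,
#'   `h`, and `mask`.
#' @export
meta_analyze <- function(tables, CorS = NULL, representatives = NULL,
                         n = NULL) {
  harm <- harmonize_studies(tables)
  if (is.null(n)) n <- harm$n
  if (any(is.na(n))) stop("per-study sample sizes unavailable; supply n")
  if (is.null(CorS)) {
    CorS <- estimate_study_correlation(harm$Z, representatives)
  }
  w <- optimal_weights(CorS, n)
  cz <- combine_z(harm$Z, w, CorS)
  keep <- !is.na(cz$z)
  v <- harm$variants[keep, , drop = FALSE]
  tab <- sumstat_table(variant_id = v$variant_id, chrom = v$chrom,
                       pos = v$pos, ref = v$ref, alt = v$alt,
                       z = cz$z[keep], n = sum(n), study_id = "meta")
  list(table = tab, weights = w, CorS = CorS, h = cz$h[keep],
       mask = harm$mask[keep, , drop = FALSE])
}
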
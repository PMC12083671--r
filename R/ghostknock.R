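# Multiple-knockoff construction on the Z-score scale.
#
# For an LD (correlation) matrix Sigma and M knockoff copies, the joint
# covariance of (Z, Ztilde^1, ..., Ztilde^M) is
#   I_{M+1} (x) D  +  J_{M+1} (x) (Sigma - D),   D = diag(s),
# which is PSD iff s >= 0 and (M+1) Sigma - M D >= 0. Knockoff Z-scores are
# drawn from the conditional law Ztilde = P Z + E, E ~ N(0, V), with
#   P = 1_M (x) (I - D Sigma^{-1}),
#   V = I_M (x) D + J_M (x) (D - D Sigma^{-1} D).

#' Solve for the knockoff diagonal s of an LD block
#'
#' `method = "equi"` uses the equicorrelated rule
#' `s_j = min((M+1)/M * lambda_min(Sigma), 1)` for all j. `method = "ldet"`
#' maximizes the log-determinant of the joint covariance by coordinate-wise
#' fixed point (suitable for small blocks). Either way the result is
#' repaired, by repeated shrinking (factor 0.99) and clipping of negatives,
#' until the joint covariance passes a numerical PSD check
#' (`min eigenvalue of (M+1) Sigma - M diag(s) >= -1e-8`).
#'
#' @param ld an `ld_matrix` from [regularize_ld()] (or a correlation matrix).
#' @param M number of knockoff copies (default 5).
#' @param method `"equi"` or `"ldet"`.
#' @return numeric vector `s` in [0, 1]^p.
#' @export
solve_s <- function(ld, M = 5, method = c("equi", "ldet")) {
  method <- match.arg(method)
  ld <- .as_ld(ld)
  Sigma <- ld$R
  p <- nrow(Sigma)
  stopifnot(M >= 1)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  lam_min <- min(ev)
  if (lam_min <= 0) stop("LD matrix must be regularized (min eigenvalue > 0)")
  if (method == "equi") {
    s <- rep(min((M + 1) / M * lam_min, 1), p)
  } else {
    # coordinate fixed point for max { M sum log s_j + log det((M+1)S - M D) }
    s <- rep(min((M + 1) / M * lam_min, 1) * 0.5, p)
    for (it in 1:100) {
      B <- (M + 1) * Sigma - M * diag(s, p)
      Binv_diag <- diag(solve(B))
      s_new <- pmin(pmax(1 / Binv_diag, 1e-8), 1)
      # damp to keep B inside the PSD cone
      s_new <- 0.5 * (s + s_new)
      if (max(abs(s_new - s)) < 1e-6) {
        s <- s_new
        break
      }
      s <- s_new
    }
  }
  joint_min_eig <- function(s) {
    min(eigen((M + 1) * Sigma - M * diag(s, p), symmetric = TRUE,
              only.values = TRUE)$values)
  }
  for (rep_i in 1:2000) {
    if (joint_min_eig(s) >= -1e-8) break
    s <- s * 0.99
    if (rep_i == 2000) stop("knockoff s repair failed: joint covariance not PSD")
  }
  pmax(s, 0)
}

#' Build the knockoff sampling model (s, P, V) for one LD block
#'
#' Computes the conditional-distribution parameters of Eq. `Ztilde = P Z + E`
#' with `E ~ N(0, V)`: `P` stacks M copies of `I - D Sigma^{-1}` and
#' `V = I_M (x) D + J_M (x) (D - D Sigma^{-1} D)` with `D = diag(s)`.
#' The factor of `V` is stored in the structured form used for sampling
#' (an exchangeable rotation across the M copies plus two p x p factors).
#'
#' @param ld an `ld_matrix`.
#' @param s knockoff diagonal from [solve_s()]; `s = 0` gives knockoffs
#'   identical to the originals, `Sigma = I, s = 1` gives independent
#'   standard-normal knockoffs.
#' @param M number of knockoff copies.
#' @return an object of class `knockoff_model` with elements `M`, `s`,
#'   `P1` (the p x p single-copy projection `I - D Sigma^{-1}`), `Q`
#'   (M x M orthonormal rotation, first column `1/sqrt(M)`), `F_shared`
#'   (factor of `(M+1) D - M D Sigma^{-1} D`, the shared-noise component),
#'   `sqrt_s`, and `variants`.
#' @export
conditional_params <- function(ld, s, M = 5) {
  ld <- .as_ld(ld)
  Sigma <- ld$R
  p <- nrow(Sigma)
  stopifnot(length(s) == p, all(s >= 0), M >= 1)
  D <- diag(s, p)
  Sigma_inv <- solve(Sigma)
  P1 <- diag(1, p) - D %*% Sigma_inv
  C_off <- D - D %*% Sigma_inv %*% D        # off-diagonal block of V
  # V in the rotated basis (Q (x) I_p) is block-diagonal:
  #   one block (M+1)D - M D Sigma^{-1} D (shared direction), M-1 blocks D.
  shared <- D + M * C_off
  es <- eigen((shared + t(shared)) / 2, symmetric = TRUE)
  if (min(es$values) < -1e-6) {
    stop("V is not PSD (min eigenvalue ", format(min(es$values)),
         "); use a smaller s")
  }
  F_shared <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), p)
  Q <- qr.Q(qr(cbind(rep(1 / sqrt(M), M), diag(1, M)[, -M, drop = FALSE])))
  # first column must be the equi-weight direction (sign itself is immaterial,
  # but fix it for cross-run determinism)
  if (Q[1, 1] < 0) Q[, 1] <- -Q[, 1]
  structure(list(M = M, s = s, P1 = P1, Q = Q, F_shared = F_shared,
                 sqrt_s = sqrt(s), variants = ld$variants),
            class = "knockoff_model")
}

#' Materialize the full pM x pM conditional covariance V of a knockoff model
#'
#' For checks and small blocks only; sampling never forms this matrix.
#'
#' @param model a `knockoff_model`.
#' @return the pM x pM matrix `V`.
#' @export
knockoff_V <- function(model) {
  p <- length(model$s)
  M <- model$M
  Vrot <- matrix(0, p * M, p * M)
  Vrot[1:p, 1:p] <- model$F_shared %*% t(model$F_shared)
  if (M > 1) {
    for (m in 2:M) {
      idx <- ((m - 1) * p + 1):(m * p)
      Vrot[idx, idx] <- diag(model$s, p)
    }
  }
  QI <- kronecker(model$Q, diag(1, p))
  QI %*% Vrot %*% t(QI)
}

#' Sample M knockoff copies of a Z-score vector
#'
#' Draws `Ztilde = P z + E`, `E ~ N(0, V)`, using the structured factor of
#' `V`. Deterministic given `(z, model, seed)`.
#'
#' @param z numeric Z-score vector, length p.
#' @param model a `knockoff_model`.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return p x M matrix; column m is the m-th knockoff Z-score vector.
#' @export
sample_knockoff_z <- function(z, model, seed = NULL) {
  p <- length(model$s)
  if (length(z) != p) stop("z length does not match the knockoff model")
  if (any(!is.finite(z))) stop("z must be finite")
  if (!is.null(seed)) set.seed(seed)
  M <- model$M
  W <- matrix(stats::rnorm(p * M), p, M)
  W[, 1] <- model$F_shared %*% W[, 1]
  if (M > 1) W[, -1] <- model$sqrt_s * W[, -1, drop = FALSE]
  E <- W %*% t(model$Q)                    # p x M, columns are E^m
  mu <- as.vector(model$P1 %*% z)
  mu + E
}

#' Knockoff importance statistics and the multiple-knockoff W
#'
#' Importance is the squared Z-score: `T = z^2` for originals and
#' `T_m = ztilde_m^2` for each knockoff copy. Per variant, `kappa = 0` when
#' the original beats every knockoff (`T >= max_m T_m`), otherwise the index
#' of the winning knockoff; `tau` is the gap between the top importance and
#' the median of the remaining M values; and
#' `W = (T - median_m T_m) * 1\{T >= max_m T_m\}` (so `W = tau` exactly when
#' `kappa = 0`, else 0). For even M the median is the midpoint convention.
#'
#' @param z numeric Z-score vector.
#' @param z_knock p x M matrix of knockoff Z-scores.
#' @return an object of class `knockoff_stats`: list with `T_orig`, `T_knock`
#'   (p x M), `kappa`, `tau`, `W`, and `M`.
#' @export
importance_and_W <- function(z, z_knock) {
  z_knock <- as.matrix(z_knock)
  p <- length(z)
  stopifnot(nrow(z_knock) == p)
  M <- ncol(z_knock)
  T_orig <- z^2
  T_knock <- z_knock^2
  max_knock <- apply(T_knock, 1, max)
  med_knock <- apply(T_knock, 1, stats::median)
  kappa <- integer(p)
  tau <- numeric(p)
  for (j in seq_len(p)) {
    vals <- c(T_orig[j], T_knock[j, ])
    top <- which.max(vals)
    kappa[j] <- top - 1L                  # 0 = original wins
    tau[j] <- vals[top] - stats::median(vals[-top])
  }
  W <- (T_orig - med_knock) * (T_orig >= max_knock)
  structure(list(T_orig = T_orig, T_knock = T_knock, kappa = kappa,
                 tau = tau, W = W, M = M),
            class = "knockoff_stats")
}

#' Multiple-knockoff selection at a target FDR
#'
#' Applies the (kappa, tau) filter: the data-dependent threshold is the
#' smallest positive tau value `t` such that
#' `(1/M + (1/M) * #\{j: kappa_j >= 1, tau_j >= t\}) /
#'  max(1, #\{j: kappa_j = 0, tau_j >= t\}) <= q`,
#' or `+Inf` (empty selection) when no such `t` exists. A variant is selected
#' iff its original importance beat all knockoffs (`kappa = 0`) and
#' `tau >= threshold`.
#'
#' @param stats a `knockoff_stats` from [importance_and_W()].
#' @param q target FDR in (0, 1).
#' @return `stats` augmented with `q`, `threshold`, and logical `selected`.
#' @export
select_fdr <- function(stats, q = 0.1) {
  if (!is.numeric(q) || q <= 0 || q >= 1) stop("q must be in (0, 1)")
  kappa <- stats$kappa
  tau <- stats$tau
  M <- stats$M
  cand <- sort(unique(tau[tau > 0]))
  threshold <- Inf
  for (t in cand) {
    fdp_hat <- (1 / M + (1 / M) * sum(kappa >= 1 & tau >= t)) /
      max(1, sum(kappa == 0 & tau >= t))
    if (fdp_hat <= q) {
      threshold <- t
      break
    }
  }
  stats$q <- q
  stats$threshold <- threshold
  stats$selected <- kappa == 0 & tau >= threshold
  stats
}

#' GhostKnockoffs inference on a summary-statistic table
#'
#' End-to-end per-block knockoff selection from marginal Z-scores and an LD
#' matrix: for each LD block, build the knockoff model (equicorrelated `s`
#' by default), sample M knockoff Z-score vectors with seed
#' `seed + block_index`, compute importance statistics, then apply the
#' multiple-knockoff filter over all blocks jointly.
#'
#' @param tab a `sumstat_table` with `z` populated, or a plain numeric
#'   Z-score vector.
#' @param ld an `ld_matrix` covering the variants of `tab` in order.
#' @param M number of knockoff copies (default 5).
#' @param q target FDR (default 0.1).
#' @param blocks `NULL` (single block) or a list of index vectors from
#'   [partition_blocks()].
#' @param seed base integer seed.
#' @param method s-solver passed to [solve_s()].
#' @return a `knockoff_stats` with selection fields and a `table`
#'   data.frame (variant_id, Z, T, W, kappa, tau, selected).
#' @export
ghostknockoff <- function(tab, ld, M = 5, q = 0.1, blocks = NULL,
                          seed = 1, method = "equi") {
  z <- if (is.numeric(tab)) tab else tab$z
  ld <- .as_ld(ld)
  p <- length(z)
  stopifnot(nrow(ld$R) == p)
  if (is.null(blocks)) blocks <- list(seq_len(p))
  z_knock <- matrix(NA_real_, p, M)
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    ldb <- regularize_ld(ld$R[idx, idx, drop = FALSE], shrinkage = 0,
                         variants = ld$variants[idx])
    s <- solve_s(ldb, M = M, method = method)
    model <- conditional_params(ldb, s, M = M)
    z_knock[idx, ] <- sample_knockoff_z(z[idx], model, seed = seed + b)
  }
  st <- importance_and_W(z, z_knock)
  st <- select_fdr(st, q = q)
  st$table <- data.frame(
    variant_id = ld$variants,
    Z = z,
    T = st$T_orig,
    W = st$W,
    kappa = st$kappa,
    tau = st$tau,
    selected = st$selected
  )
  st
}

#' Second-order knockoff copies of a genotype matrix
#'
#' Individual-level counterpart of [sample_knockoff_z()], used as a
#' comparator: for a column-standardized genotype matrix `G` with
#' correlation `Sigma`, draws M exchangeable knockoff copies
#' `Gtilde^m = G (I - Sigma^{-1} D) + E^m` with row-wise noise covariance
#' matching the same `(s, P, V)` model.
#'
#' @param G n x p numeric matrix (columns standardized to the scale on which
#'   `Sigma` is the correlation).
#' @param model a `knockoff_model` built from the same `Sigma` and `s`.
#' @param seed integer seed.
#' @return list of M matrices, each n x p.
#' @export
knockoff_genotype_copies <- function(G, model, seed = NULL) {
  p <- length(model$s)
  stopifnot(ncol(G) == p)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(G)
  M <- model$M
  GP <- G %*% t(model$P1)
  noise <- vector("list", M)
  W <- vector("list", M)
  W[[1]] <- matrix(stats::rnorm(n * p), n, p) %*% t(model$F_shared)
  if (M > 1) {
    for (k in 2:M) {
      W[[k]] <- sweep(matrix(stats::rnorm(n * p), n, p), 2, model$sqrt_s, "*")
    }
  }
  out <- vector("list", M)
  for (m in seq_len(M)) {
    E <- matrix(0, n, p)
    for (k in seq_len(M)) E <- E + model$Q[m, k] * W[[k]]
    out[[m]] <- GP + E
  }
  out
}
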
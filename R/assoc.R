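# Single-variant marginal association tests: linear/logistic score tests,
# linear mixed-model (kinship) score test, logistic mixed-model (PQL) score
# test, Wald and likelihood-ratio variants. All mixed-model fits exploit a
# block-replicated kinship structure (identical families) when available.

# --- kinship eigen machinery ------------------------------------------------

# Returns list(transform = function(vector or matrix) -> rotated copy,
#              lambda = eigenvalues of Phi, length n).
.phi_eigen <- function(Phi, n) {
  if (is.null(Phi)) {
    return(list(transform = identity, lambda = rep(1, n)))
  }
  if (inherits(Phi, "kinship_blocks")) {
    stopifnot(Phi$n == n)
    k <- nrow(Phi$block)
    nf <- Phi$n_families
    e <- eigen((Phi$block + t(Phi$block)) / 2, symmetric = TRUE)
    Ut <- t(e$vectors)
    transform <- function(x) {
      if (is.matrix(x)) {
        q <- ncol(x)
        out <- matrix(Ut %*% matrix(x, k, nf * q), n, q)
        dimnames(out) <- dimnames(x)
        out
      } else {
        as.vector(Ut %*% matrix(x, k, nf))
      }
    }
    return(list(transform = transform, lambda = rep(e$values, nf)))
  }
  Phi <- as.matrix(Phi)
  stopifnot(nrow(Phi) == n)
  if (max(abs(Phi - t(Phi))) > 1e-8) stop("Phi must be symmetric")
  e <- eigen((Phi + t(Phi)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("Phi must be positive semidefinite")
  Ut <- t(e$vectors)
  list(transform = function(x) {
    if (is.matrix(x)) Ut %*% x else as.vector(Ut %*% x)
  }, lambda = pmax(e$values, 0))
}

# --- linear mixed model -----------------------------------------------------

#' Fit the null linear mixed model y = X alpha + b + eps
#'
#' Gaussian maximum likelihood with `Cov(y) = theta * Phi + sigma2 * I`,
#' profiled over the heritability-like ratio `h = theta / (theta + sigma2)`
#' on \[0, 1 - 1e-6\] using the eigendecomposition of `Phi`. When `Phi` is a
#' [kinship_blocks()] object (replicated identical families) only the small
#' within-family matrix is decomposed, making biobank-style fits fast. ML
#' (not REML) is used: the residual-variance convention matches the score
#' test's `n`-denominator.
#'
#' @param y quantitative phenotype vector.
#' @param X covariate matrix including an intercept column.
#' @param Phi relationship matrix: `NULL` (identity), a dense symmetric PSD
#'   matrix, or a `kinship_blocks` object.
#' @return object of class `lmm_null`: `alpha_hat`, `theta_hat`,
#'   `sigma2_hat`, `loglik`, plus internals used by [lmm_score_test()].
#' @export
fit_null_lmm <- function(y, X, Phi = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  q <- ncol(X)
  if (n < q + 2) stop("too few observations for the covariate rank")
  pe <- .phi_eigen(Phi, n)
  yt <- pe$transform(y)
  Xt <- pe$transform(X)
  lam <- pe$lambda

  profile <- function(h) {
    d <- h * lam + (1 - h)
    w <- 1 / d
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    alpha <- solve(XtWX, crossprod(XtW, yt))
    r <- yt - Xt %*% alpha
    rss_w <- sum(w * r^2)
    sig_tot <- rss_w / n
    ll <- -0.5 * (n * log(sig_tot) + sum(log(d)) + n + n * log(2 * pi))
    list(ll = ll, alpha = alpha, sig_tot = sig_tot, d = d, r = r)
  }
  if (max(lam) - min(lam) < 1e-12) {
    h_hat <- 0                       # Phi proportional to I: h unidentified
  } else {
    opt <- stats::optimize(function(h) -profile(h)$ll,
                           interval = c(0, 1 - 1e-6), tol = 1e-8)
    h_hat <- opt$minimum
    # compare against the boundary h = 0 explicitly
    if (profile(0)$ll >= profile(h_hat)$ll) h_hat <- 0
  }
  pf <- profile(h_hat)
  theta_hat <- h_hat * pf$sig_tot
  sigma2_hat <- (1 - h_hat) * pf$sig_tot
  d_full <- pf$sig_tot * (h_hat * lam + (1 - h_hat))  # eigenvalues of V-hat
  w_full <- 1 / d_full
  XtVX <- crossprod(Xt, Xt * w_full)
  structure(list(alpha_hat = as.vector(pf$alpha),
                 theta_hat = theta_hat, sigma2_hat = sigma2_hat,
                 h_hat = h_hat, loglik = pf$ll, n = n,
                 transform = pe$transform,
                 w_full = w_full, Xt = Xt,
                 resid_t = as.vector(yt - Xt %*% pf$alpha),
                 XtVX_inv = solve(XtVX)),
            class = "lmm_null")
}

# Numerical floor below which a variant is treated as monomorphic.
.VAR_FLOOR <- 1e-12

# Shared tail: efficient-score variance and the (p, direction, z) table.
.score_from_parts <- function(U, gVg, gVX, XtVX_inv) {
  varU <- gVg - rowSums((gVX %*% XtVX_inv) * gVX)
  z <- rep(0, length(U))
  ok <- varU > .VAR_FLOOR
  if (any(!ok)) warning(sum(!ok), " monomorphic variant(s): p set to 1")
  z[ok] <- U[ok] / sqrt(varU[ok])
  data.frame(p = p_from_z(z),
             direction = ifelse(z >= 0, 1, -1),
             z = z)
}

#' Linear mixed-model score test for one or more variants
#'
#' Efficient score statistic at the null fit:
#' `U = g' Vinv (y - X alpha)`,
#' `var(U) = g' Vinv g - g' Vinv X (X' Vinv X)^{-1} X' Vinv g`,
#' `Z = U / sqrt(var(U))`. With `Phi = NULL` (or theta-hat 0) this equals
#' the ordinary linear-regression score test. Variants with
#' `var(U) <= 1e-12` are flagged monomorphic and reported as `(p = 1, +1)`.
#'
#' @param fit an `lmm_null` from [fit_null_lmm()].
#' @param G dosage vector or n x p matrix.
#' @return data.frame with columns `p`, `direction`, `z` (one row per
#'   variant).
#' @export
lmm_score_test <- function(fit, G) {
  stopifnot(inherits(fit, "lmm_null"))
  G <- as.matrix(G)
  stopifnot(nrow(G) == fit$n)
  Gt <- fit$transform(G)
  GtW <- Gt * fit$w_full
  U <- as.vector(crossprod(Gt, fit$w_full * fit$resid_t))
  gVg <- colSums(GtW * Gt)
  gVX <- crossprod(GtW, fit$Xt)
  .score_from_parts(U, gVg, gVX, fit$XtVX_inv)
}

# --- logistic mixed model (PQL) --------------------------------------------

# Per-family working-covariance helper: V_f = theta * Phi_b + diag(1/w_f).
# One pass accumulates X'VinvX, X'Vinv z, z'Vinv z through triangular solves
# (quad computed from the accumulators, so the loop runs once); the explicit
# per-family inverses are materialized only when `want_vinv` (at the
# converged fit, for the score test).
.pql_gls <- function(theta, zw, X, w, block, nf, want_vinv = FALSE) {
  k <- nrow(block)
  q <- ncol(X)
  XtVX <- matrix(0, q, q)
  XtVz <- numeric(q)
  ztVz <- 0
  logdet <- 0
  Vinv_list <- if (want_vinv) vector("list", nf) else NULL
  for (f in seq_len(nf)) {
    idx <- ((f - 1) * k):((f - 1) * k) + seq_len(k)
    ch <- chol(theta * block + diag(1 / w[idx], k))
    logdet <- logdet + 2 * sum(log(diag(ch)))
    # half-solves: t(ch) %*% h = [X z]
    h <- forwardsolve(ch, cbind(X[idx, , drop = FALSE], zw[idx]),
                      upper.tri = TRUE, transpose = TRUE)
    hX <- h[, seq_len(q), drop = FALSE]
    hz <- h[, q + 1]
    XtVX <- XtVX + crossprod(hX)
    XtVz <- XtVz + crossprod(hX, hz)
    ztVz <- ztVz + sum(hz^2)
    if (want_vinv) Vinv_list[[f]] <- chol2inv(ch)
  }
  alpha <- solve(XtVX, XtVz)
  quad <- ztVz - 2 * sum(alpha * XtVz) +
    as.numeric(crossprod(alpha, XtVX %*% alpha))
  list(alpha = as.vector(alpha), ll = -0.5 * (logdet + quad),
       Vinv_list = Vinv_list, XtVX = XtVX,
       resid = zw - as.vector(X %*% alpha))
}

#' Fit the null logistic mixed model by penalized quasi-likelihood
#'
#' Iterates the logistic working response `zw = eta + (y - mu) / (mu(1-mu))`
#' with weights `w = mu(1-mu)`, fitting at each step the working linear
#' mixed model `zw = X alpha + b + e`, `Cov = theta * Phi + W^{-1}`, with
#' `theta` refreshed by maximizing the working Gaussian likelihood.
#' Converges when successive `alpha` and `theta` change by less than 1e-6.
#'
#' @param y binary 0/1 phenotype.
#' @param X covariate matrix with intercept.
#' @param Phi a `kinship_blocks` object (replicated families) or dense
#'   matrix (treated as one block).
#' @param max_iter outer iteration cap (default 50).
#' @param theta_fixed optionally pin the variance component (e.g. 0 to
#'   reduce the fit to ordinary logistic regression).
#' @return object of class `glmm_null`: `alpha_hat`, `theta_hat`, plus
#'   working-model internals for [glmm_score_test()].
#' @export
fit_null_logistic_mixed <- function(y, X, Phi, max_iter = 50,
                                    theta_fixed = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(all(y %in% c(0, 1)))
  if (stats::var(y) == 0) stop("separation: phenotype is constant")
  if (inherits(Phi, "kinship_blocks")) {
    block <- Phi$block
    nf <- Phi$n_families
  } else {
    block <- as.matrix(Phi)
    nf <- 1L
  }
  stopifnot(nrow(block) * nf == n)
  g0 <- stats::glm.fit(X, y, family = stats::binomial())
  alpha <- g0$coefficients
  eta <- as.vector(X %*% alpha)
  theta <- 0.5
  k <- nrow(block)
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(eta)
    if (any(mu < 1e-10 | mu > 1 - 1e-10)) {
      stop("separation: fitted probabilities pinned at 0/1")
    }
    w <- mu * (1 - mu)
    zw <- eta + (y - mu) / w
    if (is.null(theta_fixed)) {
      # Brent over theta; search the full range first, then a window around
      # the previous estimate (re-widened if the optimum hits its edge)
      interval <- if (it == 1) c(0, 50) else
        c(max(0, theta - 1), theta + 1)
      repeat {
        opt <- stats::optimize(
          function(th) -.pql_gls(th, zw, X, w, block, nf)$ll,
          interval = interval, tol = 1e-7)
        if (opt$minimum < interval[2] - 1e-3 || interval[2] >= 50) break
        interval <- c(interval[1], min(50, interval[2] * 2 + 1))
      }
      theta_new <- opt$minimum
      if (.pql_gls(0, zw, X, w, block, nf)$ll >=
          -opt$objective) theta_new <- 0
    } else {
      theta_new <- theta_fixed
    }
    fitw <- .pql_gls(theta_new, zw, X, w, block, nf)
    alpha_new <- fitw$alpha
    # update random effects and linear predictor: b = theta Phi Vinv resid
    b <- numeric(n)
    if (theta_new > 0) {
      for (f in seq_len(nf)) {
        idx <- ((f - 1) * k + 1):(f * k)
        ch <- chol(theta_new * block + diag(1 / w[idx], k))
        b[idx] <- theta_new * block %*%
          backsolve(ch, forwardsolve(ch, fitw$resid[idx],
                                     upper.tri = TRUE, transpose = TRUE))
      }
    }
    eta_new <- as.vector(X %*% alpha_new) + b
    delta <- max(abs(alpha_new - alpha), abs(theta_new - theta))
    alpha <- alpha_new
    theta <- theta_new
    eta <- eta_new
    if (delta < 1e-6) break
  }
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  zw <- eta + (y - mu) / w
  fitw <- .pql_gls(theta, zw, X, w, block, nf, want_vinv = TRUE)
  structure(list(alpha_hat = alpha, theta_hat = theta, n = n,
                 block = block, n_families = nf,
                 Vinv_list = fitw$Vinv_list,
                 XtVX_inv = solve(fitw$XtVX),
                 resid = fitw$resid, X = X, iterations = it),
            class = "glmm_null")
}

#' Logistic mixed-model score test
#'
#' Score statistic on the converged PQL working model: same efficient-score
#' form as [lmm_score_test()] with `V` the working covariance
#' `theta * Phi + W^{-1}`.
#'
#' @param fit a `glmm_null` from [fit_null_logistic_mixed()].
#' @param G dosage vector or n x p matrix.
#' @return data.frame with columns `p`, `direction`, `z`.
#' @export
glmm_score_test <- function(fit, G) {
  stopifnot(inherits(fit, "glmm_null"))
  G <- as.matrix(G)
  stopifnot(nrow(G) == fit$n)
  p <- ncol(G)
  k <- nrow(fit$block)
  nf <- fit$n_families
  q <- ncol(fit$X)
  U <- numeric(p)
  gVg <- numeric(p)
  gVX <- matrix(0, p, q)
  for (f in seq_len(nf)) {
    idx <- ((f - 1) * k + 1):(f * k)
    Gf <- G[idx, , drop = FALSE]
    VG <- fit$Vinv_list[[f]] %*% Gf              # k x p
    U <- U + as.vector(crossprod(Gf, fit$Vinv_list[[f]] %*% fit$resid[idx]))
    gVg <- gVg + colSums(Gf * VG)
    gVX <- gVX + crossprod(VG, fit$X[idx, , drop = FALSE])
  }
  .score_from_parts(U, gVg, gVX, fit$XtVX_inv)
}

# --- fixed-effect tests -----------------------------------------------------

#' Fixed-effect single-variant association tests
#'
#' Vectorized over the columns of `G`. Linear tests use closed forms after
#' projecting out `X` (score with the ML `n`-denominator residual variance;
#' Wald from the full regression; LRT from the Gaussian deviance
#' `n log(RSS0 / RSS1)`). Logistic score uses the null IRLS fit; logistic
#' Wald/LRT refit `glm` per variant. Direction is the sign of the score /
#' estimated beta. Perfect separation in a logistic fit raises an error.
#'
#' @param y phenotype (quantitative, or binary for `family = "logistic"`).
#' @param X covariate matrix with intercept.
#' @param G dosage vector or n x p matrix.
#' @param family `"linear"` or `"logistic"`.
#' @param method `"score"`, `"wald"`, or `"lrt"`.
#' @return data.frame with columns `p`, `direction`, `z`.
#' @export
fixed_effect_test <- function(y, X, G, family = c("linear", "logistic"),
                              method = c("score", "wald", "lrt")) {
  family <- match.arg(family)
  method <- match.arg(method)
  X <- as.matrix(X)
  G <- as.matrix(G)
  n <- length(y)
  stopifnot(nrow(G) == n, nrow(X) == n)
  if (family == "logistic" && stats::var(y) == 0) {
    stop("separation: phenotype is constant")
  }

  if (family == "linear") {
    XtXi <- solve(crossprod(X))
    H <- X %*% XtXi
    r0 <- y - H %*% crossprod(X, y)            # null residuals
    rss0 <- sum(r0^2)
    Gp <- G - H %*% crossprod(X, G)            # variants projected off X
    cg <- colSums(Gp^2)
    U <- as.vector(crossprod(Gp, r0))
    mono <- cg <= .VAR_FLOOR
    if (any(mono)) warning(sum(mono), " monomorphic variant(s): p set to 1")
    z <- numeric(ncol(G))
    if (method == "score") {
      sig2 <- rss0 / n                          # ML residual variance
      z[!mono] <- U[!mono] / sqrt(sig2 * cg[!mono])
    } else {
      beta <- U / ifelse(mono, 1, cg)
      rss1 <- rss0 - U^2 / ifelse(mono, 1, cg)
      if (method == "wald") {
        sig2_full <- rss1 / (n - ncol(X) - 1)
        z[!mono] <- beta[!mono] / sqrt(sig2_full[!mono] / cg[!mono])
      } else {
        stat <- n * log(rss0 / rss1)
        z[!mono] <- sign(U[!mono]) * sqrt(pmax(stat[!mono], 0))
      }
    }
    return(data.frame(p = p_from_z(z),
                      direction = ifelse(z >= 0, 1, -1), z = z))
  }

  # logistic
  null_fit <- stats::glm.fit(X, y, family = stats::binomial())
  mu <- null_fit$fitted.values
  if (method == "score") {
    w <- mu * (1 - mu)
    U <- as.vector(crossprod(G, y - mu))
    XtWX_inv <- solve(crossprod(X, X * w))
    gVX <- crossprod(G * w, X)
    gVg <- colSums(G * (w * G))
    return(.score_from_parts(U, gVg, gVX, XtWX_inv))
  }
  p_out <- numeric(ncol(G))
  z_out <- numeric(ncol(G))
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    if (stats::var(g) <= .VAR_FLOOR) {
      p_out[j] <- 1
      z_out[j] <- 0
      next
    }
    fit1 <- suppressWarnings(
      stats::glm.fit(cbind(X, g), y, family = stats::binomial())
    )
    mu1 <- fit1$fitted.values
    bg <- fit1$coefficients[ncol(X) + 1]
    if (!fit1$converged || any(mu1 < 1e-8 | mu1 > 1 - 1e-8) && abs(bg) > 15) {
      stop("separation: logistic fit did not stabilize for variant ", j)
    }
    if (method == "wald") {
      cov1 <- solve(crossprod(cbind(X, g), cbind(X, g) * (mu1 * (1 - mu1))))
      z_out[j] <- bg / sqrt(cov1[ncol(X) + 1, ncol(X) + 1])
    } else {
      dev_diff <- null_fit$deviance - fit1$deviance
      z_out[j] <- sign(bg) * sqrt(pmax(dev_diff, 0))
    }
  }
  data.frame(p = p_from_z(z_out),
             direction = ifelse(z_out >= 0, 1, -1), z = z_out)
}

#' Assemble a summary-statistic table from individual-level tests
#'
#' Runs the requested marginal test on every column of `G` and wraps the
#' result as a [sumstat_table()].
#'
#' @param y,X,G as in the test functions.
#' @param variants character identifiers, one per column of `G`.
#' @param test `"score"`, `"mixed_score"`, `"wald"`, or `"lrt"`.
#' @param family `"linear"` or `"logistic"`.
#' @param Phi kinship (required for `mixed_score`).
#' @param chrom,pos,study_id metadata for the output table (positions
#'   default to the column index).
#' @return a `sumstat_table`.
#' @export
assoc_sumstats <- function(y, X, G, variants = NULL,
                           test = c("score", "mixed_score", "wald", "lrt"),
                           family = c("linear", "logistic"),
                           Phi = NULL, chrom = "1", pos = NULL,
                           study_id = "study1") {
  test <- match.arg(test)
  family <- match.arg(family)
  G <- as.matrix(G)
  if (is.null(variants)) variants <- paste0("v", seq_len(ncol(G)))
  if (is.null(pos)) pos <- seq_len(ncol(G))
  res <- if (test == "mixed_score") {
    if (family == "linear") {
      lmm_score_test(fit_null_lmm(y, X, Phi), G)
    } else {
      glmm_score_test(fit_null_logistic_mixed(y, X, Phi), G)
    }
  } else {
    fixed_effect_test(y, X, G, family = family, method = test)
  }
  sumstat_table(variant_id = variants, chrom = chrom, pos = pos,
                ref = "A", alt = "B", z = res$z, n = length(y),
                study_id = study_id)
}
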
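# Shrinkage grid searched by regularize_ld; smallest lambda achieving the
# eigenvalue floor wins.
.SHRINK_GRID <- c(0, 0.001, 0.01, 0.05, 0.1, 0.25)
.EIGEN_FLOOR <- 1e-4

#' Condition an LD correlation matrix for inversion
#'
#' Applies ridge shrinkage toward the identity, `R' = (1 - lambda) R +
#' lambda I`, choosing the smallest `lambda` on the grid
#' \{0, 0.001, 0.01, 0.05, 0.1, 0.25\} for which the smallest eigenvalue is
#' at least 1e-4 (knockoff construction needs `solve(R')`). A numeric
#' `shrinkage` skips the search and is applied as given.
#'
#' @param R symmetric correlation matrix with unit diagonal.
#' @param shrinkage `"auto"` (default) or a fixed value in [0, 1).
#' @param variants optional character vector of variant identifiers.
#' @return an object of class `ld_matrix`: list with elements `R` (the
#'   conditioned matrix), `variants`, `shrinkage` (the lambda used) and
#'   `min_eig`.
#' @export
regularize_ld <- function(R, shrinkage = "auto", variants = NULL) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8) {
    stop("R must be symmetric")
  }
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal")
  R <- (R + t(R)) / 2
  p <- nrow(R)
  if (is.null(variants)) {
    variants <- if (!is.null(rownames(R))) rownames(R) else
      paste0("v", seq_len(p))
  }
  shrink_once <- function(lam) {
    Rs <- (1 - lam) * R
    diag(Rs) <- 1
    Rs
  }
  if (identical(shrinkage, "auto")) {
    lam_used <- NA_real_
    for (lam in .SHRINK_GRID) {
      Rs <- shrink_once(lam)
      me <- min(eigen(Rs, symmetric = TRUE, only.values = TRUE)$values)
      if (me >= .EIGEN_FLOOR) {
        lam_used <- lam
        break
      }
    }
    if (is.na(lam_used)) {
      stop("no grid shrinkage achieves min eigenvalue >= ", .EIGEN_FLOOR)
    }
    Rs <- shrink_once(lam_used)
  } else {
    lam_used <- as.numeric(shrinkage)
    if (lam_used < 0 || lam_used >= 1) stop("shrinkage must be in [0, 1)")
    Rs <- shrink_once(lam_used)
    me <- min(eigen(Rs, symmetric = TRUE, only.values = TRUE)$values)
  }
  me <- min(eigen(Rs, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(R = Rs, variants = variants, shrinkage = lam_used,
                 min_eig = me),
            class = "ld_matrix")
}

.as_ld <- function(ld) {
  if (inherits(ld, "ld_matrix")) return(ld)
  regularize_ld(ld)
}

#' Cluster tightly linked variants by single linkage
#'
#' Agglomerates variants with single linkage on the distance `1 - |r|` and
#' cuts the tree so that no two clusters have absolute cross-correlation
#' above `cutoff` (members of a cluster are chained by links with
#' `|r| >= cutoff`). Absolute correlation is used because the knockoff
#' importance statistic `T = Z^2` is sign-free.
#'
#' @param ld an `ld_matrix` (or a plain correlation matrix).
#' @param cutoff cluster-splitting correlation, default 0.75.
#' @return an object of class `ld_clusters`: list with `cluster` (integer
#'   cluster id per variant, numbered in order of first appearance),
#'   `representative` (logical per variant, filled by
#'   [choose_representatives()]), and `variants`.
#' @export
single_linkage_clusters <- function(ld, cutoff = 0.75) {
  ld <- .as_ld(ld)
  if (abs(cutoff) >= 1) stop("|cutoff| must be < 1")
  p <- nrow(ld$R)
  if (p == 0) stop("empty variant list")
  if (p == 1) {
    cl <- 1L
  } else {
    d <- stats::as.dist(1 - abs(ld$R))
    tree <- stats::hclust(d, method = "single")
    cl <- stats::cutree(tree, h = 1 - cutoff)
    # renumber in order of first appearance for determinism
    cl <- as.integer(factor(cl, levels = unique(cl)))
  }
  structure(list(cluster = cl,
                 representative = rep(FALSE, p),
                 variants = ld$variants),
            class = "ld_clusters")
}

#' Pick one representative variant per LD cluster
#'
#' The representative is the member with the largest sum of absolute
#' within-cluster correlations (diagonal included; it is constant across
#' members so does not affect the argmax). Ties go to the lowest variant
#' index, i.e. lowest position under genomic ordering.
#'
#' @param ld an `ld_matrix`.
#' @param clusters an `ld_clusters` from [single_linkage_clusters()].
#' @return `clusters` with the `representative` flags filled.
#' @export
choose_representatives <- function(ld, clusters) {
  ld <- .as_ld(ld)
  stopifnot(inherits(clusters, "ld_clusters"),
            length(clusters$cluster) == nrow(ld$R))
  A <- abs(ld$R)
  rep_flag <- rep(FALSE, nrow(A))
  for (cid in unique(clusters$cluster)) {
    idx <- which(clusters$cluster == cid)
    sums <- rowSums(A[idx, idx, drop = FALSE])
    rep_flag[idx[which.max(sums)]] <- TRUE   # which.max: first = lowest index
  }
  clusters$representative <- rep_flag
  clusters
}

#' Assign variants to approximately independent LD blocks
#'
#' Blocks are half-open `[start, end)` intervals per chromosome (BED-style).
#' Variants outside every supplied block fall into one residual group per
#' chromosome; with no boundaries at all, each chromosome is one block.
#'
#' @param tab a `sumstat_table` (needs `chrom` and `pos`).
#' @param boundaries `NULL`, or a data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open, non-overlapping within a chromosome).
#' @return list of integer row-index vectors, one per non-empty block, in
#'   genomic order.
#' @export
partition_blocks <- function(tab, boundaries = NULL) {
  if (is.null(boundaries) || nrow(boundaries) == 0) {
    chroms <- unique(tab$chrom)
    return(lapply(chroms, function(ch) which(tab$chrom == ch)))
  }
  boundaries <- boundaries[order(boundaries$chrom, boundaries$start), ]
  for (ch in unique(boundaries$chrom)) {
    b <- boundaries[boundaries$chrom == ch, ]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      stop("overlapping block boundaries on chromosome ", ch)
    }
  }
  lab <- rep(NA_integer_, nrow(tab))
  for (k in seq_len(nrow(boundaries))) {
    hit <- tab$chrom == boundaries$chrom[k] &
      tab$pos >= boundaries$start[k] & tab$pos < boundaries$end[k]
    lab[hit] <- k
  }
  blocks <- lapply(seq_len(nrow(boundaries)), function(k) which(lab == k))
  resid <- lapply(unique(tab$chrom), function(ch) {
    which(is.na(lab) & tab$chrom == ch)
  })
  out <- c(blocks, resid)
  out[vapply(out, length, integer(1)) > 0]
}

#' Read a dense LD matrix with a sidecar variant list
#'
#' The matrix file is whitespace-delimited text (p rows by p columns); the
#' variant file has one identifier per line in matrix order.
#'
#' @param matrix_path,variants_path file paths.
#' @param shrinkage passed to [regularize_ld()].
#' @return an `ld_matrix`.
#' @export
read_ld_matrix <- function(matrix_path, variants_path, shrinkage = "auto") {
  R <- as.matrix(utils::read.table(matrix_path, header = FALSE))
  dimnames(R) <- NULL
  v <- readLines(variants_path)
  v <- v[nzchar(v)]
  if (length(v) != nrow(R)) stop("variant list length != matrix dimension")
  regularize_ld(R, shrinkage = shrinkage, variants = v)
}
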
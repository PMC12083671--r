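# Replicated simulation harness: empirical FDR and power of knockoff
# selection under the pedigree/unrelated genotype scenarios, comparator
# analyses (individual-level knockoffs, meta vs pooled), selection
# reporting, and loci merging.

#' Empirical false discovery proportion and power with cluster credit
#'
#' A selected representative counts as a true positive iff its LD cluster
#' contains a causal variant; power is the fraction of causal variants whose
#' cluster representative was selected. The empty selection yields (0, 0).
#'
#' @param selected indices of selected variants.
#' @param causal indices of causal variants.
#' @param cluster integer cluster id per variant (same indexing).
#' @return list with `fdp` and `power`.
#' @export
empirical_fdr_power <- function(selected, causal, cluster) {
  causal_cl <- cluster[causal]
  sel_cl <- cluster[selected]
  fp <- sum(!(sel_cl %in% causal_cl))
  fdp <- fp / max(1, length(selected))
  power <- if (length(causal) == 0) 0 else
    sum(causal_cl %in% sel_cl) / length(causal)
  list(fdp = fdp, power = power)
}

#' Configure a benchmark scenario
#'
#' Defaults are the desk-scale profile: 300 pedigree families (or 3000
#' unrelated individuals) x ~300 variants, 200 replicates, M = 5 knockoffs
#' at q = 0.1.
#'
#' @param genotype `"pedigree"` or `"unrelated"`.
#' @param trait `"quantitative"` or `"dichotomous"`.
#' @param test `"score"`, `"mixed_score"`, `"wald"`, or `"lrt"`.
#' @param analysis `"ghost"`, `"individual_knockoff"`, `"meta_ghost"`
#'   (two disjoint half-studies combined by [meta_analyze()] weights), or
#'   `"pooled"`.
#' @param theta variance component for mixed phenotypes.
#' @param q target FDR level.
#' @param M number of knockoff copies.
#' @param replicates number of simulation replicates.
#' @param seed base seed; replicate r uses `seed + r` and the knockoff draw
#'   `seed + 10000 + r`.
#' @param n_families,n_unrelated sample-size knobs.
#' @param p_sites,n_hap,ld_decay haplotype-pool knobs (sites before the MAF
#'   filter).
#' @param n_causal,a effect-size knobs (`a = NULL`: trait default).
#' @param scheme optional ascertainment scheme (`"A"`, `"B"`, `"C"`) applied
#'   to dichotomous pedigree data before testing.
#' @param n_case_families,n_control_families scheme-B quotas.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(genotype = c("pedigree", "unrelated"),
                            trait = c("quantitative", "dichotomous"),
                            test = c("mixed_score", "score", "wald", "lrt"),
                            analysis = c("ghost", "individual_knockoff",
                                         "meta_ghost", "pooled"),
                            theta = 4, q = 0.1, M = 5, replicates = 200,
                            seed = 1, n_families = 300, n_unrelated = 3000,
                            p_sites = 400, n_hap = 2000, ld_decay = 0.97,
                            n_causal = 10, a = NULL, scheme = NULL,
                            n_case_families = 150,
                            n_control_families = 150) {
  genotype <- match.arg(genotype)
  trait <- match.arg(trait)
  test <- match.arg(test)
  analysis <- match.arg(analysis)
  if (test == "mixed_score" && genotype != "pedigree") {
    stop("mixed_score requires pedigree genotypes (a kinship structure)")
  }
  structure(list(genotype = genotype, trait = trait, test = test,
                 analysis = analysis, theta = theta, q = q, M = M,
                 replicates = replicates, seed = seed,
                 n_families = n_families, n_unrelated = n_unrelated,
                 p_sites = p_sites, n_hap = n_hap, ld_decay = ld_decay,
                 n_causal = n_causal, a = a, scheme = scheme,
                 n_case_families = n_case_families,
                 n_control_families = n_control_families),
            class = "scenario_config")
}

# Marginal test dispatch used inside replicates.
.replicate_test <- function(cfg, y, X, G, Phi_blocks) {
  fam <- if (cfg$trait == "quantitative") "linear" else "logistic"
  if (cfg$test == "mixed_score") {
    if (fam == "linear") {
      fit <- fit_null_lmm(y, X, Phi_blocks)
      list(z = lmm_score_test(fit, G)$z, fit = fit)
    } else {
      fit <- fit_null_logistic_mixed(y, X, Phi_blocks)
      list(z = glmm_score_test(fit, G)$z, fit = fit)
    }
  } else {
    list(z = fixed_effect_test(y, X, G, family = fam,
                               method = cfg$test)$z, fit = NULL)
  }
}

# Knockoff importance for the individual-level comparator: the same marginal
# test re-run on each knockoff genotype copy.
.individual_knockoff_z <- function(cfg, y, X, G_rep, model, fit, seed) {
  mu <- colMeans(G_rep)
  sdv <- apply(G_rep, 2, stats::sd)
  Gs <- sweep(sweep(G_rep, 2, mu), 2, sdv, "/")
  copies <- knockoff_genotype_copies(Gs, model, seed = seed)
  fam <- if (cfg$trait == "quantitative") "linear" else "logistic"
  vapply(copies, function(Gk) {
    if (cfg$test == "mixed_score") {
      if (fam == "linear") lmm_score_test(fit, Gk)$z
      else glmm_score_test(fit, Gk)$z
    } else {
      fixed_effect_test(y, X, Gk, family = fam, method = cfg$test)$z
    }
  }, numeric(ncol(G_rep)))
}

#' Run a replicated FDR/power benchmark scenario
#'
#' Builds the haplotype pool and its LD once (the pool plays the external
#' LD reference panel), clusters variants at |r| = 0.75 and keeps the
#' representatives, constructs the knockoff model (equicorrelated s, M
#' copies) once, then per replicate: simulate genotypes and phenotypes,
#' run the configured marginal test on the representatives, perform the
#' configured knockoff analysis, and score FDP/power against the causal
#' clusters. Causal variants are drawn among representatives each replicate.
#'
#' @param cfg a `scenario_config`.
#' @return list of class `bench_result`: per-replicate data.frame
#'   (`fdp`, `power`, `n_selected`) and aggregates `fdr`, `power`,
#'   `se_fdr`, `se_power`, plus the scenario bookkeeping (`n_rep_variants`,
#'   `s_range`, `shrinkage`).
#' @export
run_replicates <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  pool <- generate_haplotype_pool(p = cfg$p_sites, n_hap = cfg$n_hap,
                                  ld_decay = cfg$ld_decay, seed = cfg$seed)
  ld_full <- pool_ld(pool)
  clus <- choose_representatives(ld_full,
                                 single_linkage_clusters(ld_full, 0.75))
  reps <- which(clus$representative)
  ld_rep <- regularize_ld(stats::cor(pool$H[, reps, drop = FALSE]),
                          variants = pool$variants[reps])
  M <- cfg$M
  s <- solve_s(ld_rep, M = M)
  model <- conditional_params(ld_rep, s, M = M)
  rep_cluster <- clus$cluster[reps]          # cluster id per representative
  a <- if (is.null(cfg$a)) {
    if (cfg$trait == "quantitative") 1 else 2.5
  } else cfg$a
  ped <- default_pedigree()
  Phi_b <- relationship_from_pedigree(ped)

  out <- data.frame(fdp = numeric(0), power = numeric(0),
                    n_selected = integer(0))
  failures <- 0
  for (r in seq_len(cfg$replicates)) {
    seed_r <- cfg$seed + r
    res <- tryCatch({
      if (cfg$genotype == "pedigree") {
        gd <- gene_drop_families(pool, cfg$n_families, ped, seed = seed_r)
        G <- gd$G
        fam_idx <- gd$family
        Phi_blocks <- kinship_blocks(Phi_b, cfg$n_families)
      } else {
        G <- sample_unrelated_genotypes(pool, cfg$n_unrelated, seed = seed_r)
        fam_idx <- seq_len(nrow(G))
        Phi_blocks <- NULL
      }
      beta <- causal_effects(G, n_causal = cfg$n_causal, a = a,
                             candidates = reps, seed = seed_r)
      causal <- which(beta != 0)
      spec <- phenotype_spec(cfg$trait, theta = cfg$theta)
      ph <- simulate_phenotypes(G, beta, spec, Phi_blocks, seed = seed_r)
      y <- ph$y
      X <- ph$X
      if (!is.null(cfg$scheme)) {
        sel_idx <- sample_scheme(cfg$scheme, fam_idx, y,
                                 n_case_families = cfg$n_case_families,
                                 n_control_families = cfg$n_control_families,
                                 seed = seed_r)
        if (cfg$scheme == "B" && inherits(Phi_blocks, "kinship_blocks")) {
          # whole families retained: kinship blocks still apply
          Phi_blocks <- kinship_blocks(Phi_b, length(sel_idx) / nrow(Phi_b))
        } else if (cfg$test == "mixed_score") {
          stop("mixed_score after non-family ascertainment needs a dense Phi")
        }
        G <- G[sel_idx, , drop = FALSE]
        y <- y[sel_idx]
        X <- X[sel_idx, , drop = FALSE]
      }
      G_rep <- G[, reps, drop = FALSE]
      kseed <- cfg$seed + 10000 + r
      if (cfg$analysis == "meta_ghost") {
        # two disjoint half-studies combined with overlap-aware weights
        n <- nrow(G_rep)
        half1 <- seq_len(floor(n / 2))
        half2 <- setdiff(seq_len(n), half1)
        fam <- if (cfg$trait == "quantitative") "linear" else "logistic"
        z1 <- fixed_effect_test(y[half1], X[half1, , drop = FALSE],
                                G_rep[half1, , drop = FALSE],
                                family = fam, method = "score")$z
        z2 <- fixed_effect_test(y[half2], X[half2, , drop = FALSE],
                                G_rep[half2, , drop = FALSE],
                                family = fam, method = "score")$z
        w <- optimal_weights(diag(1, 2), c(length(half1), length(half2)))
        z <- combine_z(cbind(z1, z2), w, diag(1, 2))$z
        z_knock <- sample_knockoff_z(z, model, seed = kseed)
      } else if (cfg$analysis == "individual_knockoff") {
        tst <- .replicate_test(cfg, y, X, G_rep, Phi_blocks)
        z <- tst$z
        z_knock <- .individual_knockoff_z(cfg, y, X, G_rep, model,
                                          tst$fit, seed = kseed)
      } else {  # ghost and pooled share the summary-statistic route
        tst <- .replicate_test(cfg, y, X, G_rep, Phi_blocks)
        z <- tst$z
        z_knock <- sample_knockoff_z(z, model, seed = kseed)
      }
      st <- select_fdr(importance_and_W(z, z_knock), q = cfg$q)
      sel_reps <- reps[st$selected]
      ep <- empirical_fdr_power(sel_reps, causal, clus$cluster)
      data.frame(fdp = ep$fdp, power = ep$power,
                 n_selected = length(sel_reps))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1
      if (failures > 0.05 * cfg$replicates) {
        stop("more than 5% of replicates failed; last error: ",
             conditionMessage(res))
      }
      next
    }
    out <- rbind(out, res)
  }
  nr <- nrow(out)
  structure(list(replicates = out,
                 fdr = mean(out$fdp), power = mean(out$power),
                 se_fdr = stats::sd(out$fdp) / sqrt(nr),
                 se_power = stats::sd(out$power) / sqrt(nr),
                 n_rep_variants = length(reps),
                 s_range = range(s), shrinkage = ld_rep$shrinkage,
                 failures = failures, config = cfg),
            class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Scenario: %s / %s / %s / %s (theta=%g, q=%g, M=%d)\n",
              cfg$genotype, cfg$trait, cfg$test, cfg$analysis,
              cfg$theta, cfg$q, cfg$M))
  cat(sprintf("Replicates: %d (failed: %d); representatives: %d\n",
              nrow(x$replicates), x$failures, x$n_rep_variants))
  cat(sprintf("Empirical FDR: %.4f (SE %.4f)\n", x$fdr, x$se_fdr))
  cat(sprintf("Empirical power: %.4f (SE %.4f)\n", x$power, x$se_power))
  invisible(x)
}

#' Attach high-LD, high-signal cluster neighbors to selected representatives
#'
#' For each selected representative at each q level, reports cluster members
#' that are (1) correlated with the representative at |r| >= `r_min` and
#' (2) at least as significant (`|Z|` no less than the representative's).
#'
#' @param stats a `knockoff_stats` over the representatives (from
#'   [ghostknockoff()] or [select_fdr()]), with `tau`/`kappa` filled.
#' @param ld full `ld_matrix` over all variants.
#' @param tab `sumstat_table` over all variants (for the neighbor Z-scores).
#' @param clusters `ld_clusters` over all variants with representatives
#'   chosen.
#' @param q_levels FDR levels to report (default the fitted q).
#' @param r_min neighbor correlation bound (default 0.75).
#' @return data.frame with columns `q`, `representative`, `variant_id`,
#'   `r`, `Z`, `is_representative`.
#' @export
report_selection <- function(stats, ld, tab, clusters,
                             q_levels = NULL, r_min = 0.75) {
  ld <- .as_ld(ld)
  if (is.null(q_levels)) q_levels <- stats$q
  reps <- which(clusters$representative)
  out <- list()
  for (q in q_levels) {
    st <- select_fdr(stats, q = q)
    for (i in which(st$selected)) {
      rv <- reps[i]
      members <- which(clusters$cluster == clusters$cluster[rv])
      keep <- members[abs(ld$R[members, rv]) >= r_min &
                        abs(tab$z[members]) >= abs(tab$z[rv])]
      keep <- union(rv, keep)
      out[[length(out) + 1]] <- data.frame(
        q = q,
        representative = tab$variant_id[rv],
        variant_id = tab$variant_id[keep],
        r = ld$R[keep, rv],
        Z = tab$z[keep],
        is_representative = keep == rv
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(q = numeric(0), representative = character(0),
                      variant_id = character(0), r = numeric(0),
                      Z = numeric(0), is_representative = logical(0)))
  }
  do.call(rbind, out)
}

#' Merge selected variants into independent loci
#'
#' Greedy scan per chromosome over position-sorted selections: a new locus
#' starts when the next variant lies at least `min_gap` base pairs beyond
#' the previous locus's last member.
#'
#' @param chrom,pos chromosome and position of the selected variants.
#' @param min_gap minimum inter-locus distance in bp (default 1e6, i.e.
#'   1 Mb).
#' @return data.frame with `chrom`, `start`, `end`, `n_variants`; zero rows
#'   for an empty selection.
#' @export
merge_loci <- function(chrom, pos, min_gap = 1e6) {
  if (length(pos) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_variants = integer(0)))
  }
  chrom <- rep_len(as.character(chrom), length(pos))
  ord <- order(chrom, pos)
  chrom <- chrom[ord]
  pos <- pos[ord]
  loci <- list()
  cur_chr <- chrom[1]
  cur_start <- pos[1]
  cur_end <- pos[1]
  cur_n <- 1L
  for (i in seq_along(pos)[-1]) {
    if (chrom[i] == cur_chr && pos[i] - cur_end < min_gap) {
      cur_end <- pos[i]
      cur_n <- cur_n + 1L
    } else {
      loci[[length(loci) + 1]] <- data.frame(chrom = cur_chr,
                                             start = cur_start,
                                             end = cur_end,
                                             n_variants = cur_n)
      cur_chr <- chrom[i]
      cur_start <- pos[i]
      cur_end <- pos[i]
      cur_n <- 1L
    }
  }
  loci[[length(loci) + 1]] <- data.frame(chrom = cur_chr, start = cur_start,
                                         end = cur_end, n_variants = cur_n)
  do.call(rbind, loci)
}
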
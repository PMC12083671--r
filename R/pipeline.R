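# End-to-end pipeline: summary statistics + LD panel -> clustering ->
# per-block knockoff sampling -> FDR selection -> reports, driven by a
# manifest so runs are reproducible from one file.

#' Run the summary-statistics knockoff pipeline from a manifest
#'
#' Executes read -> harmonize -> cluster -> per-block knockoff -> select ->
#' report -> merge loci. The manifest is a named list (or path to a JSON
#' file) with entries: `sumstats` (path), `ld_matrix` and `ld_variants`
#' (paths), optional `blocks` (BED-style 3-column path), `q` (default 0.1),
#' `M` (default 5), `cutoff` (default 0.75), `shrinkage` (default "auto"),
#' `seed` (default 1), and `out_dir`. Variants present in the summary
#' statistics but missing from the LD panel (or vice versa) are dropped
#' with a message; if more than half mismatch, the run aborts. All outputs
#' (selection table, loci table, the manifest with resolved parameters) are
#' written under `out_dir`.
#'
#' @param manifest named list or path to a JSON manifest.
#' @return invisibly, a list with `selection` (data.frame), `loci`,
#'   `manifest` (resolved), and output file paths.
#' @export
run_pipeline <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  defaults <- list(q = 0.1, M = 5, cutoff = 0.75, shrinkage = "auto",
                   seed = 1, blocks = NULL, out_dir = tempfile("zknock_run_"))
  manifest <- utils::modifyList(defaults, manifest)
  for (need in c("sumstats", "ld_matrix", "ld_variants")) {
    if (is.null(manifest[[need]])) stop("manifest entry missing: ", need)
  }
  tab <- read_sumstats(manifest$sumstats)
  ld <- read_ld_matrix(manifest$ld_matrix, manifest$ld_variants,
                       shrinkage = manifest$shrinkage)
  common <- intersect(tab$variant_id, ld$variants)
  frac_lost <- 1 - length(common) /
    max(length(tab$variant_id), length(ld$variants))
  if (frac_lost > 0.5) {
    stop("variant lists disagree on more than 50% of entries (",
         length(common), " shared); reconcile inputs first")
  }
  if (length(common) < length(tab$variant_id) ||
      length(common) < length(ld$variants)) {
    message("variant reconciliation: ", length(common), " shared; ",
            length(tab$variant_id) - length(common), " sumstat and ",
            length(ld$variants) - length(common), " LD rows dropped")
  }
  tab <- tab[match(common, tab$variant_id), , drop = FALSE]
  ord <- order(tab$chrom, tab$pos)
  tab <- tab[ord, , drop = FALSE]
  idx <- match(tab$variant_id, ld$variants)
  ld <- regularize_ld(ld$R[idx, idx, drop = FALSE],
                      shrinkage = manifest$shrinkage,
                      variants = tab$variant_id)
  clus <- choose_representatives(
    ld, single_linkage_clusters(ld, cutoff = manifest$cutoff))
  reps <- which(clus$representative)
  ld_rep <- regularize_ld(ld$R[reps, reps, drop = FALSE],
                          shrinkage = manifest$shrinkage,
                          variants = ld$variants[reps])
  blocks <- NULL
  if (!is.null(manifest$blocks)) {
    bed <- utils::read.table(manifest$blocks, header = FALSE,
                             col.names = c("chrom", "start", "end"))
    blocks <- partition_blocks(tab[reps, , drop = FALSE], bed)
  }
  st <- ghostknockoff(tab$z[reps], ld_rep, M = manifest$M, q = manifest$q,
                      blocks = blocks, seed = manifest$seed)
  selection <- cbind(st$table,
                     chrom = tab$chrom[reps], pos = tab$pos[reps],
                     cluster_id = clus$cluster[reps],
                     q = manifest$q, threshold = st$threshold)
  report <- report_selection(st, ld, tab, clus, q_levels = manifest$q)
  sel <- selection[selection$selected, , drop = FALSE]
  loci <- merge_loci(sel$chrom, sel$pos)
  dir.create(manifest$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    selection = file.path(manifest$out_dir, "selection.tsv"),
    report = file.path(manifest$out_dir, "neighbors.tsv"),
    loci = file.path(manifest$out_dir, "loci.tsv"),
    manifest = file.path(manifest$out_dir, "manifest.json")
  )
  utils::write.table(selection, paths$selection, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report, paths$report, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(loci, paths$loci, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$n_variants <- nrow(tab)
  manifest$n_representatives <- length(reps)
  manifest$ld_shrinkage <- ld_rep$shrinkage
  jsonlite::write_json(manifest[!vapply(manifest, is.null, logical(1))],
                       paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(selection = selection, report = report, loci = loci,
                 manifest = manifest, paths = paths))
}
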
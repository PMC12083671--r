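# Smallest p-value propagated through the p <-> z conversions. Anything
# smaller is clamped so that |z| stays finite in downstream knockoff sampling.
.P_FLOOR <- 1e-300

#' Convert a two-sided p-value and direction of effect to a signed Z-score
#'
#' Uses the two-sided convention `|z| = qnorm(1 - p/2)` with the sign taken
#' from `direction` (a sign in \{-1, +1\} or a signed effect estimate).
#' P-values below 1e-300 are clamped there with a warning so that `z` never
#' becomes infinite; a zero direction is mapped to +1 with a warning so ties
#' never drop variants.
#'
#' @param p numeric vector of two-sided p-values in (0, 1].
#' @param direction numeric vector of signs (or signed betas), recycled.
#' @return numeric vector of signed Z-scores.
#' @examples
#' z_from_p(0.05, 1)     # 1.959964
#' z_from_p(1, -1)       # 0
#' @seealso [p_from_z()]
#' @export
z_from_p <- function(p, direction = 1) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p must be in (0, 1]")
  }
  n_under <- sum(p < .P_FLOOR)
  if (n_under > 0) {
    warning(sprintf("%d p-value(s) below %.0e clamped", n_under, .P_FLOOR))
    p <- pmax(p, .P_FLOOR)
  }
  direction <- rep_len(direction, length(p))
  s <- sign(direction)
  if (any(s == 0)) {
    warning("direction of 0 mapped to +1")
    s[s == 0] <- 1
  }
  s * stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Convert a signed Z-score to a two-sided p-value
#'
#' `p = 2 * pnorm(-|z|)`, clamped below at 1e-300 so the result is always a
#' valid probability in (0, 1].
#'
#' @param z numeric vector of Z-scores (finite).
#' @return numeric vector of two-sided p-values.
#' @export
p_from_z <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) stop("z must be finite")
  pmax(2 * stats::pnorm(-abs(z)), .P_FLOOR)
}

#' Build a summary-statistic table
#'
#' Constructs a validated per-variant table of marginal association results.
#' Each row needs either (`p`, `direction`) or `z`; the missing member of the
#' pair is filled in so that `sign(z) == direction` and
#' `p == 2 * pnorm(-|z|)` always hold on the returned table.
#'
#' @param variant_id character vector of variant identifiers.
#' @param chrom,pos,ref,alt variant coordinates and alleles.
#' @param p two-sided p-values in (0, 1] (or NA when `z` given).
#' @param direction signs or signed betas (or NA when `z` given).
#' @param z signed Z-scores (or NA when `p`/`direction` given).
#' @param n per-study sample size (positive integer, recycled).
#' @param study_id study label (recycled).
#' @return a `data.frame` of class `sumstat_table` with columns
#'   `variant_id, chrom, pos, ref, alt, p, direction, z, n, study_id`.
#' @export
sumstat_table <- function(variant_id, chrom, pos, ref, alt,
                          p = NA_real_, direction = NA_real_, z = NA_real_,
                          n = NA_integer_, study_id = "study1") {
  nr <- length(variant_id)
  tab <- data.frame(
    variant_id = as.character(variant_id),
    chrom = rep_len(as.character(chrom), nr),
    pos = rep_len(as.integer(pos), nr),
    ref = rep_len(as.character(ref), nr),
    alt = rep_len(as.character(alt), nr),
    p = rep_len(as.numeric(p), nr),
    direction = rep_len(as.numeric(direction), nr),
    z = rep_len(as.numeric(z), nr),
    n = rep_len(as.integer(n), nr),
    study_id = rep_len(as.character(study_id), nr),
    stringsAsFactors = FALSE
  )
  has_z <- !is.na(tab$z)
  has_p <- !is.na(tab$p) & !is.na(tab$direction)
  if (any(!has_z & !has_p)) {
    stop("every row needs either z or (p, direction)")
  }
  # fill each representation from the other; z wins where both are present
  tab$p[has_z] <- p_from_z(tab$z[has_z])
  tab$direction[has_z] <- ifelse(tab$z[has_z] >= 0, 1, -1)
  fill <- has_p & !has_z
  if (any(fill)) {
    tab$z[fill] <- z_from_p(tab$p[fill], tab$direction[fill])
    tab$direction[fill] <- sign(tab$z[fill])
  }
  key <- paste(tab$study_id, tab$chrom, tab$pos, tab$ref, tab$alt)
  if (anyDuplicated(key)) stop("duplicate (chrom,pos,ref,alt) within a study")
  class(tab) <- c("sumstat_table", "data.frame")
  tab
}

# Default header names for delimited summary-statistic files.
.default_dialect <- function() {
  list(variant_id = "ID", chrom = "CHR", pos = "POS", ref = "REF",
       alt = "ALT", p = "P", direction = c("BETA", "DIR"), n = "N",
       study = "STUDY")
}

#' Read a delimited summary-statistic file
#'
#' Reads a tab- or comma-delimited file with a header line into a
#' [sumstat_table()]. Column names are configurable through `dialect`
#' (a named list mapping the logical fields to header names); the `direction`
#' field accepts either a sign column or a signed beta column. Rows with
#' p-values outside (0, 1] are rejected and counted in a message.
#'
#' @param path path to the file.
#' @param dialect named list overriding entries of the default column map
#'   (`ID, CHR, POS, REF, ALT, P, BETA/DIR, N, STUDY`).
#' @param sep field separator; guessed from the first line when `NULL`.
#' @return a `sumstat_table`.
#' @export
read_sumstats <- function(path, dialect = list(), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::modifyList(.default_dialect(), dialect)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- function(field, optional = FALSE) {
    hit <- intersect(d[[field]], names(raw))
    if (length(hit) == 0) {
      if (optional) return(NULL)
      stop("missing mandatory column for '", field, "' (looked for: ",
           paste(d[[field]], collapse = ", "), ")")
    }
    raw[[hit[1]]]
  }
  p_raw <- suppressWarnings(as.numeric(need("p")))
  bad_line <- which(is.na(p_raw) & !is.na(need("p")))
  if (length(bad_line) > 0) {
    stop("unparseable p-value at data line(s): ",
         paste(utils::head(bad_line, 5), collapse = ", "))
  }
  keep <- !is.na(p_raw) & p_raw > 0 & p_raw <= 1
  if (any(!keep)) {
    message(sum(!keep), " row(s) rejected: p outside (0, 1]")
  }
  n_col <- need("n", optional = TRUE)
  study_col <- need("study", optional = TRUE)
  sumstat_table(
    variant_id = need("variant_id")[keep],
    chrom = need("chrom")[keep],
    pos = need("pos")[keep],
    ref = need("ref")[keep],
    alt = need("alt")[keep],
    p = p_raw[keep],
    direction = as.numeric(need("direction"))[keep],
    n = if (is.null(n_col)) NA_integer_ else as.integer(n_col)[keep],
    study_id = if (is.null(study_col)) "study1" else study_col[keep]
  )
}

#' Write a summary-statistic table to a delimited file
#'
#' Inverse of [read_sumstats()] under the default dialect: writes header
#' `ID CHR POS REF ALT P BETA N STUDY` plus a `Z` column.
#'
#' @param tab a `sumstat_table`.
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(tab, path, sep = "\t") {
  out <- data.frame(ID = tab$variant_id, CHR = tab$chrom, POS = tab$pos,
                    REF = tab$ref, ALT = tab$alt, P = tab$p,
                    BETA = tab$direction, Z = tab$z, N = tab$n,
                    STUDY = tab$study_id)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize several study tables onto one variant list
#'
#' Matches rows across studies on (chrom, pos, ref, alt) exactly; a row whose
#' ref/alt are swapped relative to the first study is kept with its Z-score
#' sign flipped; any other allele mismatch at a shared position is dropped
#' with a message. Used before meta-analysis.
#'
#' @param tables list of `sumstat_table`s.
#' @return list with `variants` (data.frame of the union variant list),
#'   `Z` (variants x studies matrix, NA where unobserved),
#'   `mask` (binary observation matrix), `n` (per-study sample sizes).
#' @export
harmonize_studies <- function(tables) {
  stopifnot(length(tables) >= 1)
  key_of <- function(t) paste(t$chrom, t$pos, sep = ":")
  anchor <- tables[[1]]
  all_keys <- unique(unlist(lapply(tables, key_of)))
  L <- length(tables)
  Z <- matrix(NA_real_, length(all_keys), L,
              dimnames = list(all_keys, NULL))
  meta_rows <- NULL
  alleles <- new.env(parent = emptyenv())
  for (l in seq_len(L)) {
    t <- tables[[l]]
    k <- key_of(t)
    for (i in seq_len(nrow(t))) {
      ak <- k[i]
      rec <- get0(ak, envir = alleles)
      if (is.null(rec)) {
        assign(ak, list(ref = t$ref[i], alt = t$alt[i],
                        row = t[i, c("variant_id", "chrom", "pos",
                                     "ref", "alt")]),
               envir = alleles)
        Z[ak, l] <- t$z[i]
      } else if (identical(rec$ref, t$ref[i]) &&
                 identical(rec$alt, t$alt[i])) {
        Z[ak, l] <- t$z[i]
      } else if (identical(rec$ref, t$alt[i]) &&
                 identical(rec$alt, t$ref[i])) {
        Z[ak, l] <- -t$z[i]      # swapped ref/alt: flip the direction
      } else {
        message("allele mismatch at ", ak, " in study ", l, "; row dropped")
      }
    }
  }
  rows <- do.call(rbind, lapply(all_keys, function(ak) {
    get(ak, envir = alleles)$row
  }))
  ord <- order(rows$chrom, rows$pos)
  rows <- rows[ord, , drop = FALSE]
  Z <- Z[ord, , drop = FALSE]
  n <- vapply(tables, function(t) {
    nn <- t$n[!is.na(t$n)]
    if (length(nn) == 0) NA_integer_ else as.integer(max(nn))
  }, integer(1))
  list(variants = rows, Z = Z, mask = 1 * !is.na(Z), n = n)
}
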
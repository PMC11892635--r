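#' Read a per-ORF abundance table
#'
#' @param path TSV with header columns `orf_id`, `rna`, `ribo`
#'   (normalized nonnegative read abundances).
#' @return data.frame keyed by `orf_id`.
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("orf_id", "rna", "ribo") %in% names(df)))
  if (anyDuplicated(df$orf_id)) stop("duplicate orf_id in ", path)
  if (any(df$rna < 0, na.rm = TRUE) || any(df$ribo < 0, na.rm = TRUE)) {
    stop("negative abundance values in ", path)
  }
  df
}

# fetch assay values for a vector of ids
assay_values <- function(table, ids, assay) {
  table[[assay]][match(ids, table$orf_id)]
}

#' Pearson correlation between paired ORF abundances
#'
#' Correlates `log10` abundances of ORF pairs (e.g. ORF1 vs ORF2 of
#' bicistrons, or colinear control pairs).  Pairs with any zero or
#' missing value are excluded pairwise; optionally a +1 pseudocount is
#' applied instead.
#'
#' @param table abundance data.frame (see [read_abundance_table()]).
#' @param pairs data.frame with `id1`, `id2`.
#' @param assay `"rna"` or `"ribo"`.
#' @param pseudocount if TRUE, add 1 to every value and keep zeros.
#' @return list with `r` (Pearson on log10 values) and `n` (pairs used).
#'   Fewer than 3 usable pairs is an error.
#' @export
pair_correlation <- function(table, pairs, assay = c("rna", "ribo"),
                             pseudocount = FALSE) {
  assay <- match.arg(assay)
  v1 <- assay_values(table, pairs$id1, assay)
  v2 <- assay_values(table, pairs$id2, assay)
  if (pseudocount) {
    v1 <- v1 + 1
    v2 <- v2 + 1
  }
  ok <- !is.na(v1) & !is.na(v2) & v1 > 0 & v2 > 0
  if (sum(ok) < 3L) {
    stop("fewer than 3 usable pairs (", sum(ok), ") for assay ", assay)
  }
  list(r = stats::cor(log10(v1[ok]), log10(v2[ok])), n = sum(ok))
}

#' Fraction of bicistrons with higher ORF1 ribosome occupancy
#'
#' Counts loci where the Ribo-Seq abundance of ORF1 strictly exceeds
#' that of ORF2 (ties count as not-greater).
#'
#' @param table abundance data.frame.
#' @param pairs data.frame with `id1` (ORF1), `id2` (ORF2).
#' @return list with `greater` (numerator), `n` (usable loci; both
#'   values present) and `fraction`.
#' @export
occupancy_comparison <- function(table, pairs) {
  v1 <- assay_values(table, pairs$id1, "ribo")
  v2 <- assay_values(table, pairs$id2, "ribo")
  ok <- !is.na(v1) & !is.na(v2)
  stopifnot(sum(ok) >= 1L)
  greater <- sum(v1[ok] > v2[ok])
  list(greater = greater, n = sum(ok), fraction = greater / sum(ok))
}

#' Upstream Kozak strength vs relative ORF2 footprint density
#'
#' For each bicistron the upstream initiation strength is summarised as
#' the maximum bit score over the annotated ORF1 start and all internal
#' AUG sites; it is correlated against `log(ORF2 ribo / ORF1 ribo)`.
#' Under leaky scanning the correlation is negative: strong upstream
#' sites capture scanning ribosomes before they reach ORF2.
#'
#' @param profiles named list of [locus_kozak_profile()] outputs, names
#'   are locus ids.
#' @param table abundance data.frame.
#' @param pairs data.frame with `locus`, `id1` (ORF1), `id2` (ORF2)
#'   mapping loci to abundance rows.
#' @return list with `pearson_r`, `spearman_rho`, `n`, `sign`
#'   (-1/0/+1 of the Pearson r).  Loci with zero/missing ribo values are
#'   excluded pairwise; constant strength across loci is an error.
#' @export
kozak_vs_footprint <- function(profiles, table, pairs) {
  strength <- vapply(pairs$locus, function(l) {
    p <- profiles[[l]]
    if (is.null(p)) return(NA_real_)
    max(c(p$orf1_score, p$internal_sites$score), na.rm = TRUE)
  }, numeric(1))
  v1 <- assay_values(table, pairs$id1, "ribo")
  v2 <- assay_values(table, pairs$id2, "ribo")
  ok <- !is.na(strength) & !is.na(v1) & !is.na(v2) & v1 > 0 & v2 > 0
  if (sum(ok) < 3L) stop("fewer than 3 usable loci")
  x <- strength[ok]
  y <- log(v2[ok] / v1[ok])
  if (stats::sd(x) == 0) stop("constant upstream strength: r undefined")
  r <- stats::cor(x, y)
  rho <- stats::cor(x, y, method = "spearman")
  list(pearson_r = r, spearman_rho = rho, n = sum(ok), sign = sign(r))
}
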
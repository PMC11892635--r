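#' Count AUG 3-mers in a sequence
#'
#' Sliding-window count of `ATG` 3-mers (all frames; windows containing
#' `N` never match).
#'
#' @param seq nucleotide string.
#' @return integer count.
#' @examples
#' count_aug("ATGATGATG")  # 3
#' @export
count_aug <- function(seq) {
  if (nchar(seq) < 3L) return(0L)
  hits <- gregexpr("(?=ATG)", seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

#' Composition model for AUG expectation
#'
#' Base probabilities used to compute the expected AUG count of a region
#' from its length, adjusting for GC bias.  `scope = "per_class_pooled"`
#' estimates one composition from the concatenation of all sequences in
#' a region class; `"per_sequence"` estimates it per sequence.
#'
#' @param seqs character vector of sequences to estimate from.
#' @return named numeric vector `c(A=,C=,G=,T=)` summing to 1 (`N`s are
#'   ignored).
#' @export
base_composition <- function(seqs) {
  cc <- chars(paste(seqs, collapse = ""))
  cc <- cc[cc %in% BASES]
  if (length(cc) == 0) return(setNames(rep(0.25, 4), BASES))
  tab <- table(factor(cc, levels = BASES))
  setNames(as.numeric(tab) / length(cc), BASES)
}

#' Expected AUG 3-mer count
#'
#' Under an i.i.d. base model with probabilities `comp`, each of the
#' `L - 2` windows of a length-`L` sequence is `ATG` with probability
#' `pA * pT * pG`.
#'
#' @param length sequence length in nt.
#' @param comp named base-probability vector (see [base_composition()]).
#' @return expected count (0 for `length < 3`).
#' @examples
#' expected_aug(66, c(A = .25, C = .25, G = .25, T = .25))  # 1.0
#' @export
expected_aug <- function(length, comp) {
  if (length < 3L) return(0)
  (length - 2) * comp[["A"]] * comp[["T"]] * comp[["G"]]
}

#' Observed/expected AUG statistics per region class
#'
#' For every locus, counts `ATG` 3-mers in each region and computes the
#' GC-adjusted expectation from the region length.  Bicistronic loci
#' contribute `five_prime_utr`, `orf1`, `inter_orf`, `before_orf2` (the
#' concatenated sequence upstream of the ORF2 start codon) and `orf2`;
#' monocistronic loci contribute `mono_utr`, `mono_orf` and `mono_sum`
#' (UTR + ORF).  `oe` is missing when the region is shorter than 3 nt
#' (expected count 0).
#'
#' @param loci list of `region_set`s (mono and/or bicistronic).
#' @param comp_scope `"per_class_pooled"` (default; one composition per
#'   region class, from the pooled class sequence) or `"per_sequence"`.
#' @return list with `records` (data.frame: `locus`, `region_class`,
#'   `length`, `observed`, `expected`, `oe`), `class_medians` (named
#'   vector of median oe per class), and `length_count_r`, the Pearson
#'   correlation between (UTR + ORF) length and observed count across
#'   monocistronic loci (NA if < 3 such loci).
#' @export
region_bias_table <- function(loci, comp_scope = c("per_class_pooled",
                                                   "per_sequence")) {
  comp_scope <- match.arg(comp_scope)
  stopifnot(length(loci) >= 1)
  rows <- list()
  for (rs in loci) {
    if (rs$n_orfs == 2L) {
      before <- paste0(region_seq(rs, "five_prime_utr"),
                       region_seq(rs, "orf1"),
                       region_seq(rs, "inter_orf"))
      segs <- list(five_prime_utr = region_seq(rs, "five_prime_utr"),
                   orf1 = region_seq(rs, "orf1"),
                   inter_orf = region_seq(rs, "inter_orf"),
                   before_orf2 = before,
                   orf2 = region_seq(rs, "orf2"))
    } else {
      utr <- region_seq(rs, "five_prime_utr")
      orf <- region_seq(rs, "orf1")
      segs <- list(mono_utr = utr, mono_orf = orf,
                   mono_sum = paste0(utr, orf))
    }
    for (nm in names(segs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        locus = rs$transcript_id, region_class = nm,
        sequence = segs[[nm]], stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$length <- nchar(tab$sequence)
  tab$observed <- vapply(tab$sequence, count_aug, integer(1), USE.NAMES = FALSE)
  tab$expected <- NA_real_
  for (cl in unique(tab$region_class)) {
    idx <- which(tab$region_class == cl)
    if (comp_scope == "per_class_pooled") {
      comp <- base_composition(tab$sequence[idx])
      tab$expected[idx] <- vapply(tab$length[idx], expected_aug, numeric(1),
                                  comp = comp)
    } else {
      tab$expected[idx] <- vapply(idx, function(i) {
        expected_aug(tab$length[i], base_composition(tab$sequence[i]))
      }, numeric(1))
    }
  }
  tab$oe <- ifelse(tab$length >= 3L & tab$expected > 0,
                   tab$observed / tab$expected, NA_real_)
  records <- tab[, c("locus", "region_class", "length", "observed",
                     "expected", "oe")]
  rownames(records) <- NULL
  class_medians <- vapply(split(records$oe, records$region_class), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, numeric(1))
  msum <- records[records$region_class == "mono_sum", , drop = FALSE]
  length_count_r <- if (nrow(msum) >= 3 && stats::sd(msum$length) > 0 &&
                        stats::sd(msum$observed) > 0) {
    stats::cor(msum$length, msum$observed)
  } else NA_real_
  list(records = records, class_medians = class_medians,
       length_count_r = length_count_r)
}
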
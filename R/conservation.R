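#' Read tabular homology hits (BLAST outfmt 6)
#'
#' @param path 12-column tab-separated file with the standard columns
#'   qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#'   sstart, send, evalue, bitscore (no header).
#' @return data.frame with those column names.
#' @export
read_homology_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = cols, stringsAsFactors = FALSE)
  df
}

# best hit per query: highest bitscore, ties broken by lexicographically
# smaller subject id (deterministic)
best_hits <- function(hits) {
  ord <- order(hits$qseqid, -hits$bitscore, hits$sseqid)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Reciprocal best hits
#'
#' `(q, t)` is an ortholog pair iff `t` is `q`'s best hit by bitscore in
#' the query-to-target table, `q` is `t`'s best hit in the
#' target-to-query table, and both hits have `evalue <= max_evalue`.
#' Bitscore ties are broken by the lexicographically smaller subject id,
#' making the result deterministic and independent of row order.
#'
#' @param q2t,t2q hit data.frames (see [read_homology_hits()]).
#' @param max_evalue e-value ceiling (default 1e-5).
#' @return data.frame with `query`, `target`.
#' @export
reciprocal_best_hits <- function(q2t, t2q, max_evalue = 1e-5) {
  stopifnot(nrow(q2t) > 0, nrow(t2q) > 0)
  bq <- best_hits(q2t)
  bt <- best_hits(t2q)
  bq <- bq[bq$evalue <= max_evalue, , drop = FALSE]
  bt <- bt[bt$evalue <= max_evalue, , drop = FALSE]
  back <- bt$sseqid[match(bq$sseqid, bt$qseqid)]
  keep <- !is.na(back) & back == bq$qseqid
  out <- data.frame(query = bq$qseqid[keep], target = bq$sseqid[keep],
                    stringsAsFactors = FALSE)
  out[order(out$query), , drop = FALSE]
}

#' Colinearity calls for bicistron ORF pairs in a target genome
#'
#' A bicistron is called colinear in the target species when both of its
#' ORFs have ortholog genes that lie on the same strand of the same
#' chromosome, no other annotated gene intervenes between them on that
#' strand (opposite-strand genes do not break adjacency), and their
#' separation (downstream gene start minus upstream gene end) is at most
#' `max_separation_nt`.  Evidence flags upgrade the call tier: Iso-Seq
#' support to `colinear+isoseq`, else EST support to `colinear+est`.
#'
#' @param bicistrons data.frame with `locus`, `orf1_gene`, `orf2_gene`
#'   (query-side protein/gene ids used in the hit tables).
#' @param orthologs data.frame from [reciprocal_best_hits()].
#' @param target_genes data.frame of target gene models: `gene_id`,
#'   `chrom`, `strand`, `start`, `end`.
#' @param max_separation_nt maximum separation (default 20000).
#' @param evidence data.frame with `locus`, `isoseq`, `est` logical
#'   columns, or NULL.
#' @return data.frame with `locus`, `status`
#'   (none / colinear / colinear+isoseq / colinear+est), `target_pair`.
#'   An ortholog pointing at a gene id absent from `target_genes` yields
#'   a warning and `status = "none"`.
#' @export
colinearity_matrix <- function(bicistrons, orthologs, target_genes,
                               max_separation_nt = 20000L, evidence = NULL) {
  o_map <- setNames(orthologs$target, orthologs$query)
  calls <- lapply(seq_len(nrow(bicistrons)), function(i) {
    locus <- bicistrons$locus[i]
    t1 <- unname(o_map[bicistrons$orf1_gene[i]])
    t2 <- unname(o_map[bicistrons$orf2_gene[i]])
    status <- "none"
    pair <- NA_character_
    if (!is.na(t1) && !is.na(t2) && t1 != t2) {
      g1 <- target_genes[target_genes$gene_id == t1, , drop = FALSE]
      g2 <- target_genes[target_genes$gene_id == t2, , drop = FALSE]
      if (nrow(g1) == 0 || nrow(g2) == 0) {
        warning("ortholog gene id missing from target annotation for locus ",
                locus)
      } else if (g1$chrom == g2$chrom && g1$strand == g2$strand) {
        lo <- if (g1$start <= g2$start) g1 else g2
        hi <- if (g1$start <= g2$start) g2 else g1
        sep <- hi$start - lo$end
        same <- target_genes[target_genes$chrom == g1$chrom &
                             target_genes$strand == g1$strand &
                             !target_genes$gene_id %in% c(t1, t2), ,
                             drop = FALSE]
        intervening <- any(same$start > lo$end & same$end < hi$start)
        if (!intervening && sep <= max_separation_nt && sep >= 0) {
          status <- "colinear"
          pair <- paste(t1, t2, sep = "|")
          if (!is.null(evidence)) {
            ev <- evidence[evidence$locus == locus, , drop = FALSE]
            if (nrow(ev) == 1) {
              if (isTRUE(ev$isoseq)) status <- "colinear+isoseq"
              else if (isTRUE(ev$est)) status <- "colinear+est"
            }
          }
        }
      }
    }
    data.frame(locus = locus, status = status, target_pair = pair,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, calls)
}
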
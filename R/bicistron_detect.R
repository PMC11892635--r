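#' Classify loci as monocistronic, exclusively bicistronic, or mixed
#'
#' Transcripts are grouped into loci by shared ORF (gene) ids: two
#' transcripts belong to the same locus whenever they share at least one
#' gene id (connected components).  A locus is `bicistronic_exclusive`
#' only if every one of its transcripts carries the same two ORFs — no
#' isoform may carry exactly one of them.  Any transcript with more than
#' two ORFs makes the locus `polycistronic_mixed` (tricistrons are
#' reported but excluded from the bicistron set), as does any mixture of
#' ORF contents.
#'
#' @param models list of `transcript_model`s.
#' @return data.frame with one row per locus: `locus` (sorted gene ids
#'   joined by `+`), `class`, `n_transcripts`, `orf_counts`
#'   (comma-joined ORF count per transcript), `gene_ids`.
#' @export
classify_loci <- function(models) {
  if (length(models) == 0) {
    return(data.frame(locus = character(0), class = character(0),
                      n_transcripts = integer(0), orf_counts = character(0),
                      gene_ids = character(0)))
  }
  gene_sets <- lapply(models, function(m) unique(m$gene_ids))
  all_genes <- unique(unlist(gene_sets))
  # union-find over gene ids
  parent <- seq_along(all_genes)
  names(parent) <- all_genes
  findr <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (gs in gene_sets) {
    idx <- match(gs, all_genes)
    r <- findr(idx[1])
    for (j in idx[-1]) parent[findr(j)] <- r
  }
  comp <- vapply(seq_along(all_genes), findr, numeric(1))
  tr_comp <- vapply(gene_sets, function(gs) comp[match(gs[1], all_genes)],
                    numeric(1))
  out <- lapply(unique(comp), function(cc) {
    tix <- which(tr_comp == cc)
    genes <- sort(unique(unlist(gene_sets[tix])))
    counts <- vapply(models[tix], function(m) length(m$orfs), integer(1))
    sets <- gene_sets[tix]
    cls <- if (all(counts == 1L)) {
      "monocistronic"
    } else if (all(counts == 2L) && length(genes) == 2L &&
               all(vapply(sets, function(s) setequal(s, genes), logical(1)))) {
      "bicistronic_exclusive"
    } else {
      "polycistronic_mixed"
    }
    data.frame(locus = paste(genes, collapse = "+"), class = cls,
               n_transcripts = length(tix),
               orf_counts = paste(counts, collapse = ","),
               gene_ids = paste(genes, collapse = ","))
  })
  do.call(rbind, out)
}

#' Find upstream ORFs in a 5' UTR
#'
#' Scans the 5' UTR for uORFs: an `ATG` followed by the first in-frame
#' stop codon (`TAA`/`TAG`/`TGA`) lying entirely within the UTR.  uORFs
#' overlapping the main ORF start (no in-frame stop before the UTR end)
#' are not reported.  Overlapping/nested uORFs from distinct ATGs are all
#' reported.
#'
#' @param regions a `region_set` (5' UTR must be present) or a plain UTR
#'   string.
#' @param min_coding_nt minimum uORF length in nt, start and stop codons
#'   included.  Default 9 (start + one codon + stop), the smallest
#'   non-degenerate ORF.
#' @return data.frame with `start`, `end` (1-based within the UTR,
#'   stop codon included) and `length`.
#' @export
find_uorfs <- function(regions, min_coding_nt = 9L) {
  utr <- if (is.character(regions)) regions else region_seq(regions, "five_prime_utr")
  n <- nchar(utr)
  res <- list()
  if (n >= 6L) {
    cc <- chars(utr)
    starts <- which(vapply(seq_len(n - 2L), function(i) {
      cc[i] == "A" && cc[i + 1] == "T" && cc[i + 2] == "G"
    }, logical(1)))
    for (s in starts) {
      p <- s + 3L
      while (p + 2L <= n) {
        codon <- paste(cc[p:(p + 2L)], collapse = "")
        if (codon %in% STOP_CODONS) {
          len <- p + 2L - s + 1L
          if (len >= min_coding_nt) {
            res[[length(res) + 1L]] <- c(s, p + 2L, len)
          }
          break
        }
        p <- p + 3L
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  }
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2], length = m[, 3])
}

# genomic ORF span (min start / max end over CDS segments) per model
orf_genomic_span <- function(model, j) {
  o <- model$orfs[[j]]
  c(start = min(o$start), end = max(o$end))
}

#' Structural statistics of mono- vs bicistronic loci
#'
#' Per-class length vectors (5' UTR, ORF1, ORF2, inter-ORF for
#' bicistrons; UTR and ORF for monocistrons), uORF-to-main-ORF spacing,
#' and the genomic spacing between colinear monocistronic neighbours
#' (same chromosome strand, separation at most `colinear_max_nt`).
#' Spacing is reported as downstream ORF start minus upstream ORF stop
#' in genomic coordinates; uORF spacing as main ORF start minus uORF
#' stop in transcript coordinates.
#'
#' @param classifications output of [classify_loci()].
#' @param models list of `transcript_model`s (one representative isoform
#'   per locus is used: the first).
#' @param genome named character vector from [load_genome()].
#' @param colinear_max_nt maximum stop-to-start separation for a
#'   monocistronic pair to count as colinear (default 20000).
#' @param uorf_min_nt minimum uORF length passed to [find_uorfs()].
#' @return object of class `structural_stats`: list of numeric vectors
#'   (`five_prime_utr`, `orf1`, `orf2`, `inter_orf`, `mono_orf`,
#'   `mono_utr`, `colinear_spacing`, `uorf_spacing`) and a `medians`
#'   named vector (NA for empty classes).
#' @export
structural_stats <- function(classifications, models, genome,
                             colinear_max_nt = 20000L, uorf_min_nt = 9L) {
  tr_locus <- locus_of_models(classifications, models)
  first_model <- models[!duplicated(tr_locus)]
  first_locus <- tr_locus[!duplicated(tr_locus)]
  cls <- classifications$class[match(first_locus, classifications$locus)]

  vecs <- list(five_prime_utr = numeric(0), orf1 = numeric(0),
               orf2 = numeric(0), inter_orf = numeric(0),
               mono_orf = numeric(0), mono_utr = numeric(0),
               colinear_spacing = numeric(0), uorf_spacing = numeric(0))
  mono_spans <- list()
  for (i in seq_along(first_model)) {
    m <- first_model[[i]]
    if (cls[i] == "bicistronic_exclusive" && length(m$orfs) == 2L) {
      rs <- extract_regions(m, genome)
      vecs$five_prime_utr <- c(vecs$five_prime_utr, rs$regions$five_prime_utr$length)
      vecs$orf1 <- c(vecs$orf1, rs$regions$orf1$length)
      vecs$orf2 <- c(vecs$orf2, rs$regions$orf2$length)
      vecs$inter_orf <- c(vecs$inter_orf, rs$regions$inter_orf$length)
    } else if (cls[i] == "monocistronic") {
      rs <- extract_regions(m, genome)
      vecs$mono_utr <- c(vecs$mono_utr, rs$regions$five_prime_utr$length)
      vecs$mono_orf <- c(vecs$mono_orf, rs$regions$orf1$length)
      u <- find_uorfs(rs, min_coding_nt = uorf_min_nt)
      if (nrow(u) > 0) {
        main_start <- rs$regions$orf1$start
        vecs$uorf_spacing <- c(vecs$uorf_spacing, main_start - u$end)
      }
      mono_spans[[length(mono_spans) + 1L]] <- data.frame(
        chrom = m$chrom, strand = m$strand,
        start = orf_genomic_span(m, 1)[["start"]],
        end = orf_genomic_span(m, 1)[["end"]])
    }
  }
  if (length(mono_spans) > 0) {
    sp <- do.call(rbind, mono_spans)
    for (key in unique(paste(sp$chrom, sp$strand))) {
      sub <- sp[paste(sp$chrom, sp$strand) == key, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1) {
        gaps <- sub$start[-1] - sub$end[-nrow(sub)]
        vecs$colinear_spacing <- c(vecs$colinear_spacing,
                                   gaps[gaps >= 0 & gaps <= colinear_max_nt])
      }
    }
  }
  medians <- vapply(vecs, function(v) {
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, numeric(1))
  structure(c(vecs, list(medians = medians)), class = "structural_stats")
}

#' @export
print.structural_stats <- function(x, ...) {
  cat("structural_stats medians (nt):\n")
  print(round(x$medians, 1))
  invisible(x)
}

# map each model to the locus key used by classify_loci
locus_of_models <- function(classifications, models) {
  gene2locus <- list()
  for (r in seq_len(nrow(classifications))) {
    for (g in strsplit(classifications$gene_ids[r], ",")[[1]]) {
      gene2locus[[g]] <- classifications$locus[r]
    }
  }
  vapply(models, function(m) gene2locus[[m$gene_ids[1]]] %||% NA_character_,
         character(1))
}
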
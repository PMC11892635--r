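#' Load a genome FASTA file
#'
#' Reads a (multi-record) FASTA file into a named character vector of
#' uppercase nucleotide strings. Lowercase input is uppercased and `U`
#' (RNA) is normalized to `T`; the internal alphabet is `A,C,G,T,N`.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @return named character vector, one element per record, names are the
#'   first whitespace-delimited token of each header.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgu"), fa)
#' load_genome(fa)  # c(c1 = "ACGT")
#' @export
load_genome <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- normalize_nt(as.character(set))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    off <- first_bad_base(seqs[[i]])
    if (off > 0L) {
      stop("non-nucleotide character in record '", ids[i],
           "' at offset ", off)
    }
  }
  seqs
}

#' Construct a transcript model
#'
#' One mRNA with its exons and an ordered list of ORFs (CDS groups).
#' Coordinates are 1-based inclusive genomic (GFF3 convention, which is
#' also the native convention of the R/Bioconductor stack).
#'
#' @param transcript_id transcript identifier.
#' @param chrom chromosome / contig id.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` (1-based inclusive),
#'   non-overlapping; sorted internally.
#' @param orfs list of data.frames of CDS segments (`start`, `end`), one
#'   per ORF.  Reordered internally 5'->3' in transcript orientation.
#' @param gene_ids character vector, one id per ORF (same order as
#'   `orfs` after reordering).
#' @param attributes free-form named list.
#' @param valid logical; models whose CDS length is not divisible by 3
#'   are flagged invalid by [load_annotation()].
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons, orfs,
                             gene_ids, attributes = list(), valid = TRUE) {
  stopifnot(strand %in% c("+", "-"), length(gene_ids) == length(orfs))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  orfs <- lapply(orfs, function(o) {
    o <- o[order(o$start), c("start", "end"), drop = FALSE]
    rownames(o) <- NULL
    o
  })
  # order ORFs 5'->3' in transcript orientation
  first <- vapply(orfs, function(o) min(o$start), numeric(1))
  ord <- if (strand == "+") order(first) else
    order(vapply(orfs, function(o) max(o$end), numeric(1)), decreasing = TRUE)
  structure(list(
    transcript_id = transcript_id, chrom = chrom, strand = strand,
    exons = exons, orfs = orfs[ord], gene_ids = as.character(gene_ids)[ord],
    attributes = attributes, valid = valid
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model ", x$transcript_id, " (", x$chrom, x$strand, ") ",
      nrow(x$exons), " exon(s), ", length(x$orfs), " ORF(s): ",
      paste(x$gene_ids, collapse = ", "),
      if (!x$valid) "  [INVALID]", "\n", sep = "")
  invisible(x)
}

orf_len <- function(orf) sum(orf$end - orf$start + 1L)

#' Load transcript models from a GFF3 annotation
#'
#' Dialect: `mRNA` features carry an `ID`; `exon` and `CDS` features point
#' at their mRNA via `Parent`.  CDS features sharing the same `ID`
#' attribute form one ORF, so a bicistronic mRNA has two distinct CDS
#' groups among its children.  The CDS group id doubles as the ORF/gene
#' id. ORFs are ordered 5'->3' in transcript orientation regardless of
#' strand.
#'
#' @param path GFF3 file.
#' @param genome named character vector from [load_genome()].
#' @return list of [transcript_model()] objects.  A CDS group whose
#'   spliced length is not divisible by 3 triggers a warning and flags
#'   the model invalid; CDS outside the declared exons or a chromosome
#'   absent from `genome` is a hard error.
#' @export
load_annotation <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  get_parent <- function(i) {
    p <- gr$Parent[[i]]
    if (length(p) == 0) NA_character_ else as.character(p)[1]
  }
  parents <- vapply(seq_along(gr), get_parent, character(1))
  ids <- as.character(gr$ID)
  mrna_idx <- which(typ == "mRNA")
  models <- vector("list", length(mrna_idx))
  for (k in seq_along(mrna_idx)) {
    i <- mrna_idx[k]
    tid <- ids[i]
    chrom <- as.character(GenomicRanges::seqnames(gr))[i]
    strand <- as.character(BiocGenerics::strand(gr))[i]
    if (!chrom %in% names(genome)) {
      stop("transcript ", tid, " is on '", chrom,
           "', which is absent from the genome")
    }
    child <- which(parents == tid)
    ex <- child[typ[child] == "exon"]
    cds <- child[typ[child] == "CDS"]
    exons <- data.frame(start = BiocGenerics::start(gr)[ex],
                        end = BiocGenerics::end(gr)[ex])
    if (nrow(exons) == 0) {  # exon-less dialects: mRNA span is the exon
      exons <- data.frame(start = BiocGenerics::start(gr)[i],
                          end = BiocGenerics::end(gr)[i])
    }
    cds_id <- ids[cds]
    if (anyNA(cds_id)) stop("CDS feature without ID under mRNA ", tid)
    orfs <- lapply(split(cds, cds_id), function(j) {
      data.frame(start = BiocGenerics::start(gr)[j],
                 end = BiocGenerics::end(gr)[j])
    })
    valid <- TRUE
    for (nm in names(orfs)) {
      o <- orfs[[nm]]
      inside <- vapply(seq_len(nrow(o)), function(r) {
        any(o$start[r] >= exons$start & o$end[r] <= exons$end)
      }, logical(1))
      if (!all(inside)) {
        stop("CDS group ", nm, " of mRNA ", tid,
             " lies outside the declared exons")
      }
      if (orf_len(o) %% 3L != 0L) {
        warning("CDS group ", nm, " of mRNA ", tid,
                " has length not divisible by 3; model flagged invalid")
        valid <- FALSE
      }
    }
    models[[k]] <- transcript_model(
      transcript_id = tid, chrom = chrom, strand = strand,
      exons = exons, orfs = unname(orfs), gene_ids = names(orfs),
      valid = valid
    )
  }
  models
}

#' Write transcript models to GFF3
#'
#' Inverse of [load_annotation()] (same CDS-group dialect).
#'
#' @param models list of `transcript_model`s.
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, source = "bicistroscan") {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- c(min(m$exons$start), max(m$exons$end))
    lines <- c(lines, paste(m$chrom, source, "mRNA", span[1], span[2], ".",
                            m$strand, ".", paste0("ID=", m$transcript_id),
                            sep = "\t"))
    for (r in seq_len(nrow(m$exons))) {
      lines <- c(lines, paste(m$chrom, source, "exon", m$exons$start[r],
                              m$exons$end[r], ".", m$strand, ".",
                              paste0("Parent=", m$transcript_id), sep = "\t"))
    }
    for (j in seq_along(m$orfs)) {
      o <- m$orfs[[j]]
      for (r in seq_len(nrow(o))) {
        lines <- c(lines, paste(m$chrom, source, "CDS", o$start[r], o$end[r],
                                ".", m$strand, "0",
                                paste0("ID=", m$gene_ids[j], ";Parent=",
                                       m$transcript_id), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# genomic -> transcript coordinate map for one model.
# Returns function(gpos) -> tpos (1-based along the spliced mRNA, 5'->3').
g2t_map <- function(model) {
  ex <- model$exons
  lens <- ex$end - ex$start + 1L
  cum <- cumsum(c(0L, lens))
  total <- sum(lens)
  strand <- model$strand
  function(gpos) {
    i <- which(gpos >= ex$start & gpos <= ex$end)
    if (length(i) != 1L) stop("genomic position ", gpos, " not exonic")
    tp <- cum[i] + (gpos - ex$start[i] + 1L)
    if (strand == "+") tp else total - tp + 1L
  }
}

# spliced mRNA sequence (5'->3' of the transcript)
spliced_seq <- function(model, genome) {
  chromseq <- genome[[model$chrom]]
  pieces <- vapply(seq_len(nrow(model$exons)), function(r) {
    substr(chromseq, model$exons$start[r], model$exons$end[r])
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") revcomp(s) else s
}

region_or_null <- function(mrna, start, end) {
  if (is.null(start)) return(NULL)
  list(start = start, end = end, seq = substr_safe(mrna, start, end),
       length = max(0L, end - start + 1L))
}

#' Extract per-locus region sequences
#'
#' Cuts the spliced mRNA of a transcript model into 5' UTR, ORF1,
#' inter-ORF, ORF2 and 3' UTR.  Minus-strand models are reverse
#' complemented first, so every region string reads 5'->3' of the mRNA,
#' and the concatenation of the regions present reproduces the full
#' spliced transcript.  Monocistronic models have no `inter_orf`/`orf2`.
#'
#' @param model a `transcript_model` with one or two ORFs.
#' @param genome named character vector from [load_genome()].
#' @return object of class `region_set`: list with `transcript_id`,
#'   `gene_ids`, `mrna` (full spliced sequence), `n_orfs`, and `regions`,
#'   a named list (`five_prime_utr`, `orf1`, `inter_orf`, `orf2`,
#'   `three_prime_utr`) of `list(start, end, seq, length)` in transcript
#'   coordinates (1-based inclusive; empty regions have `length` 0).
#' @export
extract_regions <- function(model, genome) {
  n <- length(model$orfs)
  if (n < 1L || n > 2L) {
    stop("extract_regions supports 1 or 2 ORFs; got ", n)
  }
  mrna <- spliced_seq(model, genome)
  L <- nchar(mrna)
  map <- g2t_map(model)
  tx_interval <- function(orf) {
    pts <- unlist(lapply(seq_len(nrow(orf)), function(r) {
      c(map(orf$start[r]), map(orf$end[r]))
    }))
    c(min(pts), max(pts))
  }
  o1 <- tx_interval(model$orfs[[1]])
  regions <- list(
    five_prime_utr = region_or_null(mrna, 1L, o1[1] - 1L),
    orf1 = region_or_null(mrna, o1[1], o1[2])
  )
  if (n == 2L) {
    o2 <- tx_interval(model$orfs[[2]])
    if (o2[1] <= o1[2]) stop("ORFs overlap in transcript coordinates")
    regions$inter_orf <- region_or_null(mrna, o1[2] + 1L, o2[1] - 1L)
    regions$orf2 <- region_or_null(mrna, o2[1], o2[2])
    regions$three_prime_utr <- region_or_null(mrna, o2[2] + 1L, L)
  } else {
    regions$three_prime_utr <- region_or_null(mrna, o1[2] + 1L, L)
  }
  structure(list(
    transcript_id = model$transcript_id, gene_ids = model$gene_ids,
    mrna = mrna, n_orfs = n, regions = regions
  ), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set ", x$transcript_id, " (", x$n_orfs, " ORF", ")\n", sep = "")
  for (nm in names(x$regions)) {
    r <- x$regions[[nm]]
    cat("  ", format(nm, width = 16), r$length, " nt\n", sep = "")
  }
  invisible(x)
}

#' Region sequence accessor
#'
#' @param rs a `region_set`.
#' @param name region name.
#' @return the region's sequence string, or `""` if the region is absent
#'   or empty.
#' @export
region_seq <- function(rs, name) {
  r <- rs$regions[[name]]
  if (is.null(r)) "" else r$seq
}
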
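KOZAK_WIDTH <- 13L
KOZAK_AUG_IDX <- 6:8          # window positions holding the invariant ATG
KOZAK_FLANK_IDX <- c(1:5, 9:13)  # the 10 scored flanking positions
KOZAK_OFFSETS <- c(-5:-1, 1:3, 4:8)  # biological offsets, A of AUG = +1

#' Build a Kozak-like position weight matrix
#'
#' Trains a PWM on 13-nt initiation-site windows: five nucleotides
#' upstream of the start codon, the invariant `ATG`, and five
#' nucleotides downstream.  Per-position information content is
#' \eqn{R_i = 2 + \sum_b p_i(b) \log_2 p_i(b)} bits (0 log 0 = 0), the
#' standard sequence-logo column height for nucleotides.  The `ATG`
#' positions are recorded but excluded from scoring.
#'
#' @param sites character vector of 13-mers; positions 6-8 must be `ATG`
#'   and no `N` is allowed (sites with incomplete upstream context must
#'   be excluded by the caller).
#' @param pseudocount added to every base count at every position before
#'   normalisation (default 0.5).
#' @return object of class `kozak_pwm`: list with `probs` (4 x 13 matrix,
#'   rows A,C,G,T), `info` (13 bit values), `n_sites`, `pseudocount`,
#'   `offsets`.
#' @examples
#' pwm <- build_kozak_pwm(c("GCCGCATGGCCGC", "GCCACATGGCAGC"))
#' pwm$info
#' @export
build_kozak_pwm <- function(sites, pseudocount = 0.5) {
  if (length(sites) == 0) stop("empty site list")
  for (i in seq_along(sites)) {
    s <- sites[i]
    if (nchar(s) != KOZAK_WIDTH) {
      stop("site ", i, " has length ", nchar(s), ", expected ", KOZAK_WIDTH)
    }
    if (substr(s, 6, 8) != "ATG") {
      stop("site ", i, " does not have ATG at positions 6-8: ", s)
    }
    if (grepl("[^ACGT]", s)) stop("site ", i, " contains non-ACGT characters")
  }
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  counts <- vapply(seq_len(KOZAK_WIDTH), function(j) {
    tab <- table(factor(mat[, j], levels = BASES))
    as.numeric(tab)
  }, numeric(4))
  rownames(counts) <- BASES
  n <- length(sites)
  probs <- (counts + pseudocount) / (n + 4 * pseudocount)
  info <- apply(probs, 2, function(p) {
    nz <- p > 0
    2 + sum(p[nz] * log2(p[nz]))
  })
  structure(list(probs = probs, info = info, n_sites = n,
                 pseudocount = pseudocount, offsets = KOZAK_OFFSETS),
            class = "kozak_pwm")
}

#' Construct a `kozak_pwm` from explicit probabilities
#'
#' Used by the simulator and for serialisation round-trips; validates the
#' same invariants as [build_kozak_pwm()].
#'
#' @param probs 4 x 13 probability matrix, rows A,C,G,T; every column
#'   must sum to 1.
#' @param n_sites,pseudocount bookkeeping fields.
#' @return a `kozak_pwm`.
#' @export
kozak_pwm_from_probs <- function(probs, n_sites = NA_integer_,
                                 pseudocount = NA_real_) {
  stopifnot(nrow(probs) == 4, ncol(probs) == KOZAK_WIDTH)
  rownames(probs) <- BASES
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    stop("PWM columns must each sum to 1")
  }
  info <- apply(probs, 2, function(p) {
    nz <- p > 0
    2 + sum(p[nz] * log2(p[nz]))
  })
  structure(list(probs = probs, info = info, n_sites = n_sites,
                 pseudocount = pseudocount, offsets = KOZAK_OFFSETS),
            class = "kozak_pwm")
}

#' @export
print.kozak_pwm <- function(x, ...) {
  cat("kozak_pwm trained on", x$n_sites, "site(s); consensus:",
      consensus_site(x), "\n")
  cat("information content (bits):",
      paste(round(x$info, 2), collapse = " "), "\n")
  invisible(x)
}

#' Consensus (argmax) site of a PWM
#'
#' @param pwm a `kozak_pwm`.
#' @return the 13-mer taking the most probable base at every position
#'   (the `ATG` positions always yield `ATG` when columns are valid;
#'   they are forced regardless).
#' @export
consensus_site <- function(pwm) {
  b <- BASES[apply(pwm$probs, 2, which.max)]
  b[KOZAK_AUG_IDX] <- c("A", "T", "G")
  paste(b, collapse = "")
}

#' Bit score of an initiation-site window
#'
#' The score is the mean, over the 10 flanking positions, of the
#' sequence-logo letter height \eqn{p_i(x_i) \cdot R_i}, giving a 0-2 bit
#' scale.  Positions holding `N` (or lying outside a truncated window)
#' are skipped and the mean renormalised over the scored positions; if
#' more than 3 of the 10 flanks are unscorable the score is `NA`.
#'
#' @param site a 13-mer (may contain `N`; may be padded with `N` by
#'   [cut_site_window()] when the transcript end truncates the window).
#' @param pwm a `kozak_pwm`.
#' @return numeric bit score in `[0, 2]`, or `NA` if unscorable.
#' @export
kozak_bit_score <- function(site, pwm) {
  if (nchar(site) != KOZAK_WIDTH) {
    stop("site has length ", nchar(site), ", expected ", KOZAK_WIDTH,
         " (pad truncated windows with N)")
  }
  cc <- chars(site)
  heights <- numeric(0)
  for (j in KOZAK_FLANK_IDX) {
    b <- cc[j]
    if (b %in% BASES) {
      heights <- c(heights, pwm$probs[b, j] * pwm$info[j])
    }
  }
  if (length(heights) < length(KOZAK_FLANK_IDX) - 3L) return(NA_real_)
  mean(heights)
}

#' Cut a 13-nt initiation window from an mRNA
#'
#' @param mrna spliced transcript sequence (5'->3').
#' @param start_pos transcript position of the `A` of the start codon.
#' @return 13-mer centred on the codon, `N`-padded where the window runs
#'   off either transcript end.
#' @export
cut_site_window <- function(mrna, start_pos) {
  L <- nchar(mrna)
  idx <- (start_pos - 5L):(start_pos + 7L)
  paste(vapply(idx, function(i) {
    if (i < 1L || i > L) "N" else substr(mrna, i, i)
  }, character(1)), collapse = "")
}

# all ATG 3-mer start positions in mrna[from..to] (3-mer fully inside)
atg_positions <- function(mrna, from, to) {
  if (to - from + 1L < 3L) return(integer(0))
  s <- substr(mrna, from, to)
  hits <- gregexpr("(?=ATG)", s, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) + from - 1L
}

#' Kozak profile of a bicistronic locus
#'
#' Scores the annotated ORF1 and ORF2 initiation windows of a
#' bicistronic transcript and enumerates every other `ATG` 3-mer (any
#' frame) in the 5' UTR + ORF1 + inter-ORF region — the "internal" start
#' sites a leaky-scanning ribosome could use — each scored with a window
#' cut from the full mRNA.
#'
#' @param regions a bicistronic `region_set`.
#' @param pwm a `kozak_pwm`.
#' @return list with `orf1_score`, `orf2_score`, `ratio`
#'   (orf1/orf2), and `internal_sites`, a data.frame of `position`
#'   (transcript coordinate of the A), `frame` (0/1/2 relative to the
#'   ORF1 reading frame) and `score`.
#' @export
locus_kozak_profile <- function(regions, pwm) {
  stopifnot(regions$n_orfs == 2L)
  o1 <- regions$regions$orf1$start
  o2 <- regions$regions$orf2$start
  s1 <- kozak_bit_score(cut_site_window(regions$mrna, o1), pwm)
  s2 <- kozak_bit_score(cut_site_window(regions$mrna, o2), pwm)
  # internal starts: ATG 3-mers fully upstream of ORF2, minus the ORF1 start
  pos <- atg_positions(regions$mrna, 1L, o2 - 1L)
  pos <- pos[pos != o1]
  internal <- data.frame(position = integer(0), frame = integer(0),
                         score = numeric(0))
  if (length(pos) > 0) {
    internal <- data.frame(
      position = pos,
      frame = (pos - o1) %% 3L,
      score = vapply(pos, function(p) {
        kozak_bit_score(cut_site_window(regions$mrna, p), pwm)
      }, numeric(1)))
  }
  list(orf1_score = s1, orf2_score = s2,
       ratio = if (!is.na(s2) && s2 > 0) s1 / s2 else NA_real_,
       internal_sites = internal)
}

#' Random half split of monocistronic ids
#'
#' Half the monocistronic genes train the consensus PWM; the other half
#' provide the background bit-score distribution.  Odd counts put the
#' extra id in the evaluation half.
#'
#' @param ids character vector (length >= 2).
#' @param seed integer seed; the split is reproducible under it.
#' @return list with `train` and `eval` character vectors (disjoint,
#'   union = `ids`).
#' @export
split_train_eval <- function(ids, seed) {
  if (length(ids) < 2L) stop("need at least 2 ids to split")
  n_train <- length(ids) %/% 2L
  perm <- withr::with_seed(seed, sample(ids))
  list(train = sort(perm[seq_len(n_train)]),
       eval = sort(perm[(n_train + 1L):length(ids)]))
}

#' Serialise a PWM to JSON
#'
#' @param pwm a `kozak_pwm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kozak_pwm <- function(pwm, path) {
  obj <- list(offsets = pwm$offsets,
              probs = as.data.frame(t(pwm$probs)),
              info = pwm$info, n_sites = pwm$n_sites,
              pseudocount = pwm$pseudocount)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a PWM from JSON written by [write_kozak_pwm()]
#'
#' @param path JSON file.
#' @return a `kozak_pwm`.
#' @export
read_kozak_pwm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  probs <- t(as.matrix(obj$probs[, BASES]))
  dimnames(probs) <- list(BASES, NULL)
  kozak_pwm_from_probs(probs, n_sites = obj$n_sites,
                       pseudocount = obj$pseudocount)
}
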
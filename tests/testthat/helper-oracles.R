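# Independent oracles and small fixture builders used across the suite.
# Every oracle recomputes its quantity from first principles, sharing no
# code path with the implementation it checks.

BASES4 <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- bit score oracle: naive per-position letter-height mean, with the
# column information content recomputed from the probabilities ----------
oracle_bit_score <- function(site, pwm) {
  flanks <- c(1:5, 9:13)
  vals <- numeric(0)
  for (j in flanks) {
    b <- substr(site, j, j)
    if (b %in% BASES4) {
      p <- pwm$probs[, j]
      h <- 0
      for (q in p) if (q > 0) h <- h - q * log2(q)
      vals <- c(vals, pwm$probs[b, j] * (2 - h))
    }
  }
  if (length(vals) < 7) NA_real_ else sum(vals) / length(vals)
}

# --- random PWM with Dirichlet(1) columns, ATG fixed -------------------
random_pwm <- function() {
  p <- vapply(1:13, function(j) {
    x <- stats::rgamma(4, 1)
    x / sum(x)
  }, numeric(4))
  p[, 6] <- c(1, 0, 0, 0)
  p[, 7] <- c(0, 0, 0, 1)
  p[, 8] <- c(0, 0, 1, 0)
  kozak_pwm_from_probs(p)
}

# sample a site from a PWM, independent of the package's sampler
draw_site <- function(pwm) {
  b <- vapply(1:13, function(j) sample(BASES4, 1, prob = pwm$probs[, j]),
              character(1))
  b[6:8] <- c("A", "T", "G")
  paste(b, collapse = "")
}

# empirical bit-score background of the simulator's default PWM
site_score_ref <- function(n = 500) {
  pwm <- default_kozak_pwm()
  vapply(seq_len(n), function(i) kozak_bit_score(draw_site(pwm), pwm),
         numeric(1))
}

# --- AUG count oracle: explicit sliding window -------------------------
oracle_count_aug <- function(seq) {
  n <- nchar(seq)
  if (n < 3) return(0L)
  k <- 0L
  for (i in 1:(n - 2)) if (substr(seq, i, i + 2) == "ATG") k <- k + 1L
  k
}

# --- uORF oracle: enumerate all (ATG, in-frame stop) pairs fully inside
# the UTR, keep pairs with no earlier in-frame stop ---------------------
oracle_uorfs <- function(utr, min_nt) {
  n <- nchar(utr)
  out <- NULL
  for (i in seq_len(max(0, n - 2))) {
    if (substr(utr, i, i + 2) != "ATG") next
    stops <- c()
    p <- i + 3
    while (p + 2 <= n) {
      if (substr(utr, p, p + 2) %in% c("TAA", "TAG", "TGA")) {
        stops <- c(stops, p)
      }
      p <- p + 3
    }
    if (length(stops) > 0) {
      s <- min(stops)  # translation terminates at the first stop
      len <- s + 2 - i + 1
      if (len >= min_nt) out <- rbind(out, c(i, s + 2, len))
    }
  }
  if (is.null(out)) {
    data.frame(start = integer(0), end = integer(0), length = integer(0))
  } else {
    data.frame(start = out[, 1], end = out[, 2], length = out[, 3])
  }
}

# --- exact Wilcoxon oracle: enumerate every assignment of m ranks,
# symmetric-tail two-sided probability ----------------------------------
oracle_wilcoxon_p <- function(x, y) {
  m <- length(x)
  N <- m + length(y)
  rk <- rank(c(x, y))
  w <- sum(rk[seq_len(m)])
  e <- m * (N + 1) / 2
  sets <- combn(N, m)
  wdist <- apply(sets, 2, sum)
  mean(abs(wdist - e) >= abs(w - e) - 1e-12)
}

# --- fixture builders --------------------------------------------------
tmp_fasta <- function(records) {
  f <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), f)
  f
}

tmp_gff <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

gffline <- function(chrom, type, start, end, strand, attrs) {
  paste(chrom, "test", type, start, end, ".", strand,
        if (type == "CDS") "0" else ".", attrs, sep = "\t")
}

# a minimal region_set for functions that only need region sequences
make_rs <- function(id, utr5, orf1, inter = NULL, orf2 = NULL, utr3 = "") {
  seqs <- c(utr5, orf1, inter, orf2, utr3)
  mrna <- paste(seqs, collapse = "")
  pos <- 1L
  mk <- function(s) {
    if (is.null(s)) return(NULL)
    r <- list(start = pos, end = pos + nchar(s) - 1L, seq = s,
              length = nchar(s))
    pos <<- pos + nchar(s)
    r
  }
  regions <- list(five_prime_utr = mk(utr5), orf1 = mk(orf1))
  if (!is.null(orf2)) {
    regions$inter_orf <- mk(inter)
    regions$orf2 <- mk(orf2)
    regions$three_prime_utr <- mk(utr3)
  } else {
    regions$three_prime_utr <- mk(utr3)
  }
  structure(list(transcript_id = id,
                 gene_ids = if (is.null(orf2)) id else paste0(id, c("_1", "_2")),
                 mrna = mrna, n_orfs = if (is.null(orf2)) 1L else 2L,
                 regions = regions), class = "region_set")
}

# random iid sequence at a composition
rseq <- function(n, comp = rep(0.25, 4)) {
  paste(sample(BASES4, n, replace = TRUE, prob = comp), collapse = "")
}
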
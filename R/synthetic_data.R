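#' Default Kozak-like PWM used by the simulator
#'
#' A GC-biased green-algal-style initiation context: purine at -3, C-rich
#' flanks, G at +4, with the invariant `ATG` at the codon positions.
#' Used to sample planted initiation sites; analysis PWMs are always
#' re-trained from the simulated monocistronic genes, never taken from
#' here.
#'
#' @return a `kozak_pwm`.
#' @export
default_kozak_pwm <- function() {
  # columns: -5 -4 -3 -2 -1 | A T G | +4 +5 +6 +7 +8 ; rows A,C,G,T
  p <- cbind(
    c(.10, .50, .30, .10),  # -5
    c(.10, .55, .25, .10),  # -4
    c(.55, .08, .30, .07),  # -3: A/G purine, strongly conserved
    c(.10, .55, .25, .10),  # -2
    c(.08, .65, .20, .07),  # -1: C-rich (GC-biased algae)
    c(1, 0, 0, 0),          # +1 A
    c(0, 0, 0, 1),          # +2 T
    c(0, 0, 1, 0),          # +3 G
    c(.10, .15, .65, .10),  # +4: G, strongly conserved
    c(.18, .34, .30, .18),  # +5
    c(.18, .32, .32, .18),  # +6
    c(.18, .32, .32, .18),  # +7
    c(.18, .32, .32, .18)   # +8
  )
  kozak_pwm_from_probs(p, n_sites = NA_integer_, pseudocount = 0)
}

#' Simulation parameterisation
#'
#' All defaults are chosen to make the synthetic world resemble the
#' structural and statistical regime of curated green-algal bicistron
#' sets: region length medians (5' UTR 83 nt, ORF1 357 nt, ORF2 1113 nt,
#' inter-ORF 183 nt, monocistronic ORF 1509 nt / UTR 214 nt), a GC-rich
#' (~0.64) base composition, AUG depletion targets per region class
#' (UTR ~0.5, ORF1 ~0.7, coding regions ~1), weak-tail ORF1 / strong-tail
#' ORF2 initiation contexts, RNA-level ORF1-ORF2 log-scale correlation
#' 0.92, and a ribosome leak model `leak = exp(-k * strength)`.
#'
#' @param seed integer RNG seed; every generator output is a pure
#'   function of the spec including this seed.
#' @param n_mono,n_bicistron locus counts.
#' @param len_medians named nt medians of the log-normal length
#'   distributions.
#' @param len_sdlog common log-sd of the length distributions.
#' @param composition base probabilities (named A,C,G,T; sums to 1).
#' @param aug_oe named per-region AUG observed/expected targets in
#'   `[0, 1]` (AUG occurrences are thinned to the target in
#'   expectation).
#' @param bands named list of percentile bands (`weak_tail`, `typical`,
#'   `strong_tail`) as `c(low, high]` percentages.
#' @param site_bands which band each site role draws from.
#' @param splice_prob probability a transcript carries 1-2 introns.
#' @param intergenic_median median intergenic spacer (nt) between
#'   neighbouring loci on the pseudo-chromosome.
#' @param expression list: `mu_log10`, `sd_log10` for RNA abundance,
#'   planted ORF1-ORF2 log-scale correlation `r`, translational noise
#'   `te_sd`, leak steepness `k`, leak noise `leak_sd`.
#' @param homology list: `colinear_fraction` of bicistrons planted as
#'   colinear in the target genome, `decoy_hits` per query.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L,
                     n_mono = 500L,
                     n_bicistron = 50L,
                     len_medians = c(utr5 = 83, orf1 = 357, orf2 = 1113,
                                     inter_orf = 183, mono_orf = 1509,
                                     mono_utr = 214, utr3 = 200),
                     len_sdlog = 0.5,
                     composition = c(A = 0.18, C = 0.32, G = 0.32, T = 0.18),
                     aug_oe = c(five_prime_utr = 0.5, orf1 = 0.7,
                                inter_orf = 0.5, orf2 = 1.0,
                                mono_utr = 0.5, mono_orf = 1.0),
                     bands = list(weak_tail = c(0, 30), typical = c(30, 70),
                                  strong_tail = c(70, 100)),
                     site_bands = c(orf1 = "weak_tail", orf2 = "strong_tail",
                                    mono = "typical"),
                     splice_prob = 0.3,
                     intergenic_median = 2500,
                     expression = list(mu_log10 = 2, sd_log10 = 0.6,
                                       r = 0.92, te_sd = 0.2, k = 10,
                                       leak_sd = 0.8),
                     homology = list(colinear_fraction = 0.6,
                                     decoy_hits = 2L)) {
  stopifnot(abs(sum(composition) - 1) < 1e-9, n_mono >= 1, n_bicistron >= 1,
            all(aug_oe >= 0))
  structure(list(seed = as.integer(seed), n_mono = as.integer(n_mono),
                 n_bicistron = as.integer(n_bicistron),
                 len_medians = len_medians, len_sdlog = len_sdlog,
                 composition = composition, aug_oe = aug_oe, bands = bands,
                 site_bands = site_bands, splice_prob = splice_prob,
                 intergenic_median = intergenic_median,
                 expression = expression, homology = homology),
            class = "sim_spec")
}

rand_len <- function(n, median, sdlog) {
  pmax(10, round(stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)))
}

rand_seq <- function(n, comp) {
  paste(sample(BASES, n, replace = TRUE, prob = comp), collapse = "")
}

# thin ATG 3-mers: keep each occurrence with probability `target`,
# otherwise mutate the T to C (cannot create a stop codon or a new ATG)
thin_aug <- function(seq, target) {
  if (target >= 1) return(seq)
  pos <- atg_positions(seq, 1L, nchar(seq))
  for (p in pos) {
    if (stats::runif(1) > target) substr(seq, p + 1L, p + 1L) <- "C"
  }
  seq
}

# sample one 13-mer from a PWM (ATG forced at the codon positions)
sample_site <- function(pwm) {
  b <- vapply(seq_len(KOZAK_WIDTH), function(j) {
    sample(BASES, 1, prob = pwm$probs[, j])
  }, character(1))
  b[KOZAK_AUG_IDX] <- c("A", "T", "G")
  paste(b, collapse = "")
}

# empirical background of PWM-sampled site scores (for percentile bands)
site_score_reference <- function(pwm, n = 1000L) {
  vapply(seq_len(n), function(i) kozak_bit_score(sample_site(pwm), pwm),
         numeric(1))
}

# rejection-sample a site whose score percentile falls in `band`
# (half-open (low, high]); codon 2 of the downstream flank must not be a
# stop codon so the site can seed a valid ORF
sample_site_in_band <- function(pwm, ref_scores, band, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    s <- sample_site(pwm)
    if (substr(s, 9, 11) %in% STOP_CODONS) next
    pct <- 100 * mean(ref_scores <= kozak_bit_score(s, pwm))
    if (pct > band[1] && pct <= band[2]) return(s)
  }
  stop("percentile band (", band[1], ",", band[2],
       "] unattainable after ", max_tries, " rejections")
}

# n random non-stop codons (vectorised with resampling of the few stops)
body_codons <- function(n, comp) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(BASES, 3L * n, replace = TRUE, prob = comp), nrow = 3L)
  cods <- paste0(m[1, ], m[2, ], m[3, ])
  bad <- which(cods %in% STOP_CODONS)
  while (length(bad) > 0) {
    m2 <- matrix(sample(BASES, 3L * length(bad), replace = TRUE, prob = comp),
                 nrow = 3L)
    cods[bad] <- paste0(m2[1, ], m2[2, ], m2[3, ])
    bad <- bad[cods[bad] %in% STOP_CODONS]
  }
  cods
}

# random ORF: ATG + body codons (no stops) + stop codon; then embed the
# downstream site flank and thin internal AUGs to the target o/e
make_orf <- function(len, comp, target_oe, site) {
  len <- max(30L, (len %/% 3L) * 3L)
  n_body <- len / 3L - 2L
  orf <- paste0("ATG", paste(body_codons(n_body, comp), collapse = ""),
                sample(STOP_CODONS, 1))
  # plant the +4..+8 flank of the initiation site
  substr(orf, 4L, 8L) <- substr(site, 9L, 13L)
  # codon 3 may have become a stop through the overwrite; C-fix its 3rd base
  if (substr(orf, 7L, 9L) %in% STOP_CODONS) substr(orf, 9L, 9L) <- "C"
  # thin internal AUGs (all frames), keeping the initiator
  pos <- atg_positions(orf, 2L, nchar(orf))
  for (p in pos) {
    if (stats::runif(1) > target_oe) substr(orf, p + 1L, p + 1L) <- "C"
  }
  orf
}

# plant the upstream flank of a site at the end of a region (length >= 5)
plant_upstream_flank <- function(region, site) {
  n <- nchar(region)
  substr(region, n - 4L, n) <- substr(site, 1L, 5L)
  region
}

# insert 0-2 introns into a transcript: returns genomic (plus-oriented)
# sequence, exon intervals (local), and a tx->genomic offset map
intronate <- function(tx_seq, splice_prob, comp) {
  L <- nchar(tx_seq)
  k <- if (stats::runif(1) < splice_prob && L > 40L) sample(1:2, 1) else 0L
  if (k == 0L) {
    return(list(gseq = tx_seq, exons = data.frame(start = 1L, end = L),
                tx2g = function(t) t))
  }
  cuts <- sort(sample(20:(L - 20L), k))
  intron_lens <- 80L + stats::rgeom(k, 1 / 100)
  introns <- vapply(intron_lens, function(n) {
    paste0("GT", rand_seq(n, comp), "AG")
  }, character(1))
  pieces <- character(0)
  exons <- data.frame(start = integer(0), end = integer(0))
  gpos <- 0L
  tprev <- 0L
  offsets <- integer(0)   # genomic offset applying to tx positions > cut
  bounds <- c(cuts, L)
  for (i in seq_along(bounds)) {
    seg <- substr(tx_seq, tprev + 1L, bounds[i])
    exons <- rbind(exons, data.frame(start = gpos + 1L,
                                     end = gpos + nchar(seg)))
    pieces <- c(pieces, seg)
    gpos <- gpos + nchar(seg)
    tprev <- bounds[i]
    if (i <= length(cuts)) {
      pieces <- c(pieces, introns[i])
      gpos <- gpos + nchar(introns[i])
    }
  }
  ex <- exons
  tx_lens <- ex$end - ex$start + 1L
  tx_starts <- cumsum(c(0L, tx_lens[-length(tx_lens)])) + 1L
  tx2g <- function(t) {
    i <- max(which(tx_starts <= t))
    ex$start[i] + (t - tx_starts[i])
  }
  list(gseq = paste(pieces, collapse = ""), exons = ex, tx2g = tx2g)
}

# tx interval -> genomic (local, plus-oriented) CDS segments
tx_interval_to_segments <- function(a, b, exons, tx2g) {
  tx_lens <- exons$end - exons$start + 1L
  tx_starts <- cumsum(c(0L, tx_lens[-length(tx_lens)])) + 1L
  tx_ends <- tx_starts + tx_lens - 1L
  segs <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(nrow(exons))) {
    lo <- max(a, tx_starts[i])
    hi <- min(b, tx_ends[i])
    if (lo <= hi) {
      segs <- rbind(segs, data.frame(start = tx2g(lo), end = tx2g(hi)))
    }
  }
  segs
}

mirror_intervals <- function(df, G) {
  out <- data.frame(start = G - df$end + 1L, end = G - df$start + 1L)
  out[order(out$start), , drop = FALSE]
}

#' Simulate a genome with planted mono- and bicistronic loci
#'
#' Generates one pseudo-chromosome carrying `n_mono` monocistronic and
#' `n_bicistron` exclusively bicistronic loci (random strands, optional
#' introns), with region lengths drawn from the spec's log-normal
#' distributions, initiation-site contexts rejection-sampled from the
#' generator PWM inside the requested percentile bands, and per-region
#' AUG content thinned to the target observed/expected ratio in
#' expectation.  Deterministic under `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @param outdir if non-NULL, writes `genome.fa`, `annotation.gff3` and
#'   `truth.tsv` there.
#' @return list with `genome` (named character), `models` (list of
#'   `transcript_model`), `truth` (data.frame, one row per locus:
#'   ids, class, strand, planted region lengths, site 13-mers, bands and
#'   generator-PWM scores), `pwm` (the generator PWM) and `ref_scores`
#'   (the empirical site-score background used for banding).
#' @export
simulate_genome <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$seed, {
    pwm <- default_kozak_pwm()
    ref <- site_score_reference(pwm)
    comp <- spec$composition
    md <- spec$len_medians
    sdl <- spec$len_sdlog
    n_total <- spec$n_mono + spec$n_bicistron
    is_bic <- sample(c(rep(TRUE, spec$n_bicistron), rep(FALSE, spec$n_mono)))
    chrom_parts <- character(0)
    gpos <- 0L
    models <- list()
    truth <- list()
    i_bic <- 0L
    i_mono <- 0L
    for (i in seq_len(n_total)) {
      spacer <- rand_len(1, spec$intergenic_median, sdl)
      chrom_parts <- c(chrom_parts, rand_seq(spacer, comp))
      gpos <- gpos + spacer
      strand <- sample(c("+", "-"), 1)
      if (is_bic[i]) {
        i_bic <- i_bic + 1L
        lid <- sprintf("bic%03d", i_bic)
        tid <- paste0("t_", lid)
        gids <- paste0("g_", lid, c("_1", "_2"))
        site1 <- sample_site_in_band(pwm, ref,
                                     spec$bands[[spec$site_bands[["orf1"]]]])
        site2 <- sample_site_in_band(pwm, ref,
                                     spec$bands[[spec$site_bands[["orf2"]]]])
        utr5 <- plant_upstream_flank(
          thin_aug(rand_seq(rand_len(1, md[["utr5"]], sdl), comp),
                   spec$aug_oe[["five_prime_utr"]]), site1)
        orf1 <- make_orf(rand_len(1, md[["orf1"]], sdl), comp,
                         spec$aug_oe[["orf1"]], site1)
        inter <- plant_upstream_flank(
          thin_aug(rand_seq(max(6L, rand_len(1, md[["inter_orf"]], sdl)),
                            comp), spec$aug_oe[["inter_orf"]]), site2)
        orf2 <- make_orf(rand_len(1, md[["orf2"]], sdl), comp,
                         spec$aug_oe[["orf2"]], site2)
        utr3 <- rand_seq(rand_len(1, md[["utr3"]], sdl), comp)
        tx <- paste0(utr5, orf1, inter, orf2, utr3)
        o1 <- c(nchar(utr5) + 1L, nchar(utr5) + nchar(orf1))
        o2 <- c(o1[2] + nchar(inter) + 1L,
                o1[2] + nchar(inter) + nchar(orf2))
        orf_tx <- list(o1, o2)
        site_info <- data.frame(
          gene = gids, band = spec$site_bands[c("orf1", "orf2")],
          site = c(site1, site2),
          score = c(kozak_bit_score(site1, pwm),
                    kozak_bit_score(site2, pwm)))
        cls <- "bicistronic_exclusive"
        lens <- c(utr5 = nchar(utr5), orf1 = nchar(orf1),
                  inter_orf = nchar(inter), orf2 = nchar(orf2))
      } else {
        i_mono <- i_mono + 1L
        lid <- sprintf("mono%03d", i_mono)
        tid <- paste0("t_", lid)
        gids <- paste0("g_", lid)
        site1 <- sample_site_in_band(pwm, ref,
                                     spec$bands[[spec$site_bands[["mono"]]]])
        utr5 <- plant_upstream_flank(
          thin_aug(rand_seq(rand_len(1, md[["mono_utr"]], sdl), comp),
                   spec$aug_oe[["mono_utr"]]), site1)
        orf1 <- make_orf(rand_len(1, md[["mono_orf"]], sdl), comp,
                         spec$aug_oe[["mono_orf"]], site1)
        utr3 <- rand_seq(rand_len(1, md[["utr3"]], sdl), comp)
        tx <- paste0(utr5, orf1, utr3)
        orf_tx <- list(c(nchar(utr5) + 1L, nchar(utr5) + nchar(orf1)))
        site_info <- data.frame(gene = gids,
                                band = spec$site_bands[["mono"]],
                                site = site1,
                                score = kozak_bit_score(site1, pwm))
        cls <- "monocistronic"
        lens <- c(utr5 = nchar(utr5), orf1 = nchar(orf1),
                  inter_orf = NA, orf2 = NA)
      }
      intr <- intronate(tx, spec$splice_prob, comp)
      G <- nchar(intr$gseq)
      exons <- intr$exons
      segs <- lapply(orf_tx, function(iv) {
        tx_interval_to_segments(iv[1], iv[2], exons, intr$tx2g)
      })
      locus_seq <- intr$gseq
      if (strand == "-") {
        locus_seq <- revcomp(locus_seq)
        exons <- mirror_intervals(exons, G)
        segs <- lapply(segs, mirror_intervals, G = G)
      }
      exons$start <- exons$start + gpos
      exons$end <- exons$end + gpos
      segs <- lapply(segs, function(s) {
        s$start <- s$start + gpos
        s$end <- s$end + gpos
        s
      })
      chrom_parts <- c(chrom_parts, locus_seq)
      gpos <- gpos + G
      models[[length(models) + 1L]] <- transcript_model(
        transcript_id = tid, chrom = "chr1", strand = strand,
        exons = exons, orfs = segs, gene_ids = gids)
      truth[[length(truth) + 1L]] <- data.frame(
        locus = lid, transcript_id = tid, class = cls, strand = strand,
        gene1 = gids[1], gene2 = if (length(gids) > 1) gids[2] else NA,
        utr5_len = lens[["utr5"]], orf1_len = lens[["orf1"]],
        inter_orf_len = lens[["inter_orf"]], orf2_len = lens[["orf2"]],
        orf1_band = site_info$band[1], orf1_site = site_info$site[1],
        orf1_score = site_info$score[1],
        orf2_band = if (nrow(site_info) > 1) site_info$band[2] else NA,
        orf2_site = if (nrow(site_info) > 1) site_info$site[2] else NA,
        orf2_score = if (nrow(site_info) > 1) site_info$score[2] else NA,
        stringsAsFactors = FALSE)
    }
    chrom_parts <- c(chrom_parts, rand_seq(500L, comp))
    genome <- c(chr1 = paste(chrom_parts, collapse = ""))
    truth <- do.call(rbind, truth)
    out <- list(genome = genome, models = models, truth = truth,
                pwm = pwm, ref_scores = ref)
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(genome, file.path(outdir, "genome.fa"))
      write_gff3(models, file.path(outdir, "annotation.gff3"))
      utils::write.table(truth, file.path(outdir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  })
}

#' Simulate per-ORF RNA-Seq / Ribo-Seq abundances
#'
#' RNA abundances of a bicistron's two ORFs are drawn from a bivariate
#' normal on the log10 scale with the planted correlation `r`; ribosome
#' occupancy of ORF1 is the RNA value times multiplicative noise, and
#' ORF2 occupancy follows the attenuation model
#' `ribo2 = ribo1 * exp(-k * strength) * noise`, where `strength` is the
#' planted generator-PWM bit score of the ORF1 initiation site.
#' Monocistronic ORFs get independent values.  Deterministic under
#' `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @param truth truth table from [simulate_genome()].
#' @param outdir if non-NULL, writes `abundance.tsv` there.
#' @return data.frame with `orf_id`, `rna`, `ribo`.
#' @export
simulate_expression <- function(spec, truth, outdir = NULL) {
  ex <- spec$expression
  withr::with_seed(spec$seed + 1L, {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      z1 <- stats::rnorm(1, ex$mu_log10, ex$sd_log10)
      rna1 <- 10^z1
      ribo1 <- rna1 * exp(stats::rnorm(1, 0, ex$te_sd))
      if (tr$class == "bicistronic_exclusive") {
        z2 <- ex$mu_log10 + ex$r * (z1 - ex$mu_log10) +
          sqrt(1 - ex$r^2) * ex$sd_log10 * stats::rnorm(1)
        rna2 <- 10^z2
        leak <- exp(-ex$k * tr$orf1_score)
        ribo2 <- ribo1 * leak * exp(stats::rnorm(1, 0, ex$leak_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          orf_id = c(tr$gene1, tr$gene2), rna = c(rna1, rna2),
          ribo = c(ribo1, ribo2))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          orf_id = tr$gene1, rna = rna1, ribo = ribo1)
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(tab, file.path(outdir, "abundance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    tab
  })
}

blast6_row <- function(q, s, evalue, bitscore) {
  data.frame(qseqid = q, sseqid = s, pident = 80, length = 200, mismatch = 40,
             gapopen = 1, qstart = 1, qend = 200, sstart = 1, send = 200,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

#' Simulate homology hit tables and a target-genome gene map
#'
#' The first `floor(colinear_fraction * n_bicistron)` bicistrons are
#' planted as colinear in the target genome: both ORFs get
#' reciprocal-best ortholog hits whose target genes are adjacent on the
#' same strand.  The remaining bicistrons get ortholog pairs broken
#' either by opposite strands or by an intervening same-strand gene, so
#' the planted colinear set is recovered exactly.  Decoy hits with
#' strictly lower bitscores are added to both tables.  Deterministic
#' under `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @param truth truth table from [simulate_genome()].
#' @param outdir if non-NULL, writes `hits_q2t.tsv`, `hits_t2q.tsv` and
#'   `target_genes.tsv` there.
#' @return list with `q2t`, `t2q` (12-column hit data.frames),
#'   `target_genes` (`gene_id`, `chrom`, `strand`, `start`, `end`),
#'   `bicistrons` (`locus`, `orf1_gene`, `orf2_gene`) and
#'   `planted_colinear` (character vector of locus ids).
#' @export
simulate_homology <- function(spec, truth, outdir = NULL) {
  bic <- truth[truth$class == "bicistronic_exclusive", , drop = FALSE]
  n <- nrow(bic)
  n_col <- floor(spec$homology$colinear_fraction * n)
  withr::with_seed(spec$seed + 2L, {
    q2t <- list()
    t2q <- list()
    tg <- list()
    pos <- 0L
    add_gene <- function(id, strand, len = 900L, gap = 400L) {
      tg[[length(tg) + 1L]] <<- data.frame(
        gene_id = id, chrom = "tchr1", strand = strand,
        start = pos + gap + 1L, end = pos + gap + len)
      pos <<- pos + gap + len
    }
    all_targets <- character(0)
    for (i in seq_len(n)) {
      t1 <- paste0("T_", bic$locus[i], "_1")
      t2 <- paste0("T_", bic$locus[i], "_2")
      all_targets <- c(all_targets, t1, t2)
      if (i <= n_col) {
        strand <- sample(c("+", "-"), 1)
        add_gene(t1, strand)
        add_gene(t2, strand)
      } else if (i %% 2L == 0L) {
        add_gene(t1, "+")
        add_gene(t2, "-")           # opposite strands
      } else {
        add_gene(t1, "+")
        add_gene(paste0("T_", bic$locus[i], "_X"), "+")  # intervener
        add_gene(t2, "+")
      }
      bs <- 300 + stats::runif(2, 0, 50)
      q2t[[length(q2t) + 1L]] <- blast6_row(bic$gene1[i], t1, 1e-30, bs[1])
      q2t[[length(q2t) + 1L]] <- blast6_row(bic$gene2[i], t2, 1e-30, bs[2])
      t2q[[length(t2q) + 1L]] <- blast6_row(t1, bic$gene1[i], 1e-30, bs[1])
      t2q[[length(t2q) + 1L]] <- blast6_row(t2, bic$gene2[i], 1e-30, bs[2])
    }
    # decoys: weaker cross-hits that must never win best-hit selection
    for (i in seq_len(n)) {
      for (d in seq_len(spec$homology$decoy_hits)) {
        tgt <- sample(all_targets, 1)
        q2t[[length(q2t) + 1L]] <- blast6_row(
          bic$gene1[i], tgt, 1e-3, 40 + stats::runif(1, 0, 10))
        t2q[[length(t2q) + 1L]] <- blast6_row(
          tgt, sample(c(bic$gene1, bic$gene2), 1), 1e-3,
          40 + stats::runif(1, 0, 10))
      }
    }
    out <- list(q2t = do.call(rbind, q2t), t2q = do.call(rbind, t2q),
                target_genes = do.call(rbind, tg),
                bicistrons = data.frame(locus = bic$locus,
                                        orf1_gene = bic$gene1,
                                        orf2_gene = bic$gene2,
                                        stringsAsFactors = FALSE),
                planted_colinear = bic$locus[seq_len(n_col)])
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(out$q2t, file.path(outdir, "hits_q2t.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      utils::write.table(out$t2q, file.path(outdir, "hits_t2q.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      utils::write.table(out$target_genes,
                         file.path(outdir, "target_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  })
}
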
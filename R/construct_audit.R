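#' Default audit rule thresholds
#'
#' The design rules for a leaky-scanning bicistronic construct are
#' qualitative (short 5' UTR; suboptimal ORF1 Kozak context; no AUG
#' upstream of ORF2 besides the ORF1 start; strong ORF2 Kozak context);
#' the percentile bands that operationalise them are configuration, not
#' biology: ORF1 is "suboptimal" at or below the 40th percentile of the
#' monocistronic score distribution, ORF2 "strong" at or above the 60th,
#' and the 5' UTR "short" at or below the 50th percentile of the
#' reference UTR length distribution.
#'
#' @return named list of thresholds (percent).
#' @export
audit_thresholds <- function() {
  list(utr_max_pct = 50, orf1_max_pct = 40, orf2_min_pct = 60)
}

pct_of <- function(value, reference) {
  if (length(reference) == 0) return(NA_real_)
  100 * mean(reference <= value)
}

#' Audit a bicistronic construct against leaky-scanning design rules
#'
#' Checks an mRNA-level construct design: (i) the 5' UTR should be short
#' relative to the reference length distribution, (ii) the ORF1 Kozak
#' context should sit in the suboptimal band of the reference score
#' distribution, (iii) no AUG other than the ORF1 start should occur
#' upstream of ORF2, and (iv) the ORF2 Kozak context should sit in the
#' strong band.
#'
#' @param seq construct mRNA sequence (DNA alphabet; `U` accepted).
#' @param orf1,orf2 integer `c(start, end)` 1-based inclusive positions
#'   of each ORF (stop codon included); ORF1 must lie upstream of ORF2
#'   and must not overlap it.
#' @param pwm a `kozak_pwm`.
#' @param reference list with `utr_lengths` (numeric) and `mono_scores`
#'   (numeric): reference distributions from monocistronic genes.
#' @param thresholds see [audit_thresholds()].
#' @return object of class `audit_report`: list with `utr_length`,
#'   `utr_pct`, `orf1_score`, `orf1_pct`, `orf2_score`, `orf2_pct`,
#'   `upstream_aug_inventory` (data.frame: position, region, frame,
#'   score), `flags` (data.frame: rule, message) and `rule_version`.
#' @export
audit_construct <- function(seq, orf1, orf2, pwm, reference,
                            thresholds = audit_thresholds()) {
  seq <- normalize_nt(seq)
  stopifnot(length(orf1) == 2, length(orf2) == 2)
  if (orf1[2] >= orf2[1]) stop("ORF1 and ORF2 overlap or are out of order")
  utr_len <- orf1[1] - 1L
  s1 <- kozak_bit_score(cut_site_window(seq, orf1[1]), pwm)
  s2 <- kozak_bit_score(cut_site_window(seq, orf2[1]), pwm)
  utr_pct <- pct_of(utr_len, reference$utr_lengths)
  p1 <- pct_of(s1, reference$mono_scores)
  p2 <- pct_of(s2, reference$mono_scores)
  # upstream AUG inventory: everything before ORF2 except the ORF1 start
  pos <- atg_positions(seq, 1L, orf2[1] - 1L)
  pos <- pos[pos != orf1[1]]
  inventory <- data.frame(position = integer(0), region = character(0),
                          frame = integer(0), score = numeric(0))
  if (length(pos) > 0) {
    region <- ifelse(pos < orf1[1], "five_prime_utr",
                     ifelse(pos <= orf1[2], "orf1", "inter_orf"))
    inventory <- data.frame(
      position = pos, region = region, frame = (pos - orf1[1]) %% 3L,
      score = vapply(pos, function(p) {
        kozak_bit_score(cut_site_window(seq, p), pwm)
      }, numeric(1)))
  }
  flags <- list()
  add_flag <- function(rule, msg) {
    flags[[length(flags) + 1L]] <<- data.frame(rule = rule, message = msg)
  }
  if (!is.na(utr_pct) && utr_pct > thresholds$utr_max_pct) {
    add_flag("long_utr", sprintf(
      "5' UTR length %d nt is at the %.0fth percentile (> %.0f)",
      utr_len, utr_pct, thresholds$utr_max_pct))
  }
  if (!is.na(p1) && p1 > thresholds$orf1_max_pct) {
    add_flag("orf1_not_suboptimal", sprintf(
      "ORF1 Kozak score %.3f is at the %.0fth percentile (> %.0f)",
      s1, p1, thresholds$orf1_max_pct))
  }
  if (nrow(inventory) > 0) {
    add_flag("upstream_aug", sprintf(
      "%d AUG 3-mer(s) upstream of ORF2 besides the ORF1 start",
      nrow(inventory)))
  }
  if (!is.na(p2) && p2 < thresholds$orf2_min_pct) {
    add_flag("orf2_not_strong", sprintf(
      "ORF2 Kozak score %.3f is at the %.0fth percentile (< %.0f)",
      s2, p2, thresholds$orf2_min_pct))
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(rule = character(0), message = character(0))
  structure(list(utr_length = utr_len, utr_pct = utr_pct,
                 orf1_score = s1, orf1_pct = p1,
                 orf2_score = s2, orf2_pct = p2,
                 upstream_aug_inventory = inventory, flags = flags,
                 rule_version = "1"), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("audit_report: UTR %d nt (pct %.0f); ORF1 %.3f (pct %.0f); ORF2 %.3f (pct %.0f)\n",
              x$utr_length, x$utr_pct, x$orf1_score, x$orf1_pct,
              x$orf2_score, x$orf2_pct))
  cat("upstream AUGs:", nrow(x$upstream_aug_inventory), "\n")
  if (nrow(x$flags)) {
    cat("flags:\n")
    for (r in seq_len(nrow(x$flags))) {
      cat("  [", x$flags$rule[r], "] ", x$flags$message[r], "\n", sep = "")
    }
  } else cat("no flags\n")
  invisible(x)
}

# all index subsets of size <= k (small sets only)
subsets_upto <- function(idx, k) {
  out <- list()
  for (s in seq_len(min(k, length(idx)))) {
    cmb <- utils::combn(idx, s)
    for (j in seq_len(ncol(cmb))) out[[length(out) + 1L]] <- cmb[, j]
  }
  out
}

#' Tune a Kozak context toward weaker or stronger scores
#'
#' Exhaustively enumerates substitution variants of a 13-mer site within
#' `max_edits` edits at `mutable_positions` (default: the five positions
#' upstream of the start codon, so the encoded protein is untouched) and
#' returns those whose bit score moves strictly in the requested
#' direction, ranked by closeness to the target score (0 bits for
#' weakening, 2 bits for strengthening, unless given).
#'
#' @param site 13-mer with `ATG` at positions 6-8.
#' @param pwm a `kozak_pwm`.
#' @param direction `"weaken"` or `"strengthen"`.
#' @param mutable_positions window indices allowed to change (subset of
#'   the 10 flanking positions; default 1:5, i.e. offsets -5..-1).
#' @param max_edits maximum substitutions (default 2).
#' @param target target score; default 0 (weaken) or 2 (strengthen).
#' @return data.frame with `site`, `score`, `n_edits`, sorted by
#'   `abs(score - target)`.  Empty (with a `note` attribute) when no
#'   variant satisfies the direction, e.g. strengthening the consensus.
#' @export
tune_kozak <- function(site, pwm, direction = c("weaken", "strengthen"),
                       mutable_positions = 1:5, max_edits = 2L,
                       target = NULL) {
  direction <- match.arg(direction)
  stopifnot(all(mutable_positions %in% KOZAK_FLANK_IDX))
  if (is.null(target)) target <- if (direction == "weaken") 0 else 2
  s0 <- kozak_bit_score(site, pwm)
  cc0 <- chars(site)
  rows <- list()
  for (posset in subsets_upto(mutable_positions, max_edits)) {
    # all base assignments differing from the original at every chosen pos
    choices <- lapply(posset, function(j) setdiff(BASES, cc0[j]))
    grid <- expand.grid(choices, stringsAsFactors = FALSE)
    for (g in seq_len(nrow(grid))) {
      cc <- cc0
      cc[posset] <- unlist(grid[g, ])
      v <- paste(cc, collapse = "")
      sc <- kozak_bit_score(v, pwm)
      ok <- if (direction == "weaken") sc < s0 else sc > s0
      if (ok) {
        rows[[length(rows) + 1L]] <- data.frame(
          site = v, score = sc, n_edits = length(posset))
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(site = character(0), score = numeric(0),
                      n_edits = integer(0))
    attr(out, "note") <- paste0("no variant ", direction, "s the site ",
                                "within ", max_edits, " edit(s)")
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$score - target), out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Suggest edits removing AUG 3-mers from an ORF
#'
#' In-frame internal `ATG` codons get a Met-to-Leu (`CTG`) replacement
#' suggestion, flagged protein-changing.  Out-of-frame `ATG` 3-mers
#' spanning two codons get synonymous-codon alternatives for either
#' overlapping codon (exhaustive over the standard genetic code) when
#' any substitution removes the 3-mer without raising the total `ATG`
#' count; otherwise they are marked unresolvable.
#'
#' @param orf_seq ORF nucleotide sequence, length divisible by 3,
#'   starting with the initiator `ATG`.
#' @return data.frame with `position` (nt index of the `A`),
#'   `codon_index`, `frame` (0 in-frame, 1/2 out-of-frame),
#'   `synonymous`, `resolvable`, `edit` (description), `new_seq` (full
#'   ORF after the edit; `NA` if unresolvable).  Empty when the
#'   initiator is the only `ATG`.
#' @export
suggest_aug_removal <- function(orf_seq) {
  orf_seq <- normalize_nt(orf_seq)
  n <- nchar(orf_seq)
  stopifnot(n %% 3L == 0L)
  gc_tab <- Biostrings::GENETIC_CODE
  pos <- atg_positions(orf_seq, 1L, n)
  pos <- pos[pos != 1L]  # keep the initiator
  rows <- list()
  for (p in pos) {
    frame <- (p - 1L) %% 3L
    ci <- (p - 1L) %/% 3L + 1L
    if (frame == 0L) {
      new_seq <- orf_seq
      substr(new_seq, p, p + 2L) <- "CTG"
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, codon_index = ci, frame = frame, synonymous = FALSE,
        resolvable = TRUE,
        edit = sprintf("codon %d Met(ATG)->Leu(CTG), protein-changing", ci),
        new_seq = new_seq)
    } else {
      # the 3-mer spans codons ci and ci+1
      found <- NULL
      for (cj in c(ci, ci + 1L)) {
        if (!is.null(found) || cj * 3L > n) next
        cstart <- (cj - 1L) * 3L + 1L
        codon <- substr(orf_seq, cstart, cstart + 2L)
        aa <- gc_tab[[codon]]
        syn <- names(gc_tab)[gc_tab == aa & names(gc_tab) != codon]
        if (cj == 1L) syn <- character(0)  # never touch the initiator
        for (alt in syn) {
          cand <- orf_seq
          substr(cand, cstart, cstart + 2L) <- alt
          if (substr(cand, p, p + 2L) != "ATG" &&
              count_aug(cand) < count_aug(orf_seq)) {
            found <- list(cj = cj, codon = codon, alt = alt, seq = cand)
            break
          }
        }
      }
      if (is.null(found)) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = p, codon_index = ci, frame = frame, synonymous = NA,
          resolvable = FALSE, edit = "unresolvable without changing protein",
          new_seq = NA_character_)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          position = p, codon_index = ci, frame = frame, synonymous = TRUE,
          resolvable = TRUE,
          edit = sprintf("codon %d %s->%s (synonymous)", found$cj,
                         found$codon, found$alt),
          new_seq = found$seq)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(position = integer(0), codon_index = integer(0),
                      frame = integer(0), synonymous = logical(0),
                      resolvable = logical(0), edit = character(0),
                      new_seq = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply all resolvable AUG-removal suggestions to an ORF
#'
#' Iterates [suggest_aug_removal()] until no resolvable internal `ATG`
#' remains, applying one suggested edit per round.
#'
#' @param orf_seq ORF nucleotide sequence.
#' @param max_rounds safety cap.
#' @return edited ORF sequence.
#' @export
apply_aug_removal <- function(orf_seq, max_rounds = 100L) {
  for (i in seq_len(max_rounds)) {
    sug <- suggest_aug_removal(orf_seq)
    sug <- sug[sug$resolvable, , drop = FALSE]
    if (nrow(sug) == 0) return(orf_seq)
    orf_seq <- sug$new_seq[1]
  }
  orf_seq
}
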
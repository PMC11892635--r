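# shared fixtures: a sharp PWM whose consensus is unambiguous, and
# reference distributions spanning it
sharp_pwm <- function() build_kozak_pwm(rep("GCCGCATGGCCGC", 5),
                                        pseudocount = 0)

ref_dists <- function(pwm, n = 400, seed = 17) {
  set.seed(seed)
  scores <- vapply(1:n, function(i) kozak_bit_score(draw_site(pwm), pwm),
                   numeric(1))
  list(utr_lengths = round(rlnorm(n, log(100), 0.6)), mono_scores = scores)
}

test_that("audit_construct raises exactly the violated rules", {
  set.seed(17)
  pwm <- default_kozak_pwm()
  ref <- ref_dists(pwm)
  # clean construct: short UTR, weak ORF1 site, AUG-free upstream, ORF2 at
  # the consensus
  cons <- consensus_site(pwm)
  weak <- tune_kozak(cons, pwm, "weaken", max_edits = 5)
  weak_site <- weak$site[1]  # closest to 0 bits
  utr5 <- paste0("CCCCC", substr(weak_site, 1, 5))
  orf1 <- paste0("ATG", substr(weak_site, 9, 13), "C", "TAA")
  inter <- paste0("CCCC", substr(cons, 1, 5))
  orf2 <- paste0("ATG", substr(cons, 9, 13), "C", "TAA")
  seqs <- paste0(utr5, orf1, inter, orf2)
  o1 <- c(nchar(utr5) + 1, nchar(utr5) + nchar(orf1))
  o2 <- c(o1[2] + nchar(inter) + 1, o1[2] + nchar(inter) + nchar(orf2))
  rep1 <- audit_construct(seqs, o1, o2, pwm, ref)
  expect_equal(nrow(rep1$upstream_aug_inventory), 0)
  expect_false(any(c("orf1_not_suboptimal", "upstream_aug") %in%
                     rep1$flags$rule))

  # one extra inter-ORF AUG -> inventory length 1, upstream_aug flag
  inter_met <- paste0("ATGC", substr(cons, 1, 5))
  seqs2 <- paste0(utr5, orf1, inter_met, orf2)
  rep2 <- audit_construct(seqs2, o1, o2, pwm, ref)
  expect_equal(nrow(rep2$upstream_aug_inventory), 1)
  expect_true("upstream_aug" %in% rep2$flags$rule)
  expect_equal(rep2$upstream_aug_inventory$region, "inter_orf")

  # ORF1 flank at the consensus -> percentile 100, orf1_not_suboptimal
  utr3c <- paste0("CCCCC", substr(cons, 1, 5))
  orf1c <- paste0("ATG", substr(cons, 9, 13), "C", "TAA")
  seqs3 <- paste0(utr3c, orf1c, inter, orf2)
  rep3 <- audit_construct(seqs3, o1, o2, pwm, ref)
  expect_equal(rep3$orf1_pct, 100)
  expect_true("orf1_not_suboptimal" %in% rep3$flags$rule)

  # overlapping ORFs -> error
  expect_error(audit_construct(seqs, c(5, 30), c(20, 40), pwm, ref),
               "overlap")
})

test_that("tune_kozak respects direction, exhaustiveness and extremum", {
  pwm <- sharp_pwm()
  cons <- consensus_site(pwm)
  # consensus cannot be strengthened
  out <- tune_kozak(cons, pwm, "strengthen")
  expect_equal(nrow(out), 0)
  expect_match(attr(out, "note"), "no variant")

  # zero-entropy PWM, one upstream edit: score drops by exactly h/10 = 0.2
  out <- tune_kozak(cons, pwm, "weaken", max_edits = 1)
  expect_equal(nrow(out), 5 * 3)  # 5 positions x 3 alternative bases
  expect_true(all(out$score == 2 - 2 / 10))

  # weaken postcondition: every returned score below the input's
  set.seed(23)
  pwm2 <- random_pwm()
  site <- draw_site(pwm2)
  s0 <- kozak_bit_score(site, pwm2)
  out2 <- tune_kozak(site, pwm2, "weaken", max_edits = 2)
  if (nrow(out2) > 0) expect_true(all(out2$score < s0))
  out3 <- tune_kozak(site, pwm2, "strengthen", max_edits = 2)
  if (nrow(out3) > 0) expect_true(all(out3$score > s0))

  # default mutable positions never touch the coding side
  expect_true(all(vapply(out2$site, function(v) {
    substr(v, 6, 13) == substr(site, 6, 13)
  }, logical(1))))
})

test_that("suggest_aug_removal handles in-frame, out-of-frame and clean ORFs", {
  # internal in-frame ATG -> Met->Leu (CTG), protein-changing
  orf <- "ATGCCCATGTGCTAA"
  out <- suggest_aug_removal(orf)
  expect_equal(nrow(out), 1)
  expect_false(out$synonymous)
  expect_match(out$edit, "Leu\\(CTG\\)")
  expect_equal(count_aug(out$new_seq), count_aug(orf) - 1)

  # out-of-frame ATG spanning codons GAT|GCA: synonymous Asp codon fixes it
  orf2 <- "ATGGATGCATAA"
  out2 <- suggest_aug_removal(orf2)
  expect_equal(nrow(out2), 1)
  expect_true(out2$synonymous)
  expect_true(out2$resolvable)
  expect_equal(count_aug(out2$new_seq), count_aug(orf2) - 1)
  # protein unchanged
  aa <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s)))
  expect_equal(aa(out2$new_seq), aa(orf2))

  # initiator-only ORF -> empty
  expect_equal(nrow(suggest_aug_removal("ATGCCCGGGTAA")), 0)
})

test_that("applied removals strictly reduce ATG counts to the initiator only", {
  set.seed(41)
  for (i in 1:20) {
    body <- paste(sample(c("GAT", "ATG", "CAT", "GCA", "TGG", "AAA"),
                         12, replace = TRUE), collapse = "")
    orf <- paste0("ATG", body, "TAA")
    cleaned <- apply_aug_removal(orf)
    expect_lte(count_aug(cleaned), count_aug(orf))
    sug <- suggest_aug_removal(cleaned)
    expect_equal(sum(sug$resolvable), 0)
    # protein length preserved
    expect_equal(nchar(cleaned), nchar(orf))
  }
})
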
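test_that("build_kozak_pwm entropy arithmetic matches hand computation", {
  # zero-entropy limit: identical sites, pseudocount 0 -> R = 2 off the AUG
  site <- "GCCGCATGGCCGC"
  pwm <- build_kozak_pwm(rep(site, 5), pseudocount = 0)
  expect_equal(unname(pwm$info[c(1:5, 9:13)]), rep(2, 10))

  # uniform position -> R = 0 there
  sites <- paste0(c("A", "C", "G", "T"), "CCGC", "ATG", "GCCGC")
  pwm <- build_kozak_pwm(sites, pseudocount = 0)
  expect_equal(unname(pwm$info[1]), 0)

  # frequencies (0.5, 0.25, 0.25, 0): H = 1.5, R = 0.5
  sites <- paste0(c("A", "A", "C", "G"), "CCGC", "ATG", "GCCGC")
  pwm <- build_kozak_pwm(sites, pseudocount = 0)
  expect_equal(unname(pwm$info[1]), 0.5)
  expect_equal(unname(pwm$probs[, 1]), c(0.5, 0.25, 0.25, 0))

  # pseudocount formula: (count + pc) / (n + 4 pc)
  pwm <- build_kozak_pwm(rep(site, 4), pseudocount = 0.5)
  expect_equal(unname(pwm$probs["G", 1]), (4 + 0.5) / (4 + 2))

  expect_error(build_kozak_pwm(character(0)), "empty")
  expect_error(build_kozak_pwm(c(site, "GCCGCATGGCCG")), "site 2")
  expect_error(build_kozak_pwm("GCCGCAAGGCCGC"), "ATG")
})

test_that("kozak_bit_score endpoints, N policy and hand example", {
  uniform <- kozak_pwm_from_probs(matrix(0.25, 4, 13))
  expect_equal(kozak_bit_score("GCCGCATGGCCGC", uniform), 0)

  site <- "GCCGCATGGCCGC"
  sharp <- build_kozak_pwm(rep(site, 5), pseudocount = 0)
  expect_equal(kozak_bit_score(site, sharp), 2)
  # mismatch at all 10 flanks -> 0
  expect_equal(kozak_bit_score("ATTATATGATTAT", sharp), 0)

  # one informative flank (0.5/0.25/0.25/0), rest uniform:
  # site carrying the 0.5-base there scores (0.5 * 0.5) / 10 = 0.025
  p <- matrix(0.25, 4, 13)
  p[, 1] <- c(0.5, 0.25, 0.25, 0)
  pwm <- kozak_pwm_from_probs(p)
  expect_equal(kozak_bit_score("ACCGCATGGCCGC", pwm), 0.025)

  # N positions skipped, mean renormalised; > 3 unscorable -> NA
  expect_equal(kozak_bit_score("NCCGCATGGCCGC", sharp), 2)
  expect_true(is.na(kozak_bit_score("NNNNCATGGCCGC", sharp)))
  expect_error(kozak_bit_score("ATG", sharp), "length")
})

test_that("bit score equals the enumeration oracle on random PWMs", {
  set.seed(5)
  for (rep in 1:20) {
    pwm <- random_pwm()
    for (i in 1:30) {
      site <- draw_site(pwm)
      expect_equal(kozak_bit_score(site, pwm), oracle_bit_score(site, pwm),
                   tolerance = 1e-12)
    }
  }
})

test_that("locus_kozak_profile enumerates internal AUGs across regions", {
  rs <- make_rs("t1", utr5 = "AA", orf1 = "ATGAAATGA", inter = "TTT",
                orf2 = "ATGGGGTGA", utr3 = "CC")
  pwm <- default_kozak_pwm()
  prof <- locus_kozak_profile(rs, pwm)
  expect_equal(nrow(prof$internal_sites), 1)
  expect_equal(prof$internal_sites$position, 8)
  expect_equal(prof$internal_sites$frame, (8 - 3) %% 3)

  # no ATG upstream of ORF2 except the ORF1 start -> empty internal set
  rs2 <- make_rs("t2", utr5 = "CC", orf1 = "ATGCCCTAA", inter = "CCC",
                 orf2 = "ATGCCCTAA", utr3 = "")
  prof2 <- locus_kozak_profile(rs2, pwm)
  expect_equal(nrow(prof2$internal_sites), 0)

  # identical ORF1/ORF2 windows -> ratio 1
  rs3 <- make_rs("t3", utr5 = "GCCGC", orf1 = "ATGGCCGCCTAA",
                 inter = "GCCGC", orf2 = "ATGGCCGCCTAA", utr3 = "")
  prof3 <- locus_kozak_profile(rs3, pwm)
  expect_equal(prof3$ratio, 1)
})

test_that("split_train_eval is reproducible, disjoint and sized per rule", {
  ids <- paste0("g", 1:10)
  s1 <- split_train_eval(ids, seed = 1)
  s2 <- split_train_eval(ids, seed = 1)
  expect_identical(s1, s2)
  expect_length(s1$train, 5)
  expect_length(intersect(s1$train, s1$eval), 0)
  expect_setequal(c(s1$train, s1$eval), ids)

  s3 <- split_train_eval(paste0("g", 1:11), seed = 1)
  expect_length(s3$train, 5)
  expect_length(s3$eval, 6)

  expect_error(split_train_eval("g1", 1), "at least 2")

  # different seeds give different splits with overwhelming probability
  ids100 <- paste0("g", 1:100)
  diff <- sum(vapply(1:20, function(s) {
    !identical(split_train_eval(ids100, s)$train,
               split_train_eval(ids100, s + 1000)$train)
  }, logical(1)))
  expect_gte(diff, 19)
})

test_that("PWM JSON serialisation round-trips", {
  set.seed(3)
  pwm <- random_pwm()
  f <- tempfile(fileext = ".json")
  write_kozak_pwm(pwm, f)
  back <- read_kozak_pwm(f)
  expect_equal(back$probs, pwm$probs, tolerance = 1e-12)
  expect_equal(back$info, pwm$info, tolerance = 1e-12)
})

test_that("truncated windows near the transcript 5' end are N-padded", {
  mrna <- paste0("AT", "ATGCCCGGGTAA")  # start codon at position 3
  w <- cut_site_window(mrna, 3)
  expect_identical(substr(w, 1, 3), "NNN")
  expect_identical(substr(w, 6, 8), "ATG")
})
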
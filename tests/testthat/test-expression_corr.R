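mk_table <- function(ids, rna, ribo = rna) {
  data.frame(orf_id = ids, rna = rna, ribo = ribo)
}

test_that("pair_correlation is exact on log-linear data and excludes zeros", {
  n <- 20
  v <- 10^runif(n, 1, 3)
  tab <- mk_table(c(paste0("a", 1:n), paste0("b", 1:n)), c(v, 10 * v))
  pairs <- data.frame(id1 = paste0("a", 1:n), id2 = paste0("b", 1:n))
  out <- pair_correlation(tab, pairs, "rna")
  expect_equal(out$r, 1)
  expect_equal(out$n, n)

  # zero values drop pairwise
  tab$rna[1] <- 0
  out <- pair_correlation(tab, pairs, "rna")
  expect_equal(out$n, n - 1)

  # +1 pseudocount mode keeps them
  out <- pair_correlation(tab, pairs, "rna", pseudocount = TRUE)
  expect_equal(out$n, n)

  expect_error(pair_correlation(mk_table(c("a", "b"), c(1, 1)),
                                data.frame(id1 = "a", id2 = "b"), "rna"),
               "fewer than 3")
})

test_that("pair_correlation: permutation null and planted-r recovery", {
  set.seed(21)
  n <- 1000
  tab <- mk_table(c(paste0("a", 1:n), paste0("b", 1:n)),
                  10^rnorm(2 * n, 2, 0.5))
  pairs <- data.frame(id1 = paste0("a", 1:n), id2 = paste0("b", 1:n))
  expect_lt(abs(pair_correlation(tab, pairs, "rna")$r), 0.1)

  # bivariate log-normal with planted correlation 0.9, n = 36
  r0 <- 0.9
  reps <- vapply(1:20, function(i) {
    z1 <- rnorm(36)
    z2 <- r0 * z1 + sqrt(1 - r0^2) * rnorm(36)
    tab <- mk_table(c(paste0("a", 1:36), paste0("b", 1:36)),
                    10^c(z1, z2))
    pair_correlation(tab, data.frame(id1 = paste0("a", 1:36),
                                     id2 = paste0("b", 1:36)), "rna")$r
  }, numeric(1))
  expect_lt(abs(median(reps) - r0), 0.1)
})

test_that("r is invariant under positive rescaling of one assay", {
  set.seed(3)
  n <- 30
  tab <- mk_table(c(paste0("a", 1:n), paste0("b", 1:n)),
                  10^rnorm(2 * n, 2, 0.4))
  pairs <- data.frame(id1 = paste0("a", 1:n), id2 = paste0("b", 1:n))
  r1 <- pair_correlation(tab, pairs, "rna")$r
  tab2 <- tab
  tab2$rna <- tab2$rna * 37.5
  expect_equal(pair_correlation(tab2, pairs, "rna")$r, r1, tolerance = 1e-12)
})

test_that("occupancy_comparison counts strict inequalities", {
  tab <- mk_table(paste0("o", 1:8), rna = rep(1, 8),
                  ribo = c(5, 5, 5, 1, 4, 4, 4, 4))
  pairs <- data.frame(id1 = paste0("o", 1:4), id2 = paste0("o", 5:8))
  out <- occupancy_comparison(tab, pairs)
  expect_equal(out$greater, 3)
  expect_equal(out$fraction, 3 / 4)

  # ties count as not-greater
  tab2 <- mk_table(paste0("o", 1:4), rna = rep(1, 4), ribo = rep(2, 4))
  pairs2 <- data.frame(id1 = c("o1", "o2"), id2 = c("o3", "o4"))
  expect_equal(occupancy_comparison(tab2, pairs2)$fraction, 0)
})

test_that("kozak_vs_footprint recovers a planted monotone leak model", {
  set.seed(14)
  n <- 60
  strength <- runif(n, 0.05, 1.5)
  profiles <- lapply(seq_len(n), function(i) {
    list(orf1_score = strength[i],
         internal_sites = data.frame(position = integer(0),
                                     frame = integer(0), score = numeric(0)))
  })
  names(profiles) <- paste0("L", 1:n)
  ribo1 <- 10^rnorm(n, 2, 0.3)
  ribo2 <- ribo1 * exp(-2 * strength) * exp(rnorm(n, 0, 0.2))
  tab <- mk_table(c(paste0("a", 1:n), paste0("b", 1:n)), rna = rep(1, 2 * n),
                  ribo = c(ribo1, ribo2))
  pairs <- data.frame(locus = paste0("L", 1:n), id1 = paste0("a", 1:n),
                      id2 = paste0("b", 1:n))
  out <- kozak_vs_footprint(profiles, tab, pairs)
  expect_lt(out$pearson_r, -0.5)
  expect_equal(out$sign, -1)

  # independent strengths and ratios -> |r| small at n = 500
  n <- 500
  profiles <- lapply(runif(n, 0, 2), function(s) {
    list(orf1_score = s, internal_sites = data.frame(score = numeric(0)))
  })
  names(profiles) <- paste0("L", 1:n)
  tab <- mk_table(c(paste0("a", 1:n), paste0("b", 1:n)), rna = rep(1, 2 * n),
                  ribo = 10^rnorm(2 * n, 2, 0.4))
  pairs <- data.frame(locus = paste0("L", 1:n), id1 = paste0("a", 1:n),
                      id2 = paste0("b", 1:n))
  expect_lt(abs(kozak_vs_footprint(profiles, tab, pairs)$pearson_r), 0.15)

  # constant strength -> error
  profiles <- lapply(1:5, function(i) {
    list(orf1_score = 0.5, internal_sites = data.frame(score = numeric(0)))
  })
  names(profiles) <- paste0("L", 1:5)
  tab <- mk_table(c(paste0("a", 1:5), paste0("b", 1:5)), rna = rep(1, 10),
                  ribo = 10^rnorm(10))
  pairs <- data.frame(locus = paste0("L", 1:5), id1 = paste0("a", 1:5),
                      id2 = paste0("b", 1:5))
  expect_error(kozak_vs_footprint(profiles, tab, pairs), "constant")
})
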
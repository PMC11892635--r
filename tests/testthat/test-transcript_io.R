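test_that("load_genome normalizes and validates records", {
  f <- tmp_fasta(list(c1 = "ACGT"))
  expect_identical(load_genome(f), c(c1 = "ACGT"))

  f <- tmp_fasta(list(c1 = "acgu"))
  expect_identical(load_genome(f), c(c1 = "ACGT"))

  f <- tmp_fasta(list(c1 = "ACGT", c1 = "TTTT"))
  expect_error(load_genome(f), "duplicate")

  f <- tmp_fasta(list(c1 = "ACXT"))
  expect_error(load_genome(f), "offset 3")
})

test_that("load_annotation groups CDS by ID and orders ORFs 5'->3'", {
  genome <- c(c1 = strrep("ACGT", 150))
  plus <- c(
    gffline("c1", "mRNA", 1, 400, "+", "ID=t1"),
    gffline("c1", "exon", 1, 400, "+", "Parent=t1"),
    gffline("c1", "CDS", 101, 160, "+", "ID=orfA;Parent=t1"),
    gffline("c1", "CDS", 201, 320, "+", "ID=orfB;Parent=t1"))
  m <- load_annotation(tmp_gff(plus), genome)[[1]]
  expect_length(m$orfs, 2)
  expect_identical(m$gene_ids, c("orfA", "orfB"))

  minus <- sub("\\+", "-", plus)
  m2 <- load_annotation(tmp_gff(minus), genome)[[1]]
  expect_identical(m2$gene_ids, c("orfB", "orfA"))

  bad_len <- c(
    gffline("c1", "mRNA", 1, 100, "+", "ID=t2"),
    gffline("c1", "exon", 1, 100, "+", "Parent=t2"),
    gffline("c1", "CDS", 11, 20, "+", "ID=orfC;Parent=t2"))
  expect_warning(m3 <- load_annotation(tmp_gff(bad_len), genome),
                 "divisible by 3")
  expect_false(m3[[1]]$valid)

  outside <- c(
    gffline("c1", "mRNA", 1, 100, "+", "ID=t3"),
    gffline("c1", "exon", 1, 50, "+", "Parent=t3"),
    gffline("c1", "CDS", 40, 60, "+", "ID=orfD;Parent=t3"))
  expect_error(load_annotation(tmp_gff(outside), genome), "outside")

  wrong_chr <- c(
    gffline("c9", "mRNA", 1, 100, "+", "ID=t4"),
    gffline("c9", "exon", 1, 100, "+", "Parent=t4"),
    gffline("c9", "CDS", 1, 30, "+", "ID=orfE;Parent=t4"))
  expect_error(load_annotation(tmp_gff(wrong_chr), genome), "absent")
})

test_that("extract_regions computes interval arithmetic and strandedness", {
  # + strand single exon 1-30, ORF1 11-19, ORF2 23-28
  genome <- c(c1 = strrep("A", 30))
  m <- transcript_model("t1", "c1", "+", data.frame(start = 1, end = 30),
                        list(data.frame(start = 11, end = 19),
                             data.frame(start = 23, end = 28)),
                        c("g1", "g2"))
  rs <- extract_regions(m, genome)
  expect_equal(rs$regions$five_prime_utr$length, 10)
  expect_equal(rs$regions$inter_orf$length, 3)
  expect_equal(rs$regions$three_prime_utr$length, 2)

  # minus strand: hand reverse-complement oracle
  genome2 <- c(c1 = "AAAATTTCATAAAA")
  m2 <- transcript_model("t2", "c1", "-", data.frame(start = 1, end = 14),
                         list(data.frame(start = 5, end = 10)), "g1")
  rs2 <- extract_regions(m2, genome2)
  expect_identical(rs2$regions$orf1$seq, "ATGAAA")

  # monocistronic model: no inter_orf / orf2
  expect_null(rs2$regions$inter_orf)
  expect_null(rs2$regions$orf2)
})

test_that("concatenation invariant and GFF3 round-trip hold on random models", {
  spec <- sim_spec(seed = 42, n_mono = 40, n_bicistron = 20,
                   splice_prob = 0.6)
  sim <- simulate_genome(spec)
  for (m in sim$models) {
    rs <- extract_regions(m, sim$genome)
    concat <- paste(vapply(rs$regions, function(r) r$seq %||% "",
                           character(1)), collapse = "")
    expect_identical(concat, rs$mrna)
  }

  gff <- tempfile(fileext = ".gff3")
  write_gff3(sim$models, gff)
  reloaded <- load_annotation(gff, sim$genome)
  expect_length(reloaded, length(sim$models))
  reloaded <- reloaded[match(vapply(sim$models, `[[`, "", "transcript_id"),
                             vapply(reloaded, `[[`, "", "transcript_id"))]
  for (i in seq_along(sim$models)) {
    rs1 <- extract_regions(sim$models[[i]], sim$genome)
    rs2 <- extract_regions(reloaded[[i]], sim$genome)
    expect_identical(lapply(rs1$regions, `[[`, "seq"),
                     lapply(rs2$regions, `[[`, "seq"))
  }
})

test_that("strand symmetry: mirrored chromosome leaves region sequences unchanged", {
  spec <- sim_spec(seed = 9, n_mono = 15, n_bicistron = 10, splice_prob = 0.5)
  sim <- simulate_genome(spec)
  L <- nchar(sim$genome[["chr1"]])
  mirrored_genome <- c(chr1 = revcomp(sim$genome[["chr1"]]))
  flip <- function(df) {
    out <- data.frame(start = L - df$end + 1L, end = L - df$start + 1L)
    out[order(out$start), , drop = FALSE]
  }
  for (m in sim$models) {
    m2 <- transcript_model(m$transcript_id, m$chrom,
                           if (m$strand == "+") "-" else "+",
                           flip(m$exons), lapply(m$orfs, flip), m$gene_ids)
    rs1 <- extract_regions(m, sim$genome)
    rs2 <- extract_regions(m2, mirrored_genome)
    expect_identical(lapply(rs1$regions, `[[`, "seq"),
                     lapply(rs2$regions, `[[`, "seq"))
  }
})
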
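# Seed-and-extend mapper, overlap counting, RPKM.

toy_ref <- function(L = 2000, pad = 99, seed = 31) {
  set.seed(seed)
  g <- circ_seq("toy", rand_dna(L))
  list(genome = g, ext = build_extended_reference(g, pad),
       index = build_read_index(build_extended_reference(g, pad)))
}

test_that("map_read places exact, junction and reverse-complement reads", {
  tr <- toy_ref()
  L <- tr$genome$length
  r <- substr(tr$genome$residues, 100, 199)
  a <- map_read(r, tr$index)
  expect_identical(a[, c("canonical_start", "aligned_strand", "n_mismatches")],
                   data.frame(canonical_start = 100L,
                              aligned_strand = "heavy", n_mismatches = 0L))

  jr <- circ_substring(tr$genome$residues, L - 49L, 100L)
  aj <- map_read(jr, tr$index)
  expect_true(aj$mapped)
  expect_identical(aj$canonical_start, L - 49L)
  # the same read is unmapped on the naive pad 0 linearization
  naive <- build_read_index(build_extended_reference(tr$genome, 0L))
  expect_false(map_read(jr, naive)$mapped)

  rc <- oracle_revcomp(r)
  arc <- map_read(rc, tr$index)
  expect_identical(arc$aligned_strand, "light")
  expect_identical(arc$canonical_start, 100L)
  expect_error(map_read("ACGTACGT", tr$index), "mapping error")
})

test_that("mapper agrees with brute-force circular scan on random reads", {
  tr <- toy_ref(L = 1000, pad = 59, seed = 32)
  L <- tr$genome$length
  set.seed(33)
  n <- 200; m <- 60
  seqs <- character(n)
  for (i in seq_len(n)) {
    if (i %% 10 == 0) { seqs[i] <- rand_dna(m); next }  # unmappable garbage
    s0 <- sample(L, 1)
    r <- circ_substring(tr$genome$residues, s0, m)
    if (sample(c(TRUE, FALSE), 1)) r <- oracle_revcomp(r)
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      ch <- strsplit(r, "")[[1]]
      for (j in sample(m, nmut)) ch[j] <- sample(setdiff(c("A","C","G","T"), ch[j]), 1)
      r <- paste(ch, collapse = "")
    }
    seqs[i] <- r
  }
  got <- map_reads(seqs, tr$index, max_mismatch = 2L)
  want <- oracle_map_all(seqs, tr$genome$residues, L, max_mismatch = 2L)
  expect_identical(got$mapped, want$mapped)
  expect_identical(got$canonical_start, want$start)
  expect_identical(got$aligned_strand, want$strand)
  expect_identical(got$n_mismatches, want$mm)
})

test_that("count_overlaps applies strand protocol and ambiguity policy", {
  aln <- data.frame(read_id = sprintf("r%02d", 1:10), read_length = 50L,
                    canonical_start = seq(120, 300, length.out = 10),
                    aligned_strand = "light", n_mismatches = 0L, mapped = TRUE)
  genes <- list(gene_model("g", start = 100, end = 400, strand = "heavy"))
  ct <- count_overlaps(aln, genes, L = 1000, mode = "reverse")
  expect_identical(as.integer(ct$counts["g"]), 10L)
  expect_identical(ct$n_ambiguous, 0L)
  # forward protocol: aligned light implies transcript light -> incompatible
  ct_f <- count_overlaps(aln, genes, L = 1000, mode = "forward")
  expect_identical(as.integer(ct_f$counts["g"]), 0L)
  expect_identical(ct_f$n_unassigned, 10L)
  expect_error(count_overlaps(aln, list(), L = 1000), "configuration")

  # reads wholly inside the MDL1/MDL1AS overlap: ambiguous when unstranded
  genes2 <- mdl_genes()
  over <- data.frame(read_id = c("a", "b"), read_length = 100L,
                     canonical_start = c(16100L, 16470L),
                     aligned_strand = c("heavy", "light"),
                     n_mismatches = 0L, mapped = TRUE)
  ct_u <- count_overlaps(over, genes2, L = 16569, mode = "unstranded")
  expect_identical(ct_u$n_ambiguous, 2L)
  expect_identical(sum(ct_u$counts), 0L)
})

test_that("reverse-stranded quantification reproduces the truth table at zero error", {
  set.seed(34)
  g <- circ_seq("chrM", rand_dna(16569))
  genes <- mdl_genes()
  sim <- simulate_reads(g, genes,
                        sim_config(read_length = 100,
                                   n_reads = c(MDL1 = 300, MDL1AS = 200),
                                   error_rate = 0, strandedness = "reverse",
                                   seed = 35))
  rot <- rotate_reference(g, 8000)
  q <- quantify(sim$reads, build_extended_reference(rot$seq, 99L),
                lift_genes(genes, rot$map), strandedness = "reverse")
  expect_identical(as.integer(q$counts$counts[c("MDL1", "MDL1AS")]),
                   c(300L, 200L))
  # per-read assignment matches the simulator truth exactly
  asg <- q$counts$assignment
  expect_identical(asg$gene[match(sim$truth$read_id, asg$read_id)],
                   sim$truth$gene)
  # conservation
  ct <- q$counts
  expect_identical(sum(ct$counts) + ct$n_ambiguous + ct$n_unassigned,
                   as.integer(ct$n_mapped_total))
  expect_identical(ct$n_mapped_total + ct$n_unmapped, nrow(sim$reads))
})

test_that("rpkm follows the closed form and is scale-invariant", {
  expect_equal(rpkm(c(g = 10), c(g = 1000), n_mapped_total = 1e6),
               c(g = 10))
  expect_equal(rpkm(c(g = 0), c(g = 1000), n_mapped_total = 1e6), c(g = 0))
  expect_equal(rpkm(c(MDL1 = 1192), c(MDL1 = 1192), n_mapped_total = 1e6),
               c(MDL1 = 1000))
  expect_equal(rpkm(c(a = 20, b = 6), c(a = 500, b = 300),
                    n_mapped_total = 2e6),
               rpkm(c(a = 10, b = 3), c(a = 500, b = 300),
                    n_mapped_total = 1e6))
  expect_error(rpkm(c(g = 5), c(g = 100), n_mapped_total = 0),
               "undefined-normalization")
})

test_that("expression_matrix assembles multi-sample RPKM and counts", {
  ct1 <- structure(list(sample_id = "s1", counts = c(a = 10L, b = 0L),
                        n_mapped_total = 1000L), class = "count_table")
  ct2 <- structure(list(sample_id = "s2", counts = c(a = 5L, b = 20L),
                        n_mapped_total = 500L), class = "count_table")
  em <- expression_matrix(list(ct1, ct2), c(a = 100, b = 200))
  expect_identical(dim(em$rpkm), c(2L, 2L))
  expect_equal(em$rpkm["a", "s1"], 10 * 1e9 / (100 * 1000))
  expect_equal(em$rpkm["b", "s2"], 20 * 1e9 / (200 * 500))
})
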
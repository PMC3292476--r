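test_that("SAM/BAM streaming skips unmapped and duplicate reads", {
  d <- withr::local_tempdir()
  sam <- file.path(d, "mix.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:seq1\tLN:100",
               "r1\t0\tseq1\t5\t255\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
               "r2\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
               "r3\t1024\tseq1\t7\t255\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
               "r4\t16\tseq1\t9\t255\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII"),
             sam)
  reads <- read_alignments(sam)
  expect_equal(reads$qname, c("r1", "r4"))
  expect_equal(reads$strand, c("+", "-"))

  hdr_only <- file.path(d, "empty.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:seq1\tLN:100"), hdr_only)
  expect_equal(nrow(read_alignments(hdr_only)), 0L)
})

test_that("unsorted alignments are rejected with an explicit message", {
  d <- withr::local_tempdir()
  sam <- file.path(d, "unsorted.sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:seq1\tLN:100",
               "r1\t0\tseq1\t50\t255\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
               "r2\t0\tseq1\t5\t255\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII"),
             sam)
  expect_error(read_alignments(sam), "coordinate-sorted")
})

test_that("per-read filters match the stated rules and a brute-force recount", {
  ref <- make_ref(paste(rep("ACGTGGTTCA", 30), collapse = ""))
  cfg <- filter_config()
  clean <- ref_read(ref, 11, 40)
  expect_true(passes_read_filters(clean, cfg, ref))

  four_mm <- ref_read(ref, 11, 40, subs = c(`2` = "T", `8` = "A",
                                            `15` = "C", `22` = "T"))
  expect_false(passes_read_filters(four_mm, cfg, ref))
  three_mm <- ref_read(ref, 11, 40, subs = c(`2` = "T", `8` = "A",
                                             `15` = "C"))
  expect_true(passes_read_filters(three_mm, cfg, ref))

  # mapping-quality rules: exact-255 vs minimum-threshold mode
  mq20 <- ref_read(ref, 11, 40, mapq = 20L)
  expect_false(passes_read_filters(mq20, cfg, ref))
  expect_true(passes_read_filters(mq20, filter_config(mapq_mode = "min:20"),
                                  ref))
  expect_false(passes_read_filters(mq20, filter_config(mapq_mode = "min:21"),
                                   ref))

  set.seed(42)
  sim <- simulate_reads(noisy_sim_config(42L, reference_length = 4000L,
                                         n_sites = 10L, n_indel_sites = 4L,
                                         depth_mean = 4))
  idx <- sample(nrow(sim$reads), 100L)
  for (i in idx) {
    rd <- sim$reads[i, ]
    expect_equal(passes_read_filters(rd, cfg, sim$reference),
                 o_passes(as.list(rd), sim$reference))
  }
})

test_that("variation rate counts mismatches plus gap events over read length", {
  ref <- make_ref(paste(rep("ACGTGGTTCA", 20), collapse = ""))
  expect_equal(variation_rate(ref_read(ref, 3, 50), ref), 0)

  # 50 bp read with 2 mismatches and one 2 bp deletion event: 3/50
  s <- paste0(substr(ref[[1]], 11, 40), substr(ref[[1]], 43, 62))
  rd <- make_read(11, s, cigar = "30M2D20M")
  rd$seq <- paste0(substr(rd$seq, 1, 4), "N", substr(rd$seq, 6, 50)) # N: not counted
  substr(rd$seq, 3, 3) <- if (substr(ref[[1]], 13, 13) == "G") "T" else "G"
  substr(rd$seq, 9, 9) <- if (substr(ref[[1]], 19, 19) == "T") "A" else "T"
  expect_equal(variation_rate(rd, ref), 3 / 50)

  sim <- simulate_reads(noisy_sim_config(8L, reference_length = 3000L,
                                         n_sites = 6L, n_indel_sites = 3L,
                                         depth_mean = 3))
  for (i in seq_len(min(nrow(sim$reads), 60L))) {
    rd <- sim$reads[i, ]
    expect_equal(variation_rate(rd, sim$reference),
                 o_variation_rate(as.list(rd), sim$reference))
  }
})

test_that("distance to the 3' end respects strand and soft clips", {
  rd_plus <- make_read(10, "ACGTACGTAC")
  expect_equal(distance_to_3prime(rd_plus, 10), 0L)
  expect_equal(distance_to_3prime(rd_plus, 1), 9L)
  rd_minus <- make_read(10, paste(rep("A", 50), collapse = ""), strand = "-")
  expect_equal(distance_to_3prime(rd_minus, 1), 0L)
  expect_equal(distance_to_3prime(rd_minus, 50), 49L)
  expect_error(distance_to_3prime(rd_plus, 11), "range")

  clipped <- make_read(10, "ACGTACGTAC", cigar = "2S6M2S")
  expect_equal(distance_to_3prime(clipped, 3), 5L)
  expect_error(distance_to_3prime(clipped, 1), "clip")

  set.seed(31)
  for (k in 1:50) {
    strand <- sample(c("+", "-"), 1)
    n <- sample(20:60, 1)
    rd <- make_read(5, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = ""), strand = strand)
    qi <- sample(n, 1)
    expect_equal(distance_to_3prime(rd, qi), o_dist3(as.list(rd), qi))
  }
})

test_that("site stacks match a naive pileup on random loci", {
  sim <- simulate_reads(noisy_sim_config(17L, reference_length = 3000L,
                                         n_sites = 8L, n_indel_sites = 4L,
                                         depth_mean = 8))
  set.seed(17)
  for (pos in sample(100:2900, 40L)) {
    stack <- build_site_stack(sim$reads, "seq1", pos, sim$reference)
    naive <- o_pileup(sim$reads, sim$reference, "seq1", pos)
    if (is.null(naive)) {
      expect_equal(nrow(stack$observations), 0L)
    } else {
      obs <- stack$observations
      expect_equal(nrow(obs), nrow(naive))
      o1 <- order(obs$read_id)
      o2 <- order(naive$read)
      expect_equal(obs$base[o1], naive$base[o2])
      expect_equal(obs$qual[o1], naive$qual[o2])
      expect_equal(obs$strand[o1], naive$strand[o2])
      sel <- obs$base[o1] != "-"
      expect_equal(obs$dist3[o1][sel], naive$dist3[o2][sel])
    }
  }
})

test_that("hand-built stacks carry the expected observations", {
  ref <- make_ref(paste(rep("ACGTGGTTCA", 10), collapse = ""))
  reads <- make_reads(
    ref_read(ref, 11, 30),
    ref_read(ref, 15, 30),
    ref_read(ref, 20, 30, subs = c(`6` = "A")),   # alt at ref pos 25
    ref_read(ref, 21, 30, subs = c(`5` = "A"), strand = "-"),
    ref_read(ref, 25, 30))
  stack <- build_site_stack(reads, "seq1", 25, ref)
  expect_equal(nrow(stack$observations), 5L)
  expect_equal(sum(stack$observations$base == "A"), 2L)
  expect_equal(stack$ref_base, substr(ref[[1]], 25, 25))
  expect_equal(nrow(build_site_stack(reads, "seq1", 90, ref)$observations), 0L)
  expect_error(build_site_stack(reads, "seq1", 5000, ref), "outside")
})

test_that("pileup observations are conserved against total aligned bases", {
  sim <- simulate_reads(noisy_sim_config(23L, reference_length = 1500L,
                                         n_sites = 4L, n_indel_sites = 2L,
                                         depth_mean = 5))
  cfg <- filter_config(max_variant_events = 1000L)
  total_obs <- 0L
  for (pos in seq_len(1500L)) {
    st <- build_site_stack(sim$reads, "seq1", pos, sim$reference, cfg)
    total_obs <- total_obs + sum(st$observations$base != "-")
  }
  aligned <- sum(vapply(sim$reads$cigar, function(cg) {
    o <- o_cigar(cg); sum(o$len[o$op %in% c("M", "=", "X")])
  }, numeric(1)))
  expect_equal(total_obs, aligned)
})

test_that("reversing read strands flips observations and mirrors dist3", {
  ref <- make_ref(paste(rep("ACGTGGTTCA", 10), collapse = ""))
  reads <- make_reads(ref_read(ref, 11, 30, subs = c(`6` = "A")),
                      ref_read(ref, 13, 30, strand = "-"))
  flipped <- data.table::copy(reads)
  flipped$strand <- ifelse(reads$strand == "+", "-", "+")
  s1 <- build_site_stack(reads, "seq1", 16, ref)$observations
  s2 <- build_site_stack(flipped, "seq1", 16, ref)$observations
  expect_equal(s2$strand, ifelse(s1$strand == "+", "-", "+"))
  expect_equal(s2$dist3, 30L - 1L - s1$dist3)
})
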
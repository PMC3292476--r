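# intercept-only models give exact, hand-chosen probabilities
p_model <- function(p, type = "snp") {
  logistic_model(character(), stats::qlogis(p), numeric(),
                 platform = "constant")
}

test_that("effective depth counts base observations, not gaps or N", {
  ref <- make_ref(paste(rep("ACGTGGTTCA", 10), collapse = ""))
  alt <- if (substr(ref[[1]], 40, 40) == "A") "C" else "A"
  rows <- c(lapply(1:4, function(i) ref_read(ref, 10 + i, 40)),
            lapply(1:3, function(i) {
              ref_read(ref, 14 + i, 40,
                       subs = stats::setNames(alt, as.character(40 - 14 - i + 1)))
            }),
            list(ref_read(ref, 20, 40, subs = c(`21` = "N"))))
  reads <- do.call(make_reads, rows)
  st <- build_site_stack(reads, "seq1", 40, ref)
  expect_equal(nrow(st$observations), 8L)
  expect_equal(effective_depth(st), 7L)
  empty <- build_site_stack(reads[0, ], "seq1", 40, ref)
  expect_equal(effective_depth(empty), 0L)
})

test_that("callable regions are maximal runs of effective depth >= cutoff", {
  cfg <- filter_config()
  tr <- list(seq1 = rep(10L, 100L))
  cr <- callable_regions(tr, cfg)
  expect_equal(length(cr), 1L)
  expect_equal(callable_bp(cr), 100L)

  tr2 <- list(seq1 = c(6L, 6L, 5L, 6L))
  cr2 <- callable_regions(tr2, cfg)
  expect_equal(length(cr2), 2L)
  expect_equal(IRanges::width(IRanges::ranges(cr2)), c(2L, 1L))

  set.seed(13)
  depths <- sample(0:12, 500L, replace = TRUE)
  cr3 <- callable_regions(list(seq1 = depths), cfg)
  member <- logical(500L)
  for (k in seq_along(cr3)) {
    member[GenomicRanges::start(cr3)[k]:GenomicRanges::end(cr3)[k]] <- TRUE
  }
  expect_equal(member, depths >= 6L)
})

test_that("effective depth track matches per-locus stacks", {
  sim <- simulate_reads(noisy_sim_config(43L, reference_length = 2000L,
                                         n_sites = 5L, n_indel_sites = 2L,
                                         depth_mean = 8))
  tr <- effective_depth_track(sim$reads, sim$reference)
  set.seed(43)
  for (pos in sample(50:1950, 25L)) {
    st <- build_site_stack(sim$reads, "seq1", pos, sim$reference)
    expect_equal(tr$seq1[pos], effective_depth(st))
  }
})

test_that("adjusted variant ratio honors color-corrected bases", {
  expect_equal(adjusted_variant_ratio(5, 10), 0.5)
  expect_equal(adjusted_variant_ratio(5, 12, 2), 0.5)
  expect_error(adjusted_variant_ratio(5, 5, 5), "denominator")
  expect_error(adjusted_variant_ratio(6, 5), "var_depth")
  set.seed(14)
  for (k in 1:30) {
    tot <- sample(5:100, 1); cc <- sample(0:3, 1)
    v <- sample(0:(tot - cc), 1)
    expect_equal(adjusted_variant_ratio(v, tot, cc), v / (tot - cc))
  }
})

test_that("genotypes from t use inclusive thresholds", {
  cfg <- filter_config()
  expect_equal(genotype_from_t(c(0, 0.09, 0.1, 0.5, 0.79, 0.8, 1), cfg),
               c("none", "none", "het", "het", "het", "hom", "hom"))
  expect_error(genotype_from_t(1.2, cfg))
})

test_that("a planted homozygous SNP is called and genotyped hom", {
  cfg0 <- clean_sim_config(77L, n_sites = 1L, n_indel_sites = 0L,
                           reference_length = 3000L, depth_mean = 20)
  sim <- simulate_reads(cfg0)
  # force the single site homozygous by regenerating until gt == hom
  seed <- 77L
  while (sim$truth$genotype[1] != "hom") {
    seed <- seed + 1L
    sim <- simulate_reads(clean_sim_config(seed, n_sites = 1L,
                                           n_indel_sites = 0L,
                                           reference_length = 3000L,
                                           depth_mean = 20))
  }
  model <- load_model(system.file("extdata/models/default_snp.json",
                                  package = "exovar"))
  calls <- call_snps(sim$reads, sim$reference, model)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, sim$truth$pos)
  expect_equal(calls$alt, sim$truth$alt)
  expect_equal(calls$genotype, "hom")
  expect_gte(calls$t, 0.8)
})

test_that("single-read evidence is filtered with reason min_var_depth", {
  ref <- make_ref(paste(rep("ACGTGGTTCA", 10), collapse = ""))
  alt <- if (substr(ref[[1]], 50, 50) == "A") "C" else "A"
  rows <- c(lapply(1:9, function(i) ref_read(ref, 20 + i, 40)),
            list(ref_read(ref, 30, 40, subs = stats::setNames(alt, "21"))))
  reads <- do.call(make_reads, rows)
  calls <- call_snps(reads, ref, p_model(0.6), keep_filtered = TRUE)
  row <- calls[calls$pos == 50, ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$var_depth, 1L)
  expect_match(row$filters, "min_var_depth")
  # and nothing passes
  expect_equal(nrow(call_snps(reads, ref, p_model(0.6))), 0L)
})

test_that("zero-variant input yields zero calls", {
  cfg <- clean_sim_config(19L, n_sites = 0L, n_indel_sites = 0L,
                          reference_length = 2000L, depth_mean = 15)
  sim <- simulate_reads(cfg)
  model <- load_model(system.file("extdata/models/default_snp.json",
                                  package = "exovar"))
  imodel <- load_model(system.file("extdata/models/default_indel.json",
                                   package = "exovar"))
  expect_equal(nrow(call_snps(sim$reads, sim$reference, model)), 0L)
  expect_equal(nrow(call_indels(sim$reads, sim$reference, imodel)), 0L)
})

test_that("INDEL heuristic filter boundaries are exact", {
  # reference without repeats around the anchor so the event stays put
  set.seed(101)
  ref <- make_ref(paste(sample(c("A", "C", "G", "T"), 400, TRUE,
                               prob = c(.3, .2, .2, .3)), collapse = ""))
  anchor <- 200L

  # 1 bp deletion: p = 0.87 filtered, p = 0.88 passes
  reads <- make_del_reads(ref, anchor, 1L, n_var = 5L, n_ref = 10L)
  c87 <- call_indels(reads, ref, p_model(0.87), keep_filtered = TRUE)
  expect_match(c87$filters[c87$kind == "DEL"], "low_p")
  c88 <- call_indels(reads, ref, p_model(0.88))
  expect_equal(nrow(c88), 1L)
  expect_equal(c88$filters, "")

  # longer deletion passes at the ordinary 0.5 cutoff
  reads3 <- make_del_reads(ref, anchor, 3L, n_var = 5L, n_ref = 10L)
  expect_equal(nrow(call_indels(reads3, ref, p_model(0.5))), 1L)
  expect_equal(nrow(call_indels(reads3, ref, p_model(0.49),
                                keep_filtered = FALSE)), 0L)

  # variant depth boundary: 1 variant read filtered, 2 pass
  r1 <- make_del_reads(ref, anchor, 3L, n_var = 1L, n_ref = 10L)
  f1 <- call_indels(r1, ref, p_model(0.9), keep_filtered = TRUE)
  expect_match(f1$filters, "min_var_depth")
  r2 <- make_del_reads(ref, anchor, 3L, n_var = 2L, n_ref = 10L)
  expect_equal(call_indels(r2, ref, p_model(0.9))$var_depth, 2L)

  # variant ratio boundary: 2/41 < 0.05 fails the heuristic filter; 2/40
  # passes it exactly (and is then demoted by the separate genotype rule,
  # since t = 0.05 sits below the heterozygous threshold)
  r41 <- make_del_reads(ref, anchor, 3L, n_var = 2L, n_ref = 39L)
  f41 <- call_indels(r41, ref, p_model(0.9), keep_filtered = TRUE)
  expect_equal(f41$total_depth, 41L)
  expect_match(f41$filters, "low_var_ratio")
  r40 <- make_del_reads(ref, anchor, 3L, n_var = 2L, n_ref = 38L)
  p40 <- call_indels(r40, ref, p_model(0.9), keep_filtered = TRUE)
  expect_equal(p40$total_depth, 40L)
  expect_equal(p40$filters, "low_t")
  # with 6 variant reads of 40 the same site passes outright
  r6 <- make_del_reads(ref, anchor, 3L, n_var = 6L, n_ref = 34L)
  p6 <- call_indels(r6, ref, p_model(0.9))
  expect_equal(p6$filters, "")
  expect_equal(p6$genotype, "het")
})

test_that("filter thresholds are monotone: tightening never adds PASS calls", {
  sim <- simulate_reads(noisy_sim_config(53L, reference_length = 8000L,
                                         n_sites = 25L, n_indel_sites = 0L,
                                         depth_mean = 18))
  model <- load_model(system.file("extdata/models/default_snp.json",
                                  package = "exovar"))
  grids <- list(c(0.3, 0.5, 0.7, 0.9))
  prev <- NULL
  for (minp in grids[[1]]) {
    calls <- call_snps(sim$reads, sim$reference, model,
                       filter_config(snp_min_p = minp))
    keys <- call_key(calls)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
  prev <- NULL
  for (mv in c(2L, 4L, 6L)) {
    calls <- call_snps(sim$reads, sim$reference, model,
                       filter_config(snp_min_var_depth = mv))
    keys <- call_key(calls)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("calls respect supplied target regions", {
  sim <- simulate_reads(noisy_sim_config(59L, reference_length = 8000L,
                                         n_sites = 25L, n_indel_sites = 0L,
                                         depth_mean = 18))
  model <- load_model(system.file("extdata/models/default_snp.json",
                                  package = "exovar"))
  regions <- GenomicRanges::GRanges("seq1", IRanges::IRanges(1L, 4000L))
  all_calls <- call_snps(sim$reads, sim$reference, model)
  reg_calls <- call_snps(sim$reads, sim$reference, model, regions = regions)
  expect_true(all(reg_calls$pos <= 4000L))
  expect_setequal(call_key(reg_calls),
                  call_key(all_calls[all_calls$pos <= 4000L, ]))
})

test_that("calling from the SAM file equals calling from the reads table", {
  sim <- simulate_reads(noisy_sim_config(61L, reference_length = 6000L,
                                         n_sites = 20L, n_indel_sites = 8L))
  d <- withr::local_tempdir()
  fx <- write_sam_fixture(sim$reads, sim$reference, d)
  model <- load_model(system.file("extdata/models/default_snp.json",
                                  package = "exovar"))
  from_dt <- call_snps(sim$reads, sim$reference, model)
  from_sam <- call_snps(fx$sam, fx$fasta, model)
  expect_equal(from_sam, from_dt, ignore_attr = TRUE)
})
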
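# a small deterministic call table for VCF round trips
demo_calls <- function() {
  data.table::data.table(
    chrom = "seq1", pos = c(101L, 230L, 230L, 407L),
    ref = c("A", "G", "GTT", "C"),
    alt = c("G", "A", "G", "CTA"),
    kind = c("SNP", "SNP", "DEL", "INS"),
    p = c(0.9, 0.999999, 0.95, 0.88),
    t = c(0.5, 0.92, 0.45, 0.31),
    genotype = c("het", "hom", "het", "het"),
    var_depth = c(10L, 22L, 9L, 5L),
    total_depth = c(20L, 24L, 20L, 16L),
    effective_depth = c(20L, 24L, 20L, 16L),
    filters = c("", "", "", ""))
}

demo_ref <- function() {
  set.seed(77)
  make_ref(paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = ""))
}

test_that("an empty call set writes a header-only, parseable VCF", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(demo_calls()[0, ], "s1", demo_ref(), path)
  lines <- readLines(path)
  expect_true(all(startsWith(lines, "#")))
  expect_equal(nrow(read_vcf(path)), 0L)
})

test_that("QUAL is -10*log10(1-p), capped", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(demo_calls(), "s1", demo_ref(), path)
  rec <- read_vcf(path)
  expect_equal(rec$qual[1], 10)                 # p = 0.9
  expect_equal(rec$qual[2], 60)                 # p = 0.999999
  one <- demo_calls()[1, ][, p := 1]
  write_vcf(one, "s1", demo_ref(), path)
  expect_equal(read_vcf(path)$qual, 99.99)
})

test_that("write -> read -> write is byte-identical", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.vcf"); p2 <- file.path(d, "b.vcf")
  write_vcf(demo_calls(), "s1", demo_ref(), p1)
  back <- vcf_records_to_calls(read_vcf(p1))
  write_vcf(back, "s1", demo_ref(), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(write_vcf(demo_calls()[c(2, 1), ], "s1", demo_ref(), p2),
               "sorted")
})

test_that("read_vcf agrees field-by-field with a naive line parser", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(demo_calls(), "s1", demo_ref(), path)
  rec <- read_vcf(path)
  lines <- grep("^[^#]", readLines(path), value = TRUE)
  naive <- do.call(rbind, lapply(strsplit(lines, "\t"), function(f) {
    sam <- strsplit(f[10], ":")[[1]]
    data.frame(chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = f[5],
               qual = as.numeric(f[6]), filter = f[7],
               p = as.numeric(sub("P=", "", f[8])),
               gt = sam[1], dp = as.integer(sam[2]), vr = as.integer(sam[3]),
               tr = as.numeric(sam[4]), stringsAsFactors = FALSE)
  }))
  for (col in names(naive)) expect_equal(rec[[col]], naive[[col]])
  expect_error(read_vcf(withr::local_tempfile(lines = "not a vcf")),
               "fileformat")
})

test_that("merging one sample reproduces its content", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, "s1.vcf")
  write_vcf(demo_calls(), "s1", demo_ref(), p1)
  pop <- merge_population(p1)
  expect_equal(pop$samples, "s1")
  expect_equal(nrow(pop$sites), 4L)
  expect_equal(pop$columns[, "s1"],
               sprintf("%s:%d:%d:%.4f", c("0/1", "1/1", "0/1", "0/1"),
                       demo_calls()$total_depth, demo_calls()$var_depth,
                       demo_calls()$t))
})

test_that("population merge fills missing columns from depth tracks", {
  d <- withr::local_tempdir()
  ref <- demo_ref()
  a <- demo_calls()[1:3, ]
  b <- demo_calls()[c(1, 4), ]          # lacks sites 230/G and 230/GTT
  cc <- demo_calls()[2, ]
  pa <- file.path(d, "A.vcf"); write_vcf(a, "A", ref, pa)
  pb <- file.path(d, "B.vcf"); write_vcf(b, "B", ref, pb)
  pc <- file.path(d, "C.vcf"); write_vcf(cc, "C", ref, pc)

  # B has coverage 12 over [200,250) 0-based; C has no depth data
  track <- file.path(d, "B.track.tsv")
  writeLines("seq1\t200\t250\t12", track)

  pop <- merge_population(c(pa, pb, pc), depth_sources = list(B = track))
  expect_equal(nrow(pop$sites), 4L)
  expect_false(any(is.na(pop$columns)))
  i230 <- which(pop$sites$pos == 230L & pop$sites$alt == "A")
  expect_equal(unname(pop$columns[i230, "B"]), "0/0:12:0:0.0000")
  i101 <- which(pop$sites$pos == 101L)
  expect_equal(unname(pop$columns[i101, "C"]), "./.:0:0:.")

  # conservation: called genotypes in == non-fill genotypes out
  n_in <- nrow(a) + nrow(b) + nrow(cc)
  n_out <- sum(!pop$columns %in% c("./.:0:0:.") &
                 !startsWith(pop$columns, "0/0:"))
  expect_equal(n_out, n_in)

  # column order follows input order; content is order-insensitive
  pop2 <- merge_population(c(pc, pa, pb), depth_sources = list(B = track))
  expect_equal(pop2$samples, c("C", "A", "B"))
  expect_equal(pop2$columns[, "B"], pop$columns[, "B"])
  expect_equal(pop2$sites, pop$sites)

  expect_error(merge_population(c(pa, pa)), "duplicate")
})

test_that("population VCFs have a value for every sample at every site", {
  d <- withr::local_tempdir()
  ref <- demo_ref()
  pa <- file.path(d, "A.vcf"); write_vcf(demo_calls()[1:2, ], "A", ref, pa)
  pb <- file.path(d, "B.vcf"); write_vcf(demo_calls()[3:4, ], "B", ref, pb)
  out <- file.path(d, "pop.vcf")
  merge_population(c(pa, pb), path = out)
  rec <- read_vcf(out)
  expect_equal(nrow(rec), 8L)          # 4 sites x 2 samples
  expect_false(any(is.na(rec$gt)))
})

test_that("contig mismatches between inputs are rejected", {
  d <- withr::local_tempdir()
  pa <- file.path(d, "A.vcf"); write_vcf(demo_calls(), "A", demo_ref(), pa)
  other <- make_ref(paste(rep("ACGT", 150), collapse = ""), name = "chrX")
  calls <- demo_calls()[, chrom := "chrX"]
  pb <- file.path(d, "B.vcf"); write_vcf(calls, "B", other, pb)
  expect_error(merge_population(c(pa, pb)), "contig")
})

test_that("target splitting partitions records by 1-based position", {
  d <- withr::local_tempdir()
  path <- file.path(d, "c.vcf")
  write_vcf(demo_calls(), "s1", demo_ref(), path)

  empty_bed <- file.path(d, "empty.bed")
  writeLines(character(), empty_bed)
  sp0 <- split_by_target(path, empty_bed)
  expect_equal(nrow(sp0$on), 0L)
  expect_equal(nrow(sp0$off), 4L)

  # interval 100-101 (0-based half-open) covers exactly 1-based POS 101
  bed <- file.path(d, "t.bed")
  writeLines("seq1\t100\t101", bed)
  sp <- split_by_target(path, bed)
  expect_equal(sp$on$pos, 101L)
  expect_equal(nrow(sp$on) + nrow(sp$off), 4L)

  bad <- file.path(d, "bad.bed")
  writeLines(c("seq1\t10\t20", "seq1\toops"), bad)
  expect_error(split_by_target(path, bad), "line 2")

  set.seed(15)
  rnd_bed <- GenomicRanges::GRanges("seq1",
    IRanges::IRanges(start = sort(sample(seq(1, 500, by = 40), 6)),
                     width = sample(5:30, 6, TRUE)))
  rec <- read_vcf(path)
  sp2 <- split_by_target(rec, rnd_bed)
  expect_equal(nrow(sp2$on) + nrow(sp2$off), nrow(rec))
  inside <- vapply(rec$pos, function(p) {
    any(p >= GenomicRanges::start(rnd_bed) & p <= GenomicRanges::end(rnd_bed))
  }, logical(1))
  expect_equal(sort(sp2$on$pos), sort(rec$pos[inside]))
})
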
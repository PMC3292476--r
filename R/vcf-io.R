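# VCF 4.1 output, population-level merging with missing-coverage fill, and
# target-region splitting.
#
# Writing is deterministic (fixed numeric formats), so identical call sets
# produce byte-identical files. Parsing goes through vcfR.

.qual_from_p <- function(p) {
  q <- ifelse(p >= 1, 99.99, -10 * log10(1 - p))
  pmin(q, 99.99)
}

.gt_string <- function(genotype) {
  ifelse(is.na(genotype), "./.",
         ifelse(genotype == "hom", "1/1",
                ifelse(genotype == "het", "0/1", "./.")))
}

.vcf_header <- function(sample_names, reference = NULL, contigs = NULL) {
  h <- c("##fileformat=VCFv4.1",
         "##source=exovar")
  if (!is.null(reference)) {
    reference <- .as_reference(reference)
    contigs <- setNames(nchar(reference), names(reference))
  }
  if (!is.null(contigs)) {
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                      as.integer(contigs)))
  }
  c(h,
    "##INFO=<ID=P,Number=1,Type=Float,Description=\"Logistic model probability that the variant is true\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=VR,Number=1,Type=Integer,Description=\"Variant read depth\">",
    "##FORMAT=<ID=TR,Number=1,Type=Float,Description=\"Adjusted variant ratio t\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
}

#' Write variant calls as a single-sample VCF
#'
#' Records carry the model probability as INFO/P, QUAL = -10 log10(1 - p)
#' capped at 99.99, and per-sample fields GT:DP:VR:TR. Multi-allelic sites
#' appear as separate records sharing POS.
#'
#' @param calls calls data.table from [call_snps()]/[call_indels()], sorted
#'   by (chrom, pos).
#' @param sample_name sample column name.
#' @param reference named character vector of contigs or FASTA path (for the
#'   contig header lines).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, sample_name, reference, path) {
  if (nrow(calls) > 1L) {
    o <- order(calls$chrom, calls$pos, calls$alt)
    if (!identical(o, seq_len(nrow(calls)))) {
      stop("calls must be sorted by (chrom, pos, alt)")
    }
  }
  lines <- .vcf_header(sample_name, reference = reference)
  if (nrow(calls)) {
    filt <- ifelse(calls$filters == "" | is.na(calls$filters), "PASS",
                   calls$filters)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\t%s\tP=%.6f\tGT:DP:VR:TR\t%s:%d:%d:%.4f",
                    calls$chrom, calls$pos, calls$ref, calls$alt,
                    .qual_from_p(calls$p), filt, calls$p,
                    .gt_string(calls$genotype), calls$total_depth,
                    calls$var_depth, calls$t)
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

.parse_format_field <- function(fmt, sample_str, key) {
  keys <- strsplit(fmt, ":", fixed = TRUE)
  vals <- strsplit(sample_str, ":", fixed = TRUE)
  mapply(function(k, v) {
    i <- match(key, k)
    if (is.na(i) || i > length(v)) NA_character_ else v[i]
  }, keys, vals, USE.NAMES = FALSE)
}

#' Read a VCF into a records table
#'
#' Lossless for the fields the suite consumes: CHROM/POS/ID/REF/ALT/QUAL/
#' FILTER/INFO P and the per-sample GT/DP/VR/TR fields. Multi-sample files
#' come back in long format (one row per record x sample).
#'
#' @param path VCF path.
#' @return data.table: chrom, pos, id, ref, alt, qual, filter, p, sample,
#'   gt, dp, vr, tr.
#' @export
read_vcf <- function(path) {
  # reject files without the mandatory header up front (clearer error than
  # the parser's)
  first <- readLines(path, n = 1L)
  if (!length(first) || !grepl("^##fileformat=VCF", first)) {
    stop("missing ##fileformat header: ", path)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  empty <- data.table::data.table(
    chrom = character(), pos = integer(), id = character(),
    ref = character(), alt = character(), qual = numeric(),
    filter = character(), p = numeric(), sample = character(),
    gt = character(), dp = integer(), vr = integer(), tr = numeric())
  if (!nrow(fix)) return(empty)
  base <- data.table::data.table(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID,
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    filter = fix$FILTER,
    p = suppressWarnings(as.numeric(sub("^.*P=([0-9.eE+-]+).*$", "\\1",
                                        fix$INFO))))
  gmat <- v@gt
  if (is.null(gmat) || !ncol(gmat)) {
    base[, c("sample", "gt", "dp", "vr", "tr") :=
           list(NA_character_, NA_character_, NA_integer_, NA_integer_,
                NA_real_)]
    return(base[])
  }
  fmt <- gmat[, "FORMAT"]
  samples <- setdiff(colnames(gmat), "FORMAT")
  out <- lapply(samples, function(s) {
    b <- data.table::copy(base)
    gt_v <- .parse_format_field(fmt, gmat[, s], "GT")
    dp_v <- suppressWarnings(as.integer(.parse_format_field(fmt, gmat[, s], "DP")))
    vr_v <- suppressWarnings(as.integer(.parse_format_field(fmt, gmat[, s], "VR")))
    tr_v <- suppressWarnings(as.numeric(.parse_format_field(fmt, gmat[, s], "TR")))
    b[, c("sample", "gt", "dp", "vr", "tr") :=
        list(s, gt_v, dp_v, vr_v, tr_v)]
    b
  })
  data.table::rbindlist(out)
}

#' Convert read-back VCF records to a calls table
#'
#' Inverse of [write_vcf()] for a single-sample file; round-tripping a call
#' set through write/read/convert/write yields a byte-identical file.
#'
#' @param records output of [read_vcf()] for a single-sample VCF.
#' @return calls data.table compatible with [write_vcf()].
#' @export
vcf_records_to_calls <- function(records) {
  gt <- ifelse(records$gt == "1/1", "hom",
               ifelse(records$gt == "0/1", "het", NA_character_))
  data.table::data.table(
    chrom = records$chrom, pos = records$pos, ref = records$ref,
    alt = records$alt,
    kind = ifelse(nchar(records$ref) == 1L & nchar(records$alt) == 1L, "SNP",
                  ifelse(nchar(records$ref) > nchar(records$alt), "DEL",
                         "INS")),
    p = records$p, t = records$tr, genotype = gt,
    var_depth = records$vr, total_depth = records$dp,
    effective_depth = records$dp,
    filters = ifelse(records$filter %in% c("PASS", "."), "", records$filter))
}

#' Read a BED file (0-based half-open) into GRanges
#'
#' @param path BED path.
#' @return GRanges (1-based closed).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) return(GenomicRanges::GRanges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) < 3L || is.na(suppressWarnings(as.integer(f[2L]))) ||
        is.na(suppressWarnings(as.integer(f[3L])))) {
      stop("malformed BED line ", i, ": ", lines[i])
    }
  }
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start0 <- vapply(parts, function(f) as.integer(f[2L]), integer(1))
  end0 <- vapply(parts, function(f) as.integer(f[3L]), integer(1))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
}

#' Write GRanges as BED (0-based half-open)
#' @param regions GRanges.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  writeLines(sprintf("%s\t%d\t%d",
                     as.character(GenomicRanges::seqnames(regions)),
                     GenomicRanges::start(regions) - 1L,
                     GenomicRanges::end(regions)), path)
  invisible(path)
}

#' Read a depth track (chrom, start, end, depth; 0-based half-open)
#'
#' @param path tab-delimited track path.
#' @return data.table: chrom, start (1-based), end (closed), depth.
#' @export
read_depth_track <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "depth"))
  dt[, "start" := dt$start + 1L]
  dt[]
}

.depth_at <- function(track, chrom, pos) {
  if (is.null(track)) return(0L)
  hit <- track[track$chrom == chrom & track$start <= pos & track$end >= pos, ]
  if (!nrow(hit)) 0L else as.integer(max(hit$depth))
}

#' Merge single-sample VCFs into a population VCF
#'
#' Takes the union of sites across samples. Per-sample fields of called
#' sites are preserved verbatim. For a sample without a call at a union
#' site: if its depth source covers the site with depth >= 1 the column is
#' filled as homozygous-reference (GT 0/0 with the observed DP), otherwise
#' as missing (./., DP 0).
#'
#' @param vcf_paths character vector of single-sample VCF paths (unique
#'   sample names, same contigs).
#' @param depth_sources optional named list (sample -> depth-track path or
#'   data.table from [read_depth_track()]).
#' @param path optional output path; when given the population VCF is
#'   written there.
#' @return a `population_vcf`: list(sites, samples, columns (matrix of
#'   sample field strings), contigs).
#' @export
merge_population <- function(vcf_paths, depth_sources = NULL, path = NULL) {
  recs <- lapply(vcf_paths, read_vcf)
  samples <- vapply(recs, function(r) {
    s <- unique(r$sample[!is.na(r$sample)])
    if (length(s) != 1L) stop("each input must be a single-sample VCF")
    s
  }, character(1))
  if (anyDuplicated(samples)) {
    stop("duplicate sample name(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  contig_sets <- lapply(vcf_paths, function(p) {
    h <- grep("^##contig=", readLines(p), value = TRUE)
    sort(sub("^##contig=<ID=([^,>]+).*$", "\\1", h))
  })
  for (k in seq_along(contig_sets)) {
    if (!identical(contig_sets[[k]], contig_sets[[1L]])) {
      stop("contig mismatch between ", vcf_paths[1L], " and ", vcf_paths[k])
    }
  }
  contigs <- NULL
  h1 <- grep("^##contig=", readLines(vcf_paths[1L]), value = TRUE)
  if (length(h1)) {
    contigs <- setNames(
      as.integer(sub("^.*length=(\\d+).*$", "\\1", h1)),
      sub("^##contig=<ID=([^,>]+).*$", "\\1", h1))
  }

  if (!is.null(depth_sources)) {
    depth_sources <- lapply(depth_sources, function(d) {
      if (is.character(d)) read_depth_track(d) else data.table::as.data.table(d)
    })
  }

  all_rec <- data.table::rbindlist(recs)
  sites <- unique(all_rec[, c("chrom", "pos", "ref", "alt")])
  data.table::setorder(sites, chrom, pos, alt)
  key_of <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  skey <- key_of(sites)

  cols <- matrix(NA_character_, nrow = nrow(sites), ncol = length(samples),
                 dimnames = list(NULL, samples))
  for (k in seq_along(samples)) {
    r <- recs[[k]]
    idx <- match(key_of(r), skey)
    cols[idx, k] <- sprintf("%s:%d:%d:%.4f", r$gt, r$dp, r$vr, r$tr)
    missing_rows <- which(is.na(cols[, k]))
    for (m in missing_rows) {
      d <- .depth_at(depth_sources[[samples[k]]], sites$chrom[m],
                     sites$pos[m])
      cols[m, k] <- if (d >= 1L) sprintf("0/0:%d:0:0.0000", d)
                    else "./.:0:0:."
    }
  }
  pop <- structure(list(sites = sites, samples = samples, columns = cols,
                        contigs = contigs),
                   class = "population_vcf")
  if (!is.null(path)) write_population_vcf(pop, path)
  pop
}

#' Write a population VCF
#'
#' @param pop a `population_vcf` from [merge_population()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population_vcf <- function(pop, path) {
  lines <- .vcf_header(pop$samples, contigs = pop$contigs)
  if (nrow(pop$sites)) {
    is_called <- !startsWith(as.vector(pop$columns), "./.") &
      !startsWith(as.vector(pop$columns), "0/0")
    called <- rowSums(matrix(is_called, nrow = nrow(pop$sites)))
    body <- paste(pop$sites$chrom, pop$sites$pos, ".", pop$sites$ref,
                  pop$sites$alt, ".", ".", paste0("NS=", called),
                  "GT:DP:VR:TR",
                  apply(pop$columns, 1L, paste, collapse = "\t"),
                  sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Split VCF records by target regions
#'
#' A record is on-target iff its POS (1-based) falls inside a BED interval.
#' Every record lands in exactly one of the two outputs.
#'
#' @param vcf VCF path or records data.table from [read_vcf()].
#' @param bed BED path or GRanges.
#' @return list(on = records, off = records).
#' @export
split_by_target <- function(vcf, bed) {
  records <- if (is.character(vcf)) read_vcf(vcf) else vcf
  idx <- .region_index(if (is.character(bed)) read_bed(bed) else bed)
  if (!nrow(records)) return(list(on = records, off = records))
  on <- vapply(seq_len(nrow(records)), function(i) {
    .in_region(idx, records$chrom[i], records$pos[i])
  }, logical(1))
  list(on = records[on, ], off = records[!on, ])
}
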
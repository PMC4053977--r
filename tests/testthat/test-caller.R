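test_that("fragment NM filter keeps the 10-mismatch boundary and drops both mates above it", {
  a <- rbind(make_aln("fragA", "ACGT", flag = 99L, nm = 4L),
             make_aln("fragA", "ACGT", flag = 147L, nm = 6L),
             make_aln("fragB", "ACGT", flag = 99L, nm = 6L),
             make_aln("fragB", "ACGT", flag = 147L, nm = 5L))
  out <- filter_fragments_by_nm(a, 10L)
  expect_setequal(unique(out$qname), "fragA")  # 4+6 kept, 6+5 dropped
})

test_that("unmapped mates contribute zero mismatches", {
  a <- rbind(make_aln("frag", "ACGT", flag = 99L, nm = 9L),
             make_aln("frag", "ACGT", flag = 147L + 4L, nm = NA_integer_))
  out <- filter_fragments_by_nm(a, 10L)
  expect_equal(nrow(out), 2L)
})

test_that("missing NM on mapped records fails unless passed through", {
  a <- make_aln("frag", "ACGT", nm = NA_integer_)
  expect_error(filter_fragments_by_nm(a, 10L), "NM")
  expect_equal(nrow(filter_fragments_by_nm(a, 10L, missing_nm = "pass")), 1L)
})

test_that("pileup counts single reads once per covered column", {
  ref <- c(ctg1 = "ACGTACGTAC")
  a <- make_aln("f1", "ACGTA", pos = 1L)
  p <- build_pileup(a, ref)
  expect_equal(nrow(p), 5L)
  expect_true(all(p$depth == 1L))
  expect_equal(p$A[p$pos == 1L], 1L)
})

test_that("overlapping mates vote once when agreeing, zero when disagreeing", {
  ref <- c(ctg1 = "ACGTACGTAC")
  agree <- rbind(make_aln("f1", "ACGTA", pos = 1L, flag = 99L),
                 make_aln("f1", "ACGTA", pos = 1L, flag = 147L))
  p <- build_pileup(agree, ref)
  expect_true(all(p$depth == 1L))
  disagree <- rbind(make_aln("f1", "ACGTA", pos = 1L, flag = 99L),
                    make_aln("f1", "ACGTT", pos = 1L, flag = 147L))
  p2 <- build_pileup(disagree, ref)
  expect_false(5L %in% p2$pos)  # conflicting column contributes nothing
  expect_true(all(p2$depth[p2$pos < 5L] == 1L))
})

test_that("pileup honours mapping-quality, duplicate and base-quality filters", {
  ref <- c(ctg1 = "ACGTACGTAC")
  a <- rbind(make_aln("f1", "ACGTA", mapq = 19L),
             make_aln("f2", "ACGTA", flag = 99L + 1024L),
             make_aln("f3", "ACGTA", qual = "I!III"))  # base 2 below q20
  p <- build_pileup(a, ref)
  expect_equal(sum(p$depth), 4L)  # only f3 minus its low-quality base
})

test_that("variant calling applies coverage, alt-count, fraction and biallelic rules", {
  mk <- function(A, C, G = 0L, T = 0L, pos = 5L)
    structure(data.frame(contig = "ctg1", pos = pos, A = A, C = C, G = G,
                         T = T, depth = A + C + G + T),
              class = c("pileup", "data.frame"))
  ref <- c(ctg1 = "AAAAAAAAAA")
  # depth 3 below min_coverage
  expect_equal(nrow(call_variants(mk(2L, 1L), ref)), 0L)
  # alt seen once, below min_alt_count
  expect_equal(nrow(call_variants(mk(5L, 1L), ref)), 0L)
  # balanced site called with alt fraction 0.4
  v <- call_variants(mk(6L, 4L), ref)
  expect_equal(nrow(v), 1L)
  expect_equal(v$ref, "A"); expect_equal(v$alt, "C")
  expect_equal(v$alt_fraction, 0.4)
  # alt fraction outside [0.2, 0.8]
  expect_equal(nrow(call_variants(mk(18L, 2L), ref)), 0L)
  # three qualifying alleles: skipped and logged
  v3 <- call_variants(mk(4L, 3L, G = 3L), ref)
  expect_equal(nrow(v3), 0L)
  expect_equal(attr(v3, "skipped")$reason, "multiallelic")
  # two qualifying alleles but neither is the reference base
  v4 <- call_variants(mk(0L, 5L, G = 5L), ref)
  expect_equal(nrow(v4), 0L)
  expect_equal(attr(v4, "skipped")$reason, "ref_not_qualifying")
})

test_that("emitted sites always satisfy the threshold predicates", {
  res <- cached_pipeline("default4", sim_config(n_genes = 4L, seed = 7L))
  s <- res$sites
  expect_true(all(s$depth >= 4L))
  expect_true(all(s$alt_count >= 2L))
  expect_true(all(s$alt_fraction >= 0.2 & s$alt_fraction <= 0.8))
  expect_true(all(s$ref != s$alt))
  expect_true(all(s$depth >= s$ref_count + s$alt_count))
})

test_that("on clean balanced data every eligible truth variant is called with no false positives", {
  res <- cached_pipeline("noisefree", noise_free_config())
  truth <- truth_phase_table(res$dataset)
  called <- paste(res$sites$contig, res$sites$pos)
  truthk <- paste(truth$contig, truth$pos)
  expect_true(all(called %in% truthk))  # zero false positives
  # misses only where post-filter depth or allele counts fall short
  missed <- truth[!truthk %in% called, ]
  if (nrow(missed) > 0) {
    for (i in seq_len(nrow(missed))) {
      pc <- res$pileup[res$pileup$contig == missed$contig[i] &
                         res$pileup$pos == missed$pos[i], ]
      counts <- sort(as.integer(pc[, c("A", "C", "G", "T")]),
                     decreasing = TRUE)
      expect_true(nrow(pc) == 0L || pc$depth < 4L || counts[2] < 2L ||
                    counts[2] / pc$depth < 0.2 || counts[2] / pc$depth > 0.8)
    }
  }
})

test_that("recall stays high and false positives rare at default error rates", {
  res <- cached_pipeline("default30", default_config_30())
  truth <- truth_phase_table(res$dataset)
  called <- paste(res$sites$contig, res$sites$pos)
  truthk <- paste(truth$contig, truth$pos)
  recall <- mean(truthk %in% called)
  expect_gte(recall, 0.95)
  fp <- sum(!called %in% truthk)
  genome_kb <- sum(vapply(res$dataset$pairs, `[[`, 0L, "length")) / 1000
  expect_lte(fp / (genome_kb / 10), 1)  # <= 1 per 10 kb
})

test_that("VCF writing round-trips and is readable by an independent parser", {
  res <- cached_pipeline("default4", sim_config(n_genes = 4L, seed = 7L))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variants(res$sites, path)
  expect_error(write_variants(res$sites, path), "overwrite")
  back <- read_variants(path)
  expect_equal(back, res$sites, ignore_attr = TRUE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(nrow(v@fix), nrow(res$sites))
  expect_identical(as.integer(v@fix[, "POS"]), res$sites$pos)

  empty <- res$sites[0, ]
  class(empty) <- c("variant_sites", "data.frame")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_variants(empty, p2)
  expect_equal(nrow(read_variants(p2)), 0L)
})

test_that("malformed VCF records are rejected with their line number", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS", "ctg1\tnotanumber\t.\tA\tC\t.\tPASS\tDP=4;RO=2;AO=2"), p)
  expect_error(read_variants(p), "line 3")
})
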
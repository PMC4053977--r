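sites2 <- function(pos = c(10L, 20L), ref = c("A", "A"), alt = c("C", "C")) {
  s <- data.frame(contig = "ctg1", pos = pos, ref = ref, alt = alt,
                  stringsAsFactors = FALSE)
  class(s) <- c("variant_sites", "data.frame")
  s
}

test_that("fragment extraction excludes and tallies low-mapq, indel and duplicate records", {
  ref_read <- strrep("A", 25L)
  a <- rbind(make_aln("lowq", ref_read, pos = 1L, mapq = 29L),
             make_aln("indel", ref_read, pos = 1L,
                      cigar = "10M2D15M"),
             make_aln("dupe", ref_read, pos = 1L, flag = 99L + 1024L),
             make_aln("keep", ref_read, pos = 1L, mapq = 30L))
  fm <- extract_fragments(a, sites2())
  expect_identical(fm$fragment_ids, "keep")
  expect_equal(fm$excluded_counts[["mapq"]], 1L)
  expect_equal(fm$excluded_counts[["indel"]], 1L)
  expect_equal(fm$excluded_counts[["duplicate"]], 1L)
})

test_that("allele observations encode ref as 0, alt as 1, and conflicts as missing", {
  # fragment covers site 1 with alt (C) and site 2 with ref (A)
  read <- paste0(strrep("A", 9L), "C", strrep("A", 15L))
  a <- make_aln("f1", read, pos = 1L)
  fm <- extract_fragments(a, sites2())
  expect_identical(fm$mat[1, ], c(1L, 0L))
  # disagreeing mates at site 1 -> missing there, still 0 at site 2
  b <- rbind(make_aln("f2", read, pos = 1L, flag = 99L),
             make_aln("f2", strrep("A", 25L), pos = 1L, flag = 147L))
  fm2 <- extract_fragments(b, sites2())
  expect_identical(fm2$mat[1, ], c(NA_integer_, 0L))
})

test_that("bases matching neither allele become offsite evidence, not votes", {
  read <- paste0(strrep("A", 9L), "G", strrep("A", 15L))  # G at site 1
  fm <- extract_fragments(make_aln("f1", read, pos = 1L), sites2())
  expect_true(fm$offsite[1, 1])
  expect_true(is.na(fm$mat[1, 1]))
  expect_equal(fm$excluded_counts[["offsite_allele"]], 1L)
})

test_that("low base quality makes the observation missing", {
  read <- paste0(strrep("A", 9L), "C", strrep("A", 15L))
  qual <- paste0(strrep("I", 9L), "!", strrep("I", 15L))
  fm <- extract_fragments(make_aln("f1", read, pos = 1L, qual = qual),
                          sites2())
  expect_true(is.na(fm$mat[1, 1]))
  expect_identical(fm$mat[1, 2], 0L)
})

test_that("blocks are connected components of fragment co-observation", {
  # no fragment spans two sites -> singletons
  m <- matrix(c(0L, NA, NA, 1L), 2, 2)
  expect_equal(partition_blocks(make_fm(m)), list(1L, 2L))
  # chain s1-s2 (frag a), s2-s3 (frag b) -> one block
  m2 <- rbind(c(0L, 0L, NA), c(NA, 1L, 1L))
  expect_equal(partition_blocks(make_fm(m2)), list(1:3))
  # two clusters with no bridge -> two blocks
  m3 <- rbind(c(0L, 0L, NA, NA), c(NA, NA, 1L, 1L))
  expect_equal(partition_blocks(make_fm(m3)), list(1:2, 3:4))
})

test_that("noise-free two-haplotype fragments are phased exactly with MEC 0", {
  h <- c(0L, 1L, 1L, 0L, 1L)
  mat <- rbind(h, h, 1L - h, 1L - h, h)
  rownames(mat) <- NULL
  b <- phase_block(make_fm(mat), 1:5, seed = 3L)
  expect_equal(b$mec, 0L)
  expect_true(identical(b$hap0, h) || identical(b$hap0, 1L - h))
  expect_identical(b$hap1, 1L - b$hap0)
})

test_that("a single flipped allele costs exactly MEC 1", {
  h <- c(0L, 1L, 0L)
  mat <- rbind(h, h, 1L - h, c(0L, 0L, 0L))  # last fragment: one flip
  rownames(mat) <- NULL
  fm <- make_fm(mat)
  b <- phase_block(fm, 1:3, seed = 5L)
  expect_equal(b$mec, 1L)
  expect_equal(brute_force_phase(fm, 1:3)$mec, 1L)
})

test_that("brute force oracle resolves ties toward the smallest haplotype", {
  mat <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L))
  bf <- brute_force_phase(make_fm(mat), 1:2)
  expect_equal(bf$mec, 1L)
  expect_identical(bf$hap0, c(0L, 0L))
  expect_error(brute_force_phase(make_fm(matrix(0L, 1, 21)), 1:21),
               "guarded")
})

test_that("MEC is invariant under global complement of the haplotype", {
  inst <- random_instance(6L, 20L, noise = 0.1, seed = 17L)
  M <- inst$fm$mat
  mec <- function(h) {
    mh <- matrix(h, nrow(M), length(h), byrow = TRUE)
    mt <- rowSums(M == mh, na.rm = TRUE)
    sum(pmin(rowSums(!is.na(M)) - mt, mt))
  }
  for (s in 1:5) {
    h <- with(list(), {set.seed(s); sample(c(0L, 1L), 6L, replace = TRUE)})
    expect_equal(mec(h), mec(1L - h))
  }
})

test_that("heuristic matches the brute-force optimum on noise-free instances", {
  for (s in 1:25) {
    k <- 2L + (s %% 7L)
    inst <- random_instance(k, 20L, noise = 0, seed = 100L + s)
    b <- phase_block(inst$fm, seq_len(k), seed = s)
    expect_equal(b$mec, 0L)
    expect_true(identical(b$hap0, inst$truth) ||
                  identical(b$hap0, 1L - inst$truth))
  }
})

test_that("single-site blocks are emitted unphased with MEC 0", {
  fm <- make_fm(matrix(c(0L, 1L), 2, 1))
  b <- phase_block(fm, 1L, seed = 1L)
  expect_identical(b$hap0, 0L)
  expect_equal(b$mec, 0L)
  expect_false(b$chimeric)
})

test_that("chimerism counts adjacent phase switches in the reference pattern", {
  fm <- make_fm(matrix(0L, 1, 4))
  b <- phase_block(fm, 1:4, seed = 1L)
  b$hap0 <- c(0L, 0L, 0L, 0L)
  expect_equal(classify_chimerism(b), list(chimeric = FALSE, n_switches = 0L))
  b$hap0 <- c(0L, 0L, 1L, 1L)
  expect_equal(classify_chimerism(b), list(chimeric = TRUE, n_switches = 1L))
  b$hap0 <- c(0L, 1L, 0L, 1L)
  expect_equal(classify_chimerism(b)$n_switches, 3L)
})

test_that("phased blocks partition the called sites of each contig", {
  res <- cached_pipeline("default4", sim_config(n_genes = 4L, seed = 7L))
  for (ct in names(res$matrices)) {
    bl <- Filter(function(b) b$contig == ct, res$blocks)
    idx <- sort(unlist(lapply(bl, `[[`, "site_indices")))
    expect_identical(idx, seq_len(nrow(res$matrices[[ct]]$sites)))
  }
})

test_that("block files round-trip bit-exactly in the tabular dialect", {
  res <- cached_pipeline("default4", sim_config(n_genes = 4L, seed = 7L))
  path <- withr::local_tempfile(fileext = ".blocks")
  write_blocks(res$blocks, path)
  lines <- readLines(path)
  b1 <- res$blocks[[1]]
  expect_match(lines[1], "^BLOCK: contig=\\S+ block=1 sites=\\d+ mec=\\d+$")
  expect_equal(lines[b1$n_phased + 2L], "********")
  back <- read_blocks(path)
  expect_equal(back, res$blocks, ignore_attr = TRUE)
  # write(read(x)) is the identity on the file too
  p2 <- withr::local_tempfile()
  write_blocks(back, p2)
  expect_identical(readLines(p2), lines)

  p3 <- withr::local_tempfile()
  writeLines(c("BLOCK: contig=c block=1 sites=1 mec=0", "oops"), p3)
  expect_error(read_blocks(p3), "line 2")
  p4 <- withr::local_tempfile()
  writeLines("not a header", p4)
  expect_error(read_blocks(p4), "line 1")
  p5 <- withr::local_tempfile()
  write_blocks(list(), p5)
  expect_identical(readLines(p5), character(0))
})
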
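mk_block2 <- function(hap0, pos, contig = "gene0001", block_id = 1L)
  homeophaser:::new_phased_block(block_id, contig, seq_along(hap0), pos,
                                 rep("A", length(hap0)),
                                 rep("C", length(hap0)), hap0, mec = 0L)

mk_truth <- function(code_a, pos, contig = "gene0001")
  data.frame(contig = contig, pos = pos, allele_a = "A", allele_b = "C",
             ref_origin = ifelse(code_a == 0L, "A", "B"), code_a = code_a,
             stringsAsFactors = FALSE)

test_that("phasing accuracy is 1 for perfect or globally complemented blocks", {
  tr <- mk_truth(c(0L, 1L, 0L, 1L), c(10L, 20L, 30L, 40L))
  sc <- phasing_accuracy(list(mk_block2(c(0L, 1L, 0L, 1L),
                                        c(10L, 20L, 30L, 40L))), tr)
  expect_equal(sc$accuracy, 1)
  expect_equal(sc$switch_errors, 0L)
  sc2 <- phasing_accuracy(list(mk_block2(c(1L, 0L, 1L, 0L),
                                         c(10L, 20L, 30L, 40L))), tr)
  expect_equal(sc2$accuracy, 1)  # label complement is not an error
})

test_that("one mis-phased interior site scores 3/4 with two switch errors", {
  tr <- mk_truth(c(0L, 0L, 0L, 0L), c(10L, 20L, 30L, 40L))
  sc <- phasing_accuracy(list(mk_block2(c(0L, 0L, 1L, 0L),
                                        c(10L, 20L, 30L, 40L))), tr)
  expect_equal(sc$n_phased_snps, 4L)
  expect_equal(sc$n_correct, 3L)
  expect_equal(sc$switch_errors, 2L)
  # a terminal mis-phased site gives a single switch error
  sc2 <- phasing_accuracy(list(mk_block2(c(0L, 0L, 0L, 1L),
                                         c(10L, 20L, 30L, 40L))), tr)
  expect_equal(sc2$switch_errors, 1L)
})

test_that("accuracy is invariant under block reordering and tallies untruthed sites", {
  tr <- rbind(mk_truth(c(0L, 1L), c(10L, 20L)),
              mk_truth(c(1L, 1L), c(10L, 20L), contig = "gene0002"))
  b1 <- mk_block2(c(0L, 1L), c(10L, 20L))
  b2 <- mk_block2(c(1L, 1L), c(10L, 20L), contig = "gene0002",
                  block_id = 2L)
  expect_equal(phasing_accuracy(list(b1, b2), tr)$accuracy,
               phasing_accuracy(list(b2, b1), tr)$accuracy)
  b3 <- mk_block2(c(0L, 1L, 0L), c(10L, 20L, 99L))  # 99 not in truth
  sc <- phasing_accuracy(list(b3), tr)
  expect_equal(sc$n_untruthed, 1L)
  expect_equal(sc$n_phased_snps, 2L)
})

test_that("sorting metrics compute per-block best-mapping precision and recall", {
  truth <- data.frame(fragment_id = sprintf("f%03d", 1:200),
                      source = rep(c("A", "B"), each = 100),
                      stringsAsFactors = FALSE)
  asg <- data.frame(fragment_id = sprintf("f%03d", 1:200),
                    contig = "gene0001", block_id = 1L,
                    category = rep(c("phase0", "phase1"), each = 100),
                    reason = NA_character_, stringsAsFactors = FALSE)
  m <- sorting_metrics(asg, truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  # one B fragment in phase0 and one A fragment in phase1
  asg2 <- asg
  asg2$category[101] <- "phase0"
  asg2$category[1] <- "phase1"
  m2 <- sorting_metrics(asg2, truth)
  expect_equal(m2$n_assigned, 200L)
  expect_equal(m2$n_correct, 198L)
  expect_equal(m2$precision, 0.99)
  expect_equal(m2$recall, 0.99)
  # empty assignment -> not applicable
  asg3 <- asg; asg3$category <- "uninformative"
  expect_true(is.na(sorting_metrics(asg3, truth)$precision))
  expect_error(sorting_metrics(rbind(asg, data.frame(
    fragment_id = "zzz", contig = "gene0001", block_id = 1L,
    category = "phase0", reason = NA_character_)), truth),
    "absent from truth")
})

test_that("identity of a sequence against itself is 100", {
  p <- make_pair("ACGTACGTAC", "ACGTACGTAC")
  q <- data.frame(contig = "gene0001", start = 1L, end = 10L,
                  sequence = "ACGTACGTAC", stringsAsFactors = FALSE)
  d <- identity_distribution(q, list(p), mode = "truth")
  expect_true(all(d$identities$identity == 100))
})

test_that("phased consensus identities are bimodal with mode gap near 100 - identity mean", {
  res <- cached_pipeline("noisefree", noise_free_config())
  segs <- do.call(rbind, lapply(res$consensus, function(cs) {
    s <- cs$segments
    s$contig <- cs$contig
    s[s$end - s$start > 200L, c("contig", "start", "end", "sequence")]
  }))
  d <- identity_distribution(segs, res$dataset$pairs, mode = "truth")
  expect_gt(d$mode_high, 99)
  expected_gap <- 100 - mean(vapply(res$dataset$pairs, `[[`, 0,
                                    "realized_identity"))
  expect_lt(abs(d$mode_gap - expected_gap), 2)
})

test_that("unphased chimeric contigs sit at intermediate identities", {
  res <- cached_pipeline("noisefree", noise_free_config())
  merged <- do.call(rbind, lapply(res$dataset$contigs, function(m)
    data.frame(contig = m$contig_id, start = 1L,
               end = nchar(m$sequence), sequence = m$sequence,
               stringsAsFactors = FALSE)))
  d <- identity_distribution(merged, res$dataset$pairs, mode = "truth")
  # merged contigs are nearer both homoeologs than the homoeologs are
  # to each other: no wide bimodal separation
  pair_gap <- 100 - mean(vapply(res$dataset$pairs, `[[`, 0,
                                "realized_identity"))
  expect_true(is.na(d$mode_gap) || d$mode_gap < pair_gap)
  expect_true(all(d$identities$identity >
                    mean(vapply(res$dataset$pairs, `[[`, 0,
                                "realized_identity")) - 1))
})

test_that("alignment-mode identity finds the matching reference", {
  refs <- Biostrings::DNAStringSet(c(target = strrep("ACGTT", 40L),
                                     decoy = strrep("GGCAT", 40L)))
  q <- data.frame(contig = "q1", start = 1L, end = 60L,
                  sequence = substr(strrep("ACGTT", 40L), 21L, 80L),
                  stringsAsFactors = FALSE)
  d <- identity_distribution(q, refs, mode = "align")
  expect_equal(d$identities$target, "target")
  expect_equal(d$identities$identity, 100)
})
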
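make_small_ref <- function(seed, len = 60, mature_at = 40, anchor = 5) {
  set.seed(seed)
  reference_locus(rand_seq(len), mature_end = mature_at, anchor_len = anchor)
}

test_that("trim_linker finds exact, mismatched, and absent linkers", {
  params <- profiler_params(linker = "ACGTACGTACGTACGTACGT",
                            min_post_trim_len = 5)
  insert <- "TTTTTGGGGGCCCCCAAAAA"

  r <- trim_linker(paste0(insert, params$linker, "GATTACA"), params)
  expect_equal(r$status, "OK")
  expect_equal(r$insert, insert)

  # one substitution inside the linker is tolerated at the default allowance
  mut <- sub("ACGTACGTAC", "ACGTACTTAC", params$linker)
  r1 <- trim_linker(paste0(insert, mut), params)
  expect_equal(r1$insert, insert)

  r2 <- trim_linker(paste0(insert, rand_seq(30)), params)
  expect_equal(r2$status, "NO_LINKER")

  r3 <- trim_linker(paste0("AAA", params$linker), params)
  expect_equal(r3$status, "TOO_SHORT")

  expect_error(trim_linker("", params), "non-empty")
})

test_that("trim_linker matches a brute-force scan, leftmost occurrence wins", {
  set.seed(42)
  linker <- "ACGTTGCAACGTTGCAACGT"
  params <- profiler_params(linker = linker, min_post_trim_len = 1)
  for (i in 1:200) {
    insert <- rand_seq(sample(5:40, 1))
    read <- paste0(insert, linker, rand_seq(sample(0:20, 1)))
    # occasionally plant a second, corrupted linker copy inside the insert
    if (i %% 4 == 0) {
      mut <- linker
      substr(mut, 3, 3) <- "T"
      read <- paste0(rand_seq(5), mut, read)
    }
    expect_identical(trim_linker(read, params)$insert,
                     brute_trim(read, linker, mm = 1L))
  }
})

test_that("trim_linker accepts a clipped linker via 3'-end partial overlap", {
  linker <- "ACGTACGTACGTACGTACGT"
  params <- profiler_params(linker = linker, min_post_trim_len = 1,
                            min_linker_overlap = 8)
  insert <- rand_seq(30)
  clipped <- paste0(insert, substr(linker, 1, 10))  # only 10 nt survive
  expect_equal(trim_linker(clipped, params)$insert, insert)
  too_short <- paste0(insert, substr(linker, 1, 5))
  expect_equal(trim_linker(too_short, params)$status, "NO_LINKER")
})

test_that("anchor rule: first base exact, one mismatch in the next 18", {
  ref <- make_reference(seed = 2)
  params <- profiler_params(linker = race_linker())
  anchor <- substr(ref$sequence, 1, 19)

  expect_true(match_anchor(paste0(anchor, "GGG"), ref, params))

  one_mm <- anchor
  substr(one_mm, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                    substr(anchor, 10, 10))[1]
  expect_true(match_anchor(paste0(one_mm, "GGG"), ref, params))

  two_mm <- one_mm
  substr(two_mm, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                    substr(anchor, 15, 15))[1]
  expect_false(match_anchor(paste0(two_mm, "GGG"), ref, params))

  first_mm <- anchor
  substr(first_mm, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                    substr(anchor, 1, 1))[1]
  expect_false(match_anchor(paste0(first_mm, "GGG"), ref, params))

  expect_false(match_anchor("ACGT", ref, params))  # shorter than the anchor
})

test_that("call_terminus reproduces the canonical terminus cases", {
  ref <- make_reference(seed = 2)  # first flank base is non-A
  params <- profiler_params(linker = race_linker())
  mature_prefix <- substr(ref$sequence, 1, ref$mature_end + 1)

  exact <- call_terminus(mature_prefix, ref, params)
  expect_equal(as.character(exact$status), "ASSIGNED")
  expect_equal(exact$end_offset, 0L)
  expect_equal(exact$tail_seq, "")
  expect_equal(as.character(exact$terminus_class), "GENOMIC")

  oligo <- call_terminus(paste0(mature_prefix, "AAAA"), ref, params)
  expect_equal(oligo$end_offset, 0L)
  expect_equal(oligo$tail_seq, "AAAA")
  expect_equal(as.character(oligo$terminus_class), "OLIGO_A")

  # mono(A) over an A-starting flank: template-maximal absorbs the A and
  # the call is flagged as possibly genomically encoded
  refA <- make_reference(seed = 2, post_mature_A = TRUE)
  monoA <- call_terminus(paste0(substr(refA$sequence, 1, refA$mature_end + 1),
                                "A"),
                         refA, params)
  expect_equal(monoA$end_offset, 1L)
  expect_equal(monoA$tail_seq, "")
  expect_equal(as.character(monoA$terminus_class), "MONO_A")
  expect_true(monoA$possibly_genomic_A)
})

test_that("boundary equals exhaustive split-point maximization", {
  set.seed(7)
  for (i in 1:150) {
    ref <- make_small_ref(seed = 1000 + i, len = sample(30:60, 1),
                          mature_at = 20, anchor = 5)
    budget <- sample(0:2, 1)
    params <- profiler_params(linker = race_linker(), anchor_len = 5,
                              anchor_max_mismatch = budget,
                              body_mismatch_budget = budget,
                              min_post_trim_len = 6)
    L <- sample(10:40, 1)
    insert <- substr(ref$sequence, 1, L)
    # mutate a few positions beyond the first base (anchor stays acceptable
    # because the budget is shared)
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      for (p in sample(2:L, min(nmut, L - 1))) {
        substr(insert, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                               substr(insert, p, p)), 1)
      }
    }
    call <- call_terminus(insert, ref, params)
    if (as.character(call$status) != "ASSIGNED") next
    k_impl <- call$end_offset + ref$mature_end + 1L
    expect_identical(k_impl, brute_boundary(insert, ref$sequence, budget))
    expect_equal(call$tail_seq,
                 substr(insert, k_impl + 1L, nchar(insert)))
  }
})

test_that("classify_terminus implements the decision table", {
  ref <- make_reference(seed = 2)  # first flank base non-A
  cls <- function(d, tail) as.character(classify_terminus(d, tail, ref))
  expect_equal(cls(-3L, ""), "GENOMIC")
  expect_equal(cls(0L, ""), "GENOMIC")
  expect_equal(cls(2L, ""), "GENOMIC")   # templated extension
  expect_equal(cls(0L, "A"), "MONO_A")
  expect_equal(cls(0L, "AA"), "OLIGO_A")
  expect_equal(cls(2L, "AAA"), "OLIGO_A")  # extended AND oligoadenylated
  expect_equal(cls(-4L, "AA"), "OLIGO_A")  # truncated AND oligoadenylated
  expect_equal(cls(0L, "AGA"), "OTHER_TAIL")
  expect_equal(cls(1L, "G"), "OTHER_TAIL")
  # d=+1 with empty tail over an A-starting flank is the flagged mono(A)
  refA <- make_reference(seed = 2, post_mature_A = TRUE)
  expect_equal(as.character(classify_terminus(1L, "", refA)), "MONO_A")
  expect_equal(as.character(classify_terminus(1L, "", ref)), "GENOMIC")
})

test_that("profile_termini aggregates counts, proportions, and statuses", {
  empty <- profile_termini(data.frame(
    status = character(0), end_offset = integer(0),
    terminus_class = character(0)
  ))
  expect_equal(empty$total_assigned, 0L)
  expect_equal(nrow(empty$counts), 0L)

  calls <- data.frame(
    status = c("ASSIGNED", "ASSIGNED", "ASSIGNED"),
    end_offset = c(0L, 0L, 0L),
    terminus_class = c("GENOMIC", "GENOMIC", "GENOMIC")
  )
  p <- profile_termini(calls)
  expect_equal(nrow(p$counts), 1L)
  expect_equal(p$counts$proportion, 1)
})

test_that("the pipeline conserves reads and its proportions sum to one", {
  ref <- make_reference(seed = 8)
  params <- profiler_params(linker = race_linker())
  sim <- simulate_race_reads(ref, truth_mix(error_rate = 0.01),
                             n_reads = 2000, seed = 3)
  res <- run_tail_pipeline(sim$reads, ref, params)
  p <- res$profile
  expect_equal(sum(p$status_counts), p$total_reads)
  expect_equal(p$total_reads, 2000L)
  expect_equal(unname(p$status_counts["ASSIGNED"]), p$total_assigned)
  expect_equal(p$total_trimmed,
               unname(sum(p$status_counts[c("ASSIGNED", "NO_ANCHOR",
                                            "AMBIGUOUS")])))
  expect_equal(sum(p$counts$proportion), 1, tolerance = 1e-9)
  expect_equal(sum(p$counts$count), p$total_assigned)
})

test_that("reads without any linker are all rejected as NO_LINKER", {
  ref <- make_reference(seed = 8)
  params <- profiler_params(linker = race_linker())
  set.seed(5)
  reads <- vapply(1:100, function(i) rand_seq(100), character(1))
  res <- run_tail_pipeline(reads, ref, params)
  expect_equal(res$profile$total_assigned, 0L)
  expect_equal(unname(res$profile$status_counts["NO_LINKER"]), 100L)
})

test_that("the pipeline is deterministic over repeated runs", {
  ref <- make_reference(seed = 9)
  params <- profiler_params(linker = race_linker())
  sim <- simulate_race_reads(ref, truth_mix(), n_reads = 300, seed = 4)
  expect_identical(run_tail_pipeline(sim$reads, ref, params)$calls,
                   run_tail_pipeline(sim$reads, ref, params)$calls)
})

test_that("extending the reference flank does not change interior calls", {
  ref <- make_reference(seed = 10)
  params <- profiler_params(linker = race_linker())
  sim <- simulate_race_reads(ref, truth_mix(), n_reads = 400, seed = 5)
  res1 <- run_tail_pipeline(sim$reads, ref, params)
  ref_ext <- reference_locus(paste0(ref$sequence, rand_seq(50)),
                             mature_end = ref$mature_end,
                             anchor_len = ref$anchor_len)
  res2 <- run_tail_pipeline(sim$reads, ref_ext, params)
  expect_identical(res1$calls, res2$calls)
})

test_that("the per-read and profile TSV outputs are written and readable", {
  ref <- make_reference(seed = 11)
  params <- profiler_params(linker = race_linker())
  sim <- simulate_race_reads(ref, truth_mix(), n_reads = 50, seed = 6)
  prefix <- tempfile()
  res <- run_tail_pipeline(sim$reads, ref, params, out_prefix = prefix)
  calls <- read.delim(paste0(prefix, "_calls.tsv"))
  prof <- read.delim(paste0(prefix, "_profile.tsv"))
  expect_equal(nrow(calls), 50L)
  expect_equal(sum(prof$count), res$profile$total_assigned)
  unlink(paste0(prefix, c("_calls.tsv", "_profile.tsv")))
})
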
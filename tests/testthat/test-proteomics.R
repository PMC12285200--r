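mini_table <- function(ibaq, peptides = NULL) {
  n <- nrow(ibaq)
  if (is.null(peptides)) peptides <- rep(5L, n)
  protein_quant_table(
    data.frame(protein_id = sprintf("P%02d", seq_len(n)),
               gene_symbol = sprintf("G%02d", seq_len(n)),
               unique_peptides = peptides),
    ibaq,
    setNames(ifelse(grepl("^BAIT", colnames(ibaq)), "BAIT", "CONTROL"),
             colnames(ibaq))
  )
}

mk_ibaq <- function(bait, ctrl) {
  m <- cbind(bait, ctrl)
  colnames(m) <- c(paste0("BAIT_", seq_len(ncol(bait))),
                   paste0("CTRL_", seq_len(ncol(ctrl))))
  m
}

test_that("unique-peptide filter removes below-threshold proteins only", {
  tab <- mini_table(mk_ibaq(matrix(1, 3, 2), matrix(1, 3, 2)),
                    peptides = c(1L, 2L, 7L))
  f <- filter_unique_peptides(tab, min_peptides = 2)
  expect_equal(f$table$proteins$protein_id, c("P02", "P03"))
  expect_equal(f$filtered$protein_id, "P01")
  expect_equal(unique(f$filtered$status), "FILTERED_PEPTIDES")

  f2 <- filter_unique_peptides(f$table, min_peptides = 2)  # idempotent
  expect_equal(nrow(f2$filtered), 0L)
})

test_that("FOT normalisation divides by the within-replicate total", {
  one <- mini_table(mk_ibaq(matrix(7, 1, 2), matrix(7, 1, 2)))
  expect_equal(unname(compute_fot(one)$fot[1, ]), rep(1, 4))

  two <- mini_table(mk_ibaq(matrix(c(3, 1), 2, 2), matrix(c(3, 1), 2, 2)))
  expect_equal(unname(compute_fot(two)$fot[, 1]), c(0.75, 0.25))

  set.seed(1)
  big <- mini_table(mk_ibaq(matrix(rlnorm(150), 50, 3),
                            matrix(rlnorm(150), 50, 3)))
  sums <- colSums(compute_fot(big)$fot)
  expect_equal(unname(sums), rep(1, 6), tolerance = 1e-9)

  zero <- mini_table(mk_ibaq(matrix(c(1, 1, 0, 0), 2, 2),
                             matrix(1, 2, 2)))
  expect_error(compute_fot(zero), "BAIT_2")
})

test_that("fold changes and correlations are invariant to global scaling", {
  set.seed(2)
  ib <- mk_ibaq(matrix(rlnorm(60, 10, 1), 20, 3),
                matrix(rlnorm(60, 10, 1), 20, 3))
  tab <- mini_table(ib)
  ib_scaled <- ib
  ib_scaled[, 2] <- ib_scaled[, 2] * 2   # double one replicate's depth
  ib_scaled[, 5] <- ib_scaled[, 5] * 10
  tab_s <- mini_table(ib_scaled)

  e1 <- enrichment_test(tab)
  e2 <- enrichment_test(tab_s)
  expect_equal(e2$fold_change, e1$fold_change)
  expect_equal(e2$p_value, e1$p_value)

  cc <- replicate_correlation(mini_table(mk_ibaq(
    cbind(ib[, 1], ib[, 1] * 2, ib[, 2]), ib[, 4:6]
  )))
  expect_equal(unname(cc["BAIT_1", "BAIT_2"]), 1)  # scaled copy
  expect_equal(unname(diag(cc)), rep(1, 6))
  expect_true(all(cc >= -1 & cc <= 1))
})

test_that("replicate correlation flags zero-variance columns as NA", {
  ib <- mk_ibaq(matrix(c(rep(1, 4), 1:4), 4, 2), matrix(rlnorm(8), 4, 2))
  expect_warning(cc <- replicate_correlation(mini_table(ib)), "BAIT_1")
  expect_true(all(is.na(cc["BAIT_1", colnames(cc) != "BAIT_1"])))
  expect_equal(unname(cc["BAIT_1", "BAIT_1"]), 1)
})

test_that("simulated triplicates at cv 0.2 correlate tightly", {
  cors <- vapply(1:5, function(s) {
    tab <- simulate_proteomics(n_background = 200, n_enriched = 0,
                               cv = 0.2, n_reps = 3, seed = s)$table
    cc <- replicate_correlation(tab)
    median(cc[upper.tri(cc)])
  }, numeric(1))
  expect_true(all(cors >= 0.9))
})

test_that("enrichment_test handles degenerate and pseudocount cases", {
  # identical bait and control values: fold 1, not significant
  ib <- mk_ibaq(matrix(c(5, 1, 3), 3, 3), matrix(c(5, 1, 3), 3, 3))
  e <- enrichment_test(mini_table(ib))
  expect_equal(e$fold_change, rep(1, 3))
  expect_equal(as.character(e$status), rep("NOT_SIGNIFICANT", 3))
  expect_equal(e$p_value, rep(1, 3))

  # control all-zero: the pseudocount keeps the ratio finite; check the
  # arithmetic by hand on a 2-protein table
  ib2 <- mk_ibaq(matrix(c(3, 1, 3, 1, 3, 1), 2, 3),
                 matrix(c(0, 1, 0, 1, 0, 1), 2, 3))
  tab2 <- compute_fot(mini_table(ib2))
  # FOT: bait rows (0.75, 0.25); control rows (0, 1); min nonzero FOT = 0.25
  eps <- 0.25 / 2
  e2 <- enrichment_test(tab2)
  expect_equal(e2$fold_change[1], (0.75 + eps) / (0 + eps))
  expect_equal(e2$fold_change[2], (0.25 + eps) / (1 + eps))
  expect_true(is.finite(e2$p_value[1]))
})

test_that("peptide-poor proteins are labelled, not silently dropped", {
  ib <- mk_ibaq(matrix(c(80, 1), 2, 3), matrix(c(1, 1), 2, 3))
  e <- enrichment_test(mini_table(ib, peptides = c(1L, 5L)))
  expect_equal(as.character(e$status[1]), "FILTERED_PEPTIDES")
  expect_equal(nrow(e), 2L)
})

test_that("tightening thresholds never adds enriched proteins", {
  sim <- simulate_proteomics(n_background = 150, n_enriched = 15, fold = 4,
                             cv = 0.3, n_reps = 3, seed = 42)
  base <- enrichment_test(sim$table, fc_threshold = 2, alpha = 0.1)
  hits <- function(e) e$protein_id[e$status == "ENRICHED"]
  for (fc in c(3, 5, 8)) {
    expect_true(all(hits(enrichment_test(sim$table, fc_threshold = fc,
                                         alpha = 0.1)) %in% hits(base)))
  }
  for (a in c(0.05, 0.01)) {
    expect_true(all(hits(enrichment_test(sim$table, fc_threshold = 2,
                                         alpha = a)) %in% hits(base)))
  }
})

test_that("the screen recovers planted 8-fold proteins", {
  sim <- simulate_proteomics(n_background = 300, n_enriched = 30, fold = 8,
                             cv = 0.2, n_reps = 3, seed = 7)
  e <- enrichment_test(sim$table, fc_threshold = 3, alpha = 0.05)
  hits <- e$protein_id[e$status == "ENRICHED"]
  expect_gte(mean(sim$truth %in% hits), 0.9)
  fdr <- if (length(hits)) mean(!(hits %in% sim$truth)) else 0
  expect_lte(fdr, 0.1)
})

test_that("export_enrichment writes volcano and restricted network tables", {
  set.seed(99)
  ib <- mk_ibaq(matrix(c(50, 50, rep(1, 8)), 10, 3) *
                  matrix(rlnorm(30, 0, .05), 10),
                matrix(1, 10, 3) * matrix(rlnorm(30, 0, .05), 10))
  e <- enrichment_test(mini_table(ib))
  enriched <- e$protein_id[e$status == "ENRICHED"]
  expect_true(all(c("P01", "P02") %in% enriched))

  v <- export_enrichment(e)
  expect_named(v, "volcano")
  expect_equal(v$volcano$log2_fold_change, log2(e$fold_change))

  edges <- data.frame(source = c("P01", "P01", "P03", "P01"),
                      target = c("P02", "P03", "P04", "P01"))
  out <- export_enrichment(e, interactions = edges)
  expect_equal(nrow(out$edges), 1L)           # only the both-enriched pair
  expect_equal(out$edges$target[1], "P02")    # P03 edge and self-edge gone
  expect_true(all(out$nodes$protein_id %in% enriched))

  expect_warning(
    export_enrichment(e, interactions = data.frame(source = "P01",
                                                   target = "NOPE")),
    "unknown"
  )

  prefix <- tempfile()
  export_enrichment(e, interactions = edges, path_prefix = prefix)
  expect_true(all(file.exists(paste0(prefix, c("_volcano.tsv", "_nodes.tsv",
                                               "_edges.tsv")))))
  unlink(paste0(prefix, c("_volcano.tsv", "_nodes.tsv", "_edges.tsv")))
})

test_that("quant tables round-trip through TSV with group inference", {
  sim <- simulate_proteomics(n_background = 20, n_enriched = 5, seed = 3)
  df <- data.frame(sim$table$proteins, sim$table$ibaq, check.names = FALSE)
  tf <- tempfile(fileext = ".tsv")
  write_tsv(df, tf)
  tab <- read_quant_table(tf)
  expect_equal(tab$ibaq, sim$table$ibaq)
  expect_equal(tab$groups, sim$table$groups)
  unlink(tf)
})
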
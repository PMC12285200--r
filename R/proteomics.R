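PROT_GROUPS <- c("BAIT", "CONTROL")

#' Protein quantification table for proximity-labeling proteomics
#'
#' Container for label-free quantification of a streptavidin capture
#' experiment: per-protein unique peptide counts and an iBAQ intensity
#' matrix over replicates, with each replicate assigned to the bait fusion
#' group or the background control group.
#'
#' @param proteins data.frame with columns `protein_id`, `gene_symbol`,
#'   `unique_peptides`.
#' @param ibaq Numeric matrix (proteins x replicates), non-negative; row
#'   order matches `proteins`, column names are replicate ids.
#' @param groups Named character vector mapping every replicate id to
#'   `"BAIT"` or `"CONTROL"`; at least 2 replicates per group.
#' @return An object of class `protein_quant_table`.
#' @export
protein_quant_table <- function(proteins, ibaq, groups) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "gene_symbol", "unique_peptides") %in%
                  names(proteins)),
            is.matrix(ibaq), is.numeric(ibaq))
  if (nrow(ibaq) != nrow(proteins)) {
    stop("ibaq must have one row per protein")
  }
  if (any(ibaq < 0)) stop("iBAQ intensities must be non-negative")
  if (is.null(colnames(ibaq))) stop("ibaq must have replicate column names")
  if (anyDuplicated(proteins$protein_id)) stop("duplicate protein_id")
  groups <- vapply(groups, as.character, character(1L))
  if (!setequal(names(groups), colnames(ibaq))) {
    stop("groups must name exactly the ibaq replicate columns")
  }
  if (!all(groups %in% PROT_GROUPS)) {
    stop("groups must be 'BAIT' or 'CONTROL'")
  }
  if (any(table(factor(groups, PROT_GROUPS)) < 2L)) {
    stop("at least 2 replicates per group are required")
  }
  rownames(ibaq) <- proteins$protein_id
  structure(
    list(proteins = proteins, ibaq = ibaq,
         groups = groups[colnames(ibaq)], fot = NULL),
    class = "protein_quant_table"
  )
}

#' @export
print.protein_quant_table <- function(x, ...) {
  cat(sprintf(
    "<protein_quant_table> %d proteins x %d replicates (%d bait, %d control)%s\n",
    nrow(x$proteins), ncol(x$ibaq), sum(x$groups == "BAIT"),
    sum(x$groups == "CONTROL"),
    if (is.null(x$fot)) "" else "; FOT computed"
  ))
  invisible(x)
}

#' Read a protein quantification table from TSV/CSV
#'
#' Expects columns `protein_id`, `gene_symbol`, `unique_peptides`, followed
#' by one iBAQ column per replicate. Group assignment follows the column
#' name convention `BAIT_*` / `CTRL_*` (case-insensitive) unless an explicit
#' `groups` vector is given.
#'
#' @param path TSV (default) or CSV file.
#' @param groups Optional named character vector replicate -> group.
#' @param sep Field separator (default tab).
#' @return A [protein_quant_table()].
#' @export
read_quant_table <- function(path, groups = NULL, sep = "\t") {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta_cols <- c("protein_id", "gene_symbol", "unique_peptides")
  if (!all(meta_cols %in% names(df))) {
    stop("quant table must have columns ", paste(meta_cols, collapse = ", "))
  }
  rep_cols <- setdiff(names(df), meta_cols)
  ibaq <- as.matrix(df[rep_cols])
  if (is.null(groups)) {
    groups <- ifelse(grepl("^bait", rep_cols, ignore.case = TRUE), "BAIT",
                     ifelse(grepl("^(ctrl|control)", rep_cols,
                                  ignore.case = TRUE), "CONTROL", NA))
    if (anyNA(groups)) {
      stop("cannot infer groups from column names; pass `groups`")
    }
    names(groups) <- rep_cols
  }
  protein_quant_table(df[meta_cols], ibaq, groups)
}

#' Filter proteins on unique peptide support
#'
#' Retains proteins identified by at least `min_peptides` unique peptides
#' and reports the removed ones, the first screening step applied to the
#' quantification table.
#'
#' @param table A [protein_quant_table()].
#' @param min_peptides Minimum unique peptides (default 2; the boundary is
#'   inclusive).
#' @return A list with `table` (filtered) and `filtered` (data.frame
#'   `protein_id`, `unique_peptides`, `status = "FILTERED_PEPTIDES"`).
#' @export
filter_unique_peptides <- function(table, min_peptides = 2L) {
  stopifnot(is(table, "protein_quant_table"))
  keep <- table$proteins$unique_peptides >= min_peptides
  filtered <- data.frame(
    protein_id = table$proteins$protein_id[!keep],
    unique_peptides = table$proteins$unique_peptides[!keep],
    status = rep("FILTERED_PEPTIDES", sum(!keep)),
    stringsAsFactors = FALSE
  )
  out <- table
  out$proteins <- table$proteins[keep, , drop = FALSE]
  rownames(out$proteins) <- NULL
  out$ibaq <- table$ibaq[keep, , drop = FALSE]
  if (!is.null(table$fot)) out$fot <- table$fot[keep, , drop = FALSE]
  list(table = out, filtered = filtered)
}

#' Compute FOT (fraction of total) normalisation
#'
#' Within each replicate, every protein's iBAQ value is divided by that
#' replicate's iBAQ total, so each column of the resulting FOT matrix sums
#' to 1. This removes per-sample loading/depth differences before fold
#' changes and correlations are computed.
#'
#' @param table A [protein_quant_table()].
#' @return The table with a `fot` matrix filled in.
#' @export
compute_fot <- function(table) {
  stopifnot(is(table, "protein_quant_table"))
  totals <- colSums(table$ibaq)
  if (any(totals == 0)) {
    stop("replicate(s) with all-zero iBAQ: ",
         paste(colnames(table$ibaq)[totals == 0], collapse = ", "))
  }
  table$fot <- sweep(table$ibaq, 2L, totals, "/")
  table
}

#' Replicate-by-replicate Pearson correlation
#'
#' Quality control for the quantification: pairwise Pearson correlation of
#' log-transformed FOT values (a pseudocount keeps zeros finite). A
#' zero-variance replicate yields NA entries and a warning rather than a
#' silent 0.
#'
#' @param table A [protein_quant_table()] (FOT is computed if absent).
#' @param log Correlate log10(FOT + pseudocount) (default) or raw FOT.
#' @param pseudocount Added before the log; default half the smallest
#'   nonzero FOT.
#' @return Symmetric replicate x replicate correlation matrix with unit
#'   diagonal.
#' @export
replicate_correlation <- function(table, log = TRUE, pseudocount = NULL) {
  stopifnot(is(table, "protein_quant_table"))
  if (nrow(table$proteins) < 2L) stop("need at least 2 proteins")
  if (is.null(table$fot)) table <- compute_fot(table)
  m <- table$fot
  if (log) {
    if (is.null(pseudocount)) pseudocount <- .default_pseudocount(m)
    m <- log10(m + pseudocount)
  }
  zero_var <- apply(m, 2L, sd) == 0
  if (any(zero_var)) {
    warning("zero-variance replicate(s): ",
            paste(colnames(m)[zero_var], collapse = ", "),
            "; correlations set to NA")
  }
  cc <- suppressWarnings(cor(m, method = "pearson"))
  cc[zero_var, ] <- NA_real_
  cc[, zero_var] <- NA_real_
  diag(cc) <- 1
  cc
}

# half the smallest nonzero FOT in the matrix; keeps ratios finite while
# staying below every observed signal
.default_pseudocount <- function(fot) {
  nz <- fot[fot > 0]
  if (length(nz) == 0L) stop("all FOT values are zero")
  min(nz) / 2
}

#' Fold-change / t-test enrichment screen
#'
#' The headline screen for bait-proximal proteins: per protein, the fold
#' change is the ratio of pseudocounted group-mean FOT (bait over control),
#' and the p-value comes from a two-tailed unpaired t-test on
#' log10(FOT + pseudocount) across replicates (Student's equal-variance
#' flavour by default; set `var_equal = FALSE` for Welch). A protein is
#' `ENRICHED` when the fold change reaches `fc_threshold`, the p-value is at
#' most `alpha`, and it carries at least `min_peptides` unique peptides;
#' proteins failing only the peptide filter are labelled
#' `FILTERED_PEPTIDES`, everything else `NOT_SIGNIFICANT`. No multiple
#' testing correction is applied to the screen itself; BH-adjusted q-values
#' are reported alongside for transparency.
#'
#' @param table A [protein_quant_table()] (FOT is computed if absent).
#' @param fc_threshold Minimum bait/control fold change (default 3).
#' @param alpha Significance level (default 0.05).
#' @param pseudocount Added to FOT means and before logs; default half the
#'   smallest nonzero FOT (proteins absent from a group are retained through
#'   this path, never dropped).
#' @param min_peptides Unique-peptide filter (default 2).
#' @param var_equal Student (TRUE, default) or Welch (FALSE) t-test.
#' @return data.frame with one row per protein: `protein_id`,
#'   `gene_symbol`, `unique_peptides`, `fot_bait_mean`, `fot_ctrl_mean`,
#'   `fold_change`, `p_value`, `q_value`, `status`.
#' @export
enrichment_test <- function(table, fc_threshold = 3, alpha = 0.05,
                            pseudocount = NULL, min_peptides = 2L,
                            var_equal = TRUE) {
  stopifnot(is(table, "protein_quant_table"))
  if (is.null(table$fot)) table <- compute_fot(table)
  bait <- table$fot[, table$groups == "BAIT", drop = FALSE]
  ctrl <- table$fot[, table$groups == "CONTROL", drop = FALSE]
  if (ncol(bait) < 2L || ncol(ctrl) < 2L) {
    stop("need at least 2 replicates per group")
  }
  if (is.null(pseudocount)) pseudocount <- .default_pseudocount(table$fot)

  bait_mean <- rowMeans(bait)
  ctrl_mean <- rowMeans(ctrl)
  fc <- (bait_mean + pseudocount) / (ctrl_mean + pseudocount)
  lb <- log10(bait + pseudocount)
  lc <- log10(ctrl + pseudocount)
  p <- vapply(seq_len(nrow(lb)), function(i) {
    .t_test_p(lb[i, ], lc[i, ], var_equal = var_equal)
  }, numeric(1L))
  q <- p.adjust(p, method = "BH")

  peptide_ok <- table$proteins$unique_peptides >= min_peptides
  hit <- fc >= fc_threshold & p <= alpha
  status <- ifelse(!peptide_ok, "FILTERED_PEPTIDES",
                   ifelse(hit, "ENRICHED", "NOT_SIGNIFICANT"))
  data.frame(
    protein_id = table$proteins$protein_id,
    gene_symbol = table$proteins$gene_symbol,
    unique_peptides = table$proteins$unique_peptides,
    fot_bait_mean = bait_mean,
    fot_ctrl_mean = ctrl_mean,
    fold_change = fc,
    p_value = p,
    q_value = q,
    status = factor(status, levels = c("ENRICHED", "NOT_SIGNIFICANT",
                                       "FILTERED_PEPTIDES")),
    stringsAsFactors = FALSE
  )
}

#' Export enrichment results as volcano and network tables
#'
#' Produces the volcano-plot table (log2 fold change, -log10 p, status) and,
#' when a user-supplied interaction edge list is given, node and edge tables
#' restricted to enriched proteins (both endpoints must be enriched;
#' self-edges and edges naming unknown proteins are dropped, the latter with
#' a warning). Network retrieval and rendering are left to external tools —
#' these tables are their input.
#'
#' @param records Result of [enrichment_test()].
#' @param interactions Optional data.frame with columns `source`, `target`.
#' @param path_prefix Optional path prefix; writes
#'   `<prefix>_volcano.tsv` and, with interactions, `<prefix>_nodes.tsv` and
#'   `<prefix>_edges.tsv`.
#' @return A list with `volcano` and (when interactions are given) `nodes`
#'   and `edges` data.frames, invisibly when written to disk.
#' @export
export_enrichment <- function(records, interactions = NULL,
                              path_prefix = NULL) {
  stopifnot(is.data.frame(records),
            all(c("protein_id", "fold_change", "p_value", "status") %in%
                  names(records)))
  volcano <- data.frame(
    protein_id = records$protein_id,
    log2_fold_change = log2(records$fold_change),
    neg_log10_p = -log10(pmax(records$p_value, .Machine$double.xmin)),
    status = records$status,
    stringsAsFactors = FALSE
  )
  out <- list(volcano = volcano)

  if (!is.null(interactions)) {
    stopifnot(all(c("source", "target") %in% names(interactions)))
    known <- records$protein_id
    bad <- !(interactions$source %in% known & interactions$target %in% known)
    if (any(bad)) {
      warning(sum(bad), " edge(s) referencing unknown proteins dropped")
      interactions <- interactions[!bad, , drop = FALSE]
    }
    interactions <- interactions[interactions$source != interactions$target,
                                 , drop = FALSE]
    enriched <- records$protein_id[records$status == "ENRICHED"]
    edges <- interactions[interactions$source %in% enriched &
                            interactions$target %in% enriched, , drop = FALSE]
    rownames(edges) <- NULL
    nodes <- records[records$status == "ENRICHED",
                     c("protein_id", "gene_symbol", "fold_change", "p_value"),
                     drop = FALSE]
    rownames(nodes) <- NULL
    out$nodes <- nodes
    out$edges <- edges
  }

  if (!is.null(path_prefix)) {
    write_tsv(out$volcano, paste0(path_prefix, "_volcano.tsv"))
    if (!is.null(out$nodes)) {
      write_tsv(out$nodes, paste0(path_prefix, "_nodes.tsv"))
      write_tsv(out$edges, paste0(path_prefix, "_edges.tsv"))
    }
    return(invisible(out))
  }
  out
}

#' Simulate a proximity-labeling quantification table with planted hits
#'
#' Generates a log-normal iBAQ matrix over bait and control replicates with
#' `n_enriched` planted bait-enriched proteins whose bait-group mean is
#' `fold` times their control mean. Replicate noise is log-normal with
#' coefficient of variation `cv` (means preserved, so in the noise-free
#' limit every planted ratio equals `fold` exactly). A configurable fraction
#' of background proteins carries a single unique peptide, exercising the
#' peptide filter; planted proteins always carry at least two, reflecting
#' the good coverage of genuinely bait-proximal preys. Missing detection is
#' simulated by zeroing individual iBAQ entries with probability `dropout`.
#'
#' @param n_background,n_enriched Protein counts (truth list names the
#'   enriched ones).
#' @param fold Planted bait/control ratio (> 1).
#' @param cv Replicate coefficient of variation (> 0 unless exactly 0 for
#'   the noise-free limit).
#' @param n_reps Replicates per group (>= 2).
#' @param seed Integer seed.
#' @param low_peptide_frac Fraction of background proteins given a single
#'   unique peptide (default 0.1).
#' @param dropout Per-entry probability of a missing (zero) iBAQ value.
#' @param base_meanlog,base_sdlog Log-normal parameters of the protein
#'   abundance distribution (defaults centre iBAQ near 1e6 with ~1.5 logs of
#'   spread, the range a label-free experiment typically spans).
#' @return A list with `table` (a [protein_quant_table()]) and `truth`
#'   (character vector of planted enriched protein ids).
#' @export
simulate_proteomics <- function(n_background = 300L, n_enriched = 30L,
                                fold = 8, cv = 0.2, n_reps = 3L, seed = 1L,
                                low_peptide_frac = 0.1, dropout = 0,
                                base_meanlog = log(1e6), base_sdlog = 1.5) {
  if (n_reps < 2L) stop("n_reps must be >= 2")
  if (n_enriched > 0L && fold <= 1) stop("fold must be > 1")
  if (cv < 0) stop("cv must be >= 0")
  set.seed(as.integer(seed))
  n <- n_background + n_enriched
  ids <- c(sprintf("BG_%04d", seq_len(n_background)),
           if (n_enriched > 0L) sprintf("ENR_%04d", seq_len(n_enriched)))
  enriched <- grepl("^ENR_", ids)

  abundance <- rlnorm(n, meanlog = base_meanlog, sdlog = base_sdlog)
  ctrl_mean <- abundance
  bait_mean <- abundance * ifelse(enriched, fold, 1)

  sdlog_noise <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  noise <- function(mu) {
    if (sdlog_noise == 0) return(mu)  # exact means in the noise-free limit
    mu * rlnorm(length(mu), meanlog = -sdlog_noise^2 / 2, sdlog = sdlog_noise)
  }
  bait <- vapply(seq_len(n_reps), function(r) noise(bait_mean), numeric(n))
  ctrl <- vapply(seq_len(n_reps), function(r) noise(ctrl_mean), numeric(n))
  ibaq <- cbind(bait, ctrl)
  colnames(ibaq) <- c(sprintf("BAIT_%d", seq_len(n_reps)),
                      sprintf("CTRL_%d", seq_len(n_reps)))
  if (dropout > 0) {
    drop_mask <- matrix(runif(length(ibaq)) < dropout, nrow = n)
    ibaq[drop_mask] <- 0
  }

  peptides <- 2L + rpois(n, 4L)
  low <- !enriched & runif(n) < low_peptide_frac
  peptides[low] <- 1L

  proteins <- data.frame(protein_id = ids, gene_symbol = ids,
                         unique_peptides = peptides,
                         stringsAsFactors = FALSE)
  groups <- setNames(rep(c("BAIT", "CONTROL"), each = n_reps),
                     colnames(ibaq))
  list(table = protein_quant_table(proteins, ibaq, groups),
       truth = ids[enriched])
}
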
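#' Parameters for 3' RACE tail profiling
#'
#' Bundles the matching policy used throughout the tail profiler. Reads are
#' accepted when they match the reference at the very first base exactly and
#' at the following `anchor_len - 1` bases with at most `anchor_max_mismatch`
#' substitutions, with no insertions or deletions anywhere. The same
#' substitutions-only policy governs boundary calling: by default the anchor
#' allowance and the body allowance are a single shared budget of
#' `body_mismatch_budget` mismatches over the whole templated prefix.
#'
#' @param linker Ligated 3' linker sequence (non-empty, A/C/G/T).
#' @param anchor_len Anchor length in nt (default 19: first base + next 18).
#' @param anchor_max_mismatch Substitutions allowed in anchor positions
#'   2..`anchor_len` (default 1).
#' @param first_base_exact Must the first base match exactly? (default TRUE).
#' @param linker_max_mismatch Substitutions allowed in a full-length linker
#'   window (default 1).
#' @param min_linker_overlap Minimum accepted 3'-end partial overlap of the
#'   linker, in nt (default 8). Partial overlaps get a proportional mismatch
#'   allowance `floor(linker_max_mismatch * overlap / nchar(linker))`.
#' @param min_post_trim_len Minimum insert length after trimming; shorter
#'   inserts are rejected and counted (default `anchor_len + 1`).
#' @param body_mismatch_budget Total substitution budget for the templated
#'   prefix (default 1). Scale with the expected error rate via
#'   [mismatch_budget_for()].
#' @param shared_budget If TRUE (default) the budget covers the whole read
#'   including the anchor; if FALSE the anchor allowance is separate and
#'   `body_mismatch_budget` applies only beyond the anchor.
#' @param d_max_truncation,e_max_extension Reporting bounds (nt) for
#'   truncations below and templated extensions beyond the mature end; calls
#'   outside are still made, these document the expected offset window.
#' @return An object of class `profiler_params`.
#' @export
profiler_params <- function(linker,
                            anchor_len = 19L,
                            anchor_max_mismatch = 1L,
                            first_base_exact = TRUE,
                            linker_max_mismatch = 1L,
                            min_linker_overlap = 8L,
                            min_post_trim_len = anchor_len + 1L,
                            body_mismatch_budget = 1L,
                            shared_budget = TRUE,
                            d_max_truncation = 50L,
                            e_max_extension = 50L) {
  stopifnot(is.character(linker), length(linker) == 1L)
  linker <- toupper(linker)
  if (nchar(linker) == 0L || !.is_dna(linker)) {
    stop("linker must be a non-empty string over {A,C,G,T}")
  }
  if (anchor_max_mismatch < 0L) stop("anchor_max_mismatch must be >= 0")
  if (linker_max_mismatch < 0L) stop("linker_max_mismatch must be >= 0")
  if (body_mismatch_budget < 0L) stop("body_mismatch_budget must be >= 0")
  if (min_linker_overlap < 1L) stop("min_linker_overlap must be >= 1")
  structure(
    list(
      linker = linker,
      anchor_len = as.integer(anchor_len),
      anchor_max_mismatch = as.integer(anchor_max_mismatch),
      first_base_exact = isTRUE(first_base_exact),
      linker_max_mismatch = as.integer(linker_max_mismatch),
      min_linker_overlap = as.integer(min_linker_overlap),
      min_post_trim_len = as.integer(min_post_trim_len),
      body_mismatch_budget = as.integer(body_mismatch_budget),
      shared_budget = isTRUE(shared_budget),
      d_max_truncation = as.integer(d_max_truncation),
      e_max_extension = as.integer(e_max_extension)
    ),
    class = "profiler_params"
  )
}

TERMINUS_CLASSES <- c("GENOMIC", "MONO_A", "OLIGO_A", "OTHER_TAIL")
CALL_STATUSES <- c("ASSIGNED", "NO_ANCHOR", "NO_LINKER", "TOO_SHORT",
                   "AMBIGUOUS")

#' Trim the ligated 3' linker from a read
#'
#' Locates the leftmost acceptable occurrence of the linker — a full-length
#' window at Hamming distance at most `linker_max_mismatch` — and returns the
#' read prefix before it (the biological insert precedes the ligated linker,
#' so the leftmost acceptable occurrence wins even if an untemplated tail
#' coincidentally resembles the linker further right). When no full window is
#' acceptable, a partial 3'-end overlap is considered: a read suffix matching
#' a linker prefix of at least `min_linker_overlap` nt, at a proportionally
#' scaled mismatch allowance, with the longest acceptable overlap (leftmost
#' cut) winning.
#'
#' @param read_seq A single read sequence (non-empty).
#' @param params A [profiler_params()].
#' @return A list with `insert` (the trimmed insert, or `NA` when rejected)
#'   and `status`: `"OK"`, `"NO_LINKER"`, or `"TOO_SHORT"` (linker found but
#'   the insert is shorter than `min_post_trim_len`).
#' @export
trim_linker <- function(read_seq, params) {
  stopifnot(is(params, "profiler_params"))
  if (!is.character(read_seq) || length(read_seq) != 1L ||
      is.na(read_seq) || nchar(read_seq) == 0L) {
    stop("read_seq must be a single non-empty string")
  }
  res <- .trim_linker_batch(read_seq, params)
  list(insert = res$insert[[1L]], status = res$status[[1L]])
}

# Vectorised linker trimming. Full-length windows are located with
# Biostrings::vmatchPattern (substitutions only); partial 3' overlaps are
# checked for the minority of reads with no full-length hit.
.trim_linker_batch <- function(reads, params) {
  n <- length(reads)
  llen <- nchar(params$linker)
  cut <- rep(NA_integer_, n)  # 0-based insert length == cut position

  searchable <- nchar(reads) >= llen
  if (any(searchable)) {
    mi <- Biostrings::vmatchPattern(
      params$linker, Biostrings::DNAStringSet(reads[searchable]),
      max.mismatch = params$linker_max_mismatch, with.indels = FALSE,
      fixed = TRUE
    )
    starts <- Biostrings::startIndex(mi)
    first <- vapply(starts, function(s) {
      s <- s[s >= 1L]
      if (length(s)) min(s) else NA_integer_
    }, integer(1L))
    cut[searchable] <- first - 1L
  }

  # partial 3'-end overlap for reads without a full-length hit
  miss <- which(is.na(cut))
  for (i in miss) {
    rd <- reads[[i]]
    nl <- nchar(rd)
    max_ov <- min(llen - 1L, nl)
    if (max_ov < params$min_linker_overlap) next
    for (ov in seq(max_ov, params$min_linker_overlap)) {
      allow <- floor(params$linker_max_mismatch * ov / llen)
      if (.hamming(substr(rd, nl - ov + 1L, nl),
                   substr(params$linker, 1L, ov)) <= allow) {
        cut[i] <- nl - ov
        break
      }
    }
  }

  status <- ifelse(is.na(cut), "NO_LINKER",
                   ifelse(cut < params$min_post_trim_len, "TOO_SHORT", "OK"))
  insert <- ifelse(status == "OK", substr(reads, 1L, pmax(cut, 0L)),
                   NA_character_)
  list(insert = insert, status = status)
}

#' Test whether an insert is anchored at the reference 5' start
#'
#' The read acceptance rule: the first base must equal the first reference
#' base exactly (when `first_base_exact`), and the following
#' `anchor_len - 1` bases may differ by at most `anchor_max_mismatch`
#' substitutions, gapless. Inserts shorter than the anchor fail (a signal,
#' not an error).
#'
#' @param insert_seq Trimmed insert sequence.
#' @param ref A [reference_locus()].
#' @param params A [profiler_params()].
#' @return TRUE when the anchor is accepted.
#' @export
match_anchor <- function(insert_seq, ref, params) {
  stopifnot(is(ref, "reference_locus"), is(params, "profiler_params"))
  al <- params$anchor_len
  if (is.na(insert_seq) || nchar(insert_seq) < al) return(FALSE)
  x <- charToRaw(substr(insert_seq, 1L, al))
  r <- charToRaw(substr(ref$sequence, 1L, al))
  mm <- x != r
  if (params$first_base_exact && mm[1L]) return(FALSE)
  sum(mm[-1L]) <= params$anchor_max_mismatch
}

# Core per-insert boundary caller shared by call_terminus() and the batch
# pipeline. Returns a data.frame over the inserts.
#
# Boundary rule: the templated prefix is the largest k such that
# insert[1..k] aligns gaplessly to ref[1..k] with at most `budget`
# substitutions AND position k itself matches. Requiring the segment to end
# on a match keeps the boundary identifiable: otherwise the budget would
# absorb leading tail bases as "templated with mismatch" and untemplated
# tails over a non-matching flank would be swallowed.
.call_inserts <- function(inserts, ref, params) {
  n <- length(inserts)
  ref_raw <- charToRaw(ref$sequence)
  nref <- length(ref_raw)
  mature_pos <- ref$mature_end + 1L  # 1-based position of last mature base
  al <- params$anchor_len

  status <- rep("ASSIGNED", n)
  k_out <- rep(NA_integer_, n)
  tail_out <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    ins <- inserts[[i]]
    if (is.na(ins) || nchar(ins) < al) {
      status[i] <- "NO_ANCHOR"
      next
    }
    xr <- charToRaw(ins)
    L <- length(xr)
    M <- min(L, nref)
    mm <- xr[seq_len(M)] != ref_raw[seq_len(M)]
    if (params$first_base_exact && mm[1L]) {
      status[i] <- "NO_ANCHOR"
      next
    }
    if (sum(mm[2:al]) > params$anchor_max_mismatch) {
      status[i] <- "NO_ANCHOR"
      next
    }
    cum <- cumsum(mm)
    if (params$shared_budget) {
      within <- cum <= params$body_mismatch_budget
    } else {
      # anchor mismatches are free within the anchor; the body budget counts
      # only substitutions beyond the anchor
      anchor_mm <- cum[min(al, M)]
      within <- cum <= anchor_mm + params$body_mismatch_budget
      within[seq_len(min(al, M))] <- TRUE
    }
    ok <- which(within & !mm)
    k <- if (length(ok)) max(ok) else 0L
    k_out[i] <- k
    tail_out[i] <- if (k < L) substr(ins, k + 1L, L) else ""
  }

  assigned <- status == "ASSIGNED"
  d <- ifelse(assigned, k_out - mature_pos, NA_integer_)
  cls <- rep(NA_character_, n)
  pga <- rep(NA, n)
  if (any(assigned)) {
    cc <- classify_terminus(d[assigned], tail_out[assigned], ref)
    cls[assigned] <- as.character(cc)
    first_flank <- .ref_base_at(ref, ref$mature_end + 1L)
    pga[assigned] <- tail_out[assigned] == "" & d[assigned] == 1L &
      !is.na(first_flank) & first_flank == "A"
  }
  data.frame(
    status = factor(status, levels = CALL_STATUSES),
    end_offset = as.integer(d),
    tail_seq = ifelse(assigned, tail_out, NA_character_),
    terminus_class = factor(cls, levels = TERMINUS_CLASSES),
    possibly_genomic_A = pga,
    stringsAsFactors = FALSE
  )
}

#' Call the 3' terminus of a trimmed, anchored insert
#'
#' Finds the template-maximal boundary between the templated prefix and the
#' untemplated tail (see Details), then classifies the terminus with
#' [classify_terminus()]. The anchor rule is applied first; a failing insert
#' is returned with status `NO_ANCHOR` rather than raising an error.
#'
#' @details The boundary is the largest `k` such that the first `k` insert
#' bases align gaplessly to the first `k` reference bases with at most
#' `body_mismatch_budget` substitutions (shared with the anchor allowance by
#' default) and the `k`-th base itself matches. The signed offset is
#' `d = (k - 1) - mature_end` in 0-based coordinates, so `d = 0` is a
#' terminus exactly at the mature 3' end. A read consumed entirely by
#' templated sequence yields an empty tail. Under this maximality rule the
#' boundary is unique, so `AMBIGUOUS` cannot arise (the status level exists
#' for completeness).
#'
#' @inheritParams match_anchor
#' @param read_id Optional identifier carried into the result.
#' @return A one-row data.frame (a "tail call") with columns `read_id`,
#'   `status`, `end_offset`, `tail_seq`, `terminus_class`,
#'   `possibly_genomic_A`.
#' @export
call_terminus <- function(insert_seq, ref, params, read_id = NA_character_) {
  stopifnot(is(ref, "reference_locus"), is(params, "profiler_params"),
            is.character(insert_seq), length(insert_seq) == 1L)
  out <- .call_inserts(insert_seq, ref, params)
  cbind(read_id = read_id, out, stringsAsFactors = FALSE)
}

#' Classify a called terminus
#'
#' Decision table over the boundary offset `d` and the untemplated tail:
#' * empty tail: genomically encoded terminus at offset `d` (truncation,
#'   mature end, or templated extension) — except the special case
#'   `d = +1` with the first flank base 'A', which is reported as `MONO_A`
#'   because a single terminal adenosine may be genomically encoded there;
#' * tail `"A"`: `MONO_A` (a single untemplated adenosine; at the mature end
#'   in the canonical case, reported at its offset otherwise);
#' * tail of two or more adenosines only: `OLIGO_A`, at any offset — a
#'   templated 3' extension carrying an oligo(A) tail is still oligo(A);
#' * any tail containing a non-A: `OTHER_TAIL`.
#'
#' @param d Integer vector of boundary offsets.
#' @param tail_seq Character vector of untemplated tails (may be "").
#' @param ref A [reference_locus()].
#' @return Factor with levels `GENOMIC`, `MONO_A`, `OLIGO_A`, `OTHER_TAIL`.
#' @export
classify_terminus <- function(d, tail_seq, ref) {
  stopifnot(is(ref, "reference_locus"), length(d) == length(tail_seq))
  first_flank <- .ref_base_at(ref, ref$mature_end + 1L)
  mono_templated <- tail_seq == "" & d == 1L &
    !is.na(first_flank) & first_flank == "A"
  cls <- ifelse(
    tail_seq == "",
    ifelse(mono_templated, "MONO_A", "GENOMIC"),
    ifelse(tail_seq == "A", "MONO_A",
           ifelse(grepl("^A{2,}$", tail_seq), "OLIGO_A", "OTHER_TAIL"))
  )
  factor(cls, levels = TERMINUS_CLASSES)
}

#' Aggregate tail calls into a terminus profile
#'
#' Counts assigned calls by `(end_offset, terminus_class)` and normalises by
#' the total number of assigned reads, the denominator used when reporting
#' terminus proportions. Rejected reads are tallied by status so that every
#' input read is accounted for.
#'
#' @param calls A data.frame of tail calls (as produced by
#'   [call_terminus()] or [run_tail_pipeline()]), with at least columns
#'   `status`, `end_offset`, `terminus_class`.
#' @return An object of class `terminus_profile`: a list with `counts` (a
#'   data.frame `end_offset`, `terminus_class`, `count`, `proportion`),
#'   `total_reads`, `total_trimmed` (reads surviving trimming),
#'   `total_assigned`, and `status_counts`.
#' @export
profile_termini <- function(calls) {
  stopifnot(is.data.frame(calls), all(c("status", "end_offset",
                                        "terminus_class") %in% names(calls)))
  status <- factor(as.character(calls$status), levels = CALL_STATUSES)
  status_counts <- table(status)
  assigned <- calls[status == "ASSIGNED", , drop = FALSE]
  if (nrow(assigned) > 0L) {
    agg <- aggregate(
      list(count = rep(1L, nrow(assigned))),
      by = list(end_offset = assigned$end_offset,
                terminus_class = factor(as.character(assigned$terminus_class),
                                        levels = TERMINUS_CLASSES)),
      FUN = sum
    )
    agg <- agg[order(agg$end_offset, agg$terminus_class), , drop = FALSE]
    rownames(agg) <- NULL
    agg$proportion <- agg$count / nrow(assigned)
  } else {
    agg <- data.frame(end_offset = integer(0L),
                      terminus_class = factor(character(0L),
                                              levels = TERMINUS_CLASSES),
                      count = integer(0L), proportion = numeric(0L))
  }
  structure(
    list(
      counts = agg,
      total_reads = nrow(calls),
      total_trimmed = sum(status %in% c("ASSIGNED", "NO_ANCHOR", "AMBIGUOUS")),
      total_assigned = nrow(assigned),
      status_counts = status_counts
    ),
    class = "terminus_profile"
  )
}

#' @export
print.terminus_profile <- function(x, ...) {
  cat(sprintf(
    "<terminus_profile> %d reads: %d trimmed, %d assigned\n",
    x$total_reads, x$total_trimmed, x$total_assigned
  ))
  sc <- x$status_counts[x$status_counts > 0L]
  cat("  status:", paste(sprintf("%s=%d", names(sc), sc), collapse = ", "),
      "\n")
  if (x$total_assigned > 0L) {
    cp <- class_proportions(x)
    cat("  class proportions:",
        paste(sprintf("%s=%.3f", names(cp), cp), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Terminus class proportions of a profile
#'
#' Sums the per-(offset, class) proportions of a [profile_termini()] result
#' over offsets, returning the marginal class mix among assigned reads.
#'
#' @param profile A `terminus_profile`.
#' @return Named numeric vector over the four terminus classes (sums to 1
#'   when any read is assigned).
#' @export
class_proportions <- function(profile) {
  stopifnot(is(profile, "terminus_profile"))
  out <- setNames(numeric(length(TERMINUS_CLASSES)), TERMINUS_CLASSES)
  if (nrow(profile$counts) > 0L) {
    s <- tapply(profile$counts$proportion, profile$counts$terminus_class, sum,
                default = 0)
    out[names(s)] <- s
  }
  out
}

#' Run the full 3' RACE tail-profiling pipeline
#'
#' Reads a FASTQ file (or takes sequences directly), trims the linker,
#' applies the anchor rule, calls and classifies every terminus, and
#' aggregates the terminus profile. Optionally writes the per-read call
#' table and the profile as TSV.
#'
#' @param fastq Either a path to a FASTQ file (gzip transparent) or a
#'   character vector of read sequences (optionally named by read id).
#' @param ref A [reference_locus()].
#' @param params A [profiler_params()].
#' @param out_prefix Optional path prefix; when given,
#'   `<prefix>_calls.tsv` and `<prefix>_profile.tsv` are written.
#' @return A list with `calls` (per-read data.frame: `read_id`, `status`,
#'   `end_offset`, `tail_seq`, `terminus_class`, `possibly_genomic_A`) and
#'   `profile` (a `terminus_profile`).
#' @export
run_tail_pipeline <- function(fastq, ref, params, out_prefix = NULL) {
  stopifnot(is(ref, "reference_locus"), is(params, "profiler_params"))
  if (is.character(fastq) && length(fastq) == 1L && file.exists(fastq)) {
    ss <- tryCatch(
      Biostrings::readDNAStringSet(fastq, format = "fastq"),
      error = function(e) stop("failed to read FASTQ '", fastq, "': ",
                               conditionMessage(e))
    )
    reads <- as.character(ss)
    ids <- sub("\\s.*$", "", names(ss))
  } else {
    reads <- as.character(fastq)
    ids <- names(fastq)
    if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(reads))
  }
  n <- length(reads)

  trim <- .trim_linker_batch(reads, params)
  calls <- data.frame(
    read_id = ids,
    status = factor(rep("NO_LINKER", n), levels = CALL_STATUSES),
    end_offset = rep(NA_integer_, n),
    tail_seq = rep(NA_character_, n),
    terminus_class = factor(rep(NA_character_, n),
                            levels = TERMINUS_CLASSES),
    possibly_genomic_A = rep(NA, n),
    stringsAsFactors = FALSE
  )
  calls$status[trim$status == "TOO_SHORT"] <- "TOO_SHORT"
  ok <- trim$status == "OK"
  if (any(ok)) {
    called <- .call_inserts(trim$insert[ok], ref, params)
    calls[ok, names(called)] <- called
  }
  profile <- profile_termini(calls)

  if (!is.null(out_prefix)) {
    write.table(calls, paste0(out_prefix, "_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    prof_tab <- profile$counts
    write.table(prof_tab, paste0(out_prefix, "_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(calls = calls, profile = profile)
}
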
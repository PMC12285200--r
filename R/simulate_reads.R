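#' Default 3' RACE linker
#'
#' A fixed 20-nt linker used by the read simulator when none is supplied.
#' The linker of the original library preparation is not part of the public
#' record, so it is a free parameter throughout; this default is screened
#' against the reference at generation time.
#'
#' @return A 20-nt nucleotide string.
#' @export
race_linker <- function() "CTGTAGGCACCATCAATCGT"

#' Truth mixture for the 3' RACE read simulator
#'
#' Describes the population of 3' termini a simulated library is drawn from.
#' `p_genomic` is a per-offset probability map (names are signed offsets `d`)
#' whose total is the genomically-encoded class probability; `p_monoA`,
#' `p_oligoA` and `p_other` are class probabilities for a single untemplated
#' adenosine (planted at the mature end), oligo(A) tails (n >= 2), and mixed
#' tails containing a non-A. All probabilities must sum to 1.
#'
#' The default mixture spans truncations, the mature end, templated
#' extensions (offsets -5..+3), and all three tailed classes — the kind of
#' terminus population a 3' RACE library of a partially processed noncoding
#' RNA presents.
#'
#' @param p_genomic Named numeric vector: P(templated end at offset d).
#' @param p_monoA,p_oligoA,p_other Class probabilities.
#' @param oligoA_len_probs Named numeric vector over oligo(A) tail lengths
#'   (names are lengths >= 2), normalised internally.
#' @param other_len_probs Named numeric vector over mixed-tail lengths >= 1.
#' @param tail_offset_probs Named numeric vector over offsets at which tailed
#'   termini sit (default mostly the mature end with some truncations).
#' @param error_rate Per-base substitution probability applied to finished
#'   reads.
#' @param read_len Read length in nt. The default, 520, lets a single
#'   RNA-sense read span the amplicon 5' start, the mature 3' end, the tail
#'   and the full linker (the junction that merged read pairs cover in a
#'   real paired-end library).
#' @return An object of class `truth_mix`.
#' @export
truth_mix <- function(p_genomic = c(`-5` = 0.02, `-4` = 0.02, `-3` = 0.03,
                                    `-2` = 0.03, `-1` = 0.05, `0` = 0.30,
                                    `1` = 0.03, `2` = 0.01, `3` = 0.01),
                      p_monoA = 0.20,
                      p_oligoA = 0.25,
                      p_other = 0.05,
                      oligoA_len_probs = c(`2` = 0.4, `3` = 0.3, `4` = 0.3),
                      other_len_probs = c(`1` = 0.3, `2` = 0.3, `3` = 0.25,
                                          `4` = 0.15),
                      tail_offset_probs = c(`-2` = 0.1, `-1` = 0.15,
                                            `0` = 0.75),
                      error_rate = 0,
                      read_len = 520L) {
  stopifnot(is.numeric(p_genomic), !is.null(names(p_genomic)))
  probs <- c(sum(p_genomic), p_monoA, p_oligoA, p_other)
  if (any(probs < 0)) stop("class probabilities must be >= 0")
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("class probabilities must sum to 1 (got ", sum(probs), ")")
  }
  if (any(as.integer(names(oligoA_len_probs)) < 2L)) {
    stop("oligo(A) tail lengths must be >= 2")
  }
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  structure(
    list(
      p_genomic = p_genomic,
      p_monoA = p_monoA,
      p_oligoA = p_oligoA,
      p_other = p_other,
      oligoA_len_probs = oligoA_len_probs / sum(oligoA_len_probs),
      other_len_probs = other_len_probs / sum(other_len_probs),
      tail_offset_probs = tail_offset_probs / sum(tail_offset_probs),
      error_rate = error_rate,
      read_len = as.integer(read_len)
    ),
    class = "truth_mix"
  )
}

# Does any full-length window of the reference lie within `max_mm`
# substitutions of the linker? Used to reject linkers that would be
# confusable with templated sequence.
.linker_collides <- function(ref, linker, max_mm = 2L) {
  if (nchar(ref$sequence) < nchar(linker)) return(FALSE)
  m <- Biostrings::matchPattern(linker, ref$sequence,
                                max.mismatch = max_mm, with.indels = FALSE)
  length(m) > 0L
}

# Offsets d (0-based templated-end offsets) at which an all-A tail of length
# `tail_len` is identifiable: the flank window of `tail_len` bases following
# the templated end must contain no 'A', so no boundary extension into the
# tail can end on a matching base under any mismatch budget.
.a_free_offsets <- function(ref, offsets, tail_len) {
  ends0 <- ref$mature_end + offsets             # 0-based last templated index
  keep <- vapply(ends0, function(e0) {
    win <- substr(ref$sequence, e0 + 2L, e0 + 1L + tail_len)
    nchar(win) == tail_len && !grepl("A", win, fixed = TRUE)
  }, logical(1L))
  offsets[keep]
}

# A mixed tail of length L at templated-end offset `d`, built so every tail
# base mismatches the reference continuation (identifiable at any budget)
# and the first base is non-A (guaranteeing OTHER_TAIL content).
.make_other_tail <- function(ref, d, len) {
  e0 <- ref$mature_end + d
  vapply(seq_len(len), function(j) {
    ref_base <- .ref_base_at(ref, e0 + j)
    excl <- if (j == 1L) c("A", ref_base) else ref_base
    sample(setdiff(DNA_BASES, excl), 1L)
  }, character(1L)) |> paste(collapse = "")
}

#' Simulate a 3' RACE read library with planted ground truth
#'
#' Draws termini from a [truth_mix()], assembles sense-strand reads
#' (templated prefix from the amplicon 5' start, untemplated tail, ligated
#' linker, then random downstream filler), pads or truncates them to the
#' configured read length, and applies per-base substitution errors. The
#' returned truth table records, for every read, the planted templated-end
#' offset, tail, and terminus class.
#'
#' Planted tails are restricted to identifiable configurations: each tail
#' base must mismatch the genomic continuation at its position, so that
#' template-maximal boundary calling recovers the planted junction exactly
#' on error-free reads. For A-tails this means the downstream flank window
#' must be A-free; the offset and length of a tailed terminus are therefore
#' drawn jointly from the allowed combinations (the class mixture itself is
#' unaffected). The single deliberate exception is a mono(A) terminus over a
#' flank that itself starts with 'A' (see [make_reference()]'s
#' `post_mature_A`): there a terminal adenosine may be genomically encoded,
#' and the caller reports it as `MONO_A` with `possibly_genomic_A` set.
#'
#' @param ref A [reference_locus()].
#' @param mix A [truth_mix()].
#' @param linker Linker sequence; checked for collision with the reference.
#' @param n_reads Number of reads (>= 0).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list with `reads` (character vector named by read id) and
#'   `truth` (data.frame `read_id`, `truth_offset`, `truth_tail`,
#'   `truth_class`).
#' @export
simulate_race_reads <- function(ref, mix, linker = race_linker(),
                                n_reads, seed = 1L) {
  stopifnot(is(ref, "reference_locus"), is(mix, "truth_mix"))
  n_reads <- as.integer(n_reads)
  if (n_reads < 0L) stop("n_reads must be >= 0")
  linker <- toupper(linker)
  if (!.is_dna(linker) || nchar(linker) == 0L) {
    stop("linker must be a non-empty string over {A,C,G,T}")
  }
  if (.linker_collides(ref, linker)) {
    stop("linker collides with the reference sequence ",
         "(a reference window lies within 2 substitutions of it)")
  }
  empty <- data.frame(read_id = character(0L), truth_offset = integer(0L),
                      truth_tail = character(0L), truth_class = character(0L),
                      stringsAsFactors = FALSE)
  if (n_reads == 0L) return(list(reads = character(0L), truth = empty))

  set.seed(as.integer(seed))
  mature_pos <- ref$mature_end + 1L
  class_probs <- c(GENOMIC = sum(mix$p_genomic), MONO_A = mix$p_monoA,
                   OLIGO_A = mix$p_oligoA, OTHER_TAIL = mix$p_other)
  cls <- sample(names(class_probs), n_reads, replace = TRUE,
                prob = class_probs)

  gen_offsets <- as.integer(names(mix$p_genomic))
  tail_offsets <- as.integer(names(mix$tail_offset_probs))

  # joint (length, offset) tables for identifiable A-tails; when every
  # configured offset collides with a flank adenosine for some tail length,
  # nearby truncation offsets are searched so the planted class mixture is
  # preserved (only the within-class placement is reweighted)
  oligo_lens <- as.integer(names(mix$oligoA_len_probs))
  oligo_joint <- do.call(rbind, lapply(seq_along(oligo_lens), function(li) {
    len <- oligo_lens[li]
    offs <- .a_free_offsets(ref, tail_offsets, len)
    if (length(offs)) {
      w <- mix$tail_offset_probs[as.character(offs)]
      w <- w / sum(w)
    } else {
      fallback <- seq(min(tail_offsets, 0L), by = -1L, length.out = 30L)
      offs <- .a_free_offsets(ref, fallback, len)
      if (length(offs) == 0L) return(NULL)
      offs <- offs[1L]  # nearest identifiable truncation
      w <- 1
    }
    data.frame(len = len, d = offs, w = mix$oligoA_len_probs[li] * w)
  }))
  if (any(cls == "OLIGO_A") && is.null(oligo_joint)) {
    stop("no identifiable oligo(A) placement exists for this reference/",
         "offset combination; widen tail_offset_probs")
  }

  d <- integer(n_reads)
  tail <- character(n_reads)

  is_gen <- cls == "GENOMIC"
  if (any(is_gen)) {
    d[is_gen] <- sample(gen_offsets, sum(is_gen), replace = TRUE,
                        prob = mix$p_genomic)
    tail[is_gen] <- ""
  }

  is_mono <- cls == "MONO_A"
  d[is_mono] <- 0L
  tail[is_mono] <- "A"

  is_oligo <- cls == "OLIGO_A"
  if (any(is_oligo)) {
    pick <- sample(nrow(oligo_joint), sum(is_oligo), replace = TRUE,
                   prob = oligo_joint$w)
    d[is_oligo] <- oligo_joint$d[pick]
    tail[is_oligo] <- strrep("A", oligo_joint$len[pick])
  }

  is_other <- cls == "OTHER_TAIL"
  if (any(is_other)) {
    idx <- which(is_other)
    d[idx] <- sample(tail_offsets, length(idx), replace = TRUE,
                     prob = mix$tail_offset_probs)
    other_lens <- as.integer(names(mix$other_len_probs))
    lens <- sample(other_lens, length(idx), replace = TRUE,
                   prob = mix$other_len_probs)
    tail[idx] <- vapply(seq_along(idx), function(j) {
      .make_other_tail(ref, d[idx[j]], lens[j])
    }, character(1L))
  }

  prefix <- substring(ref$sequence, 1L, mature_pos + d)
  core <- paste0(prefix, tail, linker)
  reads <- vapply(core, function(s) {
    nl <- nchar(s)
    if (nl >= mix$read_len) {
      substr(s, 1L, mix$read_len)
    } else {
      paste0(s, .rand_dna(mix$read_len - nl))
    }
  }, character(1L), USE.NAMES = FALSE)

  if (mix$error_rate > 0) {
    n_err <- rbinom(n_reads, mix$read_len, mix$error_rate)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(mix$read_len, n_err[i])
      for (p in pos) {
        orig <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, orig), 1L)
      }
    }
  }

  ids <- sprintf("read_%06d", seq_len(n_reads))
  names(reads) <- ids
  truth <- data.frame(read_id = ids, truth_offset = d, truth_tail = tail,
                      truth_class = cls, stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Write simulated reads as FASTQ
#'
#' Writes the read set of [simulate_race_reads()] as FASTQ with constant
#' quality 'I' (simulated reads carry no quality information).
#'
#' @param sim Result of [simulate_race_reads()], or a named character vector
#'   of sequences.
#' @param path Output FASTQ path (".gz" suffix compresses transparently).
#' @return `path`, invisibly.
#' @export
write_race_fastq <- function(sim, path) {
  reads <- if (is.list(sim)) sim$reads else sim
  ss <- Biostrings::DNAStringSet(reads)
  if (is.null(names(ss))) names(ss) <- sprintf("read_%06d", seq_along(ss))
  Biostrings::writeXStringSet(ss, filepath = path, format = "fastq")
  invisible(path)
}

#' Write a truth table (or any data.frame) as headered TSV
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
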
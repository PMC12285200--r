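#' Reference locus for 3' end calling
#'
#' A `reference_locus` holds the amplicon-scale reference against which 3'
#' RACE reads are interpreted: the RNA sequence from the amplicon 5' start
#' through the mature 3' end, followed by downstream genomic flank. All
#' terminus calls are expressed as a signed offset `d` relative to
#' `mature_end` (0-based index of the last mature nucleotide), so `d = 0`
#' means a read whose templated portion ends exactly at the mature 3' end,
#' `d < 0` a truncation and `d > 0` a templated (genomically encoded)
#' extension into the flank.
#'
#' @param sequence Nucleotide string over A/C/G/T spanning the amplicon 5'
#'   start through the downstream genomic flank.
#' @param mature_end 0-based, inclusive index of the last mature nucleotide
#'   within `sequence`.
#' @param name Identifier for the locus.
#' @param anchor_len Length in nt of the 5' anchor used for read acceptance
#'   (default 19: the first base plus the next 18).
#' @return An object of class `reference_locus` with fields `name`,
#'   `sequence`, `mature_end`, `flank_len`, and `anchor_len`.
#' @seealso [make_reference()] for a seeded synthetic locus.
#' @export
reference_locus <- function(sequence, mature_end, name = "locus",
                            anchor_len = 19L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!.is_dna(sequence) || nchar(sequence) == 0L) {
    stop("reference sequence must be a non-empty string over {A,C,G,T}")
  }
  mature_end <- as.integer(mature_end)
  anchor_len <- as.integer(anchor_len)
  n <- nchar(sequence)
  if (mature_end < 0L || mature_end >= n) {
    stop("mature_end must satisfy 0 <= mature_end < length(sequence)")
  }
  if (anchor_len < 1L || anchor_len > mature_end + 1L) {
    stop("anchor_len must satisfy 1 <= anchor_len <= mature_end + 1")
  }
  structure(
    list(
      name = name,
      sequence = sequence,
      mature_end = mature_end,
      flank_len = n - mature_end - 1L,
      anchor_len = anchor_len
    ),
    class = "reference_locus"
  )
}

#' @export
print.reference_locus <- function(x, ...) {
  cat(sprintf(
    "<reference_locus> %s: %d nt (mature 0..%d, flank %d nt, anchor %d nt)\n",
    x$name, nchar(x$sequence), x$mature_end, x$flank_len, x$anchor_len
  ))
  invisible(x)
}

#' Generate a seeded synthetic reference locus
#'
#' Draws a uniform random nucleotide sequence of `mature_len + flank_len`
#' bases and marks the mature 3' end at position `mature_len - 1` (0-based).
#' The default mature length of 451 nt mirrors the mature human telomerase
#' RNA, keeping coordinates intuitive without importing a genome sequence.
#'
#' The first flank base (immediately 3' of the mature end) controls whether a
#' single terminal adenosine can be genomically templated. By default it is
#' drawn from C/G/T so a planted mono(A) tail is unambiguous; with
#' `post_mature_A = TRUE` it is forced to 'A', exercising the
#' "may be genomically encoded" ambiguity handled by the caller's
#' `possibly_genomic_A` flag.
#'
#' @param seed Integer seed; the locus is deterministic given the seed.
#' @param mature_len Mature RNA length in nt (>= 40).
#' @param flank_len Downstream genomic flank length in nt (>= 60).
#' @param post_mature_A Force the first flank base to 'A' (default FALSE).
#' @param name Locus identifier.
#' @inheritParams reference_locus
#' @return A [reference_locus()].
#' @examples
#' ref <- make_reference(seed = 1)
#' nchar(ref$sequence)  # 651
#' @export
make_reference <- function(seed, mature_len = 451L, flank_len = 200L,
                           post_mature_A = FALSE, anchor_len = 19L,
                           name = sprintf("synthetic_locus_s%d", seed)) {
  mature_len <- as.integer(mature_len)
  flank_len <- as.integer(flank_len)
  if (mature_len < 40L) stop("mature_len must be >= 40")
  if (flank_len < 60L) stop("flank_len must be >= 60")
  set.seed(as.integer(seed))
  bases <- sample(DNA_BASES, mature_len + flank_len, replace = TRUE)
  first_flank <- mature_len + 1L
  if (post_mature_A) {
    bases[first_flank] <- "A"
  } else if (bases[first_flank] == "A") {
    bases[first_flank] <- sample(c("C", "G", "T"), 1L)
  }
  reference_locus(
    sequence = paste(bases, collapse = ""),
    mature_end = mature_len - 1L,
    name = name,
    anchor_len = anchor_len
  )
}

#' Read a reference locus from FASTA plus a declared mature end
#'
#' The FASTA file carries the sequence; the mature 3' end is experiment
#' metadata and is declared by the caller (0-based index of the last mature
#' base), matching how a sidecar configuration file would supply it.
#'
#' @param fasta_path Path to a FASTA file; the first record is used.
#' @inheritParams reference_locus
#' @return A [reference_locus()].
#' @export
read_reference_fasta <- function(fasta_path, mature_end, anchor_len = 19L) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) == 0L) stop("no sequences found in ", fasta_path)
  reference_locus(
    sequence = as.character(ss[[1L]]),
    mature_end = mature_end,
    name = sub("\\s.*$", "", names(ss)[1L]),
    anchor_len = anchor_len
  )
}

#' Write a reference locus to FASTA
#'
#' @param ref A [reference_locus()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(is(ref, "reference_locus"))
  ss <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$name))
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

# 1-based character at 0-based reference position (NA outside)
.ref_base_at <- function(ref, pos0) {
  n <- nchar(ref$sequence)
  ifelse(pos0 >= 0L & pos0 < n,
         substring(ref$sequence, pos0 + 1L, pos0 + 1L),
         NA_character_)
}
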
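# Brute-force oracles, independent of the package internals.

# naive linker scan: leftmost full-length window within `mm` substitutions,
# else the longest acceptable 3'-end partial overlap (proportional allowance)
brute_trim <- function(read, linker, mm = 1L, min_overlap = 8L) {
  nl <- nchar(read)
  ll <- nchar(linker)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (nl >= ll) {
    for (i in seq_len(nl - ll + 1L)) {
      if (ham(substr(read, i, i + ll - 1L), linker) <= mm) {
        return(substr(read, 1L, i - 1L))
      }
    }
  }
  for (ov in seq(min(ll - 1L, nl), 1L)) {
    if (ov < min_overlap) break
    if (ham(substr(read, nl - ov + 1L, nl), substr(linker, 1L, ov)) <=
        floor(mm * ov / ll)) {
      return(substr(read, 1L, nl - ov))
    }
  }
  NA_character_
}

# exhaustive split-point boundary: the largest k such that insert[1..k]
# matches ref[1..k] with at most `budget` substitutions and position k
# itself matches (k = 0 when no split qualifies); recomputed per k
brute_boundary <- function(insert, refseq, budget) {
  x <- strsplit(insert, "")[[1]]
  r <- strsplit(refseq, "")[[1]]
  best <- 0L
  for (k in seq_len(min(length(x), length(r)))) {
    if (sum(x[1:k] != r[1:k]) <= budget && x[k] == r[k]) best <- k
  }
  best
}

# random DNA helper for test fixtures
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# default truth class probabilities of a truth_mix
mix_class_probs <- function(mix) {
  c(GENOMIC = sum(mix$p_genomic), MONO_A = mix$p_monoA,
    OLIGO_A = mix$p_oligoA, OTHER_TAIL = mix$p_other)
}
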
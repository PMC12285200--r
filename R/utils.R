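DNA_BASES <- c("A", "C", "G", "T")

# uniform random DNA string of length n (uses the current RNG stream)
.rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Hamming distance between equal-length strings
.hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

.is_dna <- function(x) grepl("^[ACGT]*$", x)

# Two-tailed unpaired t-test p-value that survives zero-variance input.
# Degenerate groups (both constant) get p = 1 when equal, p = 0 otherwise;
# stats::t.test would error with "data are essentially constant".
.t_test_p <- function(x, y, var_equal = TRUE) {
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  tryCatch(
    t.test(x, y, var.equal = var_equal)$p.value,
    error = function(e) if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  )
}

# geometric mean / geometric sd of positive values
.geo_mean <- function(x) exp(mean(log(x)))
.geo_sd <- function(x) if (length(x) > 1L) exp(sd(log(x))) else NA_real_

# modal value of a numeric vector, estimated from the highest histogram bin
.modal_intensity <- function(x) {
  if (length(x) == 0L) return(0)
  if (length(unique(x)) == 1L) return(x[[1L]])
  h <- graphics::hist(x, breaks = "Sturges", plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Mismatch budget matched to an expected sequencing error rate
#'
#' Boundary calling tolerates at most a fixed number of substitutions in the
#' templated prefix of a read. At a per-base substitution rate `error_rate`
#' over a templated stretch of `templated_len` nucleotides the number of
#' sequencing errors is Binomial(`templated_len`, `error_rate`); the budget is
#' chosen as its `conf` quantile, so that only a fraction `1 - conf` of reads
#' see their boundary truncated by errors alone. At `error_rate = 0` this is
#' 0, and callers should keep at least the default single-mismatch allowance.
#'
#' @param error_rate Per-base substitution probability.
#' @param templated_len Expected templated length in nt (for a full-length
#'   mature RNA read, roughly the mature length).
#' @param conf Quantile of the error-count distribution to cover.
#' @return Integer mismatch budget.
#' @examples
#' mismatch_budget_for(0.005, 470)
#' @export
mismatch_budget_for <- function(error_rate, templated_len, conf = 0.999) {
  stopifnot(error_rate >= 0, error_rate < 1, templated_len >= 1)
  max(1L, as.integer(qbinom(conf, size = templated_len, prob = error_rate)))
}
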
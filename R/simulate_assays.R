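#' Simulate qPCR Ct records with a planted fold change
#'
#' Generates comparative-CT input: for each group, target-gene Ct values are
#' shifted down by `log2(planted_fold)` cycles relative to the base Ct
#' (a doubling per cycle), and reference-gene Ct values sit at a fixed base;
#' every measured Ct receives independent Gaussian noise of SD `ct_sd`.
#'
#' @param groups Character vector of group labels.
#' @param planted_fold Named numeric vector (per group) of planted
#'   expression fold changes vs the calibrator (> 0); the calibrator group
#'   should carry fold 1.
#' @param ct_sd Gaussian noise SD in Ct units (>= 0).
#' @param n_reps Replicates (samples) per group.
#' @param seed Integer seed.
#' @param target,reference_gene Assay names written into the records.
#' @param base_ct,base_ct_ref Baseline Ct of the target (at fold 1) and of
#'   the reference gene.
#' @return data.frame with columns `sample_id`, `group`, `target`,
#'   `replicate`, `ct` (two rows per sample: target and reference gene).
#' @export
simulate_qpcr <- function(groups = c("NC", "KO"),
                          planted_fold = c(NC = 1, KO = 2),
                          ct_sd = 0.1, n_reps = 3L, seed = 1L,
                          target = "TERC", reference_gene = "GAPDH",
                          base_ct = 22, base_ct_ref = 16) {
  stopifnot(all(groups %in% names(planted_fold)))
  if (any(planted_fold <= 0)) stop("planted_fold must be > 0")
  if (ct_sd < 0) stop("ct_sd must be >= 0")
  set.seed(as.integer(seed))
  rows <- lapply(groups, function(g) {
    lapply(seq_len(n_reps), function(r) {
      sid <- sprintf("%s_%d", g, r)
      data.frame(
        sample_id = sid, group = g,
        target = c(target, reference_gene),
        replicate = r,
        ct = c(base_ct - log2(planted_fold[[g]]) + rnorm(1L, 0, ct_sd),
               base_ct_ref + rnorm(1L, 0, ct_sd)),
        stringsAsFactors = FALSE
      )
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out
}

#' Simulate TRAP assay Ct records with planted telomerase activity
#'
#' Real-time TRAP Ct values: a group with planted relative activity `a`
#' amplifies `log(a)/log(efficiency)` cycles earlier than the control, plus
#' Gaussian noise.
#'
#' @param groups Character vector of group labels.
#' @param planted_activity Named numeric vector (per group) of relative
#'   telomerase activity (> 0); the control group should carry 1.
#' @param ct_sd Gaussian noise SD in Ct units.
#' @param n_reps Replicates per group.
#' @param seed Integer seed.
#' @param efficiency Amplification efficiency the shift is expressed in.
#' @param base_ct Control-group baseline Ct.
#' @return data.frame with columns `group`, `replicate`, `target`, `ct`.
#' @export
simulate_trap_ct <- function(groups = c("NC", "KO"),
                             planted_activity = c(NC = 1, KO = 1.5),
                             ct_sd = 0.1, n_reps = 3L, seed = 1L,
                             efficiency = 2, base_ct = 26) {
  stopifnot(all(groups %in% names(planted_activity)))
  if (any(planted_activity <= 0)) stop("planted_activity must be > 0")
  if (ct_sd < 0) stop("ct_sd must be >= 0")
  set.seed(as.integer(seed))
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(
      group = g, replicate = seq_len(n_reps), target = "TRAP",
      ct = base_ct - log(planted_activity[[g]]) / log(efficiency) +
        rnorm(n_reps, 0, ct_sd),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a digitised TRF lane and its ladder calibration
#'
#' Emulates a dried, probed telomere restriction fragment gel lane after
#' densitometry: fragment sizes are log-normally distributed, so the lane's
#' intensity profile is Gaussian in log-length space, centred at
#' `log(mean_len_kb)` with spread `sd_log`. Migration is linear in log size
#' (the usual agarose regime), and the ladder bands are placed by the same
#' monotone map, so lane and calibration are mutually consistent.
#'
#' @param mean_len_kb Centre of the smear in kb (> 0).
#' @param sd_log Spread of log length (dimensionless; default 0.15, a smear
#'   spanning roughly +/- 35% around the centre, typical of a telomere
#'   blot).
#' @param ladder_kb Ladder band sizes in kb (>= 3 bands; default the lambda
#'   DNA HindIII bands commonly run beside telomere blots).
#' @param n_bins Number of migration bins the lane is digitised into.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param amplitude Peak intensity scale.
#' @param noise_sd SD of additive Gaussian intensity noise (default 0).
#' @return A list with `lane` (data.frame `migration_bin`, `intensity`) and
#'   `ladder` (data.frame `migration_bin`, `size_kb`).
#' @export
simulate_trf_lane <- function(mean_len_kb, sd_log = 0.15,
                              ladder_kb = c(23.130, 9.416, 6.557, 4.361,
                                            2.322, 2.027),
                              n_bins = 240L, seed = 1L, amplitude = 1000,
                              noise_sd = 0) {
  if (mean_len_kb <= 0) stop("mean_len_kb must be > 0")
  if (length(ladder_kb) < 3L) stop("ladder needs at least 3 bands")
  if (sd_log < 0) stop("sd_log must be >= 0")
  set.seed(as.integer(seed))
  ladder_kb <- sort(ladder_kb, decreasing = TRUE)
  # linear map: log(size) in [log(min), log(max)] -> migration bin 1..n_bins
  lmax <- log(max(ladder_kb))
  lmin <- log(min(ladder_kb))
  bins <- seq_len(n_bins)
  log_size_at_bin <- lmax - (bins - 1L) / (n_bins - 1L) * (lmax - lmin)
  if (sd_log == 0) {
    intensity <- numeric(n_bins)
    intensity[which.min(abs(log_size_at_bin - log(mean_len_kb)))] <- amplitude
  } else {
    intensity <- amplitude *
      exp(-((log_size_at_bin - log(mean_len_kb))^2) / (2 * sd_log^2))
  }
  if (noise_sd > 0) {
    intensity <- pmax(intensity + rnorm(n_bins, 0, noise_sd), 0)
  }
  ladder_bins <- 1L + (lmax - log(ladder_kb)) / (lmax - lmin) * (n_bins - 1L)
  list(
    lane = data.frame(migration_bin = bins, intensity = intensity),
    ladder = data.frame(migration_bin = ladder_bins, size_kb = ladder_kb)
  )
}
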
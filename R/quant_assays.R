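#' Comparative-CT (ddCT) relative quantification
#'
#' Standard comparative threshold-cycle reduction of a qPCR experiment. Per
#' sample, dCt = Ct(target) - Ct(reference gene); ddCt subtracts the mean
#' dCt of the calibrator group; the relative quantity is
#' `efficiency^(-ddCt)` (fold change vs the calibrator, 2^(-ddCt) at the
#' default perfect amplification efficiency). Group summaries are geometric
#' means with geometric SD, the natural scale for fold changes; the
#' calibrator group's summary rq is exactly 1 by construction.
#'
#' @param records data.frame with columns `sample_id`, `group`, `target`,
#'   `replicate`, `ct` (as produced by [simulate_qpcr()] or read from TSV).
#'   Multiple wells per (sample, gene) are averaged.
#' @param target Assay/gene being quantified.
#' @param reference_gene Stable reference gene (the normaliser).
#' @param calibrator_group Group whose mean dCt anchors ddCt = 0.
#' @param efficiency Amplification efficiency (2 = perfect doubling).
#' @return A list of class `relative_quant` with `samples` (per-sample
#'   `sample_id`, `group`, `delta_ct`, `delta_delta_ct`, `rq`) and `groups`
#'   (`group`, `rq` geometric mean, `rq_gsd` geometric SD, `n`).
#' @export
delta_delta_ct <- function(records, target, reference_gene,
                           calibrator_group, efficiency = 2) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "group", "target", "ct") %in% names(records)))
  if (any(!is.finite(records$ct)) || any(records$ct <= 0)) {
    stop("all Ct values must be finite and > 0")
  }
  tgt <- records[records$target == target, , drop = FALSE]
  ref <- records[records$target == reference_gene, , drop = FALSE]
  if (nrow(tgt) == 0L) stop("no Ct records for target '", target, "'")
  samples <- unique(tgt[c("sample_id", "group")])
  missing_ref <- setdiff(samples$sample_id, ref$sample_id)
  if (length(missing_ref)) {
    stop("missing reference-gene Ct for sample(s): ",
         paste(missing_ref, collapse = ", "))
  }
  if (!calibrator_group %in% samples$group) {
    stop("calibrator group '", calibrator_group, "' not present")
  }
  ct_of <- function(df) {
    vapply(samples$sample_id,
           function(s) mean(df$ct[df$sample_id == s]), numeric(1L))
  }
  dct <- ct_of(tgt) - ct_of(ref)
  ddct <- dct - mean(dct[samples$group == calibrator_group])
  rq <- efficiency^(-ddct)
  per_sample <- data.frame(sample_id = samples$sample_id,
                           group = samples$group,
                           delta_ct = dct, delta_delta_ct = ddct, rq = rq,
                           stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(split(per_sample, per_sample$group),
                                  function(g) {
    data.frame(group = g$group[1L], rq = .geo_mean(g$rq),
               rq_gsd = .geo_sd(g$rq), n = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  structure(list(samples = per_sample, groups = groups,
                 target = target, reference_gene = reference_gene,
                 calibrator_group = calibrator_group),
            class = "relative_quant")
}

#' @export
print.relative_quant <- function(x, ...) {
  cat(sprintf("<relative_quant> %s vs %s, calibrator %s\n",
              x$target, x$reference_gene, x$calibrator_group))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' q-TRAP relative telomerase activity
#'
#' Reduces real-time TRAP (telomerase repeated amplification protocol) Ct
#' values to relative telomerase activity: per replicate,
#' `RTA = efficiency^(-(Ct - mean Ct of the control group))`, with group
#' summaries as geometric means so the control group is exactly 1 (or 100
#' in percent mode).
#'
#' @param records data.frame with columns `group`, `replicate`, `ct`
#'   (optionally `target`, filtered via the `target` argument).
#' @param control_group Group normalised to unit activity.
#' @param efficiency Amplification efficiency (default 2).
#' @param percent Report activities as percent of control.
#' @param target Optional target name to filter `records` on.
#' @return A list with `samples` (per-replicate `group`, `replicate`,
#'   `rta`) and `groups` (`group`, `rta`, `rta_gsd`, `n`).
#' @export
qtrap_rta <- function(records, control_group, efficiency = 2,
                      percent = FALSE, target = NULL) {
  stopifnot(is.data.frame(records),
            all(c("group", "ct") %in% names(records)))
  if (!is.null(target) && "target" %in% names(records)) {
    records <- records[records$target == target, , drop = FALSE]
  }
  if (!control_group %in% records$group) {
    stop("control group '", control_group, "' not present")
  }
  ctrl_mean <- mean(records$ct[records$group == control_group])
  rta <- efficiency^(-(records$ct - ctrl_mean))
  scale <- if (percent) 100 else 1
  per_rep <- data.frame(
    group = records$group,
    replicate = if ("replicate" %in% names(records)) records$replicate else
      seq_len(nrow(records)),
    rta = rta * scale,
    stringsAsFactors = FALSE
  )
  groups <- do.call(rbind, lapply(split(per_rep, per_rep$group),
                                  function(g) {
    data.frame(group = g$group[1L], rta = .geo_mean(g$rta),
               rta_gsd = .geo_sd(g$rta), n = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  list(samples = per_rep, groups = groups)
}

#' Ladder calibration for gel densitometry
#'
#' Migration-to-size calibration from a molecular weight ladder: at least
#' three bands whose sizes are strictly decreasing with migration distance
#' (DNA runs log-linearly, so interpolation is done on log size).
#'
#' @param migration_bin Numeric migration positions of the ladder bands, or
#'   a data.frame with columns `migration_bin`, `size_kb`.
#' @param size_kb Band sizes in kb (same length).
#' @return An object of class `ladder_calibration`.
#' @export
ladder_calibration <- function(migration_bin, size_kb = NULL) {
  if (is.data.frame(migration_bin)) {
    size_kb <- migration_bin$size_kb
    migration_bin <- migration_bin$migration_bin
  }
  stopifnot(is.numeric(migration_bin), is.numeric(size_kb),
            length(migration_bin) == length(size_kb))
  if (length(size_kb) < 3L) stop("a ladder needs at least 3 bands")
  o <- order(migration_bin)
  migration_bin <- migration_bin[o]
  size_kb <- size_kb[o]
  if (any(diff(size_kb) >= 0)) {
    stop("ladder sizes must be strictly decreasing with migration distance")
  }
  structure(list(migration_bin = migration_bin, size_kb = size_kb),
            class = "ladder_calibration")
}

#' Densitometric mean terminal restriction fragment length
#'
#' Estimates the mean telomere length from a digitised Southern-blot lane:
#' sizes are assigned per migration bin by linear interpolation of log(size)
#' against the ladder's band positions, background is subtracted (floored at
#' zero), and the mean length is the intensity-weighted harmonic form
#' `sum(I) / sum(I / L)`, which weights the smear by molar abundance rather
#' than by mass and is the canonical densitometric TRF reduction.
#'
#' @param lane data.frame with columns `migration_bin`, `intensity` (>= 0).
#' @param ladder A [ladder_calibration()] (or a data.frame accepted by it).
#' @param window Optional `c(min_bin, max_bin)` analysis window; defaults to
#'   the bins the ladder spans. Must lie within the ladder range.
#' @param background Intensity to subtract; defaults to the modal intensity
#'   outside the window (0 when the window covers the whole lane).
#' @return A list of class `trf_estimate` with `mean_length_kb`, `window`,
#'   and `background`.
#' @export
trf_mean_length <- function(lane, ladder, window = NULL, background = NULL) {
  stopifnot(is.data.frame(lane),
            all(c("migration_bin", "intensity") %in% names(lane)))
  if (any(lane$intensity < 0)) stop("intensities must be >= 0")
  if (!is(ladder, "ladder_calibration")) ladder <- ladder_calibration(ladder)

  log_size <- approx(ladder$migration_bin, log(ladder$size_kb),
                     xout = lane$migration_bin, rule = 1L)$y
  in_ladder <- !is.na(log_size)
  if (is.null(window)) {
    window <- range(lane$migration_bin[in_ladder])
  } else {
    stopifnot(length(window) == 2L)
    window <- sort(as.numeric(window))
    if (window[1L] < min(ladder$migration_bin) ||
        window[2L] > max(ladder$migration_bin)) {
      stop("analysis window extends outside the ladder calibration range")
    }
  }
  in_win <- in_ladder & lane$migration_bin >= window[1L] &
    lane$migration_bin <= window[2L]
  if (!any(in_win)) stop("analysis window contains no lane bins")

  if (is.null(background)) {
    outside <- lane$intensity[!in_win]
    background <- if (length(outside)) .modal_intensity(outside) else 0
  }
  intensity <- pmax(lane$intensity[in_win] - background, 0)
  if (sum(intensity) == 0) {
    stop("no signal above background inside the analysis window")
  }
  sizes <- exp(log_size[in_win])
  structure(
    list(mean_length_kb = sum(intensity) / sum(intensity / sizes),
         window = window, background = background),
    class = "trf_estimate"
  )
}

#' @export
print.trf_estimate <- function(x, ...) {
  cat(sprintf(
    "<trf_estimate> mean length %.2f kb (window %.0f..%.0f, background %.3g)\n",
    x$mean_length_kb, x$window[1L], x$window[2L], x$background
  ))
  invisible(x)
}
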
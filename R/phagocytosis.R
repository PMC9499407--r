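#' Positivity gate from control events
#'
#' Places the phagocytosis gate at a high quantile of the no-substrate
#' control intensity distribution (linear interpolation between order
#' statistics). The control-quantile strategy is a documented,
#' configurable stand-in for a manually drawn cytometry gate.
#'
#' @param control_intensities numeric vector of control event
#'   intensities (a.u., >= 0).
#' @param quantile gate quantile, default 0.995.
#' @return gate threshold (a.u.).
#' @export
fit_gate <- function(control_intensities, quantile = 0.995) {
  x <- control_intensities
  if (!length(x)) stop("empty control sample")
  if (any(!is.finite(x)) || any(x < 0))
    stop("intensities must be finite and non-negative")
  if (quantile <= 0 || quantile >= 1) stop("'quantile' must be in (0, 1)")
  if (length(x) < 100)
    warning("fewer than 100 control events; gate may be unstable")
  unname(stats::quantile(x, quantile, type = 7))
}

#' Percent phagocytic cells and MFI above a gate
#'
#' Events strictly above the gate are positive (phagocytic). Reports
#' the percentage of positive events and the median fluorescence
#' intensity (MFI) of the positives -- the uptake readout; the mean is
#' available via `mfi_stat = "mean"`. With no positive events the MFI
#' is absent (`NA`).
#'
#' @param intensities numeric vector of event intensities (a.u.).
#' @param gate gate threshold (> 0).
#' @param mfi_stat "median" (default) or "mean".
#' @return list of class `gate_result`: `gate`, `pct_positive` (%),
#'   `mfi` (a.u. or NA), `n_events`, `n_positive`.
#' @export
quantify_phagocytosis <- function(intensities, gate,
                                  mfi_stat = c("median", "mean")) {
  mfi_stat <- match.arg(mfi_stat)
  if (!length(intensities)) stop("empty sample")
  if (!is.numeric(gate) || gate <= 0) stop("'gate' must be > 0")
  pos <- intensities > gate
  mfi <- if (any(pos)) {
    if (mfi_stat == "median") stats::median(intensities[pos])
    else mean(intensities[pos])
  } else NA_real_
  structure(list(gate = gate, pct_positive = 100 * mean(pos), mfi = mfi,
                 n_events = length(intensities), n_positive = sum(pos)),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("gate %.3g a.u.: %.2f%% positive (n = %d), MFI %.3g\n",
              x$gate, x$pct_positive, x$n_events, x$mfi))
  invisible(x)
}

#' Phagocytosis time course across groups
#'
#' For each timepoint, fits the gate on that timepoint's pooled control
#' events, quantifies every non-control sample against it, and
#' summarizes percent-positive per (timepoint, group) as mean +- SEM
#' across biological replicates. Per-timepoint group comparisons use the
#' exact Mann-Whitney test with Holm adjustment across timepoints (see
#' [mann_whitney_exact()], [holm_adjust()]). Timepoints represented in
#' fewer than two groups are dropped with a warning.
#'
#' @param events event table: columns `intensity`, `sample`,
#'   `timepoint_min`, `group`, `is_control`.
#' @param gate_quantile control quantile for [fit_gate()].
#' @param mfi_stat passed to [quantify_phagocytosis()].
#' @param p_adjust "holm" (default), "bonferroni" or "none".
#' @return list with `per_sample` (one [quantify_phagocytosis()] row per
#'   sample), `summary` (timepoint x group mean/SEM), `tests`
#'   (per-timepoint comparison with adjusted p).
#' @export
phagocytosis_timecourse <- function(events, gate_quantile = 0.995,
                                    mfi_stat = "median",
                                    p_adjust = c("holm", "bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  need <- c("intensity", "sample", "timepoint_min", "group", "is_control")
  if (!all(need %in% names(events)))
    stop("event table needs columns ", paste(need, collapse = ", "))
  per_sample <- list()
  for (tp in sort(unique(events$timepoint_min[!events$is_control]))) {
    ctrl <- events$intensity[events$is_control & events$timepoint_min == tp]
    if (!length(ctrl))
      ctrl <- events$intensity[events$is_control]   # fall back to all controls
    if (!length(ctrl)) stop("no control events available for gating")
    gate <- fit_gate(ctrl, gate_quantile)
    sub <- events[!events$is_control & events$timepoint_min == tp, ]
    for (s in unique(sub$sample)) {
      d <- sub[sub$sample == s, ]
      g <- quantify_phagocytosis(d$intensity, gate, mfi_stat = mfi_stat)
      per_sample[[length(per_sample) + 1]] <-
        data.frame(sample = s, timepoint_min = tp, group = d$group[1],
                   gate = gate, pct_positive = g$pct_positive, mfi = g$mfi,
                   n_events = g$n_events)
    }
  }
  per_sample <- do.call(rbind, per_sample)
  # drop timepoints with a single group
  ngrp <- tapply(per_sample$group, per_sample$timepoint_min,
                 function(g) length(unique(g)))
  solo <- names(ngrp)[ngrp < 2]
  if (length(solo)) {
    warning("timepoint(s) with a single group excluded from comparison: ",
            paste(solo, collapse = ", "))
  }
  summ <- do.call(rbind, lapply(
    split(per_sample, list(per_sample$timepoint_min, per_sample$group),
          drop = TRUE),
    function(d) data.frame(timepoint_min = d$timepoint_min[1],
                           group = d$group[1], n = nrow(d),
                           mean_pct = mean(d$pct_positive),
                           sem_pct = stats::sd(d$pct_positive) / sqrt(nrow(d)),
                           mean_mfi = mean(d$mfi, na.rm = TRUE))))
  rownames(summ) <- NULL
  tests <- NULL
  cmp_tp <- setdiff(as.character(unique(per_sample$timepoint_min)), solo)
  if (length(cmp_tp)) {
    rows <- lapply(cmp_tp, function(tp) {
      d <- per_sample[per_sample$timepoint_min == as.numeric(tp), ]
      gs <- sort(unique(d$group))
      mw <- mann_whitney_exact(d$pct_positive[d$group == gs[1]],
                               d$pct_positive[d$group == gs[2]])
      data.frame(timepoint_min = as.numeric(tp),
                 group1 = gs[1], group2 = gs[2],
                 U = mw$U, p = mw$p)
    })
    tests <- do.call(rbind, rows)
    tests <- tests[order(tests$timepoint_min), ]
    tests$p_adjusted <- switch(p_adjust,
      holm = holm_adjust(tests$p),
      bonferroni = pmin(tests$p * nrow(tests), 1),
      none = tests$p)
    rownames(tests) <- NULL
  }
  list(per_sample = per_sample, summary = summ, tests = tests)
}
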
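# Ratiometric Fura-2 calcium-imaging analysis.
#
# The raw measurement is a pair of fluorescence intensities per frame (340 nm
# and 380 nm excitation, one frame every 2 s by default). The Fura response is
# the 340/380 ratio; the relative response divides the ratio by the mean of
# the five samples immediately preceding drug application, so the pre-stimulus
# level is 1 by construction. A neuron is a responder to a stimulus when its
# peak relative response in the application window reaches a cutoff defined as
# mean + 3 SD of the non-responder peak distribution (1.15-fold for a
# non-responder population with mean 1.00 and SD 0.05). Population statistics
# aggregate per mouse, with responder counts normalised to the number of
# KCl-responsive (excitable) neurons of that mouse.

#' Compute the Fura-2 ratio trace
#'
#' @param f340,f380 Numeric vectors of equal length: fluorescence intensities
#'   under 340 nm and 380 nm excitation. All `f380` values must be positive.
#' @return Elementwise `f340 / f380`.
#' @export
compute_ratio <- function(f340, f380) {
  if (length(f340) != length(f380)) {
    stop("channel length mismatch: ", length(f340), " vs ", length(f380),
         call. = FALSE)
  }
  bad <- which(f380 <= 0)
  if (length(bad) > 0L) {
    stop("non-positive 380 nm intensity at sample index ", bad[1L],
         call. = FALSE)
  }
  f340 / f380
}

#' Normalise a ratio trace to its pre-stimulus baseline
#'
#' Divides the whole trace by the mean of the five samples immediately
#' preceding stimulus onset, giving a relative Fura response whose baseline
#' is 1.
#'
#' @param ratio Numeric ratio trace.
#' @param time Numeric time stamps (seconds), same length as `ratio`.
#' @param stim_onset Onset time of the first drug application (seconds).
#' @return Relative trace: `ratio` divided by the 5-sample baseline mean.
#' @export
normalize_baseline <- function(ratio, time, stim_onset) {
  stopifnot(length(ratio) == length(time))
  pre <- which(time < stim_onset)
  if (length(pre) < 5L) {
    stop("need at least 5 samples before stimulus onset, have ", length(pre),
         call. = FALSE)
  }
  base <- mean(ratio[tail(pre, 5L)])
  ratio / base
}

#' Calibration parameters for converting ratios to \[Ca2+\]i
#'
#' @param Rmin,Rmax Ratio at zero and saturating calcium (`Rmin < Rmax`).
#' @param Kd Dye dissociation constant in nM.
#' @param beta Ratio of 380 nm fluorescence of free dye to calcium-bound dye.
#' @return A `calibration_params` list.
#' @export
calibration_params <- function(Rmin, Rmax, Kd, beta) {
  stopifnot(Rmin < Rmax, Kd > 0, beta > 0)
  structure(list(Rmin = Rmin, Rmax = Rmax, Kd = Kd, beta = beta),
            class = "calibration_params")
}

#' Convert a Fura-2 ratio to absolute calcium concentration
#'
#' Standard ratiometric calibration:
#' `[Ca2+]i = Kd * beta * (R - Rmin) / (Rmax - R)` (nM).
#'
#' @param ratio_value Ratio value(s), each in `[Rmin, Rmax)`.
#' @param params A [calibration_params] object.
#' @return Calcium concentration(s) in nM.
#' @export
calibrate_ca <- function(ratio_value, params) {
  stopifnot(inherits(params, "calibration_params"))
  if (any(ratio_value >= params$Rmax)) {
    stop("ratio at or above Rmax: dye saturated", call. = FALSE)
  }
  if (any(ratio_value < params$Rmin)) {
    stop("ratio below Rmin", call. = FALSE)
  }
  params$Kd * params$beta *
    (ratio_value - params$Rmin) / (params$Rmax - ratio_value)
}

#' Peak amplitude fold within a stimulus window
#'
#' @param relative_trace Baseline-normalised trace.
#' @param time Time stamps (seconds).
#' @param window Numeric length-2 vector: window start (stimulus onset) and
#'   end (end of washout), inclusive.
#' @return Maximum of the relative trace within the window.
#' @export
amplitude_fold <- function(relative_trace, time, window) {
  stopifnot(length(relative_trace) == length(time), length(window) == 2L)
  inside <- time >= window[1L] & time <= window[2L]
  if (!any(inside)) stop("empty stimulus window", call. = FALSE)
  max(relative_trace[inside])
}

#' Responder cutoff from a non-responder peak distribution
#'
#' The response threshold is defined as the mean plus three sample standard
#' deviations of the peak amplitude folds of non-responsive neurons. For a
#' non-responder population with mean 1.00 and SD 0.05 this gives the
#' 1.15-fold cutoff.
#'
#' @param nonresponder_peaks Numeric vector (length >= 2) of peak amplitude
#'   folds of non-responsive neurons.
#' @return The cutoff fold: `mean + 3 * sd`.
#' @export
responder_threshold <- function(nonresponder_peaks) {
  if (length(nonresponder_peaks) < 2L) {
    stop("need at least 2 non-responder peaks", call. = FALSE)
  }
  mean(nonresponder_peaks) + 3 * sd(nonresponder_peaks)
}

#' Split peaks into responders/non-responders and derive the data cutoff
#'
#' When the non-responsive population is not delimited a priori, peaks at or
#' below a provisional cutoff are taken as the non-responder mode, the
#' mean + 3 SD rule is applied to them, and the split is refined once with the
#' resulting cutoff.
#'
#' @param peaks Numeric vector of peak amplitude folds for all neurons.
#' @param provisional Provisional cutoff used for the initial split
#'   (default 1.15).
#' @return A list with `cutoff` (the refined mean + 3 SD cutoff) and
#'   `nonresponder_peaks` (the final sub-cutoff population).
#' @export
derive_threshold <- function(peaks, provisional = 1.15) {
  nonresp <- peaks[peaks < provisional]
  if (length(nonresp) < 2L) {
    stop("fewer than 2 peaks below the provisional cutoff", call. = FALSE)
  }
  cutoff <- responder_threshold(nonresp)
  nonresp2 <- peaks[peaks < cutoff]
  if (length(nonresp2) >= 2L) cutoff <- responder_threshold(nonresp2)
  list(cutoff = cutoff, nonresponder_peaks = peaks[peaks < cutoff])
}

#' Classify responder calls against a cutoff
#'
#' @param calls Data frame with an `amplitude_fold` column (per neuron and
#'   stimulus).
#' @param cutoff Responder cutoff fold (default 1.15). Comparison is
#'   inclusive: a peak exactly at the cutoff is a responder.
#' @return `calls` with `is_responder` set (`NA` amplitudes give `NA` calls).
#' @export
classify_responders <- function(calls, cutoff = 1.15) {
  calls$is_responder <- calls$amplitude_fold >= cutoff
  calls
}

#' Flag stimuli compromised by incomplete recovery (desensitization)
#'
#' After a strong response to a low dose, a trace that has not returned
#' toward baseline by the next application makes that next amplitude
#' uninterpretable. A later stimulus is flagged when the level just before
#' its onset (mean of the preceding five samples) has not fallen below
#' `baseline + recovery_fraction * (low-dose peak - baseline)`, with
#' baseline = 1 on the relative scale.
#'
#' @param relative_trace Baseline-normalised trace.
#' @param time Time stamps (seconds).
#' @param schedule Stimulus schedule data frame (see [read_schedule]) with at
#'   least two pre-KCl stimuli in order.
#' @param recovery_fraction Fraction of the low-dose peak-over-baseline that
#'   must have decayed away (default 0.5).
#' @return Named logical vector over the stimuli after the first (KCl
#'   included, though in practice only intermediate doses matter).
#' @export
flag_desensitized <- function(relative_trace, time, schedule,
                              recovery_fraction = 0.5) {
  stopifnot(nrow(schedule) >= 2L)
  first <- schedule[1L, ]
  low_peak <- amplitude_fold(relative_trace, time,
                             c(first$onset, first$washout_end))
  later <- schedule[-1L, , drop = FALSE]
  flags <- vapply(seq_len(nrow(later)), function(i) {
    pre <- which(time < later$onset[i])
    pre_level <- mean(relative_trace[tail(pre, 5L)])
    pre_level > 1 + recovery_fraction * (low_peak - 1)
  }, logical(1))
  names(flags) <- later$label
  flags
}

#' Read a stimulus schedule
#'
#' CSV with columns `label`, `onset`, `offset`, `washout_end` (seconds),
#' in increasing, non-overlapping order; the final row must be the KCl
#' depolarisation used to define the excitable population.
#'
#' @param path Path to the schedule CSV.
#' @return Validated schedule data frame.
#' @export
read_schedule <- function(path) {
  sch <- read.csv(path, stringsAsFactors = FALSE)
  validate_schedule(sch)
}

validate_schedule <- function(sch) {
  need <- c("label", "onset", "offset", "washout_end")
  if (!all(need %in% names(sch))) {
    stop("schedule needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  with(sch, stopifnot(all(onset < offset), all(offset <= washout_end)))
  if (nrow(sch) > 1L &&
      any(sch$onset[-1L] < sch$washout_end[-nrow(sch)])) {
    stop("overlapping stimulus applications", call. = FALSE)
  }
  if (!grepl("kcl", tolower(sch$label[nrow(sch)]))) {
    stop("last scheduled stimulus must be KCl", call. = FALSE)
  }
  sch
}

#' Read calcium-imaging traces
#'
#' Long-format CSV with columns `neuron_id`, `mouse_id`, `time` and either
#' raw channels `f340`, `f380` or a precomputed `ratio`.
#'
#' @param path Path to the traces CSV.
#' @return Data frame with a `ratio` column (computed from the channels when
#'   absent).
#' @export
read_traces <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "mouse_id", "time")
  if (!all(need %in% names(tr))) {
    stop("traces need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"ratio" %in% names(tr)) {
    if (!all(c("f340", "f380") %in% names(tr))) {
      stop("traces need either 'ratio' or both 'f340' and 'f380'",
           call. = FALSE)
    }
    tr$ratio <- compute_ratio(tr$f340, tr$f380)
  }
  tr
}

#' Per-neuron responder calls for a full experiment
#'
#' For every neuron: normalise the ratio trace to the five samples before the
#' first application, flag later stimuli compromised by incomplete recovery,
#' compute the peak amplitude fold in every stimulus window (skipping the
#' amplitude, but not the responder call, of flagged windows), and classify
#' responders at the cutoff.
#'
#' @param traces Long data frame from [read_traces].
#' @param schedule Stimulus schedule (KCl last).
#' @param cutoff Responder cutoff fold (default 1.15).
#' @param recovery_fraction Recovery criterion for desensitization flagging
#'   (default 0.5).
#' @return Calls data frame: `neuron_id`, `mouse_id`, `stimulus`,
#'   `amplitude_fold` (`NA` when flagged), `peak_fold` (always computed),
#'   `excluded_desensitized`, `is_responder`.
#' @export
analyze_traces <- function(traces, schedule, cutoff = 1.15,
                           recovery_fraction = 0.5) {
  validate_schedule(schedule)
  per_neuron <- lapply(split(traces, traces$neuron_id), function(tr) {
    tr <- tr[order(tr$time), , drop = FALSE]
    rel <- normalize_baseline(tr$ratio, tr$time, schedule$onset[1L])
    flags <- c(FALSE,
               flag_desensitized(rel, tr$time, schedule, recovery_fraction))
    peak <- vapply(seq_len(nrow(schedule)), function(i) {
      amplitude_fold(rel, tr$time,
                     c(schedule$onset[i], schedule$washout_end[i]))
    }, numeric(1))
    data.frame(neuron_id = tr$neuron_id[1L], mouse_id = tr$mouse_id[1L],
               stimulus = schedule$label,
               amplitude_fold = ifelse(flags, NA_real_, peak),
               peak_fold = peak,
               excluded_desensitized = flags,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, c(per_neuron, list(make.row.names = FALSE)))
  # A flagged window has no interpretable amplitude, but the neuron can still
  # be called a responder from the peak in its own window.
  calls$is_responder <- calls$peak_fold >= cutoff
  calls
}

#' Per-mouse responder percentages normalised to KCl
#'
#' For each mouse, the number of responders to each stimulus is expressed as
#' a percentage of that mouse's KCl responders (the excitable population).
#' With `gate_to_kcl = TRUE` (default) the numerator only counts neurons that
#' also responded to KCl, so percentages cannot exceed 100.
#'
#' @param calls Calls data frame from [analyze_traces].
#' @param kcl_label Label of the KCl stimulus in `calls` (default `"KCl"`).
#' @param gate_to_kcl Restrict the responder numerator to KCl-responsive
#'   neurons (default `TRUE`).
#' @return Mouse-by-stimulus summary: `mouse_id`, `stimulus`, `n_neurons`,
#'   `n_kcl_responders`, `n_responders`, `pct_responders`,
#'   `mean_amplitude_fold` (over neurons with an unflagged amplitude).
#'   Mice with zero KCl responders get `NA` percentages with a warning.
#' @export
percent_responders <- function(calls, kcl_label = "KCl", gate_to_kcl = TRUE) {
  if (!kcl_label %in% calls$stimulus) {
    stop("no '", kcl_label, "' calls present", call. = FALSE)
  }
  out <- lapply(split(calls, calls$mouse_id), function(cm) {
    kcl <- cm[cm$stimulus == kcl_label, ]
    n_kcl <- sum(kcl$is_responder, na.rm = TRUE)
    excitable <- kcl$neuron_id[which(kcl$is_responder)]
    if (n_kcl == 0L) {
      warning("mouse '", cm$mouse_id[1L],
              "': no KCl responders; percentages undefined", call. = FALSE)
    }
    per_stim <- lapply(split(cm, cm$stimulus), function(cs) {
      resp <- cs$is_responder
      if (gate_to_kcl) resp <- resp & cs$neuron_id %in% excitable
      data.frame(mouse_id = cm$mouse_id[1L], stimulus = cs$stimulus[1L],
                 n_neurons = length(unique(cm$neuron_id)),
                 n_kcl_responders = n_kcl,
                 n_responders = sum(resp, na.rm = TRUE),
                 pct_responders = if (n_kcl > 0L)
                   100 * sum(resp, na.rm = TRUE) / n_kcl else NA_real_,
                 mean_amplitude_fold = mean(cs$amplitude_fold, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(per_stim, list(make.row.names = FALSE)))
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Compare two groups of per-mouse values
#'
#' Thin wrappers over the standard tests, with the mouse (not the neuron) as
#' the unit of analysis: an unpaired two-sided t-test or a one-way ANOVA.
#'
#' @param a,b Numeric vectors of per-mouse values (length >= 2 each).
#' @param test `"unpaired_t"` or `"oneway_anova"`.
#' @param var_equal For the t-test, assume equal variances (default `TRUE`,
#'   the classical unpaired Student t).
#' @return A list with `test`, `statistic` and `p_value`.
#' @export
group_compare <- function(a, b, test = c("unpaired_t", "oneway_anova"),
                          var_equal = TRUE) {
  test <- match.arg(test)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (test == "unpaired_t") {
    fit <- t.test(a, b, var.equal = var_equal)
    list(test = test, statistic = unname(fit$statistic),
         p_value = fit$p.value)
  } else {
    dat <- data.frame(value = c(a, b),
                      group = factor(rep(c("a", "b"), c(length(a), length(b)))))
    fit <- anova(aov(value ~ group, data = dat))
    list(test = test, statistic = fit[["F value"]][1L],
         p_value = fit[["Pr(>F)"]][1L])
  }
}
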
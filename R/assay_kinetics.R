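# Quantitative readings from substrate assays: blank-subtracted initial rates
# of chromogenic (pNA) substrate hydrolysis, primary-specificity calls from a
# substrate panel, first-order fits of gel-based fraction-cleaved time
# courses, and fold differences in cleavage efficiency by rate ratio or by
# enzyme titration.

#' Absorbance time series for one chromogenic substrate
#'
#' @param substrate_id Substrate identifier.
#' @param substrate_sequence Non-prime-side substrate sequence, P4..P1 (or
#'   P3..P1 for a three-residue substrate).
#' @param times Measurement times in minutes, strictly increasing from 0.
#' @param replicates Matrix of A405 readings, `length(times)` rows, one
#'   column per replicate (three in the standard assay).
#' @param blank Per-time A405 of the no-enzyme control.
#' @return An object of class `"absorbance_series"`.
#' @export
absorbance_series <- function(substrate_id, substrate_sequence, times,
                              replicates, blank) {
  replicates <- as.matrix(replicates)
  if (length(times) < 2) stop("need at least 2 time points")
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing and start at 0")
  }
  if (nrow(replicates) != length(times)) {
    stop("replicates must have one row per time point")
  }
  if (length(blank) != length(times)) {
    stop("blank must have one reading per time point")
  }
  if (!is_valid_aa(substrate_sequence)) {
    stop("invalid substrate sequence: ", substrate_sequence)
  }
  structure(list(substrate_id = substrate_id,
                 substrate_sequence = substrate_sequence,
                 times = times, replicates = replicates, blank = blank),
            class = "absorbance_series")
}

#' Fraction-cleaved time course for one recombinant substrate
#'
#' @param substrate_name Substrate name.
#' @param insert_sequence Cleavable linker sequence.
#' @param times Sampling times in minutes, starting at 0.
#' @param fraction_cleaved Fractions in `[0, 1]`, one per time.
#' @return An object of class `"cleavage_time_course"`.
#' @export
cleavage_time_course <- function(substrate_name, insert_sequence, times,
                                 fraction_cleaved) {
  if (times[1] != 0) stop("times must start at 0")
  if (any(fraction_cleaved < 0 | fraction_cleaved > 1)) {
    stop("fraction_cleaved must lie in [0, 1]")
  }
  if (length(times) != length(fraction_cleaved)) {
    stop("times and fraction_cleaved must have equal length")
  }
  structure(list(substrate_name = substrate_name,
                 insert_sequence = insert_sequence,
                 times = times, fraction_cleaved = fraction_cleaved),
            class = "cleavage_time_course")
}

#' Blank-subtracted initial rate of a chromogenic substrate
#'
#' Per replicate, the ordinary-least-squares slope of the blank-subtracted
#' absorbance over `fit_window` (minutes); the rate is the replicate mean and
#' its spread their standard deviation. Negative mean slopes are reported
#' as-is. Adding a constant to all readings of a replicate leaves the rate
#' unchanged.
#'
#' @param series An [absorbance_series()].
#' @param fit_window Two minutes bounding the fitted points; default 0-60.
#' @return List of class `"initial_rate"`: `substrate_id`, `rate` (AU/min),
#'   `sd`, `n_replicates`.
#' @export
initial_rate <- function(series, fit_window = c(0, 60)) {
  sel <- series$times >= fit_window[1] & series$times <= fit_window[2]
  if (sum(sel) < 2) {
    stop("need at least 2 time points inside the fit window")
  }
  t <- series$times[sel]
  slopes <- apply(series$replicates[sel, , drop = FALSE], 2, function(y) {
    yc <- y - series$blank[sel]
    sum((t - mean(t)) * (yc - mean(yc))) / sum((t - mean(t))^2)
  })
  structure(list(substrate_id = series$substrate_id,
                 rate = mean(slopes),
                 sd = if (length(slopes) > 1) sd(slopes) else 0,
                 n_replicates = length(slopes)),
            class = "initial_rate")
}

#' Primary specificity from a chromogenic substrate panel
#'
#' Substrates are grouped by the residue class of their P1 residue (the last
#' residue of the non-prime sequence); class activity is the maximal
#' blank-subtracted rate in the class, normalized by the panel maximum, and
#' the same thresholds as [classify_specificity_from_pwm()] yield the call.
#' When every class activity stays below the detection floor (3 times the
#' pooled replicate standard deviation by default) the call is
#' `"undetermined"` -- a protease can be too selective for any generic panel.
#'
#' @param panel List of `list(sequence =, rate =)` pairs where `rate` is an
#'   [initial_rate()], or a data.frame with columns `sequence`, `rate`, `sd`.
#' @param detection_floor Absolute rate floor; `NULL` uses 3 times the pooled
#'   replicate sd.
#' @param absolute_threshold,relative_threshold See
#'   [classify_specificity_from_pwm()].
#' @return A `"specificity_call"` with `source = "rate-panel"`.
#' @export
classify_specificity_from_rates <- function(panel, detection_floor = NULL,
                                            absolute_threshold = 0.4,
                                            relative_threshold = 0.5) {
  if (is.data.frame(panel)) {
    seqs <- panel$sequence
    rates <- panel$rate
    sds <- if ("sd" %in% names(panel)) panel$sd else rep(0, nrow(panel))
  } else {
    seqs <- vapply(panel, function(p) p$sequence, character(1))
    rates <- vapply(panel, function(p) p$rate$rate, numeric(1))
    sds <- vapply(panel, function(p) p$rate$sd, numeric(1))
  }
  p1 <- substring(seqs, nchar(seqs), nchar(seqs))
  classes <- specificity_classes()
  cls <- vapply(p1, function(r) {
    hit <- names(classes)[vapply(classes, function(set) r %in% set, logical(1))]
    if (length(hit) == 0) {
      stop("panel substrate with unclassifiable P1 residue: ", r)
    }
    hit[1]
  }, character(1))
  if (length(unique(cls)) < 2) {
    stop("panel must cover at least 2 P1 residue classes")
  }
  if (is.null(detection_floor)) {
    detection_floor <- 3 * sqrt(mean(sds^2))
  }
  class_rate <- vapply(names(classes), function(cl) {
    r <- rates[cls == cl]
    if (length(r) == 0) 0 else max(r)
  }, numeric(1))
  if (all(class_rate < detection_floor) || max(class_rate) <= 0) {
    return(structure(list(label = "undetermined",
                          evidence = setNames(rep(0, length(classes)),
                                              names(classes)),
                          source = "rate-panel"),
                     class = "specificity_call"))
  }
  evidence <- pmax(class_rate, 0) / max(class_rate)
  specificity_call_from_evidence(evidence, "rate-panel",
                                 absolute_threshold, relative_threshold)
}

#' First-order fit of a cleavage time course
#'
#' Least-squares fit of `f(t) = 1 - exp(-k t)` by one-dimensional
#' minimization of the residual sum of squares over `k` in `[0, k_max]`.
#' Fractions equal to 1 are shrunk to `1 - 1e-3` before fitting. An all-zero
#' course returns `k = 0`.
#'
#' @param tc A [cleavage_time_course()].
#' @param k_max Upper bound of the rate search (per minute).
#' @return List of class `"cleavage_rate"`: `substrate_name`, `k` (per
#'   minute), `residual` (sum of squared residuals).
#' @export
fit_first_order <- function(tc, k_max = 1) {
  t <- tc$times
  f <- pmin(tc$fraction_cleaved, 1 - 1e-3)
  if (sum(t > 0) < 2 && !all(f[t > 0] == 0)) {
    stop("need at least 2 nonzero time points")
  }
  rss <- function(k) sum((f - (1 - exp(-k * t)))^2)
  if (all(f == 0)) {
    return(structure(list(substrate_name = tc$substrate_name, k = 0,
                          residual = rss(0)),
                     class = "cleavage_rate"))
  }
  opt <- optimize(rss, c(0, k_max), tol = 1e-10)
  # optimize never probes the boundary exactly; keep 0 if it is no worse
  k <- if (rss(0) <= opt$objective) 0 else opt$minimum
  structure(list(substrate_name = tc$substrate_name, k = k,
                 residual = rss(k)),
            class = "cleavage_rate")
}

#' Fold difference in cleavage efficiency from rate ratio
#'
#' @param a,b `"cleavage_rate"` objects; `b` is the denominator.
#' @return List of class `"fold_difference"`: `numerator_id`,
#'   `denominator_id`, `fold`, `method = "rate-ratio"`.
#' @export
fold_difference_by_rate <- function(a, b) {
  if (b$k <= 0) {
    stop("denominator rate is zero: compare by titration_equivalence() instead")
  }
  structure(list(numerator_id = a$substrate_name,
                 denominator_id = b$substrate_name,
                 fold = a$k / b$k, method = "rate-ratio"),
            class = "fold_difference")
}

#' Fold difference from an enzyme titration
#'
#' The amount of enzyme reaching `target_fraction` cleavage is located on
#' each curve by piecewise-linear interpolation on log-amount (non-monotone
#' wiggles from measurement noise are flattened by a running maximum first);
#' the fold is the ratio of the two amounts, denominator curve over
#' numerator curve -- the amount ratio needed for the same extent of
#' cleavage.
#'
#' @param curve_a,curve_b Data.frames with columns `amount` (enzyme amount,
#'   positive, increasing) and `fraction` (fraction cleaved).
#' @param target_fraction Fraction of substrate cleaved to equate at.
#' @return List of class `"fold_difference"` with `method = "titration"`;
#'   `fold > 1` means curve a needs less enzyme (is the stronger activity).
#' @export
titration_equivalence <- function(curve_a, curve_b, target_fraction = 0.5) {
  locate <- function(curve, label) {
    ord <- order(curve$amount)
    a <- curve$amount[ord]
    f <- cummax(curve$fraction[ord])
    if (any(a <= 0)) stop("enzyme amounts must be positive")
    if (target_fraction < min(f) || target_fraction > max(f)) {
      stop(sprintf(
        "curve %s does not bracket target fraction %.3g (achievable range %.3g-%.3g)",
        label, target_fraction, min(f), max(f)))
    }
    exp(approx(f, log(a), xout = target_fraction, ties = "ordered")$y)
  }
  amount_a <- locate(curve_a, "a")
  amount_b <- locate(curve_b, "b")
  structure(list(numerator_id = "curve_a", denominator_id = "curve_b",
                 fold = amount_b / amount_a, method = "titration",
                 amount_a = amount_a, amount_b = amount_b),
            class = "fold_difference")
}

#' @export
print.fold_difference <- function(x, ...) {
  cat(sprintf("%.3g-fold (%s): %s vs %s\n", x$fold, x$method,
              x$numerator_id, x$denominator_id))
  invisible(x)
}

#' Initial-rate table for a chromogenic panel
#'
#' Convenience wrapper fitting [initial_rate()] to every series of a panel
#' and returning the layout [classify_specificity_from_rates()] accepts.
#'
#' @param series_list List of [absorbance_series()].
#' @param fit_window Minutes bounding the fitted points; the full series by
#'   default (synthetic series are linear throughout; for saturating real
#'   curves restrict to the early window).
#' @return Data.frame with columns `substrate_id`, `sequence`, `rate`, `sd`.
#' @export
panel_rates <- function(series_list, fit_window = c(0, Inf)) {
  rows <- lapply(series_list, function(s) {
    r <- initial_rate(s, fit_window = fit_window)
    data.frame(substrate_id = s$substrate_id,
               sequence = s$substrate_sequence,
               rate = r$rate, sd = r$sd)
  })
  do.call(rbind, rows)
}
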
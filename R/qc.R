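#' Reliability of a monocular test
#'
#' A test is unreliable when false positives exceed 10%, or when false
#' negatives exceed 10% while fixation losses simultaneously exceed 20%.
#' All comparisons are strict (a test at exactly 10% false positives is
#' reliable). False negatives and fixation losses are only disqualifying in
#' conjunction because they are weaker reliability markers than false
#' positives.
#'
#' @param vf a [monocular_vf()], or a single false-positive rate when
#'   `fn_rate`/`fl_rate` are given directly.
#' @param fn_rate,fl_rate rates in `[0, 1]` when calling with raw numbers.
#' @return `TRUE` when the test is reliable.
#' @export
check_reliability <- function(vf, fn_rate = NULL, fl_rate = NULL) {
  if (inherits(vf, "monocular_vf")) {
    fp <- vf$fp_rate; fn <- vf$fn_rate; fl <- vf$fl_rate
  } else {
    fp <- vf; fn <- fn_rate; fl <- fl_rate
  }
  if (is.null(fp) || is.null(fn) || is.null(fl) ||
      anyNA(c(fp, fn, fl)))
    stop_vf("reliability indices missing: refusing to treat as reliable")
  !(fp > 0.10 | (fn > 0.10 & fl > 0.20))
}

#' Select the analysis visit for one patient
#'
#' A visit is reliable only when both eyes' tests pass
#' [check_reliability()]. Patients with fewer than two reliable visits are
#' excluded (to mitigate the perimetric learning effect, the first usable
#' test alone is not trusted); otherwise the most recent reliable visit is
#' retained. Date ties are broken by stable input order.
#'
#' @param pairs list of [vf_pair()] objects, all for the same patient.
#' @return The selected `vf_pair`, or `NULL` when the patient is excluded.
#' @export
select_analysis_visit <- function(pairs) {
  if (length(pairs) == 0L) {
    message("select_analysis_visit: no visits supplied")
    return(NULL)
  }
  ok <- vapply(pairs, function(p) {
    check_reliability(p$right) && check_reliability(p$left)
  }, logical(1))
  if (sum(ok) < 2L) return(NULL)
  rel <- pairs[ok]
  dates <- as.Date(vapply(rel, function(p) format(p$right$test_date),
                          character(1)))
  latest <- which(dates == max(dates))
  if (length(latest) > 1L)
    message("select_analysis_visit: date tie, keeping first in input order")
  rel[[latest[1L]]]
}

#' Vertical-midline asymmetry of one monocular field
#'
#' Mean of the absolute pointwise sensitivity differences (raw dB) between
#' mirror locations across the vertical midline, over the 26 mirror pairs
#' with `|x| <= 21`. The unpaired nasal-extension points cannot enter by
#' construction. Homonymous (post-chiasmatic) defects respect the vertical
#' midline and drive this statistic up; glaucomatous defects typically do
#' not.
#'
#' @param vf a [monocular_vf()].
#' @return Mean absolute mirror difference in dB (>= 0).
#' @export
vertical_midline_asymmetry <- function(vf) {
  stopifnot(inherits(vf, "monocular_vf"))
  g <- grid_24_2(vf$eye)
  gp <- g[g$x > 0 & g$x <= 21L, ]
  right_half <- vf$sensitivities[gp$name]
  left_half <- vf$sensitivities[loc_names(-gp$x, gp$y)]
  mean(abs(right_half - left_half))
}

#' Interocular correlation of a visual-field pair
#'
#' Pearson correlation between the two eyes' sensitivities over the 52
#' locations common to both eyes (the two nasal-extension points of each
#' eye are excluded). Homonymous defects make the two fields similar and
#' push this towards 1.
#'
#' @param pair a [vf_pair()].
#' @return Correlation in `[-1, 1]`, or `NA` with a warning when either eye
#'   has zero variance.
#' @export
interocular_correlation <- function(pair) {
  stopifnot(inherits(pair, "vf_pair"))
  g <- ivf_grid()
  r <- pair$right$sensitivities[g$name]
  l <- pair$left$sensitivities[g$name]
  if (stats::sd(r) == 0 || stats::sd(l) == 0) {
    warning("interocular_correlation: zero variance in one eye, returning NA")
    return(NA_real_)
  }
  stats::cor(r, l)
}

#' Homonymous-defect (neurological) screen
#'
#' Kihara-style screen: each pair is summarised by its vertical visual-field
#' asymmetry (mean of the two monocular [vertical_midline_asymmetry()]
#' values) and its [interocular_correlation()]. Pairs with both statistics
#' high cluster together and may carry a post-chiasmatic neurological
#' defect. Flagging marks the pair for human review; it does not by itself
#' exclude the patient.
#'
#' The default thresholds (5 dB, 0.6) are documented heuristics for the
#' cluster, which in the original procedure was delineated by expert review;
#' both are configurable.
#'
#' @param pair a [vf_pair()].
#' @param asym_threshold flag when asymmetry >= this many dB.
#' @param corr_threshold flag when interocular correlation >= this value.
#' @return Object of class `neuro_screen` with fields
#'   `vertical_asymmetry_db`, `interocular_r`, `flagged`.
#' @export
neuro_screen <- function(pair, asym_threshold = 5, corr_threshold = 0.6) {
  stopifnot(inherits(pair, "vf_pair"))
  asym <- mean(c(vertical_midline_asymmetry(pair$right),
                 vertical_midline_asymmetry(pair$left)))
  r <- interocular_correlation(pair)
  flagged <- if (is.na(r)) {
    warning("neuro_screen: undefined interocular correlation, not flagging")
    FALSE
  } else {
    asym >= asym_threshold && r >= corr_threshold
  }
  structure(list(vertical_asymmetry_db = asym, interocular_r = r,
                 flagged = flagged),
            class = "neuro_screen")
}

#' @export
print.neuro_screen <- function(x, ...) {
  cat(sprintf("<neuro_screen> asymmetry %.2f dB, interocular r %s, %s\n",
              x$vertical_asymmetry_db,
              ifelse(is.na(x$interocular_r), "NA",
                     sprintf("%.3f", x$interocular_r)),
              if (x$flagged) "FLAGGED for review" else "not flagged"))
  invisible(x)
}
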
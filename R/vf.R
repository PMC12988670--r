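#' Construct a monocular visual-field test record
#'
#' Validates and packages one eye's 24-2 test: the 54 located sensitivities,
#' foveal sensitivity, and the reliability indices. Sensitivities below 0 dB
#' are coerced to 0 (quadratic summation is not meaningful for negative
#' sensitivities); values must not exceed 50 dB.
#'
#' @param patient_id opaque identifier.
#' @param eye `"right"` or `"left"` (or `"OD"`/`"OS"`).
#' @param test_date a `Date` (or ISO-8601 string).
#' @param sensitivities named numeric vector of dB values covering exactly
#'   the eye's 54 grid locations (names as in [grid_24_2()]), or an unnamed
#'   vector of length 54 in canonical grid order.
#' @param foveal_db foveal sensitivity in dB.
#' @param fp_rate,fn_rate,fl_rate false-positive, false-negative and
#'   fixation-loss fractions in `[0, 1]`.
#' @param age,gender optional demographics carried along for later stages.
#' @return An object of class `monocular_vf`.
#' @export
monocular_vf <- function(patient_id, eye, test_date, sensitivities, foveal_db,
                         fp_rate = NA_real_, fn_rate = NA_real_,
                         fl_rate = NA_real_, age = NA_real_,
                         gender = NA_integer_) {
  eye <- normalize_eye(eye)
  g <- grid_24_2(eye)
  s <- as.numeric(sensitivities)
  if (is.null(names(sensitivities))) {
    if (length(s) != 54L) stop_vf("expected 54 sensitivities, got %d", length(s))
    names(s) <- g$name
  } else {
    names(s) <- names(sensitivities)
    missing <- setdiff(g$name, names(s))
    extra <- setdiff(names(s), g$name)
    if (length(missing))
      stop_vf("missing grid locations: %s", paste(missing, collapse = ", "))
    if (length(extra))
      stop_vf("locations not on the %s-eye 24-2 grid: %s", eye,
              paste(extra, collapse = ", "))
    s <- s[g$name]
  }
  if (anyNA(s)) stop_vf("missing sensitivity values")
  s[s < 0] <- 0
  if (any(s > 50)) stop_vf("sensitivity above 50 dB")
  foveal_db <- max(0, as.numeric(foveal_db))
  for (nm in c("fp_rate", "fn_rate", "fl_rate")) {
    v <- get(nm)
    if (!is.na(v) && (v < 0 || v > 1)) stop_vf("%s outside [0, 1]", nm)
  }
  structure(
    list(patient_id = as.character(patient_id), eye = eye,
         test_date = as.Date(test_date), sensitivities = s,
         foveal_db = foveal_db, fp_rate = fp_rate, fn_rate = fn_rate,
         fl_rate = fl_rate, age = age, gender = gender),
    class = "monocular_vf")
}

#' @export
print.monocular_vf <- function(x, ...) {
  cat(sprintf("<monocular_vf> patient %s, %s eye, %s\n", x$patient_id, x$eye,
              format(x$test_date)))
  cat(sprintf("  mean sensitivity %.1f dB, fovea %.1f dB, FP/FN/FL %s/%s/%s\n",
              mean(x$sensitivities), x$foveal_db,
              format(x$fp_rate), format(x$fn_rate), format(x$fl_rate)))
  invisible(x)
}

#' Pair the two eyes' tests from one visit
#'
#' @param right,left `monocular_vf` objects with matching `patient_id` and
#'   `test_date` and the expected lateralities.
#' @return An object of class `vf_pair`.
#' @export
vf_pair <- function(right, left) {
  stopifnot(inherits(right, "monocular_vf"), inherits(left, "monocular_vf"))
  if (right$eye != "right" || left$eye != "left")
    stop_vf("vf_pair(right=, left=) lateralities do not match the slots")
  if (right$patient_id != left$patient_id)
    stop_vf("pair mixes patients %s and %s", right$patient_id, left$patient_id)
  if (right$test_date != left$test_date)
    stop_vf("pair mixes visits %s and %s (same-visit tests required)",
            format(right$test_date), format(left$test_date))
  structure(list(right = right, left = left), class = "vf_pair")
}

#' Integrate a monocular pair into a binocular visual field
#'
#' Applies quadratic binocular summation `B = sqrt(R^2 + L^2)` pointwise over
#' the 52 locations shared by the two eyes (the nasal-extension points drop
#' out), and likewise to the two foveal sensitivities. `ivf_ms` is the
#' arithmetic mean of the 52 binocular values.
#'
#' @param pair a [vf_pair()].
#' @return An object of class `integrated_vf` with fields `patient_id`,
#'   `test_date`, `sensitivities` (named, 52 values), `ivf_ms`,
#'   `foveal_binoc_db`.
#' @export
integrate_pair <- function(pair) {
  stopifnot(inherits(pair, "vf_pair"))
  g <- ivf_grid()
  r <- pair$right$sensitivities[g$name]
  l <- pair$left$sensitivities[g$name]
  b <- binocular_summation(r, l)
  structure(
    list(patient_id = pair$right$patient_id,
         test_date = pair$right$test_date,
         sensitivities = b,
         ivf_ms = mean(b),
         foveal_binoc_db = binocular_summation(pair$right$foveal_db,
                                               pair$left$foveal_db)),
    class = "integrated_vf")
}

#' @export
print.integrated_vf <- function(x, ...) {
  cat(sprintf("<integrated_vf> patient %s, %s: IVF MS %.2f dB, fovea %.2f dB\n",
              x$patient_id, format(x$test_date), x$ivf_ms, x$foveal_binoc_db))
  invisible(x)
}

# Stack integrated fields into the n x 52 matrix the archetype engine uses.
#' Matrix of integrated fields
#'
#' @param ivfs a list of `integrated_vf` objects.
#' @return Numeric matrix, one row per patient (rownames = patient ids),
#'   columns in canonical grid order.
#' @export
ivf_matrix <- function(ivfs) {
  if (inherits(ivfs, "integrated_vf")) ivfs <- list(ivfs)
  g <- ivf_grid()
  m <- do.call(rbind, lapply(ivfs, function(v) v$sensitivities[g$name]))
  rownames(m) <- unname(vapply(ivfs, function(v) v$patient_id, character(1)))
  colnames(m) <- g$name
  m
}
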
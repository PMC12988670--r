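# CSV readers/writers for the pipeline's plain-text interchange formats.

#' Read monocular visual fields from long-format CSV
#'
#' Expects columns `patient_id, eye (OD/OS), test_date (ISO-8601), x_deg,
#' y_deg, sensitivity_db`. Rows are aggregated by (patient, eye, date) and
#' each test is validated against the eye's 24-2 grid: missing, duplicate
#' or off-grid locations reject that test with an itemised message while
#' the remaining tests load. Per-test metadata (reliability rates, foveal
#' sensitivity, demographics) is joined from `meta` when supplied.
#'
#' @param path VF CSV file.
#' @param meta optional metadata data frame (see [read_meta_csv()]) or path.
#' @param strict when `TRUE`, any validation error aborts.
#' @return List of [monocular_vf()] objects, with attribute `errors`
#'   (character vector of per-record validation messages).
#' @export
read_vf_csv <- function(path, meta = NULL, strict = FALSE) {
  if (!file.exists(path)) stop_vf("no such file: %s", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "eye", "test_date", "x_deg", "y_deg",
            "sensitivity_db")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_vf("%s lacks columns: %s", path, paste(miss, collapse = ", "))
  if (is.character(meta)) meta <- read_meta_csv(meta)
  key <- interaction(d$patient_id, d$eye, d$test_date, drop = TRUE)
  groups <- split(seq_len(nrow(d)), key)
  errors <- character()
  out <- list()
  for (idx in groups) {
    rec <- d[idx, ]
    pid <- rec$patient_id[1]; eye_raw <- rec$eye[1]; date <- rec$test_date[1]
    tag <- sprintf("%s/%s/%s (lines %d..%d)", pid, eye_raw, date,
                   min(idx) + 1L, max(idx) + 1L)
    res <- tryCatch({
      eye <- normalize_eye(eye_raw)
      g <- grid_24_2(eye)
      nm <- loc_names(rec$x_deg, rec$y_deg)
      dup <- nm[duplicated(nm)]
      if (length(dup))
        stop_vf("duplicate locations: %s", paste(unique(dup), collapse = ", "))
      s <- setNames(rec$sensitivity_db, nm)
      m <- meta[meta$patient_id == pid &
                  meta$eye == eye_raw & meta$test_date == date, ]
      if (!is.null(meta) && nrow(m) == 1L) {
        monocular_vf(pid, eye, date, s, m$foveal_db, m$fp_rate, m$fn_rate,
                     m$fl_rate, age = m$age_years, gender = m$gender)
      } else {
        monocular_vf(pid, eye, date, s, foveal_db = 0)
      }
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) errors <- c(errors, paste0(tag, ": ", res))
    else out[[length(out) + 1L]] <- res
  }
  if (length(errors)) {
    if (strict) stop_vf("validation errors:\n%s", paste(errors, collapse = "\n"))
    for (e in errors) message("read_vf_csv: rejected ", e)
  }
  attr(out, "errors") <- errors
  out
}

#' Read per-test metadata CSV
#'
#' Columns: `patient_id, eye, test_date, fp_rate, fn_rate, fl_rate,
#' foveal_db, age_years, gender`.
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_meta_csv <- function(path) {
  if (!file.exists(path)) stop_vf("no such file: %s", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "eye", "test_date", "fp_rate", "fn_rate",
            "fl_rate", "foveal_db")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_vf("%s lacks columns: %s", path, paste(miss, collapse = ", "))
  d
}

# Group monocular tests into same-visit pairs, per patient.
# Returns a list keyed by patient id, each element a list of vf_pair.
#' Pair monocular tests by patient and visit
#'
#' @param vfs list of [monocular_vf()] objects.
#' @return Named list (by patient) of lists of [vf_pair()] objects; visits
#'   with only one eye tested are dropped.
#' @export
make_pairs <- function(vfs) {
  pk <- vapply(vfs, function(v) v$patient_id, character(1))
  out <- list()
  for (pid in unique(pk)) {
    mine <- vfs[pk == pid]
    dates <- vapply(mine, function(v) format(v$test_date), character(1))
    pairs <- list()
    for (dt in sort(unique(dates))) {
      at <- mine[dates == dt]
      eyes <- vapply(at, function(v) v$eye, character(1))
      if (any(eyes == "right") && any(eyes == "left"))
        pairs[[length(pairs) + 1L]] <- vf_pair(at[[which(eyes == "right")[1]]],
                                               at[[which(eyes == "left")[1]]])
    }
    out[[pid]] <- pairs
  }
  out
}

#' Write integrated fields to wide CSV
#'
#' One row per patient: `patient_id`, the 52 binocular sensitivities in
#' canonical order (columns named like `x-9y21`), `ivf_ms`,
#' `foveal_binoc_db`.
#'
#' @param ivfs list of `integrated_vf` objects.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_ivf_csv <- function(ivfs, path) {
  g <- ivf_grid()
  m <- ivf_matrix(ivfs)
  d <- data.frame(patient_id = rownames(m), check.names = FALSE)
  d[g$name] <- as.data.frame(m)
  d$ivf_ms <- vapply(ivfs, function(v) v$ivf_ms, numeric(1))
  d$foveal_binoc_db <- vapply(ivfs, function(v) v$foveal_binoc_db, numeric(1))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read integrated fields from wide CSV
#'
#' @param path a CSV written by [write_ivf_csv()].
#' @return Data frame with `patient_id`, the 52 location columns, `ivf_ms`,
#'   `foveal_binoc_db`.
#' @export
read_ivf_csv <- function(path) {
  if (!file.exists(path)) stop_vf("no such file: %s", path)
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  g <- ivf_grid()
  miss <- setdiff(g$name, names(d))
  if (length(miss))
    stop_vf("%s lacks IVF columns: %s", path, paste(miss, collapse = ", "))
  d
}

#' Read questionnaire responses CSV
#'
#' Columns: `patient_id, item_id, response_level`.
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_qol_csv <- function(path) {
  if (!file.exists(path)) stop_vf("no such file: %s", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "item_id", "response_level")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_vf("%s lacks columns: %s", path, paste(miss, collapse = ", "))
  d
}

# Association results as portable JSON (coefficients + cutpoints per
# aspect), so `predict` can run in a separate process from `associate`.
write_assoc_json <- function(assoc, path) {
  stopifnot(inherits(assoc, "qol_association"))
  obj <- list(schema_version = 1L, alpha = assoc$alpha,
              n_tests = assoc$n_tests, threshold = assoc$threshold,
              predictors = assoc$predictors,
              foveal_adjusted = assoc$foveal_adjusted,
              models = lapply(assoc$models, function(m) {
                list(type = m$type,
                     coefficients = as.list(m$coefficients),
                     zeta = as.numeric(m$zeta), values = m$values,
                     se = as.list(m$se))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

read_assoc_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(obj$models, function(m) {
    list(type = m$type, coefficients = unlist(m$coefficients),
         zeta = as.numeric(m$zeta), values = as.numeric(m$values),
         se = unlist(m$se))
  })
  structure(list(table = NULL, models = models, alpha = obj$alpha,
                 n_tests = obj$n_tests, threshold = obj$threshold,
                 predictors = obj$predictors,
                 foveal_adjusted = obj$foveal_adjusted,
                 notes = character()),
            class = "qol_association")
}
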
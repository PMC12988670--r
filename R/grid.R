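#' Humphrey 24-2 test-point layout for one eye
#'
#' Enumerates the 54 test locations of the 24-2 pattern in visual-field
#' coordinates shared by both eyes: negative `x` is the left visual field,
#' positive `y` the superior field. Rows at `y = +/-21` hold 4 points, rows
#' at `y = +/-15` hold 6, rows at `y = +/-9` hold 8, and rows at `y = +/-3`
#' hold 8 plus one nasal-extension point at `x = -27` (right eye) or
#' `x = +27` (left eye). The two blind-spot locations are `(15, +/-3)` for
#' the right eye and `(-15, +/-3)` for the left eye.
#'
#' @param eye `"right"` or `"left"` (also accepts `"OD"`/`"OS"`).
#' @return A data frame with integer columns `x`, `y`, a character column
#'   `name` (e.g. `"x-9y21"`), and a logical column `blind_spot`, in
#'   canonical row-major order (`y` descending, `x` ascending).
#' @examples
#' g <- grid_24_2("right")
#' nrow(g)            # 54
#' sum(g$x == -27)    # 2 nasal-extension points
#' @export
grid_24_2 <- function(eye) {
  eye <- normalize_eye(eye)
  rows <- list(
    `21` = seq(-9, 9, by = 6),
    `15` = seq(-15, 15, by = 6),
    `9`  = seq(-21, 21, by = 6),
    `3`  = seq(-21, 21, by = 6)
  )
  nasal_x <- if (eye == "right") -27L else 27L
  ys <- c(21L, 15L, 9L, 3L, -3L, -9L, -15L, -21L)
  out <- do.call(rbind, lapply(ys, function(y) {
    x <- as.integer(rows[[as.character(abs(y))]])
    if (abs(y) == 3L) x <- sort(c(x, nasal_x))
    data.frame(x = x, y = y)
  }))
  bs_x <- if (eye == "right") 15L else -15L
  out$name <- loc_names(out$x, out$y)
  out$blind_spot <- out$x == bs_x & abs(out$y) == 3L
  stopifnot(nrow(out) == 54L)
  out
}

normalize_eye <- function(eye) {
  if (length(eye) != 1L || is.na(eye)) stop_vf("eye must be a single value")
  e <- tolower(as.character(eye))
  if (e %in% c("right", "od", "r")) return("right")
  if (e %in% c("left", "os", "l")) return("left")
  stop_vf("unknown laterality: %s", eye)
}

#' Shared binocular (integrated) visual-field grid
#'
#' The 52 locations present in both eyes' 24-2 layouts, i.e. all points with
#' `|x| <= 21`; each eye's two nasal-extension points drop out. Blind-spot
#' locations are retained: each is a regular point for the fellow eye.
#'
#' @return Data frame with columns `x`, `y`, `name` in canonical order.
#' @export
ivf_grid <- function() {
  r <- grid_24_2("right")
  g <- r[abs(r$x) <= 21L, c("x", "y", "name")]
  rownames(g) <- NULL
  stopifnot(nrow(g) == 52L)
  g
}

#' Binocular summation of two monocular sensitivities
#'
#' Combines pointwise monocular sensitivities `R` and `L` (raw dB) into a
#' binocular sensitivity `B = sqrt(R^2 + L^2)` (quadratic summation).
#' Vectorised; commutative; `max(r, l) <= B <= sqrt(2) * max(r, l)`.
#'
#' @param r_db,l_db non-negative finite sensitivities in dB.
#' @return Binocular sensitivities in dB.
#' @examples
#' binocular_summation(30, 40) # 50
#' @export
binocular_summation <- function(r_db, l_db) {
  if (!all(is.finite(r_db)) || !all(is.finite(l_db)))
    stop_vf("sensitivities must be finite")
  if (any(r_db < 0) || any(l_db < 0))
    stop_vf("negative sensitivity: values below 0 dB must be clamped at import")
  sqrt(r_db^2 + l_db^2)
}
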
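#' Write an archetype model to JSON
#'
#' Serialises the model (grid, archetypes in row-major order, fit metadata)
#' at full double precision, so a read-back model decomposes fields
#' identically to the original.
#'
#' @param model an [fit_archetypes()] model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "archetype_model"))
  obj <- list(
    schema_version = 1L,
    grid = model$grid,
    K = model$K,
    Z = as.numeric(t(model$Z)), # row-major
    mean_weights = model$mean_weights,
    fit = list(rss = model$rss, rss_trace = model$rss_trace,
               iterations = model$iterations, reinits = model$reinits,
               best_restart = model$best_restart, restarts = model$restarts,
               max_iter = model$max_iter, tol = model$tol,
               penalty = model$penalty, seed = model$seed))
  # 17 significant digits: lossless decimal round-trip for IEEE doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read an archetype model from JSON
#'
#' @param path a file written by [write_model()].
#' @return An `archetype_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop_vf("unsupported model schema in %s", path)
  K <- as.integer(obj$K)
  grid <- as.character(obj$grid)
  Z <- matrix(as.numeric(obj$Z), nrow = K, byrow = TRUE,
              dimnames = list(paste0("AT", seq_len(K)), grid))
  f <- obj$fit
  structure(
    list(K = K, Z = Z, grid = grid,
         mean_weights = as.numeric(obj$mean_weights),
         rss = f$rss, rss_trace = as.numeric(f$rss_trace),
         iterations = f$iterations, reinits = f$reinits,
         best_restart = f$best_restart, restarts = f$restarts,
         max_iter = f$max_iter, tol = f$tol, penalty = f$penalty,
         seed = f$seed),
    class = "archetype_model")
}

#' Heatmap-style display of fitted archetypes
#'
#' Draws each archetype as a filled grid over the 52 binocular locations
#' (darker = lower sensitivity), the conventional way visual-field loss
#' patterns are displayed.
#'
#' @param x an `archetype_model` whose grid is the standard binocular grid.
#' @param ... unused.
#' @export
plot.archetype_model <- function(x, ...) {
  g <- ivf_grid()
  if (!identical(x$grid, g$name)) stop_vf("model grid is not the 24-2 binocular grid")
  k <- x$K
  nc <- ceiling(sqrt(k))
  nr <- ceiling(k / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::gray.colors(64, start = 0.05, end = 0.98)
  top <- sqrt(2) * 50
  for (j in seq_len(k)) {
    v <- x$Z[j, ]
    graphics::plot(g$x, g$y, type = "n", axes = FALSE, xlab = "", ylab = "",
                   main = sprintf("AT%d (%.0f%%)", j, 100 * x$mean_weights[j]),
                   asp = 1)
    idx <- pmax(1L, pmin(64L, 1L + floor(63 * v / top)))
    graphics::symbols(g$x, g$y, squares = rep(5.6, nrow(g)), inches = FALSE,
                      add = TRUE, bg = pal[idx], fg = "grey40")
  }
  invisible(x)
}
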
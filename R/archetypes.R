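#' Simplex-constrained least squares
#'
#' Projects a target vector on the convex hull of the rows of `basis`:
#' returns the weights minimising `||target - t(weights) %*% basis||^2`
#' subject to `weights >= 0` and `sum(weights) == 1`. The active set is
#' found by non-negative least squares on the system augmented with a
#' constant row of magnitude `penalty` (the classical sum-to-one device),
#' then the weights on that support are refit exactly under the equality
#' constraint, so the returned weights sum to one to machine precision.
#'
#' @param target numeric vector of length `d`.
#' @param basis numeric `m x d` matrix whose rows span the hull.
#' @param penalty magnitude of the augmented sum-to-one row (default 200).
#' @return List with `weights` (length `m`, simplex) and `residual` (the
#'   squared reconstruction residual).
#' @examples
#' b <- rbind(c(1, 0), c(0, 1))
#' simplex_ls(c(0.3, 0.7), b)$weights  # 0.3, 0.7
#' @export
simplex_ls <- function(target, basis, penalty = 200) {
  basis <- as.matrix(basis)
  target <- as.numeric(target)
  if (nrow(basis) < 1L) stop_vf("empty basis")
  if (length(target) != ncol(basis))
    stop_vf("target length %d does not match basis dimension %d",
            length(target), ncol(basis))
  if (!all(is.finite(target)) || !all(is.finite(basis)))
    stop_vf("non-finite input")
  fit <- cpp_simplex_ls(matrix(target, nrow = 1L), basis, penalty)
  list(weights = as.numeric(fit$weights), residual = as.numeric(fit$rss))
}

# Batch form used internally: one row of W / rss per row of `targets`.
simplex_ls_batch <- function(targets, basis, penalty = 200) {
  fit <- cpp_simplex_ls(as.matrix(targets), as.matrix(basis), penalty)
  list(weights = fit$weights, rss = as.numeric(fit$rss))
}

#' Fit an archetype model by alternating simplex-constrained least squares
#'
#' Cutler-Breiman archetypal analysis of the field matrix `X` (rows =
#' patients, columns = the 52 binocular grid locations; any column
#' dimension is accepted). Each restart seeds the composition matrix from
#' `k` random data points and alternates: (i) weight step - every field is
#' projected on the current archetypes by [simplex_ls()]; (ii) unconstrained
#' solve for ideal archetypes; (iii) composition step - each ideal archetype
#' is projected back on the convex hull of the data. Training RSS
#' `||X - W Z||_F^2` is monitored every iteration and is non-increasing by
#' construction (an iteration that would increase it is rolled back and the
#' restart stops). The restart with the lowest RSS wins. An archetype that
#' loses all weight is re-seeded on the worst-reconstructed field.
#'
#' @param X numeric matrix of fields (one row per patient).
#' @param k number of archetypes, `1 <= k < nrow(X)`.
#' @param restarts random restarts (100 matches the reference procedure;
#'   tests use 10-20).
#' @param max_iter iteration cap per restart.
#' @param tol relative RSS improvement below which a restart stops.
#' @param penalty sum-to-one penalty magnitude, see [simplex_ls()].
#' @param seed integer seed; restart initialisations come from independent
#'   sub-streams so results do not depend on evaluation order.
#' @return Object of class `archetype_model`: `K`, `Z` (k x d archetype
#'   matrix, rows ordered by descending mean training weight and named
#'   `AT1..ATk`), `grid` (column names), `mean_weights`, `rss`, `rss_trace`,
#'   `best_restart`, `iterations`, `reinits`, and the fit hyperparameters.
#' @export
fit_archetypes <- function(X, k, restarts = 100L, max_iter = 100L,
                           tol = 1e-6, penalty = 200, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1L) stop_vf("k must be >= 1")
  if (k >= n) stop_vf("need more data points (%d) than archetypes (%d)", n, k)
  if (!all(is.finite(X))) stop_vf("non-finite values in X")

  best <- NULL
  best_restart <- NA_integer_
  for (r in seq_len(restarts)) {
    idx <- with_seed(mix_seed(seed, 7771L, r), sample.int(n, k))
    fit <- cpp_aa_fit(X, idx, as.integer(max_iter), tol, penalty)
    if (is.null(best) || fit$rss < best$rss) {
      best <- fit
      best_restart <- r
    }
  }
  Z <- best$Z
  W <- best$W
  mw <- colMeans(W)
  ord <- order(mw, decreasing = TRUE)
  Z <- Z[ord, , drop = FALSE]
  mw <- mw[ord]
  rownames(Z) <- paste0("AT", seq_len(k))
  colnames(Z) <- colnames(X)
  structure(
    list(K = as.integer(k), Z = Z, grid = colnames(X),
         mean_weights = unname(mw), rss = best$rss,
         rss_trace = as.numeric(best$rss_trace),
         iterations = best$iterations, reinits = best$reinits,
         best_restart = best_restart, restarts = as.integer(restarts),
         max_iter = as.integer(max_iter), tol = tol, penalty = penalty,
         seed = as.integer(seed)),
    class = "archetype_model")
}

#' @export
print.archetype_model <- function(x, ...) {
  cat(sprintf(
    "<archetype_model> K = %d on %d locations; training RSS %.4g\n",
    x$K, length(x$grid), x$rss))
  cat(sprintf("  best of %d restarts (restart %d, %d iterations); seed %d\n",
              x$restarts, x$best_restart, x$iterations, x$seed))
  cat("  mean training weights (%):",
      paste(sprintf("%.1f", 100 * x$mean_weights), collapse = " "), "\n")
  invisible(x)
}

#' Decompose fields into archetype weights
#'
#' Projects each field on the convex hull of the model's archetypes and
#' reports simplex weights as percentages summing to 100.
#'
#' @param model an [fit_archetypes()] model.
#' @param x an `integrated_vf`, a numeric vector on the model grid, or a
#'   matrix/data frame of fields (one row each).
#' @return Data frame with columns `AT1..ATK` (percent) and `rss`; row names
#'   carry patient ids when available.
#' @export
decompose <- function(model, x) {
  stopifnot(inherits(model, "archetype_model"))
  if (inherits(x, "integrated_vf")) {
    m <- matrix(x$sensitivities[model$grid], nrow = 1L,
                dimnames = list(x$patient_id, model$grid))
    if (anyNA(m)) stop_vf("field does not cover the model grid")
  } else if (is.null(dim(x))) {
    if (length(x) != length(model$grid))
      stop_vf("field length %d does not match model grid (%d locations)",
              length(x), length(model$grid))
    m <- matrix(as.numeric(x), nrow = 1L)
  } else {
    m <- as.matrix(x)
    if (!is.null(colnames(m)) && all(model$grid %in% colnames(m)))
      m <- m[, model$grid, drop = FALSE]
    if (ncol(m) != length(model$grid))
      stop_vf("field matrix has %d columns, model grid has %d",
              ncol(m), length(model$grid))
  }
  fit <- simplex_ls_batch(m, model$Z, model$penalty)
  out <- as.data.frame(100 * fit$weights)
  names(out) <- rownames(model$Z)
  out$rss <- fit$rss
  rownames(out) <- rownames(m)
  out
}

#' Cross-validate the number of archetypes
#'
#' Partitions patients once into `folds` folds (seeded; the assignment is
#' shared across all candidate `k`), fits an archetype model on the training
#' folds for every `(k, fold)` with the stated restart policy, and scores
#' the held-out fold by the mean per-field squared residual of the simplex
#' projection on the fitted archetypes. Restart streams are derived from
#' `(seed, k, fold, restart)`, so changing the restart count does not change
#' the folds.
#'
#' @inheritParams fit_archetypes
#' @param k_min,k_max candidate archetype counts (inclusive), `k_min >= 2`.
#' @param folds number of folds (10 matches the reference procedure).
#' @return Object of class `cv_result`: a data frame with columns `k`,
#'   `fold`, `score`, plus attributes `seed`, `folds`, `normalization`
#'   (`"mean_per_field_rss"`) and `k_range`.
#' @export
crossvalidate_k <- function(X, k_min = 2L, k_max = 17L, folds = 10L,
                            restarts = 100L, max_iter = 100L, tol = 1e-6,
                            penalty = 200, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k_min < 2L) stop_vf("k_min must be >= 2")
  if (k_max < k_min) stop_vf("k_max must be >= k_min")
  if (folds <= 1L || n < folds) stop_vf("need 1 < folds <= n")
  fold_id <- with_seed(mix_seed(seed, 15551L),
                       sample(rep(seq_len(folds), length.out = n)))
  res <- vector("list", (k_max - k_min + 1L) * folds)
  i <- 0L
  for (k in seq.int(k_min, k_max)) {
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f)
      va <- which(fold_id == f)
      if (length(tr) <= k)
        stop_vf("training split for fold %d has %d patients, fewer than k = %d",
                f, length(tr), k)
      model <- fit_archetypes(X[tr, , drop = FALSE], k, restarts = restarts,
                              max_iter = max_iter, tol = tol,
                              penalty = penalty,
                              seed = mix_seed(seed, 3331L, k, f))
      sc <- simplex_ls_batch(X[va, , drop = FALSE], model$Z, penalty)
      i <- i + 1L
      res[[i]] <- data.frame(k = k, fold = f, score = mean(sc$rss))
    }
  }
  out <- do.call(rbind, res)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "folds") <- as.integer(folds)
  attr(out, "normalization") <- "mean_per_field_rss"
  attr(out, "k_range") <- c(k_min, k_max)
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Select the number of archetypes by the BIC slope criterion
#'
#' For each candidate `K`, fold scores at archetype counts from `K` upward
#' are pooled and two Gaussian least-squares models are compared: score as
#' a linear function of `k` versus a constant. With
#' `BIC = n * log(RSS/n) + p * log(n)` (p = 2 and 1), a positive
#' `BIC(slope) - BIC(null)` means no further slope is warranted from `K`
#' on; the smallest such `K` is selected. When the validation score still
#' declines over the whole range, `k_max` is returned with a warning.
#'
#' The `window` controls which counts enter each candidate's regression.
#' The default `"local"` pools the `span` counts `K, K+1, ...` - the local
#' question the slope criterion poses. `"tail"` pools every count
#' `>= K`; this variant gains power to detect the small residual decline
#' that extra archetypes always buy (noise chasing) as the scan range
#' widens, and therefore tends to over-select on wide scans (see the
#' methods vignette).
#'
#' @param cv a [crossvalidate_k()] result covering at least 3 consecutive
#'   candidate counts.
#' @param window `"local"` (default) or `"tail"`.
#' @param span number of counts in a local window (>= 2).
#' @return The selected `K` (integer) with attribute `delta_bic`, a data
#'   frame of the per-candidate BIC differences.
#' @export
select_k <- function(cv, window = c("local", "tail"), span = 3L) {
  stopifnot(inherits(cv, "cv_result") || is.data.frame(cv))
  window <- match.arg(window)
  if (span < 2L) stop_vf("span must be >= 2")
  ks <- sort(unique(cv$k))
  if (length(ks) < 3L) stop_vf("select_k needs at least 3 candidate counts")
  if (stats::sd(cv$score) == 0) {
    warning("select_k: all scores identical, returning k_min")
    out <- ks[1L]
    attr(out, "delta_bic") <- NULL
    return(out)
  }
  k_max <- max(ks)
  cand <- ks[ks < k_max]
  db <- vapply(cand, function(K) {
    kin <- ks[ks >= K]
    if (window == "local") kin <- kin[seq_len(min(span, length(kin)))]
    d <- cv[cv$k %in% kin, ]
    nobs <- nrow(d)
    rss1 <- sum(stats::resid(stats::lm(score ~ k, data = d))^2)
    rss0 <- sum((d$score - mean(d$score))^2)
    bic1 <- nobs * log(rss1 / nobs) + 2 * log(nobs)
    bic0 <- nobs * log(rss0 / nobs) + 1 * log(nobs)
    bic1 - bic0
  }, numeric(1))
  tab <- data.frame(k = cand, delta_bic = db, window = window,
                    span = if (window == "local") span else NA_integer_)
  pos <- which(db > 0)
  if (length(pos) == 0L) {
    warning("select_k: validation score still declining at k_max; returning k_max")
    out <- k_max
  } else {
    out <- cand[pos[1L]]
  }
  out <- as.integer(out)
  attr(out, "delta_bic") <- tab
  out
}
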
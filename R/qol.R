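#' Read a questionnaire item map
#'
#' The item map declares, per ordinal item: its identifier, its number of
#' ordered response levels, whether level 1 is the best response (items are
#' aligned so that after scoring, higher always means better), and an
#' optional subscale membership. Subscale scores replace their member items
#' as modelled "aspects" of vision-related quality of life, the usual
#' NEI-VFQ-25 convention.
#'
#' @param path YAML file with top-level keys `items` (list of `id`,
#'   `levels`, `level1_best`, optional `subscale`) and optional
#'   `missing_codes`.
#' @return Object of class `item_map`: a data frame with columns `item_id`,
#'   `levels`, `level1_best`, `subscale`, and attribute `missing_codes`.
#' @export
read_item_map <- function(path) {
  y <- yaml::read_yaml(path)
  items <- do.call(rbind, lapply(y$items, function(it) {
    data.frame(item_id = it$id, levels = as.integer(it$levels),
               level1_best = isTRUE(it$level1_best),
               subscale = it$subscale %||% NA_character_)
  }))
  if (any(items$levels < 2L)) stop_vf("items need >= 2 levels")
  if (anyDuplicated(items$item_id)) stop_vf("duplicate item ids in map")
  attr(items, "missing_codes") <- as.integer(y$missing_codes %||% integer())
  class(items) <- c("item_map", "data.frame")
  items
}

#' The shipped default item map
#'
#' 43 ordinal items compiled in the style of combined NEI-VFQ-25 / GQL-15
#' instruments: 10 items grouped into 4 subscales (near activities,
#' distance activities, driving, social functioning) and 33 standalone
#' items, giving 37 modelled aspects of vision-related quality of life.
#'
#' @return An `item_map`.
#' @export
default_item_map <- function() {
  read_item_map(system.file("extdata", "items_default.yaml",
                            package = "vfarch", mustWork = TRUE))
}

#' Score ordinal responses on the 0-100 scale
#'
#' After direction alignment (so that level 1 is best), a response at level
#' `l` of an `L`-level item scores `100 * (L - l) / (L - 1)`: the best
#' response scores 100, the worst 0, intermediate levels are equally
#' spaced. Responses matching a missing-value code score `NA`.
#'
#' @param raw data frame with columns `patient_id`, `item_id`,
#'   `response_level`.
#' @param map an [read_item_map()] item map.
#' @return Wide data frame: `patient_id` plus one 0-100 column per item.
#' @export
score_items <- function(raw, map) {
  stopifnot(all(c("patient_id", "item_id", "response_level") %in% names(raw)))
  unknown <- setdiff(unique(raw$item_id), map$item_id)
  if (length(unknown))
    stop_vf("responses reference unknown items: %s",
            paste(unknown, collapse = ", "))
  mc <- attr(map, "missing_codes")
  ids <- unique(as.character(raw$patient_id))
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(map))) {
    it <- map$item_id[j]
    L <- map$levels[j]
    rows <- raw[raw$item_id == it, ]
    lev <- rows$response_level
    is_miss <- lev %in% mc
    bad <- !is_miss & (lev < 1L | lev > L | lev != floor(lev))
    if (any(bad))
      stop_vf("item %s: response level %s outside 1..%d",
              it, paste(unique(lev[bad]), collapse = ","), L)
    l_eff <- if (map$level1_best[j]) lev else L + 1L - lev
    sc <- ifelse(is_miss, NA_real_, 100 * (L - l_eff) / (L - 1))
    out[[it]] <- sc[match(ids, as.character(rows$patient_id))]
  }
  out
}

#' Subscale scores
#'
#' A subscale scores the unweighted mean of its answered member items and
#' is missing only when none of its items was answered.
#'
#' @param item_scores wide data frame from [score_items()].
#' @param map the item map.
#' @return Data frame: `patient_id` plus one column per subscale.
#' @export
score_subscales <- function(item_scores, map) {
  subs <- unique(map$subscale[!is.na(map$subscale)])
  out <- data.frame(patient_id = item_scores$patient_id,
                    stringsAsFactors = FALSE)
  for (s in subs) {
    members <- map$item_id[!is.na(map$subscale) & map$subscale == s]
    miss <- setdiff(members, names(item_scores))
    if (length(miss))
      stop_vf("subscale %s references unscored items: %s", s,
              paste(miss, collapse = ", "))
    m <- as.matrix(item_scores[, members, drop = FALSE])
    out[[s]] <- rowMeans(m, na.rm = TRUE)
    out[[s]][rowSums(!is.na(m)) == 0L] <- NA_real_
  }
  out
}

#' Modelled QoL aspects
#'
#' The aspects entering the association analysis: one column per subscale
#' plus one per standalone (subscale-free) item. With the shipped map this
#' yields 37 aspects.
#'
#' @inheritParams score_subscales
#' @return Data frame `patient_id` + aspect columns.
#' @export
aspect_scores <- function(item_scores, map) {
  subs <- score_subscales(item_scores, map)
  standalone <- map$item_id[is.na(map$subscale)]
  cbind(subs, item_scores[, standalone, drop = FALSE])
}

#' Ordinal regression of QoL aspects on archetype weights
#'
#' Fits one proportional-odds (cumulative-logit) model per aspect: the
#' ordered aspect score as outcome; the archetype weights (percent,
#' excluding archetype 1, which is the normal-field reference absorbed by
#' the intercepts) plus age, gender and binocular foveal sensitivity as
#' predictors. The sign convention is that a positive coefficient means
#' higher (better) scores. Wald p-values are compared against the
#' Bonferroni threshold `alpha / n_tests`, applied to the whole ensemble of
#' aspects rather than per questionnaire. IVF mean sensitivity is
#' deliberately not a covariate (collinear with the weights);
#' `adjust_foveal = FALSE` reproduces the sensitivity analysis without the
#' foveal covariate.
#'
#' Aspects with fewer than 3 distinct observed scores fall back to binary
#' logistic regression with a notice; non-convergence is recorded per
#' aspect and does not abort the batch.
#'
#' @param aspects data frame `patient_id` + aspect score columns.
#' @param weights data frame `patient_id` + `AT1..ATK` percent weights
#'   (AT1 is dropped internally if present).
#' @param covariates data frame `patient_id`, `age`, `gender` (0/1),
#'   `foveal_binoc_db`.
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests Bonferroni family size (default 43, the shipped map's
#'   item count).
#' @param adjust_foveal include binocular foveal sensitivity as covariate.
#' @return Object of class `qol_association`: `table` (aspect x predictor
#'   rows: estimate, se, p, significant), `models` (per-aspect coefficient
#'   and cutpoint sets used by [predict_qol()]), `threshold`, `alpha`,
#'   `n_tests`, `predictors`, `notes`.
#' @export
fit_association <- function(aspects, weights, covariates, alpha = 0.05,
                            n_tests = 43L, adjust_foveal = TRUE) {
  wcols <- grep("^AT[0-9]+$", names(weights), value = TRUE)
  wcols <- setdiff(wcols, "AT1")
  if (length(wcols) == 0L) stop_vf("no archetype weight columns AT2..ATK")
  cov_cols <- c("age", "gender", if (adjust_foveal) "foveal_binoc_db")
  stopifnot(all(cov_cols %in% names(covariates)))
  dd <- merge(merge(weights[, c("patient_id", wcols)],
                    covariates[, c("patient_id", cov_cols)],
                    by = "patient_id"),
              aspects, by = "patient_id")
  predictors <- c(wcols, cov_cols)
  if (any(!complete.cases(dd[, predictors])))
    stop_vf("missing predictor values for included patients")
  aspect_cols <- setdiff(names(aspects), "patient_id")
  threshold <- alpha / n_tests

  rows <- list()
  models <- list()
  notes <- character()
  for (a in aspect_cols) {
    y <- dd[[a]]
    keep <- !is.na(y)
    da <- dd[keep, predictors, drop = FALSE]
    ya <- y[keep]
    vals <- sort(unique(ya))
    fit_one <- function() {
      if (length(vals) >= 3L) {
        da$.y <- factor(ya, levels = vals, ordered = TRUE)
        fit <- MASS::polr(.y ~ ., data = da, Hess = TRUE,
                          method = "logistic")
        list(type = "polr", coefficients = coef(fit), zeta = fit$zeta,
             values = vals,
             se = sqrt(diag(vcov(fit)))[names(coef(fit))])
      } else if (length(vals) == 2L) {
        notes <<- c(notes, sprintf(
          "aspect %s: only 2 distinct scores, binary logistic fallback", a))
        da$.y <- as.integer(ya == vals[2L])
        fit <- stats::glm(.y ~ ., data = da, family = stats::binomial())
        cf <- coef(fit)[-1L]
        list(type = "binary", coefficients = cf,
             zeta = unname(-coef(fit)[1L]), values = vals,
             se = sqrt(diag(vcov(fit)))[names(cf)])
      } else {
        stop("degenerate outcome (single value)")
      }
    }
    res <- tryCatch(suppressWarnings(fit_one()), error = function(e) e)
    if (inherits(res, "error")) {
      notes <- c(notes, sprintf("aspect %s: fit failed (%s)", a,
                                conditionMessage(res)))
      rows[[a]] <- data.frame(aspect = a, predictor = predictors,
                              estimate = NA_real_, se = NA_real_,
                              p = NA_real_, significant = NA)
      next
    }
    est <- res$coefficients[predictors]
    se <- res$se[predictors]
    z <- est / se
    p <- 2 * pnorm(-abs(z))
    rows[[a]] <- data.frame(aspect = a, predictor = predictors,
                            estimate = unname(est), se = unname(se),
                            p = unname(p),
                            significant = unname(p < threshold))
    models[[a]] <- res
  }
  for (msg in notes) message(msg)
  structure(
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         models = models, alpha = alpha, n_tests = as.integer(n_tests),
         threshold = threshold, predictors = predictors,
         foveal_adjusted = adjust_foveal, notes = notes),
    class = "qol_association")
}

#' @export
print.qol_association <- function(x, ...) {
  nsig <- sum(x$table$significant, na.rm = TRUE)
  cat(sprintf(
    "<qol_association> %d aspects x %d predictors; Bonferroni %g/%d = %.3g; %d significant cells\n",
    length(unique(x$table$aspect)), length(x$predictors), x$alpha,
    x$n_tests, x$threshold, nsig))
  invisible(x)
}

# Category probabilities of one fitted cumulative-logit model at linear
# predictor eta: P(Y = j) = logistic(zeta_j - eta) - logistic(zeta_{j-1} - eta).
po_category_probs <- function(zeta, eta) {
  cum <- cbind(plogis(outer(eta, zeta, function(e, z) z - e)), 1)
  cbind(cum[, 1, drop = FALSE],
        cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE])
}

#' Expected QoL score under a fitted association model
#'
#' For each requested aspect, computes the model's category probabilities
#' at the patient's predictor values and returns the probability-weighted
#' mean of the observed score categories. Predictions are therefore always
#' inside the observed score range.
#'
#' @param assoc a [fit_association()] result.
#' @param newdata data frame with the model's predictor columns (and
#'   optionally `patient_id`).
#' @param aspects which aspects to predict (default: all fitted).
#' @return Data frame of expected scores, one column per aspect.
#' @export
predict_qol <- function(assoc, newdata, aspects = NULL) {
  stopifnot(inherits(assoc, "qol_association"))
  aspects <- aspects %||% names(assoc$models)
  miss <- setdiff(assoc$predictors, names(newdata))
  if (length(miss))
    stop_vf("newdata lacks predictors: %s", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, assoc$predictors, drop = FALSE])
  out <- data.frame(row.names = seq_len(nrow(X)))
  if ("patient_id" %in% names(newdata)) out$patient_id <- newdata$patient_id
  for (a in aspects) {
    m <- assoc$models[[a]]
    if (is.null(m)) { out[[a]] <- NA_real_; next }
    eta <- as.numeric(X[, names(m$coefficients), drop = FALSE] %*%
                        m$coefficients)
    pr <- po_category_probs(m$zeta, eta)
    out[[a]] <- as.numeric(pr %*% m$values)
  }
  out
}

#' Correlations between archetype weights and clinical attributes
#'
#' Pearson correlations over all pairs of variables (archetype weights
#' including archetype 1, binocular foveal sensitivity, IVF mean
#' sensitivity), with two-sided p-values and Bonferroni-adjusted
#' significance over the number of unique pairs.
#'
#' @param weights data frame `patient_id` + `AT1..ATK` percent weights.
#' @param clinical data frame `patient_id` + clinical columns (e.g.
#'   `foveal_binoc_db`, `ivf_ms`).
#' @param alpha family-wise error rate.
#' @return List with matrices `r`, `p`, `significant`, and scalars `alpha`,
#'   `n_pairs`.
#' @export
archetype_clinical_correlations <- function(weights, clinical, alpha = 0.05) {
  dd <- merge(weights, clinical, by = "patient_id")
  if (nrow(dd) < 3L) stop_vf("need at least 3 patients")
  vars <- setdiff(names(dd), c("patient_id", "rss"))
  X <- as.matrix(dd[, vars, drop = FALSE])
  nv <- ncol(X)
  zero_var <- apply(X, 2, stats::sd) == 0
  if (any(zero_var))
    warning("zero-variance variables reported as missing: ",
            paste(vars[zero_var], collapse = ", "))
  r <- matrix(NA_real_, nv, nv, dimnames = list(vars, vars))
  p <- r
  for (i in seq_len(nv)) {
    r[i, i] <- if (zero_var[i]) NA_real_ else 1
    for (j in seq_len(nv)) {
      if (j <= i || zero_var[i] || zero_var[j]) next
      ct <- cor.test(X[, i], X[, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  n_pairs <- nv * (nv - 1) / 2
  list(r = r, p = p, significant = p < alpha / n_pairs,
       alpha = alpha, n_pairs = n_pairs)
}
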
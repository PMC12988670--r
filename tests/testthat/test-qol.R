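make_map <- function() default_item_map()

test_that("the shipped item map defines 43 items and 37 aspects", {
  map <- make_map()
  expect_equal(nrow(map), 43L)
  subs <- unique(map$subscale[!is.na(map$subscale)])
  expect_equal(length(subs) + sum(is.na(map$subscale)), 37L)
  expect_true(all(map$levels >= 2))
})

test_that("item scoring: linear 0-100 with direction alignment and missing codes", {
  map <- make_map()
  raw <- data.frame(
    patient_id = "A",
    item_id = c("q01", "q02", "q03", "q21", "q11", "q04"),
    # q01..q03 are 5-level best-first; q21 reverse-coded; q11 has 6 levels
    response_level = c(1L, 5L, 3L, 5L, 4L, 99L))
  sc <- score_items(raw, map)
  expect_equal(sc$q01, 100) # best level
  expect_equal(sc$q02, 0)   # worst level
  expect_equal(sc$q03, 50)  # midpoint of 5 levels
  expect_equal(sc$q21, 100) # reverse-coded: raw 5 is best
  expect_equal(sc$q11, 40)  # level 4 of 6 -> 100*(6-4)/5
  expect_true(is.na(sc$q04)) # missing code 99
  bad <- data.frame(patient_id = "A", item_id = "q01", response_level = 9L)
  expect_error(score_items(bad, map), "q01")
  expect_error(score_items(data.frame(patient_id = "A", item_id = "zz",
                                      response_level = 1L), map), "unknown")
})

test_that("subscales average answered member items", {
  map <- make_map()
  mk <- function(l1, l2, l3) {
    data.frame(patient_id = "A",
               item_id = c("q01", "q02", "q03"),
               response_level = c(l1, l2, l3))
  }
  # scores 100, 50 (and one missing) -> mean of answered
  sc <- score_items(mk(1L, 3L, 99L), map)
  ss <- score_subscales(sc, map)
  expect_equal(ss$near_activities, 75)
  # single answered item carries the subscale
  sc2 <- score_items(mk(99L, 3L, 99L), map)
  expect_equal(score_subscales(sc2, map)$near_activities, 50)
  # none answered -> missing
  sc3 <- score_items(mk(99L, 99L, 99L), map)
  expect_true(is.na(score_subscales(sc3, map)$near_activities))
  expect_equal(ncol(aspect_scores(sc, map)), 38L) # patient_id + 37 aspects
})

sim_assoc_inputs <- function(n = 250, seed = 42, k_true = 4L, beta = NULL) {
  sim <- simulate_cohort(n, k_true = k_true, noise_sigma = 1, seed = seed)
  qol <- simulate_qol(sim$truth, beta = beta, seed = seed)
  map <- default_item_map()
  aspects <- aspect_scores(score_items(qol, map), map)
  weights <- data.frame(patient_id = sim$truth$patient_id,
                        100 * sim$truth$weights)
  names(weights)[-1] <- paste0("AT", seq_len(k_true))
  covs <- data.frame(patient_id = sim$truth$patient_id,
                     age = sim$truth$age, gender = sim$truth$gender,
                     foveal_binoc_db = sim$truth$foveal_binoc_true)
  list(aspects = aspects, weights = weights, covs = covs, sim = sim)
}

test_that("fit_association: Bonferroni flags, reference archetype, batch order", {
  inp <- sim_assoc_inputs(200, seed = 8)
  a <- suppressMessages(fit_association(inp$aspects[, 1:6], inp$weights,
                                        inp$covs))
  expect_equal(a$threshold, 0.05 / 43)
  expect_false("AT1" %in% a$table$predictor) # normal archetype is reference
  ok <- !is.na(a$table$p)
  expect_identical(a$table$significant[ok], a$table$p[ok] < 0.05 / 43)
  # order independence: permuting aspect columns gives the same rows
  sh <- c(1, 5, 3, 2, 4)
  a2 <- suppressMessages(fit_association(inp$aspects[, c(1, 1 + sh)],
                                         inp$weights, inp$covs))
  t1 <- a$table[order(a$table$aspect, a$table$predictor), ]
  t2 <- a2$table[order(a2$table$aspect, a2$table$predictor), ]
  expect_equal(t1$estimate, t2$estimate)
  # unadjusted mode drops the foveal covariate
  a3 <- suppressMessages(fit_association(inp$aspects[, 1:3], inp$weights,
                                         inp$covs, adjust_foveal = FALSE))
  expect_false("foveal_binoc_db" %in% a3$predictors)
})

test_that("association recovers a strong known effect with the right sign", {
  k <- 4L
  beta <- c(AT2 = -0.002, AT3 = -0.002, AT4 = -0.06, age = -0.002,
            gender = 0, foveal_binoc_db = 0.002)
  inp <- sim_assoc_inputs(800, seed = 10, beta = beta)
  a <- suppressMessages(fit_association(inp$aspects[, c("patient_id", "q15")],
                                        inp$weights, inp$covs))
  at4 <- a$table[a$table$predictor == "AT4", ]
  expect_lt(at4$estimate, 0)
  expect_true(at4$significant)
  expect_equal(at4$estimate, -0.06, tolerance = 0.35)
})

test_that("binary fallback engages below 3 distinct scores", {
  inp <- sim_assoc_inputs(120, seed = 12)
  two <- inp$aspects[, c("patient_id", "q12")]
  two$q12 <- ifelse(two$q12 > 50, 100, 0)
  expect_message(a <- fit_association(two, inp$weights, inp$covs),
                 "binary logistic")
  expect_equal(a$models$q12$type, "binary")
  expect_false(anyNA(a$table$estimate))
})

test_that("predict_qol: expectation over categories, bounds, monotonicity", {
  # hand-built null model: no coefficients active, symmetric cutpoints
  assoc <- structure(list(
    models = list(asp = list(type = "polr",
                             coefficients = c(AT2 = 0, age = 0),
                             zeta = c(-1, 1), values = c(0, 50, 100))),
    predictors = c("AT2", "age"), threshold = 0.05 / 43, alpha = 0.05,
    n_tests = 43L, foveal_adjusted = TRUE, table = NULL,
    notes = character()), class = "qol_association")
  nd <- data.frame(AT2 = c(0, 30), age = c(60, 80))
  pr <- predict_qol(assoc, nd)
  expect_equal(pr$asp, c(50, 50)) # symmetric null -> midpoint
  # category probabilities sum to one
  probs <- vfarch:::po_category_probs(c(-1, 0.2, 1.4), c(-2, 0, 3))
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-9)
  expect_true(all(probs >= 0))

  # fitted model: moving weight from the reference to a deleterious
  # archetype must lower the expected score
  inp <- sim_assoc_inputs(400, seed = 14,
                          beta = c(AT2 = -0.05, AT3 = -0.01, AT4 = -0.01,
                                   age = -0.02, gender = 0,
                                   foveal_binoc_db = 0.05))
  a <- suppressMessages(fit_association(inp$aspects[, c("patient_id", "q20")],
                                        inp$weights, inp$covs))
  base <- data.frame(AT2 = 0, AT3 = 10, AT4 = 10, age = 70, gender = 1,
                     foveal_binoc_db = 40)
  shifted <- base; shifted$AT2 <- 60
  expect_gt(predict_qol(a, base)$q20, predict_qol(a, shifted)$q20)
  # predictions stay inside the observed category range
  expect_true(all(predict_qol(a, rbind(base, shifted))$q20 >= 0))
  expect_true(all(predict_qol(a, rbind(base, shifted))$q20 <= 100))
  expect_error(predict_qol(a, base[, 1:2]), "lacks predictors")
})

test_that("archetype-clinical correlation matrix", {
  inp <- sim_assoc_inputs(200, seed = 16)
  ivf_ms <- as.numeric(inp$sim$truth$weights %*%
                         rowMeans(inp$sim$truth$templates))
  clin <- data.frame(patient_id = inp$sim$truth$patient_id,
                     foveal_binoc_db = inp$covs$foveal_binoc_db,
                     ivf_ms = ivf_ms)
  cc <- archetype_clinical_correlations(inp$weights, clin)
  expect_equal(unname(diag(cc$r)), rep(1, ncol(cc$r)))
  expect_equal(cc$r, t(cc$r), tolerance = 1e-12)
  expect_equal(cc$n_pairs, choose(ncol(cc$r), 2))
  # normal-archetype weight tracks overall sensitivity; defect archetypes
  # (here the hemifield templates) oppose it
  expect_gt(cc$r["AT1", "ivf_ms"], 0)
  expect_lt(cc$r["AT2", "ivf_ms"], 0)
  # zero-variance column -> NA with warning
  clin2 <- clin; clin2$ivf_ms <- 1
  expect_warning(cc2 <- archetype_clinical_correlations(inp$weights, clin2),
                 "zero-variance")
  expect_true(all(is.na(cc2$r["ivf_ms", ])))
  expect_error(archetype_clinical_correlations(inp$weights[1:2, ], clin),
               "3 patients")
})
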
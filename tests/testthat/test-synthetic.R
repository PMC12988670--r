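test_that("normal monocular field follows its closed form", {
  vf <- normal_monocular_vf(45, "right", seed = 1, noise_sigma = 0)
  expect_equal(unname(vf$sensitivities["x3y3"]), 34 - 0.3 * sqrt(18),
               tolerance = 1e-9)
  expect_equal(unname(vf$sensitivities[c("x15y3", "x15y-3")]), c(0, 0))
  lvf <- normal_monocular_vf(45, "left", seed = 1, noise_sigma = 0)
  expect_equal(unname(lvf$sensitivities[c("x-15y3", "x-15y-3")]), c(0, 0))
  # age decline
  old <- normal_monocular_vf(85, "right", seed = 1, noise_sigma = 0)
  expect_equal(unname(old$sensitivities["x3y3"]),
               34 - 0.3 * sqrt(18) - 0.05 * 40, tolerance = 1e-9)
  expect_equal(old$foveal_db, 35 - 0.05 * 40, tolerance = 1e-9)
  # determinism and bounded rates
  a <- normal_monocular_vf(60, "right", seed = 9)
  b <- normal_monocular_vf(60, "right", seed = 9)
  expect_identical(a$sensitivities, b$sensitivities)
  expect_true(all(c(a$fp_rate, a$fn_rate, a$fl_rate) >= 0 &
                    c(a$fp_rate, a$fn_rate, a$fl_rate) <= 1))
  expect_error(normal_monocular_vf(10, "right"), "age")
})

test_that("template library geometry", {
  tpl <- template_library()
  g <- ivf_grid()
  expect_equal(dim(tpl), c(6L, 52L))
  expect_true(all(tpl >= 0 & tpl <= sqrt(2) * 50))
  # template 1 is the sqrt(2)-scaled monocular normal
  expect_equal(unname(tpl["normal", "x3y3"]),
               sqrt(2) * (34 - 0.3 * sqrt(18)), tolerance = 1e-9)
  # template 5 = template 1 - 15, clamped
  expect_equal(tpl["general_depression", ],
               pmax(tpl["normal", ] - 15, 0))
  # templates 2 and 3 mirror across the horizontal midline
  flip <- loc_names(g$x, -g$y)
  expect_equal(unname(tpl["superior_hemifield", ]),
               unname(tpl["inferior_hemifield", flip]))
})

test_that("simulate_cohort: determinism, truth invariants, stream stability", {
  s1 <- simulate_cohort(15, k_true = 4, noise_sigma = 1, seed = 3)
  s2 <- simulate_cohort(15, k_true = 4, noise_sigma = 1, seed = 3)
  expect_identical(s1$vf, s2$vf)
  expect_identical(s1$meta, s2$meta)
  expect_equal(unname(rowSums(s1$truth$weights)), rep(1, 15))
  expect_true(all(s1$truth$weights >= 0))
  # near-pure patients present (every fifth)
  expect_true(all(apply(s1$truth$weights[seq(5, 15, 5), ], 1, max) >= 0.9))
  # growing n preserves earlier patients
  s3 <- simulate_cohort(25, k_true = 4, noise_sigma = 1, seed = 3)
  expect_identical(s3$vf[s3$vf$patient_id %in% s1$vf$patient_id, ], s1$vf)
  expect_error(simulate_cohort(20, k_true = 9), "library")
  expect_error(simulate_cohort(5), "n >= 10")
})

test_that("generated files round-trip through the package readers", {
  dir <- tempfile()
  sim <- simulate_cohort(12, k_true = 3, noise_sigma = 1.5, seed = 21,
                         out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c("vf.csv", "meta.csv",
                                               "truth.json")))))
  vfs <- read_vf_csv(file.path(dir, "vf.csv"),
                     meta = file.path(dir, "meta.csv"))
  expect_length(attr(vfs, "errors"), 0L)
  expect_length(vfs, 12 * 2 * 2) # 2 eyes x 2 visits
  pairs <- make_pairs(vfs)
  sel <- lapply(pairs, select_analysis_visit)
  expect_true(all(!vapply(sel, is.null, logical(1)))) # both visits reliable
  expect_true(all(vapply(sel, function(p)
    format(p$right$test_date), character(1)) == "2020-01-15"))
  qol <- simulate_qol(sim$truth, seed = 21)
  expect_length(attr(qol, "beta"), 5L) # AT2, AT3 + age, gender, foveal
})

test_that("homonymous generator: midline loss, spared right field, correlated eyes", {
  p0 <- simulate_neuro_pair(25, seed = 4, noise_sigma = 0, age = 65)
  base <- normal_monocular_vf(65, "right", seed = vfarch:::mix_seed(4, 1),
                              noise_sigma = 0)
  g <- grid_24_2("right")
  keep <- g$x >= 0
  expect_equal(p0$right$sensitivities[keep], base$sensitivities[keep])
  expect_equal(unname(p0$right$sensitivities["x-9y3"]),
               max(0, unname(base$sensitivities["x-9y3"]) - 25))
  # closed-form asymmetry check on the noise-free right eye: mean over the
  # 26 mirror pairs of |S(x) - S(-x)| computed independently
  sh <- g[g$x > 0 & g$x <= 21, ]
  man <- mean(abs(p0$right$sensitivities[sh$name] -
                    p0$right$sensitivities[loc_names(-sh$x, sh$y)]))
  expect_equal(vertical_midline_asymmetry(p0$right), man)
  expect_gt(man, 15)
  # interocular correlation stays far above the 0.6 screen threshold under
  # test-retest noise (~0.87-0.92 for this hill-of-vision model)
  rs <- vapply(1:25, function(s)
    interocular_correlation(simulate_neuro_pair(25, seed = s,
                                                noise_sigma = 1.5)),
    numeric(1))
  expect_true(all(rs >= 0.85))
})

test_that("simulate_qol: determinism, null frequencies, monotone burden", {
  # null model: beta = 0 -> level frequencies follow the cutpoints
  truth <- structure(list(
    patient_id = sprintf("S%05d", 1:10000),
    weights = matrix(1 / 4, 10000, 4,
                     dimnames = list(NULL, rownames(template_library())[1:4])),
    templates = template_library()[1:4, ], k_true = 4L, noise_sigma = 0,
    dirichlet_alpha = 1, age = rep(65, 10000), gender = rep(0L, 10000),
    foveal_binoc_true = rep(45, 10000), seed = 1L),
    class = "synthetic_truth")
  beta0 <- setNames(rep(0, 6), c("AT2", "AT3", "AT4", "age", "gender",
                                 "foveal_binoc_db"))
  map <- default_item_map()[1:2, ] # two 5-level items suffice
  class(map) <- c("item_map", "data.frame")
  attr(map, "missing_codes") <- integer()
  qol <- simulate_qol(truth, map = map, beta = beta0, seed = 2)
  qol2 <- simulate_qol(truth, map = map, beta = beta0, seed = 2)
  expect_identical(qol, qol2)
  th <- attr(qol, "cutpoints")[["5"]]
  expected <- diff(c(0, plogis(th), 1)) # ascending score categories
  lv <- table(factor(qol$response_level[qol$item_id == "q01"], levels = 1:5))
  # item q01 is best-first: raw level = L + 1 - ascending category
  got <- rev(as.numeric(lv) / sum(lv))
  expect_true(all(abs(got - expected) < 0.02))

  # heavier general-loss weight -> lower scores (k_true = 5 reaches the
  # general-depression template)
  sim5 <- simulate_cohort(300, k_true = 5, noise_sigma = 1, seed = 6)
  beta5 <- c(AT2 = 0, AT3 = 0, AT4 = 0, AT5 = -0.08, age = 0, gender = 0,
             foveal_binoc_db = 0)
  q5 <- simulate_qol(sim5$truth, beta = beta5, seed = 6)
  sc <- score_items(q5, default_item_map())
  msc <- rowMeans(as.matrix(sc[, -1]), na.rm = TRUE)
  w5 <- 100 * sim5$truth$weights[, "general_depression"]
  hi <- w5 > stats::median(w5)
  expect_gt(mean(msc[!hi]) - mean(msc[hi]), 5)
  expect_error(simulate_qol(sim5$truth, cutpoints = list(`5` = c(1, 0.5, 2, 3),
                                                         `6` = 1:5),
                            seed = 1), "increasing")
})
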
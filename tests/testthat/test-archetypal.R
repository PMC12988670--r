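test_that("simplex_ls: exact membership, convexity, input validation", {
  set.seed(1)
  B <- matrix(runif(3 * 6, 0, 40), 3, 6)
  r2 <- simplex_ls(B[2, ], B)
  expect_equal(r2$weights, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(r2$residual, 0, tolerance = 1e-9)
  mid <- simplex_ls(colMeans(B[1:2, ]), B[1:2, ])
  expect_equal(mid$weights, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(mid$residual, 0, tolerance = 1e-9)
  expect_error(simplex_ls(1:3, B[0, , drop = FALSE]), "empty")
  expect_error(simplex_ls(c(1, NA, 3, 4, 5, 6), B), "finite")
  expect_error(simplex_ls(1:5, B), "length")
})

test_that("simplex_ls matches an independent QP solve on random instances", {
  set.seed(202)
  for (i in 1:40) {
    m <- sample(2:8, 1)
    d <- sample(m:12, 1)
    B <- matrix(rnorm(m * d, sd = 10), m, d)
    target <- rnorm(d, sd = 15) # typically outside the hull
    got <- simplex_ls(target, B)
    oracle <- oracle_simplex_qp(target, B)
    expect_equal(got$weights, oracle, tolerance = 1e-6)
    expect_equal(sum(got$weights), 1, tolerance = 1e-12)
  }
})

test_that("fit_archetypes recovers exact and degenerate geometries", {
  set.seed(5)
  # K distinct points, K archetypes -> perfect representation
  V <- matrix(runif(3 * 8, 0, 40), 3, 8)
  W <- matrix(rgamma(60 * 3, 1), 60, 3)
  W <- W / rowSums(W)
  W[1:3, ] <- diag(3) # vertices present in the data
  X <- W %*% V
  m <- fit_archetypes(X, 3, restarts = 10, seed = 2, tol = 1e-14,
                      max_iter = 500)
  expect_lt(m$rss, 1e-12 * sum(X^2) + 1e-8)
  expect_lt(matched_mae(m$Z, V), 1e-6)

  # K = 1: the hull point minimising total squared distance equals the
  # simplex projection of the column mean (QP oracle on a 20 x 3 toy)
  X1 <- matrix(rnorm(20 * 3, sd = 5), 20, 3)
  m1 <- fit_archetypes(X1, 1, restarts = 20, seed = 3)
  w_or <- oracle_simplex_qp(colMeans(X1), X1)
  expect_equal(as.numeric(m1$Z), as.numeric(w_or %*% X1), tolerance = 1e-4)

  expect_error(fit_archetypes(X1, 20, restarts = 1), "more data")
  expect_error(fit_archetypes(X1, 0, restarts = 1), ">= 1")
})

test_that("fit_archetypes recovers noise-free mixture vertices", {
  tpl <- template_library()[1:3, ]
  set.seed(9)
  W <- matrix(rgamma(200 * 3, 0.8), 200, 3)
  W <- W / rowSums(W)
  near <- seq(1, 200, by = 10)
  for (i in seq_along(near)) { # near-pure rows so vertices are touched
    w <- rep(0.02, 3); w[(i %% 3) + 1] <- 0.96
    W[near[i], ] <- w
  }
  X <- W %*% tpl
  m <- fit_archetypes(X, 3, restarts = 15, seed = 4)
  expect_lt(matched_mae(m$Z, tpl), 0.5)
  # archetypes stay in the data hull (bounded by data range)
  expect_true(all(m$Z >= min(X) - 1e-9 & m$Z <= max(X) + 1e-9))
})

test_that("training RSS is monotone within restarts and across K", {
  sim <- simulate_cohort(120, k_true = 4, noise_sigma = 1, seed = 31)
  X <- cohort_ivf(sim)$X
  prev <- Inf
  for (k in 2:6) {
    m <- fit_archetypes(X, k, restarts = 20, seed = 6)
    expect_true(all(diff(m$rss_trace) <= 1e-9))
    expect_lte(m$rss, prev * 1.005) # non-increasing in K within 0.5%
    prev <- m$rss
  }
})

test_that("decompose returns simplex percentages and honours the grid", {
  sim <- simulate_cohort(80, k_true = 3, noise_sigma = 1, seed = 13)
  X <- cohort_ivf(sim)$X
  m <- fit_archetypes(X, 3, restarts = 10, seed = 8)
  # each archetype decomposes to 100% on itself
  d_self <- decompose(m, m$Z)
  for (k in 1:3) expect_equal(d_self[[paste0("AT", k)]][k], 100,
                              tolerance = 1e-6)
  # equal blend of two archetypes
  blend <- decompose(m, 0.5 * m$Z[1, ] + 0.5 * m$Z[2, ])
  expect_equal(unlist(blend[1, c("AT1", "AT2")], use.names = FALSE),
               c(50, 50), tolerance = 1e-6)
  # weights always sum to 100
  w <- decompose(m, X)
  expect_true(all(abs(rowSums(w[, 1:3]) - 100) < 1e-6))
  expect_true(all(w$rss >= 0))
  expect_error(decompose(m, rep(30, 10)), "grid|length")
})

test_that("model JSON round-trip reproduces decompositions exactly", {
  sim <- simulate_cohort(40, k_true = 3, noise_sigma = 1, seed = 17)
  X <- cohort_ivf(sim)$X
  m <- fit_archetypes(X, 3, restarts = 5, seed = 12)
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m$Z, m2$Z)
  d1 <- decompose(m, X)
  d2 <- decompose(m2, X)
  expect_equal(as.matrix(d1), as.matrix(d2), tolerance = 1e-12)
})

test_that("crossvalidate_k bookkeeping, determinism and errors", {
  sim <- simulate_cohort(60, k_true = 3, noise_sigma = 1, seed = 19)
  X <- cohort_ivf(sim)$X
  cv <- crossvalidate_k(X, 2, 3, folds = 10, restarts = 3, seed = 7)
  expect_equal(nrow(cv), 20L) # 2 candidates x 10 folds
  expect_true(all(cv$score >= 0))
  expect_equal(attr(cv, "normalization"), "mean_per_field_rss")
  cv2 <- crossvalidate_k(X, 2, 3, folds = 10, restarts = 3, seed = 7)
  expect_identical(as.data.frame(cv), as.data.frame(cv2))
  # changing restarts must not change the fold assignment: scores at
  # restart-insensitive K = 2 on well-separated data stay comparable
  expect_error(crossvalidate_k(X, 2, 3, folds = 61, restarts = 2), "folds")
  expect_error(crossvalidate_k(X[1:12, ], 11, 11, folds = 10, restarts = 1),
               "fewer than k")
})

test_that("select_k implements the BIC slope criterion", {
  # constructed fold-score table: linear decrease K = 2..4, flat + small
  # iid noise for K >= 4
  set.seed(23)
  ks <- 2:8
  tab <- do.call(rbind, lapply(ks, function(k) {
    mu <- if (k <= 4) 40 - 10 * (k - 2) else 20
    data.frame(k = k, fold = 1:10, score = mu + rnorm(10, 0, 0.3))
  }))
  class(tab) <- c("cv_result", "data.frame")
  got <- select_k(tab)
  expect_equal(as.integer(got), 4L)
  # verify the Delta-BIC values against an independent regression over the
  # same local window of 3 counts
  db <- attr(got, "delta_bic")
  for (i in seq_len(nrow(db))) {
    kin <- intersect(db$k[i] + 0:2, ks)
    d <- tab[tab$k %in% kin, ]
    n <- nrow(d)
    f1 <- lm(score ~ k, data = d)
    rss1 <- sum(resid(f1)^2)
    rss0 <- sum((d$score - mean(d$score))^2)
    expect_equal(db$delta_bic[i],
                 (n * log(rss1 / n) + 2 * log(n)) -
                   (n * log(rss0 / n) + 1 * log(n)), tolerance = 1e-12)
  }
  expect_true(all(db$delta_bic[db$k < 4] < 0))
  # the all-tail window agrees on this clean fixture
  expect_equal(as.integer(select_k(tab, window = "tail")), 4L)

  # strictly decreasing scores -> k_max with a warning
  tab2 <- do.call(rbind, lapply(ks, function(k)
    data.frame(k = k, fold = 1:10, score = 100 - 5 * k + rnorm(10, 0, 0.1))))
  expect_warning(k2 <- select_k(tab2), "k_max")
  expect_equal(as.integer(k2), 8L)

  # degenerate: all scores identical -> k_min with a warning
  tab3 <- expand.grid(k = 2:5, fold = 1:10)
  tab3$score <- 7
  expect_warning(k3 <- select_k(tab3), "k_min")
  expect_equal(as.integer(k3), 2L)

  expect_error(select_k(tab3[tab3$k <= 3, ]), "3 candidate")
})
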
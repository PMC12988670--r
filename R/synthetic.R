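# Synthetic-data generators. These state, with full ground truth, the world
# the pipeline assumes: binocular fields that are noisy convex mixtures of a
# small library of defect templates, homonymous pairs for the neurological
# screen, reliability indices, and ordinal questionnaire responses drawn
# from a known proportional-odds model.

monocular_normal_db <- function(x, y, age) {
  34 - 0.3 * sqrt(x^2 + y^2) - 0.05 * (age - 45)
}

#' Simulate a normal monocular visual field
#'
#' The hill of vision is `34 - 0.3 * sqrt(x^2 + y^2)` dB at age 45,
#' declining 0.05 dB per year of age, with independent Gaussian test-retest
#' noise (sigma = 1.5 dB by default), clamped to `[0, 40]`. The eye's two
#' blind-spot locations are set to 0. Foveal sensitivity is
#' `35 - 0.05 * (age - 45)` plus the same noise. Reliability rates are
#' drawn from Beta(2, 30).
#'
#' @param age years, in `[18, 100]`.
#' @param eye `"right"` or `"left"`.
#' @param seed integer seed (same seed, same field).
#' @param noise_sigma test-retest noise SD in dB; 0 gives the noise-free
#'   hill of vision.
#' @param patient_id,test_date identifiers for the record.
#' @return A [monocular_vf()].
#' @export
normal_monocular_vf <- function(age, eye, seed = 1L, noise_sigma = 1.5,
                                patient_id = "SYN", test_date = "2020-01-01") {
  stopifnot(age >= 18, age <= 100)
  eye <- normalize_eye(eye)
  g <- grid_24_2(eye)
  with_seed(seed, {
    s <- monocular_normal_db(g$x, g$y, age) + rnorm(54, 0, noise_sigma)
    s <- pmin(40, pmax(0, s))
    s[g$blind_spot] <- 0
    names(s) <- g$name
    fov <- min(40, max(0, 35 - 0.05 * (age - 45) + rnorm(1, 0, noise_sigma)))
    rates <- rbeta(3, 2, 30)
    monocular_vf(patient_id, eye, test_date, s, fov,
                 fp_rate = rates[1], fn_rate = rates[2], fl_rate = rates[3],
                 age = age)
  })
}

#' Library of binocular defect templates
#'
#' Six fixed 52-vectors built from the noise-free age-45 binocular normal
#' field (the monocular hill of vision scaled by `sqrt(2)`):
#' normal; superior-hemifield depression (-20 dB for `y > 0`);
#' inferior-hemifield depression (-20 dB for `y < 0`); superior
#' paracentral defect (-15 dB for `|x| <= 9`, `3 <= y <= 9`); general
#' depression (-15 dB everywhere); right-blind-spot-region loss (-20 dB
#' for `x` in 9..21, `|y| <= 9`). All clamped at 0.
#'
#' @return 6 x 52 matrix, rows named by pattern, columns the binocular grid.
#' @export
template_library <- function() {
  g <- ivf_grid()
  base <- sqrt(2) * monocular_normal_db(g$x, g$y, 45)
  tpl <- rbind(
    normal               = base,
    superior_hemifield   = base - 20 * (g$y > 0),
    inferior_hemifield   = base - 20 * (g$y < 0),
    superior_paracentral = base - 15 * (abs(g$x) <= 9 & g$y >= 3 & g$y <= 9),
    general_depression   = base - 15,
    right_blindspot      = base - 20 * (g$x >= 9 & g$x <= 21 & abs(g$y) <= 9))
  tpl[tpl < 0] <- 0
  colnames(tpl) <- g$name
  tpl
}

# Binocular foveal sensitivity of each template at a given age: sqrt(2)
# times the monocular normal fovea, minus the general-depression deficit.
template_foveal <- function(age) {
  f <- sqrt(2) * (35 - 0.05 * (age - 45))
  pmax(0, c(f, f, f, f, f - 15, f))
}

#' Simulate a cohort of paired monocular visual-field tests
#'
#' Each patient's true binocular field is a convex mixture
#' `T = sum(w_k * template_k)` over the first `k_true` library templates,
#' with Dirichlet-distributed weights; every fifth patient is forced
#' near-pure (max weight >= 0.9) so the template vertices are attainable
#' from the data. Monocular fields are `R = L = T / sqrt(2)` on all 52
#' shared locations - blind-spot points included, so quadratic summation
#' reproduces `T` exactly at zero noise - with nasal-extension points from
#' the monocular normal formula; independent Gaussian noise is added per
#' eye and location, clamped to `[0, 40]`. Two reliable visits a year apart
#' are emitted per patient so visit selection is exercised. Ages are
#' Uniform(50, 85), gender Bernoulli(0.5). Draws are streamed per patient,
#' so growing `n` preserves earlier patients.
#'
#' @param n number of patients (>= 10).
#' @param k_true number of active templates (<= 6).
#' @param dirichlet_alpha concentration of the weight prior.
#' @param noise_sigma per-eye, per-location noise SD in dB.
#' @param seed integer seed.
#' @param out_dir if non-`NULL`, writes `vf.csv`, `meta.csv`, `truth.json`.
#' @return List with `vf` (long data frame), `meta` (per-test metadata) and
#'   `truth` (class `synthetic_truth`: true weights, templates, noise,
#'   demographics, true binocular foveal sensitivities).
#' @export
simulate_cohort <- function(n, k_true = 4L, dirichlet_alpha = 1,
                            noise_sigma = 1, seed = 1L, out_dir = NULL) {
  stopifnot(n >= 10L)
  tpl <- template_library()
  if (k_true > nrow(tpl))
    stop_vf("k_true = %d exceeds the template library size (%d)",
            k_true, nrow(tpl))
  tpl <- tpl[seq_len(k_true), , drop = FALSE]
  gshared <- ivf_grid()
  dates <- as.Date(c("2019-01-15", "2020-01-15"))

  ids <- sprintf("P%04d", seq_len(n))
  Wtrue <- matrix(NA_real_, n, k_true,
                  dimnames = list(ids, rownames(tpl)))
  age <- numeric(n); gender <- integer(n); fov_true <- numeric(n)
  vf_rows <- vector("list", n)
  meta_rows <- vector("list", n)

  for (i in seq_len(n)) {
    with_seed(mix_seed(seed, 101L, i), {
      age[i] <- runif(1, 50, 85)
      gender[i] <- rbinom(1, 1, 0.5)
      w <- rgamma(k_true, dirichlet_alpha)
      w <- w / sum(w)
      if (i %% 5L == 0L) { # forced near-pure patient
        j <- ((i %/% 5L - 1L) %% k_true) + 1L
        pm <- runif(1, 0.9, 0.98)
        rest <- rgamma(k_true, 1); rest[j] <- 0
        w <- rest / max(sum(rest), 1e-12) * (1 - pm)
        w[j] <- pm
      }
      Wtrue[i, ] <- w
      Tfield <- as.numeric(w %*% tpl)
      names(Tfield) <- colnames(tpl)
      # 2 dB between-patient foveal variability: without it the true foveal
      # sensitivity would be an exact linear function of age whenever all
      # active templates spare the fovea, making the regression covariates
      # collinear by construction
      fov_true[i] <- max(0, sum(w * template_foveal(age[i])[seq_len(k_true)]) +
                           rnorm(1, 0, 2))

      vf_i <- list(); meta_i <- list()
      for (v in 1:2) {
        for (eye in c("right", "left")) {
          g <- grid_24_2(eye)
          s <- numeric(54); names(s) <- g$name
          shared <- intersect(g$name, gshared$name)
          s[shared] <- Tfield[shared] / sqrt(2)
          nasal <- g$name[abs(g$x) > 21]
          s[nasal] <- monocular_normal_db(g$x[abs(g$x) > 21],
                                          g$y[abs(g$x) > 21], age[i])
          # blind spots keep T/sqrt(2) so quadratic summation reproduces the
          # binocular target exactly at zero noise (see methods vignette)
          s <- pmin(40, pmax(0, s + rnorm(54, 0, noise_sigma)))
          fov <- min(40, max(0, fov_true[i] / sqrt(2) +
                               rnorm(1, 0, noise_sigma)))
          rates <- pmin(rbeta(3, 2, 30), 0.10) # both visits kept reliable
          vf_i[[length(vf_i) + 1L]] <- data.frame(
            patient_id = ids[i], eye = ifelse(eye == "right", "OD", "OS"),
            test_date = format(dates[v]), x_deg = g$x, y_deg = g$y,
            sensitivity_db = unname(s))
          meta_i[[length(meta_i) + 1L]] <- data.frame(
            patient_id = ids[i], eye = ifelse(eye == "right", "OD", "OS"),
            test_date = format(dates[v]), fp_rate = rates[1],
            fn_rate = rates[2], fl_rate = rates[3], foveal_db = fov,
            age_years = age[i], gender = gender[i])
        }
      }
      vf_rows[[i]] <- do.call(rbind, vf_i)
      meta_rows[[i]] <- do.call(rbind, meta_i)
    })
  }
  truth <- structure(
    list(patient_id = ids, weights = Wtrue, templates = tpl,
         k_true = as.integer(k_true), noise_sigma = noise_sigma,
         dirichlet_alpha = dirichlet_alpha, age = age, gender = gender,
         foveal_binoc_true = fov_true, seed = as.integer(seed)),
    class = "synthetic_truth")
  out <- list(vf = do.call(rbind, vf_rows), meta = do.call(rbind, meta_rows),
              truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out$vf, file.path(out_dir, "vf.csv"), row.names = FALSE)
    write.csv(out$meta, file.path(out_dir, "meta.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(patient_id = ids, weights = Wtrue, templates = tpl,
           k_true = k_true, noise_sigma = noise_sigma,
           dirichlet_alpha = dirichlet_alpha, age = age, gender = gender,
           foveal_binoc_true = fov_true, seed = seed),
      file.path(out_dir, "truth.json"), digits = NA, auto_unbox = TRUE,
      matrix = "rowmajor")
  }
  out
}

#' Simulate a homonymous (post-chiasmatic) pair
#'
#' Both eyes start from the normal monocular field of the same patient;
#' every location in the left visual field (`x < 0`) is then reduced by
#' `severity_db` in both eyes, clamped at 0 - a homonymous left-field loss
#' that respects the vertical midline in the same way in the two eyes.
#'
#' @param severity_db depth of the homonymous defect (> 0).
#' @param seed integer seed.
#' @param age patient age in years.
#' @param noise_sigma per-location noise SD in dB.
#' @param patient_id,test_date identifiers.
#' @return A [vf_pair()].
#' @export
simulate_neuro_pair <- function(severity_db = 25, seed = 1L, age = 65,
                                noise_sigma = 1.5, patient_id = "NEURO",
                                test_date = "2020-01-01") {
  stopifnot(severity_db > 0)
  mk <- function(eye, sub_seed) {
    vf <- normal_monocular_vf(age, eye, seed = mix_seed(seed, sub_seed),
                              noise_sigma = noise_sigma,
                              patient_id = patient_id, test_date = test_date)
    g <- grid_24_2(eye)
    s <- vf$sensitivities
    s[g$x < 0] <- pmax(0, s[g$x < 0] - severity_db)
    monocular_vf(patient_id, eye, test_date, s, vf$foveal_db,
                 fp_rate = vf$fp_rate, fn_rate = vf$fn_rate,
                 fl_rate = vf$fl_rate, age = age)
  }
  vf_pair(right = mk("right", 1L), left = mk("left", 2L))
}

#' Simulate questionnaire responses from a proportional-odds model
#'
#' Each modelled aspect has latent `eta = beta . x`, where `x` holds the
#' archetype weights 2..k_true in percent, age, gender and the true
#' binocular foveal sensitivity. Score categories are sampled with
#' `P(category <= c) = logistic(theta_c - eta)` on the best-is-highest
#' ordering, then emitted as raw response levels in each item's own coding
#' (reverse-coded items reversed). Items of one subscale share their
#' aspect's latent but are sampled independently.
#'
#' @param truth a `synthetic_truth` from [simulate_cohort()].
#' @param map an item map (default [default_item_map()]).
#' @param beta named coefficient vector over
#'   `AT2..ATk_true, age, gender, foveal_binoc_db`; the default is
#'   -0.03 per percent on every defect archetype, -0.02 per year of age,
#'   0 for gender and +0.05 per dB of foveal sensitivity.
#' @param cutpoints optional list keyed by level count (`"5"`, `"6"`, ...)
#'   of strictly increasing cutpoint vectors; by default cutpoints are the
#'   logistic quantiles at `c/L`, centred on the cohort mean latent.
#' @param seed integer seed.
#' @return Long data frame `patient_id`, `item_id`, `response_level`, with
#'   attributes `beta` and `cutpoints` recording the generating model.
#' @export
simulate_qol <- function(truth, map = default_item_map(), beta = NULL,
                         cutpoints = NULL, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  k <- truth$k_true
  Wpct <- 100 * truth$weights
  X <- cbind(Wpct[, -1L, drop = FALSE], age = truth$age,
             gender = truth$gender, foveal_binoc_db = truth$foveal_binoc_true)
  colnames(X)[seq_len(k - 1L)] <- paste0("AT", 2:k)
  if (is.null(beta)) {
    beta <- c(rep(-0.03, k - 1L), -0.02, 0, 0.05)
    names(beta) <- colnames(X)
  }
  miss <- setdiff(colnames(X), names(beta))
  if (length(miss))
    stop_vf("beta does not cover predictors: %s", paste(miss, collapse = ", "))
  eta <- as.numeric(X %*% beta[colnames(X)])
  center <- mean(eta)
  theta_for <- function(L) {
    th <- if (!is.null(cutpoints)) {
      as.numeric(cutpoints[[as.character(L)]] %||%
                   stop_vf("no cutpoints supplied for %d-level items", L))
    } else {
      center + qlogis(seq_len(L - 1L) / L)
    }
    if (any(diff(th) <= 0)) stop_vf("cutpoints must be strictly increasing")
    th
  }
  n <- length(eta)
  out <- vector("list", nrow(map))
  with_seed(mix_seed(seed, 909L), {
    for (j in seq_len(nrow(map))) {
      L <- map$levels[j]
      th <- theta_for(L)
      cum <- plogis(outer(eta, th, function(e, z) z - e)) # n x (L-1)
      u <- runif(n)
      cat_asc <- rowSums(u > cum) + 1L # 1 = worst ... L = best score
      l_eff <- L - cat_asc + 1L        # 1 = best response after alignment
      raw <- if (map$level1_best[j]) l_eff else L + 1L - l_eff
      out[[j]] <- data.frame(patient_id = truth$patient_id,
                             item_id = map$item_id[j],
                             response_level = raw)
    }
  })
  res <- do.call(rbind, out)
  attr(res, "beta") <- beta
  attr(res, "cutpoints") <- lapply(
    setNames(nm = as.character(sort(unique(map$levels)))),
    function(L) theta_for(as.integer(L)))
  res
}
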
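# Shared fixture builders and independent oracles.

# Constant-sensitivity monocular test with reliable indices.
flat_vf <- function(value, eye = "right", patient_id = "P1",
                    test_date = "2020-06-01", foveal_db = value,
                    fp = 0.02, fn = 0.02, fl = 0.05) {
  g <- grid_24_2(eye)
  monocular_vf(patient_id, eye, test_date,
               setNames(rep(value, 54), g$name), foveal_db,
               fp_rate = fp, fn_rate = fn, fl_rate = fl)
}

flat_pair <- function(r_value, l_value, patient_id = "P1",
                      test_date = "2020-06-01", ...) {
  vf_pair(flat_vf(r_value, "right", patient_id, test_date, ...),
          flat_vf(l_value, "left", patient_id, test_date, ...))
}

# Monocular test with named overrides on specific locations.
vf_with <- function(base = 30, overrides = numeric(), eye = "right", ...) {
  g <- grid_24_2(eye)
  s <- setNames(rep(base, 54), g$name)
  s[names(overrides)] <- overrides
  monocular_vf("P1", eye, "2020-06-01", s, base, fp_rate = 0.02,
               fn_rate = 0.02, fl_rate = 0.05, ...)
}

# Independent oracle for the simplex projection: quadratic program
#   min ||t(B) w - t||^2  s.t. sum(w) = 1, w >= 0
# solved by quadprog (dual active set) - a different algorithm and code
# path from the package's augmented NNLS + KKT refit.
oracle_simplex_qp <- function(target, basis) {
  m <- nrow(basis)
  D <- 2 * basis %*% t(basis) + 1e-10 * diag(m)
  dvec <- 2 * as.numeric(basis %*% target)
  A <- cbind(rep(1, m), diag(m))
  quadprog::solve.QP(D, dvec, A, c(1, rep(0, m)), meq = 1)$solution
}

# Assignment-matched mean absolute error between fitted archetypes and the
# true templates (brute force over permutations, fine for K <= 5).
perm_all <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perm_all(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}
matched_mae <- function(Z, templates) {
  stopifnot(nrow(Z) == nrow(templates))
  min(vapply(perm_all(seq_len(nrow(Z)))
             , function(p) mean(abs(Z[p, , drop = FALSE] - templates))
             , numeric(1)))
}

# Cohort -> IVF matrix via the package's own reader/QC/integration path.
cohort_ivf <- function(sim) {
  vfp <- tempfile(fileext = ".csv")
  mtp <- tempfile(fileext = ".csv")
  write.csv(sim$vf, vfp, row.names = FALSE)
  write.csv(sim$meta, mtp, row.names = FALSE)
  vfs <- read_vf_csv(vfp, meta = mtp)
  pairs <- make_pairs(vfs)
  ivfs <- lapply(pairs, function(p) integrate_pair(select_analysis_visit(p)))
  list(X = ivf_matrix(ivfs), ivfs = ivfs, pairs = pairs)
}

# Proportional-odds sampler used as the independent generator for the
# ordinal-recovery checks (kept separate from simulate_qol on purpose).
sample_ordinal <- function(eta, zeta) {
  cum <- plogis(outer(eta, zeta, function(e, z) z - e))
  rowSums(runif(length(eta)) > cum) + 1L
}
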
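# Random in-domain parameter generators for property-style tests.
# Each returns a data frame with one row per draw; ranges span the factor
# domains at the scales typical of livestock/crop genomic-selection designs.

rand_within_params <- function(k, h2_max = 1) {
  data.frame(
    n_train = sample(10:10000, k, replace = TRUE),
    h2 = runif(k, 0.01, h2_max),
    h2_m = runif(k, 0.01, h2_max),
    me = runif(k, 1, 5000),
    ne = runif(k, 1, 2000),
    m_markers = sample(10:50000, k, replace = TRUE),
    b = runif(k, 0, 1),
    eterm = runif(k, 0, 5)
  )
}

# Genetic correlations among populations A, B and C must be jointly
# feasible: the 3x3 correlation matrix [[1, rAB, rAC], [rAB, 1, rBC],
# [rAC, rBC, 1]] has to be positive semidefinite.  Independent uniform
# draws describe impossible covariance structures (and can push the
# selection-index accuracy above 1), so draws are rejection-sampled.
rand_corr_triple <- function() {
  repeat {
    r <- runif(3, -1, 1)  # rAB, rAC, rBC
    det3 <- 1 - sum(r^2) + 2 * prod(r)
    if (det3 >= 0) return(r)
  }
}

rand_multi_params <- function(k) {
  cors <- t(vapply(seq_len(k), function(i) rand_corr_triple(), numeric(3)))
  data.frame(
    n_a = sample(10:10000, k, replace = TRUE),
    n_b = sample(10:10000, k, replace = TRUE),
    h2_a = runif(k, 0.05, 1),
    h2_b = runif(k, 0.05, 1),
    me_ac = runif(k, 10, 5000),
    me_bc = runif(k, 10, 5000),
    r_g_ab = cors[, 1],
    r_g_ac = cors[, 2],
    r_g_bc = cors[, 3],
    b_ac = runif(k, 0, 1),
    b_bc = runif(k, 0, 1)
  )
}

wientjes_row <- function(p, i) {
  accuracy_wientjes(p$n_a[i], p$n_b[i], p$h2_a[i], p$h2_b[i],
                    p$me_ac[i], p$me_bc[i], p$r_g_ac[i], p$r_g_bc[i],
                    p$r_g_ab[i], p$b_ac[i], p$b_bc[i])
}

# A small fixed sweep used across serialization tests.
demo_sweep_table <- function(n_points = 5) {
  run_sweep(sweep_spec("daetwyler", "N", 100, 10000, n_points = n_points,
                       fixed = list(h2 = 0.5, Me = 1000)))
}

demo_surface_table <- function(n = 3) {
  run_surface(surface_spec(
    "wientjes", "NA", 100, 5000, "NB", 100, 5000,
    n_points = n, y_points = n,
    fixed = list(h2A = 0.4, h2B = 0.4, MeAC = 500, MeBC = 500,
                 rGAC = 0.8, rGBC = 0.8, rGAB = 0.6, bAC = 0.9, bBC = 0.9)))
}
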
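# Unit and property tests for the eight deterministic accuracy formulas.

test_that("daetwyler matches direct arithmetic and its limits", {
  # symmetry case N*h2 = Me
  expect_equal(accuracy_daetwyler(1000, 0.5, 500), sqrt(0.5), tolerance = 1e-15)
  # direct arithmetic oracle
  expect_equal(accuracy_daetwyler(1000, 0.3, 1000), sqrt(300 / 1300),
               tolerance = 1e-15)
  # Me -> 0+ limit
  expect_gt(accuracy_daetwyler(1000, 0.5, 1e-9), 1 - 1e-9)
})

test_that("goddard_terms matches its definitions", {
  gt <- goddard_terms(1000, 0.5, 500, 100)
  expect_equal(gt$lambda, 500 / (0.5 * log(200)), tolerance = 1e-15)
  expect_equal(gt$alpha, 1 + 2 * 500 / (1000 * 0.5 * log(200)), tolerance = 1e-15)
  expect_equal(round(gt$lambda, 2), 188.74)
  expect_equal(round(gt$alpha, 5), 1.37748)
  # N -> infinity: alpha -> 1+
  expect_lt(goddard_terms(1e9, 0.5, 500, 100)$alpha - 1, 1e-5)
  # lambda halves exactly when h2 doubles
  expect_equal(goddard_terms(1000, 0.8, 500, 100)$lambda,
               goddard_terms(1000, 0.4, 500, 100)$lambda / 2, tolerance = 1e-15)
  expect_error(goddard_terms(1000, 0.5, 500, 0.4), class = "gpasim_validation_error")
})

test_that("goddard2009 matches the printed expression and is stable", {
  # spot value against the printed form evaluated directly
  lam <- 500 / (0.5 * log(200))
  alp <- 1 + 2 * 500 / (1000 * 0.5 * log(200))
  printed <- sqrt(1 - lam / (2 * 1000 * sqrt(alp)) *
                    log((1 + alp + 2 * sqrt(alp)) / (1 + alp - 2 * sqrt(alp))))
  expect_equal(accuracy_goddard2009(1000, 0.5, 500, 100), printed,
               tolerance = 1e-13)
  expect_equal(round(accuracy_goddard2009(1000, 0.5, 500, 100), 3), 0.770)
  # N -> infinity limit: r -> 1
  expect_gt(accuracy_goddard2009(1e9, 0.5, 500, 100), 0.9999)
  # stable vs printed over random in-domain parameter sets
  withr::with_seed(11, {
    p <- rand_within_params(1000)
    for (i in seq_len(nrow(p))) {
      a <- accuracy_goddard2009(p$n_train[i], p$h2[i], p$me[i], p$ne[i])
      b <- accuracy_goddard2009(p$n_train[i], p$h2[i], p$me[i], p$ne[i],
                                form = "printed")
      expect_lt(abs(a - b) / max(a, .Machine$double.eps), 1e-12)
    }
  })
})

test_that("goddard2011 handles the b / m_markers choice and reduces to daetwyler", {
  expect_equal(accuracy_goddard2011(1000, 0.5, 500, m_markers = 500),
               sqrt(0.5 * (0.5 / 1.5)), tolerance = 1e-15)
  expect_equal(accuracy_goddard2011(1000, 0.5, 500, b = 0), 0)
  expect_error(accuracy_goddard2011(1000, 0.5, 500, b = 0.5, m_markers = 100),
               "one of", class = "gpasim_validation_error")
  expect_error(accuracy_goddard2011(1000, 0.5, 500),
               class = "gpasim_validation_error")
  # b = 1 identical to daetwyler over random parameter sets
  withr::with_seed(12, {
    p <- rand_within_params(500)
    for (i in seq_len(nrow(p))) {
      a <- accuracy_goddard2011(p$n_train[i], p$h2[i], p$me[i], b = 1)
      d <- accuracy_daetwyler(p$n_train[i], p$h2[i], p$me[i])
      expect_lt(abs(a - d) / d, 1e-12)
    }
  })
})

test_that("rabier forms match arithmetic, agree at eterm = Me/N, dominate daetwyler", {
  expect_equal(accuracy_rabier(1000, 0.5, 500), sqrt(1 / 1.5), tolerance = 1e-15)
  expect_equal(accuracy_rabier_eterm(0.5, 1), sqrt(0.5), tolerance = 1e-15)
  expect_equal(accuracy_rabier_eterm(0.5, 0), 1)
  # Me/N -> 0 limit
  expect_gt(accuracy_rabier(100000, 0.5, 1e-6), 1 - 1e-9)
  expect_error(accuracy_rabier(1000, 1, 500), class = "gpasim_domain_error")
  expect_error(accuracy_rabier_eterm(1, 0.5), class = "gpasim_domain_error")
  expect_error(accuracy_rabier_eterm(0.5, -0.1), class = "gpasim_validation_error")
  withr::with_seed(13, {
    p <- rand_within_params(1000, h2_max = 0.999)
    for (i in seq_len(nrow(p))) {
      rs <- accuracy_rabier(p$n_train[i], p$h2[i], p$me[i])
      re <- accuracy_rabier_eterm(p$h2[i], p$me[i] / p$n_train[i])
      expect_lt(abs(rs - re), 1e-12)
      # dominance over daetwyler on identical inputs
      expect_gte(rs, accuracy_daetwyler(p$n_train[i], p$h2[i], p$me[i]) - 1e-15)
    }
  })
})

test_that("deloscampos matches arithmetic and is bounded by sqrt(h2)", {
  expect_equal(accuracy_deloscampos(0.5, 0.64), sqrt(0.75 * 0.64), tolerance = 1e-15)
  expect_equal(accuracy_deloscampos(1, 0.37), sqrt(0.37), tolerance = 1e-15)
  expect_equal(accuracy_deloscampos(0, 0.9), 0)
  withr::with_seed(14, {
    p <- rand_within_params(1000)
    for (i in seq_len(nrow(p))) {
      expect_lte(accuracy_deloscampos(p$b[i], p$h2[i]), sqrt(p$h2[i]) + 1e-15)
    }
  })
})

test_that("karaman matches arithmetic and equals daetwyler-with-h2M scaled", {
  expect_equal(accuracy_karaman(1000, 0.5, 500), 0.5, tolerance = 1e-15)
  # h2M = 1: equals daetwyler at h2 = 1
  expect_equal(accuracy_karaman(1000, 1, 500), accuracy_daetwyler(1000, 1, 500),
               tolerance = 1e-15)
  # general identity r = sqrt(h2M) * daetwyler(N, h2M, Me)
  withr::with_seed(15, {
    p <- rand_within_params(200)
    for (i in seq_len(nrow(p))) {
      expect_equal(accuracy_karaman(p$n_train[i], p$h2_m[i], p$me[i]),
                   sqrt(p$h2_m[i]) *
                     accuracy_daetwyler(p$n_train[i], p$h2_m[i], p$me[i]),
                   tolerance = 1e-12)
    }
  })
  # Me -> infinity: r -> 0
  expect_lt(accuracy_karaman(1000, 0.5, 1e12), 1e-4)
})

test_that("wientjes is label-symmetric, reduces correctly, and zeroes out", {
  # label symmetry A <-> B
  withr::with_seed(16, {
    p <- rand_multi_params(200)
    for (i in seq_len(nrow(p))) {
      r1 <- wientjes_row(p, i)
      r2 <- accuracy_wientjes(p$n_b[i], p$n_a[i], p$h2_b[i], p$h2_a[i],
                              p$me_bc[i], p$me_ac[i], p$r_g_bc[i], p$r_g_ac[i],
                              p$r_g_ab[i], p$b_bc[i], p$b_ac[i])
      expect_equal(r1, r2, tolerance = 1e-12)
    }
  })
  # second population inert -> daetwyler(N_A, h2_A, Me_AC)
  expect_equal(
    accuracy_wientjes(1000, 500, 0.5, 0.3, 500, 400, 1, 0.7, 0, 1, 0),
    accuracy_daetwyler(1000, 0.5, 500), tolerance = 1e-12)
  # zero numerator vector
  expect_equal(
    accuracy_wientjes(1000, 500, 0.5, 0.3, 500, 400, 0, 0, 0.5, 1, 1), 0)
  # near-singular P (|rGAB| = 1, negligible 1/N) raises a linear-algebra error
  expect_error(
    accuracy_wientjes(1e15, 1e15, 0.5, 0.5, 500, 500, 0.8, 0.8, 1, 1, 1),
    "condition", class = "gpasim_linalg_error")
})

test_that("validation rejects out-of-domain values and names the field", {
  expect_error(accuracy_daetwyler(0, 0.5, 500), "n_train",
               class = "gpasim_validation_error")
  expect_error(accuracy_daetwyler(1000, 1.2, 500), "h2",
               class = "gpasim_validation_error")
  expect_error(accuracy_daetwyler(1000, 0.5, -5), "me",
               class = "gpasim_validation_error")
  expect_error(accuracy_daetwyler(1000.5, 0.5, 500), "n_train",
               class = "gpasim_validation_error")
  err <- tryCatch(accuracy_karaman(1000, 0, 500), condition = identity)
  expect_s3_class(err, "gpasim_validation_error")
  expect_identical(err$field, "h2_m")
})

test_that("registry has eight ordered entries and evaluate_formula dispatches", {
  reg <- formula_registry()
  expect_identical(nrow(reg), 8L)
  expect_identical(reg$formula_id,
                   c("daetwyler", "goddard2009", "goddard2011", "rabier",
                     "rabier_eterm", "deloscampos", "karaman", "wientjes"))
  expect_identical(reg$letter, letters[1:8])
  expect_false(anyDuplicated(reg$formula_id) > 0)

  # dispatch identity, with alias names
  expect_identical(evaluate_formula("daetwyler", list(N = 1000, h2 = 0.5, Me = 500)),
                   accuracy_daetwyler(1000, 0.5, 500))
  expect_identical(
    evaluate_formula("wientjes",
                     list("NA" = 1000, NB = 500, h2A = 0.5, h2B = 0.3,
                          MeAC = 500, MeBC = 400, rGAC = 1, rGBC = 0.7,
                          rGAB = 0, bAC = 1, bBC = 0)),
    accuracy_wientjes(1000, 500, 0.5, 0.3, 500, 400, 1, 0.7, 0, 1, 0))
  expect_error(evaluate_formula("nosuch", list()), "valid identifiers",
               class = "gpasim_lookup_error")
  # missing required field
  expect_error(evaluate_formula("goddard2009", list(N = 100, h2 = 0.5, Me = 50)),
               "ne", class = "gpasim_validation_error")
})

test_that("every formula stays in [0, 1] and is monotone as stated", {
  withr::with_seed(17, {
    k <- 1000
    p <- rand_within_params(k, h2_max = 0.999)
    for (i in seq_len(k)) {
      vals <- c(
        accuracy_daetwyler(p$n_train[i], p$h2[i], p$me[i]),
        accuracy_goddard2009(p$n_train[i], p$h2[i], p$me[i], p$ne[i]),
        accuracy_goddard2011(p$n_train[i], p$h2[i], p$me[i], b = p$b[i]),
        accuracy_rabier(p$n_train[i], p$h2[i], p$me[i]),
        accuracy_rabier_eterm(p$h2[i], p$eterm[i]),
        accuracy_deloscampos(p$b[i], p$h2[i]),
        accuracy_karaman(p$n_train[i], p$h2_m[i], p$me[i])
      )
      expect_true(all(vals >= 0 & vals <= 1))
    }
    pm <- rand_multi_params(k)
    for (i in seq_len(k)) {
      r <- wientjes_row(pm, i)
      expect_true(r >= 0 && r <= 1 + 1e-12)
    }
    # pairwise monotonicity on ordered random inputs
    for (i in seq_len(200)) {
      n1 <- p$n_train[i]; n2 <- n1 + sample(1:5000, 1)
      h1 <- p$h2[i] * 0.5; h2b <- p$h2[i]
      m1 <- p$me[i]; m2 <- m1 + runif(1, 1, 1000)
      expect_lte(accuracy_daetwyler(n1, h1, m1), accuracy_daetwyler(n2, h1, m1))
      expect_lte(accuracy_daetwyler(n1, h1, m1), accuracy_daetwyler(n1, h2b, m1))
      expect_gte(accuracy_daetwyler(n1, h1, m1), accuracy_daetwyler(n1, h1, m2))
      expect_lte(accuracy_goddard2009(n1, h1, m1, p$ne[i]),
                 accuracy_goddard2009(n2, h1, m1, p$ne[i]) + 1e-12)
      expect_lte(accuracy_rabier(n1, h1, m1), accuracy_rabier(n2, h1, m1))
      expect_gte(accuracy_rabier(n1, h1, m1), accuracy_rabier(n1, h1, m2))
      expect_lte(accuracy_goddard2011(n1, h1, m1, b = p$b[i] * 0.5),
                 accuracy_goddard2011(n1, h1, m1, b = p$b[i]) + 1e-15)
      expect_lte(accuracy_karaman(n1, h1, m1), accuracy_karaman(n2, h1, m1))
    }
  })
})
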
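# Published component sets used throughout: the two pairings' behavioural
# and technical G-study columns.
vc_mh_b <- preset_components("last_mh_behavioural")
vc_mh_t <- preset_components("last_mh_technical")
vc_hem_b <- preset_components("last_hem_behavioural")
vc_hem_t <- preset_components("last_hem_technical")

test_that("relative error variance follows the sigma2_delta formula", {
  no_err <- variance_components(c(p = 2, t = 1, r = 1, pt = 0, pr = 0,
                                  tr = 0.5, e = 0))
  expect_equal(relative_error_variance(no_err, 3, 2), 0)
  # direct arithmetic from the behavioural components:
  # 2.14/2 + 0.42/2 + 0.81/4
  expect_equal(relative_error_variance(vc_mh_b, 2, 2), 1.4825)
  # doubling both facet sizes halves the interaction terms, quarters error
  v1 <- relative_error_variance(vc_mh_b, 2, 2)
  v2 <- relative_error_variance(vc_mh_b, 4, 4)
  expect_equal(v2, 2.14 / 4 + 0.42 / 4 + 0.81 / 16)
  expect_lt(v2, v1)
})

test_that("absolute error variance adds facet main effects", {
  no_mains <- variance_components(c(p = 2, t = 0, r = 0, pt = 1, pr = 0.5,
                                    tr = 0, e = 0.8))
  expect_equal(absolute_error_variance(no_mains, 3, 2),
               relative_error_variance(no_mains, 3, 2))
  expect_equal(absolute_error_variance(vc_hem_b, 2, 2),
               relative_error_variance(vc_hem_b, 2, 2) + 3.51 / 2 + 0.51 / 2)
  zero <- variance_components(rep(0, 7))
  expect_equal(absolute_error_variance(zero, 2, 2), 0)
})

test_that("g_coefficient recovers the published reliability footers", {
  # components are printed to 2 dp, so recomputed coefficients can sit up
  # to ~0.01 from the printed ones; compare with that tolerance
  expect_g <- function(vc, nt, nr, printed) {
    expect_lt(abs(g_coefficient(vc, nt, nr) - printed), 0.0105)
  }
  # LAST/MH behavioural: 0.43 at (2,2), 0.61 at (10,1), 0.76 at (20,2)
  expect_g(vc_mh_b, 2, 2, 0.43)
  expect_g(vc_mh_b, 10, 1, 0.61)
  expect_g(vc_mh_b, 20, 2, 0.76)
  # technical column: 0.41, 0.54, 0.71
  expect_g(vc_mh_t, 2, 2, 0.41)
  expect_g(vc_mh_t, 10, 1, 0.54)
  expect_g(vc_mh_t, 20, 2, 0.71)
  # LAST/Hemorrhage behavioural: 0.34, 0.37, 0.56
  expect_g(vc_hem_b, 2, 2, 0.34)
  expect_g(vc_hem_b, 10, 1, 0.37)
  expect_g(vc_hem_b, 20, 2, 0.56)
  # technical: 0.27 and 0.58 at (2,2) and (20,2); the printed (10,1) entry
  # is inconsistent with the printed components and is not asserted
  expect_g(vc_hem_t, 2, 2, 0.27)
  expect_g(vc_hem_t, 20, 2, 0.58)

  perfect <- variance_components(c(p = 1, t = 0, r = 0, pt = 0, pr = 0,
                                   tr = 0, e = 0))
  expect_equal(g_coefficient(perfect, 1, 1), 1)
  no_person <- variance_components(c(p = 0, t = 0, r = 0, pt = 1, pr = 0,
                                     tr = 0, e = 1))
  expect_error(g_coefficient(no_person, 2, 2),
               class = "gcross_degenerate_error")
})

test_that("phi equals g without facet main effects and never exceeds it", {
  no_mains <- variance_components(c(p = 2, t = 0, r = 0, pt = 1, pr = 0.5,
                                    tr = 0, e = 0.8))
  expect_equal(phi_coefficient(no_mains, 2, 2),
               g_coefficient(no_mains, 2, 2))
  expect_lt(phi_coefficient(vc_hem_b, 2, 2), g_coefficient(vc_hem_b, 2, 2))
  perfect <- variance_components(c(p = 1, t = 0, r = 0, pt = 0, pr = 0,
                                   tr = 0, e = 0))
  expect_equal(phi_coefficient(perfect, 1, 1), 1)
})

test_that("g and phi are monotone in both facets and properly bounded", {
  for (vc in list(vc_mh_b, vc_mh_t, vc_hem_b, vc_hem_t)) {
    g <- outer(1:50, 1:10, Vectorize(function(nt, nr) {
      g_coefficient(vc, nt, nr)
    }))
    phi <- outer(1:50, 1:10, Vectorize(function(nt, nr) {
      phi_coefficient(vc, nt, nr)
    }))
    expect_true(all(g > 0 & g <= 1))
    expect_true(all(phi <= g + 1e-12))
    expect_true(all(diff(g) >= -1e-12))         # nondecreasing in tasks
    expect_true(all(t(diff(t(g))) >= -1e-12))   # nondecreasing in raters
  }
})

test_that("g approaches 1 as both facets grow without bound", {
  for (vc in list(vc_mh_b, vc_hem_t)) {
    expect_equal(g_coefficient(vc, 1e6, 1e6), 1, tolerance = 1e-5)
  }
})

test_that("min_tasks_for_target finds the published scenario requirement", {
  # behavioural LAST/MH with 2 raters needs 10 tasks for G >= 0.70
  expect_equal(min_tasks_for_target(vc_mh_b, 2, 0.70), 10L,
               ignore_attr = TRUE)
  # consistency: the found size meets the target, one fewer does not
  expect_gte(g_coefficient(vc_mh_b, 10, 2), 0.70)
  expect_lt(g_coefficient(vc_mh_b, 9, 2), 0.70)

  # LAST/Hemorrhage behavioural: asymptote ~0.597 < 0.70, unattainable
  mt <- min_tasks_for_target(vc_hem_b, 2, 0.70)
  expect_true(is.na(mt))
  expect_equal(attr(mt, "asymptote"), 0.69 / (0.69 + 0.93 / 2),
               tolerance = 1e-12)

  perfect <- variance_components(c(p = 1, t = 0, r = 0, pt = 0, pr = 0,
                                   tr = 0, e = 0))
  expect_equal(min_tasks_for_target(perfect, 1, 0.95), 1L,
               ignore_attr = TRUE)
  expect_error(min_tasks_for_target(vc_mh_b, 2, 1.2),
               class = "gcross_validation_error")
})

test_that("g_table evaluates the default designs in order", {
  tab <- g_table(vc_mh_t)
  expect_equal(tab$n_tasks, c(2L, 10L, 20L))
  expect_equal(tab$n_raters, c(2L, 1L, 2L))
  expect_true(all(abs(tab$g - c(0.41, 0.54, 0.71)) < 0.0105))
  expect_true(all(tab$abs_error_var >= tab$rel_error_var - 1e-12))

  tab4 <- g_table(vc_hem_b, list(c(2, 2), c(20, 2)))
  expect_true(all(abs(tab4$g - c(0.34, 0.56)) < 0.0105))

  expect_error(g_table(vc_mh_b, list()), class = "gcross_validation_error")
})
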
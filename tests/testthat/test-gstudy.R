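test_that("degenerate cubes give the textbook mean squares", {
  const <- rating_cube(array(6, c(2, 2, 2)), "behavioural")
  ms <- anova_mean_squares(const)
  expect_true(all(ms$ms == 0))
  expect_equal(unname(ms$df), c(1, 1, 1, 1, 1, 1, 1))

  # person-only variation: persons score 4 and 6 across every task/rater,
  # so MS_p = n_t * n_r * var(person means) = 4 * 2 = 8, all else 0
  y <- array(rep(c(4, 6), 4), c(2, 2, 2))
  ms2 <- anova_mean_squares(rating_cube(y, "behavioural"))
  expect_equal(ms2$ms[["p"]], 8)
  expect_equal(unname(ms2$ms[c("t", "r", "pt", "pr", "tr", "e")]),
               rep(0, 6))

  vc <- solve_variance_components(ms2)
  expect_equal(vc$sigma2[["p"]], 2)
  expect_equal(unname(vc$sigma2[c("t", "r", "pt", "pr", "tr", "e")]),
               rep(0, 6))
})

test_that("single-level facets are rejected as non-estimable", {
  expect_error(anova_mean_squares(random_cube(5, 1, 2)),
               class = "gcross_estimability_error")
  expect_error(anova_mean_squares(random_cube(5, 2, 1)),
               class = "gcross_estimability_error")
})

test_that("mean squares agree with the brute-force oracle on all small designs", {
  set.seed(101)
  for (n_p in 2:4) for (n_t in 2:3) for (n_r in 2:3) {
    for (rep in 1:3) {
      cube <- random_cube(n_p, n_t, n_r, integers = (rep == 1))
      ms <- anova_mean_squares(cube)
      ss_oracle <- oracle_sums_of_squares(cube$scores)
      expect_equal(unname(ms$ss), unname(ss_oracle[names(ms$ss)]),
                   tolerance = 1e-9)
      # ANOVA identity: df-weighted mean squares sum to total SS
      expect_equal(sum(ms$df * ms$ms),
                   sum((cube$scores - mean(cube$scores))^2),
                   tolerance = 1e-9)
    }
  }
})

test_that("sums of squares match stats::aov on a crossed factorial", {
  set.seed(202)
  cube <- random_cube(4, 3, 2)
  long <- cube_to_records(cube)
  long$P <- factor(long$person_id)
  long$T <- factor(long$task_id)
  long$R <- factor(long$rater_id)
  fit <- summary(stats::aov(score ~ P * T * R, data = long))[[1L]]
  aov_ss <- setNames(fit[["Sum Sq"]], trimws(rownames(fit)))
  ms <- anova_mean_squares(cube)
  expect_equal(ms$ss[["p"]], aov_ss[["P"]], tolerance = 1e-8)
  expect_equal(ms$ss[["t"]], aov_ss[["T"]], tolerance = 1e-8)
  expect_equal(ms$ss[["r"]], aov_ss[["R"]], tolerance = 1e-8)
  expect_equal(ms$ss[["pt"]], aov_ss[["P:T"]], tolerance = 1e-8)
  expect_equal(ms$ss[["pr"]], aov_ss[["P:R"]], tolerance = 1e-8)
  expect_equal(ms$ss[["tr"]], aov_ss[["T:R"]], tolerance = 1e-8)
  expect_equal(ms$ss[["e"]], aov_ss[["P:T:R"]], tolerance = 1e-8)
})

test_that("the EMS solution matches hand substitution and truncates negatives", {
  set.seed(303)
  for (i in 1:10) {
    cube <- random_cube(3, 2, 2)
    ms <- anova_mean_squares(cube)
    vc <- solve_variance_components(ms)
    hand <- oracle_solve_ems(ms$ms, ms$n_p, ms$n_t, ms$n_r)
    expect_equal(unname(vc$raw), unname(hand[names(vc$raw)]),
                 tolerance = 1e-10)
    expect_true(all(vc$sigma2 >= 0))
    expect_equal(vc$sigma2[vc$raw >= 0], vc$raw[vc$raw >= 0])
    expect_true(all(vc$sigma2[vc$raw < 0] == 0))
  }
})

test_that("variance components are invariant to score translation", {
  set.seed(404)
  cube <- random_cube(6, 3, 2)
  shifted <- rating_cube(cube$scores + 2.3, cube$measure)
  expect_equal(gstudy(cube)$raw, gstudy(shifted)$raw, tolerance = 1e-9)
})

test_that("EMS estimators are unbiased over replicated simulation", {
  truth <- c(p = 1.10, t = 0.30, r = 0.20, pt = 2.14, pr = 0.42,
             tr = 0.16, e = 0.81)
  n_reps <- 1000
  spec <- simulation_spec(20, 4, 3, truth, seed = 515, n_reps = n_reps)
  rep <- recovery_experiment(spec)
  # each component's Monte-Carlo mean within 3 standard errors of truth
  z <- abs(rep$components$bias) / rep$components$mc_se
  expect_true(all(z < 3), info = paste(round(z, 2), collapse = ", "))
  # RMSE^2 >= bias^2 by construction
  expect_true(all(rep$components$rmse^2 >=
                    rep$components$bias^2 - 1e-12))
})

test_that("percent_of_total reproduces published person shares", {
  vc_b <- variance_components(c(p = 1.10, t = 0, r = 0, pt = 2.14,
                                pr = 0.42, tr = 0.16, e = 0.81))
  expect_equal(percent_of_total(vc_b)[["p"]], 23.8)
  vc_t <- variance_components(c(p = 1.01, t = 0, r = 0, pt = 1.93,
                                pr = 0.60, tr = 0, e = 0.79))
  expect_equal(percent_of_total(vc_t)[["p"]], 23.3)
  expect_equal(sum(percent_of_total(vc_b)), 100, tolerance = 0.3)

  single <- variance_components(c(p = 0.5, t = 0, r = 0, pt = 0, pr = 0,
                                  tr = 0, e = 0))
  expect_equal(percent_of_total(single)[["p"]], 100)
  zero <- variance_components(rep(0, 7))
  expect_error(percent_of_total(zero), class = "gcross_degenerate_error")
})

test_that("lme4 REML cross-checks the EMS components on a well-filled design", {
  # independent estimation route for balanced data with all-positive truth
  spec <- simulation_spec(40, 4, 4,
                          c(p = 1.2, t = 0.5, r = 0.4, pt = 1.0, pr = 0.5,
                            tr = 0.3, e = 0.8),
                          seed = 616)
  cube <- simulate_ratings(spec)
  vc <- gstudy(cube)

  long <- cube_to_records(cube)
  fit <- lme4::lmer(
    score ~ 1 + (1 | person_id) + (1 | task_id) + (1 | rater_id) +
      (1 | person_id:task_id) + (1 | person_id:rater_id) +
      (1 | task_id:rater_id),
    data = long,
    control = lme4::lmerControl(check.conv.singular = lme4::.makeCC("ignore", 1e-4))
  )
  vc_reml <- as.data.frame(lme4::VarCorr(fit))
  reml <- setNames(vc_reml$vcov, vc_reml$grp)
  expect_equal(vc$sigma2[["p"]], reml[["person_id"]], tolerance = 0.15)
  expect_equal(vc$sigma2[["pt"]], reml[["person_id:task_id"]], tolerance = 0.15)
  expect_equal(vc$sigma2[["e"]], reml[["Residual"]], tolerance = 0.1)
})
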
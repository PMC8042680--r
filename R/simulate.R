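#' @title Synthetic crossed rating data
#' @description Seeded generator of balanced person x task x rater scores
#'   under the additive random-effects model the G study assumes, and
#'   Monte-Carlo parameter-recovery experiments built on it.
#' @name synthetic-data
NULL

#' Specification of a synthetic crossed-rating simulation
#'
#' @param n_p,n_t,n_r design sizes (persons, tasks, raters).
#' @param sigma2 the seven component variances, in squared score points:
#'   either a [variance_components()] object (e.g. from
#'   [preset_components()]) or a named/ordered length-7 numeric vector
#'   (`p, t, r, pt, pr, tr, e`).
#' @param mu grand mean in score points; defaults to 5.5, the midpoint of
#'   the 1-9 scale. The grand mean never affects variance components.
#' @param seed integer seed governing the full replication stream.
#' @param discretize if `TRUE`, scores are rounded to the nearest integer
#'   and clipped to `[1, 9]` after simulation, emulating raw 9-point
#'   ratings. Off by default: rounding and clipping shrink the total
#'   variance, so component-recovery properties are stated for the
#'   continuous generator.
#' @param n_reps number of replications for [recovery_experiment()].
#' @param measure measure label attached to simulated cubes.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_p, n_t, n_r, sigma2, mu = 5.5, seed = 1L,
                            discretize = FALSE, n_reps = 1L,
                            measure = "behavioural") {
  if (inherits(sigma2, "variance_components")) {
    if (is.null(measure) && !is.null(sigma2$measure)) measure <- sigma2$measure
    sigma2 <- sigma2$sigma2
  }
  if (is.null(names(sigma2))) {
    stopifnot(length(sigma2) == 7L)
    names(sigma2) <- COMPONENT_NAMES
  }
  sigma2 <- sigma2[COMPONENT_NAMES]
  stopifnot(n_p >= 1, n_t >= 1, n_r >= 1, n_reps >= 1,
            all(sigma2 >= 0), is.finite(mu))
  structure(list(n_p = as.integer(n_p), n_t = as.integer(n_t),
                 n_r = as.integer(n_r), mu = mu, sigma2 = sigma2,
                 seed = as.integer(seed), discretize = isTRUE(discretize),
                 n_reps = as.integer(n_reps), measure = measure),
            class = "simulation_spec")
}

#' Simulate a balanced crossed rating cube
#'
#' Draws scores under the additive random-effects model
#' \deqn{y_{ptr} = \mu + a_p + b_t + c_r + (ab)_{pt} + (ac)_{pr} +
#'       (bc)_{tr} + e_{ptr}}
#' with every effect independent normal with its specified variance.
#' Identical spec and seed give identical output. Discretization to the
#' 9-point scale, when requested, is applied last.
#'
#' @param spec a [simulation_spec()].
#' @return a [rating_cube()]; the attribute `continuous_var` records the
#'   total sample variance before any discretization so the shrinkage it
#'   causes is visible.
#' @export
simulate_ratings <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(spec$seed)
  simulate_ratings_stream(spec)
}

# Simulation body without seed management: used inside replication loops
# where one seed governs the whole stream.
simulate_ratings_stream <- function(spec) {
  n_p <- spec$n_p; n_t <- spec$n_t; n_r <- spec$n_r
  s <- sqrt(spec$sigma2)
  a_p <- stats::rnorm(n_p, 0, s[["p"]])
  b_t <- stats::rnorm(n_t, 0, s[["t"]])
  c_r <- stats::rnorm(n_r, 0, s[["r"]])
  ab <- matrix(stats::rnorm(n_p * n_t, 0, s[["pt"]]), n_p, n_t)
  ac <- matrix(stats::rnorm(n_p * n_r, 0, s[["pr"]]), n_p, n_r)
  bc <- matrix(stats::rnorm(n_t * n_r, 0, s[["tr"]]), n_t, n_r)
  e <- array(stats::rnorm(n_p * n_t * n_r, 0, s[["e"]]), c(n_p, n_t, n_r))

  y <- spec$mu + e +
    outer(a_p, rep(1, n_t)) %o% rep(1, n_r) +
    outer(rep(1, n_p), b_t) %o% rep(1, n_r) +
    outer(rep(1, n_p), rep(1, n_t)) %o% c_r +
    ab %o% rep(1, n_r) +
    aperm(ac %o% rep(1, n_t), c(1L, 3L, 2L)) +
    aperm(bc %o% rep(1, n_p), c(3L, 1L, 2L))

  cont_var <- stats::var(as.vector(y))
  if (spec$discretize) {
    y <- pmin(pmax(round(y), 1), 9)
  }
  dimnames(y) <- list(
    sprintf("P%02d", seq_len(n_p)),
    sprintf("T%02d", seq_len(n_t)),
    sprintf("R%02d", seq_len(n_r))
  )
  cube <- rating_cube(y, spec$measure)
  attr(cube, "continuous_var") <- cont_var
  cube
}

#' Monte-Carlo parameter-recovery experiment
#'
#' Simulates `n_reps` cubes from the spec, runs the G study on each, and
#' summarises how well the EMS estimator recovers the generating
#' components: per component the truth, mean raw estimate, bias, RMSE and
#' Monte-Carlo standard error (bias uses raw, untruncated estimates —
#' truncation induces positive bias by construction), plus the
#' distribution of the estimated generalizability coefficient at the
#' (2 tasks, 2 raters) design computed from truncated components. Mean
#' continuous and post-discretization total variances are recorded so the
#' shrinkage caused by discretizing to the 9-point scale is visible.
#'
#' @param spec a [simulation_spec()] with `n_p, n_t, n_r >= 2`; `n_reps`
#'   replications are drawn from the single seed's stream.
#' @return object of class `recovery_report`: list with `components` (data
#'   frame: `component`, `truth`, `mean_estimate`, `bias`, `rmse`,
#'   `mc_se`), `g22` (vector of estimated G(2,2), `NA` where the person
#'   component truncated to zero), `mean_g22`, `total_var_continuous`,
#'   `total_var_observed`, and the spec.
#' @export
recovery_experiment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$n_p < 2L || spec$n_t < 2L || spec$n_r < 2L) {
    gc_stop("gcross_estimability_error",
            "recovery needs at least 2 levels of every facet")
  }
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(spec$seed)

  raws <- matrix(NA_real_, spec$n_reps, 7L,
                 dimnames = list(NULL, COMPONENT_NAMES))
  g22 <- rep(NA_real_, spec$n_reps)
  cont_var <- obs_var <- rep(NA_real_, spec$n_reps)
  for (i in seq_len(spec$n_reps)) {
    cube <- simulate_ratings_stream(spec)
    vc <- gstudy(cube)
    raws[i, ] <- vc$raw
    if (vc$sigma2[["p"]] > 0) g22[i] <- g_coefficient(vc, 2L, 2L)
    cont_var[i] <- attr(cube, "continuous_var")
    obs_var[i] <- stats::var(as.vector(cube$scores))
  }

  truth <- spec$sigma2
  mean_est <- colMeans(raws)
  bias <- mean_est - truth
  rmse <- sqrt(colMeans(sweep(raws, 2L, truth)^2))
  mc_se <- apply(raws, 2L, stats::sd) / sqrt(spec$n_reps)

  structure(list(
    components = data.frame(
      component = COMPONENT_NAMES, truth = unname(truth),
      mean_estimate = unname(mean_est), bias = unname(bias),
      rmse = unname(rmse), mc_se = unname(mc_se),
      stringsAsFactors = FALSE
    ),
    g22 = g22,
    mean_g22 = mean(g22, na.rm = TRUE),
    total_var_continuous = mean(cont_var),
    total_var_observed = mean(obs_var),
    spec = spec
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d reps of a %d x %d x %d design\n",
              x$spec$n_reps, x$spec$n_p, x$spec$n_t, x$spec$n_r))
  df <- x$components
  df[-1L] <- lapply(df[-1L], round_half_up, digits = 4)
  print(df, row.names = FALSE)
  cat(sprintf("mean estimated G(2,2): %.3f (truth-implied %.3f)\n",
              x$mean_g22,
              tryCatch(g_coefficient(variance_components(x$spec$sigma2), 2, 2),
                       error = function(e) NA_real_)))
  if (x$spec$discretize) {
    cat(sprintf("total variance: continuous %.3f -> discretized %.3f\n",
                x$total_var_continuous, x$total_var_observed))
  }
  invisible(x)
}
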
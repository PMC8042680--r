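#' @title D study: projecting components onto hypothetical designs
#' @description Error variances and reliability coefficients for designs
#'   with `n_t'` tasks and `n_r'` raters, computed from (truncated) variance
#'   components, plus a search for the smallest design reaching a target
#'   reliability.
#' @name dstudy
NULL

#' Relative error variance of a hypothetical design
#'
#' The error affecting rank-order (relative) decisions when each person is
#' measured on `n_t_prime` tasks by `n_r_prime` raters, all randomly drawn:
#' \deqn{\sigma^2_\delta = \sigma^2_{pt}/n'_t + \sigma^2_{pr}/n'_r +
#'       \sigma^2_e/(n'_t n'_r)}
#'
#' @param vc a [variance_components()] object (reported, i.e. truncated,
#'   components are used).
#' @param n_t_prime,n_r_prime numbers of tasks and raters in the
#'   hypothetical design (positive integers).
#' @return nonnegative real.
#' @export
relative_error_variance <- function(vc, n_t_prime, n_r_prime) {
  stopifnot(inherits(vc, "variance_components"),
            n_t_prime >= 1, n_r_prime >= 1)
  s <- vc$sigma2
  s[["pt"]] / n_t_prime + s[["pr"]] / n_r_prime +
    s[["e"]] / (n_t_prime * n_r_prime)
}

#' Absolute error variance of a hypothetical design
#'
#' Adds the facet main effects and their interaction, giving the error for
#' absolute (criterion-referenced) decisions:
#' \deqn{\sigma^2_\Delta = \sigma^2_t/n'_t + \sigma^2_r/n'_r +
#'       \sigma^2_{pt}/n'_t + \sigma^2_{pr}/n'_r +
#'       (\sigma^2_{tr} + \sigma^2_e)/(n'_t n'_r)}
#'
#' @inheritParams relative_error_variance
#' @return nonnegative real, `>=` the relative error variance.
#' @export
absolute_error_variance <- function(vc, n_t_prime, n_r_prime) {
  stopifnot(inherits(vc, "variance_components"),
            n_t_prime >= 1, n_r_prime >= 1)
  s <- vc$sigma2
  s[["t"]] / n_t_prime + s[["r"]] / n_r_prime +
    s[["pt"]] / n_t_prime + s[["pr"]] / n_r_prime +
    (s[["tr"]] + s[["e"]]) / (n_t_prime * n_r_prime)
}

#' Generalizability coefficient (relative reliability)
#'
#' \deqn{E\rho^2 = \sigma^2_p / (\sigma^2_p + \sigma^2_\delta(n'_t, n'_r))}
#'
#' This is the coefficient reported as "G" in crossed-design reliability
#' tables; both facets are treated as random (tasks and raters drawn from
#' their universes), which is also the right reading of a design with one
#' randomly selected rater per task.
#'
#' @inheritParams relative_error_variance
#' @return real in `(0, 1]`.
#' @export
g_coefficient <- function(vc, n_t_prime, n_r_prime) {
  stopifnot(inherits(vc, "variance_components"))
  s2p <- vc$sigma2[["p"]]
  if (s2p <= 0) {
    gc_stop("gcross_degenerate_error",
            "reliability is undefined when the person variance component is zero")
  }
  s2p / (s2p + relative_error_variance(vc, n_t_prime, n_r_prime))
}

#' Dependability coefficient (absolute reliability)
#'
#' \deqn{\Phi = \sigma^2_p / (\sigma^2_p + \sigma^2_\Delta(n'_t, n'_r))}
#'
#' Companion to [g_coefficient()] for absolute decisions; always
#' `<=` the generalizability coefficient.
#'
#' @inheritParams relative_error_variance
#' @return real in `(0, 1]`.
#' @export
phi_coefficient <- function(vc, n_t_prime, n_r_prime) {
  stopifnot(inherits(vc, "variance_components"))
  s2p <- vc$sigma2[["p"]]
  if (s2p <= 0) {
    gc_stop("gcross_degenerate_error",
            "reliability is undefined when the person variance component is zero")
  }
  s2p / (s2p + absolute_error_variance(vc, n_t_prime, n_r_prime))
}

#' Smallest number of tasks reaching a target reliability
#'
#' Increments `n_t'` from 1 until the generalizability coefficient at
#' (`n_t'`, `n_r_prime`) reaches `target`. As `n_t'` grows the coefficient
#' approaches the asymptote
#' \eqn{\sigma^2_p / (\sigma^2_p + \sigma^2_{pr}/n'_r)}; when that limit is
#' below the target no number of tasks suffices and `NA` is returned
#' (with an attribute carrying the asymptote).
#'
#' @param vc a [variance_components()] object with `sigma2_p > 0`.
#' @param n_r_prime number of raters in the hypothetical design.
#' @param target required reliability, in (0, 1).
#' @return smallest integer `n_t'` meeting the target, or `NA_integer_`
#'   with attribute `asymptote` when unattainable.
#' @export
min_tasks_for_target <- function(vc, n_r_prime, target) {
  stopifnot(inherits(vc, "variance_components"), n_r_prime >= 1)
  if (!is.numeric(target) || length(target) != 1L ||
      target <= 0 || target >= 1) {
    gc_stop("gcross_validation_error",
            "target reliability must be a single value in (0, 1)")
  }
  s2p <- vc$sigma2[["p"]]
  if (s2p <= 0) {
    gc_stop("gcross_degenerate_error",
            "reliability is undefined when the person variance component is zero")
  }
  asymptote <- s2p / (s2p + vc$sigma2[["pr"]] / n_r_prime)
  if (asymptote < target) {
    return(structure(NA_integer_, asymptote = asymptote))
  }
  n_t <- 1L
  while (g_coefficient(vc, n_t, n_r_prime) < target) n_t <- n_t + 1L
  n_t
}

#' D-study table over a list of designs
#'
#' Evaluates error variances and both reliability coefficients for each
#' hypothetical design. The default designs mirror the customary reporting
#' footer: (2 tasks, 2 raters), (10 tasks, 1 rater), (20 tasks, 2 raters).
#'
#' @param vc a [variance_components()] object.
#' @param designs list of `c(n_t_prime, n_r_prime)` pairs, or a 2-column
#'   matrix with one design per row.
#' @return data frame with columns `n_tasks`, `n_raters`, `rel_error_var`,
#'   `abs_error_var`, `g`, `phi`, one row per design in input order.
#' @export
g_table <- function(vc, designs = list(c(2, 2), c(10, 1), c(20, 2))) {
  stopifnot(inherits(vc, "variance_components"))
  if (is.matrix(designs)) {
    designs <- lapply(seq_len(nrow(designs)), function(i) designs[i, ])
  }
  if (length(designs) == 0L) {
    gc_stop("gcross_validation_error", "design list is empty")
  }
  rows <- lapply(designs, function(d) {
    stopifnot(length(d) == 2L)
    nt <- as.integer(d[[1L]]); nr <- as.integer(d[[2L]])
    data.frame(
      n_tasks = nt, n_raters = nr,
      rel_error_var = relative_error_variance(vc, nt, nr),
      abs_error_var = absolute_error_variance(vc, nt, nr),
      g = g_coefficient(vc, nt, nr),
      phi = phi_coefficient(vc, nt, nr)
    )
  })
  do.call(rbind, rows)
}
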
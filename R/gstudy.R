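#' @title G study: variance components of the crossed p x t x r design
#' @description Balanced three-way random-effects ANOVA and the expected
#'   mean squares (EMS) solution for the seven variance components
#'   (person, task, rater, their pairwise interactions, and residual).
#' @name gstudy
NULL

#' ANOVA mean squares of a balanced crossed cube
#'
#' Computes the classical balanced three-way ANOVA decomposition directly
#' from marginal means. For the fully crossed design with one observation
#' per (person, task, rater) cell, the seven sums of squares are
#'
#' \deqn{SS_p = n_t n_r \sum_p (\bar y_{p..} - \bar y)^2}
#' \deqn{SS_{pt} = n_r \sum_{p,t} (\bar y_{pt.} - \bar y_{p..} - \bar y_{.t.} + \bar y)^2}
#'
#' (and analogously for the other mains and interactions), with the
#' three-way interaction cell residual absorbing everything left; it plays
#' the role of the error term since there is no replication within cells.
#' Each mean square is its sum of squares divided by its degrees of
#' freedom, and the decomposition satisfies the ANOVA identity
#' \eqn{\sum_{effects} df \cdot MS = \sum (y - \bar y)^2}.
#'
#' All three facets must have at least two levels, otherwise some of the
#' seven effects are confounded and not estimable.
#'
#' @param cube a [rating_cube()] with `n_p, n_t, n_r >= 2`.
#' @return object of class `mean_squares`: list with numeric vectors `ms`
#'   and `df` (names `p, t, r, pt, pr, tr, e`), `ss`, and the design sizes
#'   `n_p`, `n_t`, `n_r`.
#' @export
anova_mean_squares <- function(cube) {
  stopifnot(inherits(cube, "rating_cube"))
  y <- cube$scores
  n <- dim(y)
  n_p <- n[1L]; n_t <- n[2L]; n_r <- n[3L]
  if (n_p < 2L || n_t < 2L || n_r < 2L) {
    small <- c("p", "t", "r")[n < 2L]
    gc_stop("gcross_estimability_error",
            "facet(s) with a single level (%s): the corresponding main and interaction effects are not estimable",
            paste(small, collapse = ", "))
  }

  gm <- mean(y)
  m_p <- apply(y, 1L, mean)            # person margins
  m_t <- apply(y, 2L, mean)
  m_r <- apply(y, 3L, mean)
  m_pt <- apply(y, c(1L, 2L), mean)    # two-way margins
  m_pr <- apply(y, c(1L, 3L), mean)
  m_tr <- apply(y, c(2L, 3L), mean)

  ss <- c(
    p = n_t * n_r * sum((m_p - gm)^2),
    t = n_p * n_r * sum((m_t - gm)^2),
    r = n_p * n_t * sum((m_r - gm)^2),
    pt = n_r * sum((m_pt - outer(m_p, m_t, "+") + gm)^2),
    pr = n_t * sum((m_pr - outer(m_p, m_r, "+") + gm)^2),
    tr = n_p * sum((m_tr - outer(m_t, m_r, "+") + gm)^2),
    e = NA_real_
  )
  ss_total <- sum((y - gm)^2)
  ss["e"] <- ss_total - sum(ss[c("p", "t", "r", "pt", "pr", "tr")])
  ss["e"] <- max(ss[["e"]], 0)  # clip the tiny negative round-off can produce

  df <- c(
    p = n_p - 1L,
    t = n_t - 1L,
    r = n_r - 1L,
    pt = (n_p - 1L) * (n_t - 1L),
    pr = (n_p - 1L) * (n_r - 1L),
    tr = (n_t - 1L) * (n_r - 1L),
    e = (n_p - 1L) * (n_t - 1L) * (n_r - 1L)
  )
  structure(list(ms = ss / df, ss = ss, df = df,
                 n_p = n_p, n_t = n_t, n_r = n_r,
                 measure = cube$measure),
            class = "mean_squares")
}

#' @export
print.mean_squares <- function(x, ...) {
  cat(sprintf("<mean_squares> design %d x %d x %d\n", x$n_p, x$n_t, x$n_r))
  print(data.frame(effect = names(x$ms), df = unname(x$df),
                   SS = unname(round_half_up(x$ss, 4)),
                   MS = unname(round_half_up(x$ms, 4))), row.names = FALSE)
  invisible(x)
}

#' Solve the EMS equations for the variance components
#'
#' For the fully random balanced model the expected mean squares are
#' \deqn{E[MS_e] = \sigma^2_e}
#' \deqn{E[MS_{pt}] = \sigma^2_e + n_r \sigma^2_{pt}}
#' \deqn{E[MS_{pr}] = \sigma^2_e + n_t \sigma^2_{pr}}
#' \deqn{E[MS_{tr}] = \sigma^2_e + n_p \sigma^2_{tr}}
#' \deqn{E[MS_p] = \sigma^2_e + n_r \sigma^2_{pt} + n_t \sigma^2_{pr} + n_t n_r \sigma^2_p}
#' \deqn{E[MS_t] = \sigma^2_e + n_r \sigma^2_{pt} + n_p \sigma^2_{tr} + n_p n_r \sigma^2_t}
#' \deqn{E[MS_r] = \sigma^2_e + n_t \sigma^2_{pr} + n_p \sigma^2_{tr} + n_p n_t \sigma^2_r}
#'
#' The system is triangular, so the method-of-moments solution is obtained
#' by substitution. Raw solutions may be negative by sampling error; the
#' reported components truncate negatives to zero (the usual G-theory
#' convention, and what produces the zero rows in published component
#' tables). The raw solutions are kept alongside for bias diagnostics.
#'
#' @param ms a `mean_squares` object from [anova_mean_squares()].
#' @return a [variance_components()] object.
#' @export
solve_variance_components <- function(ms) {
  stopifnot(inherits(ms, "mean_squares"))
  m <- ms$ms
  n_p <- ms$n_p; n_t <- ms$n_t; n_r <- ms$n_r
  raw <- c(
    p = (m[["p"]] - m[["pt"]] - m[["pr"]] + m[["e"]]) / (n_t * n_r),
    t = (m[["t"]] - m[["pt"]] - m[["tr"]] + m[["e"]]) / (n_p * n_r),
    r = (m[["r"]] - m[["pr"]] - m[["tr"]] + m[["e"]]) / (n_p * n_t),
    pt = (m[["pt"]] - m[["e"]]) / n_r,
    pr = (m[["pr"]] - m[["e"]]) / n_t,
    tr = (m[["tr"]] - m[["e"]]) / n_p,
    e = m[["e"]]
  )
  variance_components(sigma2 = pmax(raw, 0), raw = raw,
                      n_p = n_p, n_t = n_t, n_r = n_r,
                      measure = ms$measure)
}

#' Variance components container
#'
#' Holds the seven variance components of the two-facet crossed model:
#' person (`p`), task (`t`), rater (`r`), person x task (`pt`),
#' person x rater (`pr`), task x rater (`tr`) and residual (`e`), in
#' squared score-point units. Reported components are nonnegative; when the
#' object comes from [solve_variance_components()] the pre-truncation raw
#' estimates ride along.
#'
#' @param sigma2 named numeric vector of the seven nonnegative components
#'   (names `p, t, r, pt, pr, tr, e`). A plain unnamed length-7 vector in
#'   that order is also accepted.
#' @param raw optional named vector of raw (possibly negative) estimates.
#' @param n_p,n_t,n_r design sizes of the generating G study, if known.
#' @param measure,label optional annotations.
#' @return object of class `variance_components`.
#' @export
variance_components <- function(sigma2, raw = NULL,
                                n_p = NA_integer_, n_t = NA_integer_,
                                n_r = NA_integer_,
                                measure = NULL, label = NULL) {
  if (is.null(names(sigma2))) {
    stopifnot(length(sigma2) == 7L)
    names(sigma2) <- COMPONENT_NAMES
  }
  stopifnot(setequal(names(sigma2), COMPONENT_NAMES))
  sigma2 <- sigma2[COMPONENT_NAMES]
  if (any(sigma2 < 0)) {
    gc_stop("gcross_validation_error",
            "reported variance components must be nonnegative")
  }
  if (is.null(raw)) raw <- sigma2
  structure(list(sigma2 = sigma2, raw = raw[COMPONENT_NAMES],
                 n_p = n_p, n_t = n_t, n_r = n_r,
                 measure = measure, label = label),
            class = "variance_components")
}

#' Percent-of-total decomposition
#'
#' Expresses each reported (truncated) component as a percentage of the sum
#' of all seven, rounded half-up to one decimal — the "%" column of a
#' G-study table. Percentages are computed from the unrounded components.
#'
#' @param vc a [variance_components()] object.
#' @param digits decimal places (default 1).
#' @return named numeric vector of seven percentages summing to 100 within
#'   rounding.
#' @export
percent_of_total <- function(vc, digits = 1) {
  stopifnot(inherits(vc, "variance_components"))
  total <- sum(vc$sigma2)
  if (total <= 0) {
    gc_stop("gcross_degenerate_error",
            "percent decomposition is undefined when all components are zero")
  }
  round_half_up(100 * vc$sigma2 / total, digits)
}

#' @export
print.variance_components <- function(x, digits = 2, ...) {
  hdr <- "<variance_components>"
  if (!is.null(x$label)) hdr <- paste(hdr, x$label)
  if (!is.null(x$measure)) hdr <- paste0(hdr, " [", x$measure, "]")
  cat(hdr, "\n")
  pct <- if (sum(x$sigma2) > 0) percent_of_total(x) else rep(NA_real_, 7L)
  print(data.frame(
    source = c("Person (P)", "Task (T)", "Rater (R)", "Person x Task",
               "Person x Rater", "Task x Rater", "Error"),
    estimate = unname(round_half_up(x$sigma2, digits)),
    percent = unname(pct)
  ), row.names = FALSE)
  invisible(x)
}

#' One-call G study
#'
#' Convenience wrapper: [anova_mean_squares()] followed by
#' [solve_variance_components()].
#'
#' @param cube a [rating_cube()].
#' @return a [variance_components()] object.
#' @export
gstudy <- function(cube) {
  solve_variance_components(anova_mean_squares(cube))
}

#' G-study table in published form
#'
#' @param vc a [variance_components()] object.
#' @param digits decimal places for the estimates.
#' @return data frame with columns `source`, `estimate`, `percent`.
#' @export
gstudy_table <- function(vc, digits = 2) {
  stopifnot(inherits(vc, "variance_components"))
  data.frame(
    source = c("Person (P)", "Task (T)", "Rater (R)", "Person x Task",
               "Person x Rater", "Task x Rater", "Error"),
    estimate = unname(round_half_up(vc$sigma2, digits)),
    percent = unname(percent_of_total(vc)),
    stringsAsFactors = FALSE
  )
}
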
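#' @title Scenario and rater descriptives
#' @description Per-cell means/SDs (scenario difficulty and rater
#'   stringency) and the pooled inter-rater and inter-task Pearson
#'   correlations.
#' @name descriptives
NULL

#' Mean and SD per task x rater cell
#'
#' Averages scores over persons within each task x rater cell, giving the
#' scenario-by-rater summary used to describe scenario difficulty and rater
#' stringency. SD uses the sample (n-1) denominator and is `NA` for cells
#' with a single person.
#'
#' @param cube a [rating_cube()].
#' @return data frame with columns `task_id`, `rater_id`, `measure`,
#'   `mean`, `sd`, `n`, one row per task x rater cell.
#' @export
cell_means <- function(cube) {
  stopifnot(inherits(cube, "rating_cube"))
  dn <- dimnames(cube$scores)
  n_p <- dim(cube$scores)[1L]
  out <- expand.grid(task_id = dn[[2L]], rater_id = dn[[3L]],
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$measure <- cube$measure
  out$mean <- as.vector(apply(cube$scores, c(2L, 3L), mean))
  out$sd <- if (n_p >= 2L) {
    as.vector(apply(cube$scores, c(2L, 3L), stats::sd))
  } else {
    NA_real_
  }
  out$n <- n_p
  out[order(out$task_id, out$rater_id), ]
}

#' Pearson correlation with domain validation
#'
#' Thin wrapper around [stats::cor()] that enforces the preconditions under
#' which the correlation is meaningful here: equal lengths of at least 3
#' and nonconstant inputs.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return the sample Pearson correlation, in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) {
    gc_stop("gcross_validation_error",
            "correlation inputs differ in length (%d vs %d)",
            length(x), length(y))
  }
  if (length(x) < 3L) {
    gc_stop("gcross_validation_error",
            "need at least 3 paired observations, got %d", length(x))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    gc_stop("gcross_degenerate_error",
            "correlation is undefined for a constant input")
  }
  stats::cor(x, y)
}

#' Correlation between the two raters' scores
#'
#' Pools all (person, task) units across tasks — i.e. independent of which
#' scenario was being rated — and correlates the two raters' scores on those
#' units. Requires exactly two raters, the design under which the study's
#' rater agreement is defined. Set `per_task = TRUE` for one correlation per
#' task instead of the pooled default.
#'
#' @param cube a [rating_cube()] with exactly 2 raters.
#' @param per_task if `TRUE`, return a named vector with one correlation per
#'   task rather than pooling.
#' @return a single correlation, or a named vector when `per_task = TRUE`.
#' @export
inter_rater_correlation <- function(cube, per_task = FALSE) {
  stopifnot(inherits(cube, "rating_cube"))
  if (dim(cube$scores)[3L] != 2L) {
    gc_stop("gcross_validation_error",
            "inter-rater correlation requires exactly 2 raters, got %d",
            dim(cube$scores)[3L])
  }
  if (per_task) {
    tasks <- dimnames(cube$scores)[[2L]]
    out <- vapply(seq_along(tasks), function(t) {
      pearson(cube$scores[, t, 1L], cube$scores[, t, 2L])
    }, numeric(1L))
    names(out) <- tasks
    return(out)
  }
  pearson(as.vector(cube$scores[, , 1L]), as.vector(cube$scores[, , 2L]))
}

#' Correlation between the two tasks' performances
#'
#' Averages each person's raters within each task, then correlates the two
#' per-person task scores across persons. A small value relative to the
#' rater agreement is the signature of context specificity (large
#' person x task variance). Requires exactly two tasks.
#'
#' @param cube a [rating_cube()] with exactly 2 tasks.
#' @return the Pearson correlation across persons.
#' @export
inter_task_correlation <- function(cube) {
  stopifnot(inherits(cube, "rating_cube"))
  if (dim(cube$scores)[2L] != 2L) {
    gc_stop("gcross_validation_error",
            "inter-task correlation requires exactly 2 tasks, got %d",
            dim(cube$scores)[2L])
  }
  task_scores <- apply(cube$scores, c(1L, 2L), mean)  # persons x tasks
  pearson(task_scores[, 1L], task_scores[, 2L])
}

#' Table of mean (SD) by scenario and rater
#'
#' Reshapes [cell_means()] into the customary presentation: one row per
#' task, one pair of columns (mean, sd) per rater.
#'
#' @param cube a [rating_cube()].
#' @param digits decimal places for half-up rounding of means and SDs.
#' @return data frame with `task_id` and `<rater>_mean` / `<rater>_sd`
#'   columns.
#' @export
descriptives_table <- function(cube, digits = 1) {
  cm <- cell_means(cube)
  tasks <- sort(unique(cm$task_id))
  raters <- sort(unique(cm$rater_id))
  out <- data.frame(task_id = tasks, stringsAsFactors = FALSE)
  for (r in raters) {
    sub <- cm[cm$rater_id == r, ]
    sub <- sub[match(tasks, sub$task_id), ]
    out[[paste0(r, "_mean")]] <- round_half_up(sub$mean, digits)
    out[[paste0(r, "_sd")]] <- round_half_up(sub$sd, digits)
  }
  out
}
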
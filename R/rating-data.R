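#' @title Rating records and crossed rating cubes
#' @description Readers, validators and containers for long-format rating
#'   records and the dense person x task x rater score arrays ("cubes") that
#'   the G-study estimator consumes.
#' @name rating-data
NULL

#' Default column mapping for rating CSV files
#'
#' Maps the canonical record fields to column names in an input CSV.
#' Pass a modified copy to [read_ratings()] to read files with other
#' headers. The four `dim_*` entries are optional columns carrying the
#' behaviourally anchored rating scale (BARS) dimension scores
#' (Vigilance/Situation Awareness, Decision-Making, Communication,
#' Teamwork).
#'
#' @return named character vector.
#' @export
default_schema <- function() {
  c(
    person_id = "person_id",
    task_id = "task_id",
    rater_id = "rater_id",
    measure = "measure",
    score = "score",
    dim_vigilance = "dim_vigilance",
    dim_decision = "dim_decision",
    dim_communication = "dim_communication",
    dim_teamwork = "dim_teamwork"
  )
}

DIM_FIELDS <- c("dim_vigilance", "dim_decision", "dim_communication", "dim_teamwork")

#' BARS total score from the four dimension scores
#'
#' The behavioural total on the 9-point scale is defined as the arithmetic
#' mean of the four dimension scores.
#'
#' @param dimensions numeric vector of exactly four scores, each in `[1, 9]`.
#' @return the mean of the four scores.
#' @examples
#' bars_total(c(6, 7, 8, 9))  # 7.5
#' @export
bars_total <- function(dimensions) {
  if (!is.numeric(dimensions) || length(dimensions) != 4L) {
    gc_stop("gcross_validation_error",
            "bars_total() needs exactly four numeric dimension scores, got %d",
            length(dimensions))
  }
  if (anyNA(dimensions) || any(dimensions < 1 | dimensions > 9)) {
    gc_stop("gcross_validation_error",
            "BARS dimension scores must lie in [1, 9]; got (%s)",
            paste(format(dimensions), collapse = ", "))
  }
  mean(dimensions)
}

#' Read and validate long-format rating records
#'
#' Reads a CSV of one-score-per-row rating records (one row = one score given
#' by one rater to one person on one task for one measure), validates scores
#' against the 1-9 scale, and returns a canonical data frame of records.
#'
#' If the four BARS dimension columns are present, each row's total score is
#' checked against (or, when the score column is absent/NA, derived from)
#' their mean via [bars_total()]. A supplied total that disagrees with the
#' dimension mean by more than `1e-9` is a validation error, because the
#' total is defined as that mean.
#'
#' @param path path to a CSV file with a header row.
#' @param schema named character vector mapping canonical field names to the
#'   file's column names; see [default_schema()].
#' @return data frame with columns `person_id`, `task_id`, `rater_id`,
#'   `measure`, `score`, plus the four `dim_*` columns when present in the
#'   input. One row per record.
#' @export
read_ratings <- function(path, schema = default_schema()) {
  if (!file.exists(path)) {
    gc_stop("gcross_io_error", "ratings file does not exist: %s", path)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("person_id", "task_id", "rater_id", "measure")
  missing_cols <- setdiff(schema[required], names(raw))
  if (length(missing_cols) > 0L) {
    gc_stop("gcross_schema_error", "missing required column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  has_score <- schema[["score"]] %in% names(raw)
  has_dims <- all(schema[DIM_FIELDS] %in% names(raw))
  if (!has_score && !has_dims) {
    gc_stop("gcross_schema_error",
            "need a score column ('%s') or all four dimension columns",
            schema[["score"]])
  }

  rec <- data.frame(
    person_id = as.character(raw[[schema[["person_id"]]]]),
    task_id = as.character(raw[[schema[["task_id"]]]]),
    rater_id = as.character(raw[[schema[["rater_id"]]]]),
    measure = as.character(raw[[schema[["measure"]]]]),
    stringsAsFactors = FALSE
  )
  bad_measure <- !rec$measure %in% MEASURES
  if (any(bad_measure)) {
    gc_stop("gcross_validation_error",
            "row %d: unknown measure '%s' (expected one of: %s)",
            which(bad_measure)[1L], rec$measure[which(bad_measure)[1L]],
            paste(MEASURES, collapse = ", "))
  }

  if (has_score) {
    score <- suppressWarnings(as.numeric(raw[[schema[["score"]]]]))
    unparsed <- is.na(score) & !is.na(raw[[schema[["score"]]]]) &
      nzchar(trimws(as.character(raw[[schema[["score"]]]])))
    if (any(unparsed)) {
      gc_stop("gcross_validation_error", "row %d: score '%s' is not a number",
              which(unparsed)[1L], raw[[schema[["score"]]]][which(unparsed)[1L]])
    }
  } else {
    score <- rep(NA_real_, nrow(raw))
  }

  if (has_dims) {
    dims <- sapply(DIM_FIELDS, function(f) {
      suppressWarnings(as.numeric(raw[[schema[[f]]]]))
    })
    dims <- matrix(dims, nrow = nrow(raw),
                   dimnames = list(NULL, DIM_FIELDS))
    dim_present <- rowSums(!is.na(dims)) > 0L
    partial <- dim_present & rowSums(is.na(dims)) > 0L
    if (any(partial)) {
      gc_stop("gcross_validation_error",
              "row %d: dimension scores must be all present or all absent",
              which(partial)[1L])
    }
    if (any(dim_present)) {
      out_of_range <- dim_present & (rowSums(dims < 1, na.rm = TRUE) +
                                       rowSums(dims > 9, na.rm = TRUE) > 0L)
      if (any(out_of_range)) {
        gc_stop("gcross_validation_error",
                "row %d: dimension score outside [1, 9]", which(out_of_range)[1L])
      }
      dim_mean <- rowMeans(dims)
      derive <- dim_present & is.na(score)
      score[derive] <- dim_mean[derive]
      mismatch <- dim_present & !is.na(score) &
        abs(score - dim_mean) > 1e-9
      if (any(mismatch)) {
        i <- which(mismatch)[1L]
        gc_stop("gcross_validation_error",
                "row %d: score %.6g does not equal the mean of its four dimension scores (%.6g)",
                i, score[i], dim_mean[i])
      }
      rec <- cbind(rec, as.data.frame(dims))
    }
  }

  if (anyNA(score)) {
    gc_stop("gcross_validation_error", "row %d: missing score",
            which(is.na(score))[1L])
  }
  out_of_range <- score < 1 | score > 9
  if (any(out_of_range)) {
    i <- which(out_of_range)[1L]
    gc_stop("gcross_validation_error",
            "row %d: score %.6g outside the 1-9 scale", i, score[i])
  }
  rec$score <- score
  # keep score before any dimension columns
  rec <- rec[, c("person_id", "task_id", "rater_id", "measure", "score",
                 intersect(DIM_FIELDS, names(rec)))]

  key <- paste(rec$person_id, rec$task_id, rec$rater_id, rec$measure, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    gc_stop("gcross_duplication_error",
            "duplicate record for (person %s, task %s, rater %s, measure %s)",
            rec$person_id[i], rec$task_id[i], rec$rater_id[i], rec$measure[i])
  }
  rec
}

#' Write rating records to the canonical long CSV format
#'
#' Inverse of [read_ratings()] under the default schema; used for fixtures
#' and round-trip checks.
#'
#' @param records data frame of records as returned by [read_ratings()] or
#'   [cube_to_records()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a rating cube
#'
#' A rating cube is the dense `n_p x n_t x n_r` score array of a balanced,
#' fully crossed person x task x rater design for one outcome measure. The
#' dimnames carry the person, task and rater identifiers.
#'
#' @param scores 3-dimensional numeric array (persons x tasks x raters),
#'   with dimnames; no missing values.
#' @param measure `"behavioural"` or `"technical"`.
#' @return object of class `rating_cube`.
#' @export
rating_cube <- function(scores, measure) {
  if (!is.array(scores) || length(dim(scores)) != 3L) {
    gc_stop("gcross_validation_error", "scores must be a 3-dimensional array")
  }
  measure <- match.arg(measure, MEASURES)
  if (anyNA(scores)) {
    gc_stop("gcross_validation_error", "rating cube contains missing cells")
  }
  if (dim(scores)[1L] < 2L) {
    gc_stop("gcross_validation_error",
            "a rating cube needs at least two persons, got %d", dim(scores)[1L])
  }
  if (is.null(dimnames(scores))) {
    dimnames(scores) <- list(
      paste0("P", seq_len(dim(scores)[1L])),
      paste0("T", seq_len(dim(scores)[2L])),
      paste0("R", seq_len(dim(scores)[3L]))
    )
  }
  names(dimnames(scores)) <- c("person", "task", "rater")
  structure(list(scores = scores, measure = measure), class = "rating_cube")
}

#' @export
print.rating_cube <- function(x, ...) {
  d <- dim(x$scores)
  cat(sprintf("<rating_cube> %s measure: %d persons x %d tasks x %d raters\n",
              x$measure, d[1L], d[2L], d[3L]))
  cat(sprintf("  grand mean %.3f, score range [%.2f, %.2f]\n",
              mean(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' @export
dim.rating_cube <- function(x) dim(x$scores)

#' Assemble a balanced crossed cube from long-format records
#'
#' Filters the records to one measure and fills the dense person x task x
#' rater array. Axes are ordered lexicographically by identifier so that
#' downstream output is deterministic. Every combination must be present
#' exactly once: missing cells are a hard error (the crossed-design
#' estimator requires complete data; nothing is imputed).
#'
#' @param records data frame as returned by [read_ratings()].
#' @param measure which measure to extract.
#' @return a [rating_cube()].
#' @export
build_cube <- function(records, measure) {
  measure <- match.arg(measure, MEASURES)
  rec <- records[records$measure == measure, , drop = FALSE]
  if (nrow(rec) == 0L) {
    gc_stop("gcross_validation_error", "no records for measure '%s'", measure)
  }
  persons <- sort(unique(rec$person_id))
  tasks <- sort(unique(rec$task_id))
  raters <- sort(unique(rec$rater_id))
  arr <- array(NA_real_, dim = c(length(persons), length(tasks), length(raters)),
               dimnames = list(persons, tasks, raters))
  idx <- cbind(match(rec$person_id, persons),
               match(rec$task_id, tasks),
               match(rec$rater_id, raters))
  if (anyDuplicated(idx)) {
    i <- which(duplicated(idx))[1L]
    gc_stop("gcross_duplication_error",
            "duplicate record for (person %s, task %s, rater %s)",
            rec$person_id[i], rec$task_id[i], rec$rater_id[i])
  }
  arr[idx] <- rec$score
  if (anyNA(arr)) {
    miss <- which(is.na(arr), arr.ind = TRUE)
    labels <- apply(miss, 1L, function(m) {
      sprintf("(%s, %s, %s)", persons[m[1L]], tasks[m[2L]], raters[m[3L]])
    })
    gc_stop("gcross_incomplete_design_error",
            "design is not fully crossed; %d missing cell(s): %s",
            nrow(miss), paste(utils::head(labels, 10L), collapse = ", "))
  }
  rating_cube(arr, measure)
}

#' Flatten a rating cube back to long-format records
#'
#' @param cube a [rating_cube()].
#' @return data frame with one row per (person, task, rater) cell, in the
#'   canonical column order accepted by [write_ratings()].
#' @export
cube_to_records <- function(cube) {
  stopifnot(inherits(cube, "rating_cube"))
  dn <- dimnames(cube$scores)
  grid <- expand.grid(person_id = dn[[1L]], task_id = dn[[2L]],
                      rater_id = dn[[3L]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$measure <- cube$measure
  grid$score <- as.vector(cube$scores)
  grid[order(grid$person_id, grid$task_id, grid$rater_id),
       c("person_id", "task_id", "rater_id", "measure", "score")]
}

#' Bundle the two measures of one scenario pairing
#'
#' A pairing study holds the behavioural and technical cubes of one scenario
#' pairing (e.g. LAST/MH); both must share persons, tasks and raters.
#'
#' @param label pairing label, e.g. `"LAST/MH"`.
#' @param cube_behavioural,cube_technical the two [rating_cube()]s.
#' @return object of class `pairing_study`.
#' @export
pairing_study <- function(label, cube_behavioural, cube_technical) {
  stopifnot(inherits(cube_behavioural, "rating_cube"),
            inherits(cube_technical, "rating_cube"))
  if (!identical(dimnames(cube_behavioural$scores),
                 dimnames(cube_technical$scores))) {
    gc_stop("gcross_validation_error",
            "the two cubes of pairing '%s' do not share identical persons, tasks and raters",
            label)
  }
  structure(list(label = label,
                 behavioural = cube_behavioural,
                 technical = cube_technical),
            class = "pairing_study")
}
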
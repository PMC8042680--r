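#' @title Full analysis pipeline
#' @description Orchestrates descriptives, G study and D study per scenario
#'   pairing and measure, writing deterministic CSV and aligned-text tables
#'   plus a run manifest.
#' @name pipeline
NULL

#' Build a pipeline configuration
#'
#' A configuration names either an input ratings CSV or a simulation preset,
#' the pairings (label plus task pair) and measures to analyse, the D-study
#' designs, the reliability-target search, and output settings. It can also
#' be loaded from a YAML file with [read_pipeline_config()]; CLI flags
#' override file keys.
#'
#' @param input path to a long-format ratings CSV (see [read_ratings()]),
#'   an in-memory data frame of validated records, or `NULL` to simulate.
#'   File input is validated against the 1-9 scale; data-frame input is
#'   taken as-is, which also admits continuous simulated scores.
#' @param preset a [preset_names()] entry used (with `sim_n_p`) to simulate
#'   input when `input` is `NULL`.
#' @param sim_n_p,sim_n_t,sim_n_r simulated design sizes when simulating.
#' @param pairings named list: `label = c(task1, task2)`. `NULL` analyses
#'   all tasks found in the input as a single study per measure.
#' @param measures character vector of measures to analyse.
#' @param designs list of `c(n_tasks, n_raters)` D-study designs.
#' @param target,target_raters reliability target for the minimum-tasks
#'   search and the rater count to search under.
#' @param out_dir output directory (created if needed).
#' @param digits decimal places for component estimates in tables.
#' @param seed integer seed (used only when simulating).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, preset = NULL,
                            sim_n_p = 10L, sim_n_t = 2L, sim_n_r = 2L,
                            pairings = NULL,
                            measures = c("behavioural", "technical"),
                            designs = list(c(2, 2), c(10, 1), c(20, 2)),
                            target = 0.70, target_raters = 2L,
                            out_dir = "gcross-output", digits = 2,
                            seed = 1L) {
  if (is.null(input) && is.null(preset)) {
    gc_stop("gcross_config_error",
            "config needs an input ratings file or a simulation preset")
  }
  if (length(measures) == 0L) {
    gc_stop("gcross_config_error", "config lists no measures")
  }
  bad <- setdiff(measures, MEASURES)
  if (length(bad) > 0L) {
    gc_stop("gcross_config_error", "unknown measure(s): %s",
            paste(bad, collapse = ", "))
  }
  structure(list(input = input, preset = preset,
                 sim_n_p = as.integer(sim_n_p), sim_n_t = as.integer(sim_n_t),
                 sim_n_r = as.integer(sim_n_r),
                 pairings = pairings, measures = measures, designs = designs,
                 target = target, target_raters = as.integer(target_raters),
                 out_dir = out_dir, digits = digits, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are the arguments of
#'   [pipeline_config()]; `designs` entries may be written `"2x2"`.
#' @param overrides named list of values taking precedence over the file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  if (!is.null(cfg$designs)) cfg$designs <- parse_designs(cfg$designs)
  do.call(pipeline_config, cfg)
}

# "2x2,10x1" or list entries "2x2" -> list(c(2,2), c(10,1))
parse_designs <- function(x) {
  if (is.list(x) && all(vapply(x, is.numeric, logical(1L)))) return(x)
  parts <- unlist(strsplit(unlist(x), ","))
  lapply(parts, function(p) {
    d <- suppressWarnings(as.numeric(strsplit(trimws(p), "[xX]")[[1L]]))
    if (length(d) != 2L || anyNA(d)) {
      gc_stop("gcross_config_error", "cannot parse design '%s' (want e.g. 2x2)", p)
    }
    d
  })
}

#' Run the full G/D-study pipeline
#'
#' For each (pairing, measure): builds the crossed cube, computes the
#' scenario x rater descriptives, the inter-rater and inter-task
#' correlations (two-task pairings only), the variance-component table with
#' percents, the D-study footer over the configured designs, and the
#' minimum-tasks search for the target reliability. Everything is computed
#' in memory first and only then written, so a failure leaves no partial
#' output. Identical config and input give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a named list of per-(pairing, measure) result
#'   bundles; each bundle has `cube`, `descriptives`, `correlations`,
#'   `components`, `gstudy_table`, `dstudy_table`, `min_tasks`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  records <- if (is.data.frame(config$input)) {
    config$input
  } else if (!is.null(config$input)) {
    read_ratings(config$input)
  } else {
    simulated_records(config)
  }

  pairings <- config$pairings
  if (is.null(pairings)) {
    pairings <- list(all = sort(unique(records$task_id)))
  }

  bundles <- list()
  for (pl in names(pairings)) {
    tasks <- pairings[[pl]]
    sub <- records[records$task_id %in% tasks, , drop = FALSE]
    for (ms in config$measures) {
      cube <- build_cube(sub, ms)
      vc <- gstudy(cube)
      vc$label <- pl
      two_tasks <- dim(cube)[2L] == 2L
      two_raters <- dim(cube)[3L] == 2L
      corr <- data.frame(
        statistic = c("inter_rater", "inter_task"),
        value = c(
          if (two_raters) round_half_up(inter_rater_correlation(cube), 2) else NA_real_,
          if (two_tasks) round_half_up(inter_task_correlation(cube), 2) else NA_real_
        )
      )
      mt <- tryCatch(
        min_tasks_for_target(vc, config$target_raters, config$target),
        gcross_degenerate_error = function(e) NA_integer_
      )
      # an estimated person component truncated to zero (possible in small
      # G studies) leaves reliability undefined rather than failing the run
      dt <- tryCatch(
        g_table(vc, config$designs),
        gcross_degenerate_error = function(e) {
          d <- do.call(rbind, lapply(config$designs, function(dd) {
            data.frame(n_tasks = as.integer(dd[1L]),
                       n_raters = as.integer(dd[2L]))
          }))
          d$rel_error_var <- vapply(seq_len(nrow(d)), function(i) {
            relative_error_variance(vc, d$n_tasks[i], d$n_raters[i])
          }, numeric(1L))
          d$abs_error_var <- vapply(seq_len(nrow(d)), function(i) {
            absolute_error_variance(vc, d$n_tasks[i], d$n_raters[i])
          }, numeric(1L))
          d$g <- NA_real_
          d$phi <- NA_real_
          d
        }
      )
      dt$g <- round_half_up(dt$g, 2)
      dt$phi <- round_half_up(dt$phi, 2)
      dt$rel_error_var <- round_half_up(dt$rel_error_var, 4)
      dt$abs_error_var <- round_half_up(dt$abs_error_var, 4)
      bundles[[paste(pl, ms, sep = ".")]] <- list(
        pairing = pl, measure = ms, cube = cube,
        descriptives = descriptives_table(cube),
        correlations = corr,
        components = vc,
        gstudy_table = gstudy_table(vc, config$digits),
        dstudy_table = dt,
        min_tasks = mt
      )
    }
  }

  write_bundles(bundles, config)
  invisible(bundles)
}

simulated_records <- function(config) {
  vc <- preset_components(config$preset)
  spec <- simulation_spec(config$sim_n_p, config$sim_n_t, config$sim_n_r,
                          sigma2 = vc, seed = config$seed,
                          measure = vc$measure)
  cube <- simulate_ratings(spec)
  cube_to_records(cube)
}

write_bundles <- function(bundles, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  txt <- character(0)
  for (b in bundles) {
    stem <- file.path(config$out_dir,
                      paste0(gsub("[^A-Za-z0-9]+", "_", b$pairing),
                             "_", b$measure))
    utils::write.csv(b$descriptives, paste0(stem, "_descriptives.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(b$correlations, paste0(stem, "_correlations.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(b$gstudy_table, paste0(stem, "_components.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(b$dstudy_table, paste0(stem, "_dstudy.csv"),
                     row.names = FALSE, quote = FALSE)
    txt <- c(txt,
             sprintf("== %s / %s ==", b$pairing, b$measure),
             utils::capture.output(print(b$components)),
             utils::capture.output(print(b$dstudy_table, row.names = FALSE)),
             sprintf("minimum tasks for G >= %.2f with %d rater(s): %s",
                     config$target, config$target_raters,
                     ifelse(is.na(b$min_tasks), "unattainable", b$min_tasks)),
             "")
  }
  writeLines(txt, file.path(config$out_dir, "report.txt"))

  manifest <- list(
    package = "gcross",
    version = as.character(utils::packageVersion("gcross")),
    seed = config$seed,
    input = if (is.null(config$input)) {
      "simulated"
    } else if (is.data.frame(config$input)) {
      "in-memory records"
    } else {
      config$input
    },
    preset = config$preset,
    measures = config$measures,
    designs = vapply(config$designs,
                     function(d) paste0(d[1L], "x", d[2L]), character(1L)),
    target = config$target,
    target_raters = config$target_raters
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(NULL)
}
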
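#' Published variance-component presets
#'
#' Named sets of variance components for the two scenario pairings
#' (LAST/MH with 10 participants, LAST/Hemorrhage with 8) and the two
#' outcome measures (behavioural BARS total, technical global rating) of
#' the crossed simulation-assessment G studies. These serve two purposes:
#' as D-study inputs (the reliability footers are exactly reproducible from
#' them) and as ground truth for the synthetic generator's
#' parameter-recovery experiments.
#'
#' @param name one of `"last_mh_behavioural"`, `"last_mh_technical"`,
#'   `"last_hem_behavioural"`, `"last_hem_technical"`.
#' @return a [variance_components()] object.
#' @examples
#' vc <- preset_components("last_mh_behavioural")
#' g_coefficient(vc, 2, 2)  # ~0.43
#' @export
preset_components <- function(name = c("last_mh_behavioural",
                                       "last_mh_technical",
                                       "last_hem_behavioural",
                                       "last_hem_technical")) {
  name <- match.arg(name)
  tab <- list(
    last_mh_behavioural = list(
      s = c(p = 1.10, t = 0, r = 0, pt = 2.14, pr = 0.42, tr = 0.16, e = 0.81),
      n_p = 10L, label = "LAST/MH", measure = "behavioural"),
    last_mh_technical = list(
      s = c(p = 1.01, t = 0, r = 0, pt = 1.93, pr = 0.60, tr = 0, e = 0.79),
      n_p = 10L, label = "LAST/MH", measure = "technical"),
    last_hem_behavioural = list(
      s = c(p = 0.69, t = 3.51, r = 0.51, pt = 1.21, pr = 0.93, tr = 0, e = 0.99),
      n_p = 8L, label = "LAST/Hemorrhage", measure = "behavioural"),
    last_hem_technical = list(
      s = c(p = 0.50, t = 1.86, r = 1.70, pt = 1.14, pr = 0.49, tr = 0, e = 2.14),
      n_p = 8L, label = "LAST/Hemorrhage", measure = "technical")
  )[[name]]
  variance_components(tab$s, n_p = tab$n_p, n_t = 2L, n_r = 2L,
                      measure = tab$measure, label = tab$label)
}

#' Names of the available component presets
#' @return character vector.
#' @export
preset_names <- function() {
  c("last_mh_behavioural", "last_mh_technical",
    "last_hem_behavioural", "last_hem_technical")
}
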
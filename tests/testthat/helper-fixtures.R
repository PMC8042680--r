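# Small long-format record data frames built in code.

make_records <- function(n_p = 2, n_t = 2, n_r = 2,
                         measure = "behavioural", scores = NULL) {
  grid <- expand.grid(
    person_id = sprintf("P%d", 1:n_p),
    task_id = sprintf("T%d", 1:n_t),
    rater_id = sprintf("R%d", 1:n_r),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$measure <- measure
  grid$score <- if (is.null(scores)) rep(6, nrow(grid)) else scores
  grid[, c("person_id", "task_id", "rater_id", "measure", "score")]
}

write_records_csv <- function(records, path = tempfile(fileext = ".csv")) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  path
}

# A 10 x 2 x 2 cube constructed by inverting the EMS equations so that its
# estimated variance components are exactly
#   p 1.10, t 0, r 0, pt 2.14, pr 0.42, tr 0.16, e 0.81
# (the LAST/MH behavioural set). Each effect is built in its own ANOVA
# subspace (all relevant margins zero) with the sum of squares that yields
# the target mean square, so the decomposition is exact, not stochastic.
make_ems_inversion_cube <- function(mu = 5.5) {
  n_p <- 10L; n_t <- 2L; n_r <- 2L
  # target mean squares implied by the component targets
  ms <- c(p = 10.33, t = 6.69, r = 3.25, pt = 5.09, pr = 1.65, tr = 2.41,
          e = 0.81)
  half <- c(rep(1, 5), rep(-1, 5))  # person +/- pattern, sums to zero

  a <- half * sqrt((n_p - 1) * ms[["p"]] / (n_t * n_r) / n_p)
  b <- c(1, -1) * sqrt((n_t - 1) * ms[["t"]] / (n_p * n_r) / n_t)
  cc <- c(1, -1) * sqrt((n_r - 1) * ms[["r"]] / (n_p * n_t) / n_r)
  v_pt <- half * sqrt((n_p - 1) * (n_t - 1) * ms[["pt"]] / n_r / (n_p * n_t))
  ab <- cbind(v_pt, -v_pt)
  v_pr <- half * sqrt((n_p - 1) * (n_r - 1) * ms[["pr"]] / n_t / (n_p * n_r))
  ac <- cbind(v_pr, -v_pr)
  h <- sqrt((n_t - 1) * (n_r - 1) * ms[["tr"]] / n_p / (n_t * n_r))
  bc <- matrix(c(h, -h, -h, h), 2, 2)
  v_e <- half * sqrt((n_p - 1) * (n_t - 1) * (n_r - 1) * ms[["e"]] /
                       (n_p * n_t * n_r))

  y <- array(mu, c(n_p, n_t, n_r))
  for (p in 1:n_p) for (t in 1:n_t) for (r in 1:n_r) {
    y[p, t, r] <- mu + a[p] + b[t] + cc[r] + ab[p, t] + ac[p, r] +
      bc[t, r] + v_e[p] * c(1, -1)[t] * c(1, -1)[r]
  }
  rating_cube(y, "behavioural")
}
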
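# Brute-force oracle for the balanced three-way ANOVA decomposition:
# explicit loops over the textbook definitions of each sum of squares.
# Deliberately slow and independent of the package's vectorized code path.
oracle_sums_of_squares <- function(y) {
  n_p <- dim(y)[1L]; n_t <- dim(y)[2L]; n_r <- dim(y)[3L]
  gm <- mean(y)
  m_p <- sapply(1:n_p, function(p) mean(y[p, , ]))
  m_t <- sapply(1:n_t, function(t) mean(y[, t, ]))
  m_r <- sapply(1:n_r, function(r) mean(y[, , r]))

  ss <- c(p = 0, t = 0, r = 0, pt = 0, pr = 0, tr = 0, e = 0)
  for (p in 1:n_p) ss[["p"]] <- ss[["p"]] + n_t * n_r * (m_p[p] - gm)^2
  for (t in 1:n_t) ss[["t"]] <- ss[["t"]] + n_p * n_r * (m_t[t] - gm)^2
  for (r in 1:n_r) ss[["r"]] <- ss[["r"]] + n_p * n_t * (m_r[r] - gm)^2
  for (p in 1:n_p) for (t in 1:n_t) {
    ss[["pt"]] <- ss[["pt"]] +
      n_r * (mean(y[p, t, ]) - m_p[p] - m_t[t] + gm)^2
  }
  for (p in 1:n_p) for (r in 1:n_r) {
    ss[["pr"]] <- ss[["pr"]] +
      n_t * (mean(y[p, , r]) - m_p[p] - m_r[r] + gm)^2
  }
  for (t in 1:n_t) for (r in 1:n_r) {
    ss[["tr"]] <- ss[["tr"]] +
      n_p * (mean(y[, t, r]) - m_t[t] - m_r[r] + gm)^2
  }
  for (p in 1:n_p) for (t in 1:n_t) for (r in 1:n_r) {
    resid <- y[p, t, r] -
      mean(y[p, t, ]) - mean(y[p, , r]) - mean(y[, t, r]) +
      m_p[p] + m_t[t] + m_r[r] - gm
    ss[["e"]] <- ss[["e"]] + resid^2
  }
  ss
}

# Hand-solved EMS system (substitution order: e, two-ways, mains), kept
# separate from the package's solver.
oracle_solve_ems <- function(ms, n_p, n_t, n_r) {
  e <- ms[["e"]]
  pt <- (ms[["pt"]] - e) / n_r
  pr <- (ms[["pr"]] - e) / n_t
  tr <- (ms[["tr"]] - e) / n_p
  p <- (ms[["p"]] - e - n_r * pt - n_t * pr) / (n_t * n_r)
  t <- (ms[["t"]] - e - n_r * pt - n_p * tr) / (n_p * n_r)
  r <- (ms[["r"]] - e - n_t * pr - n_p * tr) / (n_p * n_t)
  c(p = p, t = t, r = r, pt = pt, pr = pr, tr = tr, e = e)
}

random_cube <- function(n_p, n_t, n_r, measure = "behavioural",
                        integers = FALSE) {
  vals <- if (integers) {
    sample(1:9, n_p * n_t * n_r, replace = TRUE)
  } else {
    stats::rnorm(n_p * n_t * n_r, 5.5, 1.5)
  }
  rating_cube(array(as.numeric(vals), c(n_p, n_t, n_r)), measure)
}
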
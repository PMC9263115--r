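# Independent brute-force oracles used to cross-check the implementation.

# product-limit estimator computed directly from its definition
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# exhaustive pairwise concordance count; usable pairs are those whose event
# ordering is determinable under right censoring, tied risks count one half
oracle_concordance <- function(risk, time, event) {
  conc <- disc <- tied <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (time[i] == time[j]) next
      s <- if (time[i] < time[j]) i else j
      o <- if (s == i) j else i
      if (!event[s]) next
      if (risk[s] > risk[o]) conc <- conc + 1
      else if (risk[s] < risk[o]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / (conc + disc + tied)
}

# double-loop tally of the endotype x variant cross-tabulation
oracle_crosstab <- function(endotype, variant, keep = rep(TRUE, length(endotype))) {
  m <- matrix(0L, 4, 4, dimnames = list(1:4, c("1A", "2A", "3A", "4A")))
  for (i in seq_along(endotype)) {
    if (keep[i]) {
      m[as.integer(endotype[i]), as.character(variant[i])] <-
        m[as.integer(endotype[i]), as.character(variant[i])] + 1L
    }
  }
  m
}

# closed-form simple linear regression via the normal equations
oracle_least_squares <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  resid <- y - a - b * x
  list(intercept = a, slope = b,
       r = sum((x - mean(x)) * (y - mean(y))) /
         sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
       see = sqrt(sum(resid^2) / (n - 2)))
}

# random positive velocity pairs for property tests
random_velocity_pairs <- function(n, seed) {
  set.seed(seed)
  data.frame(dpv_r = exp(rnorm(n, log(25), 0.4)),
             dpv_h = exp(rnorm(n, log(75), 0.4)))
}

# minimal valid cohort rows for io tests
make_cohort_rows <- function(n = 2) {
  data.frame(subject_id = sprintf("S%02d", seq_len(n)),
             group = "ht",
             dpv_r = seq(20, by = 2, length.out = n),
             dpv_h = seq(60, by = 3, length.out = n),
             sap_r = 130, dap_r = 85, sap_h = 125, dap_h = 80,
             hr_r = 80, hr_h = 95,
             time_years = seq(8, by = 1, length.out = n),
             event = rep_len(c(1L, 0L), n))
}
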
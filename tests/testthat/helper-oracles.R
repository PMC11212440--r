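# Independent re-evaluations of the estimation equations, written along a
# different arithmetic path (log-space for the power forms, magnitude-sorted
# summation for the linear form) so that agreement with the implementation
# checks the closed forms, not a shared code path.

oracle_kawasaki <- function(una, ucrea_mg_dl, sex, age, weight, height) {
  body <- if (sex == "male") {
    sum(sort(c(15.12 * weight, 7.39 * height, -12.63 * age, -79.9)))
  } else {
    sum(sort(c(8.58 * weight, 5.09 * height, -4.72 * age, -74.5)))
  }
  if (una == 0) return(0)
  exp(log(23) + log(16.3) + 0.5 * (log(una) - log(ucrea_mg_dl) - log(10) + log(body)))
}

oracle_tanaka <- function(una, ucrea_mg_dl, age, weight, height) {
  body <- sum(sort(c(-2.04 * age, 14.89 * weight, 16.14 * height, -2244.45)))
  if (una == 0) return(0)
  exp(log(23) + log(21.98) + 0.392 * (log(una) - log(ucrea_mg_dl) - log(10) + log(body)))
}

oracle_intersalt <- function(una, uk, ucrea_mmol_l, sex, age, bmi) {
  terms <- if (sex == "male") {
    c(25.46, 0.46 * una, -2.75 * ucrea_mmol_l, -0.13 * uk, 4.10 * bmi, 0.26 * age)
  } else {
    c(5.07, 0.34 * una, -2.16 * ucrea_mmol_l, -0.09 * uk, 2.39 * bmi,
      2.35 * age, -0.03 * age^2)
  }
  23 * sum(terms[order(abs(terms))])
}

# Brute-force O(n^2) Spearman: midranks by pairwise counting, correlation by
# the raw-sums formula. Returns NA for a constant vector.
oracle_spearman <- function(x, y) {
  n <- length(x)
  count_rank <- function(v) {
    vapply(seq_len(n), function(i) {
      1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2
    }, numeric(1))
  }
  rx <- count_rank(x)
  ry <- count_rank(y)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den2 <- (n * sum(rx^2) - sum(rx)^2) * (n * sum(ry^2) - sum(ry)^2)
  if (den2 <= 0) return(NA_real_)
  num / sqrt(den2)
}

# Random physiological inputs for equation property tests.
random_physio_inputs <- function(n) {
  tibble::tibble(
    una = runif(n, 5, 300),
    ucrea_mg_dl = runif(n, 20, 400),
    uk = runif(n, 5, 150),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = runif(n, 19, 74),
    weight = runif(n, 45, 140),
    height = runif(n, 145, 200),
    bmi = runif(n, 17, 45)
  )
}
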
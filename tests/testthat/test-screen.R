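# independent oracle: explicit average-rank + closed-form t reference
naive_cor <- function(x, y, method = "spearman") {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2)); 2 * pt(-abs(t), n - 2)
  }
  list(r = r, p = p, n = n)
}

test_that("correlate handles canonical monotone and linear cases", {
  expect_equal(correlate(1:5, (1:5)^2, "spearman")$r, 1.0)
  expect_equal(correlate(c(1, 2, 3), c(3, 2, 1), "pearson")$r, -1.0)
  got <- correlate(c(2, 4, 4, 7, 9), c(5, 3, 8, 6, 10), "spearman")
  exp <- naive_cor(c(2, 4, 4, 7, 9), c(5, 3, 8, 6, 10))
  expect_equal(got$r, exp$r, tolerance = 1e-12)
  expect_equal(got$p, exp$p, tolerance = 1e-12)
})

test_that("correlate signals too-few pairs and zero variance", {
  expect_error(correlate(c(1, 2, NA), c(NA, 1, 2)), class = "csf_too_few_pairs")
  expect_error(correlate(rep(1, 10), 1:10, "pearson"),
               class = "csf_zero_variance")
})

test_that("correlate is symmetric and Spearman is invariant to monotone maps", {
  set.seed(101)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    x[sample(30, 3)] <- NA
    a <- correlate(x, y); b <- correlate(y, x)
    expect_equal(a[c("r", "p", "n")], b[c("r", "p", "n")])
    expect_equal(correlate(exp(x), y)$r, a$r, tolerance = 1e-12)
  }
})

test_that("correlate matches the naive oracle on 100 random vectors", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- round(rnorm(n), 2); y <- round(rnorm(n), 2)  # rounding induces ties
    for (m in c("spearman", "pearson")) {
      got <- correlate(x, y, m); exp <- naive_cor(x, y, m)
      expect_equal(got$r, exp$r, tolerance = 1e-10)
      expect_equal(got$p, exp$p, tolerance = 1e-10)
    }
  }
})

test_that("screen flags planted dependence and obeys the gate contract", {
  ds <- generate_cohort(cohort_config(seed = 12))
  scr <- screen_associations(ds)
  # biomarkers and dominant-block elements share a latent factor: the
  # Se <-> VILIP-1 record must pass the 0.001 gate at n = 193
  rec <- scr[scr$biomarker == "vilip1" & scr$element == "csf_Se", ]
  expect_true(rec$passes_gate)
  expect_equal(rec$n, 193)
  # vacuous gate passes everything
  scr1 <- screen_associations(ds, gate = 1.0)
  expect_true(all(scr1$passes_gate))
  # gate monotonicity: passing at 0.001 implies passing at 0.01
  scr2 <- screen_associations(ds, gate = 0.01)
  key <- function(s) paste(s$biomarker, s$element, s$view)
  expect_true(all(key(scr)[scr$passes_gate] %in% key(scr2)[scr2$passes_gate]))
})

test_that("empty covariate set reduces adjustment to the plain correlation", {
  ds <- generate_cohort(cohort_config(seed = 12))
  plain <- correlate(ds$data$vilip1, ds$data$csf_Se)
  adj <- adjust_association(ds, "vilip1", "csf_Se", covariates = character())
  expect_equal(adj$r_partial, plain$r)
  expect_equal(adj$p_partial, plain$p)
})

test_that("adjustment removes purely age-driven dependence and keeps direct effects", {
  deflagged <- 0L; kept <- 0L
  n_rep <- 30
  for (s in 1:n_rep) {
    ds <- generate_cohort(cohort_config(seed = 4000 + s,
                                        factor_blocks = list()))
    d <- ds$data
    set.seed(9000 + s)
    age_c <- scale(d$age)
    # x and y depend only on age
    d$vilip1 <- exp(0.8 * age_c + 0.4 * rnorm(193))
    d$csf_Se <- exp(0.8 * age_c + 0.4 * rnorm(193))
    # a direct pair orthogonal to age
    z <- rnorm(193)
    d$ttau <- exp(0.7 * z + 0.4 * rnorm(193))
    d$csf_K <- exp(0.7 * z + 0.4 * rnorm(193))
    ds$data <- d
    a1 <- adjust_association(ds, "vilip1", "csf_Se", covariates = "age")
    a2 <- adjust_association(ds, "ttau", "csf_K", covariates = "age")
    if (!a1$retained) deflagged <- deflagged + 1L
    if (a2$retained) kept <- kept + 1L
  }
  expect_gte(deflagged / n_rep, 0.95)
  expect_gte(kept / n_rep, 0.95)
})

test_that("collinear covariates fail with an informative error", {
  ds <- generate_cohort(cohort_config(seed = 12))
  ds$data$age2 <- ds$data$age * 2
  ds$views$clinical <- c(ds$views$clinical, "age2")
  expect_error(adjust_association(ds, "vilip1", "csf_Se",
                                  covariates = c("age", "age2")),
               "collinear")
})
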
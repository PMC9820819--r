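# independent direct-formula oracles for the adequacy statistics
oracle_bartlett <- function(X) {
  n <- nrow(X); p <- ncol(X)
  R <- cor(X)
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(det(R))
  list(chi2 = chi2, dof = p * (p - 1) / 2,
       p = pchisq(chi2, p * (p - 1) / 2, lower.tail = FALSE))
}
oracle_kmo <- function(X) {
  R <- cor(X); Ri <- solve(R)
  D <- diag(1 / sqrt(diag(Ri)))
  Q <- -D %*% Ri %*% D; diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  sum(R0^2) / (sum(R0^2) + sum(Q^2))
}

test_that("Bartlett sphericity matches its closed form and handles degeneracy", {
  set.seed(31)
  X <- matrix(rnorm(193 * 5), 193, 5)
  got <- bartlett_sphericity(X)
  exp <- oracle_bartlett(X)
  expect_equal(got$chi2, exp$chi2, tolerance = 1e-8)
  expect_equal(got$dof, exp$dof)
  expect_equal(got$p, exp$p, tolerance = 1e-8)
  # exactly uncorrelated columns (orthogonal and mean-zero): R = I,
  # chi2 = 0, p = 1
  Q <- qr.Q(qr(scale(matrix(rnorm(50 * 3), 50, 3), scale = FALSE)))
  expect_equal(bartlett_sphericity(Q)$chi2, 0, tolerance = 1e-8)
  expect_equal(bartlett_sphericity(Q)$p, 1)
  # two perfectly correlated columns make R singular
  Z <- cbind(rnorm(50)); Z <- cbind(Z, 2 * Z)
  expect_error(bartlett_sphericity(Z), "singular")
})

test_that("KMO matches the anti-image oracle and the 2-variable closed form", {
  set.seed(32)
  X <- matrix(rnorm(100 * 6), 100, 6)
  X[, 2] <- X[, 1] + 0.7 * X[, 2]
  expect_equal(kmo(X)$overall_msa, oracle_kmo(X), tolerance = 1e-8)
  # with exactly two variables the anti-image partial correlation equals the
  # correlation itself, so the overall MSA is exactly 1/2
  expect_equal(kmo(X[, 1:2])$overall_msa, 0.5, tolerance = 1e-10)
  # two independent high-correlation blocks are adequate (MSA > 0.5)
  set.seed(33)
  f1 <- rnorm(200); f2 <- rnorm(200)
  B <- cbind(sapply(1:4, function(i) f1 + 0.5 * rnorm(200)),
             sapply(1:4, function(i) f2 + 0.5 * rnorm(200)))
  expect_gt(kmo(B)$overall_msa, 0.5)
})

test_that("assign_groups follows the threshold rule and preserves signs", {
  L <- rbind(Ca = c(0.845, 0.1, 0.05),
             Hg = c(-0.505, 0.3, 0.1),
             Tl = c(0.39, 0.2, 0.1))
  colnames(L) <- paste0("F", 1:3)
  g <- assign_groups(L, 0.4)
  expect_equal(g$groups$F1$element, c("Ca", "Hg"))
  expect_equal(g$groups$F1$loading, c(0.845, -0.505))
  expect_equal(g$unassigned$element, "Tl")
  expect_equal(g$unassigned$best_loading, 0.39)
  # the assignment partitions the elements exactly once
  all_named <- c(unlist(lapply(g$groups, `[[`, "element")),
                 g$unassigned$element)
  expect_setequal(all_named, rownames(L))
  expect_equal(length(all_named), nrow(L))
})

test_that("six planted disjoint blocks are recovered exactly at threshold 0.4", {
  els <- cohort_views()$csf_elements
  els <- setdiff(els, "csf_P")
  blocks <- split(els, rep(1:6, length.out = length(els)))
  blk <- lapply(blocks, function(a)
    list(view = "csf_elements", attributes = a, rho = 0.8))
  ds <- generate_cohort(cohort_config(seed = 77, factor_blocks = unname(blk),
                                      missingness = no_missingness()))
  sol <- fit_factors(ds, "csf_elements", n_factors = 6)
  expect_equal(nrow(sol$unassigned), 0)
  recovered <- lapply(sol$groups, function(g) sort(g$element))
  planted <- lapply(blocks, sort)
  # same partition up to factor relabelling
  expect_setequal(
    unname(vapply(recovered, paste, "", collapse = ",")),
    unname(vapply(planted, paste, "", collapse = ",")))
})

test_that("varimax rotation is orthogonal and invariant where it must be", {
  ds <- generate_cohort(cohort_config(seed = 21))
  sol <- fit_factors(ds, "csf_elements")
  T <- sol$rotation
  expect_equal(crossprod(T), diag(ncol(T)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # communalities and total explained variance are rotation-invariant
  X <- ds$data[complete.cases(ds$data[, setdiff(ds$views$csf_elements,
                                                "csf_P")]),
               setdiff(ds$views$csf_elements, "csf_P")]
  R <- cor(X)
  ev <- eigen(R, symmetric = TRUE)
  L0 <- ev$vectors[, 1:6] %*% diag(sqrt(ev$values[1:6]))
  expect_equal(unname(sol$communalities), unname(rowSums(L0^2)),
               tolerance = 1e-8)
  expect_equal(sol$variance_explained_total, sum(L0^2) / ncol(X),
               tolerance = 1e-10)
  # reduced-rank reconstruction error identical before and after rotation
  expect_equal(norm(R - tcrossprod(sol$loadings), "F"),
               norm(R - tcrossprod(L0), "F"), tolerance = 1e-10)
})

test_that("varimax leaves an already-simple loading matrix unchanged", {
  L <- matrix(0, 8, 2)
  L[1:4, 1] <- c(0.9, 0.85, 0.8, 0.75)
  L[5:8, 2] <- c(0.9, 0.85, 0.8, 0.75)
  rot <- stats::varimax(L, normalize = TRUE, eps = 1e-10)
  Lr <- L %*% rot$rotmat
  # identical up to column permutation and sign
  M <- abs(crossprod(Lr, L) / sqrt(colSums(Lr^2) %o% colSums(L^2)))
  expect_equal(sort(apply(M, 1, max)), c(1, 1), tolerance = 1e-8)
})

test_that("factor regressions recover a planted coefficient and the orthogonal identity", {
  ds <- generate_cohort(cohort_config(seed = 55))
  sol <- fit_factors(ds, "csf_elements")
  # biomarker built as 0.5 * F1 score + noise (on the standardized scale)
  set.seed(56)
  y <- 0.5 * sol$scores[, "F1"] + sqrt(1 - 0.25) * rnorm(nrow(sol$scores))
  d2 <- ds
  yy <- setNames(rep(NA_real_, nrow(ds$data)), ds$data$patient_id)
  yy[rownames(sol$scores)] <- y
  d2$data$ttau <- unname(yy)
  reg <- regress_on_factors(d2, sol, "ttau")
  b1 <- reg[reg$factor == "F1", ]
  expect_lt(abs(b1$beta_std - 0.5), 3 * b1$se / sd(y) * sd(sol$scores[, "F1"]))
  expect_true(all(abs(reg$beta_std[reg$factor != "F1"]) < 0.2))
  # centred orthonormal regressors: standardized betas equal correlations
  set.seed(57)
  S <- qr.Q(qr(scale(matrix(rnorm(100 * 3), 100, 3), scale = FALSE)))
  yv <- as.vector(S %*% c(0.4, -0.2, 0.1) + 0.05 * rnorm(100))
  fit <- lm(yv ~ S)
  bstd <- coef(fit)[-1] * apply(S, 2, sd) / sd(yv)
  expect_equal(unname(bstd), as.vector(cor(S, yv)), tolerance = 1e-10)
})
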
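# Dimensionality reduction of the element views.
#
# PCA on standardized complete-case element data, varimax rotation with
# Kaiser normalization, Bartlett/KMO adequacy diagnostics, >=0.4 loading
# group assignment, regression-method factor scores, and multiple linear
# regression of each biomarker on the factor scores.

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix of `X` is the identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * log det R` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @param X Complete-case numeric matrix (n rows > p columns).
#' @return List with `chi2`, `dof`, `p`.
#' @export
bartlett_sphericity <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete-case")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more rows than columns")
  R <- cor(X)
  detR <- det(R)
  if (!is.finite(detR) || detR < .Machine$double.eps)
    stop("correlation matrix is singular; remove collinear columns")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  dof <- p * (p - 1) / 2
  list(chi2 = chi2, dof = dof, p = pchisq(chi2, dof, lower.tail = FALSE))
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Compares squared correlations with squared anti-image partial
#' correlations; values near 1 favour factor analysis.
#'
#' @param X Complete-case numeric matrix with invertible correlation matrix.
#' @return List with `overall_msa` and named `per_variable_msa`.
#' @export
kmo <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete-case")
  R <- cor(X)
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is not invertible"))
  S <- diag(1 / sqrt(diag(Rinv)))
  A <- -S %*% Rinv %*% S          # anti-image partial correlations
  diag(A) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; a2 <- A^2
  overall <- sum(r2) / (sum(r2) + sum(a2))
  per_var <- colSums(r2) / (colSums(r2) + colSums(a2))
  names(per_var) <- colnames(X)
  list(overall_msa = overall, per_variable_msa = per_var)
}

#' Assign elements to factors by a loading threshold
#'
#' Each element goes to the factor of its largest absolute loading when that
#' absolute loading reaches the threshold (0.4 by default); the sign of the
#' loading is preserved in the report.  Elements whose best absolute loading
#' falls below the threshold are listed as unassigned together with their
#' best loading, so near-misses are visible.
#'
#' @param loadings Element-by-factor numeric matrix with dimnames.
#' @param threshold Absolute-loading threshold, default 0.4.
#' @return List with `groups` (per factor, data.frame of element/loading)
#'   and `unassigned` (data.frame element/best_factor/best_loading).
#' @export
assign_groups <- function(loadings, threshold = 0.4) {
  loadings <- as.matrix(loadings)
  stopifnot(all(is.finite(loadings)))
  if (is.null(colnames(loadings)))
    colnames(loadings) <- paste0("F", seq_len(ncol(loadings)))
  best <- apply(abs(loadings), 1, which.max)
  best_val <- loadings[cbind(seq_len(nrow(loadings)), best)]
  assigned <- abs(best_val) >= threshold
  groups <- lapply(seq_len(ncol(loadings)), function(j) {
    i <- which(assigned & best == j)
    data.frame(element = rownames(loadings)[i], loading = best_val[i],
               stringsAsFactors = FALSE)
  })
  names(groups) <- colnames(loadings)
  unassigned <- data.frame(
    element = rownames(loadings)[!assigned],
    best_factor = colnames(loadings)[best[!assigned]],
    best_loading = best_val[!assigned], stringsAsFactors = FALSE)
  list(groups = groups, unassigned = unassigned)
}

#' Fit a rotated principal-component factor solution to an element view
#'
#' Columns are standardized and the first `n_factors` principal components
#' extracted; loadings are varimax-rotated with Kaiser row normalization and
#' each column's sign is fixed so its largest-magnitude loading is positive.
#' Per-patient scores use the regression (Thompson) method on the
#' standardized data.  Patients with any missing value in the view are
#' excluded (complete-case).
#'
#' @param dataset A `cohort_dataset`.
#' @param view `"csf_elements"` or `"plasma_elements"`.
#' @param n_factors Number of factors, default 6; `"kaiser"` selects by the
#'   eigenvalue > 1 rule instead.
#' @param threshold Loading threshold passed to [assign_groups()].
#' @param drop Attributes excluded before the fit.  For the CSF view the
#'   default drops phosphorus, which is measured in too few patients.
#' @return Object of class `factor_solution` with fields `view`, `n_factors`,
#'   `loadings`, `rotation`, `variance_explained_total`, `bartlett`,
#'   `kmo_overall`, `kmo_per_variable`, `groups`, `unassigned`, `scores`,
#'   `patients`, `communalities`.
#' @export
fit_factors <- function(dataset, view = c("csf_elements", "plasma_elements"),
                        n_factors = 6, threshold = 0.4, drop = NULL) {
  view <- match.arg(view)
  if (is.null(drop))
    drop <- if (view == "csf_elements") "csf_P" else character()
  vd <- view_data(dataset, view)
  vd <- vd[, setdiff(colnames(vd), drop), drop = FALSE]
  cc <- complete.cases(vd)
  X <- as.matrix(vd[cc, , drop = FALSE])
  p <- ncol(X)
  if (nrow(X) <= p)
    stop("complete-case submatrix has too few rows (", nrow(X),
         ") for ", p, " elements")
  Z <- scale(X)
  R <- cor(X)
  ev <- eigen(R, symmetric = TRUE)
  if (identical(n_factors, "kaiser")) n_factors <- sum(ev$values > 1)
  n_factors <- as.integer(n_factors)
  if (n_factors > p) stop("n_factors exceeds the number of elements")
  L <- ev$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(ev$values[seq_len(n_factors)]), n_factors)
  rownames(L) <- colnames(X)
  rot <- stats::varimax(L, normalize = TRUE, eps = 1e-10)
  Lr <- L %*% rot$rotmat
  # fix column signs: largest-magnitude loading positive
  for (j in seq_len(ncol(Lr))) {
    i <- which.max(abs(Lr[, j]))
    if (Lr[i, j] < 0) Lr[, j] <- -Lr[, j]
  }
  colnames(Lr) <- paste0("F", seq_len(n_factors))
  grp <- assign_groups(Lr, threshold)
  # regression (Thompson) scores on standardized data
  scores <- Z %*% solve(R, Lr)
  colnames(scores) <- colnames(Lr)
  rownames(scores) <- rownames(vd)[cc]
  structure(list(
    view = view, n_factors = n_factors, loadings = Lr,
    rotation = rot$rotmat,
    variance_explained_total = sum(Lr^2) / p,
    bartlett = bartlett_sphericity(X),
    kmo_overall = kmo(X)$overall_msa,
    kmo_per_variable = kmo(X)$per_variable_msa,
    groups = grp$groups, unassigned = grp$unassigned,
    scores = scores, patients = rownames(vd)[cc],
    communalities = rowSums(Lr^2), threshold = threshold,
    eigenvalues = ev$values), class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf(
    "Factor solution (%s): %d factors over %d elements, %d patients\n",
    x$view, x$n_factors, nrow(x$loadings), nrow(x$scores)))
  cat(sprintf("  variance explained: %.1f%%   KMO: %.3f   Bartlett p: %.3g\n",
              100 * x$variance_explained_total, x$kmo_overall, x$bartlett$p))
  for (f in names(x$groups)) {
    g <- x$groups[[f]]
    if (!nrow(g)) { cat(" ", f, ": none loaded\n"); next }
    cat(" ", f, ":", paste(sprintf("%s (%.3f)", g$element, g$loading),
                           collapse = ", "), "\n")
  }
  if (nrow(x$unassigned))
    cat("  unassigned (best |loading| < ", x$threshold, "): ",
        paste(sprintf("%s (%.2f)", x$unassigned$element,
                      x$unassigned$best_loading), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Regress biomarkers on factor scores
#'
#' One multiple linear regression per biomarker on all factor scores
#' simultaneously, on patients that have complete element data (hence
#' scores) and a non-missing biomarker.  Reports the standardized
#' coefficient, the conventional per-coefficient standard error of the
#' unstandardized coefficient, its p-value and a 95% confidence interval.
#'
#' @param dataset A `cohort_dataset`.
#' @param solution A `factor_solution` fitted on the same cohort.
#' @param biomarkers Character vector of biomarker attributes, or `"all"`.
#' @return data.frame of class `factor_regression`: one row per
#'   (biomarker, factor) with `beta_std`, `se`, `p`, `ci_lo`, `ci_hi`, `n`.
#' @export
regress_on_factors <- function(dataset, solution, biomarkers = "all") {
  stopifnot(inherits(solution, "factor_solution"))
  if (identical(biomarkers, "all"))
    biomarkers <- dataset$views$csf_biomarkers
  d <- dataset$data
  rows <- list()
  for (bm in biomarkers) {
    if (is.null(d[[bm]])) stop("unknown biomarker: ", bm)
    y_all <- setNames(d[[bm]], d$patient_id)[solution$patients]
    keep <- !is.na(y_all)
    n <- sum(keep)
    if (n < 10) stop("fewer than 10 complete cases for ", bm)
    y <- y_all[keep]
    S <- solution$scores[keep, , drop = FALSE]
    fit <- lm(y ~ S)
    if (any(is.na(coef(fit)))) stop("rank-deficient factor scores for ", bm)
    sm <- summary(fit)$coefficients
    b <- coef(fit)[-1]
    rows[[bm]] <- data.frame(
      biomarker = bm, factor = colnames(S),
      members = vapply(colnames(S), function(f) {
        g <- solution$groups[[f]]
        if (nrow(g)) paste(sub("^(csf|plasma)_", "", g$element),
                           collapse = ", ") else "none"
      }, ""),
      beta_std = b * apply(S, 2, sd) / sd(y),
      se = sm[-1, "Std. Error"], p = sm[-1, "Pr(>|t|)"],
      ci_lo = b - qnorm(0.975) * sm[-1, "Std. Error"],
      ci_hi = b + qnorm(0.975) * sm[-1, "Std. Error"],
      n = n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("factor_regression", "data.frame")
  out
}
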
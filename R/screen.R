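# Pairwise biomarker-by-element correlation screen.
#
# One record per (biomarker, element, view) pair with pairwise-complete
# observations.  After a Bonferroni-motivated hard gate (p <= 0.001 by
# default), gate-passing associations can be re-tested for confounding by
# clinical covariates through residual-on-residual partial correlation.

#' Correlation of two vectors with missing values
#'
#' Spearman is computed as Pearson on average ranks; the p-value uses the t
#' approximation with `n - 2` degrees of freedom, where `n` counts
#' pairwise-complete observations.
#'
#' @param x,y Numeric vectors of equal length; `NA`s allowed.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `r`, `p`, `n`.  Errors of class `csf_too_few_pairs` when
#'   fewer than 3 complete pairs remain, `csf_zero_variance` when either
#'   vector is constant.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3)
    stop(structure(class = c("csf_too_few_pairs", "error", "condition"),
                   list(message = sprintf(
                     "fewer than 3 complete pairs (n=%d)", n), call = NULL)))
  xv <- x[ok]; yv <- y[ok]
  if (method == "spearman") { xv <- rank(xv); yv <- rank(yv) }
  if (sd(xv) == 0 || sd(yv) == 0)
    stop(structure(class = c("csf_zero_variance", "error", "condition"),
                   list(message = "zero variance in a correlated vector",
                        call = NULL)))
  r <- cor(xv, yv)
  p <- .cor_pvalue(r, n, df = n - 2L)
  list(r = r, p = p, n = n)
}

.cor_pvalue <- function(r, n, df) {
  r <- min(max(r, -1), 1)
  if (df <= 0) return(NA_real_)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(df / (1 - r^2))
  2 * pt(-abs(t), df)
}

#' Screen all biomarker-by-element pairs
#'
#' @param dataset A `cohort_dataset`.
#' @param gate Significance gate; a record passes when `p <= gate`.  Default
#'   0.001, the Bonferroni-motivated threshold used throughout the analysis.
#' @param method Correlation reported in the `r`/`p`/`passes_gate` columns;
#'   both Spearman and Pearson are always computed and emitted alongside.
#' @return Object of class `assoc_screen`: a data.frame with one row per
#'   computed pair (`biomarker`, `element`, `view`, `n`, `r_spearman`,
#'   `p_spearman`, `r_pearson`, `p_pearson`, `r`, `p`, `passes_gate`).
#'   Pairs with fewer than 3 complete observations or zero variance are
#'   omitted (and counted in the `skipped` attribute).
#' @export
screen_associations <- function(dataset, gate = 0.001,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "cohort_dataset"), gate > 0, gate <= 1)
  d <- dataset$data
  biomarkers <- dataset$views$csf_biomarkers
  element_sets <- list(CSF = dataset$views$csf_elements,
                       plasma = dataset$views$plasma_elements)
  rows <- list(); skipped <- 0L
  for (vw in names(element_sets)) {
    for (el in element_sets[[vw]]) {
      for (bm in biomarkers) {
        rs <- tryCatch(correlate(d[[bm]], d[[el]], "spearman"),
                       error = function(e) NULL)
        if (is.null(rs)) { skipped <- skipped + 1L; next }
        rp <- correlate(d[[bm]], d[[el]], "pearson")
        rec <- if (method == "spearman") rs else rp
        rows[[length(rows) + 1L]] <- data.frame(
          biomarker = bm, element = el, view = vw, n = rs$n,
          r_spearman = rs$r, p_spearman = rs$p,
          r_pearson = rp$r, p_pearson = rp$p,
          r = rec$r, p = rec$p, passes_gate = rec$p <= gate,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("assoc_screen", "data.frame"),
            gate = gate, method = method, skipped = skipped)
}

#' @export
`[.assoc_screen` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.assoc_screen <- function(x, ...) {
  cat("Correlation screen:", nrow(x), "pairs, gate p <=",
      attr(x, "gate"), "(", attr(x, "method"), ")\n")
  cat("  passing gate:", sum(x$passes_gate), "\n")
  if (attr(x, "skipped") > 0)
    cat("  skipped (n < 3 or constant):", attr(x, "skipped"), "\n")
  NextMethod()
}

#' Confounder-adjusted partial correlation for one pair
#'
#' Both variables are regressed on the covariates (ranks first when
#' `method = "spearman"`; categorical covariates one-hot encoded) and the
#' residuals are correlated.  The p-value uses a t reference with
#' `n - 2 - q` degrees of freedom, `q` being the number of covariate design
#' columns.  Complete cases over x, y and all covariates are used.
#'
#' @param dataset A `cohort_dataset`.
#' @param biomarker,element Attribute names.
#' @param covariates Character vector of clinical attribute names; empty
#'   gives back the unadjusted correlation.
#' @param method `"spearman"` or `"pearson"`.
#' @param gate Gate used for the `retained` flag.
#' @return List with `r_partial`, `p_partial`, `n`, `covariates`, `retained`.
#' @export
adjust_association <- function(dataset, biomarker, element,
                               covariates = c("age", "gender", "diagnosis",
                                              "duration"),
                               method = c("spearman", "pearson"),
                               gate = 0.001) {
  method <- match.arg(method)
  d <- dataset$data
  for (a in c(biomarker, element, covariates))
    if (is.null(d[[a]])) stop("unknown attribute: ", a)
  use <- complete.cases(d[, c(biomarker, element, covariates), drop = FALSE])
  n <- sum(use)
  if (!length(covariates)) {
    cc <- correlate(d[[biomarker]][use], d[[element]][use], method)
    return(list(r_partial = cc$r, p_partial = cc$p, n = cc$n,
                covariates = character(), retained = cc$p <= gate))
  }
  if (n < length(covariates) + 3)
    stop("too few complete cases (", n, ") for ", length(covariates),
         " covariates")
  x <- d[[biomarker]][use]; y <- d[[element]][use]
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  cov_df <- d[use, covariates, drop = FALSE]
  for (j in seq_along(cov_df))
    if (is.character(cov_df[[j]])) cov_df[[j]] <- factor(cov_df[[j]])
  mm <- model.matrix(~ ., data = cov_df)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    drop_cols <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  rx <- qr.resid(qrm, x); ry <- qr.resid(qrm, y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop(structure(class = c("csf_zero_variance", "error", "condition"),
                   list(message = "residuals have zero variance", call = NULL)))
  r <- cor(rx, ry)
  q <- ncol(mm) - 1L  # intercept absorbs nothing beyond centring
  p <- .cor_pvalue(r, n, df = n - 2L - q)
  list(r_partial = r, p_partial = p, n = n, covariates = covariates,
       retained = p <= gate)
}

#' Adjust every gate-passing record of a screen
#'
#' @param screen An `assoc_screen`.
#' @param dataset The cohort the screen was computed on.
#' @param covariates Clinical covariates to adjust for.
#' @param only_passing Adjust only gate-passing records (default) or all.
#' @return data.frame in long format: one row per (record, covariate set)
#'   with `r_partial`, `p_partial`, `n_partial`, `retained`.
#' @export
adjust_screen <- function(screen, dataset,
                          covariates = c("age", "gender", "diagnosis",
                                         "duration"),
                          only_passing = TRUE) {
  stopifnot(inherits(screen, "assoc_screen"))
  idx <- if (only_passing) which(screen$passes_gate) else seq_len(nrow(screen))
  gate <- attr(screen, "gate"); method <- attr(screen, "method")
  out <- screen[idx, c("biomarker", "element", "view", "r", "p"), drop = FALSE]
  out$covariates <- paste(covariates, collapse = "+")
  res <- lapply(idx, function(i) {
    tryCatch(adjust_association(dataset, screen$biomarker[i],
                                screen$element[i], covariates, method, gate),
             error = function(e) list(r_partial = NA_real_,
                                      p_partial = NA_real_, n = NA_integer_,
                                      retained = NA))
  })
  out$r_partial <- vapply(res, `[[`, 0, "r_partial")
  out$p_partial <- vapply(res, `[[`, 0, "p_partial")
  out$n_partial <- vapply(res, function(z) as.integer(z$n %||% NA), 0L)
  out$retained <- vapply(res, function(z) as.logical(z$retained), TRUE)
  rownames(out) <- NULL
  out
}
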
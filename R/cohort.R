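# Synthetic multi-view cohort generator.
#
# The generator emulates a memory-clinic cohort in which every patient carries
# four attribute views: clinical covariates, eleven CSF biomarkers of
# Alzheimer pathology (plus the derived abeta42/p-tau181 ratio), 24 element
# concentrations in CSF and 21 in plasma.  Concentrations are log-normal
# (ICP-MS data are right-skewed), correlated element blocks are induced by a
# Gaussian copula with one latent factor per block, and biomarkers load on a
# latent disease-severity score (shifted by diagnosis) plus the dominant CSF
# element factor so that the screen and factor-regression stages have
# recoverable signal.  Known cross-view subgroups ("planted redescriptions")
# can be embedded as ground truth for the miner.

#' Attribute names of the four cohort views
#'
#' @return Named list of character vectors: `clinical`, `csf_biomarkers`,
#'   `csf_elements`, `plasma_elements`.
#' @export
cohort_views <- function() {
  csf_el <- c("Al", "As", "B", "Ba", "Ca", "Cd", "Co", "Cu", "Fe", "Hg", "K",
              "Li", "Mg", "Mn", "Mo", "Na", "Ni", "P", "Pb", "S", "Se", "Sr",
              "Tl", "Zn")
  pl_el <- setdiff(csf_el, c("Al", "Ba", "K"))
  list(
    clinical = c("diagnosis", "age", "gender", "mmse", "apoe", "duration"),
    csf_biomarkers = c("abeta42", "ttau", "ptau181", "ptau199", "ptau231",
                       "vilip1", "nfl", "s100b", "ykl40", "pappa", "albumin",
                       "abeta_ratio"),
    csf_elements = paste0("csf_", csf_el),
    plasma_elements = paste0("plasma_", pl_el)
  )
}

# log-scale location (median) and spread per concentration attribute.
# Medians are placed so that typical values fall inside the interval ranges a
# clinical ICP-MS/ELISA panel would report (e.g. CSF Se around 0.3-3.7 ug/L,
# CSF K around 37-243 mg/L); electrolytes get a tighter spread than trace
# elements because they are homeostatically regulated.
.default_element_params <- function() {
  csf_med <- c(Al = 2.2, As = 0.35, B = 12, Ba = 8, Ca = 50, Cd = 0.015,
               Co = 0.12, Cu = 17, Fe = 40, Hg = 0.15, K = 120, Li = 1.5,
               Mg = 30, Mn = 1.2, Mo = 0.4, Na = 2700, Ni = 0.8, P = 450,
               Pb = 2.5, S = 15, Se = 1.3, Sr = 25, Tl = 0.02, Zn = 80)
  csf_sd <- ifelse(names(csf_med) %in% c("Na", "K", "Ca", "Mg", "S"), 0.35, 0.6)
  pl_med <- c(As = 1.2, B = 25, Ca = 78, Cd = 0.03, Co = 0.45, Cu = 950,
              Fe = 1500, Hg = 0.4, Li = 22, Mg = 26, Mn = 1.3, Mo = 1.2,
              Na = 3600, Ni = 1.8, P = 130, Pb = 1.0, S = 750, Se = 75,
              Sr = 25, Tl = 0.01, Zn = 700)
  pl_sd <- ifelse(names(pl_med) %in% c("Na", "Ca", "Mg", "S"), 0.25, 0.5)
  bio_med <- c(abeta42 = 600, ttau = 300, ptau181 = 55, ptau199 = 3,
               ptau231 = 4.5, vilip1 = 110, nfl = 90, s100b = 550,
               ykl40 = 120000, pappa = 200, albumin = 250)
  bio_sd <- c(abeta42 = 0.4, ttau = 0.6, ptau181 = 0.55, ptau199 = 0.7,
              ptau231 = 0.8, vilip1 = 0.6, nfl = 0.6, s100b = 0.6,
              ykl40 = 0.8, pappa = 0.6, albumin = 0.6)
  med <- c(setNames(csf_med, paste0("csf_", names(csf_med))),
           setNames(pl_med, paste0("plasma_", names(pl_med))), bio_med)
  sdv <- c(setNames(csf_sd, paste0("csf_", names(csf_med))),
           setNames(pl_sd, paste0("plasma_", names(pl_med))), bio_sd)
  list(log_mean = log(med), log_sd = sdv)
}

# severity loading (lam) and dominant-CSF-block loading (gam) per biomarker,
# on the standardized log scale.  Amyloid loads negatively on severity; tau
# isoforms and neurodegeneration/glial markers positively.
.default_biomarker_loadings <- function() {
  lam <- c(abeta42 = -0.50, ttau = 0.55, ptau181 = 0.50, ptau199 = 0.45,
           ptau231 = 0.50, vilip1 = 0.45, nfl = 0.40, s100b = 0.35,
           ykl40 = 0.35, pappa = 0.30, albumin = 0.20)
  gam <- c(abeta42 = 0.00, ttau = 0.25, ptau181 = 0.30, ptau199 = 0.30,
           ptau231 = 0.30, vilip1 = 0.55, nfl = 0.35, s100b = 0.40,
           ykl40 = 0.35, pappa = 0.40, albumin = 0.35)
  list(lam = lam, gam = gam)
}

# Default correlated element blocks: one dominant CSF block of 16 elements,
# a heavy-metal block (Al, Cd, Pb), B+Li and Hg+Mo in CSF; an 11-element
# dominant plasma block, a B/Cd/Li/Mo/Pb block and As+Hg in plasma.
.default_factor_blocks <- function() {
  b <- function(view, els, rho) list(view = view, attributes = els, rho = rho)
  csf <- function(x) paste0("csf_", x)
  pl <- function(x) paste0("plasma_", x)
  list(
    b("csf_elements", csf(c("As", "Ba", "Ca", "Co", "Cu", "Fe", "K", "Mg",
                            "Mn", "Na", "Ni", "S", "Se", "Sr", "Tl", "Zn")), 0.55),
    b("csf_elements", csf(c("Al", "Cd", "Pb")), 0.55),
    b("csf_elements", csf(c("B", "Li")), 0.50),
    b("csf_elements", csf(c("Hg", "Mo")), 0.45),
    b("plasma_elements", pl(c("Ca", "Co", "Cu", "Mg", "Mn", "Na", "P", "S",
                              "Se", "Tl", "Zn")), 0.50),
    b("plasma_elements", pl(c("B", "Cd", "Li", "Mo", "Pb")), 0.45),
    b("plasma_elements", pl(c("As", "Hg")), 0.50)
  )
}

# Per-attribute completely-at-random missingness; fractions mirror the varying
# per-assay ns of a real panel (some assays run on subsets of the cohort).
.default_missingness <- function() {
  c(ykl40 = 0.08, s100b = 0.18, nfl = 0.38, albumin = 0.26, pappa = 0.08,
    csf_P = 0.60, csf_Ni = 0.025, duration = 0.10)
}

#' Describe a planted cross-view subgroup
#'
#' A planted redescription embeds a patient subgroup whose members fall inside
#' every listed interval, while non-members satisfy each view's full condition
#' set only with probability `leak_fraction`.  It provides ground truth for
#' evaluating the redescription miner.
#'
#' @param member_fraction Fraction of the cohort in the subgroup, in (0,1).
#' @param conditions List of conditions, each a list with fields `view`,
#'   `attribute`, `low`, `high`; at least two distinct views must appear.
#' @param leak_fraction Probability that a non-member satisfies all the
#'   conditions of one view, in (0,1) (0 is accepted and gives a leak-free
#'   plant).
#' @return Object of class `planted_redescription`.
#' @export
planted_redescription <- function(member_fraction, conditions,
                                  leak_fraction = 0.05) {
  stopifnot(is.numeric(member_fraction), member_fraction > 0,
            member_fraction < 1, is.numeric(leak_fraction),
            leak_fraction >= 0, leak_fraction < 1, length(conditions) >= 2)
  for (cond in conditions) {
    if (!all(c("view", "attribute", "low", "high") %in% names(cond)))
      stop("each condition needs fields view, attribute, low, high")
    if (!(cond$low < cond$high))
      stop("condition on '", cond$attribute, "': low must be < high")
  }
  if (length(unique(vapply(conditions, `[[`, "", "view"))) < 2)
    stop("a planted redescription must span at least two distinct views")
  structure(list(member_fraction = member_fraction, conditions = conditions,
                 leak_fraction = leak_fraction),
            class = "planted_redescription")
}

#' Configure a synthetic cohort
#'
#' Defaults reproduce the modelled study conditions: 124 AD, 50 MCI and 19 HC
#' patients (193 in total) with plasma measured in a 143-patient subset,
#' log-normal element concentrations with correlated blocks, severity-driven
#' biomarkers and per-attribute missingness.
#'
#' @param n_ad,n_mci,n_hc Diagnostic group sizes.
#' @param plasma_subset_n Number of patients with a plasma element view.
#' @param missingness Named numeric vector of per-attribute missingness
#'   fractions in \[0,1\]; replaces matching defaults.
#' @param element_params List with named vectors `log_mean` and `log_sd`
#'   giving the log-scale location/spread per concentration attribute;
#'   entries override the defaults.
#' @param factor_blocks List of blocks `list(view, attributes, rho)` inducing
#'   within-block correlation `rho` (in \[0,1)) on the log scale.  The first
#'   `csf_elements` block is the dominant factor on which biomarkers load.
#' @param planted_redescriptions List of [planted_redescription()] objects.
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   cohorts.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_ad = 124, n_mci = 50, n_hc = 19,
                          plasma_subset_n = 143,
                          missingness = NULL,
                          element_params = NULL,
                          factor_blocks = .default_factor_blocks(),
                          planted_redescriptions = list(),
                          seed = 1L) {
  stopifnot(n_ad >= 0, n_mci >= 0, n_hc >= 0)
  n <- n_ad + n_mci + n_hc
  if (n < 1) stop("cohort must contain at least one patient")
  if (plasma_subset_n > n)
    stop("plasma_subset_n (", plasma_subset_n, ") exceeds cohort size ", n)
  params <- .default_element_params()
  if (!is.null(element_params)) {
    for (fld in c("log_mean", "log_sd"))
      if (!is.null(element_params[[fld]]))
        params[[fld]][names(element_params[[fld]])] <- element_params[[fld]]
  }
  miss <- .default_missingness()
  if (!is.null(missingness)) {
    if (is.null(names(missingness)) || any(!nzchar(names(missingness))))
      stop("missingness must be a named vector")
    if (any(missingness < 0 | missingness > 1))
      stop("missingness fractions must lie in [0,1]")
    miss[names(missingness)] <- missingness
  }
  views <- cohort_views()
  all_attrs <- unlist(views, use.names = FALSE)
  bad <- setdiff(names(miss), all_attrs)
  if (length(bad))
    stop("missingness names unknown attributes: ", paste(bad, collapse = ", "))
  for (blk in factor_blocks) {
    if (!blk$view %in% names(views)) stop("unknown view in factor block: ", blk$view)
    bad <- setdiff(blk$attributes, views[[blk$view]])
    if (length(bad))
      stop("factor block attributes not in view '", blk$view, "': ",
           paste(bad, collapse = ", "))
    if (!(blk$rho >= 0 && blk$rho < 1))
      stop("block correlation must lie in [0,1)")
  }
  for (pl in planted_redescriptions) {
    if (!inherits(pl, "planted_redescription"))
      stop("planted_redescriptions must be planted_redescription objects")
    for (cond in pl$conditions) {
      if (!cond$view %in% names(views))
        stop("unknown view in planted condition: ", cond$view)
      # clinical query attributes (MMSE, age) may ride on the biomarker
      # side, as they do in first-view rules
      ok_attr <- cond$attribute %in% views[[cond$view]] ||
        (cond$view == "csf_biomarkers" &&
           cond$attribute %in% c("mmse", "age"))
      if (!ok_attr)
        stop("planted condition attribute not in view '", cond$view, "': ",
             cond$attribute)
      .check_interval_feasible(cond$attribute, cond$low, cond$high)
    }
  }
  structure(list(n_ad = n_ad, n_mci = n_mci, n_hc = n_hc,
                 plasma_subset_n = plasma_subset_n, missingness = miss,
                 element_params = params, factor_blocks = factor_blocks,
                 planted_redescriptions = planted_redescriptions,
                 biomarker_loadings = .default_biomarker_loadings(),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# attribute support: concentrations live on (0, Inf); mmse on 0..30;
# age on 18..110; duration on 0..40.
.attr_support <- function(attribute) {
  switch(attribute,
         mmse = c(0, 30),
         age = c(18, 110),
         duration = c(0, 40),
         c(0, Inf))
}

.attr_integer <- function(attribute) attribute %in% c("mmse", "age", "duration")

.check_interval_feasible <- function(attribute, low, high) {
  sup <- .attr_support(attribute)
  if (high <= sup[1] || low >= sup[2])
    stop("infeasible interval for attribute '", attribute,
         "': [", low, ", ", high, "] lies outside its support [",
         sup[1], ", ", sup[2], "]")
  invisible(TRUE)
}

# draw values inside [low, high] respecting integer attributes
.draw_inside <- function(attribute, low, high, nn) {
  sup <- .attr_support(attribute)
  lo <- max(low, sup[1]); hi <- min(high, sup[2])
  if (.attr_integer(attribute)) {
    vals <- ceiling(lo):floor(hi)
    if (!length(vals))
      stop("infeasible interval for attribute '", attribute,
           "': contains no integer value")
    vals[1L + floor(runif(nn) * length(vals))]
  } else {
    runif(nn, lo, hi)
  }
}

# push values of `idx` rows outside [low, high] by redrawing from the
# attribute's marginal (log-normal for concentrations, uniform over the
# complement for bounded integers)
.draw_outside <- function(attribute, low, high, nn, log_mean, log_sd) {
  sup <- .attr_support(attribute)
  if (.attr_integer(attribute)) {
    vals <- setdiff(sup[1]:sup[2], ceiling(low):floor(high))
    if (!length(vals))
      stop("infeasible interval for attribute '", attribute,
           "': covers the whole attribute support")
    return(vals[1L + floor(runif(nn) * length(vals))])
  }
  out <- rep(NA_real_, nn)
  todo <- seq_len(nn)
  for (i in 1:200) {
    if (!length(todo)) break
    cand <- exp(rnorm(length(todo), log_mean, log_sd))
    ok <- cand < low | cand > high
    out[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  if (length(todo))
    stop("interval for attribute '", attribute,
         "' covers essentially all of its marginal support")
  out
}

#' Generate a synthetic multi-view cohort
#'
#' @param config A [cohort_config()].
#' @return Object of class `cohort_dataset`: a list with `data` (one row per
#'   patient, `patient_id` plus all view attributes, `NA` for missing cells),
#'   `views` (attribute-to-view map) and the generating `config`.
#' @examples
#' ds <- generate_cohort(cohort_config(seed = 7))
#' table(ds$data$diagnosis)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  views <- cohort_views()
  n <- config$n_ad + config$n_mci + config$n_hc
  diagnosis <- c(rep("AD", config$n_ad), rep("MCI", config$n_mci),
                 rep("HC", config$n_hc))
  id <- sprintf("P%03d", seq_len(n))

  ## latent structure ---------------------------------------------------
  base <- c(AD = 1, MCI = 0, HC = -1)[diagnosis]
  sev_raw <- base + rnorm(n, 0, 0.6)
  sev <- as.numeric(scale(sev_raw))

  blocks <- config$factor_blocks
  block_scores <- lapply(blocks, function(b) rnorm(n))
  attr_block <- list()   # attribute -> list(score index, rho)
  for (i in seq_along(blocks))
    for (a in blocks[[i]]$attributes)
      attr_block[[a]] <- list(idx = i, rho = blocks[[i]]$rho)
  dom_idx <- which(vapply(blocks, function(b) b$view == "csf_elements", TRUE))
  f_dom <- if (length(dom_idx)) block_scores[[dom_idx[1]]] else rep(0, n)

  lm_ <- config$element_params$log_mean
  ls_ <- config$element_params$log_sd
  dat <- data.frame(patient_id = id, diagnosis = diagnosis,
                    stringsAsFactors = FALSE)

  ## clinical ------------------------------------------------------------
  dat$age <- pmin(pmax(round(rnorm(n, 72, 8)), 49), 91)
  dat$gender <- c("F", "M")[1L + (runif(n) < 0.4)]
  apoe_levels <- c("e2e3", "e3e3", "e3e4", "e4e4", "e2e4")
  apoe_p <- rbind(AD = c(0.04, 0.38, 0.40, 0.15, 0.03),
                  MCI = c(0.07, 0.50, 0.32, 0.08, 0.03),
                  HC = c(0.10, 0.62, 0.22, 0.03, 0.03))
  dat$apoe <- vapply(diagnosis, function(d)
    sample(apoe_levels, 1L, prob = apoe_p[d, ]), "")
  dat$mmse <- pmin(pmax(round(26 - 4 * sev + rnorm(n, 0, 2)), 0), 30)
  dat$duration <- ifelse(diagnosis == "HC", 0,
                         pmin(round(rexp(n, 1 / 3) + 0.5), 15))

  ## biomarkers ----------------------------------------------------------
  loads <- config$biomarker_loadings
  for (b in setdiff(views$csf_biomarkers, "abeta_ratio")) {
    lam <- loads$lam[[b]]; gam <- loads$gam[[b]]
    res <- sqrt(max(0, 1 - lam^2 - gam^2))
    z <- lam * sev + gam * f_dom + res * rnorm(n)
    dat[[b]] <- exp(lm_[[b]] + ls_[[b]] * z)
  }

  ## elements ------------------------------------------------------------
  for (a in c(views$csf_elements, views$plasma_elements)) {
    ab <- attr_block[[a]]
    z <- if (is.null(ab)) rnorm(n) else
      sqrt(ab$rho) * block_scores[[ab$idx]] + sqrt(1 - ab$rho) * rnorm(n)
    dat[[a]] <- exp(lm_[[a]] + ls_[[a]] * z)
  }

  ## planted subgroups ---------------------------------------------------
  planted <- list()
  for (pi in seq_along(config$planted_redescriptions)) {
    pl <- config$planted_redescriptions[[pi]]
    m <- max(1L, round(pl$member_fraction * n))
    members <- sort(sample.int(n, m))
    nonmem <- setdiff(seq_len(n), members)
    for (cond in pl$conditions)
      dat[[cond$attribute]][members] <-
        .draw_inside(cond$attribute, cond$low, cond$high, m)
    sides <- split(pl$conditions,
                   vapply(pl$conditions, `[[`, "", "view"))
    for (side in sides) {
      leak <- runif(length(nonmem)) < pl$leak_fraction
      leak_rows <- nonmem[leak]
      if (length(leak_rows))
        for (cond in side)
          dat[[cond$attribute]][leak_rows] <-
            .draw_inside(cond$attribute, cond$low, cond$high, length(leak_rows))
      hold_rows <- nonmem[!leak]
      if (length(hold_rows)) {
        inside_all <- rep(TRUE, length(hold_rows))
        for (cond in side) {
          v <- dat[[cond$attribute]][hold_rows]
          inside_all <- inside_all & v >= cond$low & v <= cond$high
        }
        fix <- hold_rows[inside_all]
        if (length(fix)) {
          cond <- side[[1]]
          dat[[cond$attribute]][fix] <-
            .draw_outside(cond$attribute, cond$low, cond$high, length(fix),
                          lm_[[cond$attribute]] %||% 0,
                          ls_[[cond$attribute]] %||% 1)
        }
      }
    }
    planted[[pi]] <- list(members = id[members], plant = pl)
  }

  ## plasma subset and missingness --------------------------------------
  plasma_rows <- sort(sample.int(n, config$plasma_subset_n))
  out_rows <- setdiff(seq_len(n), plasma_rows)
  for (a in views$plasma_elements) dat[[a]][out_rows] <- NA_real_

  for (a in names(config$missingness)) {
    q <- config$missingness[[a]]
    if (q > 0) dat[[a]][runif(n) < q] <- NA
  }

  dat$abeta_ratio <- dat$abeta42 / dat$ptau181

  structure(list(data = dat, views = views, config = config,
                 planted = planted, plasma_subset = id[plasma_rows]),
            class = "cohort_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_dataset <- function(x, ...) {
  d <- x$data
  cat("Synthetic multi-view cohort:", nrow(d), "patients\n")
  tb <- table(factor(d$diagnosis, levels = c("AD", "MCI", "HC")))
  cat("  diagnosis:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  for (v in names(x$views)) {
    cols <- x$views[[v]]
    miss <- sum(is.na(d[, cols]))
    cat(sprintf("  view %-16s %2d attributes, %d missing cells\n",
                v, length(cols), miss))
  }
  if (length(x$planted))
    cat("  planted redescriptions:", length(x$planted), "\n")
  invisible(x)
}

#' Extract one view of a cohort as a data.frame
#'
#' @param dataset A `cohort_dataset`.
#' @param view One of `"clinical"`, `"csf_biomarkers"`, `"csf_elements"`,
#'   `"plasma_elements"`.
#' @param extra Additional attribute names to append (e.g. clinical query
#'   attributes attached to the biomarker view).
#' @return data.frame with rownames set to patient ids.
#' @export
view_data <- function(dataset, view, extra = character()) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (!view %in% names(dataset$views))
    stop("unknown view: ", view)
  cols <- c(dataset$views[[view]], extra)
  out <- dataset$data[, cols, drop = FALSE]
  rownames(out) <- dataset$data$patient_id
  out
}
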
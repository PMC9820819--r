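# One-command orchestration of the full analysis with a reproducible
# report bundle: correlation screen table, factor solutions and factor
# regressions, redescription sets per view combination, co-occurrence
# counts, and a manifest of seeds/parameters/row counts.

#' Configure a pipeline run
#'
#' @param cohort Either a `cohort_dataset`, a [cohort_config()] (the cohort
#'   is then generated), or a path to a cohort file readable by
#'   [read_cohort()].
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param gate Correlation-screen significance gate.
#' @param covariates Clinical covariates for adjusted re-testing.
#' @param n_factors Factors per element view.
#' @param loading_threshold Loading threshold for factor groups.
#' @param miner Base [miner_params()]; support bounds are overridden per
#'   view combination by `support_bounds`.
#' @param view_combinations List of view vectors to mine; default the
#'   CSF pair, the plasma pair and the three-view combination.
#' @param support_bounds Named list mapping combination name to
#'   `c(min, max)` support bounds; defaults follow the protocol presets
#'   (30-155 CSF pair, 30-115 plasma pair, 20-110 three-view).
#' @param stages Character vector of stages to run, a subset of
#'   `c("screen", "factors", "mining")`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            out_dir = "csfmetals_out",
                            seed = 1L,
                            gate = 0.001,
                            covariates = c("age", "gender", "diagnosis",
                                           "duration"),
                            n_factors = 6L,
                            loading_threshold = 0.4,
                            miner = miner_params(),
                            view_combinations = list(
                              pair_csf = c("csf_biomarkers", "csf_elements"),
                              pair_plasma = c("csf_biomarkers",
                                              "plasma_elements"),
                              triple = c("csf_biomarkers", "csf_elements",
                                         "plasma_elements")),
                            support_bounds = list(
                              pair_csf = c(30L, 155L),
                              pair_plasma = c(30L, 115L),
                              triple = c(20L, 110L)),
                            stages = c("screen", "factors", "mining")) {
  structure(list(cohort = cohort, out_dir = out_dir, seed = as.integer(seed),
                 gate = gate, covariates = covariates,
                 n_factors = n_factors,
                 loading_threshold = loading_threshold, miner = miner,
                 view_combinations = view_combinations,
                 support_bounds = support_bounds, stages = stages),
            class = "pipeline_config")
}

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

.solution_json <- function(sol) {
  list(view = sol$view, n_factors = sol$n_factors,
       variance_explained_total = sol$variance_explained_total,
       bartlett = sol$bartlett, kmo_overall = sol$kmo_overall,
       loadings = as.data.frame(round(sol$loadings, 6)),
       groups = lapply(sol$groups, function(g)
         if (nrow(g)) setNames(as.list(round(g$loading, 3)), g$element)
         else list()),
       unassigned = sol$unassigned, n_patients = nrow(sol$scores))
}

.redescription_json <- function(rd) {
  list(queries = lapply(rd$queries, function(q)
         list(view = q$view, rule = format(q))),
       support = rd$support, support_sizes = rd$support_sizes,
       jaccard = rd$jaccard, p_value = rd$p_value, p_method = rd$p_method,
       per_diagnosis_pct = as.list(round(rd$per_diagnosis_pct, 1)),
       specificity_label = rd$specificity_label)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages on the cohort and writes a report bundle:
#' `cohort.csv`, `correlations.csv` (+ `correlations_adjusted.csv`),
#' `factors_csf.json`/`factors_plasma.json`, `factor_regressions.csv`,
#' `redescriptions_<combo>.json` + `redescriptions_<combo>.tsv`,
#' `cooccurrence_counts.csv`, and `manifest.json`.  Two invocations with the
#' same config produce byte-identical bundles.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  dataset <- config$cohort
  if (inherits(dataset, "cohort_config")) {
    dataset$seed <- config$seed
    dataset <- generate_cohort(dataset)
  } else if (is.character(dataset)) {
    dataset <- read_cohort(dataset)
  }
  stopifnot(inherits(dataset, "cohort_dataset"))
  write_cohort(dataset, out("cohort.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("csfmetals")),
    master_seed = config$seed,
    n_patients = nrow(dataset$data),
    group_sizes = as.list(table(dataset$data$diagnosis)),
    stages_run = config$stages, stages_skipped =
      setdiff(c("screen", "factors", "mining"), config$stages),
    parameters = list(gate = config$gate, n_factors = config$n_factors,
                      loading_threshold = config$loading_threshold,
                      miner = unclass(config$miner)))
  results <- list(dataset = dataset)

  if ("screen" %in% config$stages) {
    scr <- screen_associations(dataset, gate = config$gate)
    tab <- as.data.frame(scr)
    for (cl in c("r_spearman", "p_spearman", "r_pearson", "p_pearson",
                 "r", "p"))
      tab[[cl]] <- signif(tab[[cl]], 6)
    write.csv(tab, out("correlations.csv"), row.names = FALSE)
    adj <- adjust_screen(scr, dataset, config$covariates)
    adj$r <- signif(adj$r, 6); adj$p <- signif(adj$p, 6)
    adj$r_partial <- signif(adj$r_partial, 6)
    adj$p_partial <- signif(adj$p_partial, 6)
    write.csv(adj, out("correlations_adjusted.csv"), row.names = FALSE)
    manifest$screen <- list(n_pairs = nrow(scr),
                            n_passing = sum(scr$passes_gate),
                            n_retained = sum(adj$retained, na.rm = TRUE))
    results$screen <- scr; results$adjusted <- adj
  }

  if ("factors" %in% config$stages) {
    regs <- list()
    for (vw in c("csf_elements", "plasma_elements")) {
      sol <- fit_factors(dataset, vw, n_factors = config$n_factors,
                         threshold = config$loading_threshold)
      tag <- if (vw == "csf_elements") "csf" else "plasma"
      .write_json(.solution_json(sol), out(paste0("factors_", tag, ".json")))
      regs[[tag]] <- cbind(element_view = tag,
                           regress_on_factors(dataset, sol))
      results[[paste0("factors_", tag)]] <- sol
    }
    reg <- do.call(rbind, regs)
    for (cl in c("beta_std", "se", "p", "ci_lo", "ci_hi"))
      reg[[cl]] <- signif(reg[[cl]], 6)
    write.csv(reg, out("factor_regressions.csv"), row.names = FALSE)
    manifest$factors <- list(
      csf_variance_explained = results$factors_csf$variance_explained_total,
      csf_kmo = results$factors_csf$kmo_overall,
      plasma_variance_explained =
        results$factors_plasma$variance_explained_total,
      plasma_kmo = results$factors_plasma$kmo_overall)
    results$factor_regressions <- reg
  }

  if ("mining" %in% config$stages) {
    mined <- list(); cooc <- list()
    for (combo in names(config$view_combinations)) {
      mp <- config$miner
      sb <- config$support_bounds[[combo]]
      if (!is.null(sb)) {
        mp$min_support <- as.integer(sb[1]); mp$max_support <- as.integer(sb[2])
      }
      mp$seed <- config$seed
      rset <- mine_redescriptions(dataset,
                                  config$view_combinations[[combo]],
                                  params = mp)
      .write_json(lapply(rset$redescriptions, .redescription_json),
                  out(paste0("redescriptions_", combo, ".json")))
      write.table(as.data.frame(rset),
                  out(paste0("redescriptions_", combo, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      mined[[combo]] <- rset
      ## co-occurrence counts over all attribute pairs that actually occur
      attrs <- lapply(rset$redescriptions, function(rd)
        unique(unlist(lapply(rd$queries, function(q)
          vapply(q$conditions, `[[`, "", "attribute")))))
      pair_counts <- list()
      for (aa in attrs) {
        if (length(aa) < 2) next
        cmb <- utils::combn(sort(aa), 2)
        for (ci in seq_len(ncol(cmb))) {
          kk <- paste(cmb[1, ci], cmb[2, ci], sep = "|")
          pair_counts[[kk]] <- (pair_counts[[kk]] %||% 0L) + 1L
        }
      }
      if (length(pair_counts)) {
        parts <- strsplit(names(pair_counts), "|", fixed = TRUE)
        cooc[[combo]] <- data.frame(
          combination = combo,
          attr_a = vapply(parts, `[[`, "", 1L),
          attr_b = vapply(parts, `[[`, "", 2L),
          count = unlist(pair_counts, use.names = FALSE),
          stringsAsFactors = FALSE)
      }
      manifest$mining[[combo]] <- list(
        n_redescriptions = length(rset$redescriptions),
        min_support = mp$min_support, max_support = mp$max_support)
    }
    cooc_df <- if (length(cooc)) do.call(rbind, cooc) else
      data.frame(combination = character(), attr_a = character(),
                 attr_b = character(), count = integer())
    cooc_df <- cooc_df[order(cooc_df$combination, -cooc_df$count,
                             cooc_df$attr_a, cooc_df$attr_b), ]
    write.csv(cooc_df, out("cooccurrence_counts.csv"), row.names = FALSE)
    results$mined <- mined
  }

  .write_json(manifest, out("manifest.json"))
  results$manifest <- manifest
  invisible(results)
}
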
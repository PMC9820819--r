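# Multi-view redescription mining.
#
# A redescription is a tuple of AND-only conjunctive queries over distinct
# attribute views that describe (nearly) the same patient set.  Candidate
# rules are induced by alternating multi-target trees (one view's rules
# become the targets for the next), supplemented by a bootstrap forest and a
# greedy conjunctive refinement, then filtered by support-set bounds,
# Jaccard accuracy and an exact random-subset significance model.

#' Build a single query condition
#'
#' @param attribute Attribute name.
#' @param low,high Closed interval bounds (interval condition).
#' @param level Categorical level (categorical condition).
#' @return Object of class `rd_condition`.
#' @export
rd_condition <- function(attribute, low = NULL, high = NULL, level = NULL) {
  if (!is.null(level)) {
    structure(list(attribute = attribute, kind = "categorical",
                   level = as.character(level)), class = "rd_condition")
  } else {
    stopifnot(is.numeric(low), is.numeric(high))
    if (low > high) stop("condition on '", attribute, "': low > high")
    structure(list(attribute = attribute, kind = "interval",
                   low = low, high = high), class = "rd_condition")
  }
}

#' Build an AND-only query over one view
#'
#' @param view View id the conditions refer to.
#' @param conditions Nonempty list of [rd_condition()]s.
#' @return Object of class `rd_query`.
#' @export
rd_query <- function(view, conditions) {
  stopifnot(length(conditions) >= 1)
  structure(list(view = view, conditions = conditions), class = "rd_query")
}

.format_condition <- function(cond) {
  if (cond$kind == "categorical")
    paste0(cond$attribute, " = ", cond$level)
  else
    sprintf("%s (%.6g-%.6g)", cond$attribute, cond$low, cond$high)
}

#' @export
format.rd_query <- function(x, ...)
  paste(vapply(x$conditions, .format_condition, ""), collapse = " AND ")

#' @export
print.rd_query <- function(x, ...) {
  cat("[", x$view, "] ", format(x), "\n", sep = "")
  invisible(x)
}

# canonical text key for deduplication
query_signature <- function(q) {
  paste(q$view, paste(sort(vapply(q$conditions, .format_condition, "")),
                      collapse = " & "))
}

# evaluate a query against a view data.frame -> logical over rows.
# A patient is described iff every condition's attribute is non-missing and
# the value lies in the closed interval / equals the level.
evaluate_query_df <- function(query, view_df) {
  keep <- rep(TRUE, nrow(view_df))
  for (cond in query$conditions) {
    v <- view_df[[cond$attribute]]
    if (is.null(v)) stop("unknown attribute: ", cond$attribute)
    ok <- if (cond$kind == "categorical")
      !is.na(v) & as.character(v) == cond$level
    else
      !is.na(v) & v >= cond$low & v <= cond$high
    keep <- keep & ok
  }
  keep
}

#' Evaluate a query on a cohort
#'
#' @param query An [rd_query()].
#' @param dataset A `cohort_dataset`.
#' @return Character vector of patient ids described by the query (missing
#'   values exclude a patient).
#' @export
evaluate_query <- function(query, dataset) {
  stopifnot(inherits(query, "rd_query"), inherits(dataset, "cohort_dataset"))
  d <- dataset$data
  keep <- rep(TRUE, nrow(d))
  for (cond in query$conditions) {
    v <- d[[cond$attribute]]
    if (is.null(v)) stop("unknown attribute: ", cond$attribute)
    ok <- if (cond$kind == "categorical")
      !is.na(v) & as.character(v) == cond$level
    else
      !is.na(v) & v >= cond$low & v <= cond$high
    keep <- keep & ok
  }
  d$patient_id[keep]
}

#' Jaccard index of 2-3 support sets
#'
#' @param supports List of 2 or 3 patient-id vectors.
#' @return List with `intersection_size`, `union_size`, `jaccard`
#'   (`0/0` defined as 0).
#' @export
jaccard_index <- function(supports) {
  stopifnot(length(supports) >= 2, length(supports) <= 3)
  inter <- Reduce(intersect, supports)
  uni <- Reduce(union, supports)
  j <- if (!length(uni)) 0 else length(inter) / length(uni)
  list(intersection_size = length(inter), union_size = length(uni),
       jaccard = j)
}

#' Significance of a redescription under the random-subset model
#'
#' Probability that independently uniform random subsets of the observed
#' sizes intersect in at least `intersection` patients.  For two sets this
#' is the hypergeometric upper tail; for three sets an exact two-stage
#' hypergeometric convolution is used when `n <= 500`, otherwise seeded
#' Monte Carlo with `mc_samples` draws.
#'
#' @param support_sizes Integer vector of 2 or 3 per-query support sizes.
#' @param intersection Observed intersection size.
#' @param n Number of patients in the universe.
#' @param mc_samples Monte-Carlo sample count for large-n three-set cases.
#' @param seed Seed for the Monte-Carlo path.
#' @return The p-value (1 when `intersection` is 0).
#' @export
redescription_pvalue <- function(support_sizes, intersection, n,
                                 mc_samples = 100000L, seed = 1L) {
  support_sizes <- as.integer(support_sizes)
  stopifnot(length(support_sizes) %in% c(2L, 3L), all(support_sizes <= n),
            all(support_sizes >= 0))
  if (intersection > min(support_sizes))
    stop("intersection exceeds the smallest support size")
  if (intersection <= 0) return(1)
  a <- support_sizes[1]; b <- support_sizes[2]
  if (length(support_sizes) == 2L)
    return(phyper(intersection - 1, a, n - a, b, lower.tail = FALSE))
  cc <- support_sizes[3]
  if (n <= 500) {
    j <- max(0, a + b - n):min(a, b)
    pj <- dhyper(j, a, n - a, b)
    tail3 <- phyper(intersection - 1, j, n - j, cc, lower.tail = FALSE)
    return(sum(pj * tail3))
  }
  set.seed(seed)
  hits <- 0L
  for (s in seq_len(mc_samples)) {
    A <- sample.int(n, a); B <- sample.int(n, b); C <- sample.int(n, cc)
    if (length(intersect(intersect(A, B), C)) >= intersection)
      hits <- hits + 1L
  }
  hits / mc_samples
}

#' Miner parameters
#'
#' Defaults follow the analysis protocol: 10 random-restart runs of 30
#' alternations each, a 20-tree supplement forest, support bounds 30-155,
#' minimal Jaccard 0.5 and maximal p-value 0.01.  Support-bound presets per
#' view combination: (30, 155) for CSF element pairs, (30, 115) for plasma
#' pairs, (20, 110) for three-view mining.
#'
#' @param n_runs Random-restart runs.
#' @param n_iterations Alternations per run.
#' @param forest_size Bootstrap trees in the supplement forest (per view,
#'   applied once per run).
#' @param min_support,max_support Bounds on emitted support-set sizes.
#' @param min_jaccard Minimal Jaccard accuracy.
#' @param max_p Maximal significance p-value.
#' @param max_rule_length Maximal number of conditions per query.
#' @param initial_clusters k for the initial k-means patient clustering.
#' @param tree_max_depth Depth limit of the rule-inducing trees.
#' @param min_leaf Minimal patients per tree branch.
#' @param target_cap Most-recent rule supports used as tree targets.
#' @param max_pool Cap on stored candidate rules per view and run.
#' @param refine_cap Candidates refined per run.
#' @param seed Master seed; per-run streams are derived from it.
#' @return List of class `miner_params`.
#' @export
miner_params <- function(n_runs = 10L, n_iterations = 30L, forest_size = 20L,
                         min_support = 30L, max_support = 155L,
                         min_jaccard = 0.5, max_p = 0.01,
                         max_rule_length = 8L, initial_clusters = 8L,
                         tree_max_depth = 3L, min_leaf = 10L,
                         target_cap = 16L, max_pool = 300L,
                         refine_cap = 200L, seed = 1L) {
  p <- list(n_runs = as.integer(n_runs), n_iterations = as.integer(n_iterations),
            forest_size = as.integer(forest_size),
            min_support = as.integer(min_support),
            max_support = as.integer(max_support),
            min_jaccard = min_jaccard, max_p = max_p,
            max_rule_length = as.integer(max_rule_length),
            initial_clusters = as.integer(initial_clusters),
            tree_max_depth = as.integer(tree_max_depth),
            min_leaf = as.integer(min_leaf),
            target_cap = as.integer(target_cap),
            max_pool = as.integer(max_pool),
            refine_cap = as.integer(refine_cap), seed = as.integer(seed))
  stopifnot(p$min_support > 0, p$min_support <= p$max_support,
            p$min_jaccard > 0, p$min_jaccard <= 1,
            p$max_p > 0, p$max_p <= 1)
  class(p) <- "miner_params"
  p
}

#' Diagnosis-specificity label of a support set
#'
#' Per-diagnosis percentage = share of that diagnostic group inside the
#' support.  A single-group label requires that group's percentage to be at
#' least `dominance` times each other group's; an adjacent two-group label
#' (AD&MCI or HC&MCI) requires both groups to dominate the third the same
#' way; otherwise `"none"`.
#'
#' @param support Character vector of patient ids.
#' @param dataset A `cohort_dataset`.
#' @param dominance Dominance ratio, default 1.5.
#' @return List with `label` and `per_diagnosis_pct` (named HC/MCI/AD).
#' @export
label_specificity <- function(support, dataset, dominance = 1.5) {
  d <- dataset$data
  lev <- c("HC", "MCI", "AD")
  gi <- match(d$diagnosis, lev)
  tot <- tabulate(gi, 3L)
  ins <- tabulate(gi[d$patient_id %in% support], 3L)
  pct <- ifelse(tot > 0, 100 * ins / tot, 0)
  names(pct) <- lev
  if (!length(support))
    return(list(label = "none", per_diagnosis_pct = pct))
  ord <- order(pct, decreasing = TRUE)
  top <- names(pct)[ord]
  lbl <- "none"
  if (pct[ord[1]] >= dominance * pct[ord[2]] &&
      pct[ord[1]] >= dominance * pct[ord[3]]) {
    lbl <- top[1]
  } else if (pct[ord[1]] >= dominance * pct[ord[3]] &&
             pct[ord[2]] >= dominance * pct[ord[3]]) {
    pair <- sort(top[1:2])
    lbl <- if (identical(pair, c("AD", "MCI"))) "AD&MCI"
    else if (identical(pair, c("HC", "MCI"))) "HC&MCI"
    else "none"
  }
  list(label = lbl, per_diagnosis_pct = pct)
}

# support-closure tightening: rewrite each query's interval conditions as
# the bounding box of the redescription's support on that attribute (the
# tightest data-valued interval still containing every supported patient)
# and keep the rewrite when the Jaccard index strictly improves.  This is
# one "rule-from-support" step: it clips stray patients that the tree grid
# and the condition pool cannot separate.
.support_closure <- function(rd, view_dfs, ids, dataset, params,
                             dominance = 1.5) {
  repeat {
    sup_rows <- match(rd$support, ids)
    if (!length(sup_rows)) return(rd)
    queries <- rd$queries
    changed <- FALSE
    for (qi in seq_along(queries)) {
      q <- queries[[qi]]
      vdf <- view_dfs[[q$view]]
      for (ci in seq_along(q$conditions)) {
        cond <- q$conditions[[ci]]
        if (cond$kind != "interval") next
        v <- vdf[[cond$attribute]][sup_rows]
        lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
        if (is.finite(lo) && is.finite(hi) &&
            (lo > cond$low || hi < cond$high)) {
          q$conditions[[ci]] <- rd_condition(cond$attribute,
                                             low = lo, high = hi)
          changed <- TRUE
        }
      }
      queries[[qi]] <- q
    }
    if (!changed) return(rd)
    sups <- lapply(queries, function(q)
      evaluate_query_df(q, view_dfs[[q$view]]))
    cand <- .make_redescription(queries, sups, ids, dataset, dominance)
    if (cand$jaccard > rd$jaccard + 1e-12 &&
        cand$intersection_size >= params$min_support &&
        cand$intersection_size <= params$max_support) {
      rd <- cand
    } else {
      return(rd)
    }
  }
}

# assemble a redescription object from queries + logical supports
.make_redescription <- function(queries, sups, ids, dataset, dominance = 1.5) {
  inter <- Reduce(`&`, sups)
  uni <- Reduce(`|`, sups)
  isz <- sum(inter); usz <- sum(uni)
  lab <- label_specificity(ids[inter], dataset, dominance)
  structure(list(
    queries = queries, support = ids[inter],
    support_sizes = vapply(sups, sum, 0L),
    intersection_size = isz, union_size = usz,
    jaccard = if (usz == 0) 0 else isz / usz,
    p_value = NA_real_, p_method = NA_character_,
    per_diagnosis_pct = lab$per_diagnosis_pct,
    specificity_label = lab$label), class = "redescription")
}

#' @export
print.redescription <- function(x, ...) {
  cat(sprintf("Redescription [%s]  |support|=%d  JS=%.5f  p=%.3g\n",
              x$specificity_label, x$intersection_size, x$jaccard,
              x$p_value))
  for (q in x$queries)
    cat("  ", q$view, ": ", format(q), "\n", sep = "")
  cat(sprintf("  HC %.1f%%  MCI %.1f%%  AD %.1f%%\n",
              x$per_diagnosis_pct["HC"], x$per_diagnosis_pct["MCI"],
              x$per_diagnosis_pct["AD"]))
  invisible(x)
}

#' Greedy conjunctive refinement of a redescription
#'
#' Attempts to AND single conditions (drawn from discovered rules on the
#' same view) into one of the queries; a refinement is kept only when the
#' Jaccard index strictly increases and the redescription support stays at
#' or above `min_support`; stops when no improving condition exists or a
#' query reaches `max_rule_length` conditions.
#'
#' @param redescription A `redescription`.
#' @param cond_pool Per-view list: each element a list with `conditions`
#'   (list of `rd_condition`) and `sup` (logical support matrix, patients x
#'   conditions).
#' @param view_dfs Named list of view data.frames (rownames = patient ids).
#' @param dataset The cohort (for relabelling).
#' @param params A `miner_params`.
#' @return The (possibly improved) redescription.
#' @export
refine_conjunctive <- function(redescription, cond_pool, view_dfs, dataset,
                               params, sups = NULL) {
  ids <- rownames(view_dfs[[1]])
  if (is.null(sups))
    sups <- lapply(redescription$queries, function(q)
      evaluate_query_df(q, view_dfs[[q$view]]))
  queries <- redescription$queries
  repeat {
    best <- NULL
    cur_j <- {
      isz <- sum(Reduce(`&`, sups)); usz <- sum(Reduce(`|`, sups))
      if (usz == 0) 0 else isz / usz
    }
    for (qi in seq_along(queries)) {
      q <- queries[[qi]]
      if (length(q$conditions) >= params$max_rule_length) next
      pool <- cond_pool[[q$view]]
      if (is.null(pool) || !length(pool$conditions)) next
      others <- sups[-qi]
      o_inter <- if (length(others)) Reduce(`&`, others) else
        rep(TRUE, length(sups[[qi]]))
      o_union <- if (length(others)) Reduce(`|`, others) else
        rep(FALSE, length(sups[[qi]]))
      sq <- sups[[qi]]
      new_int <- as.vector(crossprod(pool$sup, as.numeric(sq & o_inter)))
      new_uni <- sum(o_union) +
        as.vector(crossprod(pool$sup, as.numeric(sq & !o_union)))
      new_j <- ifelse(new_uni == 0, 0, new_int / new_uni)
      ok <- new_int >= params$min_support & new_j > cur_j + 1e-12
      if (any(ok)) {
        ci <- which(ok)[which.max(new_j[ok])]
        if (is.null(best) || new_j[ci] > best$j) {
          best <- list(j = new_j[ci], qi = qi, ci = ci)
        }
      }
    }
    if (is.null(best)) break
    q <- queries[[best$qi]]
    add <- cond_pool[[q$view]]$conditions[[best$ci]]
    # intersect with an existing interval on the same attribute instead of
    # stacking duplicate conditions
    merged <- FALSE
    if (add$kind == "interval") {
      for (ci2 in seq_along(q$conditions)) {
        old <- q$conditions[[ci2]]
        if (old$kind == "interval" && old$attribute == add$attribute) {
          q$conditions[[ci2]] <- rd_condition(
            add$attribute, low = max(old$low, add$low),
            high = min(old$high, add$high))
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) q$conditions <- c(q$conditions, list(add))
    queries[[best$qi]] <- q
    sups[[best$qi]] <- sups[[best$qi]] &
      (cond_pool[[q$view]]$sup[, best$ci] > 0)
  }
  .make_redescription(queries, sups, ids, dataset)
}

#' Count redescriptions mentioning two attributes together
#'
#' @param redescriptions A `redescription_set` or list of redescriptions.
#' @param attr_a,attr_b Attribute names.
#' @return Number of redescriptions whose combined queries contain both.
#' @export
count_cooccurrence <- function(redescriptions, attr_a, attr_b) {
  rds <- if (inherits(redescriptions, "redescription_set"))
    redescriptions$redescriptions else redescriptions
  sum(vapply(rds, function(rd) {
    attrs <- unlist(lapply(rd$queries, function(q)
      vapply(q$conditions, `[[`, "", "attribute")))
    attr_a %in% attrs && attr_b %in% attrs
  }, TRUE))
}

#' Mine redescriptions across two or three views
#'
#' For each of `n_runs` seeded runs: an initial k-means clustering of the
#' first view seeds the targets; for `n_iterations` alternations, rules are
#' induced on each view with the latest rule supports of the next view
#' (round-robin) as tree targets; a bootstrap forest supplements each
#' view's rule pool; all cross-view query combinations are scored by
#' Jaccard, greedily refined, and filtered by support bounds, Jaccard and
#' the random-subset significance model.  Results are deduplicated across
#' runs by support set and attribute multiset (keeping the higher Jaccard,
#' then the shorter rule text) and sorted by p-value.
#'
#' @param dataset A `cohort_dataset`.
#' @param views Character vector of 2 or 3 distinct view ids; the first
#'   view is the biomarker view by convention.
#' @param params A [miner_params()].
#' @param clinical_in_first Attach the clinical query attributes (MMSE, age,
#'   APOE genotype) to the first view, as they appear in first-view rules.
#' @param dominance Dominance ratio for specificity labelling.
#' @return Object of class `redescription_set`.
#' @export
mine_redescriptions <- function(dataset,
                                views = c("csf_biomarkers", "csf_elements"),
                                params = miner_params(),
                                clinical_in_first = TRUE,
                                dominance = 1.5) {
  stopifnot(inherits(dataset, "cohort_dataset"),
            length(views) %in% c(2L, 3L), !anyDuplicated(views))
  nv <- length(views)
  view_dfs <- list()
  for (i in seq_along(views)) {
    extra <- if (i == 1L && clinical_in_first) c("mmse", "age", "apoe")
             else character()
    df <- view_data(dataset, views[i], extra = extra)
    if (views[i] == "csf_biomarkers")
      df <- df[, setdiff(colnames(df), "abeta_ratio"), drop = FALSE]
    attr(df, "view") <- views[i]
    view_dfs[[views[i]]] <- df
  }
  ids <- rownames(view_dfs[[1]])
  n <- length(ids)
  if (n < params$min_support) {
    warning("fewer patients (", n, ") than min_support (",
            params$min_support, "); empty result")
    return(.empty_rdset(views, params))
  }

  all_cands <- list()
  for (run in seq_len(params$n_runs)) {
    set.seed((params$seed + run * 1000003L) %% 2147483647L)
    ## (1) initial k-means clustering per view; the first view's partition
    ## seeds the first targets, and every view's partition stays among the
    ## targets of the views that describe it.  The first run clusters each
    ## full view; later runs cluster random attribute subspaces, so that
    ## subgroups distinctive in only a few attributes are not washed out by
    ## the Euclidean metric of the full standardized view -- this is what
    ## varies across the random-restart runs besides the RNG stream.
    memb_of <- lapply(view_dfs, function(v) {
      num <- v[, vapply(v, is.numeric, TRUE), drop = FALSE]
      if (run > 1L && ncol(num) > 3L) {
        take <- sort(sample.int(ncol(num), max(3L, ceiling(ncol(num) / 3))))
        num <- num[, take, drop = FALSE]
      }
      cc <- complete.cases(num)
      mm <- matrix(0, n, params$initial_clusters)
      if (sum(cc) > params$initial_clusters) {
        km <- kmeans(scale(as.matrix(num[cc, , drop = FALSE])),
                     centers = params$initial_clusters, nstart = 1L,
                     iter.max = 25L)
        mm[cbind(which(cc), km$cluster)] <- 1
      } else {
        mm[, 1] <- 1
      }
      mm
    })
    memb <- memb_of[[1]]
    latest_idx <- setNames(rep(list(integer()), nv), views)
    pools <- setNames(vector("list", nv), views)   # list of (query, sup)
    keys <- new.env(parent = emptyenv())
    matched <- list()                              # matching rule pairs

    add_to_pool <- function(view, qs) {
      idx <- rep(NA_integer_, length(qs))
      for (i in seq_along(qs)) {
        q <- qs[[i]]
        key <- paste(view, query_signature(q))
        if (exists(key, envir = keys, inherits = FALSE)) {
          idx[i] <- get(key, envir = keys)
          next
        }
        if (length(pools[[view]]) >= params$max_pool) next
        sup <- rownames(view_dfs[[view]]) %in% attr(q, "support")
        pos <- length(pools[[view]]) + 1L
        pools[[view]][[pos]] <<- list(query = q, sup = sup)
        assign(key, pos, envir = keys)
        idx[i] <- pos
      }
      idx
    }

    ## (2) alternations.  Rules induced on one view use the latest rule
    ## supports of the next view (round-robin) as tree targets; the partner
    ## view's initial clustering stays among the targets throughout, so one
    ## wayward tree cannot collapse the search onto a single structure.
    ## Each induced rule is paired with its best-matching target rule: these
    ## matching pairs are candidate redescriptions in their own right.
    for (it in seq_len(params$n_iterations)) {
      for (vi in seq_len(nv)) {
        nxt <- views[vi %% nv + 1L]
        rule_idx <- tail(latest_idx[[nxt]], params$target_cap)
        tgt <- memb_of[[nxt]]
        if (length(rule_idx))
          tgt <- cbind(tgt, vapply(pools[[nxt]][rule_idx], `[[`,
                                   logical(n), "sup"))
        qs <- induce_rules(view_dfs[[views[vi]]], tgt, params)
        if (length(qs)) {
          pidx <- add_to_pool(views[vi], qs)
          ok <- !is.na(pidx)
          latest_idx[[views[vi]]] <- pidx[ok]
          if (length(rule_idx) && any(ok)) {
            tsup <- vapply(pools[[nxt]][rule_idx], `[[`, logical(n), "sup")
            tsz <- colSums(tsup)
            for (qi in which(ok)) {
              s <- pools[[views[vi]]][[pidx[qi]]]$sup
              inter <- as.vector(crossprod(tsup, s))
              jj <- inter / (sum(s) + tsz - inter)
              bi <- which.max(jj)
              if (jj[bi] > 0)
                matched[[length(matched) + 1L]] <-
                  c(vi = vi, qi = pidx[qi], ni = vi %% nv + 1L,
                    pj = rule_idx[bi])
            }
          }
        }
      }
    }
    ## forest supplement, once per run: each bootstrap tree chases a single
    ## randomly chosen rule support of the partner view, which sharpens
    ## individual rules instead of averaging the split criterion over many
    ## targets
    if (params$forest_size > 0L) {
      for (vi in seq_len(nv)) {
        nxt <- views[vi %% nv + 1L]
        pool_n <- pools[[nxt]]
        for (b in seq_len(params$forest_size)) {
          tgt <- if (length(pool_n))
            matrix(as.numeric(pool_n[[sample.int(length(pool_n), 1L)]]$sup),
                   ncol = 1) else memb
          qs <- induce_rules(view_dfs[[views[vi]]], tgt, params, forest = 1L)
          if (length(qs)) add_to_pool(views[vi], qs)
        }
      }
    }

    ## (3) score all cross-view combinations
    if (any(vapply(pools, length, 0L) == 0L)) next
    S <- lapply(views, function(v)
      vapply(pools[[v]], `[[`, logical(n), "sup"))
    names(S) <- views
    cands <- .score_combinations(S, views, params)
    ord <- order(-cands$jaccard, cands$total_len)
    sel <- as.matrix(cands[head(ord, params$refine_cap), seq_len(nv),
                           drop = FALSE])
    if (nv == 2L && length(matched)) {
      mm <- do.call(rbind, matched)
      mp <- cbind(ifelse(mm[, "vi"] == 1L, mm[, "qi"], mm[, "pj"]),
                  ifelse(mm[, "vi"] == 1L, mm[, "pj"], mm[, "qi"]))
      mp <- unique(mp)
      sel <- unique(rbind(sel, head(mp, params$refine_cap)))
    }
    if (!nrow(sel)) next

    ## (4) conjunctive refinement of the most promising candidates
    cond_pool <- lapply(views, function(v)
      .condition_pool(pools[[v]], view_dfs[[v]]))
    names(cond_pool) <- views
    for (ri in seq_len(nrow(sel))) {
      qidx <- as.integer(sel[ri, ])
      queries <- lapply(seq_len(nv), function(vi)
        pools[[views[vi]]][[qidx[vi]]]$query)
      sups <- lapply(seq_len(nv), function(vi)
        pools[[views[vi]]][[qidx[vi]]]$sup)
      rd <- .make_redescription(queries, sups, ids, dataset, dominance)
      rd <- refine_conjunctive(rd, cond_pool, view_dfs, dataset, params,
                               sups = sups)
      rd <- .support_closure(rd, view_dfs, ids, dataset, params, dominance)
      ## (5) final filters
      if (rd$intersection_size < params$min_support ||
          rd$intersection_size > params$max_support) next
      if (rd$jaccard < params$min_jaccard) next
      rd$p_value <- redescription_pvalue(rd$support_sizes,
                                         rd$intersection_size, n,
                                         seed = params$seed)
      rd$p_method <- if (length(rd$support_sizes) == 2L) "hypergeometric"
                     else if (n <= 500) "exact-convolution" else "monte-carlo"
      if (rd$p_value > params$max_p) next
      all_cands[[length(all_cands) + 1L]] <- rd
    }
  }

  ## dedup across runs
  if (length(all_cands)) {
    key <- vapply(all_cands, function(rd) {
      attrs <- sort(unlist(lapply(rd$queries, function(q)
        vapply(q$conditions, `[[`, "", "attribute"))))
      paste(paste(sort(rd$support), collapse = ","),
            paste(attrs, collapse = "|"))
    }, "")
    txt <- vapply(all_cands, function(rd)
      paste(vapply(rd$queries, format, ""), collapse = " || "), "")
    nlen <- vapply(all_cands, function(rd)
      sum(vapply(rd$queries, function(q) length(q$conditions), 0L)), 0L)
    jac <- vapply(all_cands, `[[`, 0, "jaccard")
    ord <- order(key, -jac, nlen, txt)
    all_cands <- all_cands[ord[!duplicated(key[ord])]]
    pv <- vapply(all_cands, `[[`, 0, "p_value")
    txt <- vapply(all_cands, function(rd)
      paste(vapply(rd$queries, format, ""), collapse = " || "), "")
    all_cands <- all_cands[order(pv, -vapply(all_cands, `[[`, 0, "jaccard"),
                                 txt)]
  }
  structure(list(redescriptions = all_cands, views = views, params = params,
                 n_patients = n), class = "redescription_set")
}

.empty_rdset <- function(views, params)
  structure(list(redescriptions = list(), views = views, params = params,
                 n_patients = 0L), class = "redescription_set")

# cross-view scoring: returns a data.frame of index tuples with jaccard
.score_combinations <- function(S, views, params) {
  n <- nrow(S[[1]])
  empty <- as.data.frame(setNames(rep(list(numeric(0)), length(S) + 2L),
                                  c(paste0("q", seq_along(S)),
                                    "jaccard", "total_len")))
  sizes <- lapply(S, colSums)
  I12 <- crossprod(S[[1]], S[[2]])
  U12 <- outer(sizes[[1]], sizes[[2]], `+`) - I12
  J12 <- ifelse(U12 == 0, 0, I12 / U12)
  if (length(S) == 2L) {
    sel <- which(I12 >= params$min_support & I12 <= params$max_support &
                   J12 >= params$min_jaccard, arr.ind = TRUE)
    if (!nrow(sel)) return(empty)
    out <- data.frame(q1 = sel[, 1], q2 = sel[, 2],
                      jaccard = J12[sel])
    out$total_len <- 0L
    return(out)
  }
  # triples: Jaccard is monotone non-increasing when a view is added, so a
  # pair below threshold cannot yield a passing triple
  sel <- which(I12 >= params$min_support & J12 >= params$min_jaccard,
               arr.ind = TRUE)
  if (!nrow(sel)) return(empty)
  rows <- list()
  for (r in seq_len(nrow(sel))) {
    i <- sel[r, 1]; j <- sel[r, 2]
    s_and <- S[[1]][, i] & S[[2]][, j]
    s_or <- S[[1]][, i] | S[[2]][, j]
    i3 <- as.vector(crossprod(S[[3]], s_and))
    u3 <- sum(s_or) + as.vector(crossprod(S[[3]], !s_or))
    j3 <- ifelse(u3 == 0, 0, i3 / u3)
    ok <- which(i3 >= params$min_support & i3 <= params$max_support &
                  j3 >= params$min_jaccard)
    for (k in ok)
      rows[[length(rows) + 1L]] <- c(i, j, k, j3[k])
  }
  if (!length(rows)) return(empty)
  m <- do.call(rbind, rows)
  out <- data.frame(q1 = m[, 1], q2 = m[, 2], q3 = m[, 3], jaccard = m[, 4])
  out$total_len <- 0L
  out
}

# flatten a rule pool into a deduplicated single-condition pool with a
# patients x conditions support matrix
.condition_pool <- function(pool, view_df) {
  n <- nrow(view_df)
  conds <- list(); seen <- character()
  for (entry in pool) {
    for (cond in entry$query$conditions) {
      key <- .format_condition(cond)
      if (key %in% seen) next
      seen <- c(seen, key)
      conds[[length(conds) + 1L]] <- cond
    }
  }
  if (!length(conds))
    return(list(conditions = list(), sup = matrix(FALSE, n, 0)))
  sup <- vapply(conds, function(cond) {
    v <- view_df[[cond$attribute]]
    if (cond$kind == "categorical")
      !is.na(v) & as.character(v) == cond$level
    else
      !is.na(v) & v >= cond$low & v <= cond$high
  }, logical(n))
  storage.mode(sup) <- "double"
  list(conditions = conds, sup = sup)
}

#' @export
print.redescription_set <- function(x, ...) {
  cat("Redescription set over views:", paste(x$views, collapse = " + "), "\n")
  cat("  emitted:", length(x$redescriptions), "redescriptions (",
      x$n_patients, "patients )\n")
  if (length(x$redescriptions)) {
    cat("  best by p-value:\n")
    print(x$redescriptions[[1]])
  }
  invisible(x)
}

#' @export
summary.redescription_set <- function(object, ...) {
  as.data.frame(object)
}

#' Tabulate a redescription set
#'
#' One row per redescription, mirroring the reporting layout: specificity
#' label, per-diagnosis percentages, per-view rule texts, Jaccard and p.
#'
#' @param x A `redescription_set`.
#' @param ... Unused.
#' @return data.frame.
#' @export
as.data.frame.redescription_set <- function(x, ...) {
  rds <- x$redescriptions
  if (!length(rds)) {
    cols <- c("label", "HC_pct", "MCI_pct", "AD_pct",
              paste0("W", seq_along(x$views), "R"), "support", "JS", "p")
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  out <- data.frame(
    label = vapply(rds, `[[`, "", "specificity_label"),
    HC_pct = round(vapply(rds, function(r) r$per_diagnosis_pct[["HC"]], 0), 1),
    MCI_pct = round(vapply(rds, function(r) r$per_diagnosis_pct[["MCI"]], 0), 1),
    AD_pct = round(vapply(rds, function(r) r$per_diagnosis_pct[["AD"]], 0), 1),
    stringsAsFactors = FALSE)
  for (vi in seq_along(x$views))
    out[[paste0("W", vi, "R")]] <- vapply(rds, function(r)
      format(r$queries[[vi]]), "")
  out$support <- vapply(rds, `[[`, 0L, "intersection_size")
  out$JS <- round(vapply(rds, `[[`, 0, "jaccard"), 5)
  out$p <- vapply(rds, `[[`, 0, "p_value")
  out
}
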
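# Multi-target variance-reduction trees: the rule-generation engine of the
# redescription miner.
#
# A tree is grown on one view's attributes to predict a multi-column 0/1
# membership matrix (cluster memberships or the other view's rule supports),
# with the split criterion being the summed per-target sum-of-squares
# reduction -- the canonical predictive-clustering-tree choice.  Every
# root-to-node path of depth >= 1 becomes an AND-only conjunctive query;
# per-attribute constraints are intersected into closed intervals whose
# endpoints are snapped to attained data values, so reported intervals read
# like "Se (1.1-3.35)" rather than machine thresholds.

# Grow one tree and return the list of constraint paths.
# view_df: data.frame of the view's attributes (numeric + character/factor)
# targets: n x k numeric 0/1 matrix
# rows:    integer row indices used at the root (bootstrap sample for forests)
# mtry:    number of attributes sampled per split (NULL = all)
.grow_paths <- function(view_df, targets, rows, max_depth, min_leaf,
                        max_cuts = 24L, mtry = NULL) {
  num_cols <- names(view_df)[vapply(view_df, is.numeric, TRUE)]
  cat_cols <- setdiff(names(view_df), num_cols)
  Xnum <- if (length(num_cols))
    as.matrix(view_df[, num_cols, drop = FALSE]) else
      matrix(numeric(), nrow(view_df), 0)
  paths <- list()

  recurse <- function(rows, depth, constraints) {
    if (depth >= max_depth || length(rows) < 2L * min_leaf) return()
    attrs_num <- num_cols
    attrs_cat <- cat_cols
    if (!is.null(mtry)) {
      all_attrs <- c(num_cols, cat_cols)
      pick <- sample(all_attrs, min(mtry, length(all_attrs)))
      attrs_num <- intersect(num_cols, pick)
      attrs_cat <- intersect(cat_cols, pick)
    }
    best <- list(gain = 0)
    if (length(attrs_num)) {
      sp <- best_numeric_split(Xnum, targets, as.integer(rows - 1L),
                               as.integer(match(attrs_num, num_cols) - 1L),
                               as.integer(min_leaf), as.integer(max_cuts))
      if (sp$attr > 0)
        best <- list(gain = sp$gain, kind = "interval",
                     attr = num_cols[sp$attr], threshold = sp$threshold)
    }
    for (a in attrs_cat) {
      v <- as.character(view_df[[a]])[rows]
      ok <- !is.na(v)
      m <- sum(ok)
      if (m < 2L * min_leaf) next
      Ysub <- targets[rows[ok], , drop = FALSE]
      tot <- colSums(Ysub)
      base <- sum(tot^2) / m
      for (lv in unique(v[ok])) {
        inl <- v[ok] == lv
        nl <- sum(inl); nr <- m - nl
        if (nl < min_leaf || nr < min_leaf) next
        sl <- colSums(Ysub[inl, , drop = FALSE])
        gain <- sum(sl^2) / nl + sum((tot - sl)^2) / nr - base
        if (gain > best$gain + 1e-12)
          best <- list(gain = gain, kind = "categorical", attr = a,
                       level = lv)
      }
    }
    if (best$gain <= 0) return()
    if (best$kind == "interval") {
      vv <- Xnum[rows, best$attr]
      keep <- !is.na(vv)
      left <- rows[keep][vv[keep] <= best$threshold]
      right <- rows[keep][vv[keep] > best$threshold]
      cl <- c(constraints, list(list(attr = best$attr, op = "le",
                                     value = best$threshold)))
      cr <- c(constraints, list(list(attr = best$attr, op = "gt",
                                     value = best$threshold)))
      paths[[length(paths) + 1L]] <<- cl
      paths[[length(paths) + 1L]] <<- cr
      recurse(left, depth + 1L, cl)
      recurse(right, depth + 1L, cr)
    } else {
      v <- as.character(view_df[[best$attr]])[rows]
      keep <- !is.na(v)
      left <- rows[keep][v[keep] == best$level]
      right <- rows[keep][v[keep] != best$level]
      cl <- c(constraints, list(list(attr = best$attr, op = "eq",
                                     value = best$level)))
      cr <- c(constraints, list(list(attr = best$attr, op = "ne",
                                     value = best$level)))
      paths[[length(paths) + 1L]] <<- cl
      # complement branch not representable as a positive AND rule;
      # grown further but its own path is not harvested
      recurse(left, depth + 1L, cl)
      recurse(right, depth + 1L, cr)
    }
  }
  recurse(rows, 0L, list())
  paths
}

# Convert a constraint path into an AND-only query with closed intervals.
# Numeric bounds are snapped to attained values of the attribute (over the
# full data): lower bounds up to the smallest value above the threshold,
# upper bounds down to the largest value at or below it.  Paths containing a
# negated categorical constraint are not representable and yield NULL.
.path_to_query <- function(path, view_df, view) {
  lo_map <- list(); hi_map <- list(); eq_map <- list()
  for (cn in path) {
    if (cn$op == "ne") return(NULL)
    if (cn$op == "eq") { eq_map[[cn$attr]] <- cn$value; next }
    if (cn$op == "gt") {
      cur <- lo_map[[cn$attr]]
      lo_map[[cn$attr]] <- if (is.null(cur)) cn$value else max(cur, cn$value)
    } else {
      cur <- hi_map[[cn$attr]]
      hi_map[[cn$attr]] <- if (is.null(cur)) cn$value else min(cur, cn$value)
    }
  }
  conds <- vector("list", length(eq_map) +
                    length(unique(c(names(lo_map), names(hi_map)))))
  k <- 0L
  for (a in names(eq_map)) {
    k <- k + 1L
    conds[[k]] <- rd_condition(a, level = eq_map[[a]])
  }
  for (a in unique(c(names(lo_map), names(hi_map)))) {
    vals <- view_df[[a]]
    vals <- vals[!is.na(vals)]
    lo_thr <- lo_map[[a]] %||% -Inf
    hi_thr <- hi_map[[a]] %||% Inf
    lo_vals <- vals[vals > lo_thr]
    hi_vals <- vals[vals <= hi_thr]
    if (!length(lo_vals) || !length(hi_vals)) return(NULL)
    lo <- min(lo_vals); hi <- max(hi_vals)
    if (lo > hi) return(NULL)
    k <- k + 1L
    conds[[k]] <- rd_condition(a, low = lo, high = hi)
  }
  rd_query(view, conds[seq_len(k)])
}

#' Induce candidate queries on one view by multi-target trees
#'
#' Grows a depth-limited multi-target regression tree predicting the target
#' membership matrix from the view's attributes, plus (optionally) a
#' bootstrap forest with random attribute subsets, and harvests every
#' representable root-to-node path as an AND-only query.  Queries are
#' filtered by support bounds and rule length and deduplicated by their
#' support set and attribute multiset.
#'
#' @param view_df data.frame of the view's attributes, rownames = patient
#'   ids.
#' @param targets Numeric 0/1 matrix (patients x target sets).
#' @param params A [miner_params()].
#' @param forest Number of bootstrap trees to add (0 = main tree only).
#' @return List of `rd_query` objects, each carrying its support (patient
#'   ids) in attribute `"support"`.
#' @export
induce_rules <- function(view_df, targets, params, forest = 0L) {
  if (!ncol(view_df)) stop("empty view: no attributes to split on")
  targets <- as.matrix(targets)
  storage.mode(targets) <- "double"
  if (!nrow(targets) || !ncol(targets)) return(list())
  n <- nrow(view_df)
  all_rows <- seq_len(n)
  paths <- .grow_paths(view_df, targets, all_rows,
                       params$tree_max_depth, params$min_leaf)
  if (forest > 0L) {
    p_attrs <- ncol(view_df)
    mtry <- max(1L, ceiling(sqrt(p_attrs)))
    for (b in seq_len(forest)) {
      boot <- sample.int(n, n, replace = TRUE)
      paths <- c(paths, .grow_paths(view_df, targets, boot,
                                    params$tree_max_depth, params$min_leaf,
                                    mtry = mtry))
    }
  }
  out <- list(); seen <- new.env(parent = emptyenv())
  for (pth in paths) {
    if (length(pth) > params$max_rule_length) next
    q <- .path_to_query(pth, view_df, attr(view_df, "view") %||% "view")
    if (is.null(q)) next
    sup <- evaluate_query_df(q, view_df)
    ns <- sum(sup)
    if (ns < params$min_support || ns > params$max_support) next
    key <- query_signature(q)
    if (exists(key, envir = seen, inherits = FALSE)) next
    assign(key, TRUE, envir = seen)
    attr(q, "support") <- rownames(view_df)[sup]
    out[[length(out) + 1L]] <- q
  }
  out
}
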
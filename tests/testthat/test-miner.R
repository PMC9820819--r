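# ---- query evaluation ------------------------------------------------------

test_that("query evaluation uses closed endpoints and missing-excludes", {
  ds <- tiny_dataset(b1 = c(1, 2, 3, NA, 5, 2),
                     b2 = c(0, 1, 2, 3, 4, 5),
                     e1 = c(10, 20, 30, 40, 50, 60),
                     e2 = c(1, 1, 2, 2, 3, 3))
  # degenerate interval [v, v] includes the patient with exactly v
  q <- rd_query("csf_biomarkers", list(rd_condition("b1", low = 2, high = 2)))
  expect_setequal(evaluate_query(q, ds), c("T02", "T06"))
  # a missing measurement excludes the patient
  q2 <- rd_query("csf_biomarkers", list(rd_condition("b1", low = 0, high = 9)))
  expect_false("T04" %in% evaluate_query(q2, ds))
  # brute-force per-row oracle on a conjunctive query
  q3 <- rd_query("csf_biomarkers", list(rd_condition("b1", low = 1, high = 3),
                                        rd_condition("b2", low = 0, high = 5)))
  manual <- ds$data$patient_id[
    vapply(seq_len(6), function(i) {
      r <- ds$data[i, ]
      !is.na(r$b1) && !is.na(r$b2) &&
        r$b1 >= 1 && r$b1 <= 3 && r$b2 >= 0 && r$b2 <= 5
    }, TRUE)]
  expect_setequal(evaluate_query(q3, ds), manual)
  expect_error(evaluate_query(
    rd_query("csf_biomarkers", list(rd_condition("nope", low = 0, high = 1))),
    ds), "nope")
})

test_that("jaccard handles identity, disjoint sets and the 49/86 worked case", {
  expect_equal(jaccard_index(list(letters[1:5], letters[1:5]))$jaccard, 1.0)
  expect_equal(jaccard_index(list(letters[1:3], letters[4:6]))$jaccard, 0.0)
  expect_equal(jaccard_index(list(character(), character()))$jaccard, 0)
  j <- jaccard_index(list(as.character(1:49), as.character(c(1:49, 100:136))))
  expect_equal(j$intersection_size, 49)
  expect_equal(j$union_size, 86)
  expect_equal(round(j$jaccard, 5), 0.56977)
})

# ---- significance model ----------------------------------------------------

test_that("two-set significance equals enumeration on small universes", {
  expect_equal(redescription_pvalue(c(5, 5), 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(redescription_pvalue(c(4, 6), 0, 10), 1)
  for (n in c(6, 9)) {
    for (a in 1:n) for (b in 1:n) {
      prev <- Inf
      for (k in 0:min(a, b)) {
        p <- redescription_pvalue(c(a, b), k, n)
        expect_equal(p, enum_tail2(n, a, b, k), tolerance = 1e-12)
        expect_lte(p, prev + 1e-15)  # monotone nonincreasing in k
        prev <- p
      }
    }
  }
})

test_that("three-set significance equals enumeration at n = 12", {
  for (sz in list(c(6, 5, 4), c(7, 7, 7))) {
    dist <- enum_dist3(12, sz[1], sz[2], sz[3])
    for (k in 0:min(sz)) {
      tail_k <- sum(dist[(k + 1):length(dist)])
      expect_equal(redescription_pvalue(sz, k, 12), tail_k,
                   tolerance = 1e-12)
    }
  }
  expect_error(redescription_pvalue(c(3, 3, 3), 4, 12), "exceeds")
})

# ---- rule induction --------------------------------------------------------

test_that("a separable target is recovered by one threshold rule", {
  set.seed(71)
  n <- 80
  x <- c(runif(40, 0, 1), runif(40, 2, 3))
  df <- data.frame(xattr = x, noise = rnorm(n))
  rownames(df) <- sprintf("P%02d", 1:n)
  attr(df, "view") <- "v"
  target <- matrix(as.numeric(x > 1.5), n, 1)
  qs <- induce_rules(df, target, miner_params(min_support = 10,
                                              max_support = 70,
                                              min_leaf = 5))
  sup <- lapply(qs, attr, "support")
  expect_true(any(vapply(sup, function(s)
    setequal(s, rownames(df)[x > 1.5]), TRUE)))
})

test_that("constant attributes admit no splits", {
  df <- data.frame(a = rep(1, 40), b = rep(2.5, 40))
  rownames(df) <- sprintf("P%02d", 1:40)
  attr(df, "view") <- "v"
  target <- matrix(rep(c(0, 1), 20), 40, 1)
  expect_length(induce_rules(df, target, miner_params(min_support = 5,
                                                      max_support = 40,
                                                      min_leaf = 5)), 0)
})

test_that("interval snapping preserves the raw path support", {
  set.seed(72)
  n <- 120
  df <- data.frame(x = rnorm(n), y = rnorm(n), z = rnorm(n))
  rownames(df) <- sprintf("P%03d", 1:n)
  attr(df, "view") <- "v"
  target <- matrix(as.numeric(df$x > 0.2 & df$x < 1.4 & df$y > 0), n, 1)
  qs <- induce_rules(df, target, miner_params(min_support = 5,
                                              max_support = 115,
                                              min_leaf = 5,
                                              tree_max_depth = 4))
  expect_gt(length(qs), 0)
  for (q in qs) {
    # support of the closed snapped interval must equal direct evaluation
    expect_setequal(attr(q, "support"),
                    rownames(df)[evaluate_query_df(q, df)])
    # closed bounds are attained data values
    for (cond in q$conditions)
      if (cond$kind == "interval") {
        expect_true(cond$low %in% df[[cond$attribute]])
        expect_true(cond$high %in% df[[cond$attribute]])
      }
  }
})

# ---- support anti-monotonicity (property) ----------------------------------

test_that("adding a condition never grows a query's support", {
  ds <- generate_cohort(cohort_config(seed = 88))
  set.seed(89)
  views <- c("csf_biomarkers", "csf_elements", "plasma_elements")
  n_checks <- 0L
  while (n_checks < 200L) {
    vw <- sample(views, 1)
    attrs <- sample(setdiff(ds$views[[vw]], "abeta_ratio"), 2)
    v1 <- ds$data[[attrs[1]]]; v2 <- ds$data[[attrs[2]]]
    if (all(is.na(v1)) || all(is.na(v2))) next
    r1 <- range(v1, na.rm = TRUE); r2 <- range(v2, na.rm = TRUE)
    lo1 <- runif(1, r1[1], r1[2]); hi1 <- runif(1, lo1, r1[2])
    lo2 <- runif(1, r2[1], r2[2]); hi2 <- runif(1, lo2, r2[2])
    q <- rd_query(vw, list(rd_condition(attrs[1], low = lo1, high = hi1)))
    qe <- rd_query(vw, list(rd_condition(attrs[1], low = lo1, high = hi1),
                            rd_condition(attrs[2], low = lo2, high = hi2)))
    expect_true(all(evaluate_query(qe, ds) %in% evaluate_query(q, ds)))
    n_checks <- n_checks + 1L
  }
})

# ---- refinement ------------------------------------------------------------

test_that("refinement is a fixed point without improving conditions and improves with one", {
  ds <- tiny_dataset(b1 = c(1, 1, 1, 5, 5, 1, 1, 1),
                     b2 = c(1, 2, 3, 9, 9, 9, 9, 4),
                     e1 = c(2, 2, 2, 2, 2, 9, 9, 2),
                     e2 = c(1, 2, 1, 2, 1, 2, 1, 2))
  view_dfs <- list(
    csf_biomarkers = structure(
      data.frame(b1 = ds$data$b1, b2 = ds$data$b2,
                 row.names = ds$data$patient_id), view = "csf_biomarkers"),
    csf_elements = structure(
      data.frame(e1 = ds$data$e1, e2 = ds$data$e2,
                 row.names = ds$data$patient_id), view = "csf_elements"))
  # b1 in [0,2] -> {1,2,3,6,7,8}; e1 in [0,3] -> {1,2,3,4,5,8}
  q1 <- rd_query("csf_biomarkers", list(rd_condition("b1", low = 0, high = 2)))
  q2 <- rd_query("csf_elements", list(rd_condition("e1", low = 0, high = 3)))
  p <- miner_params(min_support = 2, max_support = 8)
  rd <- csfmetals:::.make_redescription(
    list(q1, q2),
    list(evaluate_query_df(q1, view_dfs[[1]]),
         evaluate_query_df(q2, view_dfs[[2]])),
    ds$data$patient_id, ds)
  # empty pools: unchanged
  empty_pool <- list(csf_biomarkers = list(conditions = list(),
                                           sup = matrix(0, 8, 0)),
                     csf_elements = list(conditions = list(),
                                         sup = matrix(0, 8, 0)))
  rd0 <- refine_conjunctive(rd, empty_pool, view_dfs, ds, p)
  expect_equal(rd0$jaccard, rd$jaccard)
  expect_equal(length(rd0$queries[[1]]$conditions), 1)
  # a condition that removes only union-side patients strictly improves J:
  # b2 <= 4 drops patients 6 and 7 from query 1's side while keeping the
  # whole intersection {1,2,3,8}
  cnd <- rd_condition("b2", low = 1, high = 4)
  pool <- empty_pool
  pool$csf_biomarkers <- list(
    conditions = list(cnd),
    sup = matrix(as.numeric(evaluate_query_df(
      rd_query("csf_biomarkers", list(cnd)), view_dfs[[1]])), ncol = 1))
  rd1 <- refine_conjunctive(rd, pool, view_dfs, ds, p)
  expect_gt(rd1$jaccard, rd$jaccard)
  expect_gte(rd1$intersection_size, p$min_support)
})

# ---- labelling and co-occurrence -------------------------------------------

test_that("specificity labelling reproduces the documented patterns", {
  # 193-patient layout: 19 HC, 50 MCI, 124 AD
  ds <- generate_cohort(cohort_config(seed = 13))
  d <- ds$data
  pick <- function(k_hc, k_mci, k_ad)
    c(head(d$patient_id[d$diagnosis == "HC"], k_hc),
      head(d$patient_id[d$diagnosis == "MCI"], k_mci),
      head(d$patient_id[d$diagnosis == "AD"], k_ad))
  # (5.3%, 6%, 36%) of (19, 50, 124): single-group AD dominance
  l1 <- label_specificity(pick(1, 3, 45), ds)
  expect_equal(l1$label, "AD")
  expect_equal(unname(round(l1$per_diagnosis_pct["HC"], 1)), 5.3)
  # (42.1%, 50%, 18.5%): HC&MCI
  l2 <- label_specificity(pick(8, 25, 23), ds)
  expect_equal(l2$label, "HC&MCI")
  # equal percentages in all groups: none
  l3 <- label_specificity(pick(19, 50, 124), ds)
  expect_equal(l3$label, "none")
  expect_equal(label_specificity(character(), ds)$label, "none")
})

test_that("co-occurrence counting matches a brute-force scan", {
  expect_equal(count_cooccurrence(list(), "vilip1", "csf_Se"), 0)
  q1 <- rd_query("csf_biomarkers", list(rd_condition("vilip1", low = 1, high = 2)))
  q2 <- rd_query("csf_elements", list(rd_condition("csf_Se", low = 1, high = 2)))
  rd <- structure(list(queries = list(q1, q2)), class = "redescription")
  expect_equal(count_cooccurrence(list(rd), "vilip1", "csf_Se"), 1)
  expect_equal(count_cooccurrence(list(rd), "vilip1", "csf_Cu"), 0)
})

# ---- end-to-end mining -----------------------------------------------------

test_that("a zero-leak plant is found with Jaccard 1 and exact support", {
  plant <- standard_plants(leak = 0)[[1]]
  ds <- generate_cohort(cohort_config(seed = 15,
                                      planted_redescriptions = list(plant),
                                      missingness = no_missingness()))
  rset <- mine_redescriptions(
    ds, params = miner_params(n_runs = 2, n_iterations = 8, seed = 4))
  tr <- ds$planted[[1]]$members
  perfect <- Filter(function(rd)
    rd$jaccard == 1 && setequal(rd$support, tr), rset$redescriptions)
  expect_gt(length(perfect), 0)
})

test_that("mining is deterministic for a fixed seed", {
  plant <- standard_plants()[[1]]
  ds <- generate_cohort(cohort_config(seed = 16,
                                      planted_redescriptions = list(plant)))
  p <- miner_params(n_runs = 2, n_iterations = 5, seed = 4)
  a <- mine_redescriptions(ds, params = p)
  b <- mine_redescriptions(ds, params = p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(lapply(a$redescriptions, `[[`, "support"),
                   lapply(b$redescriptions, `[[`, "support"))
})

test_that("every emitted redescription satisfies all three filters", {
  plant <- standard_plants()[[2]]
  ds <- generate_cohort(cohort_config(seed = 17,
                                      planted_redescriptions = list(plant)))
  p <- miner_params(n_runs = 3, n_iterations = 10, seed = 6)
  rset <- mine_redescriptions(ds, params = p)
  expect_gt(length(rset$redescriptions), 0)
  for (rd in rset$redescriptions) {
    expect_gte(rd$intersection_size, p$min_support)
    expect_lte(rd$intersection_size, p$max_support)
    expect_gte(rd$jaccard, p$min_jaccard)
    expect_lte(rd$p_value, p$max_p)
    # stored support/jaccard are consistent with re-evaluating the queries
    sups <- lapply(rd$queries, function(q) evaluate_query(q, ds))
    expect_setequal(rd$support, Reduce(intersect, sups))
    expect_equal(rd$jaccard, jaccard_index(sups)$jaccard)
  }
})

test_that("tiny instances are mined at least as well as exhaustive single-condition search", {
  set.seed(91)
  b1 <- c(1, 1, 2, 2, 3, 3, 8, 8, 9, 9, 10, 10)
  e1 <- c(5, 5, 6, 6, 7, 7, 1, 1, 2, 2, 3, 3)
  ds <- tiny_dataset(b1 = b1, b2 = rnorm(12), e1 = e1, e2 = rnorm(12))
  p <- miner_params(n_runs = 3, n_iterations = 6, min_support = 2,
                    max_support = 12, min_jaccard = 0.01, max_p = 1,
                    min_leaf = 2, initial_clusters = 3, seed = 9)
  rset <- mine_redescriptions(ds, views = c("csf_biomarkers", "csf_elements"),
                              params = p, clinical_in_first = FALSE)
  # exhaustive search over single-interval-per-view redescriptions on the
  # attained value grids
  best <- 0
  for (lo1 in unique(b1)) for (hi1 in unique(b1)) for (lo2 in unique(e1))
    for (hi2 in unique(e1)) {
      if (lo1 > hi1 || lo2 > hi2) next
      s1 <- ds$data$patient_id[b1 >= lo1 & b1 <= hi1]
      s2 <- ds$data$patient_id[e1 >= lo2 & e1 <= hi2]
      if (length(s1) < 2 || length(s2) < 2) next
      best <- max(best, jaccard_index(list(s1, s2))$jaccard)
    }
  got <- max(vapply(rset$redescriptions, `[[`, 0, "jaccard"), 0)
  expect_gte(got, best)
})
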
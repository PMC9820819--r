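# Shared fixtures: small cohorts and planted-structure configurations built
# in code at test time.

# the three standard planted cross-view subgroups used for recovery checks:
# supports 40-60 patients, two conditions per side, leak 5% per side
standard_plants <- function(leak = 0.05) {
  list(
    planted_redescription(0.26, list(
      list(view = "csf_biomarkers", attribute = "vilip1", low = 150, high = 400),
      list(view = "csf_biomarkers", attribute = "mmse", low = 10, high = 23),
      list(view = "csf_elements", attribute = "csf_Se", low = 1.8, high = 4.2),
      list(view = "csf_elements", attribute = "csf_S", low = 19, high = 45)),
      leak_fraction = leak),
    planted_redescription(0.21, list(
      list(view = "csf_biomarkers", attribute = "abeta42", low = 150, high = 300),
      list(view = "csf_biomarkers", attribute = "age", low = 78, high = 91),
      list(view = "csf_elements", attribute = "csf_B", low = 28, high = 70),
      list(view = "csf_elements", attribute = "csf_Li", low = 4, high = 20)),
      leak_fraction = leak),
    planted_redescription(0.31, list(
      list(view = "csf_biomarkers", attribute = "ptau231", low = 9, high = 60),
      list(view = "csf_biomarkers", attribute = "ptau199", low = 6, high = 40),
      list(view = "csf_elements", attribute = "csf_Cu", low = 21, high = 37),
      list(view = "csf_elements", attribute = "csf_Fe", low = 55, high = 120)),
      leak_fraction = leak)
  )
}

# the true per-view queries of a planted redescription
plant_queries <- function(plant) {
  sides <- split(plant$conditions,
                 vapply(plant$conditions, `[[`, "", "view"))
  lapply(names(sides), function(vw)
    rd_query(vw, lapply(sides[[vw]], function(cn)
      rd_condition(cn$attribute, low = cn$low, high = cn$high))))
}

# zero out every default missingness fraction
no_missingness <- function()
  c(ykl40 = 0, s100b = 0, nfl = 0, albumin = 0, pappa = 0,
    csf_P = 0, csf_Ni = 0, duration = 0)

# a minimal hand-built two-view dataset for miner unit tests
tiny_dataset <- function(b1, b2, e1, e2, diagnosis = NULL) {
  n <- length(b1)
  if (is.null(diagnosis))
    diagnosis <- rep(c("AD", "MCI", "HC"), length.out = n)
  d <- data.frame(patient_id = sprintf("T%02d", seq_len(n)),
                  diagnosis = diagnosis, b1 = b1, b2 = b2, e1 = e1, e2 = e2,
                  stringsAsFactors = FALSE)
  structure(list(data = d,
                 views = list(clinical = "diagnosis",
                              csf_biomarkers = c("b1", "b2"),
                              csf_elements = c("e1", "e2")),
                 config = NULL, planted = list(), plasma_subset = character()),
            class = "cohort_dataset")
}

# ---- independent enumeration oracles for the significance model ----------
# bitmask enumeration of the intersection distribution of uniform random
# subsets; fixing the first set at {1..a} is exact by exchangeability

popcount <- function(v) {
  n <- integer(length(v))
  while (any(v > 0)) { n <- n + (v %% 2L); v <- v %/% 2L }
  n
}

enum_tail2 <- function(n, a, b, k) {
  masks <- 0:(2^n - 1)
  pc <- popcount(masks)
  maskA <- 2^a - 1
  inter <- popcount(bitwAnd(masks[pc == b], maskA))
  mean(inter >= k)
}

# distribution of |A ∩ B ∩ C| over all (B, C) pairs with A fixed
enum_dist3 <- function(n, a, b, cc) {
  masks <- 0:(2^n - 1)
  pc <- popcount(masks)
  maskA <- 2^a - 1
  Bs <- masks[pc == b]; Cs <- masks[pc == cc]
  counts <- numeric(min(a, b, cc) + 1)
  for (bm in Bs) {
    ab <- bitwAnd(bm, maskA)
    tb <- tabulate(popcount(bitwAnd(Cs, ab)) + 1L, nbins = length(counts))
    counts <- counts + tb
  }
  counts / (length(Bs) * length(Cs))
}

# jaccard of an emitted redescription's support against a reference set
support_jaccard <- function(rd, reference)
  jaccard_index(list(rd$support, reference))$jaccard

best_recovery <- function(rset, reference) {
  if (!length(rset$redescriptions)) return(0)
  max(vapply(rset$redescriptions, support_jaccard, 0, reference = reference))
}
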
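# brute-force reference for the running-sum statistic, kept deliberately
# independent of the package implementation
des_brute <- function(S, L) {
  ns <- nrow(L)
  hit <- L$key %in% S
  nm <- sum(hit)
  if (nm == 0) return(0)
  if (nm == ns) return(1)
  running <- numeric(ns)
  acc <- 0
  denom <- sum(1 - L$p_value[hit])
  for (i in seq_len(ns)) {
    acc <- acc + if (hit[i]) (1 - L$p_value[i]) / denom else -1 / abs(ns - nm)
    running[i] <- acc
  }
  max(running)
}

mk_list <- function(keys, p) tibble::tibble(key = keys, p_value = p)

test_that("DES matches hand-worked examples and edge rules", {
  # two near-certain expected entries, first one predicted: running stat hits 1
  L <- mk_list(c("lr1", "lr2"), c(1e-6, 1e-6))
  expect_equal(des_for_pair("lr1", L), 1, tolerance = 1e-5)
  # disjoint prediction: no matched mass
  expect_equal(des_for_pair(c("x", "y"), L), 0)
  # superset prediction: no unmatched penalty exists
  expect_equal(des_for_pair(c("lr1", "lr2", "z"), L), 1)
})

test_that("DES equals a brute-force running-sum on random instances and stays in [0,1]", {
  set.seed(8)
  for (i in 1:300) {
    ns <- sample(2:20, 1)
    L <- mk_list(sprintf("lr%02d", sample(100, ns)), runif(ns, 0.001, 1))
    S <- sample(sprintf("lr%02d", 1:100), sample(0:25, 1))
    got <- des_for_pair(S, L)
    expect_equal(got, des_brute(S, L))
    expect_gte(got, 0)
    expect_lte(got, 1)
    # a set is a set: order and duplication of S are irrelevant
    expect_equal(des_for_pair(rev(c(S, S)), L), got)
  }
})

test_that("adding the top-ranked interaction never decreases the DES", {
  set.seed(9)
  for (i in 1:50) {
    ns <- sample(3:15, 1)
    L <- mk_list(sprintf("lr%02d", 1:ns), runif(ns, 0.001, 0.9))
    S <- sample(L$key, sample(0:(ns - 1), 1))
    expect_gte(des_for_pair(union(S, L$key[1]), L), des_for_pair(S, L))
  }
})

test_that("expected lists follow the documented sort with tie-breaks", {
  tend <- tibble::tibble(
    interaction_name = c("a", "b", "c", "d", "e", "f"),
    ligand = paste0("L", 1:6), receptor = paste0("R", 1:6),
    d_ratio = c(0.2, 0.5, 0.5, 3.0, 2.0, 1.0),
    p_left = c(0.002, 0.004, 0.003, 0.9, 0.8, 0.5),
    p_right = c(0.99, 0.99, 0.99, 0.005, 0.002, 0.5),
    range_class = c("short", "short", "short", "long", "long", "medium")
  )
  lists <- build_expected_lists(tend)
  # ascending d_ratio; tie between b and c broken by p_left
  expect_equal(lists$short$interaction_name, c("a", "c", "b"))
  expect_equal(lists$short$p_value, c(0.002, 0.003, 0.004))
  # descending d_ratio for the long side
  expect_equal(lists$long$interaction_name, c("d", "e"))
  expect_equal(lists$long$p_value, c(0.005, 0.002))
  # independent oracle: re-sort with base order()
  o <- order(tend$d_ratio[1:3], tend$p_left[1:3], tend$interaction_name[1:3])
  expect_equal(lists$short$interaction_name, tend$interaction_name[1:3][o])
})

test_that("tool scoring pools both directions per pair and averages over scored pairs", {
  tend <- tibble::tibble(
    interaction_name = c("s1", "s2", "l1"),
    ligand = c("LA", "LB", "LC"), receptor = c("RA", "RB", "RC"),
    d_ratio = c(0.2, 0.3, 4), p_left = c(0.002, 0.003, 0.9),
    p_right = c(0.9, 0.9, 0.004), range_class = c("short", "short", "long")
  )
  lists <- build_expected_lists(tend)
  pairs <- structure(
    tibble::tibble(
      type_a = c("T1", "T1", "T2"), type_b = c("T2", "T3", "T3"),
      distance = c(1, 50, 100), pair_class = c("near", "medium", "far")
    ),
    class = c("cci_pairs", "tbl_df", "tbl", "data.frame")
  )
  # predictions come in the reverse direction; pooling must still match
  pred <- pred_table("toolX", list(
    c("T2", "T1", "LA", "RA"), c("T1", "T2", "LB", "RB"),
    c("T3", "T2", "LC", "RC")
  ))
  res <- tool_des(pred, pairs, lists)
  expect_equal(nrow(res), 2) # medium pair skipped
  expect_equal(res$des, c(1, 1)) # full coverage on both sides
  expect_equal(attr(res, "mean_des"), 1)
  # an empty table scores zero everywhere, with a warning
  expect_warning(res0 <- tool_des(pred_table("empty", list()), pairs, lists), "empty")
  expect_equal(attr(res0, "mean_des"), 0)
})

test_that("tool ranking uses average ranks for ties and reproduces rank averaging", {
  tab <- tibble::tibble(tool = c("a", "b", "c"), mean_des = c(0.9, 0.5, 0.1))
  expect_equal(rank_tools(tab)$rank, c(1, 2, 3))
  tab2 <- tibble::tibble(tool = c("a", "b", "c"), mean_des = c(0.7, 0.7, 0.1))
  expect_equal(sort(rank_tools(tab2)$rank), c(1.5, 1.5, 3))
  # cross-dataset averaging arithmetic: ranks {2,4,1,4,1} average 2.4
  expect_equal(mean(c(2, 4, 1, 4, 1)), 2.4)
})
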
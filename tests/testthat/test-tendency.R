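test_that("tendency statistics follow the add-one permutation estimator", {
  s <- tendency_statistics(5, rep(5, 100))
  expect_equal(s$d_ratio, 1)
  expect_equal(tendency_statistics(10, rep(5, 100))$d_ratio, 2)
  # observed below every one of 1000 null draws
  s2 <- tendency_statistics(0.1, runif(1000, 1, 2))
  expect_equal(s2$p_left, 1 / 1001)
  expect_equal(s2$p_right, 1)
  expect_error(tendency_statistics(1, numeric(0)), "empty")
  expect_error(tendency_statistics(1, rep(0, 10)), "degenerate")
})

test_that("permutation null is seed-reproducible and degenerates on a single-point slide", {
  v <- rbind(A = c(3, 1, 0, 2), B = c(0, 2, 2, 1))
  st <- toy_slide(v, nx = 2, ny = 2)
  s1 <- permutation_null(st, "A", "B", n_perm = 5, seed = 11)
  s2 <- permutation_null(st, "A", "B", n_perm = 5, seed = 11)
  expect_identical(s1, s2)
  expect_length(s1, 5)
  # all spots at one coordinate: every permuted distance is zero
  stz <- spatial_expression(
    matrix(c(1, 2, 2, 1), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2"))),
    data.frame(spot_id = c("s1", "s2"), x = c(1, 1), y = c(1, 1))
  )
  expect_equal(permutation_null(stz, "A", "B", n_perm = 4, seed = 1), rep(0, 4))
  expect_error(permutation_null(st, "A", "B", n_perm = 0), "n_perm")
})

test_that("sampled permutation null matches exhaustive enumeration on a 4-spot slide", {
  v <- rbind(A = c(4, 1, 0, 0), B = c(0, 0, 3, 2))
  st <- toy_slide(v, nx = 2, ny = 2)
  stn <- apply_transform(st, "none")
  # enumerate all 4! x 4! coordinate assignments of the two genes
  xs <- st$coords$x
  ys <- st$coords$y
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  li <- which(v["A", ] > 0)
  ri <- which(v["B", ] > 0)
  lw <- v["A", li] / sum(v["A", li])
  rw <- v["B", ri] / sum(v["B", ri])
  all_vals <- c()
  for (i in seq_len(nrow(perms))) {
    for (j in seq_len(nrow(perms))) {
      pl <- perms[i, ]
      pr <- perms[j, ]
      all_vals <- c(all_vals, wasserstein_lr(
        tibble::tibble(x = xs[pl[li]], y = ys[pl[li]], weight = lw),
        tibble::tibble(x = xs[pr[ri]], y = ys[pr[ri]], weight = rw),
        reg = 0.005
      ))
    }
  }
  sims <- permutation_null(st, "A", "B", n_perm = 400, reg = 0.005, seed = 3)
  expect_equal(mean(sims), mean(all_vals), tolerance = 0.05)
  expect_lt(
    suppressWarnings(ks.test(sims, function(q) ecdf(all_vals)(q))$statistic),
    0.12
  )
})

test_that("range classification intersects top-fraction sets and respects alpha", {
  set.seed(12)
  n <- 100
  tend <- tibble::tibble(
    interaction_name = sprintf("i%03d", 1:n),
    ligand = sprintf("L%03d", 1:n), receptor = sprintf("R%03d", 1:n),
    d_ratio = rnorm(n, 1, 0.05),
    p_left = runif(n, 0.2, 1), p_right = runif(n, 0.2, 1)
  )
  # plant clear extremes
  tend$d_ratio[1:3] <- c(0.1, 0.15, 0.2)
  tend$p_left[1:3] <- 0.001
  tend$d_ratio[4:6] <- c(3, 2.9, 2.8)
  tend$p_right[4:6] <- 0.001
  out <- classify_ranges(tend, top_fraction = 0.10, alpha = 0.01)
  expect_setequal(out$interaction_name[out$range_class == "short"], sprintf("i%03d", 1:3))
  expect_setequal(out$interaction_name[out$range_class == "long"], sprintf("i%03d", 4:6))
  # candidate sets are capped at floor(top_fraction * n) before significance
  expect_lte(sum(out$range_class == "short"), 10)
  expect_lte(sum(out$range_class == "long"), 10)
  # every interaction gets exactly one class
  expect_equal(sum(table(out$range_class)), n)
  # no significance, no calls
  tend2 <- dplyr::mutate(tend, p_left = pmax(p_left, 0.02), p_right = pmax(p_right, 0.02))
  out2 <- classify_ranges(tend2)
  expect_equal(unique(out2$range_class), "medium")
  # composite strategy also recovers the planted extremes here
  out3 <- classify_ranges(tend, strategy = "composite")
  expect_true(all(out3$range_class[1:3] == "short"))
})

test_that("planted extreme interactions are recovered exactly from a slide", {
  fix <- planted_tendency_slide(n_background = 16)
  tend <- lr_spatial_tendency(fix$st, fix$db,
    n_perm = 199, reg = 0.01,
    min_spot_fraction = 0.05, seed = 21
  )
  expect_equal(nrow(tend), 20)
  out <- classify_ranges(tend, top_fraction = 0.10, alpha = 0.01)
  expect_setequal(out$interaction_name[out$range_class == "short"], fix$planted_short)
  expect_setequal(out$interaction_name[out$range_class == "long"], fix$planted_long)
  # short plants sit near zero distance, long plants well above the null
  expect_lt(max(out$d_ratio[out$range_class == "short"]), 0.2)
  expect_gt(min(out$d_ratio[out$range_class == "long"]), 1.5)
})

test_that("tendency table is reproducible under a seed and carries the schema", {
  fix <- planted_tendency_slide(n_background = 2)
  t1 <- lr_spatial_tendency(fix$st, fix$db, n_perm = 25, reg = 0.01,
    min_spot_fraction = 0.05, seed = 5)
  t2 <- lr_spatial_tendency(fix$st, fix$db, n_perm = 25, reg = 0.01,
    min_spot_fraction = 0.05, seed = 5)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_true(all(c(
    "interaction_name", "ligand", "receptor", "d_real", "d_sim_mean",
    "d_ratio", "p_left", "p_right", "n_perm"
  ) %in% names(t1)))
  expect_true(all(t1$p_left > 0 & t1$p_left <= 1))
  expect_true(all(t1$p_right > 0 & t1$p_right <= 1))
  expect_true(all(t1$d_real >= 0))
})
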
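# one scaled-down simulation shared across the blocks below
tpl <- test_template()
db <- test_db(tpl)
cfg <- test_sim_config()
mapped <- suppressWarnings(select_celltypes_and_map(tpl, cfg))
planted <- plant_interactions(mapped, db, cfg)
sim <- suppressMessages(consistency_filter(planted, db, cfg))

test_that("the tissue template yields near and far pairs and honest markers", {
  pairs <- classify_pairs(
    celltype_pair_distances(tpl$spot_annotation, tpl$st$coords),
    seed = 1
  )
  expect_gte(sum(pairs$pair_class == "near"), 1)
  expect_gte(sum(pairs$pair_class == "far"), 1)
  # same seed, bit-identical template
  tpl2 <- test_template()
  expect_identical(as.matrix(tpl$sc_counts), as.matrix(tpl2$sc_counts))
  expect_identical(as.matrix(tpl$st$values), as.matrix(tpl2$st$values))
  # marker genes separate their own type by roughly the configured fold
  mk <- names(which(tpl$type_means[, "type01"] > 4 * tpl$type_means[, "type02"]))[1]
  cells1 <- tpl$cell_annotation$cell_id[tpl$cell_annotation$cell_type == "type01"]
  cells2 <- tpl$cell_annotation$cell_id[tpl$cell_annotation$cell_type == "type02"]
  m1 <- mean(tpl$sc_counts[mk, cells1])
  m2 <- mean(tpl$sc_counts[mk, cells2])
  expect_gt(m1, 3 * max(m2, 0.05))
  expect_error(make_fixture(n_types = 3), "at least 4")
})

test_that("cell-to-spot mapping respects types, counts and the 2-5 range", {
  n_spots <- ncol(mapped$st$values)
  expect_gte(nrow(mapped$mapping), cfg$cells_per_spot[1] * n_spots)
  expect_lte(nrow(mapped$mapping), cfg$cells_per_spot[2] * n_spots)
  # each spot receives only cells of its annotated type
  m <- dplyr::inner_join(mapped$mapping, mapped$spot_annotation,
    by = "spot_id", suffix = c("_cell", "_spot"))
  expect_true(all(m$cell_type_cell == m$cell_type_spot))
  # spot expression is exactly the sum of its mapped cells
  s1 <- mapped$spot_annotation$spot_id[5]
  cells <- mapped$mapping$cell_id[mapped$mapping$spot_id == s1]
  expect_equal(
    as.numeric(mapped$st$values[, s1]),
    as.numeric(Matrix::rowSums(mapped$sc_counts[, cells, drop = FALSE]))
  )
  # coordinates are inherited unchanged from the template
  expect_equal(
    mapped$st$coords,
    tpl$st$coords[match(mapped$st$coords$spot_id, tpl$st$coords$spot_id), ]
  )
})

test_that("planting overexpresses exactly the selected genes and records truth", {
  n_target <- sum(mapped$pairs$pair_class %in% c("near", "far")) * cfg$n_lr_per_pair
  expect_equal(nrow(planted$truth), n_target)
  expect_equal(
    unname(table(planted$truth$pair_class)[["near"]] %% cfg$n_lr_per_pair), 0
  )
  ann <- mapped$cell_annotation
  for (i in c(1, nrow(planted$truth))) {
    row <- planted$truth[i, ]
    lig <- db$ligand_subunits[[match(row$interaction_name, db$interaction_name)]][1]
    sender_cells <- ann$cell_id[ann$cell_type == row$source_celltype]
    expect_gt(
      mean(planted$sc_counts[lig, sender_cells]),
      mean(mapped$sc_counts[lig, sender_cells])
    )
  }
  # untouched genes are bit-identical
  planted_genes <- unique(unlist(c(
    db$ligand_subunits[db$interaction_name %in% planted$truth$interaction_name],
    db$receptor_subunits[db$interaction_name %in% planted$truth$interaction_name]
  )))
  other <- setdiff(rownames(mapped$sc_counts), planted_genes)
  expect_identical(
    as.matrix(planted$sc_counts[other, ]),
    as.matrix(mapped$sc_counts[other, ])
  )
})

test_that("the consistency filter keeps only spatially coherent plants and restores the rest", {
  tr <- sim$truth
  expect_true(all(
    (tr$pair_class[tr$kept] == "near" & tr$range_class[tr$kept] == "short") |
      (tr$pair_class[tr$kept] == "far" & tr$range_class[tr$kept] == "long")
  ))
  expect_gte(sum(tr$kept & tr$pair_class == "near"), 1)
  expect_gte(sum(tr$kept & tr$pair_class == "far"), 1)
  # a discarded plant's ligand gene is restored to its pre-plant counts
  disc <- tr[!tr$kept, ][1, ]
  lig <- db$ligand_subunits[[match(disc$interaction_name, db$interaction_name)]][1]
  sender_cells <- mapped$cell_annotation$cell_id[
    mapped$cell_annotation$cell_type == disc$source_celltype
  ]
  expect_identical(
    as.numeric(sim$sc_counts[lig, sender_cells]),
    as.numeric(mapped$sc_counts[lig, sender_cells])
  )
  # ST spot sums still equal cell sums for every gene
  s1 <- sim$spot_annotation$spot_id[1]
  cells <- sim$mapping$cell_id[sim$mapping$spot_id == s1]
  expect_equal(
    as.numeric(sim$st$values[, s1]),
    as.numeric(Matrix::rowSums(sim$sc_counts[, cells, drop = FALSE]))
  )
})

test_that("the simulation is deterministic given config and seed", {
  sim2 <- suppressMessages(suppressWarnings(
    simulate_paired_dataset(tpl, db, cfg)
  ))
  expect_identical(as.matrix(sim$sc_counts), as.matrix(sim2$sc_counts))
  expect_identical(as.matrix(sim$st$values), as.matrix(sim2$st$values))
  expect_identical(as.data.frame(sim$truth), as.data.frame(sim2$truth))
})

test_that("ground truth round-trips through the accuracy metric at F1 = 1", {
  truth_pred <- truth_predictions(sim$truth)
  ref <- sim$truth[sim$truth$kept, c("source_celltype", "target_celltype", "ligand", "receptor")]
  acc <- accuracy_vs_reference(truth_pred, ref)
  expect_equal(acc$f1, 1)
  expect_equal(acc$micro_f1, 1)
  # the spatial oracle saturates the DES; a random predictor does not
  lists <- build_expected_lists(sim$tendency)
  orc <- oracle_predictions(lists, sim$pairs)
  expect_equal(attr(tool_des(orc, sim$pairs, lists), "mean_des"), 1)
  rnd <- random_predictions(db, sim$pairs, n_per_pair = 5, seed = 3)
  expect_lt(attr(tool_des(rnd, sim$pairs, lists), "mean_des"), 1)
})

test_that("TF/target overexpression runs when a regulatory table is supplied", {
  reg_tab <- tibble::tibble(
    interaction_name = sim$truth$interaction_name[sim$truth$kept][1],
    gene = setdiff(rownames(tpl$sc_counts), c(db$ligand, unlist(db$receptor_subunits)))[1]
  )
  sim3 <- suppressWarnings(simulate_paired_dataset(tpl, db, cfg, regulatory_table = reg_tab))
  rec_cells <- sim3$cell_annotation$cell_id[
    sim3$cell_annotation$cell_type ==
      sim3$truth$target_celltype[match(reg_tab$interaction_name, sim3$truth$interaction_name)]
  ]
  expect_gt(
    mean(sim3$sc_counts[reg_tab$gene, rec_cells]),
    mean(mapped$sc_counts[reg_tab$gene, rec_cells])
  )
})
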
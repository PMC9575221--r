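test_that("consensus keeps interactions shared by at least min_tools tools", {
  tables <- lapply(sprintf("tool%d", 1:10), function(tl) {
    rows <- list(c("A", "B", "L1", "R1")) # in all 10 tools
    if (tl %in% c("tool1", "tool2", "tool3")) rows <- c(rows, list(c("A", "B", "L2", "R2")))
    if (tl %in% c("tool1", "tool2")) rows <- c(rows, list(c("A", "B", "L3", "R3")))
    pred_table(tl, rows)
  })
  cons <- build_consensus(tables, min_tools = 3)
  expect_setequal(paste(cons$ligand, cons$receptor), c("L1 R1", "L2 R2"))
  expect_equal(cons$n_tools[cons$ligand == "L1"], 10)
  # duplicated rows inside a single tool count once
  dup <- tables
  dup[[5]] <- dplyr::bind_rows(dup[[5]], pred_table("tool5", list(c("A", "B", "L3", "R3"))),
    pred_table("tool5", list(c("A", "B", "L3", "R3"))))
  cons2 <- build_consensus(dup, min_tools = 3)
  expect_setequal(paste(cons2$ligand, cons2$receptor), c("L1 R1", "L2 R2", "L3 R3"))
  # monotone decreasing in min_tools
  for (k in 3:6) {
    expect_true(all(
      paste(build_consensus(tables, k)$ligand, build_consensus(tables, k)$receptor) %in%
        paste(build_consensus(tables, 3)$ligand, build_consensus(tables, 3)$receptor)
    ))
  }
  expect_error(build_consensus(tables[1:2], min_tools = 3), "at least")
})

test_that("precision/recall/F1 match direct arithmetic", {
  ref <- pred_table("ref", list(
    c("A", "B", "L1", "R1"), c("A", "B", "L2", "R2"),
    c("A", "B", "L3", "R3"), c("A", "B", "L4", "R4")
  ))[, -1]
  # TP = 2 (L1,L2), FP = 1 (LX), FN = 2 (L3,L4)
  pred <- pred_table("t", list(
    c("A", "B", "L1", "R1"), c("A", "B", "L2", "R2"), c("A", "B", "LX", "RX")
  ))
  acc <- accuracy_vs_reference(pred, ref)
  expect_equal(acc$precision, 2 / 3)
  expect_equal(acc$recall, 1 / 2)
  expect_equal(acc$f1, 4 / 7)
  expect_equal(c(acc$tp, acc$fp, acc$fn), c(2, 1, 2))
  # perfect and disjoint predictors
  expect_equal(accuracy_vs_reference(dplyr::mutate(ref, tool = "t"), ref)$f1, 1)
  off <- pred_table("t", list(c("A", "B", "ZZ", "QQ")))
  expect_equal(accuracy_vs_reference(off, ref)$f1, 0)
  # invariant to record order
  expect_equal(accuracy_vs_reference(pred[c(3, 1, 2), ], ref), acc, ignore_attr = TRUE)
})

test_that("macro metrics average per pair while micro pools counts", {
  ref <- pred_table("ref", list(
    c("A", "B", "L1", "R1"),
    c("B", "C", "L2", "R2"), c("B", "C", "L3", "R3")
  ))[, -1]
  pred <- pred_table("t", list(
    c("A", "B", "L1", "R1"), # perfect on A->B
    c("B", "C", "L9", "R9") # total miss on B->C
  ))
  acc <- accuracy_vs_reference(pred, ref)
  expect_equal(acc$precision, 0.5) # mean of 1 and 0
  expect_equal(acc$micro_precision, 1 / 2)
  expect_equal(acc$micro_recall, 1 / 3)
  per_pair <- tidy(acc)
  expect_equal(nrow(per_pair), 2)
})

test_that("expression-product baseline ranks by sender-ligand x receiver-receptor means", {
  genes <- c("La", "Lb", "Lc", "Ra", "Rb", "Rc")
  # sender means for ligands (2,1,3); receiver means all 1
  sender_cells <- paste0("s", 1:4)
  receiver_cells <- paste0("r", 1:4)
  m <- matrix(0, 6, 8, dimnames = list(genes, c(sender_cells, receiver_cells)))
  m["La", sender_cells] <- 2
  m["Lb", sender_cells] <- 1
  m["Lc", sender_cells] <- 3
  m[c("Ra", "Rb", "Rc"), receiver_cells] <- 1
  ann <- tibble::tibble(
    cell_id = c(sender_cells, receiver_cells),
    cell_type = rep(c("S", "T"), each = 4)
  )
  db <- toy_db(list(c("i1", "La", "Ra"), c("i2", "Lb", "Rb"), c("i3", "Lc", "Rc")))
  out <- lr_product_baseline(m, ann, db, top_n = 2)
  st <- out[out$source_celltype == "S", ]
  expect_equal(st$ligand, c("Lc", "La")) # products 3, 2 beat 1
  # zero expression in the reverse direction: no T->S ligand signal
  expect_equal(nrow(out[out$source_celltype == "T", ]), 0)
  # all-zero matrix gives an empty table
  expect_equal(nrow(lr_product_baseline(m * 0, ann, db)), 0)
})
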
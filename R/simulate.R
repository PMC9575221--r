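#' Simulation configuration
#'
#' Collects the knobs of the paired scRNA-seq/ST simulation. Defaults follow
#' the study conditions: four selected cell types, 2-5 cells mapped per
#' spot, 30 interactions planted per near/far cell-type pair, and the
#' spatial-tendency thresholds used on real slides.
#'
#' @param n_celltypes_selected Cell types retained per simulation round.
#' @param cells_per_spot Integer interval `c(lo, hi)`; each spot receives a
#'   uniform draw of cells in this range.
#' @param n_lr_per_pair Interactions planted per near/far cell-type pair.
#' @param donor_quantile Donor genes for the semi-synthetic overexpression
#'   are drawn from above this quantile of per-type mean expression.
#' @param n_perm,reg,top_fraction,alpha,min_spot_fraction Passed to the
#'   spatial-tendency rerun in the consistency filter.
#' @param seed Integer seed driving every random choice of the round.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_celltypes_selected = 4,
                              cells_per_spot = c(2L, 5L),
                              n_lr_per_pair = 30,
                              donor_quantile = 0.95,
                              n_perm = 1000, reg = 0.001,
                              top_fraction = 0.10, alpha = 0.01,
                              min_spot_fraction = 0.10,
                              seed = 1L) {
  stopifnot(
    length(cells_per_spot) == 2, cells_per_spot[1] >= 1,
    cells_per_spot[2] >= cells_per_spot[1],
    n_lr_per_pair >= 1, n_celltypes_selected >= 2
  )
  structure(
    list(
      n_celltypes_selected = n_celltypes_selected,
      cells_per_spot = as.integer(cells_per_spot),
      n_lr_per_pair = n_lr_per_pair,
      donor_quantile = donor_quantile,
      n_perm = n_perm, reg = reg,
      top_fraction = top_fraction, alpha = alpha,
      min_spot_fraction = min_spot_fraction,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Fully synthetic tissue template
#'
#' Generates a matched scRNA-seq/ST template with a layered 2-D tissue of
#' mixed and segregated domains: cell types are grouped in pairs, each pair
#' sharing one vertical band of the spot grid in a checkerboard interleaving
#' (these mixed pairs are spatially near), while types in different bands
#' are segregated — adjacent bands give intermediate distances and distant
#' bands far pairs. Counts are negative-binomial with gamma-distributed
#' baseline gene means and type-specific marker genes at a configurable
#' fold change.
#'
#' @param seed Integer seed; the template is bit-reproducible given it.
#' @param n_types Number of cell types (bands), at least 4.
#' @param slide_dim `c(n_cols, n_rows)` of the spot grid (unit spacing).
#' @param n_genes Number of genes.
#' @param cells_per_type scRNA-seq cells simulated per type.
#' @param n_markers Marker genes per type.
#' @param marker_fold Mean fold change of a marker in its own type.
#' @param nb_size Negative-binomial size (dispersion) parameter.
#' @return A list of class `cci_template`: `sc_counts`, `cell_annotation`,
#'   `st` (a [spatial_expression()] of the template slide),
#'   `spot_annotation`, and the per-type mean matrix `type_means`.
#' @export
make_fixture <- function(seed = 1L, n_types = 6, slide_dim = c(12, 12),
                         n_genes = 600, cells_per_type = 120,
                         n_markers = 8, marker_fold = 10, nb_size = 2) {
  if (n_types < 4) abort("need at least 4 cell types")
  n_bands <- ceiling(n_types / 2)
  if (slide_dim[1] < n_bands) abort("slide has fewer columns than cell-type bands")
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  types <- sprintf("type%02d", seq_len(n_types))
  # sparse baseline typical of spot-level data: most genes lowly expressed
  base_mu <- rgamma(n_genes, shape = 0.5, rate = 4)
  type_means <- matrix(rep(base_mu, n_types), n_genes, n_types,
    dimnames = list(genes, types)
  )
  marker_pool <- sample(genes, n_types * n_markers)
  for (t in seq_len(n_types)) {
    mk <- marker_pool[(t - 1) * n_markers + seq_len(n_markers)]
    type_means[mk, t] <- pmax(base_mu[match(mk, genes)], 0.4) * marker_fold
  }

  # scRNA-seq template
  cell_type <- rep(types, each = cells_per_type)
  cell_id <- sprintf("cell%05d", seq_along(cell_type))
  sc <- matrix(0L, n_genes, length(cell_id), dimnames = list(genes, cell_id))
  for (t in seq_len(n_types)) {
    idx <- which(cell_type == types[t])
    sc[, idx] <- rnbinom(n_genes * length(idx), mu = type_means[, t], size = nb_size)
  }

  # ST template: two interleaved types per band, ~3 cells of counts per spot
  grid <- expand.grid(x = seq_len(slide_dim[1]), y = seq_len(slide_dim[2]))
  band <- ceiling(grid$x / (slide_dim[1] / n_bands))
  parity <- (grid$x + grid$y) %% 2
  spot_type <- pmin(2L * band - 1L + parity, n_types)
  spot_id <- sprintf("spot%04d", seq_len(nrow(grid)))
  st_counts <- matrix(0L, n_genes, nrow(grid), dimnames = list(genes, spot_id))
  for (t in seq_len(n_types)) {
    idx <- which(spot_type == t)
    st_counts[, idx] <- rnbinom(n_genes * length(idx), mu = 3 * type_means[, t], size = nb_size)
  }
  coords <- tibble(spot_id = spot_id, x = as.numeric(grid$x), y = as.numeric(grid$y))
  structure(
    list(
      sc_counts = Matrix::Matrix(sc, sparse = TRUE),
      cell_annotation = tibble(cell_id = cell_id, cell_type = cell_type),
      st = spatial_expression(st_counts, coords),
      spot_annotation = tibble(spot_id = spot_id, cell_type = types[spot_type]),
      type_means = type_means
    ),
    class = "cci_template"
  )
}

#' Synthetic ligand-receptor database over a gene pool
#'
#' Draws interactions over disjoint gene sets (no gene appears in two
#' interactions) so that planting one interaction never perturbs another.
#' A fraction of receptors are two-subunit complexes.
#'
#' @param genes Character vector of available gene symbols.
#' @param n_interactions Number of interactions to draw.
#' @param frac_complex Fraction of interactions with a two-subunit receptor.
#' @param seed Integer seed.
#' @return An `lr_database`.
#' @export
simulate_lr_database <- function(genes, n_interactions = 150,
                                 frac_complex = 0.1, seed = 1L) {
  set.seed(seed)
  n_complex <- floor(n_interactions * frac_complex)
  need <- 2 * n_interactions + n_complex
  if (length(genes) < need) {
    abort(sprintf("gene pool too small: need %d genes for %d interactions", need, n_interactions))
  }
  pool <- sample(genes, need)
  is_complex <- seq_len(n_interactions) <= n_complex
  rows <- vector("list", n_interactions)
  k <- 1
  for (i in seq_len(n_interactions)) {
    lig <- pool[k]
    k <- k + 1
    rec <- if (is_complex[i]) {
      r <- paste(sort(pool[k + 0:1]), collapse = "+")
      k <- k + 2
      r
    } else {
      r <- pool[k]
      k <- k + 1
      r
    }
    rows[[i]] <- tibble(
      interaction_name = paste0(lig, "_", gsub("\\+", "_", rec)),
      ligand = lig, receptor = rec,
      annotation = sample(c("secreted_signaling", "cell_cell_contact"), 1)
    )
  }
  lr_database(bind_rows(rows), source_label = "synthetic")
}

#' Step 1: select cell types and map cells to spots
#'
#' Chooses `n_celltypes_selected` cell types whose pairs (classified on the
#' template slide) include at least one near and one far pair, subsets the
#' template to those types, then maps a uniform 2-5 (configurable) cells of
#' the matching type to every spot. Spot expression becomes the sum of its
#' mapped cells' counts; coordinates are untouched. Cells are sampled
#' without replacement while the pool lasts, then with replacement (flagged
#' in the result).
#'
#' @param template A `cci_template` from [make_fixture()], or any list with
#'   the same elements built from real data.
#' @param config A [simulation_config()].
#' @return A list of class `cci_mapped`: `sc_counts`, `cell_annotation`,
#'   `st`, `spot_annotation`, `mapping`, `pairs` (classified, restricted to
#'   the selected types), `cells_reused`.
#' @export
select_celltypes_and_map <- function(template, config = simulation_config()) {
  set.seed(config$seed)
  all_pairs <- classify_pairs(
    celltype_pair_distances(template$spot_annotation, template$st$coords),
    seed = config$seed
  )
  types <- sort(unique(template$spot_annotation$cell_type))
  ksel <- config$n_celltypes_selected
  if (length(types) < ksel) abort("template has fewer cell types than requested")
  combos <- utils::combn(types, ksel, simplify = FALSE)
  ok <- purrr::map_lgl(combos, function(tt) {
    sub <- all_pairs[all_pairs$type_a %in% tt & all_pairs$type_b %in% tt, ]
    any(sub$pair_class == "near") && any(sub$pair_class == "far")
  })
  if (!any(ok)) abort("no cell-type subset contains both a near and a far pair")
  sel <- combos[ok][[sample.int(sum(ok), 1)]]
  pairs <- all_pairs[all_pairs$type_a %in% sel & all_pairs$type_b %in% sel, ]

  keep_spots <- template$spot_annotation$cell_type %in% sel
  spot_ann <- template$spot_annotation[keep_spots, ]
  coords <- template$st$coords[match(spot_ann$spot_id, template$st$coords$spot_id), ]

  lo <- config$cells_per_spot[1]
  hi <- config$cells_per_spot[2]
  n_cells_per_spot <- sample(lo:hi, nrow(spot_ann), replace = TRUE)
  mapping <- vector("list", nrow(spot_ann))
  reused <- FALSE
  for (ct in sel) {
    spots_ct <- which(spot_ann$cell_type == ct)
    pool <- template$cell_annotation$cell_id[template$cell_annotation$cell_type == ct]
    demand <- sum(n_cells_per_spot[spots_ct])
    if (demand <= length(pool)) {
      drawn <- sample(pool, demand)
    } else {
      reused <- TRUE
      drawn <- c(sample(pool), sample(pool, demand - length(pool), replace = TRUE))
    }
    off <- 0
    for (s in spots_ct) {
      mapping[[s]] <- tibble(
        spot_id = spot_ann$spot_id[s], cell_type = ct,
        template_cell = drawn[off + seq_len(n_cells_per_spot[s])]
      )
      off <- off + n_cells_per_spot[s]
    }
  }
  mapping <- bind_rows(mapping)
  mapping$cell_id <- sprintf("simcell%05d", seq_len(nrow(mapping)))

  sc <- template$sc_counts[, mapping$template_cell, drop = FALSE]
  colnames(sc) <- mapping$cell_id
  st_counts <- rowsum_cells_to_spots(sc, mapping, spot_ann$spot_id)
  structure(
    list(
      sc_counts = sc,
      cell_annotation = tibble(cell_id = mapping$cell_id, cell_type = mapping$cell_type),
      st = spatial_expression(st_counts, coords),
      spot_annotation = spot_ann,
      mapping = mapping[, c("cell_id", "template_cell", "spot_id", "cell_type")],
      pairs = pairs,
      cells_reused = reused
    ),
    class = "cci_mapped"
  )
}

rowsum_cells_to_spots <- function(sc, mapping, spot_ids) {
  agg <- Matrix::sparseMatrix(
    i = seq_len(nrow(mapping)),
    j = match(mapping$spot_id, spot_ids),
    x = 1, dims = c(nrow(mapping), length(spot_ids))
  )
  out <- sc %*% agg
  dimnames(out) <- list(rownames(sc), spot_ids)
  methods::as(methods::as(out, "CsparseMatrix"), "generalMatrix")
}

#' Step 2: plant overexpressed ligand-receptor signals
#'
#' For every near and far cell-type pair, `n_lr_per_pair` database
#' interactions are sampled without replacement (globally, so no gene is
#' planted twice); each is given a random sender/receiver orientation, and
#' the ligand's counts in sender cells and the receptor's counts in
#' receiver cells are replaced by counts resampled with replacement from a
#' donor gene drawn from the top `1 - donor_quantile` fraction of that
#' type's mean expression. This keeps realistic count dispersion while
#' guaranteeing strong signal. Spot sums are recomputed for planted genes
#' only; everything else is untouched.
#'
#' @param mapped A `cci_mapped` from [select_celltypes_and_map()].
#' @param db An `lr_database` (gene symbols must exist in the dataset).
#' @param config A [simulation_config()].
#' @return A list of class `cci_planted` adding `truth` (provisional: one
#'   row per plant with `source_celltype`, `target_celltype`, `ligand`,
#'   `receptor`, `pair_class`) and `original_rows` (pre-plant counts, used
#'   by the consistency filter to restore discarded plants).
#' @export
plant_interactions <- function(mapped, db, config = simulation_config()) {
  set.seed(config$seed + 1L)
  genes <- rownames(mapped$sc_counts)
  eligible <- purrr::map2_lgl(
    db$ligand_subunits, db$receptor_subunits,
    ~ all(c(.x, .y) %in% genes)
  )
  pool <- which(eligible)
  target_pairs <- mapped$pairs[mapped$pairs$pair_class %in% c("near", "far"), ]
  if (nrow(target_pairs) == 0) abort("no near or far cell-type pair to plant into")

  sc <- as.matrix(mapped$sc_counts)
  ann <- mapped$cell_annotation
  type_mean <- sapply(sort(unique(ann$cell_type)), function(ct) {
    rowMeans(sc[, ann$cell_type == ct, drop = FALSE])
  })
  original_rows <- list()
  truth <- list()

  overexpress <- function(gene_set, ct) {
    cells <- which(ann$cell_type == ct)
    mu <- type_mean[, ct]
    thresh <- quantile(mu[mu > 0], config$donor_quantile)
    donors <- names(mu)[mu >= thresh & mu > 0]
    for (g in gene_set) {
      key <- paste(g, ct, sep = "\r")
      if (is.null(original_rows[[key]])) {
        original_rows[[key]] <<- sc[g, cells]
      }
      donor <- sample(setdiff(donors, g), 1)
      sc[g, cells] <<- sample(sc[donor, cells], length(cells), replace = TRUE)
    }
  }

  for (p in seq_len(nrow(target_pairs))) {
    a <- target_pairs$type_a[p]
    b <- target_pairs$type_b[p]
    take <- min(config$n_lr_per_pair, length(pool))
    if (take < config$n_lr_per_pair) {
      warn(sprintf(
        "only %d eligible interactions left for pair %s-%s (wanted %d)",
        take, a, b, config$n_lr_per_pair
      ))
    }
    if (take == 0) next
    picked <- sample(pool, take)
    pool <- setdiff(pool, picked)
    for (i in picked) {
      dir_flip <- runif(1) < 0.5
      sender <- if (dir_flip) b else a
      receiver <- if (dir_flip) a else b
      overexpress(db$ligand_subunits[[i]], sender)
      overexpress(db$receptor_subunits[[i]], receiver)
      truth[[length(truth) + 1]] <- tibble(
        source_celltype = sender, target_celltype = receiver,
        ligand = db$ligand[i], receptor = db$receptor[i],
        interaction_name = db$interaction_name[i],
        pair_class = target_pairs$pair_class[p]
      )
    }
  }
  truth <- bind_rows(truth)
  planted_genes <- unique(names(original_rows) |> strsplit("\r") |> purrr::map_chr(1))

  out <- mapped
  out$sc_counts <- Matrix::Matrix(sc, sparse = TRUE)
  out$st <- refresh_st_rows(out, planted_genes)
  out$truth <- truth
  out$original_rows <- original_rows
  class(out) <- c("cci_planted", "cci_mapped")
  out
}

refresh_st_rows <- function(ds, genes) {
  st_counts <- ds$st$values
  sub <- rowsum_cells_to_spots(
    ds$sc_counts[genes, ds$mapping$cell_id, drop = FALSE],
    ds$mapping, colnames(st_counts)
  )
  st_counts[genes, ] <- sub
  spatial_expression(st_counts, ds$st$coords)
}

#' Step 3: keep only spatially consistent plants
#'
#' Reruns the spatial-tendency pipeline on the simulated slide and keeps a
#' plant only when its classified range agrees with its cell-type pair:
#' short-range plants in near pairs, long-range plants in far pairs.
#' Discarded plants have their original counts restored in both the
#' scRNA-seq and the ST matrices. When a regulatory table is supplied, the
#' TFs/targets of kept interactions are overexpressed in the receiver type
#' with the same resampling mechanism; otherwise this step is skipped with
#' a message.
#'
#' @param planted A `cci_planted` from [plant_interactions()].
#' @param db The `lr_database` used for planting; the tendency rerun scores
#'   every database interaction covered by the slide, so plants are ranked
#'   in the same context as a real analysis.
#' @param config A [simulation_config()].
#' @param regulatory_table Optional tibble with columns `interaction_name`,
#'   `gene` naming downstream TFs/targets per interaction.
#' @return A list of class `cci_simulation`: the dataset with final
#'   `sc_counts`/`st`, `truth` gaining `range_class` and `kept`, and the
#'   tendency table of the rerun as `tendency`.
#' @export
consistency_filter <- function(planted, db, config = simulation_config(),
                               regulatory_table = NULL) {
  tend <- lr_spatial_tendency(
    planted$st, db,
    n_perm = config$n_perm, reg = config$reg,
    min_spot_fraction = config$min_spot_fraction,
    seed = config$seed + 2L
  )
  tend <- classify_ranges(tend, top_fraction = config$top_fraction, alpha = config$alpha)
  cls <- setNames(tend$range_class, tend$interaction_name)
  truth <- planted$truth
  truth$range_class <- unname(cls[truth$interaction_name])
  truth$range_class[is.na(truth$range_class)] <- "medium"
  truth$kept <- (truth$pair_class == "near" & truth$range_class == "short") |
    (truth$pair_class == "far" & truth$range_class == "long")

  out <- planted
  discarded <- truth$interaction_name[!truth$kept]
  if (length(discarded) > 0) {
    sc <- as.matrix(out$sc_counts)
    ann <- out$cell_annotation
    restore_genes <- character(0)
    for (i in which(!truth$kept)) {
      row <- truth[i, ]
      idx <- which(db$interaction_name == row$interaction_name)
      gsets <- list(
        list(genes = db$ligand_subunits[[idx]], ct = row$source_celltype),
        list(genes = db$receptor_subunits[[idx]], ct = row$target_celltype)
      )
      for (gs in gsets) {
        for (g in gs$genes) {
          key <- paste(g, gs$ct, sep = "\r")
          orig <- planted$original_rows[[key]]
          if (!is.null(orig)) {
            sc[g, which(ann$cell_type == gs$ct)] <- orig
            restore_genes <- c(restore_genes, g)
          }
        }
      }
    }
    out$sc_counts <- Matrix::Matrix(sc, sparse = TRUE)
    out$st <- refresh_st_rows(out, unique(restore_genes))
  }

  if (!is.null(regulatory_table)) {
    out <- overexpress_regulatory(out, truth, regulatory_table, config)
  } else {
    inform("no regulatory table supplied; skipping TF/target overexpression")
  }
  out$truth <- truth[, c(
    "source_celltype", "target_celltype", "ligand", "receptor",
    "interaction_name", "pair_class", "range_class", "kept"
  )]
  out$tendency <- tend
  out$original_rows <- NULL
  class(out) <- c("cci_simulation", "cci_mapped")
  out
}

overexpress_regulatory <- function(ds, truth, regulatory_table, config) {
  set.seed(config$seed + 3L)
  kept <- truth[truth$kept, ]
  reg <- as_tibble(regulatory_table)
  reg <- reg[reg$interaction_name %in% kept$interaction_name &
    reg$gene %in% rownames(ds$sc_counts), ]
  if (nrow(reg) == 0) return(ds)
  sc <- as.matrix(ds$sc_counts)
  ann <- ds$cell_annotation
  touched <- character(0)
  for (i in seq_len(nrow(reg))) {
    ct <- kept$target_celltype[match(reg$interaction_name[i], kept$interaction_name)]
    cells <- which(ann$cell_type == ct)
    mu <- rowMeans(sc[, cells, drop = FALSE])
    donors <- names(mu)[mu >= quantile(mu[mu > 0], config$donor_quantile) & mu > 0]
    donor <- sample(setdiff(donors, reg$gene[i]), 1)
    sc[reg$gene[i], cells] <- sample(sc[donor, cells], length(cells), replace = TRUE)
    touched <- c(touched, reg$gene[i])
  }
  ds$sc_counts <- Matrix::Matrix(sc, sparse = TRUE)
  ds$st <- refresh_st_rows(ds, unique(touched))
  ds
}

#' Run the full three-step simulation
#'
#' Convenience wrapper: [select_celltypes_and_map()], then
#' [plant_interactions()], then [consistency_filter()].
#'
#' @inheritParams consistency_filter
#' @param template A `cci_template` from [make_fixture()].
#' @param db An `lr_database`.
#' @return A `cci_simulation`.
#' @export
simulate_paired_dataset <- function(template, db, config = simulation_config(),
                                    regulatory_table = NULL) {
  mapped <- select_celltypes_and_map(template, config)
  planted <- plant_interactions(mapped, db, config)
  consistency_filter(planted, db, config, regulatory_table)
}

#' Write a simulated dataset bundle to a directory
#'
#' Emits `sc_counts.mtx` (+ features/barcodes), `cell_annotation.tsv`,
#' `st_counts.mtx` (+ features/barcodes), `st_coords.tsv` and `truth.tsv`.
#'
#' @param sim A `cci_simulation`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(
    sim$sc_counts, file.path(dir, "sc_counts.mtx"),
    file.path(dir, "sc_features.tsv"), file.path(dir, "sc_barcodes.tsv")
  )
  readr::write_tsv(sim$cell_annotation, file.path(dir, "cell_annotation.tsv"))
  write_counts(
    sim$st$values, file.path(dir, "st_counts.mtx"),
    file.path(dir, "st_features.tsv"), file.path(dir, "st_barcodes.tsv")
  )
  readr::write_tsv(sim$st$coords, file.path(dir, "st_coords.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Reference predictors for benchmarking exercises
#'
#' `oracle_predictions()` emits, for every near pair, exactly the expected
#' short-range list and, for every far pair, the expected long-range list —
#' the best any tool could do under the DES. `truth_predictions()` converts
#' a simulation's kept ground truth into a prediction table.
#' `random_predictions()` draws database interactions uniformly per pair.
#'
#' @param lists Expected lists from [build_expected_lists()].
#' @param pairs A classified `cci_pairs`.
#' @param tool Tool name recorded in the table.
#' @return A prediction table.
#' @export
oracle_predictions <- function(lists, pairs, tool = "oracle") {
  use <- pairs[pairs$pair_class %in% c("near", "far"), ]
  sided <- list(near = lists$short, far = lists$long)
  purrr::pmap_dfr(
    list(use$type_a, use$type_b, use$pair_class),
    function(a, b, cls) {
      L <- sided[[cls]]
      if (nrow(L) == 0) return(NULL)
      tibble(
        tool = tool, source_celltype = a, target_celltype = b,
        ligand = L$ligand, receptor = L$receptor,
        score = rev(seq_len(nrow(L))), pvalue = L$p_value
      )
    }
  )
}

#' @rdname oracle_predictions
#' @param truth A simulation truth table (rows with `kept = TRUE` are used).
#' @export
truth_predictions <- function(truth, tool = "truth") {
  kept <- truth[truth$kept, ]
  tibble(
    tool = tool,
    source_celltype = kept$source_celltype,
    target_celltype = kept$target_celltype,
    ligand = kept$ligand, receptor = kept$receptor,
    score = 1, pvalue = NA_real_
  )
}

#' @rdname oracle_predictions
#' @param db An `lr_database` to draw from.
#' @param n_per_pair Predictions drawn per near/far pair.
#' @param seed Integer seed.
#' @export
random_predictions <- function(db, pairs, n_per_pair = 10, seed = 1L,
                               tool = "random") {
  set.seed(seed)
  use <- pairs[pairs$pair_class %in% c("near", "far"), ]
  purrr::pmap_dfr(
    list(use$type_a, use$type_b),
    function(a, b) {
      idx <- sample(nrow(db), min(n_per_pair, nrow(db)))
      tibble(
        tool = tool, source_celltype = a, target_celltype = b,
        ligand = db$ligand[idx], receptor = db$receptor[idx],
        score = runif(length(idx)), pvalue = NA_real_
      )
    }
  )
}
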
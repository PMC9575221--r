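# shared in-code fixtures; everything is generated, nothing is read from disk

# tiny slide with named genes on a unit grid
toy_slide <- function(values, nx = 4, ny = 4) {
  n <- nx * ny
  stopifnot(ncol(values) == n)
  coords <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  ids <- sprintf("s%02d", seq_len(n))
  colnames(values) <- ids
  spatial_expression(
    values,
    data.frame(spot_id = ids, x = as.numeric(coords$x), y = as.numeric(coords$y))
  )
}

# random weighted point set for OT tests
random_point_set <- function(n, lim = 20) {
  w <- runif(n)
  tibble::tibble(
    spot_id = sprintf("p%d", seq_len(n)),
    x = runif(n, 0, lim), y = runif(n, 0, lim),
    weight = w / sum(w)
  )
}

point_mass <- function(x, y) {
  tibble::tibble(spot_id = "p1", x = x, y = y, weight = 1)
}

# small db in code
toy_db <- function(rows) {
  lr_database(do.call(rbind, lapply(rows, function(r) {
    data.frame(
      interaction_name = r[1], ligand = r[2], receptor = r[3],
      annotation = if (length(r) > 3) r[4] else "other"
    )
  })))
}

# a prediction table from a compact spec list
pred_table <- function(tool, rows) {
  if (length(rows) == 0) {
    return(tibble::tibble(
      tool = character(), source_celltype = character(),
      target_celltype = character(), ligand = character(),
      receptor = character(), score = numeric(), pvalue = numeric()
    ))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(
      tool = tool, source_celltype = r[1], target_celltype = r[2],
      ligand = r[3], receptor = r[4], score = 1, pvalue = NA_real_
    )
  })) |> tibble::as_tibble()
}

# slide fixture with planted extreme short/long pairs plus i.i.d. background:
# short pairs are colocalized in a tight cluster, long pairs sit in opposite
# corners, background gene values are i.i.d. across spots.
planted_tendency_slide <- function(n_background = 16, nx = 8, ny = 8, seed = 42) {
  set.seed(seed)
  n <- nx * ny
  coords <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  corner_a <- which(coords$x <= 2 & coords$y <= 2)
  corner_b <- which(coords$x >= nx - 1 & coords$y >= ny - 1)
  center <- which(abs(coords$x - nx / 2) <= 1 & abs(coords$y - ny / 2) <= 1)
  genes <- list()
  rows <- list()
  add_gene <- function(name, v) {
    genes[[name]] <<- v
  }
  # two extreme short pairs: ligand and receptor identically colocalized
  for (k in 1:2) {
    v <- rep(0, n)
    v[center] <- 10
    add_gene(sprintf("SL%d", k), v)
    add_gene(sprintf("SR%d", k), v)
    rows[[length(rows) + 1]] <- c(sprintf("short%d", k), sprintf("SL%d", k), sprintf("SR%d", k))
  }
  # two extreme long pairs: opposite corners
  for (k in 1:2) {
    vl <- rep(0, n)
    vl[corner_a] <- 10
    vr <- rep(0, n)
    vr[corner_b] <- 10
    add_gene(sprintf("LL%d", k), vl)
    add_gene(sprintf("LR%d", k), vr)
    rows[[length(rows) + 1]] <- c(sprintf("long%d", k), sprintf("LL%d", k), sprintf("LR%d", k))
  }
  # background: i.i.d. values on a sparse random support (keeps OT instances small)
  sparse_gene <- function() {
    v <- rep(0, n)
    idx <- sample(n, 16)
    v[idx] <- rpois(16, 3) + 1
    v
  }
  for (k in seq_len(n_background)) {
    add_gene(sprintf("BL%d", k), sparse_gene())
    add_gene(sprintf("BR%d", k), sparse_gene())
    rows[[length(rows) + 1]] <- c(sprintf("bg%02d", k), sprintf("BL%d", k), sprintf("BR%d", k))
  }
  values <- do.call(rbind, genes)
  rownames(values) <- names(genes)
  list(
    st = toy_slide(values, nx, ny),
    db = toy_db(rows),
    planted_short = c("short1", "short2"),
    planted_long = c("long1", "long2")
  )
}

# scaled-down simulation settings used across simulator tests
test_sim_config <- function(seed = 7L, ...) {
  simulation_config(
    n_lr_per_pair = 4, n_perm = 60, top_fraction = 0.3, alpha = 0.02,
    seed = seed, ...
  )
}

test_template <- function(seed = 7L) {
  make_fixture(
    seed = seed, n_types = 4, slide_dim = c(12, 6), n_genes = 120,
    cells_per_type = 80, n_markers = 4, marker_fold = 10
  )
}

test_db <- function(template, seed = 7L, n = 16) {
  simulate_lr_database(rownames(template$sc_counts),
    n_interactions = n, frac_complex = 0.1, seed = seed
  )
}
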
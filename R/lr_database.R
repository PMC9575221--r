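#' Ligand-receptor interaction databases
#'
#' A ligand-receptor (L-R) database is a tibble with one row per interaction
#' and columns `interaction_name`, `ligand`, `receptor`, `annotation`,
#' `ligand_subunits` and `receptor_subunits`. Multi-subunit complexes are
#' written with `+` between gene symbols (e.g. receptor `ITGAV+ITGB5`); the
#' `*_subunits` columns hold the parsed character vectors. Annotations follow
#' the CellChatDB categories: `secreted_signaling`, `cell_cell_contact`,
#' `ecm_receptor`, with anything unrecognized mapped to `other`.
#'
#' @param path Path to a CSV file with header
#'   `interaction_name,ligand,receptor,annotation`.
#' @param source_label Optional label recorded as the `source_label` attribute.
#' @return A tibble of class `lr_database`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "interaction_name,ligand,receptor,annotation",
#'   "POSTN_ITGAV_ITGB5,POSTN,ITGAV+ITGB5,Secreted Signaling"
#' ), f)
#' db <- read_lr_database(f)
#' db$receptor_subunits[[1]]
#' @export
read_lr_database <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) abort(paste0("L-R database file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) abort("L-R database file is empty")
  lr_database(raw, source_label = source_label)
}

#' Build an L-R database from a data frame
#'
#' @param x Data frame with columns `interaction_name`, `ligand`, `receptor`
#'   and optionally `annotation`.
#' @param source_label Label stored as an attribute.
#' @return A tibble of class `lr_database`, deduplicated on the canonical
#'   (sorted-subunit) ligand/receptor key.
#' @export
lr_database <- function(x, source_label = "user") {
  need <- c("interaction_name", "ligand", "receptor")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("L-R database is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"annotation" %in% names(x)) x$annotation <- "other"
  db <- as_tibble(x[, c(need, "annotation")])
  db$ligand <- trimws(as.character(db$ligand))
  db$receptor <- trimws(as.character(db$receptor))
  db$interaction_name <- as.character(db$interaction_name)
  db$annotation <- normalize_annotation(db$annotation)
  db$ligand_subunits <- split_subunits(db$ligand)
  db$receptor_subunits <- split_subunits(db$receptor)
  bad <- purrr::map_lgl(db$ligand_subunits, ~ length(.x) == 0 || anyDuplicated(.x) > 0) |
    purrr::map_lgl(db$receptor_subunits, ~ length(.x) == 0 || anyDuplicated(.x) > 0)
  if (any(bad)) {
    abort(paste0(
      "invalid subunit lists (empty or duplicated symbols) for: ",
      paste(db$interaction_name[bad], collapse = ", ")
    ))
  }
  db <- db[!duplicated(canonical_key(db)), , drop = FALSE]
  db <- db[!duplicated(db$interaction_name), , drop = FALSE]
  structure(db, class = c("lr_database", class(db)), source_label = source_label)
}

split_subunits <- function(x) {
  purrr::map(strsplit(x, "+", fixed = TRUE), ~ trimws(.x[nzchar(trimws(.x))]))
}

normalize_annotation <- function(x) {
  key <- gsub("[^a-z]+", "_", tolower(trimws(as.character(x))))
  key <- gsub("^_|_$", "", key)
  out <- dplyr::case_when(
    key %in% c("secreted_signaling", "secreted") ~ "secreted_signaling",
    key %in% c("cell_cell_contact", "contact") ~ "cell_cell_contact",
    key %in% c("ecm_receptor", "ecm") ~ "ecm_receptor",
    TRUE ~ "other"
  )
  out[is.na(x)] <- "other"
  out
}

canonical_key <- function(db) {
  paste(
    purrr::map_chr(db$ligand_subunits, ~ paste(sort(.x), collapse = "+")),
    purrr::map_chr(db$receptor_subunits, ~ paste(sort(.x), collapse = "+")),
    sep = "->"
  )
}

#' Expand multi-subunit complexes into single-subunit interactions
#'
#' Every complex interaction is split into the cross product of its ligand
#' subunits and receptor subunits; the original complex entries are retained,
#' and the union is deduplicated on the canonical subunit key. Applying the
#' expansion twice gives the same database as applying it once.
#'
#' @param db An `lr_database`.
#' @return The expanded `lr_database`.
#' @examples
#' db <- lr_database(data.frame(
#'   interaction_name = "L_R1R2", ligand = "L", receptor = "R1+R2",
#'   annotation = "other"
#' ))
#' nrow(expand_multisubunit(db)) # complex + two single-subunit forms
#' @export
expand_multisubunit <- function(db) {
  stopifnot(inherits(db, "lr_database"))
  singles <- purrr::pmap_dfr(
    list(db$ligand_subunits, db$receptor_subunits, db$annotation),
    function(ls, rs, ann) {
      if (length(ls) == 1 && length(rs) == 1) return(NULL)
      grid <- expand.grid(ligand = ls, receptor = rs,
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      tibble(
        interaction_name = paste(grid$ligand, grid$receptor, sep = "_"),
        ligand = grid$ligand, receptor = grid$receptor, annotation = ann
      )
    }
  )
  if (is.null(singles) || nrow(singles) == 0) return(db)
  out <- bind_rows(
    as_tibble(db)[, c("interaction_name", "ligand", "receptor", "annotation")],
    singles
  )
  lr_database(out, source_label = attr(db, "source_label"))
}

#' Filter an L-R database by spot coverage on a slide
#'
#' Keeps interactions whose ligand and receptor genes are expressed in at
#' least a fraction `min_spot_fraction` of slide spots ("at least" is
#' inclusive). For complexes, every subunit must pass: a complex cannot be
#' formed unless all of its subunits are present.
#'
#' @param db An `lr_database`.
#' @param st A [spatial_expression()] object.
#' @param min_spot_fraction Minimum fraction of spots with a nonzero count,
#'   default 0.10.
#' @return The filtered `lr_database` (possibly empty).
#' @export
filter_by_coverage <- function(db, st, min_spot_fraction = 0.10) {
  stopifnot(inherits(db, "lr_database"), inherits(st, "spatial_expression"))
  if (ncol(st$values) < 1) abort("slide has no spots")
  cov <- Matrix::rowSums(st$values > 0) / ncol(st$values)
  gene_ok <- function(genes) {
    all(genes %in% names(cov)) && all(cov[genes] >= min_spot_fraction)
  }
  keep <- purrr::map2_lgl(
    db$ligand_subunits, db$receptor_subunits,
    ~ gene_ok(.x) && gene_ok(.y)
  )
  out <- db[keep, , drop = FALSE]
  structure(out, class = class(db), source_label = attr(db, "source_label"))
}

#' Write an L-R database to CSV
#'
#' @param db An `lr_database`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lr_database <- function(db, path) {
  readr::write_csv(
    as_tibble(db)[, c("interaction_name", "ligand", "receptor", "annotation")],
    path
  )
  invisible(path)
}
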
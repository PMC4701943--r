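#' Default column aliases for Imaris-style exports
#'
#' Maps spreadsheet headers as written by common segmentation exports onto
#' the canonical column names used throughout the package (`id`, `x`, `y`,
#' `z`, `region`, `Volume`, `Area`, `Length`, `MaxDiameter`,
#' `NeckMeanDiameter`, `MembranePotentialPeak`). Matching is
#' case-insensitive on the trimmed header. Extend or override via the
#' `aliases:` block of the YAML config.
#'
#' @return Named character vector: `names()` are canonical columns, values
#'   are regular expressions matched against incoming headers.
#' @export
imaris_alias_map <- function() {
  c(id = "^(id|spine ?id|name|collection)$",
    x = "^(x|pos(ition)? ?x|spine position x)$",
    y = "^(y|pos(ition)? ?y|spine position y)$",
    z = "^(z|pos(ition)? ?z|spine position z)$",
    region = "^(region|compartment|dendrite ?type)$",
    Volume = "^(volume|spine ?(part ?)?volume)$",
    Area = "^(area|spine ?(part ?)?area)$",
    Length = "^(length|spine ?(part ?)?length)$",
    MaxDiameter = "^(max ?diameter|spine ?max(imum)? ?diameter)$",
    NeckMeanDiameter = "^(neck ?mean ?diameter|spine ?neck ?mean ?diameter)$",
    MembranePotentialPeak = "^(membrane ?pot(ential)?\\.? ?peak)$")
}

.canonical_names <- function(nms, aliases) {
  out <- nms
  low <- tolower(trimws(nms))
  for (canon in names(aliases)) {
    hit <- grepl(aliases[[canon]], low)
    out[hit] <- canon
  }
  out
}

#' Feature columns of a spine table
#'
#' Every column other than the metadata set (`id`, `x`, `y`, `z`, `region`,
#' `spine_class`) is a feature available to queries.
#'
#' @param table a spine feature table (tibble).
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table) {
  setdiff(names(table), .meta_cols)
}

#' Read a per-spine feature table from CSV
#'
#' One row per spine. An `id` column is required (after alias resolution);
#' `x`/`y`/`z` positions and a `region` label are optional. Region values
#' outside `apical_main` / `apical_collateral` / `basal` become `unknown`.
#' Feature cells that do not parse as numbers become `NA` (flagged missing)
#' rather than errors; missing values are preserved, never imputed.
#'
#' @param path CSV file with a header row, comma-separated, `.` decimal.
#' @param aliases alias map, see [imaris_alias_map()].
#' @return Tibble with metadata columns first, then feature columns.
#' @export
read_feature_table <- function(path, aliases = imaris_alias_map()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(raw) <- .canonical_names(names(raw), aliases)
  if (!"id" %in% names(raw)) {
    abort(sprintf("schema error: no id column in %s (headers: %s)",
                  path, paste(names(raw), collapse = ", ")))
  }
  dup <- unique(raw$id[duplicated(raw$id)])
  if (length(dup)) {
    abort(sprintf("duplicate spine ids in %s: %s", path,
                  paste(utils::head(dup, 10), collapse = ", ")))
  }
  if (!"region" %in% names(raw)) raw$region <- "unknown"
  raw$region[!(raw$region %in% .regions) | is.na(raw$region)] <- "unknown"
  numcols <- setdiff(names(raw), c("id", "region", "spine_class"))
  raw[numcols] <- lapply(raw[numcols], function(col) {
    suppressWarnings(as.numeric(col))
  })
  meta <- intersect(.meta_cols, names(raw))
  dplyr::relocate(as_tibble(raw), dplyr::all_of(meta))
}

#' Write a per-spine feature table to CSV
#'
#' @param table tibble as returned by [read_feature_table()] or
#'   [generate_feature_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Write query scores joined to their spine records
#'
#' Produces the CSV a session would save after a query: one row per scored
#' spine with its metadata, features, raw and final scores and rank, in
#' rank order. Spines the query could not score (missing features) are
#' omitted; their ids live in `unscored_ids(scores)`.
#'
#' @param table the queried feature table.
#' @param scores a `spine_scores` object from [cell_distribution_query()] or
#'   [spine_comparison_query()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(table, scores, path) {
  sc <- tidy(scores)
  missing_ids <- setdiff(sc$id, table$id)
  if (length(missing_ids)) {
    abort(sprintf("scores reference ids absent from the table: %s",
                  paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  out <- dplyr::inner_join(sc, table, by = "id")
  out <- dplyr::arrange(out, .data$rank)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
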
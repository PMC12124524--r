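#' @importFrom rlang .data
#' @importFrom stats median mad sd cor quantile prcomp rnorm rlnorm runif
#'   kmeans pt wilcox.test setNames complete.cases
#' @importFrom utils read.csv read.delim write.csv
NULL

#' Mandatory metadata columns of a well feature table
#'
#' Every feature table carries these columns; all remaining numeric columns
#' are treated as morphological features.
#' @export
WELL_METADATA_COLS <- c(
  "run_id", "plate_id", "well", "donor_id", "drug_id",
  "dose_uM", "bioreplicate", "tech_replicate", "n_cells"
)

#' Construct a well feature table
#'
#' The central container of the screen: one row per unit (cell, well, or
#' aggregated donor-drug pair), metadata columns plus one numeric column per
#' morphological feature. Wells with `drug_id == "DMSO"` are the carrier
#' controls.
#'
#' @param data data frame with the columns in [WELL_METADATA_COLS] plus
#'   numeric feature columns.
#' @param feature_names character vector naming the feature columns; by
#'   default every non-metadata column.
#' @param level one of `"cell"`, `"well"`, `"donor_drug"`.
#' @return A `well_feature_table`: a tibble of `data` with attributes
#'   `feature_names` and `level`.
#' @export
well_table <- function(data, feature_names = NULL,
                       level = c("well", "cell", "donor_drug")) {
  level <- match.arg(level)
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(WELL_METADATA_COLS, names(data))
  if (length(missing_cols) > 0) {
    stop("missing mandatory metadata column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- setdiff(names(data), WELL_METADATA_COLS)
  }
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names", call. = FALSE)
  }
  if (!all(feature_names %in% names(data))) {
    stop("feature columns absent from data", call. = FALSE)
  }
  for (f in feature_names) {
    if (!is.numeric(data[[f]])) {
      stop("feature column not numeric: ", f, call. = FALSE)
    }
  }
  if (level != "cell") {
    key <- paste(data$run_id, data$plate_id, data$well, sep = "\r")
    if (level == "well" && anyDuplicated(key)) {
      stop("duplicate (run_id, plate_id, well) records", call. = FALSE)
    }
  }
  structure(data,
            feature_names = as.character(feature_names),
            level = level,
            class = c("well_feature_table", class(data)))
}

#' @export
print.well_feature_table <- function(x, ...) {
  cat(sprintf("<well_feature_table> level=%s, %d records, %d features\n",
              table_level(x), nrow(x), length(feature_names(x))))
  NextMethod()
}

#' Feature names of a well feature table
#' @param x a `well_feature_table`.
#' @export
feature_names <- function(x) attr(x, "feature_names")

#' Aggregation level of a well feature table
#' @param x a `well_feature_table`.
#' @export
table_level <- function(x) attr(x, "level")

#' Extract the feature matrix of a table
#' @param x a `well_feature_table`.
#' @param features optional subset of feature names.
#' @return numeric matrix, rows in table order.
#' @export
feature_matrix <- function(x, features = NULL) {
  if (is.null(features)) features <- feature_names(x)
  as.matrix(as.data.frame(x)[, features, drop = FALSE])
}

#' Replace the feature columns of a table, keeping metadata
#' @keywords internal
set_feature_matrix <- function(x, m) {
  stopifnot(nrow(m) == nrow(x), !is.null(colnames(m)))
  meta <- as.data.frame(x)[, WELL_METADATA_COLS, drop = FALSE]
  well_table(cbind(meta, as.data.frame(m)),
             feature_names = colnames(m), level = table_level(x))
}

#' Subset a table to a set of retained features
#'
#' @param x a `well_feature_table`.
#' @param features character vector of features to keep (e.g. the
#'   `retained` component of a filter report, or the report itself).
#' @export
select_features <- function(x, features) {
  if (inherits(features, "feature_filter_report")) features <- features$retained
  keep <- intersect(feature_names(x), features)
  if (length(keep) == 0) stop("no features retained", call. = FALSE)
  dat <- as.data.frame(x)[, c(WELL_METADATA_COLS, keep), drop = FALSE]
  out <- well_table(dat, feature_names = keep, level = table_level(x))
  if (inherits(x, "robust_z_table")) {
    out <- inherit_robust_z(out, x)
  }
  out
}

#' Read a well feature table from CSV/TSV
#'
#' Delimited text with the mandatory metadata columns (possibly under other
#' names, remapped via `schema`); every remaining numeric column is a
#' feature. Non-numeric cells in feature columns become missing values and
#' are counted in the attached load report.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated.
#' @param schema optional named character vector mapping file column names to
#'   canonical names, e.g. `c(drug = "drug_id")`.
#' @param level level of the stored table (default `"well"`).
#' @return a `well_feature_table` with attribute `load_report`
#'   (list with `n_coerced_missing`).
#' @export
read_feature_table <- function(path, schema = NULL, level = "well") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (grepl("\\.(tsv|txt)$", path)) read.delim else read.csv
  dat <- reader(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    idx <- match(names(schema), names(dat))
    if (anyNA(idx)) {
      stop("schema refers to absent column(s): ",
           paste(names(schema)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    names(dat)[idx] <- unname(schema)
  }
  missing_cols <- setdiff(WELL_METADATA_COLS, names(dat))
  if (length(missing_cols) > 0) {
    stop("missing mandatory metadata column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  feat_cols <- setdiff(names(dat), WELL_METADATA_COLS)
  n_coerced <- 0L
  for (f in feat_cols) {
    if (!is.numeric(dat[[f]])) {
      v <- suppressWarnings(as.numeric(dat[[f]]))
      n_coerced <- n_coerced + sum(is.na(v) & !is.na(dat[[f]]) &
                                     trimws(dat[[f]]) != "")
      dat[[f]] <- v
    }
  }
  out <- well_table(dat, feature_names = feat_cols, level = level)
  attr(out, "load_report") <- list(n_coerced_missing = n_coerced)
  out
}

#' Write a well feature table to CSV
#'
#' Feature values are written with 17 significant digits so that a
#' write/read round trip reproduces doubles bit-identically.
#'
#' @param x a `well_feature_table`.
#' @param path output path.
#' @export
write_feature_table <- function(x, path) {
  dat <- as.data.frame(x)
  for (f in feature_names(x)) {
    v <- sprintf("%.17g", dat[[f]])
    v[is.na(dat[[f]])] <- NA
    dat[[f]] <- v
  }
  write.csv(dat, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Aggregate a feature table to a coarser level
#'
#' Combines cell-level rows into one row per well, or well-level rows into
#' one row per (run, donor, drug) pair, using the median (default) or mean
#' of each feature. `n_cells` is summed over group members. Missing feature
#' values propagate (use `na_rm = TRUE` to drop them within groups).
#'
#' @param x a `well_feature_table`.
#' @param to_level target level, `"well"` or `"donor_drug"`.
#' @param statistic `"median"` (default) or `"mean"`.
#' @param na_rm drop missing values within groups before summarizing.
#' @return a `well_feature_table` at `to_level`.
#' @export
aggregate_features <- function(x, to_level = c("well", "donor_drug"),
                               statistic = c("median", "mean"),
                               na_rm = FALSE) {
  to_level <- match.arg(to_level)
  statistic <- match.arg(statistic)
  from <- table_level(x)
  ord <- c(cell = 1L, well = 2L, donor_drug = 3L)
  if (ord[[from]] > ord[[to_level]]) {
    stop("cannot aggregate from ", from, " to finer level ", to_level,
         call. = FALSE)
  }
  keys <- switch(to_level,
    well = c("run_id", "plate_id", "well", "donor_id", "drug_id",
             "dose_uM", "bioreplicate"),
    donor_drug = c("run_id", "donor_id", "drug_id", "dose_uM")
  )
  stat_fun <- if (statistic == "median") {
    function(v) median(v, na.rm = na_rm)
  } else {
    function(v) mean(v, na.rm = na_rm)
  }
  feats <- feature_names(x)
  dat <- as.data.frame(x)
  if (nrow(dat) == 0) stop("empty table", call. = FALSE)
  agg <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      .tech_replicate = min(.data$tech_replicate),
      .n_cells = sum(.data$n_cells),
      dplyr::across(dplyr::all_of(feats), stat_fun),
      .groups = "drop"
    )
  filled <- setdiff(WELL_METADATA_COLS, c(keys, "tech_replicate", "n_cells"))
  for (col in filled) agg[[col]] <- dat[[col]][match_key(agg, dat, keys)]
  agg$tech_replicate <- agg$.tech_replicate
  agg$n_cells <- agg$.n_cells
  agg$.tech_replicate <- agg$.n_cells <- NULL
  agg <- agg[, c(WELL_METADATA_COLS, feats)]
  out_level <- if (to_level == "donor_drug") "donor_drug" else "well"
  out <- well_table(agg, feature_names = feats, level = out_level)
  if (inherits(x, "robust_z_table")) out <- inherit_robust_z(out, x)
  out
}

match_key <- function(a, b, keys) {
  ka <- do.call(paste, c(a[keys], sep = "\r"))
  kb <- do.call(paste, c(b[keys], sep = "\r"))
  match(ka, kb)
}

#' Describe an assay run
#'
#' @param run_id run identifier, e.g. `"2021-02"`.
#' @param donors character vector of donor line ids.
#' @param drugs character vector of drug ids; `"DMSO"` entries are ignored by
#'   [count_pairs()].
#' @param doses optional named numeric vector of per-drug doses (µM).
#' @param n_plates,imaging_system optional metadata.
#' @return a `run_manifest` list.
#' @export
run_manifest <- function(run_id, donors, drugs, doses = NULL,
                         n_plates = NA_integer_, imaging_system = NA_character_) {
  stopifnot(length(donors) >= 1, length(drugs) >= 1)
  structure(
    list(run_id = run_id, donors = unique(as.character(donors)),
         drugs = unique(as.character(drugs)), doses = doses,
         n_plates = n_plates, imaging_system = imaging_system),
    class = "run_manifest"
  )
}

#' Number of drug-donor pairs declared by a run manifest
#'
#' The product of the number of donors and the number of non-control drugs;
#' e.g. 52 drugs across 28 donors gives 1,456 pairs.
#'
#' @param manifest a [run_manifest()].
#' @return integer pair count.
#' @export
count_pairs <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  n_drugs <- sum(manifest$drugs != "DMSO")
  length(manifest$donors) * n_drugs
}

#' Read a plate map CSV
#'
#' Expected columns: plate_id, well, donor_id, drug_id, dose_uM.
#' @param path file path.
#' @return tibble.
#' @export
read_plate_map <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "donor_id", "drug_id", "dose_uM")
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols) > 0) {
    stop("plate map missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(dat)
}

#' Well name for a 384-well plate position
#'
#' Positions 1..384 map row-major onto rows A-P and zero-padded columns
#' 01-24 ("A01" ... "P24").
#' @param pos integer position(s) in 1..384.
#' @export
well_name_384 <- function(pos) {
  stopifnot(all(pos >= 1 & pos <= 384))
  row <- LETTERS[(pos - 1L) %/% 24L + 1L]
  col <- (pos - 1L) %% 24L + 1L
  sprintf("%s%02d", row, col)
}
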
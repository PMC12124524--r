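#' Induction: the scalar drug-response statistic
#'
#' For each (donor, drug) pair, induction is the fraction of retained
#' features whose robust-z magnitude exceeds `sigma` (default 2, i.e. more
#' than two standard deviations away from the DMSO control). Missing feature
#' values are excluded from both numerator and denominator. DMSO rows are
#' not scored.
#'
#' @param z a `robust_z_table` aggregated to `donor_drug` level (one feature
#'   vector per donor-drug pair).
#' @param sigma exceedance cutoff in robust-z units (default 2).
#' @return an `induction_matrix`: list with `values` (donors x drugs matrix
#'   in \[0, 1\]), `sigma`, and `n_features_used`.
#' @export
induction <- function(z, sigma = 2) {
  stopifnot(inherits(z, "well_feature_table"))
  if (table_level(z) != "donor_drug") {
    stop("induction expects a donor_drug-level table; aggregate first",
         call. = FALSE)
  }
  if (length(feature_names(z)) == 0) stop("zero retained features",
                                          call. = FALSE)
  trt <- z[z$drug_id != "DMSO", , drop = FALSE]
  vals <- feature_matrix(z)[z$drug_id != "DMSO", , drop = FALSE]
  donors <- sort(unique(trt$donor_id))
  drugs <- sort(unique(trt$drug_id))
  m <- matrix(NA_real_, length(donors), length(drugs),
              dimnames = list(donors, drugs))
  frac <- rowMeans(abs(vals) > sigma, na.rm = TRUE)
  m[cbind(trt$donor_id, trt$drug_id)] <- frac
  structure(list(values = m, sigma = sigma,
                 n_features_used = length(feature_names(z))),
            class = "induction_matrix")
}

#' @export
print.induction_matrix <- function(x, ...) {
  cat(sprintf("<induction_matrix> %d donors x %d drugs, sigma=%g, %d features\n",
              nrow(x$values), ncol(x$values), x$sigma, x$n_features_used))
  invisible(x)
}

#' Euclidean distance of each donor-drug profile to the donor's DMSO profile
#'
#' Distances are computed within each run between a pair's aggregated
#' feature vector and the same donor's aggregated DMSO vector, over the
#' supplied (typically Spearman-filtered) features. Per drug, the mean,
#' sample SD and CoV (= SD/mean) of the distance across donors summarize how
#' variable the response is in the cohort.
#'
#' @param x a `donor_drug`-level `well_feature_table` (usually robust-z).
#' @param features optional feature subset.
#' @return a `distance_table`: list with `pairs` (tibble: run_id, donor_id,
#'   drug_id, distance; `NA` where the donor lacks a DMSO vector) and
#'   `per_drug` (tibble: drug_id, mean, sd, cov across donors).
#' @export
distance_to_control <- function(x, features = NULL) {
  stopifnot(inherits(x, "well_feature_table"))
  if (table_level(x) != "donor_drug") {
    stop("distance_to_control expects a donor_drug-level table", call. = FALSE)
  }
  if (is.null(features)) features <- feature_names(x)
  vals <- feature_matrix(x, features)
  key <- paste(x$run_id, x$donor_id, sep = "\r")
  dmso_idx <- which(x$drug_id == "DMSO")
  dmso_of <- setNames(dmso_idx, key[dmso_idx])
  trt_idx <- which(x$drug_id != "DMSO")
  dist <- vapply(trt_idx, function(i) {
    j <- dmso_of[key[i]]
    if (is.na(j)) return(NA_real_)
    sqrt(sum((vals[i, ] - vals[j, ])^2))
  }, numeric(1))
  pairs <- tibble::tibble(run_id = x$run_id[trt_idx],
                          donor_id = x$donor_id[trt_idx],
                          drug_id = x$drug_id[trt_idx],
                          distance = dist)
  per_drug <- pairs |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(mean = mean(.data$distance, na.rm = TRUE),
                     sd = sd(.data$distance, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(cov = ifelse(.data$mean > 0, .data$sd / .data$mean, NA_real_))
  structure(list(pairs = pairs, per_drug = per_drug),
            class = "distance_table")
}

#' Drug-drug correlation of induction patterns across donors
#'
#' Correlates the columns of an induction matrix (one induction value per
#' donor) for a chosen drug subset, over pairwise-complete donor sets. Drugs
#' with constant induction across donors have undefined correlations,
#' reported as `NA`.
#'
#' @param im an [induction()] result.
#' @param drugs optional drug subset (default all).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_donors minimum complete donors required per pair (default 3).
#' @return symmetric drugs x drugs correlation matrix with unit diagonal.
#' @export
induction_correlation <- function(im, drugs = NULL,
                                  method = c("pearson", "spearman"),
                                  min_donors = 3) {
  stopifnot(inherits(im, "induction_matrix"))
  method <- match.arg(method)
  v <- im$values
  if (!is.null(drugs)) {
    missing_drugs <- setdiff(drugs, colnames(v))
    if (length(missing_drugs) > 0) {
      stop("drug(s) not in induction matrix: ",
           paste(missing_drugs, collapse = ", "), call. = FALSE)
    }
    v <- v[, drugs, drop = FALSE]
  }
  n_ok <- crossprod(!is.na(v))
  if (any(n_ok < min_donors)) {
    stop("some drug pairs share fewer than ", min_donors, " donors",
         call. = FALSE)
  }
  cc <- suppressWarnings(cor(v, method = method,
                             use = "pairwise.complete.obs"))
  diag(cc) <- 1
  cc
}

#' Stratify donors into high and low responders for one drug
#'
#' Donors are ranked by induction for the drug (descending), ties broken by
#' donor id in lexicographic order; the top `k` are the high responders and
#' the bottom `k` the low responders.
#'
#' @param im an [induction()] result.
#' @param drug_id drug to stratify on.
#' @param k number of donors per stratum; must be at most half the donors
#'   with an induction value for this drug.
#' @return a `responder_stratification`: list with `drug_id`, `ranking`
#'   (tibble: donor_id, induction, rank), `high`, `low`, `k`, and
#'   `tie_policy`.
#' @export
stratify_responders <- function(im, drug_id, k) {
  stopifnot(inherits(im, "induction_matrix"))
  if (!drug_id %in% colnames(im$values)) {
    stop("drug not in induction matrix: ", drug_id, call. = FALSE)
  }
  v <- im$values[, drug_id]
  v <- v[!is.na(v)]
  if (k > floor(length(v) / 2)) {
    stop(sprintf("k = %d exceeds floor(n_donors/2) = %d", k,
                 floor(length(v) / 2)), call. = FALSE)
  }
  ord <- order(-v, names(v))
  ranking <- tibble::tibble(donor_id = names(v)[ord],
                            induction = unname(v[ord]),
                            rank = seq_along(v))
  high <- if (k > 0) ranking$donor_id[seq_len(k)] else character()
  low <- if (k > 0) rev(ranking$donor_id)[seq_len(k)] else character()
  structure(
    list(drug_id = drug_id, ranking = ranking, high = high, low = sort(low),
         k = k, tie_policy = "descending induction, ties by donor_id"),
    class = "responder_stratification"
  )
}

#' 2-D embedding of donor-drug profiles
#'
#' Projects the (filtered) feature matrix of a donor-drug-level table to two
#' dimensions for visualization: PCA (with variance explained) or UMAP
#' (n_neighbours 15, min_dist 0.01, cosine metric by default, matching the
#' screen's visualization settings; requires the `uwot` package).
#'
#' @param x a `donor_drug`-level `well_feature_table`.
#' @param method `"pca"` or `"umap"`.
#' @param features optional feature subset.
#' @param n_neighbors,min_dist,metric UMAP parameters.
#' @param seed seed for UMAP reproducibility.
#' @return tibble with run_id, donor_id, drug_id, dim1, dim2; for PCA the
#'   attribute `variance_explained` holds per-component fractions.
#' @export
embed_profiles <- function(x, method = c("pca", "umap"), features = NULL,
                           n_neighbors = 15, min_dist = 0.01,
                           metric = "cosine", seed = 1) {
  stopifnot(inherits(x, "well_feature_table"))
  method <- match.arg(method)
  if (is.null(features)) features <- feature_names(x)
  vals <- feature_matrix(x, features)
  vals <- vals[, colSums(is.na(vals)) == 0, drop = FALSE]
  out <- tibble::tibble(run_id = x$run_id, donor_id = x$donor_id,
                        drug_id = x$drug_id)
  if (method == "pca") {
    pc <- prcomp(vals, center = TRUE, scale. = FALSE)
    out$dim1 <- pc$x[, 1]
    out$dim2 <- if (ncol(pc$x) >= 2) pc$x[, 2] else 0
    attr(out, "variance_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  } else {
    if (!requireNamespace("uwot", quietly = TRUE)) {
      stop("the uwot package is required for UMAP embeddings", call. = FALSE)
    }
    if (nrow(vals) <= n_neighbors) {
      stop(sprintf(
        "%d profiles <= n_neighbors (%d); reduce n_neighbors or use PCA",
        nrow(vals), n_neighbors), call. = FALSE)
    }
    set.seed(seed)
    um <- uwot::umap(vals, n_neighbors = n_neighbors, min_dist = min_dist,
                     metric = metric, n_threads = 1)
    out$dim1 <- um[, 1]
    out$dim2 <- um[, 2]
  }
  out
}
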
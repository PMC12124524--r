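#' First Wasserstein (Earth Mover) distance between two 1-D samples
#'
#' Empirical distributions with uniform weights, computed by the
#' sorted-quantile formulation: the integral over u in (0, 1] of
#' |Qa(u) - Qb(u)|, where Q are the empirical quantile functions. Handles
#' unequal sample sizes naturally and is symmetric in its arguments.
#'
#' @param a,b non-empty numeric vectors (missing values dropped).
#' @return non-negative scalar distance.
#' @export
emd_1d <- function(a, b) {
  a <- sort(a[!is.na(a)])
  b <- sort(b[!is.na(b)])
  if (length(a) == 0 || length(b) == 0) {
    stop("emd_1d requires non-empty samples", call. = FALSE)
  }
  na <- length(a)
  nb <- length(b)
  u <- sort(unique(c(seq_len(na) / na, seq_len(nb) / nb)))
  du <- diff(c(0, u))
  qa <- a[pmin(na, ceiling(u * na - 1e-9))]
  qb <- b[pmin(nb, ceiling(u * nb - 1e-9))]
  sum(du * abs(qa - qb))
}

#' Compare two assay runs feature by feature
#'
#' For every (drug, donor) pair shared between two normalized runs, computes
#' the Earth Mover Distance between the runs' well-level robust-z value
#' distributions, feature by feature. DMSO wells of donors present in both
#' runs provide the reference: their cross-run EMDs define the band of
#' distances expected from assay noise alone (upper edge at
#' `band_quantile`). Per (drug, feature), the median EMD across donors is
#' reported, giving the per-drug EMD frequency distributions; induction
#' matrices restricted to the shared donors and drugs are paired and
#' correlated.
#'
#' @param run_a,run_b well-level `robust_z_table`s, each normalized against
#'   its own plates' DMSO wells.
#' @param features feature subset to compare (default: features retained in
#'   both runs).
#' @param sigma induction cutoff for the paired induction matrices.
#' @param band_quantile quantile of the DMSO-vs-DMSO EMDs that defines the
#'   reference band (default 0.95).
#' @return a `run_comparison`: list with `pair_emd` (tibble: drug_id,
#'   donor_id, feature, emd), `drug_feature_emd` (tibble: drug_id, feature,
#'   median_emd, within_band), `dmso_emd` (tibble: donor_id, feature, emd),
#'   `dmso_band` (scalar), `per_drug` (tibble summary), `induction_a`,
#'   `induction_b` (paired matrices over shared donors/drugs), and
#'   `induction_correlation` (Pearson over the paired entries).
#' @export
compare_runs <- function(run_a, run_b, features = NULL, sigma = 2,
                         band_quantile = 0.95) {
  stopifnot(inherits(run_a, "well_feature_table"),
            inherits(run_b, "well_feature_table"))
  if (is.null(features)) {
    features <- intersect(feature_names(run_a), feature_names(run_b))
  }
  if (length(features) == 0) stop("no shared features", call. = FALSE)
  key_a <- paste(run_a$donor_id, run_a$drug_id, sep = "\r")
  key_b <- paste(run_b$donor_id, run_b$drug_id, sep = "\r")
  shared <- intersect(unique(key_a), unique(key_b))
  shared_trt <- shared[!grepl("\rDMSO$", shared)]
  if (length(shared_trt) == 0) stop("no shared (donor, drug) pairs",
                                    call. = FALSE)
  va <- feature_matrix(run_a, features)
  vb <- feature_matrix(run_b, features)

  emd_block <- function(keys, keyvec_a, keyvec_b) {
    res <- vector("list", length(keys))
    for (i in seq_along(keys)) {
      ia <- which(keyvec_a == keys[i])
      ib <- which(keyvec_b == keys[i])
      e <- vapply(seq_along(features), function(f) {
        emd_1d(va[ia, f], vb[ib, f])
      }, numeric(1))
      parts <- strsplit(keys[i], "\r", fixed = TRUE)[[1]]
      res[[i]] <- tibble::tibble(donor_id = parts[1], drug_id = parts[2],
                                 feature = features, emd = e)
    }
    dplyr::bind_rows(res)
  }

  pair_emd <- emd_block(shared_trt, key_a, key_b)
  shared_dmso <- shared[grepl("\rDMSO$", shared)]
  if (length(shared_dmso) == 0) {
    stop("no shared DMSO donors to build the reference band", call. = FALSE)
  }
  dmso_emd <- emd_block(shared_dmso, key_a, key_b)
  dmso_band <- unname(quantile(dmso_emd$emd, band_quantile, na.rm = TRUE))

  drug_feature_emd <- pair_emd |>
    dplyr::group_by(.data$drug_id, .data$feature) |>
    dplyr::summarise(median_emd = median(.data$emd, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(within_band = .data$median_emd <= dmso_band)
  per_drug <- drug_feature_emd |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(median_emd = median(.data$median_emd),
                     frac_within_band = mean(.data$within_band),
                     .groups = "drop")

  donors <- unique(sub("\r.*$", "", shared_trt))
  drugs <- unique(sub("^.*\r", "", shared_trt))
  paired_induction <- function(run) {
    dd <- aggregate_features(run, "donor_drug")
    dd <- dd[dd$donor_id %in% donors &
               (dd$drug_id %in% drugs | dd$drug_id == "DMSO"), , drop = FALSE]
    im <- induction(select_features(dd, features), sigma = sigma)
    im$values[donors, drugs, drop = FALSE]
  }
  ia <- paired_induction(run_a)
  ib <- paired_induction(run_b)
  ok <- !is.na(ia) & !is.na(ib)
  ind_cor <- if (sum(ok) >= 3) cor(ia[ok], ib[ok]) else NA_real_

  structure(
    list(pair_emd = pair_emd, drug_feature_emd = drug_feature_emd,
         dmso_emd = dmso_emd, dmso_band = dmso_band, per_drug = per_drug,
         induction_a = ia, induction_b = ib,
         induction_correlation = ind_cor,
         band_quantile = band_quantile, features = features),
    class = "run_comparison"
  )
}

#' @export
print.run_comparison <- function(x, ...) {
  cat(sprintf(
    "<run_comparison> %d drugs x %d features; DMSO band %.3g; induction r = %.3f\n",
    length(unique(x$drug_feature_emd$drug_id)), length(x$features),
    x$dmso_band, x$induction_correlation))
  invisible(x)
}
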
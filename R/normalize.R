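#' Robust Z-score normalization against per-plate DMSO controls
#'
#' For each plate and feature, computes the median `mu` and median absolute
#' deviation `M` over that plate's DMSO wells, then scales every well as
#' `z = (x - mu) / (mad_scale * M)`. With the default
#' `mad_scale = 1.4826`, z is expressed as the number of standard deviations
#' from the DMSO control under approximate normality; `mad_scale = 1` gives
#' the unscaled MAD denominator.
#'
#' Features whose DMSO MAD is zero on any plate (constant controls) cannot be
#' scaled there; they are dropped from the output and listed in the returned
#' `flagged_features` attribute. All-missing features are flagged likewise.
#'
#' @param x a well-level `well_feature_table` of raw feature values.
#' @param mad_scale MAD consistency constant (default 1.4826).
#' @param min_dmso minimum DMSO wells required per plate (default 4).
#' @return a `robust_z_table` (a `well_feature_table` whose features hold z
#'   values) with attributes `plate_stats` (tibble: plate_id, feature, mu,
#'   mad), `mad_scale` and `flagged_features`.
#' @export
robust_z <- function(x, mad_scale = 1.4826, min_dmso = 4) {
  stopifnot(inherits(x, "well_feature_table"))
  if (table_level(x) != "well") stop("robust_z expects a well-level table",
                                     call. = FALSE)
  feats <- feature_names(x)
  vals <- feature_matrix(x)
  plates <- unique(x$plate_id)
  is_dmso <- x$drug_id == "DMSO"
  z <- vals
  stats_rows <- vector("list", length(plates))
  flagged <- character()
  for (i in seq_along(plates)) {
    p <- plates[i]
    on_plate <- x$plate_id == p
    ctrl <- vals[on_plate & is_dmso, , drop = FALSE]
    if (nrow(ctrl) == 0) {
      stop("plate has no DMSO wells: ", p, call. = FALSE)
    }
    if (nrow(ctrl) < min_dmso) {
      stop(sprintf("plate %s has %d DMSO wells (< min_dmso = %d)",
                   p, nrow(ctrl), min_dmso), call. = FALSE)
    }
    mu <- apply(ctrl, 2, median, na.rm = TRUE)
    mm <- apply(ctrl, 2, mad, constant = 1, na.rm = TRUE)
    bad <- !is.finite(mm) | mm == 0 | !is.finite(mu)
    flagged <- union(flagged, feats[bad])
    z[on_plate, ] <- sweep(sweep(vals[on_plate, , drop = FALSE], 2, mu),
                           2, mad_scale * mm, "/")
    stats_rows[[i]] <- tibble::tibble(plate_id = p, feature = feats,
                                      mu = unname(mu), mad = unname(mm))
  }
  keep <- setdiff(feats, flagged)
  if (length(keep) == 0) stop("all features flagged (zero DMSO MAD)",
                              call. = FALSE)
  out <- set_feature_matrix(x, z[, keep, drop = FALSE])
  attr(out, "plate_stats") <- dplyr::bind_rows(stats_rows)
  attr(out, "mad_scale") <- mad_scale
  attr(out, "flagged_features") <- flagged
  class(out) <- c("robust_z_table", class(out))
  out
}

# carry robust-z attributes through feature subsetting / aggregation
inherit_robust_z <- function(out, from) {
  attr(out, "plate_stats") <- attr(from, "plate_stats")
  attr(out, "mad_scale") <- attr(from, "mad_scale")
  attr(out, "flagged_features") <- attr(from, "flagged_features")
  if (!inherits(out, "robust_z_table")) {
    class(out) <- c("robust_z_table", class(out))
  }
  out
}

#' @rdname robust_z
#' @param z a `robust_z_table`.
#' @param tol numeric tolerance for the control contract.
#' @return `check_robust_z()`: (invisibly) a tibble of per-plate, per-feature
#'   DMSO median z and scaled MAD of z; errors if the contract (median 0,
#'   scaled MAD 1) is violated beyond `tol`.
#' @export
check_robust_z <- function(z, tol = 1e-9) {
  stopifnot(inherits(z, "robust_z_table"))
  ms <- attr(z, "mad_scale")
  vals <- feature_matrix(z)
  is_dmso <- z$drug_id == "DMSO"
  res <- lapply(unique(z$plate_id), function(p) {
    ctrl <- vals[z$plate_id == p & is_dmso, , drop = FALSE]
    tibble::tibble(
      plate_id = p, feature = colnames(ctrl),
      median_z = apply(ctrl, 2, median, na.rm = TRUE),
      scaled_mad_z = ms * apply(ctrl, 2, mad, constant = 1, na.rm = TRUE)
    )
  })
  res <- dplyr::bind_rows(res)
  dev <- max(abs(res$median_z), abs(res$scaled_mad_z - 1))
  if (dev > tol) {
    stop(sprintf("robust-z control contract violated (max deviation %g)",
                 dev), call. = FALSE)
  }
  invisible(res)
}

new_filter_report <- function(all_features, removed_by_cov = NULL,
                              removed_zero_mean = character(),
                              removed_by_spearman = NULL) {
  if (is.null(removed_by_cov)) {
    removed_by_cov <- tibble::tibble(feature = character(), cov = numeric())
  }
  if (is.null(removed_by_spearman)) {
    removed_by_spearman <- tibble::tibble(feature = character(),
                                          partner = character(), s = numeric())
  }
  removed <- unique(c(removed_by_cov$feature, removed_zero_mean,
                      removed_by_spearman$feature))
  structure(
    list(removed_by_cov = removed_by_cov,
         removed_zero_mean = removed_zero_mean,
         removed_by_spearman = removed_by_spearman,
         retained = setdiff(all_features, removed)),
    class = "feature_filter_report"
  )
}

#' @export
print.feature_filter_report <- function(x, ...) {
  cat(sprintf(
    "<feature_filter_report> retained %d; removed: %d by CoV, %d zero-mean, %d by Spearman\n",
    length(x$retained), nrow(x$removed_by_cov), length(x$removed_zero_mean),
    nrow(x$removed_by_spearman)))
  invisible(x)
}

#' Remove high-variability features by coefficient of variation
#'
#' CoV = sample SD / |mean| is computed per feature over the pooled raw-scale
#' DMSO wells of the table; features with CoV above `max_cov` are removed.
#' Features with zero mean (CoV undefined) are removed and reported
#' separately.
#'
#' @param x a well-level `well_feature_table` of raw (pre-normalization)
#'   values.
#' @param max_cov removal threshold (default 0.50).
#' @return a `feature_filter_report`; apply with [select_features()].
#' @export
filter_cov <- function(x, max_cov = 0.50) {
  stopifnot(inherits(x, "well_feature_table"))
  ref <- feature_matrix(x)[x$drug_id == "DMSO", , drop = FALSE]
  if (nrow(ref) < 3) stop("fewer than 3 DMSO reference wells", call. = FALSE)
  mu <- colMeans(ref, na.rm = TRUE)
  s <- apply(ref, 2, sd, na.rm = TRUE)
  zero_mean <- names(mu)[mu == 0 | !is.finite(mu)]
  cov <- s / abs(mu)
  drop <- names(cov)[!(names(cov) %in% zero_mean) & cov > max_cov]
  new_filter_report(
    feature_names(x),
    removed_by_cov = tibble::tibble(feature = drop, cov = unname(cov[drop])),
    removed_zero_mean = zero_mean
  )
}

#' Remove redundant features by Spearman correlation
#'
#' Pairwise Spearman correlations are computed over all wells; features are
#' visited in the table's column order and a feature is dropped iff its
#' absolute correlation with an earlier *retained* feature exceeds
#' `max_abs_s`. The greedy fixed-order pass makes the retained set
#' deterministic and leaves no retained pair above the threshold.
#'
#' @param x a `well_feature_table` (typically robust-z normalized).
#' @param max_abs_s threshold on |Spearman| (default 0.98).
#' @return a `feature_filter_report` recording each dropped feature and the
#'   retained partner that triggered the drop.
#' @export
filter_spearman <- function(x, max_abs_s = 0.98) {
  stopifnot(inherits(x, "well_feature_table"))
  if (nrow(x) < 2) stop("need at least 2 wells", call. = FALSE)
  feats <- feature_names(x)
  if (length(feats) == 1) return(new_filter_report(feats))
  sc <- cor(feature_matrix(x), method = "spearman",
            use = "pairwise.complete.obs")
  retained <- feats[1]
  dropped <- character()
  partner <- character()
  sval <- numeric()
  for (f in feats[-1]) {
    s <- sc[f, retained]
    s[is.na(s)] <- 0
    hit <- which(abs(s) > max_abs_s)
    if (length(hit) > 0) {
      dropped <- c(dropped, f)
      partner <- c(partner, retained[hit[1]])
      sval <- c(sval, s[hit[1]])
    } else {
      retained <- c(retained, f)
    }
  }
  new_filter_report(
    feats,
    removed_by_spearman = tibble::tibble(feature = dropped, partner = partner,
                                         s = sval)
  )
}
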
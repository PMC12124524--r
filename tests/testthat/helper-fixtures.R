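# fixture builders and independent oracles shared across tests

# minimal well-level table: one plate, explicit feature values
# features: named list of numeric vectors (one value per well)
make_plate_table <- function(drug_id, features, donor_id = "d1",
                             plate_id = "p1", run_id = "r1") {
  n <- length(drug_id)
  meta <- tibble::tibble(
    run_id = run_id, plate_id = plate_id, well = well_name_384(seq_len(n)),
    donor_id = rep_len(donor_id, n), drug_id = drug_id,
    dose_uM = ifelse(drug_id == "DMSO", 0, 5),
    bioreplicate = 1L, tech_replicate = seq_len(n), n_cells = 100L
  )
  well_table(cbind(meta, tibble::as_tibble(lapply(features, rep_len, n))),
             feature_names = names(features), level = "well")
}

# donor_drug-level table straight from a feature matrix (rows = pairs)
make_pair_table <- function(donor_id, drug_id, m) {
  n <- length(donor_id)
  meta <- tibble::tibble(
    run_id = "r1", plate_id = "p1", well = well_name_384(seq_len(n)),
    donor_id = donor_id, drug_id = drug_id,
    dose_uM = ifelse(drug_id == "DMSO", 0, 5),
    bioreplicate = 1L, tech_replicate = 1L, n_cells = 100L
  )
  well_table(cbind(meta, as.data.frame(m)), feature_names = colnames(m),
             level = "donor_drug")
}

# small screen config used throughout the suite: study-default effect and
# noise settings, scaled-down dimensions
small_screen_config <- function(...) {
  args <- utils::modifyList(
    list(n_donors = 8, n_drugs = 6, n_features = 60, n_moa_classes = 3,
         cells_per_well = c(50, 80)),
    list(...)
  )
  do.call(screen_sim_config, args)
}

# normalize + CoV filter + Spearman filter, as the pipeline prescribes
normalize_and_filter <- function(tab, mad_scale = 1.4826) {
  z <- robust_z(tab, mad_scale = mad_scale)
  z <- select_features(z, intersect(feature_names(z),
                                    filter_cov(tab)$retained))
  select_features(z, filter_spearman(z))
}

# independent EMD oracle 1: integral of |ECDF_a - ECDF_b| over x
# (closed form for 1-D optimal transport with uniform weights)
emd_ecdf_oracle <- function(a, b) {
  x <- sort(unique(c(a, b)))
  if (length(x) == 1) return(0)
  fa <- stats::ecdf(a)(x)
  fb <- stats::ecdf(b)(x)
  k <- seq_len(length(x) - 1)
  sum(abs(fa[k] - fb[k]) * diff(x))
}

# independent EMD oracle 2: brute-force assignment. Samples are replicated
# to a common multiset size L = lcm(na, nb) (uniform weights become unit
# masses) and the minimum mean |a - b[perm]| over all L! assignments is
# taken. Only feasible for small L.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

emd_bruteforce_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  l <- na * nb / g(na, nb)
  if (l > 7) return(NA_real_)
  aa <- rep(sort(a), each = l / na)
  bb <- rep(sort(b), each = l / nb)
  min(vapply(all_perms(l), function(p) mean(abs(aa - bb[p])), numeric(1)))
}

# Rand index between two partitions (pair-counting)
rand_index <- function(x, y) {
  n <- length(x)
  same_x <- outer(x, x, "==")[upper.tri(diag(n))]
  same_y <- outer(y, y, "==")[upper.tri(diag(n))]
  mean(same_x == same_y)
}

# balanced accuracy of recovered high/low responder sets vs planted labels
stratification_balanced_accuracy <- function(im, truth) {
  accs <- c()
  for (drug in colnames(im$values)) {
    lab <- truth$responder_label[, drug]
    k <- min(sum(lab == "high"), sum(lab == "low"))
    if (k == 0) next
    st <- stratify_responders(im, drug, k)
    accs <- c(accs, (mean(st$high %in% names(lab)[lab == "high"]) +
                       mean(st$low %in% names(lab)[lab == "low"])) / 2)
  }
  mean(accs)
}
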
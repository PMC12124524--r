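test_that("induction counts two-sided sigma exceedances over valid features", {
  m <- rbind(c(2.5, -2.5, 1.0, 0.0))
  colnames(m) <- paste0("f", 1:4)
  tab <- make_pair_table("d1", "drugA", m)
  expect_equal(induction(tab, sigma = 2)$values["d1", "drugA"], 0.5)
  # all-zero vector -> 0; sigma 0 with nonzero entries -> 1
  zero <- make_pair_table("d1", "drugA", matrix(0, 1, 4,
                                                dimnames = list(NULL, paste0("f", 1:4))))
  expect_equal(induction(zero, sigma = 2)$values[1], 0)
  nz <- make_pair_table("d1", "drugA", m[, 1:3, drop = FALSE])
  expect_equal(induction(nz, sigma = 0)$values[1], 1)
  # missing features leave both numerator and denominator: 1 of 2 valid
  mm <- rbind(c(3, NA, 0))
  colnames(mm) <- paste0("f", 1:3)
  expect_equal(induction(make_pair_table("d1", "drugA", mm))$values[1], 1 / 2)
})

test_that("induction is non-increasing in the sigma cutoff", {
  gs <- generate_screen(small_screen_config(), seed = 21)
  dd <- aggregate_features(normalize_and_filter(gs$table), "donor_drug")
  grid <- seq(0.5, 4, by = 0.5)
  vals <- lapply(grid, function(s) induction(dd, sigma = s)$values)
  for (i in seq_along(grid)[-1]) {
    expect_true(all(vals[[i]] <= vals[[i - 1]] + 1e-12))
  }
  expect_true(all(vals[[1]] >= 0 & vals[[1]] <= 1))
})

test_that("distance to control is Euclidean against the donor's DMSO vector", {
  m <- rbind(c(3, 4), c(0, 0), c(5, 5), c(5, 5))
  colnames(m) <- c("f1", "f2")
  tab <- make_pair_table(c("d1", "d1", "d2", "d2"),
                         c("drugA", "DMSO", "drugA", "DMSO"), m)
  dt <- distance_to_control(tab)
  expect_equal(dt$pairs$distance[dt$pairs$donor_id == "d1"], 5)
  expect_equal(dt$pairs$distance[dt$pairs$donor_id == "d2"], 0)
  # donor without a DMSO vector is reported missing
  tab2 <- make_pair_table(c("d1", "d1", "d3"), c("drugA", "DMSO", "drugA"),
                          m[1:3, ])
  expect_true(is.na(distance_to_control(tab2)$pairs$distance[2]))
})

test_that("per-drug distance summaries use the sample SD and CoV", {
  m <- matrix(c(1, 0, 1, 0, 1, 0), 6, 1, dimnames = list(NULL, "f1"))
  tab <- make_pair_table(paste0("d", c(1, 1, 2, 2, 3, 3)),
                         rep(c("drugA", "DMSO"), 3), m)
  pd <- distance_to_control(tab)$per_drug
  expect_equal(pd$mean, 1)
  expect_equal(pd$sd, 0)
  expect_equal(pd$cov, 0)
})

test_that("distance to control grows with the planted effect magnitude", {
  means <- vapply(c(1, 2, 4), function(strength) {
    cfg <- small_screen_config(signature_strength = strength)
    gs <- generate_screen(cfg, seed = 33)
    dd <- aggregate_features(robust_z(gs$table), "donor_drug")
    mean(distance_to_control(dd)$per_drug$mean)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("induction correlation handles collinearity and degeneracy", {
  v <- matrix(c(0.1, 0.2, 0.3,
                0.2, 0.4, 0.6,
                0.3, 0.2, 0.1,
                0.5, 0.5, 0.5), 3, 4,
              dimnames = list(paste0("d", 1:3), paste0("x", 1:4)))
  im <- structure(list(values = v, sigma = 2, n_features_used = 10),
                  class = "induction_matrix")
  cc <- induction_correlation(im)
  expect_equal(diag(cc), setNames(rep(1, 4), paste0("x", 1:4)))
  expect_equal(cc["x1", "x2"], 1)
  expect_equal(cc["x1", "x3"], -1)
  expect_equal(cc, t(cc))
  # constant induction vector: undefined, reported missing
  expect_true(all(is.na(cc["x4", c("x1", "x2", "x3")])))
  expect_error(induction_correlation(im, min_donors = 4), "fewer than 4")
  # drug subset and Spearman variant
  cs <- induction_correlation(im, drugs = c("x1", "x3"), method = "spearman")
  expect_equal(dim(cs), c(2, 2))
  expect_equal(cs["x1", "x3"], -1)
})

test_that("responder stratification ranks by induction with stated ties", {
  v <- matrix(c(0.8, 0.7, 0.2, 0.1), 4, 1,
              dimnames = list(letters[1:4], "drugA"))
  im <- structure(list(values = v, sigma = 2, n_features_used = 10),
                  class = "induction_matrix")
  st <- stratify_responders(im, "drugA", 2)
  expect_equal(st$high, c("a", "b"))
  expect_equal(st$low, c("c", "d"))
  expect_equal(st$ranking$donor_id, letters[1:4])
  # k = 0 gives empty strata
  st0 <- stratify_responders(im, "drugA", 0)
  expect_length(st0$high, 0)
  expect_length(st0$low, 0)
  # boundary tie resolved lexicographically and recorded
  vt <- matrix(c(0.5, 0.5, 0.1), 3, 1,
               dimnames = list(c("a", "b", "c"), "drugA"))
  imt <- structure(list(values = vt, sigma = 2, n_features_used = 10),
                   class = "induction_matrix")
  stt <- stratify_responders(imt, "drugA", 1)
  expect_equal(stt$high, "a")
  expect_match(stt$tie_policy, "donor_id")
  expect_error(stratify_responders(imt, "drugA", 2), "k = 2")
})

test_that("PCA embedding reports variance explained and is orientation-stable", {
  set.seed(14)
  base <- rnorm(10)
  m <- outer(base, c(1, 2, 3))  # rank 1
  colnames(m) <- paste0("f", 1:3)
  tab <- make_pair_table(paste0("d", 1:10), rep("drugA", 10), m)
  emb <- embed_profiles(tab, "pca")
  expect_equal(attr(emb, "variance_explained")[1], 1)
  # coordinates invariant (up to sign) under feature-order permutation
  m2 <- m[, c(3, 1, 2)]
  tab2 <- make_pair_table(paste0("d", 1:10), rep("drugA", 10), m2)
  emb2 <- embed_profiles(tab2, "pca")
  expect_equal(abs(emb2$dim1), abs(emb$dim1), tolerance = 1e-8)
})

test_that("UMAP separates well-separated MoA classes", {
  cfg <- small_screen_config(n_drugs = 9, n_features = 90, n_moa_classes = 3,
                             signature_strength = 6, magnitude_sdlog = 0.2)
  gs <- generate_screen(cfg, seed = 19)
  dd <- aggregate_features(normalize_and_filter(gs$table), "donor_drug")
  trt <- dd[dd$drug_id != "DMSO", ]
  emb <- embed_profiles(trt, "umap", n_neighbors = 15, seed = 42)
  labels <- factor(unname(gs$truth$moa_of_drug[emb$drug_id]))
  sil <- cluster::silhouette(as.integer(labels),
                             dist(cbind(emb$dim1, emb$dim2)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_error(embed_profiles(trt[1:10, ], "umap"), "n_neighbors")
})
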
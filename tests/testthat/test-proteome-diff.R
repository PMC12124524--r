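# deterministic quant matrix builder: values per (protein, run) supplied
make_quant <- function(values, lines, treatments, replicates = NULL) {
  n_runs <- length(lines)
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_len(n_runs), paste(lines, treatments),
                             FUN = seq_along)
  }
  ann <- tibble::tibble(
    run_id = sprintf("s%02d", seq_len(n_runs)),
    line_id = lines, treatment = treatments, replicate = replicates
  )
  m <- matrix(values, ncol = n_runs, byrow = TRUE,
              dimnames = list(sprintf("P%03d", seq_len(length(values) / n_runs)),
                              ann$run_id))
  protein_quant_matrix(m, ann)
}

test_that("valid-value filtering uses an inclusive fraction of runs", {
  m <- matrix(rnorm(36), 3, 12,
              dimnames = list(paste0("P", 1:3), paste0("s", 1:12)))
  m[1, 4:12] <- NA   # present in 3/12 < 1/3: removed
  m[2, 5:12] <- NA   # present in 4/12 = 1/3 exactly: kept ("at least")
  ann <- tibble::tibble(run_id = paste0("s", 1:12),
                        line_id = rep(c("l1", "l2"), each = 6),
                        treatment = rep(c("drug", "DMSO"), 6),
                        replicate = rep(1:3, 4))
  q <- protein_quant_matrix(m, ann)
  kept <- filter_valid(q)
  expect_setequal(rownames(kept$intensities), c("P2", "P3"))
})

test_that("imputation draws from the downshifted run distribution", {
  # a run with observed mean 25, sd 2 should impute around 25 - 1.8*2 = 21.4
  # with sd 0.3*2 = 0.6
  set.seed(90)
  n <- 4000
  obs <- rnorm(n, 25, 2)
  obs <- (obs - mean(obs)) / sd(obs) * 2 + 25  # exact moments
  m <- matrix(c(obs, rep(NA, 1000), rnorm(n + 1000, 25, 2)), ncol = 2)
  rownames(m) <- paste0("P", seq_len(nrow(m)))
  colnames(m) <- c("s1", "s2")
  ann <- tibble::tibble(run_id = c("s1", "s2"), line_id = "l1",
                        treatment = c("drug", "DMSO"), replicate = 1)
  q <- protein_quant_matrix(m, ann)
  qi <- impute_missing(q, seed = 3)
  imputed <- qi$intensities[n + 1:1000, 1]
  expect_lt(abs(mean(imputed) - (25 - 1.8 * 2)), 0.2)
  expect_lt(abs(sd(imputed) - 0.6), 0.1)
  # determinism and no-op on complete matrices
  expect_identical(qi$intensities, impute_missing(q, seed = 3)$intensities)
  expect_identical(impute_missing(qi, seed = 4)$intensities, qi$intensities)
})

test_that("median normalization equalizes run medians and is idempotent", {
  m <- matrix(c(19, 20, 21, 21, 22, 23), 3, 2,
              dimnames = list(paste0("P", 1:3), c("s1", "s2")))
  ann <- tibble::tibble(run_id = c("s1", "s2"), line_id = "l1",
                        treatment = c("drug", "DMSO"), replicate = 1)
  qn <- median_normalize(protein_quant_matrix(m, ann))
  expect_equal(unname(apply(qn$intensities, 2, median)), c(21, 21))
  expect_equal(median_normalize(qn)$intensities, qn$intensities)
  # already-equal medians: unchanged
  expect_equal(median_normalize(qn)$intensities, qn$intensities)
})

test_that("differential orientation, degenerate groups and antisymmetry", {
  q <- make_quant(
    c(10, 10, 10, 11, 11, 11,       # P001: clean shift of -1
      5, 5, 5, 5, 5, 5,             # P002: zero variance in both groups
      rnorm(6, 20, 0.1)),           # P003: null-ish
    lines = rep("l1", 6), treatments = rep(c("drug", "DMSO"), each = 3)
  )
  g1 <- q$annotations$run_id[q$annotations$treatment == "drug"]
  g2 <- q$annotations$run_id[q$annotations$treatment == "DMSO"]
  d <- differential(q, g1, g2, n_permutations = 100, seed = 1)
  expect_equal(d$log2fc[d$protein_id == "P001"], -1)
  expect_true(d$flag_zero_variance[d$protein_id == "P002"])
  expect_true(is.na(d$p[d$protein_id == "P002"]))
  # swapped labels negate every fold change exactly
  d2 <- differential(q, g2, g1, n_permutations = 0)
  expect_equal(d2$log2fc, -d$log2fc)
  # identical groups (same three columns duplicated): fc 0 and q near 1
  m <- matrix(rnorm(30, 20, 0.5), 10, 3)
  m <- cbind(m, m)
  dimnames(m) <- list(paste0("P", 1:10), paste0("s", 1:6))
  ann <- tibble::tibble(run_id = paste0("s", 1:6), line_id = "l1",
                        treatment = rep(c("drug", "DMSO"), each = 3),
                        replicate = rep(1:3, 2))
  did <- differential(protein_quant_matrix(m, ann),
                      paste0("s", 1:3), paste0("s", 4:6),
                      n_permutations = 100, seed = 2)
  expect_equal(did$log2fc, rep(0, 10))
  expect_true(all(did$q[!did$flag_zero_variance] > 0.9))
})

test_that("q values are in [0,1] and monotone in p rank", {
  set.seed(91)
  m <- matrix(rnorm(200 * 8, 20, 1), 200, 8,
              dimnames = list(paste0("P", 1:200), paste0("s", 1:8)))
  m[1:5, 1:4] <- m[1:5, 1:4] + 8
  ann <- tibble::tibble(run_id = paste0("s", 1:8), line_id = "l1",
                        treatment = rep(c("drug", "DMSO"), each = 4),
                        replicate = rep(1:4, 2))
  d <- differential(protein_quant_matrix(m, ann), paste0("s", 1:4),
                    paste0("s", 5:8), n_permutations = 200, seed = 5)
  expect_true(all(d$q >= 0 & d$q <= 1))
  ord <- order(d$p)
  expect_true(all(diff(d$q[ord]) >= -1e-12))
  expect_true(all(d$q[d$protein_id %in% paste0("P", 1:5)] < 0.05))
})

test_that("pooled drug-vs-DMSO analysis recovers an up-regulated set", {
  cfg <- small_screen_config(proteome = list(
    n_proteins = 1000, n_diff_shared = 30, n_diff_interaction = 0,
    effect_high = 1.0, effect_low = 1.0
  ))
  truth <- make_ground_truth(cfg, 70)
  drug <- "drug01"
  lab <- truth$responder_label[, drug]
  lines <- c(names(lab)[lab == "high"][1:2], names(lab)[lab == "low"][1:2])
  q <- generate_proteome(cfg, truth, lines, drug, seed = 71)
  qn <- median_normalize(impute_missing(filter_valid(q), seed = 72))
  expect_equal(length(select_runs(qn, treatment = drug)), 12)
  pv <- pooled_volcano(qn, drug = drug, n_permutations = 300, seed = 73)
  planted <- intersect(truth$differential_proteins$protein_id, pv$protein_id)
  hit <- pv[match(planted, pv$protein_id), ]
  expect_gte(mean(hit$log2fc > 0 & hit$q < 0.05), 0.9)
})

test_that("stratified gates follow the dual-p and fold-change rules", {
  # 2 high lines + 2 low lines x (drug, DMSO) x 3 runs; near-noiseless
  lines <- rep(c("h1", "h2", "lo1", "lo2"), each = 6)
  treatments <- rep(rep(c("drug", "DMSO"), each = 3), 4)
  is_drug <- treatments == "drug"
  in_high <- lines %in% c("h1", "h2")
  set.seed(92)
  base <- matrix(rnorm(3 * 24, 20, 0.01), 3, 24)
  base[1, is_drug & in_high] <- base[1, is_drug & in_high] + 1.0
  base[1, is_drug & !in_high] <- base[1, is_drug & !in_high] + 0.2
  base[2, is_drug] <- base[2, is_drug] + 0.5           # equal in both strata
  base[3, is_drug & in_high] <- base[3, is_drug & in_high] + 1.0
  base[3, is_drug & !in_high] <- base[3, is_drug & !in_high] + 0.2
  base[3, lines == "lo1"] <- 20                        # kill low-stratum p
  base[3, lines == "lo2"] <- rnorm(6, 20, 2)
  dimnames(base) <- list(paste0("P00", 1:3), sprintf("s%02d", 1:24))
  ann <- tibble::tibble(run_id = colnames(base), line_id = lines,
                        treatment = treatments, replicate = rep(1:3, 8))
  q <- protein_quant_matrix(base, ann)
  sd3 <- stratified_differential(q, c("h1", "h2"), c("lo1", "lo2"), "drug")
  r <- sd3$records
  expect_equal(r$log2fc_high_low, r$fc_high - r$fc_low)
  # P1: both p small, |0.8| > 0.263 -> survives
  expect_true(r$pass_p[1] && r$pass_fc[1])
  # P2: both p small but FC_high = FC_low -> fails the fc gate
  expect_true(r$pass_p[2])
  expect_false(r$pass_fc[2])
  expect_lt(abs(r$log2fc_high_low[2]), 0.05)
  # P3: low-stratum p large -> fails the dual-p gate regardless of FC
  expect_false(r$pass_p[3])
  expect_setequal(sd3$surviving$protein_id, "P001")
})

test_that("exchanging the strata negates the interaction fold change", {
  cfg <- small_screen_config(proteome = list(n_proteins = 300,
                                             n_diff_shared = 10,
                                             n_diff_interaction = 10))
  truth <- make_ground_truth(cfg, 75)
  drug <- "drug03"
  lab <- truth$responder_label[, drug]
  high <- names(lab)[lab == "high"][1:2]
  low <- names(lab)[lab == "low"][1:2]
  q <- generate_proteome(cfg, truth, c(high, low), drug, seed = 76)
  qn <- median_normalize(impute_missing(filter_valid(q), seed = 77))
  fwd <- stratified_differential(qn, high, low, drug)
  rev <- stratified_differential(qn, low, high, drug)
  expect_equal(rev$records$log2fc_high_low, -fwd$records$log2fc_high_low)
  expect_equal(rev$records$pass_p, fwd$records$pass_p)
  expect_error(stratified_differential(qn, c(high, "ghost"), low, drug),
               "ghost")
})

test_that("heatmap rows are z-scored and planted clusters are recovered", {
  # 2 lines up-in-high vs 2 up-in-low; 20 proteins per planted cluster
  set.seed(93)
  lines <- rep(c("h1", "h2", "lo1", "lo2"), each = 6)
  treatments <- rep(rep(c("drug", "DMSO"), each = 3), 4)
  n_prot <- 40
  m <- matrix(rnorm(n_prot * 24, 20, 0.05), n_prot, 24)
  up_high <- 1:20
  up_low <- 21:40
  in_high <- lines %in% c("h1", "h2")
  is_drug <- treatments == "drug"
  m[up_high, is_drug & in_high] <- m[up_high, is_drug & in_high] + 1
  m[up_low, is_drug & !in_high] <- m[up_low, is_drug & !in_high] + 1
  dimnames(m) <- list(sprintf("P%03d", 1:n_prot), sprintf("s%02d", 1:24))
  ann <- tibble::tibble(run_id = sprintf("s%02d", 1:24), line_id = lines,
                        treatment = treatments, replicate = rep(1:3, 8))
  q <- protein_quant_matrix(m, ann)
  recs <- tibble::tibble(protein_id = rownames(m))
  hm <- heatmap_matrix(recs, q, drug = "drug", k = 2, seed = 9)
  expect_equal(unname(rowMeans(hm)), rep(0, n_prot), tolerance = 1e-9)
  expect_equal(unname(apply(hm, 1, sd)), rep(1, n_prot), tolerance = 1e-9)
  planted <- rep(1:2, each = 20)
  expect_gte(rand_index(attr(hm, "cluster"), planted), 0.9)
  # degenerate rows (identical fold changes) are excluded with a warning
  m2 <- m
  m2[1, ] <- 20
  q2 <- protein_quant_matrix(m2, ann)
  expect_warning(hm2 <- heatmap_matrix(recs, q2, drug = "drug"),
                 "excluded")
  expect_equal(nrow(hm2), n_prot - 1)
})
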
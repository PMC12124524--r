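#' Configuration for the synthetic screen generator
#'
#' Defaults emulate the design of the large assay run: 28 donor lines by 52
#' drugs, 871 morphological features, 6 technical replicate wells per
#' condition in each of 2 bioreplicates, and 6,000-8,000 cells accruing per
#' donor-drug pair. Drugs fall into mechanism-of-action (MoA) classes; each
#' class perturbs a sparse signed subset of features, and each donor carries
#' a per-class positive response magnitude (log-normal), so donors are hyper-
#' or hypo-sensitive consistently across drugs that share a target.
#'
#' @param n_donors,n_drugs,n_features screen dimensions.
#' @param n_moa_classes number of MoA classes; drugs are assigned round-robin.
#' @param signature_sparsity fraction of features perturbed per MoA class.
#' @param signature_strength scale of nonzero signature entries, in units of
#'   the well-level noise SD.
#' @param magnitude_sdlog SD of the per-(donor, class) log-normal response
#'   magnitude (meanlog 0).
#' @param noise_sd well-level Gaussian noise SD.
#' @param plate_shift_sd SD of the per-plate baseline shift of each feature.
#' @param wells_per_condition technical replicate wells per donor-drug pair
#'   per bioreplicate.
#' @param bioreplicates number of bioreplicates (independent plate sets).
#' @param cells_per_well inclusive integer range for per-well cell counts.
#' @param dmso_wells_per_plate control wells reserved at the top of each
#'   384-well plate, assigned round-robin to the donors on that plate.
#' @param dose_uM nominal dose recorded for every drug.
#' @param responder_quantiles magnitude quantiles below/above which a donor
#'   is labelled a low/high responder for a drug (`c(low, high)`).
#' @param global_high_donor if `TRUE`, donor 1 gets a global magnitude
#'   multiplier (emulating a line with elevated induction to many drugs).
#' @param global_high_factor the multiplier used when `global_high_donor`.
#' @param cytotoxic_drugs drug ids whose wells get inflated variance and
#'   reduced cell counts (emulating cell death during incubation).
#' @param cytotoxic_var_inflation multiplier on the noise SD for those wells.
#' @param cytotoxic_cell_factor multiplier on cell counts for those wells.
#' @param proteome list of DIA-proteome generator settings: `n_proteins`
#'   (quantified proteins), `baseline_meanlog2`/`baseline_sdlog2` (log2
#'   intensity distribution), `noise_sd` (log2 run-to-run noise),
#'   `run_shift_sd` (per-run median offset), `n_diff_shared` and
#'   `n_diff_interaction` (planted drug-responsive proteins), `effect_high`
#'   and `effect_low` (log2 drug effects in high/low responder lines for
#'   interaction proteins; shared proteins use `effect_high` in all lines),
#'   `diff_abundance_min_q` (planted proteins are drawn above this abundance
#'   quantile, keeping them in the reliably quantified range),
#'   `missing_mid`/`missing_scale` (logistic intensity-dependent missingness).
#' @return a `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_donors = 28, n_drugs = 52, n_features = 871,
                              n_moa_classes = 13,
                              signature_sparsity = 0.25,
                              signature_strength = 3,
                              magnitude_sdlog = 0.5,
                              noise_sd = 1,
                              plate_shift_sd = 0.2,
                              wells_per_condition = 6,
                              bioreplicates = 2,
                              cells_per_well = c(500, 667),
                              dmso_wells_per_plate = 24,
                              dose_uM = 5,
                              responder_quantiles = c(0.25, 0.75),
                              global_high_donor = FALSE,
                              global_high_factor = 2,
                              cytotoxic_drugs = character(),
                              cytotoxic_var_inflation = 3,
                              cytotoxic_cell_factor = 0.4,
                              proteome = list()) {
  cfg <- list(
    n_donors = as.integer(n_donors), n_drugs = as.integer(n_drugs),
    n_features = as.integer(n_features),
    n_moa_classes = as.integer(n_moa_classes),
    signature_sparsity = signature_sparsity,
    signature_strength = signature_strength,
    magnitude_sdlog = magnitude_sdlog,
    noise_sd = noise_sd, plate_shift_sd = plate_shift_sd,
    wells_per_condition = as.integer(wells_per_condition),
    bioreplicates = as.integer(bioreplicates),
    cells_per_well = as.integer(cells_per_well),
    dmso_wells_per_plate = as.integer(dmso_wells_per_plate),
    dose_uM = dose_uM,
    responder_quantiles = responder_quantiles,
    global_high_donor = isTRUE(global_high_donor),
    global_high_factor = global_high_factor,
    cytotoxic_drugs = as.character(cytotoxic_drugs),
    cytotoxic_var_inflation = cytotoxic_var_inflation,
    cytotoxic_cell_factor = cytotoxic_cell_factor,
    proteome = utils::modifyList(list(
      n_proteins = 5895,
      baseline_meanlog2 = 25, baseline_sdlog2 = 2,
      noise_sd = 0.2, run_shift_sd = 0.1,
      n_diff_shared = 100, n_diff_interaction = 50,
      effect_high = 1.1, effect_low = 0.5,
      diff_abundance_min_q = 0.3,
      missing_mid = 21.5, missing_scale = 0.5
    ), proteome)
  )
  if (cfg$n_donors < 1 || cfg$n_drugs < 1) {
    stop("n_donors and n_drugs must be >= 1", call. = FALSE)
  }
  if (cfg$n_features < 1 || cfg$n_moa_classes < 1 ||
      cfg$wells_per_condition < 1 || cfg$bioreplicates < 1) {
    stop("all counts must be >= 1", call. = FALSE)
  }
  if (cfg$signature_sparsity <= 0 || cfg$signature_sparsity > 1) {
    stop("signature_sparsity must be in (0, 1]", call. = FALSE)
  }
  if (cfg$responder_quantiles[1] >= cfg$responder_quantiles[2]) {
    stop("responder_quantiles must be increasing", call. = FALSE)
  }
  structure(cfg, class = "screen_sim_config")
}

#' Draw the ground truth of a synthetic screen
#'
#' Fixes the drug-to-MoA map, the sparse signed feature signature of each
#' MoA class, the per-(donor, class) response magnitudes, the derived
#' high/mid/low responder label per (donor, drug), and the planted
#' differentially expressed protein set.
#'
#' @param config a [screen_sim_config()].
#' @param seed integer seed; the truth is deterministic given it.
#' @return a `ground_truth` list with elements `donors`, `drugs`,
#'   `moa_of_drug`, `signature_of_moa` (classes x features matrix),
#'   `magnitude` (donors x classes matrix), `responder_label` (donors x
#'   drugs character matrix), `baseline_log2` (per-protein log2 abundance),
#'   and `differential_proteins` (tibble with `protein_id`, `kind`,
#'   `effect_high`, `effect_low`).
#' @export
make_ground_truth <- function(config, seed) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(seed)
  donors <- sprintf("donor%02d", seq_len(config$n_donors))
  drugs <- sprintf("drug%02d", seq_len(config$n_drugs))
  classes <- sprintf("moa%02d", seq_len(config$n_moa_classes))
  moa_of_drug <- setNames(
    classes[(seq_len(config$n_drugs) - 1L) %% config$n_moa_classes + 1L],
    drugs
  )
  n_hit <- max(1L, round(config$signature_sparsity * config$n_features))
  sig <- matrix(0, config$n_moa_classes, config$n_features,
                dimnames = list(classes,
                                sprintf("f%04d", seq_len(config$n_features))))
  for (k in seq_len(config$n_moa_classes)) {
    idx <- sample.int(config$n_features, n_hit)
    # wide spread of per-feature effect sizes keeps induction graded in the
    # donor magnitude instead of saturating at the sparsity plateau
    sig[k, idx] <- sample(c(-1, 1), n_hit, replace = TRUE) *
      runif(n_hit, 0.2, 1) * config$signature_strength
  }
  mag <- matrix(rlnorm(config$n_donors * config$n_moa_classes,
                       meanlog = 0, sdlog = config$magnitude_sdlog),
                config$n_donors, config$n_moa_classes,
                dimnames = list(donors, classes))
  if (config$global_high_donor) mag[1, ] <- mag[1, ] * config$global_high_factor
  resp <- matrix("mid", config$n_donors, config$n_drugs,
                 dimnames = list(donors, drugs))
  for (d in drugs) {
    m <- mag[, moa_of_drug[[d]]]
    qs <- quantile(m, config$responder_quantiles, type = 7)
    resp[m <= qs[1], d] <- "low"
    resp[m >= qs[2], d] <- "high"
  }
  pr <- config$proteome
  n_diff <- pr$n_diff_shared + pr$n_diff_interaction
  stopifnot(n_diff <= pr$n_proteins)
  # per-protein baseline abundance is a property of the proteome; planted
  # drug-responsive proteins are drawn from the reliably quantified range
  # (above the missingness-prone low-abundance tail)
  baseline_log2 <- rnorm(pr$n_proteins, pr$baseline_meanlog2,
                         pr$baseline_sdlog2)
  eligible <- which(baseline_log2 >=
                      quantile(baseline_log2, pr$diff_abundance_min_q))
  stopifnot(n_diff <= length(eligible))
  diff_idx <- sample(eligible, n_diff)
  diff_prot <- tibble::tibble(
    protein_id = sprintf("P%05d", diff_idx),
    kind = rep(c("shared", "interaction"),
               c(pr$n_diff_shared, pr$n_diff_interaction)),
    effect_high = pr$effect_high,
    effect_low = rep(c(pr$effect_high, pr$effect_low),
                     c(pr$n_diff_shared, pr$n_diff_interaction))
  )
  structure(
    list(donors = donors, drugs = drugs, moa_of_drug = moa_of_drug,
         signature_of_moa = sig, magnitude = mag, responder_label = resp,
         differential_proteins = diff_prot, baseline_log2 = baseline_log2,
         seed = seed),
    class = "ground_truth"
  )
}

# Plate layout: the first dmso_wells_per_plate positions of every 384-well
# plate are DMSO controls (round-robin over the donors treated on that
# plate); remaining positions hold wells_per_condition-well blocks of
# donor-drug conditions. Each bioreplicate is an independent plate set.
build_layout <- function(config, truth, run_id) {
  w <- config$wells_per_condition
  n_ctrl <- config$dmso_wells_per_plate
  per_plate <- (384L - n_ctrl) %/% w
  if (per_plate < 1) stop("wells_per_condition too large for one plate",
                          call. = FALSE)
  conditions <- expand.grid(drug_id = truth$drugs, donor_id = truth$donors,
                            stringsAsFactors = FALSE)[, c(2, 1)]
  rows <- vector("list", config$bioreplicates)
  for (b in seq_len(config$bioreplicates)) {
    n_plates <- ceiling(nrow(conditions) / per_plate)
    plate_rows <- vector("list", n_plates)
    for (p in seq_len(n_plates)) {
      cond <- conditions[((p - 1L) * per_plate + 1L):
                           min(p * per_plate, nrow(conditions)), , drop = FALSE]
      plate_id <- sprintf("%s_B%d_P%02d", run_id, b, p)
      ctrl_donors <- rep_len(unique(cond$donor_id), n_ctrl)
      ctrl <- tibble::tibble(
        plate_id = plate_id, pos = seq_len(n_ctrl),
        donor_id = ctrl_donors, drug_id = "DMSO",
        tech_replicate = stats::ave(seq_len(n_ctrl), ctrl_donors,
                                    FUN = seq_along)
      )
      trt <- tibble::tibble(
        plate_id = plate_id,
        pos = n_ctrl + seq_len(nrow(cond) * w),
        donor_id = rep(cond$donor_id, each = w),
        drug_id = rep(cond$drug_id, each = w),
        tech_replicate = rep(seq_len(w), nrow(cond))
      )
      plate_rows[[p]] <- dplyr::bind_rows(ctrl, trt)
    }
    br <- dplyr::bind_rows(plate_rows)
    br$bioreplicate <- b
    rows[[b]] <- br
  }
  layout <- dplyr::bind_rows(rows)
  layout$well <- well_name_384(layout$pos)
  layout$run_id <- run_id
  layout$dose_uM <- ifelse(layout$drug_id == "DMSO", 0, config$dose_uM)
  layout
}

#' Generate a plate-structured synthetic Cell Painting screen
#'
#' Produces a well-level feature table with known ground truth. DMSO wells
#' are feature-wise Gaussian noise around per-plate baselines; drug wells add
#' `magnitude(donor, moa) * signature(moa)` to the baseline. Well values are
#' generated directly at the well level (a well stands for the summary of
#' its cells); `n_cells` is drawn per well and reduced for cytotoxic drugs,
#' whose wells also get inflated noise.
#'
#' @param config a [screen_sim_config()].
#' @param seed integer seed; output is deterministic given `(config, seed)`.
#' @param truth optional [make_ground_truth()] result to reuse across runs
#'   (e.g. to simulate replicate assay runs of the same biology); by default
#'   drawn from `seed`.
#' @param run_id run identifier stamped on every record.
#' @return list with `table` (a `well_feature_table`, level `"well"`) and
#'   `truth` (the `ground_truth` used).
#' @export
generate_screen <- function(config, seed, truth = NULL, run_id = "run1") {
  stopifnot(inherits(config, "screen_sim_config"))
  if (is.null(truth)) truth <- make_ground_truth(config, seed)
  set.seed(seed + 1L)
  layout <- build_layout(config, truth, run_id)
  n_wells <- nrow(layout)
  nf <- config$n_features
  feat_names <- colnames(truth$signature_of_moa)

  # per-feature raw-scale means: log-normal so a minority of features have
  # small means and fail the CoV <= 0.5 screen, as in real feature sets
  feature_mean <- rlnorm(nf, meanlog = log(8), sdlog = 0.6)
  plates <- unique(layout$plate_id)
  plate_shift <- matrix(rnorm(length(plates) * nf, 0, config$plate_shift_sd),
                        length(plates), nf,
                        dimnames = list(plates, feat_names))

  effect <- matrix(0, n_wells, nf)
  is_drug <- layout$drug_id != "DMSO"
  if (any(is_drug)) {
    moa <- truth$moa_of_drug[layout$drug_id[is_drug]]
    m <- truth$magnitude[cbind(layout$donor_id[is_drug], moa)]
    effect[is_drug, ] <- m * truth$signature_of_moa[moa, , drop = FALSE]
  }
  noise_sd <- rep(config$noise_sd, n_wells)
  cyto <- layout$drug_id %in% config$cytotoxic_drugs
  noise_sd[cyto] <- noise_sd[cyto] * config$cytotoxic_var_inflation

  values <- matrix(rep(feature_mean, each = n_wells), n_wells, nf) +
    plate_shift[layout$plate_id, , drop = FALSE] +
    effect +
    matrix(rnorm(n_wells * nf), n_wells, nf) * noise_sd
  colnames(values) <- feat_names

  n_cells <- sample(config$cells_per_well[1]:config$cells_per_well[2],
                    n_wells, replace = TRUE)
  n_cells[cyto] <- as.integer(round(n_cells[cyto] *
                                      config$cytotoxic_cell_factor))
  meta <- tibble::tibble(
    run_id = layout$run_id, plate_id = layout$plate_id, well = layout$well,
    donor_id = layout$donor_id, drug_id = layout$drug_id,
    dose_uM = layout$dose_uM, bioreplicate = layout$bioreplicate,
    tech_replicate = layout$tech_replicate, n_cells = n_cells
  )
  tab <- well_table(cbind(meta, tibble::as_tibble(values)),
                    feature_names = feat_names, level = "well")
  list(table = tab, truth = truth)
}

#' Generate a DIA-style protein quantification matrix
#'
#' Emulates label-free triplicate-run proteomics of selected lines treated
#' with one drug or DMSO: log-normal baseline intensities, planted
#' differential proteins shifted in drug runs by an effect scaled to the
#' line's responder label for that drug, per-run median offsets, and
#' intensity-dependent missingness (the lower the underlying intensity, the
#' likelier the value is missing).
#'
#' @param config a [screen_sim_config()] (its `proteome` settings are used).
#' @param truth a [make_ground_truth()] result.
#' @param lines donor ids to culture (must exist in `truth`).
#' @param drug drug id whose response is profiled.
#' @param n_runs_per_condition MS runs per line per condition (default 3).
#' @param seed integer seed.
#' @return a `protein_quant_matrix`: list with `intensities` (proteins x
#'   runs log2 matrix, `NA` = missing) and `annotations` (tibble: `run_id`,
#'   `line_id`, `treatment`, `replicate`).
#' @export
generate_proteome <- function(config, truth, lines, drug,
                              n_runs_per_condition = 3, seed = 1) {
  stopifnot(inherits(config, "screen_sim_config"),
            inherits(truth, "ground_truth"))
  unknown <- setdiff(lines, truth$donors)
  if (length(unknown) > 0) {
    stop("unknown line id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!drug %in% truth$drugs) stop("unknown drug id: ", drug, call. = FALSE)
  pr <- config$proteome
  set.seed(seed)
  proteins <- sprintf("P%05d", seq_len(pr$n_proteins))
  ann <- expand.grid(replicate = seq_len(n_runs_per_condition),
                     treatment = c(drug, "DMSO"), line_id = lines,
                     stringsAsFactors = FALSE)[, 3:1]
  ann <- tibble::as_tibble(ann)
  ann$run_id <- sprintf("%s_%s_r%d", ann$line_id, ann$treatment, ann$replicate)
  n_runs <- nrow(ann)

  stopifnot(length(truth$baseline_log2) == pr$n_proteins)
  baseline <- truth$baseline_log2
  effect_of_line <- function(line, dp) {
    switch(truth$responder_label[line, drug],
           high = dp$effect_high,
           low = dp$effect_low,
           mid = (dp$effect_high + dp$effect_low) / 2)
  }
  dp <- truth$differential_proteins
  didx <- match(dp$protein_id, proteins)
  shift <- matrix(0, pr$n_proteins, n_runs)
  for (j in seq_len(n_runs)) {
    if (ann$treatment[j] != "DMSO") {
      shift[didx, j] <- vapply(seq_len(nrow(dp)), function(i) {
        effect_of_line(ann$line_id[j], dp[i, ])
      }, numeric(1))
    }
  }
  run_shift <- rnorm(n_runs, 0, pr$run_shift_sd)
  x <- baseline + shift +
    matrix(rnorm(pr$n_proteins * n_runs, 0, pr$noise_sd), pr$n_proteins) +
    rep(run_shift, each = pr$n_proteins)
  p_missing <- stats::plogis((pr$missing_mid - x) / pr$missing_scale)
  x[matrix(runif(length(x)), nrow(x)) < p_missing] <- NA
  dimnames(x) <- list(proteins, ann$run_id)
  protein_quant_matrix(x, ann)
}
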
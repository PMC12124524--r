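#' Construct a protein quantification matrix
#'
#' Proteins x sample-runs label-free intensities on the log2 scale, with
#' explicit missing entries and per-run annotations.
#'
#' @param intensities numeric matrix (proteins x runs, log2), `NA` = missing;
#'   row names are protein ids, column names run ids.
#' @param annotations data frame with one row per run: `run_id`, `line_id`,
#'   `treatment`, `replicate`; `run_id` must match the matrix columns.
#' @return a `protein_quant_matrix`.
#' @export
protein_quant_matrix <- function(intensities, annotations) {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)),
            !is.null(colnames(intensities)))
  annotations <- tibble::as_tibble(annotations)
  need <- c("run_id", "line_id", "treatment", "replicate")
  missing_cols <- setdiff(need, names(annotations))
  if (length(missing_cols) > 0) {
    stop("annotations missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!identical(sort(annotations$run_id), sort(colnames(intensities)))) {
    stop("annotation run_ids do not match intensity columns", call. = FALSE)
  }
  annotations <- annotations[match(colnames(intensities),
                                   annotations$run_id), ]
  if (any(is.infinite(intensities))) {
    stop("intensities must be finite where present", call. = FALSE)
  }
  structure(list(intensities = intensities, annotations = annotations),
            class = "protein_quant_matrix")
}

#' @export
print.protein_quant_matrix <- function(x, ...) {
  cat(sprintf("<protein_quant_matrix> %d proteins x %d runs (%.1f%% missing)\n",
              nrow(x$intensities), ncol(x$intensities),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Runs matching a treatment/line selection
#' @param q a `protein_quant_matrix`.
#' @param treatment,lines optional filters.
#' @return character vector of run ids.
#' @export
select_runs <- function(q, treatment = NULL, lines = NULL) {
  ann <- q$annotations
  keep <- rep(TRUE, nrow(ann))
  if (!is.null(treatment)) keep <- keep & ann$treatment %in% treatment
  if (!is.null(lines)) keep <- keep & ann$line_id %in% lines
  ann$run_id[keep]
}

#' Keep proteins quantified in at least a fraction of runs
#'
#' A protein is retained iff it has valid (non-missing) values in at least
#' `min_frac` of the total sample runs (default one third, inclusive).
#'
#' @param q a `protein_quant_matrix`.
#' @param min_frac minimum valid fraction in (0, 1].
#' @return filtered `protein_quant_matrix`.
#' @export
filter_valid <- function(q, min_frac = 1 / 3) {
  stopifnot(inherits(q, "protein_quant_matrix"),
            min_frac > 0, min_frac <= 1)
  frac <- rowMeans(!is.na(q$intensities))
  protein_quant_matrix(q$intensities[frac >= min_frac, , drop = FALSE],
                       q$annotations)
}

#' Impute missing values from a downshifted normal distribution
#'
#' Per sample run, missing entries are drawn from
#' `Normal(mean_run - downshift * sd_run, (width * sd_run)^2)` where mean and
#' sd are over that run's observed log2 intensities — the standard
#' left-censored imputation for label-free proteomics, placing imputed
#' values in the low-intensity tail.
#'
#' @param q a `protein_quant_matrix` (typically after [filter_valid()]).
#' @param width,downshift distribution parameters in run-SD units.
#' @param seed integer seed; imputation is deterministic given it.
#' @return complete `protein_quant_matrix`.
#' @export
impute_missing <- function(q, width = 0.3, downshift = 1.8, seed = 1) {
  stopifnot(inherits(q, "protein_quant_matrix"))
  x <- q$intensities
  set.seed(seed)
  for (j in seq_len(ncol(x))) {
    obs <- x[, j][!is.na(x[, j])]
    if (length(obs) < 2) {
      stop("run with fewer than 2 observed values: ", colnames(x)[j],
           call. = FALSE)
    }
    miss <- which(is.na(x[, j]))
    if (length(miss) > 0) {
      x[miss, j] <- rnorm(length(miss),
                          mean = mean(obs) - downshift * sd(obs),
                          sd = width * sd(obs))
    }
  }
  protein_quant_matrix(x, q$annotations)
}

#' Median-normalize sample runs
#'
#' Subtracts each run's median log2 intensity and adds back the grand median
#' of the matrix, so all run medians are equal afterwards. Idempotent.
#'
#' @param q a complete `protein_quant_matrix` (post-imputation).
#' @return normalized `protein_quant_matrix`.
#' @export
median_normalize <- function(q) {
  stopifnot(inherits(q, "protein_quant_matrix"))
  x <- q$intensities
  med <- apply(x, 2, median, na.rm = TRUE)
  grand <- median(x, na.rm = TRUE)
  x <- sweep(x, 2, med) + grand
  protein_quant_matrix(x, q$annotations)
}

# vectorized two-sample t statistics per protein (rows)
row_t_stats <- function(x1, x2, var_equal = TRUE) {
  n1 <- ncol(x1)
  n2 <- ncol(x2)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  list(log2fc = m1 - m2, t = t, p = p, se = se)
}

#' Two-group differential protein expression with permutation FDR
#'
#' Per protein, a two-sample Student t-test (pooled variance by default)
#' between the `group1` and `group2` runs yields the log2 fold change
#' (group1 - group2), t statistic and two-sided p value. q values estimate
#' the false discovery rate by group-label permutation: for each protein's
#' |t|, q is the median over permutations of
#' (null tests with |t'| >= |t|) / (observed tests with |t'| >= |t|),
#' clipped to \[0, 1\] and made monotone non-decreasing in p-rank.
#'
#' Proteins with zero variance in both groups have no test; their p and q
#' are `NA` and they are flagged.
#'
#' @param q a normalized, complete `protein_quant_matrix`.
#' @param group1,group2 disjoint run-id sets, each of size >= 2.
#' @param n_permutations label permutations for the FDR (default 1000);
#'   `0` skips q-value estimation.
#' @param seed integer seed for the permutations.
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @return a `differential_result` tibble: protein_id, log2fc, t, p, q,
#'   flag_zero_variance; attribute `params` records the groups, permutation
#'   count and seed.
#' @export
differential <- function(q, group1, group2, n_permutations = 1000, seed = 1,
                         var_equal = TRUE) {
  stopifnot(inherits(q, "protein_quant_matrix"))
  if (length(intersect(group1, group2)) > 0) {
    stop("group1 and group2 overlap", call. = FALSE)
  }
  missing_runs <- setdiff(c(group1, group2), colnames(q$intensities))
  if (length(missing_runs) > 0) {
    stop("unknown run id(s): ", paste(missing_runs, collapse = ", "),
         call. = FALSE)
  }
  if (length(group1) < 2 || length(group2) < 2) {
    stop("each group needs at least 2 runs", call. = FALSE)
  }
  if (anyNA(q$intensities[, c(group1, group2)])) {
    stop("matrix has missing values; run filter_valid/impute_missing first",
         call. = FALSE)
  }
  x <- q$intensities[, c(group1, group2), drop = FALSE]
  n1 <- length(group1)
  obs <- row_t_stats(x[, seq_len(n1), drop = FALSE],
                     x[, -seq_len(n1), drop = FALSE], var_equal)
  zero_var <- !is.finite(obs$t)
  qval <- rep(NA_real_, nrow(x))
  if (n_permutations > 0) {
    set.seed(seed)
    abs_t <- abs(obs$t[!zero_var])
    ord <- order(abs_t, decreasing = TRUE)
    sorted_t <- abs_t[ord]
    n_obs_ge <- seq_along(sorted_t)   # observed tests with |t| >= each sorted |t|
    ratios <- matrix(NA_real_, length(sorted_t), n_permutations)
    n_cols <- ncol(x)
    for (b in seq_len(n_permutations)) {
      idx <- sample.int(n_cols)
      perm <- row_t_stats(x[, idx[seq_len(n1)], drop = FALSE],
                          x[, idx[-seq_len(n1)], drop = FALSE], var_equal)
      pt_sorted <- sort(abs(perm$t[is.finite(perm$t)]))
      # null tests with |t| >= threshold, via position in the sorted null
      n_null_ge <- length(pt_sorted) -
        findInterval(sorted_t, pt_sorted, left.open = TRUE)
      ratios[, b] <- n_null_ge / n_obs_ge
    }
    qv <- pmin(1, apply(ratios, 1, median))
    # enforce monotone non-decreasing q along increasing p (decreasing |t|)
    qv <- rev(cummin(rev(qv)))
    tmp <- rep(NA_real_, length(abs_t))
    tmp[ord] <- qv
    qval[!zero_var] <- tmp
  }
  out <- tibble::tibble(
    protein_id = rownames(x),
    log2fc = unname(obs$log2fc),
    t = unname(ifelse(zero_var, NA_real_, obs$t)),
    p = unname(ifelse(zero_var, NA_real_, obs$p)),
    q = qval,
    flag_zero_variance = unname(zero_var)
  )
  attr(out, "params") <- list(group1 = group1, group2 = group2,
                              orientation = "log2fc = mean(group1) - mean(group2)",
                              n_permutations = n_permutations, seed = seed,
                              var_equal = var_equal)
  class(out) <- c("differential_result", class(out))
  out
}

#' Pooled drug-vs-DMSO differential expression (volcano table)
#'
#' All drug-treated runs across the profiled lines are one group and all
#' DMSO runs the other (in the study design, 4 lines x 3 MS runs = 12 per
#' group); the result feeds a volcano plot of log2FC against -log10 p.
#'
#' @param q a normalized, complete `protein_quant_matrix`.
#' @param drug drug id; by default run groups are taken from the
#'   annotations (`treatment == drug` vs `treatment == "DMSO"`).
#' @param drug_runs,dmso_runs explicit run-id sets overriding the default.
#' @inheritParams differential
#' @return a `differential_result` (log2fc = drug - DMSO).
#' @export
pooled_volcano <- function(q, drug = NULL, drug_runs = NULL, dmso_runs = NULL,
                           n_permutations = 1000, seed = 1,
                           var_equal = TRUE) {
  if (is.null(drug_runs)) drug_runs <- select_runs(q, treatment = drug)
  if (is.null(dmso_runs)) dmso_runs <- select_runs(q, treatment = "DMSO")
  differential(q, drug_runs, dmso_runs, n_permutations = n_permutations,
               seed = seed, var_equal = var_equal)
}

#' Responder-stratified differential expression
#'
#' Computes drug-vs-DMSO fold changes and p values separately within the
#' high-responder lines (FC_high, P_high; all their drug runs vs all their
#' DMSO runs) and within the low-responder lines (FC_low, P_low), then
#' applies the two-stage gate: a protein passes `pass_p` iff
#' P_high <= p_max AND P_low <= p_max, and passes `pass_fc` iff
#' |log2FC_high-low| > fc_threshold, where
#' log2FC_high-low = FC_high - FC_low. The default threshold 0.263
#' corresponds to a 1.2-fold difference between the strata.
#'
#' @param q a normalized, complete `protein_quant_matrix`.
#' @param high_lines,low_lines line ids of the high/low responder strata.
#' @param drug drug id being profiled.
#' @param fc_threshold gate on |log2FC_high-low| (default 0.263).
#' @param p_max gate on both stratum p values (default 0.05).
#' @param n_permutations,seed,var_equal passed to [differential()]
#'   (permutation q values are reported per stratum but the gates use the
#'   t-test p values, as in the stratified procedure).
#' @return a `stratified_differential` list: `records` (tibble with
#'   protein_id, fc_high, p_high, fc_low, p_low, log2fc_high_low, pass_p,
#'   pass_fc), `surviving` (records passing both gates), and `params`.
#' @export
stratified_differential <- function(q, high_lines, low_lines, drug,
                                    fc_threshold = 0.263, p_max = 0.05,
                                    n_permutations = 0, seed = 1,
                                    var_equal = TRUE) {
  stopifnot(inherits(q, "protein_quant_matrix"))
  ann <- q$annotations
  for (ln in c(high_lines, low_lines)) {
    for (trt in c(drug, "DMSO")) {
      if (!any(ann$line_id == ln & ann$treatment == trt)) {
        stop(sprintf("missing condition: line %s, treatment %s", ln, trt),
             call. = FALSE)
      }
    }
  }
  d_high <- differential(q,
                         select_runs(q, treatment = drug, lines = high_lines),
                         select_runs(q, treatment = "DMSO", lines = high_lines),
                         n_permutations = n_permutations, seed = seed,
                         var_equal = var_equal)
  d_low <- differential(q,
                        select_runs(q, treatment = drug, lines = low_lines),
                        select_runs(q, treatment = "DMSO", lines = low_lines),
                        n_permutations = n_permutations, seed = seed,
                        var_equal = var_equal)
  records <- tibble::tibble(
    protein_id = d_high$protein_id,
    fc_high = d_high$log2fc, p_high = d_high$p,
    fc_low = d_low$log2fc, p_low = d_low$p,
    log2fc_high_low = d_high$log2fc - d_low$log2fc
  )
  records$pass_p <- !is.na(records$p_high) & !is.na(records$p_low) &
    records$p_high <= p_max & records$p_low <= p_max
  records$pass_fc <- abs(records$log2fc_high_low) > fc_threshold
  structure(
    list(records = records,
         surviving = records[records$pass_p & records$pass_fc, , drop = FALSE],
         params = list(high_lines = high_lines, low_lines = low_lines,
                       drug = drug, fc_threshold = fc_threshold,
                       p_max = p_max)),
    class = "stratified_differential"
  )
}

#' @export
print.stratified_differential <- function(x, ...) {
  cat(sprintf(
    "<stratified_differential> %s: %d proteins, %d pass p-gate, %d survive both gates\n",
    x$params$drug, nrow(x$records), sum(x$records$pass_p), nrow(x$surviving)))
  invisible(x)
}

#' Z-scored fold-change matrix for heatmap display
#'
#' For each surviving protein, computes the per-line drug-vs-DMSO log2 fold
#' change (mean over that line's replicate runs) and z-scores each protein
#' row to mean 0, SD 1. Rows with zero SD cannot be z-scored; they are
#' dropped with a warning. Optionally k-means clusters the rows (Euclidean
#' distance, fixed seed).
#'
#' @param records a `stratified_differential` (its surviving set) or a tibble
#'   with a `protein_id` column.
#' @param q the normalized `protein_quant_matrix` the records came from.
#' @param drug drug id (default: from the stratified params).
#' @param k optional number of k-means row clusters.
#' @param seed seed for k-means.
#' @return matrix (proteins x lines) of z-scored fold changes; if `k` is
#'   given, attribute `cluster` holds the per-row k-means labels.
#' @export
heatmap_matrix <- function(records, q, drug = NULL, k = NULL, seed = 1) {
  stopifnot(inherits(q, "protein_quant_matrix"))
  if (inherits(records, "stratified_differential")) {
    if (is.null(drug)) drug <- records$params$drug
    records <- records$surviving
  }
  if (nrow(records) == 0) stop("empty protein set", call. = FALSE)
  if (is.null(drug)) stop("drug must be given", call. = FALSE)
  proteins <- records$protein_id
  ann <- q$annotations
  lines <- unique(ann$line_id)
  fc <- sapply(lines, function(ln) {
    dr <- q$intensities[proteins, ann$line_id == ln & ann$treatment == drug,
                        drop = FALSE]
    ct <- q$intensities[proteins, ann$line_id == ln & ann$treatment == "DMSO",
                        drop = FALSE]
    rowMeans(dr) - rowMeans(ct)
  })
  fc <- matrix(fc, nrow = length(proteins),
               dimnames = list(proteins, lines))
  if (ncol(fc) < 2) stop("z-score undefined with a single line", call. = FALSE)
  row_sd <- apply(fc, 1, sd)
  if (any(row_sd == 0)) {
    warning(sum(row_sd == 0),
            " protein(s) with identical fold changes across lines excluded")
    fc <- fc[row_sd > 0, , drop = FALSE]
    if (nrow(fc) == 0) stop("no rows left to z-score", call. = FALSE)
    row_sd <- row_sd[row_sd > 0]
  }
  zm <- (fc - rowMeans(fc)) / row_sd
  if (!is.null(k)) {
    set.seed(seed)
    attr(zm, "cluster") <- kmeans(zm, centers = k, nstart = 10)$cluster
  }
  zm
}
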
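#' Per-subject cortex intensity reference
#'
#' Computes the arithmetic mean intensity of the contralateral renal
#' cortex on the T2-weighted image and on the unenhanced T1-weighted
#' image. These two means are the subject's calibration denominators:
#' T2W tumor voxels are divided by the T2 cortex mean, and all three
#' T1-family tumor voxel intensities by the unenhanced-T1 cortex mean.
#' Dividing by the same-subject cortex makes intensities comparable
#' across scanners and acquisition protocols, since any global
#' multiplicative scanner gain cancels in the ratio.
#'
#' All cortex voxels are included in the mean (no trimming or outlier
#' handling).
#'
#' @param study A `study_volumes` object from [load_study()].
#' @return A `cortex_reference`: `t2_cortex_mean`, `t1_cortex_mean`,
#'   `cortex_voxel_count`.
#' @export
compute_cortex_reference <- function(study) {
  stopifnot(inherits(study, "study_volumes"))
  m <- study$cortex_mask
  if (sum(m) < 1) stop("calibration error: empty cortex mask")
  t2_mean <- mean(study$volumes$t2w[m])
  t1_mean <- mean(study$volumes$t1w[m])
  if (!is.finite(t2_mean) || t2_mean <= 0)
    stop("calibration error: non-positive or non-finite T2W cortex mean (",
         format(t2_mean), ")")
  if (!is.finite(t1_mean) || t1_mean <= 0)
    stop("calibration error: non-positive or non-finite T1W cortex mean (",
         format(t1_mean), ")")
  structure(list(t2_cortex_mean = t2_mean,
                 t1_cortex_mean = t1_mean,
                 cortex_voxel_count = sum(m)),
            class = "cortex_reference")
}

#' Calibrate tumor voxel intensities against the cortex reference
#'
#' Produces the per-tumor voxel feature table: one row per tumor-mask
#' voxel with its (i, j, k) grid index and the four calibrated channel
#' intensities. T2W intensities are divided by the subject's T2 cortex
#' mean; T1W, arterial- and venous-phase contrast-enhanced T1W by the
#' unenhanced-T1 cortex mean. No clamping or rescaling is applied beyond
#' these ratios.
#'
#' @param study A `study_volumes` object.
#' @param ref A `cortex_reference` for the same subject.
#' @return A voxel feature table: data frame with columns `subject_id`,
#'   `i`, `j`, `k`, `c_t2`, `c_t1`, `c_t1art`, `c_t1ven`, carrying
#'   attributes `stage = "calibrated"` and `cohort`.
#' @export
calibrate <- function(study, ref) {
  stopifnot(inherits(study, "study_volumes"), inherits(ref, "cortex_reference"))
  if (sum(study$tumor_mask) < 1) stop("calibration error: empty tumor mask")
  idx <- which(study$tumor_mask, arr.ind = TRUE)
  colnames(idx) <- c("i", "j", "k")

  raw <- vapply(mri_channels(), function(ch) study$volumes[[ch]][study$tumor_mask],
                numeric(nrow(idx)))
  if (!all(is.finite(raw))) {
    bad <- which(!apply(is.finite(raw), 1, all))[1]
    stop(sprintf(
      "data error: non-finite tumor intensity at voxel (i=%d, j=%d, k=%d)",
      idx[bad, 1], idx[bad, 2], idx[bad, 3]))
  }

  denom <- c(ref$t2_cortex_mean, rep(ref$t1_cortex_mean, 3))
  feats <- sweep(raw, 2, denom, "/")
  colnames(feats) <- feature_cols()

  tab <- data.frame(subject_id = study$subject_id, idx, feats,
                    row.names = NULL, check.names = FALSE)
  attr(tab, "stage") <- "calibrated"
  attr(tab, "cohort") <- study$cohort
  tab
}

#' Extract the 4-column feature matrix from a voxel feature table
#' @param table A voxel feature table.
#' @return Numeric matrix, one row per voxel, columns in channel order.
#' @export
feature_matrix <- function(table) {
  as.matrix(table[, feature_cols(), drop = FALSE])
}

table_stage <- function(table) attr(table, "stage") %||% "unknown"
table_cohort <- function(table) attr(table, "cohort") %||% NA_character_

new_channel_stats <- function(mean, sd, n_voxels) {
  names(mean) <- feature_cols()
  names(sd) <- feature_cols()
  if (any(!is.finite(sd)) || any(sd <= 0))
    stop("degenerate-data error: zero or non-finite channel SD")
  structure(list(mean = mean, sd = sd, n_voxels = n_voxels),
            class = "channel_stats")
}

#' Fit pooled channel normalization statistics
#'
#' Pools all voxels of all supplied calibrated tables (voxel-level
#' pooling: large tumors contribute proportionally more voxels) and
#' computes the per-channel mean and population standard deviation
#' (divide by n). These statistics define the variance normalization
#' applied to every cohort, and must be fitted only on
#' training + validation subjects: a table tagged with the test cohort
#' raises an error, so held-out data can never leak into the
#' normalization.
#'
#' @param tables List of calibrated voxel feature tables.
#' @return A `channel_stats` object.
#' @export
fit_channel_stats <- function(tables) {
  if (!is.list(tables) || length(tables) == 0)
    stop("fit_channel_stats expects a non-empty list of calibrated tables")
  if (inherits(tables, "data.frame")) tables <- list(tables)
  for (tab in tables) {
    if (table_stage(tab) != "calibrated")
      stop("usage error: channel stats are fitted on stage=calibrated tables, got ",
           table_stage(tab))
    if (identical(table_cohort(tab), "test"))
      stop("leakage guard: test-cohort table passed to fit_channel_stats (",
           tab$subject_id[1], ")")
  }
  pooled <- do.call(rbind, lapply(tables, feature_matrix))
  if (nrow(pooled) < 2)
    stop("degenerate-data error: need >= 2 pooled voxels to fit channel stats")
  mu <- colMeans(pooled)
  sdev <- sqrt(colMeans(sweep(pooled, 2, mu)^2)) # population SD
  new_channel_stats(mu, sdev, nrow(pooled))
}

#' Variance-normalize a calibrated voxel feature table
#'
#' Replaces every channel value by (value - channel mean) / channel SD
#' using frozen statistics from [fit_channel_stats()]. Test-cohort
#' tables are normalized with the same training + validation statistics;
#' the statistics are never refitted downstream.
#'
#' @param table A calibrated voxel feature table.
#' @param stats A `channel_stats` object.
#' @return The table with `stage = "normalized"`.
#' @export
normalize_table <- function(table, stats) {
  stopifnot(inherits(stats, "channel_stats"))
  if (table_stage(table) != "normalized" && table_stage(table) != "calibrated")
    stop("usage error: cannot normalize a table of stage ", table_stage(table))
  if (table_stage(table) == "normalized")
    stop("usage error: table is already normalized")
  feats <- feature_matrix(table)
  feats <- sweep(sweep(feats, 2, stats$mean), 2, stats$sd, "/")
  table[, feature_cols()] <- feats
  attr(table, "stage") <- "normalized"
  table
}
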
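#' Default intra-tumor phenotype profiles
#'
#' One mixture of phenotype subpopulations per class, on the calibrated
#' intensity scale (cortex = 1 by construction). Sarcomatoid (sRCC)
#' subpopulations are hypointense on the three T1-family channels
#' (unenhanced, arterial, venous), reflecting poorly enhancing
#' fibrous/necrotic tissue; non-sarcomatoid (nsRCC) subpopulations are
#' hyperintense on the contrast-enhanced channels and get more
#' subpopulations, each with a wider intensity spread, reproducing the
#' "busier" activation maps of non-sarcomatoid tumors against the
#' sparser sarcomatoid fingerprints: a tight, poorly enhancing
#' sarcomatoid mixture occupies few SOM neurons, while the broader,
#' heterogeneously enhancing non-sarcomatoid mixture spreads its hits
#' over many.
#'
#' @return Named list (`sRCC`, `nsRCC`) of lists of profiles, each with
#'   `mean` and `sd` (length-4, channel order of [mri_channels()]) and a
#'   mixing `weight`.
#' @export
default_profiles <- function() {
  prof <- function(mean, sd, weight)
    list(mean = stats::setNames(mean, mri_channels()),
         sd = stats::setNames(sd, mri_channels()), weight = weight)
  list(
    sRCC = list(
      # one dominant, tightly distributed, poorly enhancing phenotype:
      # sarcomatoid hits concentrate on few neurons (sparse fingerprint)
      prof(c(0.90, 0.45, 0.50, 0.55), rep(0.02, 4), 0.85),
      prof(c(1.70, 0.55, 0.65, 0.60), rep(0.05, 4), 0.15)
    ),
    nsRCC = list(
      prof(c(1.20, 0.90, 1.80, 1.50), rep(0.15, 4), 0.25),
      prof(c(1.00, 1.05, 1.35, 1.60), rep(0.15, 4), 0.25),
      prof(c(1.50, 0.80, 2.10, 1.30), rep(0.15, 4), 0.175),
      prof(c(0.80, 1.10, 1.15, 1.05), rep(0.15, 4), 0.175),
      # broad necrotic/hemorrhagic component spanning phenotype space,
      # including the poorly enhancing region shared with sarcomatoid
      # tissue; this is what makes non-sarcomatoid fingerprints busier
      prof(c(1.10, 0.80, 1.20, 1.00), rep(0.45, 4), 0.15)
    )
  )
}

validate_profiles <- function(profiles) {
  stopifnot(setequal(names(profiles), c("sRCC", "nsRCC")))
  for (cl in names(profiles)) {
    w <- vapply(profiles[[cl]], `[[`, numeric(1), "weight")
    if (abs(sum(w) - 1) > 1e-9)
      stop("phantom configuration error: ", cl,
           " profile weights must sum to 1")
    for (p in profiles[[cl]])
      if (any(p$sd < 0) || length(p$mean) != 4 || length(p$sd) != 4)
        stop("phantom configuration error: profiles need 4 means and 4",
             " non-negative SDs")
  }
  invisible(profiles)
}

#' Synthetic phantom cohort configuration
#'
#' Describes a cohort of co-registered 4-channel phantom studies: grid
#' geometry, per-cohort subject counts per class, tumor volume range,
#' cortex intensity levels, per-subject multiplicative scanner gains
#' (one for the T2 channel, one shared by the three T1-family channels,
#' mirroring the single unenhanced-T1 cortex reference that calibrates
#' all three), additive Gaussian noise, and the class phenotype
#' mixtures. Tumor and cortex are disjoint ellipsoids; the pipeline only
#' ever sees masked voxel sets, so anatomical shape realism is
#' irrelevant downstream.
#'
#' @param dim Grid dimensions (voxels).
#' @param spacing Voxel spacing in mm.
#' @param subjects_per_class Named list/vector of subjects per class in
#'   each cohort (`training`, `validation`, `test`).
#' @param volume_range_cm3 Uniform draw range for tumor volume.
#' @param cortex_levels Raw cortex intensity per channel (before gain).
#' @param t2_gain_range,t1_gain_range Uniform draw ranges for the
#'   per-subject multiplicative scanner gains.
#' @param noise_sd Additive Gaussian noise SD in raw intensity units.
#' @param background_level Raw background intensity.
#' @param profiles Class phenotype mixtures; see [default_profiles()].
#' @param seed Integer seed; the whole cohort is a deterministic
#'   function of the configuration.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(dim = c(64L, 64L, 32L), spacing = c(2, 2, 2),
                           subjects_per_class = c(training = 8L,
                                                  validation = 3L,
                                                  test = 5L),
                           volume_range_cm3 = c(2, 15),
                           cortex_levels = c(t2w = 400, t1w = 300,
                                             t1w_ceart = 620,
                                             t1w_ceven = 560),
                           t2_gain_range = c(0.6, 1.8),
                           t1_gain_range = c(0.6, 1.8),
                           noise_sd = 5, background_level = 30,
                           profiles = default_profiles(), seed = 42L) {
  stopifnot(length(dim) == 3, all(dim >= 8), length(spacing) == 3,
            all(spacing > 0), all(t2_gain_range > 0),
            all(t1_gain_range > 0), noise_sd >= 0,
            all(volume_range_cm3 > 0),
            all(cortex_levels > 0),
            all(cohort_levels() %in% names(subjects_per_class)))
  validate_profiles(profiles)
  structure(list(dim = as.integer(dim), spacing = as.double(spacing),
                 subjects_per_class = subjects_per_class,
                 volume_range_cm3 = volume_range_cm3,
                 cortex_levels = cortex_levels,
                 t2_gain_range = t2_gain_range,
                 t1_gain_range = t1_gain_range,
                 noise_sd = noise_sd, background_level = background_level,
                 profiles = profiles, seed = as.integer(seed)),
            class = "phantom_config")
}

# logical ellipsoid mask on the configured grid, all lengths in mm
ellipsoid_mask <- function(dim, spacing, center_mm, semi_mm) {
  cx <- (seq_len(dim[1]) - 0.5) * spacing[1]
  cy <- (seq_len(dim[2]) - 0.5) * spacing[2]
  cz <- (seq_len(dim[3]) - 0.5) * spacing[3]
  dx2 <- ((cx - center_mm[1]) / semi_mm[1])^2
  dy2 <- ((cy - center_mm[2]) / semi_mm[2])^2
  dz2 <- ((cz - center_mm[3]) / semi_mm[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

write_nifti_vol <- function(arr, spacing, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Generate a synthetic phantom cohort on disk
#'
#' For each subject: draws a tumor volume and the two scanner gains;
#' places an ellipsoidal tumor and a disjoint ellipsoidal cortex on the
#' grid; samples every tumor voxel's calibrated 4-channel intensity from
#' the class's phenotype mixture; converts to raw scanner units by
#' multiplying the T2 channel by (T2 gain x cortex T2 level) and the
#' T1-family channels by (T1 gain x cortex unenhanced-T1 level); fills
#' the cortex with its configured levels times the same gains; adds
#' Gaussian noise; and writes the four NIfTI volumes, both masks, and a
#' manifest row. The recorded `tumor_volume_cm3` is the realized mask
#' volume (voxel count x voxel volume), so manifest and mask agree
#' exactly.
#'
#' Because tumor intensities are defined on the calibrated scale and the
#' cortex carries the same per-subject gains, calibration recovers the
#' configured phenotype profiles for any gain draw — exactly, when
#' `noise_sd = 0` and profile SDs are 0.
#'
#' The generation is a deterministic function of `(config, seed)`:
#' regenerating with the same configuration yields byte-identical files.
#'
#' @param config A `phantom_config`.
#' @param out_dir Output directory (created if needed).
#' @return The cohort manifest, as returned by [read_manifest()] on the
#'   freshly written `manifest.csv`.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  dims <- config$dim; spacing <- config$spacing
  fov <- dims * spacing
  voxel_cm3 <- prod(spacing) / 1000

  cortex_center <- c(0.22, 0.5, 0.5) * fov
  cortex_semi <- c(13, 11, 9)
  tumor_center <- c(0.68, 0.5, 0.5) * fov

  max_r <- (3 * max(config$volume_range_cm3) * 1000 / (4 * pi))^(1 / 3)
  tumor_semi_max <- max_r * c(1.2, 1, 1 / 1.2)
  if (any(tumor_center + tumor_semi_max > fov) ||
      any(tumor_center - tumor_semi_max < 0) ||
      any(cortex_center + cortex_semi > fov) ||
      any(cortex_center - cortex_semi < 0) ||
      (tumor_center[1] - tumor_semi_max[1]) <= (cortex_center[1] + cortex_semi[1]))
    stop("phantom configuration error: tumor/cortex ellipsoids do not fit ",
         "disjointly inside the grid")

  cortex_mask <- ellipsoid_mask(dims, spacing, cortex_center, cortex_semi)

  rows <- list()
  withr::with_seed(config$seed, {
    for (cohort in cohort_levels()) {
      n_per <- config$subjects_per_class[[cohort]]
      for (class in c("nsRCC", "sRCC")) {
        for (s in seq_len(n_per)) {
          sid <- sprintf("%s_%s_%02d", class, cohort, s)
          vol_cm3 <- runif(1, config$volume_range_cm3[1],
                           config$volume_range_cm3[2])
          r <- (3 * vol_cm3 * 1000 / (4 * pi))^(1 / 3)
          tumor_mask <- ellipsoid_mask(dims, spacing, tumor_center,
                                       r * c(1.2, 1, 1 / 1.2))
          if (sum(tumor_mask) < 1 || any(tumor_mask & cortex_mask))
            stop("phantom configuration error: degenerate tumor mask for ",
                 sid)

          g_t2 <- runif(1, config$t2_gain_range[1], config$t2_gain_range[2])
          g_t1 <- runif(1, config$t1_gain_range[1], config$t1_gain_range[2])
          gain <- c(t2w = g_t2, t1w = g_t1, t1w_ceart = g_t1,
                    t1w_ceven = g_t1)
          raw_scale <- c(t2w = g_t2 * config$cortex_levels[["t2w"]],
                         t1w = g_t1 * config$cortex_levels[["t1w"]],
                         t1w_ceart = g_t1 * config$cortex_levels[["t1w"]],
                         t1w_ceven = g_t1 * config$cortex_levels[["t1w"]])

          profs <- config$profiles[[class]]
          w <- vapply(profs, `[[`, numeric(1), "weight")
          n_vox <- sum(tumor_mask)
          comp <- sample.int(length(profs), n_vox, replace = TRUE, prob = w)
          mean_mat <- do.call(rbind, lapply(profs, `[[`, "mean"))
          sd_mat <- do.call(rbind, lapply(profs, `[[`, "sd"))

          paths <- character(0)
          for (ch in mri_channels()) {
            vol <- array(config$background_level, dim = dims)
            vol[cortex_mask] <- config$cortex_levels[[ch]] * gain[[ch]]
            calib <- mean_mat[comp, ch] +
              (if (any(sd_mat[, ch] > 0)) rnorm(n_vox) * sd_mat[comp, ch]
               else 0)
            vol[tumor_mask] <- calib * raw_scale[[ch]]
            if (config$noise_sd > 0)
              vol <- vol + array(rnorm(prod(dims), sd = config$noise_sd),
                                 dim = dims)
            f <- sprintf("%s_%s.nii.gz", sid, ch)
            write_nifti_vol(vol, spacing, file.path(out_dir, f))
            paths[ch] <- f
          }
          f_tum <- sprintf("%s_tumor_mask.nii.gz", sid)
          f_ctx <- sprintf("%s_cortex_mask.nii.gz", sid)
          write_nifti_vol(array(as.double(tumor_mask), dim = dims), spacing,
                          file.path(out_dir, f_tum))
          write_nifti_vol(array(as.double(cortex_mask), dim = dims), spacing,
                          file.path(out_dir, f_ctx))

          rows[[sid]] <- data.frame(
            subject_id = sid, class = class, cohort = cohort,
            tumor_volume_cm3 = n_vox * voxel_cm3,
            t2w_path = paths[["t2w"]], t1w_path = paths[["t1w"]],
            t1w_ceart_path = paths[["t1w_ceart"]],
            t1w_ceven_path = paths[["t1w_ceven"]],
            tumor_mask_path = f_tum, cortex_mask_path = f_ctx)
        }
      }
    }
  })

  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  read_manifest(file.path(out_dir, "manifest.csv"))
}
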
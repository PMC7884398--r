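test_that("cohort generation is byte-deterministic per seed", {
  cfg <- phantom_config(dim = c(32L, 32L, 16L),
                        subjects_per_class = c(training = 1L,
                                               validation = 1L, test = 1L),
                        volume_range_cm3 = c(1, 3), seed = 7L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(h1, h2)

  d3 <- withr::local_tempdir()
  cfg2 <- phantom_config(dim = c(32L, 32L, 16L),
                         subjects_per_class = c(training = 1L,
                                                validation = 1L, test = 1L),
                         volume_range_cm3 = c(1, 3), seed = 8L)
  generate_cohort(cfg2, d3)
  expect_false(identical(h1, unname(tools::md5sum(file.path(d3, f1)))))
})

test_that("manifest bookkeeping and mask geometry hold for every subject", {
  fix <- phantom_fixture()
  man <- fix$manifest
  expect_equal(nrow(man), 2 * (2 + 1 + 1))
  expect_equal(sum(man$class == "sRCC"), sum(man$class == "nsRCC"))

  voxel_cm3 <- prod(fix$config$spacing) / 1000
  for (i in seq_len(nrow(man))) {
    study <- load_study(man[i, ], base_dir = fix$dir)
    expect_gte(sum(study$tumor_mask), 1)
    expect_gte(sum(study$cortex_mask), 1)
    expect_false(any(study$tumor_mask & study$cortex_mask))
    expect_lt(abs(study$mask_volume_cm3 - man$tumor_volume_cm3[i]),
              voxel_cm3)
  }
})

test_that("a 5+5 test cohort produces ten balanced manifest rows", {
  cfg <- phantom_config(dim = c(32L, 32L, 16L),
                        subjects_per_class = c(training = 1L,
                                               validation = 1L, test = 5L),
                        volume_range_cm3 = c(1, 3), seed = 9L)
  man <- generate_cohort(cfg, withr::local_tempdir())
  test_rows <- man[man$cohort == "test", ]
  expect_equal(nrow(test_rows), 10)
  expect_equal(sum(test_rows$class == "sRCC"), 5)
})

test_that("noise-free generation round-trips the configured phenotype exactly", {
  prof <- function(mean) list(mean = setNames(mean, mri_channels()),
                              sd = setNames(rep(0, 4), mri_channels()),
                              weight = 1)
  profiles <- list(sRCC = list(prof(c(0.9, 0.5, 0.5, 0.6))),
                   nsRCC = list(prof(c(1.2, 1.0, 1.8, 1.5))))
  cfg <- phantom_config(dim = c(32L, 32L, 16L),
                        subjects_per_class = c(training = 1L,
                                               validation = 1L, test = 1L),
                        volume_range_cm3 = c(1, 3), noise_sd = 0,
                        profiles = profiles, seed = 10L)
  dir <- withr::local_tempdir()
  man <- generate_cohort(cfg, dir)
  for (i in seq_len(nrow(man))) {
    study <- load_study(man[i, ], base_dir = dir)
    tab <- calibrate(study, compute_cortex_reference(study))
    mean_target <- profiles[[man$class[i]]][[1]]$mean
    feats <- feature_matrix(tab)
    expect_lt(max(abs(sweep(feats, 2, mean_target))), 1e-12)
  }
})

test_that("calibrated tables are invariant to the scanner gain draws", {
  prof <- function(mean) list(mean = setNames(mean, mri_channels()),
                              sd = setNames(rep(0, 4), mri_channels()),
                              weight = 1)
  profiles <- list(sRCC = list(prof(c(0.9, 0.5, 0.5, 0.6))),
                   nsRCC = list(prof(c(1.2, 1.0, 1.8, 1.5))))
  base_args <- list(dim = c(32L, 32L, 16L),
                    subjects_per_class = c(training = 1L, validation = 1L,
                                           test = 1L),
                    volume_range_cm3 = c(1, 3), noise_sd = 0,
                    profiles = profiles, seed = 12L)
  cfg_a <- do.call(phantom_config, c(base_args,
                                     list(t2_gain_range = c(0.9, 1.1),
                                          t1_gain_range = c(0.9, 1.1))))
  cfg_b <- do.call(phantom_config, c(base_args,
                                     list(t2_gain_range = c(0.3, 3.0),
                                          t1_gain_range = c(0.3, 3.0))))
  da <- withr::local_tempdir(); db <- withr::local_tempdir()
  ma <- generate_cohort(cfg_a, da)
  mb <- generate_cohort(cfg_b, db)
  for (i in seq_len(nrow(ma))) {
    sa <- load_study(ma[i, ], base_dir = da)
    sb <- load_study(mb[i, ], base_dir = db)
    ta <- feature_matrix(calibrate(sa, compute_cortex_reference(sa)))
    tb <- feature_matrix(calibrate(sb, compute_cortex_reference(sb)))
    expect_lt(max(abs(ta - tb) / pmax(abs(ta), .Machine$double.eps)), 1e-12)
  }
})

test_that("default profiles encode the class phenotype contrasts", {
  profiles <- default_profiles()
  expect_gt(length(profiles$nsRCC), length(profiles$sRCC))

  mean_of <- function(cl, ch)
    mean(vapply(profiles[[cl]], function(p) p$mean[[ch]], numeric(1)))
  for (ch in c("t1w", "t1w_ceart", "t1w_ceven"))
    expect_lt(mean_of("sRCC", ch), mean_of("nsRCC", ch))
})

test_that("pooled sarcomatoid maps are sparser than non-sarcomatoid maps", {
  # the dominant tight sarcomatoid phenotype concentrates hits on few
  # neurons once SOM training is long enough for density equalization
  sparser <- vapply(1:5, function(s) {
    cfg <- phantom_config(dim = c(48L, 48L, 24L),
                          subjects_per_class = c(training = 3L,
                                                 validation = 1L, test = 1L),
                          volume_range_cm3 = c(4, 10), seed = 200L + s)
    dir <- file.path(tempdir(), sprintf("sparsity_%d", s))
    man <- generate_cohort(cfg, dir)
    train <- man[man$cohort == "training", ]
    tabs <- lapply(seq_len(nrow(train)), function(i) {
      study <- load_study(train[i, ], base_dir = dir)
      calibrate(study, compute_cortex_reference(study))
    })
    names(tabs) <- train$subject_id
    stats <- fit_channel_stats(tabs)
    norm <- lapply(tabs, normalize_table, stats = stats)

    pool <- do.call(rbind, norm)
    attr(pool, "stage") <- "normalized"
    som <- train_som(init_som(som_config(iterations = 2e5, seed = s), pool),
                     pool)
    active <- function(cl) {
      m <- pooled_activation_map(som, norm[train$subject_id[train$class == cl]],
                                 cl)
      sum(m$raw_hits >= 0.01 * m$total_voxels)
    }
    out <- active("sRCC") < active("nsRCC")
    unlink(dir, recursive = TRUE)
    out
  }, logical(1))
  expect_gte(sum(sparser), 4)
})

test_that("differential neurons carry the T1-family hypointensity signature", {
  # rank the neurons most characteristic of each class on a pooled
  # phantom cohort and check the sign of their T1-family phenotypes
  cfg <- phantom_config(dim = c(48L, 48L, 24L),
                        subjects_per_class = c(training = 3L,
                                               validation = 1L, test = 1L),
                        volume_range_cm3 = c(4, 10), seed = 250L)
  dir <- withr::local_tempdir()
  man <- generate_cohort(cfg, dir)
  train <- man[man$cohort == "training", ]
  tabs <- lapply(seq_len(nrow(train)), function(i) {
    study <- load_study(train[i, ], base_dir = dir)
    calibrate(study, compute_cortex_reference(study))
  })
  names(tabs) <- train$subject_id
  stats <- fit_channel_stats(tabs)
  norm <- lapply(tabs, normalize_table, stats = stats)
  pool <- do.call(rbind, norm)
  attr(pool, "stage") <- "normalized"
  som <- train_som(init_som(som_config(iterations = 1e5, seed = 251), pool),
                   pool)

  by_class <- function(cl)
    pooled_activation_map(som, norm[train$subject_id[train$class == cl]], cl)
  map_s <- by_class("sRCC"); map_n <- by_class("nsRCC")

  t1_cols <- c("c_t1", "c_t1art", "c_t1ven")
  top_s <- rank_differential_neurons(map_s, map_n, 5)
  top_n <- rank_differential_neurons(map_n, map_s, 5)
  expect_lt(mean(som$codebook[top_s + 1L, t1_cols]), 0)
  expect_gt(mean(som$codebook[top_n + 1L, t1_cols]), 0)
})
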
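# Shared in-code fixtures. Everything is generated programmatically and
# cached for the duration of one test run.

.fixture_env <- new.env(parent = emptyenv())

# A study_volumes object built directly in memory (no files), with
# constant-filled channels unless a filler function is given.
make_study <- function(dim = c(8L, 8L, 4L), spacing = c(2, 2, 2),
                       fill = list(t2w = 200, t1w = 100, t1w_ceart = 300,
                                   t1w_ceven = 250),
                       subject_id = "synthetic01", class = "nsRCC",
                       cohort = "training") {
  vols <- lapply(somlvq::mri_channels(), function(ch) {
    f <- fill[[ch]]
    if (is.function(f)) array(f(prod(dim)), dim = dim)
    else array(f, dim = dim)
  })
  names(vols) <- somlvq::mri_channels()
  tumor <- array(FALSE, dim = dim)
  tumor[3:6, 3:6, 2:3] <- TRUE
  cortex <- array(FALSE, dim = dim)
  cortex[1:2, 1:2, 1] <- TRUE
  structure(list(subject_id = subject_id, class = class, cohort = cohort,
                 volumes = vols, tumor_mask = tumor, cortex_mask = cortex,
                 spacing = spacing, dim = dim,
                 mask_volume_cm3 = sum(tumor) * prod(spacing) / 1000),
            class = "study_volumes")
}

# A voxel feature table wrapped around a given feature matrix.
make_table <- function(x, stage = "normalized", cohort = "training",
                       subject_id = "synthetic01") {
  x <- as.matrix(x)
  colnames(x) <- c("c_t2", "c_t1", "c_t1art", "c_t1ven")
  n <- nrow(x)
  tab <- data.frame(subject_id = subject_id,
                    i = seq_len(n), j = 1L, k = 1L, x,
                    check.names = FALSE)
  attr(tab, "stage") <- stage
  attr(tab, "cohort") <- cohort
  tab
}

# 4-channel Gaussian-mixture feature table emulating intra-tumor
# phenotype subpopulations in normalized units.
make_mixture_table <- function(n = 2000, seed = 1,
                               centers = rbind(c(-1, -1.2, -1.0, -1.1),
                                               c(0.5, 0.8, 1.2, 0.9),
                                               c(1.2, -0.2, 0.4, 1.4)),
                               sd = 0.15, stage = "normalized",
                               cohort = "training") {
  withr::with_seed(seed, {
    comp <- sample.int(nrow(centers), n, replace = TRUE)
    x <- centers[comp, , drop = FALSE] + matrix(rnorm(n * 4, sd = sd), n)
  })
  make_table(x, stage = stage, cohort = cohort)
}

# A som_model wrapper around an arbitrary codebook (for BMU/activation
# tests that need exact control over the lattice contents).
make_model <- function(codebook, rows = 9L, cols = 9L) {
  colnames(codebook) <- c("c_t2", "c_t1", "c_t1art", "c_t1ven")
  structure(list(codebook = codebook,
                 config = somlvq::som_config(rows = rows, cols = cols,
                                             iterations = 1),
                 training_log = NULL, trained = TRUE),
            class = "som_model")
}

# Small phantom cohort on disk, generated once per test run.
phantom_fixture <- function() {
  if (is.null(.fixture_env$phantom)) {
    dir <- file.path(tempdir(), "somlvq_phantom_fixture")
    cfg <- somlvq::phantom_config(
      dim = c(32L, 32L, 16L),
      subjects_per_class = c(training = 2L, validation = 1L, test = 1L),
      volume_range_cm3 = c(1, 3), seed = 101L)
    man <- somlvq::generate_cohort(cfg, dir)
    .fixture_env$phantom <- list(dir = dir, config = cfg, manifest = man)
  }
  .fixture_env$phantom
}

# Random activation map over a 9x9 lattice.
make_map <- function(seed = 1, label = "map", n_neurons = 81) {
  hits <- withr::with_seed(seed, {
    h <- rpois(n_neurons, 3)
    if (sum(h) == 0) h[1] <- 1L
    h
  })
  somlvq:::new_activation_map(hits, label)
}
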
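new_activation_map <- function(raw_hits, label) {
  raw_hits <- as.integer(raw_hits)
  total <- sum(raw_hits)
  if (total < 1)
    stop("usage error: activation map must contain at least one hit")
  structure(list(label = label,
                 raw_hits = raw_hits,
                 normalized = raw_hits / max(raw_hits),
                 total_voxels = total),
            class = "activation_map")
}

validate_activation_map <- function(map) {
  stopifnot(inherits(map, "activation_map"))
  if (any(map$raw_hits < 0)) stop("activation map: negative hit count")
  if (sum(map$raw_hits) != map$total_voxels || map$total_voxels < 1)
    stop("activation map: hit counts do not sum to total_voxels >= 1")
  if (max(map$normalized) != 1)
    stop("activation map: max(normalized) must be exactly 1")
  if (any(map$normalized != map$raw_hits / max(map$raw_hits)))
    stop("activation map: normalized values inconsistent with raw hits")
  invisible(map)
}

#' Compute a tumor's activation map
#'
#' Assigns every voxel of the table to its best matching unit on the
#' trained SOM and counts hits per neuron, producing the tumor's 2D
#' fingerprint: 81 raw hit counts in row-major lattice order plus the
#' same counts normalized by the map's own maximum (so every map has
#' exactly one neuron at 1.0).
#'
#' @param model A trained `som_model`.
#' @param table A normalized voxel feature table.
#' @param label Map label; defaults to the table's subject id.
#' @return An `activation_map`.
#' @export
compute_activation_map <- function(model, table, label = NULL) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("usage error: cannot compute an activation map from an empty table",
         " (all-zero maps are undefined under max-normalization)")
  bmu <- find_bmu(model, feature_matrix(table))
  n_code <- model$config$rows * model$config$cols
  hits <- tabulate(bmu + 1L, nbins = n_code)
  new_activation_map(hits, label %||% table$subject_id[1])
}

#' Pooled activation map over several tumors
#'
#' Counts hits over the concatenated voxels of all tables (raw voxel
#' pooling: each tumor contributes its actual voxel count), then
#' max-normalizes. Raw hits of the pooled map equal the element-wise sum
#' of the constituent maps' raw hits.
#'
#' @param model A trained `som_model`.
#' @param tables Non-empty list of normalized voxel feature tables.
#' @param label Pool label, e.g. `"sRCC_pooled"`.
#' @return An `activation_map`.
#' @export
pooled_activation_map <- function(model, tables, label = "pooled") {
  if (!is.list(tables) || length(tables) == 0)
    stop("usage error: pooled_activation_map needs >= 1 table")
  if (is.data.frame(tables)) tables <- list(tables)
  n_code <- model$config$rows * model$config$cols
  hits <- integer(n_code)
  for (tab in tables) {
    if (!is.data.frame(tab) || nrow(tab) == 0)
      stop("usage error: empty table in pool")
    bmu <- find_bmu(model, feature_matrix(tab))
    hits <- hits + tabulate(bmu + 1L, nbins = n_code)
  }
  new_activation_map(hits, label)
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("activation_map '%s': %d voxels over %d neurons (%d active)\n",
              x$label, x$total_voxels, length(x$raw_hits),
              sum(x$raw_hits > 0)))
  invisible(x)
}

#' Rank neurons by differential activation between two maps
#'
#' Orders neurons by descending difference of per-class hit fractions,
#' `raw_hits_a / total_a - raw_hits_b / total_b`, with ties broken by
#' smaller index, and returns the first `k` (0-based indices). The hit
#' fraction difference (rather than a ratio) keeps neurons that one
#' class never visits well-defined. With `map_a` the pooled sarcomatoid
#' map this yields the neurons most characteristic of sarcomatoid
#' tumors.
#'
#' @param map_a,map_b `activation_map`s on the same lattice.
#' @param k Number of neurons to return (0 gives an empty vector).
#' @return Integer vector of `k` neuron indices.
#' @export
rank_differential_neurons <- function(map_a, map_b, k = 5L) {
  validate_activation_map(map_a)
  validate_activation_map(map_b)
  if (length(map_a$raw_hits) != length(map_b$raw_hits))
    stop("usage error: maps come from different lattices")
  k <- as.integer(k)
  stopifnot(k >= 0, k <= length(map_a$raw_hits))
  if (k == 0) return(integer(0))
  diff <- map_a$raw_hits / map_a$total_voxels -
    map_b$raw_hits / map_b$total_voxels
  ord <- order(-diff, seq_along(diff))
  as.integer(ord[seq_len(k)] - 1L)
}

#' Per-channel neuron phenotype maps
#'
#' Rearranges the trained codebook into four lattice-shaped grids, one
#' per MRI channel: grid `c` holds codebook component `c` of neuron `n`
#' at `n`'s lattice position. Values are in calibrated,
#' variance-normalized units, so 0 is the pooled training+validation
#' tumor-voxel mean on that channel and +/-1 is one pooled SD above or
#' below it; negative values read as hypointensity, positive as
#' hyperintensity.
#'
#' @param model A trained `som_model`.
#' @return Named list of four `rows x cols` matrices (channel order of
#'   [mri_channels()]).
#' @export
neuron_phenotype_maps <- function(model) {
  stopifnot(inherits(model, "som_model"))
  cfg <- model$config
  grids <- lapply(seq_len(ncol(model$codebook)), function(ch)
    matrix(model$codebook[, ch], nrow = cfg$rows, ncol = cfg$cols,
           byrow = TRUE))
  names(grids) <- mri_channels()
  grids
}
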
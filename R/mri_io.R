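#' Read and validate a cohort manifest
#'
#' The manifest lists one study subject per row with the class label,
#' cohort assignment, tumor volume and the six image files (four MRI
#' sequences plus tumor and cortex masks). CSV and JSON (array of
#' objects with identical keys) are both accepted; the format is chosen
#' by file extension.
#'
#' Required columns: `subject_id`, `class` (one of `sRCC`, `nsRCC`,
#' `unknown`), `cohort` (one of `training`, `validation`, `test`),
#' `tumor_volume_cm3` (> 0), and the path columns `t2w_path`,
#' `t1w_path`, `t1w_ceart_path`, `t1w_ceven_path`, `tumor_mask_path`,
#' `cortex_mask_path`. Training- and validation-cohort rows must carry a
#' known class label. Relative paths are resolved against the manifest's
#' directory by [load_study()].
#'
#' @param path Path to a `.csv` or `.json` manifest.
#' @return A data frame with one validated row per subject and attribute
#'   `manifest_dir` recording the directory paths are relative to.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  man <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    tryCatch(
      read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
      error = function(e) stop("manifest schema error: unparseable file (",
                               conditionMessage(e), ")")
    )
  }

  required <- c("subject_id", "class", "cohort", "tumor_volume_cm3",
                manifest_path_cols())
  missing <- setdiff(required, names(man))
  if (length(missing) > 0)
    stop("manifest schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(man) == 0) stop("manifest schema error: no subject rows")

  man$tumor_volume_cm3 <- suppressWarnings(as.numeric(man$tumor_volume_cm3))

  bad_class <- setdiff(unique(man$class), class_levels())
  if (length(bad_class) > 0)
    stop("manifest value error: unknown class token(s): ",
         paste(bad_class, collapse = ", "))
  bad_cohort <- setdiff(unique(man$cohort), cohort_levels())
  if (length(bad_cohort) > 0)
    stop("manifest value error: unknown cohort token(s): ",
         paste(bad_cohort, collapse = ", "))
  if (anyNA(man$tumor_volume_cm3) || any(man$tumor_volume_cm3 <= 0))
    stop("manifest value error: tumor_volume_cm3 must be a positive number ",
         "for every subject")
  if (anyDuplicated(man$subject_id))
    stop("manifest value error: duplicated subject_id")
  needs_label <- man$cohort %in% c("training", "validation")
  if (any(man$class[needs_label] == "unknown"))
    stop("manifest value error: training/validation subjects must have a ",
         "known class label")

  attr(man, "manifest_dir") <- dirname(normalizePath(path))
  man
}

manifest_path_cols <- function() {
  c("t2w_path", "t1w_path", "t1w_ceart_path", "t1w_ceven_path",
    "tumor_mask_path", "cortex_mask_path")
}

#' Load the co-registered volumes and masks for one subject
#'
#' Reads the four NIfTI sequences and the two binary masks referenced by
#' a manifest row, promotes intensities to double precision, and checks
#' the co-registration contract: all six grids must share dimensions and
#' voxel spacing, masks must be strictly binary (foreground value 1
#' exactly) and non-empty, and the tumor and cortex masks must be
#' disjoint.
#'
#' @param record One manifest row (data frame or list) as produced by
#'   [read_manifest()].
#' @param base_dir Directory against which relative paths are resolved;
#'   defaults to the manifest directory carried on the record.
#' @return A `study_volumes` object: named list of the four volumes,
#'   logical `tumor_mask` and `cortex_mask` arrays, `spacing` (mm),
#'   `dim`, subject metadata, and `mask_volume_cm3` (tumor voxel count
#'   times voxel volume, for cross-checking against the manifest).
#' @export
load_study <- function(record, base_dir = NULL) {
  record <- as.list(record)
  base_dir <- base_dir %||% attr(record, "manifest_dir") %||% "."

  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)

  seq_paths <- vapply(c("t2w_path", "t1w_path", "t1w_ceart_path",
                        "t1w_ceven_path"), function(cl) resolve(record[[cl]]),
                      character(1))
  read_vol <- function(p) {
    if (!file.exists(p)) stop("volume file does not exist: ", p)
    img <- RNifti::readNifti(p)
    list(data = array(as.double(img), dim = dim(img)),
         spacing = RNifti::pixdim(img))
  }

  vols <- lapply(seq_paths, read_vol)
  names(vols) <- mri_channels()
  tum <- read_vol(resolve(record$tumor_mask_path))
  ctx <- read_vol(resolve(record$cortex_mask_path))

  dims <- lapply(c(vols, list(tum, ctx)), function(v) dim(v$data))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("co-registration error: grids do not share dimensions (",
         record$subject_id %||% "?", ")")
  spac <- lapply(c(vols, list(tum, ctx)), function(v) v$spacing)
  if (!all(vapply(spac, function(s) isTRUE(all.equal(s, spac[[1]])), logical(1))))
    stop("co-registration error: grids do not share voxel spacing (",
         record$subject_id %||% "?", ")")

  check_mask <- function(m, what) {
    vals <- unique(as.vector(m))
    if (!all(vals %in% c(0, 1)))
      stop("mask error: ", what, " mask contains value(s) other than 0/1: ",
           paste(utils::head(setdiff(vals, c(0, 1)), 3), collapse = ", "))
    if (sum(m) < 1) stop("mask error: ", what, " mask has no foreground voxel")
    m == 1
  }
  tumor_mask <- check_mask(tum$data, "tumor")
  cortex_mask <- check_mask(ctx$data, "cortex")
  if (any(tumor_mask & cortex_mask))
    stop("mask error: tumor and cortex masks overlap")

  spacing <- as.double(spac[[1]][seq_len(3)])
  structure(list(
    subject_id = record$subject_id %||% NA_character_,
    class = record$class %||% "unknown",
    cohort = record$cohort %||% NA_character_,
    volumes = lapply(vols, `[[`, "data"),
    tumor_mask = tumor_mask,
    cortex_mask = cortex_mask,
    spacing = spacing,
    dim = dims[[1]],
    mask_volume_cm3 = sum(tumor_mask) * prod(spacing) / 1000
  ), class = "study_volumes")
}

#' @export
print.study_volumes <- function(x, ...) {
  cat("study_volumes:", x$subject_id, sprintf("(%s, %s)\n", x$class, x$cohort))
  cat("  grid", paste(x$dim, collapse = "x"), "at",
      paste(x$spacing, collapse = "x"), "mm\n")
  cat("  tumor voxels:", sum(x$tumor_mask),
      sprintf("(%.2f cm^3)", x$mask_volume_cm3),
      " cortex voxels:", sum(x$cortex_mask), "\n")
  invisible(x)
}

#' Write an activation map to CSV
#'
#' One row per neuron in row-major lattice order, columns `neuron`
#' (0-based index), `raw_hits`, `normalized`. Values are written with
#' full precision so that [read_activation_map()] round-trips
#' bit-exactly.
#'
#' @param map An `activation_map` object.
#' @param path Output CSV path.
#' @export
write_activation_map <- function(map, path) {
  validate_activation_map(map)
  df <- data.frame(neuron = seq_along(map$raw_hits) - 1L,
                   raw_hits = map$raw_hits,
                   normalized = sprintf("%.17g", map$normalized))
  tryCatch(write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("I/O error writing activation map: ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read an activation map written by [write_activation_map()]
#'
#' @param path CSV path.
#' @param label Map label (subject id or pool name); defaults to the
#'   file name without extension.
#' @return An `activation_map` object.
#' @export
read_activation_map <- function(path, label = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron", "raw_hits", "normalized")
  if (!all(need %in% names(df)))
    stop("activation map file missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  map <- new_activation_map(as.integer(df$raw_hits),
                            label %||% tools::file_path_sans_ext(basename(path)))
  # stored normalized values are authoritative for the round trip
  stopifnot(max(abs(map$normalized - as.numeric(df$normalized))) == 0)
  map
}

#' Serialize a trained SOM to JSON
#'
#' Stores the configuration, the row-major 81x4 codebook, and the
#' quantization-error training log with full floating-point precision.
#'
#' @param model A `som_model`.
#' @param path Output JSON path.
#' @export
save_som_model <- function(model, path) {
  stopifnot(inherits(model, "som_model"))
  obj <- list(
    config = unclass(model$config),
    codebook = unname(apply(model$codebook, 1, as.numeric, simplify = FALSE)),
    channels = colnames(model$codebook),
    training_log = model$training_log,
    trained = model$trained
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a SOM saved by [save_som_model()]
#' @param path JSON path.
#' @return A `som_model`.
#' @export
load_som_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  cb <- obj$codebook
  if (is.list(cb)) cb <- do.call(rbind, cb)
  colnames(cb) <- obj$channels
  cfg <- do.call(som_config, obj$config[setdiff(names(obj$config), NULL)])
  structure(list(codebook = cb, config = cfg,
                 training_log = as.data.frame(obj$training_log),
                 trained = isTRUE(obj$trained)),
            class = "som_model")
}

#' Serialize a trained LVQ model to JSON
#' @param model An `lvq_model`.
#' @param path Output JSON path.
#' @export
save_lvq_model <- function(model, path) {
  stopifnot(inherits(model, "lvq_model"))
  obj <- list(
    config = unclass(model$config),
    labels = model$labels,
    prototypes = unname(apply(model$prototypes, 1, as.numeric,
                              simplify = FALSE)),
    loss_curve = model$loss_curve
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load an LVQ model saved by [save_lvq_model()]
#' @param path JSON path.
#' @return An `lvq_model`.
#' @export
load_lvq_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  protos <- obj$prototypes
  if (is.list(protos)) protos <- do.call(rbind, protos)
  structure(list(prototypes = protos,
                 labels = obj$labels,
                 config = do.call(lvq_config, obj$config),
                 loss_curve = as.numeric(obj$loss_curve)),
            class = "lvq_model")
}

#' Serialize channel normalization statistics to JSON
#' @param stats A `channel_stats` object.
#' @param path Output JSON path.
#' @export
save_channel_stats <- function(stats, path) {
  stopifnot(inherits(stats, "channel_stats"))
  jsonlite::write_json(list(mean = as.list(stats$mean),
                            sd = as.list(stats$sd),
                            n_voxels = stats$n_voxels),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load channel statistics saved by [save_channel_stats()]
#' @param path JSON path.
#' @return A `channel_stats` object.
#' @export
load_channel_stats <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new_channel_stats(unlist(obj$mean), unlist(obj$sd), obj$n_voxels)
}
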
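#' Self-organizing map configuration
#'
#' Defaults follow the study conditions: a 9x9 lattice (81 neurons, one
#' per combination of three intensity levels across four channels),
#' bubble neighborhood, initial learning rate 0.2, and one million
#' sequential training iterations. Learning rate and neighborhood radius
#' both decay by inverse time, `value(t) = value0 / (1 + t/(T/2))` with
#' `T` the total iteration count; bubble membership is lattice Chebyshev
#' distance at most the current radius.
#'
#' @param rows,cols Lattice dimensions.
#' @param neighborhood Neighborhood function; only `"bubble"` is
#'   implemented.
#' @param learning_rate Initial learning rate, in (0, 1].
#' @param radius Initial bubble radius in lattice units.
#' @param iterations Number of sequential updates.
#' @param decay Decay schedule identifier; only `"inverse_time"` is
#'   implemented.
#' @param seed Integer seed governing codebook initialization and the
#'   per-iteration sampling of data rows.
#' @return A `som_config` object.
#' @export
som_config <- function(rows = 9L, cols = 9L, neighborhood = "bubble",
                       learning_rate = 0.2, radius = 1.0,
                       iterations = 1e6, decay = "inverse_time",
                       seed = 42L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 1, cols >= 1, rows * cols >= 1)
  if (!identical(neighborhood, "bubble"))
    stop("only the bubble neighborhood is implemented")
  if (!identical(decay, "inverse_time"))
    stop("only inverse_time decay is implemented")
  stopifnot(learning_rate > 0, learning_rate <= 1, radius >= 0,
            iterations >= 1)
  structure(list(rows = rows, cols = cols, neighborhood = neighborhood,
                 learning_rate = learning_rate, radius = radius,
                 iterations = as.double(iterations), decay = decay,
                 seed = as.integer(seed)),
            class = "som_config")
}

#' Initialize a SOM codebook from data rows
#'
#' Each of the `rows * cols` codebook vectors is a data row drawn
#' uniformly with replacement under the configured seed. Initializing
#' from data (rather than a fixed box) keeps the starting codebook on
#' the scale of the normalized input space, and every subsequent update
#' is a convex step toward a data point, so trained codebooks stay
#' inside the data's bounding box.
#'
#' Neuron `n` (0-based, row-major) sits at lattice position
#' `(n %/% cols, n %% cols)`; this indexing convention is shared with
#' activation maps and the LVQ input vectors.
#'
#' @param config A `som_config`.
#' @param table A normalized voxel feature table.
#' @return An untrained `som_model`.
#' @export
init_som <- function(config, table) {
  stopifnot(inherits(config, "som_config"))
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("usage error: init_som needs a non-empty feature table")
  if (table_stage(table) != "normalized")
    stop("usage error: SOM input must be stage=normalized, got ",
         table_stage(table))
  x <- feature_matrix(table)
  n_code <- config$rows * config$cols
  idx <- withr::with_seed(config$seed,
                          sample.int(nrow(x), n_code, replace = TRUE))
  codebook <- x[idx, , drop = FALSE]
  rownames(codebook) <- NULL
  structure(list(codebook = codebook, config = config,
                 training_log = NULL, trained = FALSE),
            class = "som_model")
}

#' Train a SOM by sequential Kohonen updates
#'
#' Runs `config$iterations` updates: at each step a data row is drawn
#' uniformly with replacement (seeded), its best matching unit (BMU) is
#' found by Euclidean distance, and the BMU plus all neurons within the
#' current bubble radius (lattice Chebyshev distance) move toward the
#' sample by the current learning rate. Quantization error is logged at
#' iteration 0 and after every tenth of training (11 checkpoints).
#'
#' @param model An initialized `som_model`.
#' @param table A normalized voxel feature table.
#' @param checkpoints Number of post-start quantization-error
#'   checkpoints (default 10).
#' @return The trained `som_model` with a `training_log` data frame of
#'   `(iteration, quantization_error)`.
#' @export
train_som <- function(model, table, checkpoints = 10L) {
  stopifnot(inherits(model, "som_model"))
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("usage error: train_som needs a non-empty feature table")
  if (table_stage(table) != "normalized")
    stop("usage error: SOM input must be stage=normalized, got ",
         table_stage(table))
  x <- feature_matrix(table)
  cfg <- model$config
  sample_idx <- withr::with_seed(cfg$seed + 1L,
    sample.int(nrow(x), cfg$iterations, replace = TRUE))
  fit <- som_train_cpp(model$codebook, x, sample_idx,
                       cfg$learning_rate, cfg$radius,
                       cfg$rows, cfg$cols, as.integer(checkpoints))
  codebook <- fit$codebook
  colnames(codebook) <- feature_cols()
  if (!all(is.finite(codebook))) stop("numeric error: non-finite codebook")
  model$codebook <- codebook
  model$training_log <- data.frame(iteration = fit$log_iteration,
                                   quantization_error = fit$log_qe)
  model$trained <- TRUE
  model
}

#' @export
print.som_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("som_model: %dx%d lattice, %s neighborhood, lr %g, %g iterations (%s)\n",
              cfg$rows, cfg$cols, cfg$neighborhood, cfg$learning_rate,
              cfg$iterations, if (x$trained) "trained" else "untrained"))
  if (!is.null(x$training_log)) {
    n <- nrow(x$training_log)
    cat(sprintf("  quantization error: %.4f (start) -> %.4f (final)\n",
                x$training_log$quantization_error[1],
                x$training_log$quantization_error[n]))
  }
  invisible(x)
}

#' Best matching unit lookup
#'
#' Returns the 0-based row-major index of the codebook vector with
#' minimal Euclidean distance to each query vector; ties break to the
#' smallest index.
#'
#' @param model A `som_model`.
#' @param x A single 4-component vector or an n x 4 matrix of queries.
#' @return Integer vector of neuron indices in `0 .. rows*cols - 1`.
#' @export
find_bmu <- function(model, x) {
  stopifnot(inherits(model, "som_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$codebook))
    stop("usage error: query has ", ncol(x), " components, codebook has ",
         ncol(model$codebook))
  if (!all(is.finite(x))) stop("usage error: non-finite query vector")
  as.integer(bmu_cpp(model$codebook, x))
}

#' Quantization error of a SOM on a feature table
#'
#' Mean Euclidean distance from each voxel vector to its best matching
#' unit; the standard SOM fit diagnostic.
#'
#' @param model A `som_model`.
#' @param table A normalized voxel feature table (or 4-column matrix).
#' @return Mean BMU distance (dimensionless, normalized-intensity
#'   units).
#' @export
quantization_error <- function(model, table) {
  stopifnot(inherits(model, "som_model"))
  x <- if (is.data.frame(table)) feature_matrix(table) else as.matrix(table)
  if (nrow(x) == 0) stop("usage error: empty data")
  quantization_error_cpp(model$codebook, x)
}
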
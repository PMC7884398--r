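#' LVQ classifier configuration
#'
#' Defaults are the selected operating point of the study conditions:
#' constant learning rate 0.001 and 1000 training epochs, one prototype
#' per class. The variant is LVQ1: per visited sample the single nearest
#' prototype moves toward it when labels agree and away when they
#' disagree; the learning rate stays constant across epochs.
#'
#' @param learning_rate Constant LVQ1 step size (>= 0; zero freezes the
#'   prototypes at initialization, useful as a control).
#' @param epochs Number of training epochs (>= 1).
#' @param prototypes_per_class Prototypes per class (>= 1).
#' @param init Prototype initialization: `"class_mean"` (deterministic
#'   class means; extra prototypes beyond the first get a small seeded
#'   jitter so they can separate) or `"sample"` (seeded draw of class
#'   examples).
#' @param seed Integer seed for per-epoch shuffling (and `"sample"`
#'   init).
#' @return An `lvq_config` object.
#' @export
lvq_config <- function(learning_rate = 0.001, epochs = 1000L,
                       prototypes_per_class = 1L, init = "class_mean",
                       seed = 42L) {
  stopifnot(learning_rate >= 0, epochs >= 1, prototypes_per_class >= 1)
  init <- match.arg(init, c("class_mean", "sample"))
  structure(list(learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 prototypes_per_class = as.integer(prototypes_per_class),
                 init = init, seed = as.integer(seed)),
            class = "lvq_config")
}

#' Flatten an activation map into an LVQ input vector
#'
#' Row-major flattening of the max-normalized 9x9 grid into an
#' 81-component vector; component `n` (0-based) is neuron `n` under the
#' shared lattice indexing, matching the row order of the activation-map
#' CSV.
#'
#' @param map An `activation_map`.
#' @return Numeric vector of normalized activations.
#' @export
flatten_map <- function(map) {
  validate_activation_map(map)
  as.numeric(map$normalized)
}

#' Train an LVQ1 classifier on activation-map vectors
#'
#' Prototypes are initialized per class (class means by default), then
#' trained by LVQ1 over seeded, per-epoch shuffled passes through the
#' examples. After every epoch the training-set misclassification ratio
#' is recorded, giving the loss curve used for choosing the learning
#' rate and epoch count.
#'
#' @param x Matrix of training vectors (rows = examples, typically
#'   81 columns), or a list of `activation_map`s.
#' @param labels Class label per example (`"sRCC"` / `"nsRCC"`).
#' @param config An `lvq_config`.
#' @return An `lvq_model`: `prototypes` matrix, parallel `labels`
#'   vector, `config`, and per-epoch `loss_curve`.
#' @export
train_lvq <- function(x, labels, config = lvq_config()) {
  stopifnot(inherits(config, "lvq_config"))
  if (is.list(x) && !is.data.frame(x) && is.null(dim(x)))
    x <- do.call(rbind, lapply(x, flatten_map))
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("usage error: non-finite training vectors")
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- unique(labels)
  if (length(classes) < 2)
    stop("usage error: LVQ training needs examples from >= 2 classes")

  ppc <- config$prototypes_per_class
  proto_list <- withr::with_seed(config$seed, {
    lapply(classes, function(cl) {
      rows <- x[labels == cl, , drop = FALSE]
      if (config$init == "class_mean") {
        base <- matrix(colMeans(rows), nrow = ppc, ncol = ncol(x),
                       byrow = TRUE)
        if (ppc > 1) # break symmetry between duplicate class means
          base[-1, ] <- base[-1, ] +
            matrix(rnorm((ppc - 1) * ncol(x), sd = 1e-3), ppc - 1)
        base
      } else {
        rows[sample.int(nrow(rows), ppc, replace = nrow(rows) < ppc), ,
             drop = FALSE]
      }
    })
  })
  prototypes <- do.call(rbind, proto_list)
  proto_labels <- rep(classes, each = ppc)

  orders <- withr::with_seed(config$seed + 1L,
    vapply(seq_len(config$epochs), function(e) sample.int(nrow(x)),
           integer(nrow(x))))
  if (is.null(dim(orders))) orders <- matrix(orders, nrow = 1)

  class_code <- match(labels, classes)
  fit <- lvq_train_cpp(prototypes, match(proto_labels, classes),
                       x, class_code, orders, config$learning_rate)
  structure(list(prototypes = fit$prototypes,
                 labels = proto_labels,
                 config = config,
                 loss_curve = as.numeric(fit$loss)),
            class = "lvq_model")
}

#' Predict class labels with a trained LVQ model
#'
#' Assigns each query to the class of its nearest prototype (Euclidean
#' distance, Voronoi-cell decision rule); ties break to the
#' earliest-inserted prototype.
#'
#' @param object An `lvq_model`.
#' @param newdata A single vector or a matrix of query vectors.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.lvq_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (!all(is.finite(newdata))) stop("usage error: non-finite query vector")
  if (ncol(newdata) != ncol(object$prototypes))
    stop("usage error: query dimension ", ncol(newdata),
         " does not match prototype dimension ", ncol(object$prototypes))
  idx <- bmu_cpp(object$prototypes, newdata) # strict < keeps first inserted
  object$labels[idx + 1L]
}

#' @export
print.lvq_model <- function(x, ...) {
  cat(sprintf("lvq_model: %d prototypes (%s), lr %g, %d epochs\n",
              nrow(x$prototypes), paste(x$labels, collapse = ", "),
              x$config$learning_rate, x$config$epochs))
  cat(sprintf("  final training loss: %.4f\n",
              x$loss_curve[length(x$loss_curve)]))
  invisible(x)
}
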
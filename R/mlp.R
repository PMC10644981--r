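#' Multilayer perceptron for edge-vector classification
#'
#' The classifier is a four-layer perceptron mapping a connectome edge
#' vector (3486 values for the 84-region DK parcellation) through hidden
#' layers of 1024, 256 and 64 rectified-linear units to 2 output logits,
#' one per group. `mlp_init` draws fan-in-scaled Gaussian ("He") initial
#' weights with zero biases, deterministically for a given seed — the seed
#' of the initial network weights is the unit of replication in repeated
#' cross-validation experiments.
#'
#' @param input_dim Length of the input edge vector.
#' @param hidden Integer vector of hidden-layer widths.
#' @param n_classes Number of output classes (2).
#' @param init_seed Integer seed for the weight draw.
#' @return An object of class `mlp`: list with `W` (list of weight
#'   matrices, input-by-output orientation), `b` (list of bias row
#'   vectors), `dims`, `init_seed`.
#' @examples
#' m <- mlp_init(6, hidden = c(4, 3), init_seed = 1)
#' mlp_forward(m, matrix(rnorm(12), 2))$prob
#' @export
mlp_init <- function(input_dim, hidden = c(1024L, 256L, 64L),
                     n_classes = 2L, init_seed = 0L) {
  stopifnot(input_dim >= 1, all(hidden >= 1), n_classes >= 2)
  dims <- c(as.integer(input_dim), as.integer(hidden), as.integer(n_classes))
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  withr_seed(init_seed, {
    for (l in seq_len(L)) {
      fan_in <- dims[l]
      W[[l]] <- matrix(stats::rnorm(fan_in * dims[l + 1L],
                                    sd = sqrt(2 / fan_in)),
                       fan_in, dims[l + 1L])
      b[[l]] <- rep(0, dims[l + 1L])
    }
  })
  structure(list(W = W, b = b, dims = dims,
                 init_seed = as.integer(init_seed)),
            class = "mlp")
}

#' @export
print.mlp <- function(x, ...) {
  cat("MLP:", paste(x$dims, collapse = " -> "),
      "(", format(sum(vapply(x$W, length, 1)) + sum(lengths(x$b)),
                  big.mark = ","), "parameters ),",
      "init seed", x$init_seed, "\n")
  invisible(x)
}

as_input_matrix <- function(x, input_dim) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != input_dim) {
    stop("input has ", ncol(x), " features, model expects ", input_dim)
  }
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite input")
  x
}

# Forward pass keeping pre-activations, for reuse by the gradient path.
mlp_forward_full <- function(model, X) {
  L <- length(model$W)
  Z <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A %*% model$W[[l]], 2, model$b[[l]], "+")
    A <- if (l < L) pmax(Z[[l]], 0) else Z[[l]]
  }
  Z
}

softmax_rows <- function(Z) {
  E <- exp(Z - apply(Z, 1, max))
  E / rowSums(E)
}

#' Forward pass: logits, probabilities, predicted class
#'
#' Double-precision forward evaluation. Probabilities are the softmax of
#' the logits; the predicted class is the argmax (0-based, matching group
#' labels), with ties broken toward class 0.
#'
#' @param model An [mlp_init()] (possibly trained) model.
#' @param x Input matrix (rows = participants) or a single edge vector.
#' @return List with `logits` (n x 2), `prob` (n x 2, rows sum to 1),
#'   `class` (integer vector of 0-based predicted classes).
#' @export
mlp_forward <- function(model, x) {
  X <- as_input_matrix(x, model$dims[1])
  Z <- mlp_forward_full(model, X)
  logits <- Z[[length(Z)]]
  prob <- softmax_rows(logits)
  list(logits = logits, prob = prob,
       class = max.col(prob, ties.method = "first") - 1L)
}

#' Training configuration
#'
#' Training is full-batch gradient descent with Adam-style adaptive
#' updates on the mean cross-entropy of the true labels: with cohorts of
#' a few dozen participants a full batch is natural and removes any
#' batch-order nondeterminism. Defaults: 100 epochs, learning rate 1e-3.
#'
#' @param epochs Number of full-batch updates (>= 1).
#' @param learning_rate Adam step size (> 0; 0 is allowed and leaves
#'   parameters unchanged, useful for testing).
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  stopifnot(epochs >= 1, learning_rate >= 0,
            beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1, adam_eps > 0)
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps),
            class = "train_config")
}

#' Train the perceptron on labelled edge vectors
#'
#' Runs `config$epochs` full-batch updates minimizing mean cross-entropy
#' `-log p[label]`. The compute kernel runs in single precision (the
#' standard working precision for neural-network training); returned
#' parameters are stored as doubles and evaluated by the double-precision
#' forward/gradient path. Deterministic for fixed data, initial
#' parameters and configuration.
#'
#' @param model Initial [mlp_init()] model.
#' @param X Input matrix, rows = participants.
#' @param y Integer labels in `{0, 1}` (generally `0..n_classes-1`).
#' @param config A [train_config()].
#' @return The trained `mlp`, with the per-epoch training-loss trajectory
#'   in `$loss` (loss is measured before each update, so `loss[1]` is the
#'   loss of the initial parameters).
#' @export
mlp_train <- function(model, X, y, config = train_config()) {
  stopifnot(inherits(model, "mlp"), inherits(config, "train_config"))
  X <- as_input_matrix(X, model$dims[1])
  y <- as.integer(y)
  n_classes <- model$dims[length(model$dims)]
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (any(y < 0L | y >= n_classes)) stop("labels out of range")
  if (length(unique(y)) < 2L) {
    stop("degenerate training set: only one class present")
  }
  fit <- cpp_train_mlp(model$W, lapply(model$b, rbind), X, y,
                       config$epochs, config$learning_rate,
                       config$beta1, config$beta2, config$adam_eps)
  model$W <- fit$W
  model$b <- lapply(fit$b, as.numeric)
  model$loss <- as.numeric(fit$loss)
  model$trained <- TRUE
  model
}

#' Gradient of a class output with respect to the input edges
#'
#' Computes `d f_c / d x` by backpropagation, where `f_c` is, per `mode`:
#' the softmax probability `p_c` (default), the raw logit `z_c`, or the
#' margin `z_c - z_{1-c}`. In probability mode with two classes the
#' class-0 and class-1 gradients on the same input are exact negatives,
#' because `p_0 + p_1 = 1`; this is the mechanical basis for the
#' positive/negative duality of per-group gradient scores.
#'
#' @param model A (typically trained) `mlp`.
#' @param x Input matrix (rows = participants) or single edge vector.
#' @param target_class 0-based class index, scalar or one per row of `x`.
#' @param mode One of `"probability"`, `"logit"`, `"margin"`.
#' @return Gradient matrix, same shape as the input matrix (one row per
#'   participant); a vector input yields a 1-row matrix.
#' @export
mlp_input_gradient <- function(model, x, target_class,
                               mode = c("probability", "logit", "margin")) {
  mode <- match.arg(mode)
  X <- as_input_matrix(x, model$dims[1])
  n <- nrow(X)
  n_classes <- model$dims[length(model$dims)]
  target_class <- as.integer(target_class)
  if (length(target_class) == 1L) target_class <- rep(target_class, n)
  if (length(target_class) != n ||
      any(target_class < 0L | target_class >= n_classes)) {
    stop("invalid target class index")
  }
  if (mode %in% c("margin") && n_classes != 2L) {
    stop("margin mode requires 2 classes")
  }
  L <- length(model$W)
  Z <- mlp_forward_full(model, X)
  cols <- target_class + 1L
  dZ <- matrix(0, n, n_classes)
  if (mode == "logit") {
    dZ[cbind(seq_len(n), cols)] <- 1
  } else if (mode == "margin") {
    dZ[cbind(seq_len(n), cols)] <- 1
    dZ[cbind(seq_len(n), 3L - cols)] <- -1
  } else {
    P <- softmax_rows(Z[[L]])
    if (n_classes == 2L) {
      # p0*p1 computed once and signed, so the two class gradients are
      # bitwise negatives of each other
      s <- P[, 1] * P[, 2]
      sgn <- ifelse(target_class == 0L, 1, -1)
      dZ[, 1] <- s * sgn
      dZ[, 2] <- -s * sgn
    } else {
      pc <- P[cbind(seq_len(n), cols)]
      dZ <- -P * pc
      dZ[cbind(seq_len(n), cols)] <- pc * (1 - pc)
    }
  }
  for (l in L:1) {
    dZ <- dZ %*% t(model$W[[l]])
    if (l > 1L) dZ <- dZ * (Z[[l - 1L]] > 0)
  }
  dZ
}

#' Model checkpoints
#'
#' Checkpoints are JSON key-value containers holding the layer dimensions,
#' init seed, weights and biases written at 17 significant digits, so a
#' reloaded model agrees with the original to within one unit in the
#' last place of every parameter.
#'
#' @param model An `mlp`.
#' @param path Destination / source path.
#' @return `read_mlp`: the restored `mlp`.
#' @export
write_mlp <- function(model, path) {
  stopifnot(inherits(model, "mlp"))
  obj <- list(format = "connectomlp-mlp-v1", dims = model$dims,
              init_seed = model$init_seed,
              trained = isTRUE(model$trained),
              loss = model$loss,
              W = model$W, b = model$b)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "connectomlp-mlp-v1")) {
    stop("not a connectomlp model checkpoint: ", path)
  }
  dims <- as.integer(obj$dims)
  W <- lapply(obj$W, function(w) matrix(as.numeric(w), nrow = nrow(w)))
  structure(list(W = W, b = lapply(obj$b, as.numeric), dims = dims,
                 init_seed = as.integer(obj$init_seed),
                 loss = obj$loss,
                 trained = isTRUE(obj$trained)),
            class = "mlp")
}
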
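#' @name autoencoder
#' @title Stacked autoencoder with softmax head
#'
#' @description
#' A depth (stacked) autoencoder built from the coding/decoding maps
#' `H = sigma(W x + b)` and `y = sigma(W' H + b')`, trained by minimizing
#' the summed binary cross-entropy reconstruction loss
#' `G(x, y) = -sum_i [x_i log y_i + (1 - x_i) log(1 - y_i)]` over inputs
#' scaled to \[0, 1\]. Training is greedy layer-wise pretraining (each
#' hidden layer fitted as a one-hidden-layer autoencoder on the previous
#' layer's codes) followed by end-to-end full-batch gradient descent with
#' a backtracking (halve-on-increase) step size, so the per-epoch mean
#' loss is nonincreasing and runs are exactly reproducible from the seed.
#' The code-layer activations are the "fine features" used in the
#' classifier comparison.
NULL

.sigmoid <- function(z) 1 / (1 + exp(-z))

.activate <- function(z, tag) switch(tag, sigmoid = .sigmoid(z),
                                     identity = z,
                                     stop("unknown activation: ", tag))

#' Construct one network layer
#' @param in_dim,out_dim layer dimensions.
#' @param activation `"sigmoid"` (default) or `"identity"`.
#' @param W,b optional explicit weights (out_dim x in_dim) and bias;
#'   when omitted, weights are drawn Uniform(-1/sqrt(in_dim),
#'   1/sqrt(in_dim)) from the current RNG state.
#' @export
make_layer <- function(in_dim, out_dim, activation = "sigmoid",
                       W = NULL, b = NULL) {
  if (is.null(W)) {
    lim <- 1 / sqrt(in_dim)
    W <- matrix(stats::runif(out_dim * in_dim, -lim, lim), out_dim, in_dim)
  }
  if (is.null(b)) b <- numeric(out_dim)
  stopifnot(all(dim(W) == c(out_dim, in_dim)), length(b) == out_dim,
            all(is.finite(W)), all(is.finite(b)))
  list(W = W, b = b, activation = activation)
}

# forward through a layer list; rows of A are samples.
# returns list of activations, element 1 = input.
.forward <- function(A, layers) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1]] <- A
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    Z <- sweep(acts[[l]] %*% t(ly$W), 2L, ly$b, "+")
    acts[[l + 1L]] <- .activate(Z, ly$activation)
  }
  acts
}

#' Encode / decode through an autoencoder
#'
#' `encode()` applies the encoder stack (`H = sigma(W x + b)` per layer);
#' `decode()` applies the mirrored decoder stack, mapping the hidden
#' feature back to a reconstruction in (0, 1).
#'
#' @param x numeric vector of length `input_dim`, or a matrix with one
#'   sample per row.
#' @param model an autoencoder model (see [train_autoencoder()]), or any
#'   list with `encoder` / `decoder` layer lists.
#' @return hidden feature (encode) or reconstruction (decode), matching
#'   the input's vector/matrix form.
#' @export
encode <- function(x, model) .run_stack(x, model$encoder)

#' @rdname encode
#' @param H hidden feature vector or matrix.
#' @export
decode <- function(H, model) .run_stack(H, model$decoder)

.run_stack <- function(x, layers) {
  vec <- is.null(dim(x))
  A <- if (vec) matrix(x, nrow = 1) else x
  if (ncol(A) != ncol(layers[[1]]$W))
    stop(sprintf("input has %d components, layer expects %d",
                 ncol(A), ncol(layers[[1]]$W)))
  if (!all(is.finite(A))) stop("non-finite input")
  out <- .forward(A, layers)[[length(layers) + 1L]]
  if (vec) drop(out) else out
}

#' Binary cross-entropy reconstruction loss
#'
#' Summed elementwise binary cross-entropy between an input in \[0, 1\]
#' and a reconstruction in (0, 1), with the convention 0 log 0 = 0.
#' Reconstruction components outside (0, 1) are clamped to
#' \[1e-12, 1 - 1e-12\] and a message is logged.
#'
#' @param x input vector/matrix, values in \[0, 1\].
#' @param y reconstruction of the same shape.
#' @return total loss (scalar, >= 0); zero only for exact binary
#'   reconstruction.
#' @export
reconstruction_loss <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  eps <- 1e-12
  # 0*log(0) := 0, applied before clamping so exact binary agreement is 0;
  # y values outside (0, 1) that still contribute are clamped and logged
  if (any(y[x > 0] <= 0) || any(y[x < 1] >= 1))
    message("reconstruction values clamped to (0, 1) for the loss")
  term1 <- ifelse(x == 0, 0, x * log(pmax(y, eps)))
  term2 <- ifelse(x == 1, 0, (1 - x) * log(pmax(1 - y, eps)))
  -sum(term1 + term2)
}

# mean-per-sample BCE for training (y strictly inside (0,1) via sigmoid)
.bce_mean <- function(X, Y) {
  eps <- 1e-12
  Yc <- pmin(pmax(Y, eps), 1 - eps)
  -sum(X * log(Yc) + (1 - X) * log(1 - Yc)) / nrow(X)
}

# backprop gradients of mean BCE wrt all layer params of a full stack
# (encoder then decoder); final layer must be sigmoid (BCE shortcut).
.bce_gradients <- function(X, layers, acts) {
  n <- nrow(X)
  L <- length(layers)
  grads <- vector("list", L)
  delta <- (acts[[L + 1L]] - X) / n          # dL/dz at sigmoid+BCE output
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(delta, acts[[l]]),
                       b = colSums(delta))
    if (l > 1L) {
      dA <- delta %*% layers[[l]]$W
      a <- acts[[l]]
      delta <- switch(layers[[l - 1L]]$activation,
                      sigmoid = dA * a * (1 - a),
                      identity = dA)
    }
  }
  grads
}

.apply_step <- function(layers, grads, lr) {
  for (l in seq_along(layers)) {
    layers[[l]]$W <- layers[[l]]$W - lr * grads[[l]]$W
    layers[[l]]$b <- layers[[l]]$b - lr * grads[[l]]$b
  }
  layers
}

# full-batch gradient descent with a backtracking step size: the step is
# halved until the loss does not increase (so the recorded loss is
# nonincreasing) and grows by 10% after each accepted step, which lets the
# optimizer escape the slow small-gain regime of stacked sigmoids without
# ever accepting an uphill move.
.gd_train <- function(X, layers, epochs, lr, loss_fn, grad_fn) {
  acts <- .forward(X, layers)
  loss <- loss_fn(X, acts)
  history <- numeric(epochs)
  step <- lr
  for (e in seq_len(epochs)) {
    grads <- grad_fn(X, layers, acts)
    repeat {
      cand <- .apply_step(layers, grads, step)
      cand_acts <- .forward(X, cand)
      cand_loss <- loss_fn(X, cand_acts)
      if (is.finite(cand_loss) && cand_loss <= loss) {
        layers <- cand; acts <- cand_acts; loss <- cand_loss
        step <- step * 1.1
        break
      }
      step <- step / 2
      if (step < 1e-14) break   # no improving step this epoch: stay put
    }
    history[e] <- loss
  }
  list(layers = layers, history = history)
}

#' Train a stacked autoencoder
#'
#' Greedy layer-wise pretraining followed by end-to-end fine-tuning of the
#' full encoder/decoder stack by full-batch gradient descent on the binary
#' cross-entropy reconstruction loss. The learning rate backtracks (is
#' halved) whenever a step would increase the loss, so the recorded
#' per-epoch mean loss is nonincreasing. Deterministic given `seed`.
#'
#' @param data n x M matrix with values in \[0, 1\].
#' @param layer_dims hidden layer widths, strictly decreasing from M
#'   toward the code layer. Default: the geometric schedule
#'   ceiling(M/2), ceiling(M/4), ceiling(M/8) (three hidden layers).
#' @param epochs fine-tuning epochs (pretraining uses `pretrain_epochs`).
#' @param learning_rate initial step size (default 0.1).
#' @param seed integer seed for weight initialization.
#' @param pretrain_epochs epochs per greedy stage.
#' @return autoencoder model: `encoder`, `decoder` (mirrored layer lists),
#'   `input_dim`, `layer_dims`, `history` (fine-tuning mean loss per
#'   epoch), `seed`.
#' @export
train_autoencoder <- function(data, layer_dims = NULL, epochs = 150L,
                              learning_rate = 0.1, seed = 1L,
                              pretrain_epochs = 100L) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("need at least 2 samples")
  if (any(data < 0 | data > 1) || anyNA(data))
    stop("data must lie in [0, 1] (cross-entropy loss domain)")
  M <- ncol(data)
  if (is.null(layer_dims)) {
    layer_dims <- unique(pmax(1L, ceiling(M / c(2, 4, 8))))
    layer_dims <- layer_dims[layer_dims < M]
  }
  dims <- c(M, as.integer(layer_dims))
  if (any(diff(dims) >= 0))
    stop("layer_dims must be strictly decreasing from the input dimension")
  set.seed(as.integer(seed))
  encoder <- list(); decoder_rev <- list()
  A <- data
  for (h in seq_along(layer_dims)) {
    din <- dims[h]; dout <- dims[h + 1L]
    stage <- list(make_layer(din, dout), make_layer(dout, din))
    fit <- .gd_train(A, stage, pretrain_epochs, learning_rate,
                     loss_fn = function(X, acts) .bce_mean(X, acts[[3L]]),
                     grad_fn = .bce_gradients)
    encoder[[h]] <- fit$layers[[1L]]
    decoder_rev[[h]] <- fit$layers[[2L]]
    A <- .forward(A, encoder[h])[[2L]]
  }
  stack <- c(encoder, rev(decoder_rev))
  L <- length(stack)
  fit <- .gd_train(data, stack, epochs, learning_rate,
                   loss_fn = function(X, acts) .bce_mean(X, acts[[L + 1L]]),
                   grad_fn = .bce_gradients)
  k <- length(layer_dims)
  structure(list(encoder = fit$layers[seq_len(k)],
                 decoder = fit$layers[(k + 1L):L],
                 input_dim = M, layer_dims = as.integer(layer_dims),
                 history = fit$history, seed = as.integer(seed)),
            class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf("<autoencoder> %d -> %s; final loss %.4f after %d epochs\n",
              x$input_dim, paste(x$layer_dims, collapse = " -> "),
              utils::tail(x$history, 1), length(x$history)))
  invisible(x)
}

#' Code-layer ("fine") features
#' @param data n x M matrix in \[0, 1\].
#' @param model trained [train_autoencoder()] model (or any encoder list).
#' @return n x code_dim matrix of code-layer activations.
#' @export
fine_features <- function(data, model) encode(as.matrix(data), model)

# ---- softmax classifier ----------------------------------------------------

.softmax_prob <- function(X, W, b) {
  Z <- sweep(X %*% t(W), 2L, b, "+")
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

.ce_loss <- function(P, Y) -sum(Y * log(pmax(P, 1e-300))) / nrow(P)

#' Fit a softmax (multinomial logistic) classifier
#'
#' Full-batch gradient descent with backtracking on the multinomial
#' cross-entropy; predicted class is the argmax probability and the
#' probability rows sum to 1.
#'
#' @param features n x d numeric matrix.
#' @param labels factor (or coercible) with at least 2 classes present.
#' @param epochs,lr gradient descent settings.
#' @param seed seed for the (zero) initialization order; kept for
#'   reproducibility of downstream splits.
#' @return list: `W`, `b`, `classes`, `history`.
#' @export
softmax_fit <- function(features, labels, epochs = 300L, lr = 0.5,
                        seed = 1L) {
  X <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(droplevels(y)) < 2L) stop("need at least 2 classes")
  y <- droplevels(y)
  k <- nlevels(y); d <- ncol(X); n <- nrow(X)
  Y <- matrix(0, n, k); Y[cbind(seq_len(n), as.integer(y))] <- 1
  set.seed(as.integer(seed))
  W <- matrix(0, k, d); b <- numeric(k)
  loss <- .ce_loss(.softmax_prob(X, W, b), Y)
  history <- numeric(epochs)
  step <- lr
  for (e in seq_len(epochs)) {
    P <- .softmax_prob(X, W, b)
    G <- (P - Y) / n
    gW <- crossprod(G, X); gb <- colSums(G)
    repeat {
      W2 <- W - step * gW; b2 <- b - step * gb
      l2 <- .ce_loss(.softmax_prob(X, W2, b2), Y)
      if (is.finite(l2) && l2 <= loss) {
        W <- W2; b <- b2; loss <- l2; step <- step * 1.1
        break
      }
      step <- step / 2
      if (step < 1e-14) break
    }
    history[e] <- loss
  }
  list(W = W, b = b, classes = levels(y), history = history)
}

#' @rdname softmax_fit
#' @param fit a fitted softmax model.
#' @export
softmax_predict <- function(fit, features) {
  P <- .softmax_prob(as.matrix(features), fit$W, fit$b)
  factor(fit$classes[max.col(P)], levels = fit$classes)
}

#' @rdname softmax_fit
#' @export
softmax_prob <- function(fit, features) {
  .softmax_prob(as.matrix(features), fit$W, fit$b)
}

#' Train a softmax classifier with a held-out split
#'
#' Seeded random split; the classifier is fitted on the training part and
#' scored on the held-out part.
#'
#' @inheritParams softmax_fit
#' @param split_fraction held-out fraction.
#' @return list: `fit`, `accuracy`, `n_train`, `n_test`, `seed`.
#' @export
train_softmax <- function(features, labels, epochs = 300L, lr = 0.5,
                          seed = 1L, split_fraction = 0.3) {
  X <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(droplevels(y)) < 2L) stop("need at least 2 classes")
  sp <- .class_safe_split(y, split_fraction, seed)
  fit <- softmax_fit(X[sp$train, , drop = FALSE], y[sp$train], epochs, lr,
                     seed)
  pred <- softmax_predict(fit, X[sp$test, , drop = FALSE])
  list(fit = fit, accuracy = mean(pred == y[sp$test]),
       n_train = length(sp$train), n_test = length(sp$test),
       seed = as.integer(seed))
}

# split with every class present on both sides; re-split (logged) if not
.class_safe_split <- function(y, split_fraction, seed) {
  n <- length(y)
  set.seed(as.integer(seed))
  for (attempt in 1:100) {
    test <- sort(sample.int(n, max(1L, round(split_fraction * n))))
    train <- setdiff(seq_len(n), test)
    if (nlevels(droplevels(y[train])) == nlevels(droplevels(y)) &&
        nlevels(droplevels(y[test])) == nlevels(droplevels(y))) {
      if (attempt > 1L) message("re-split needed to cover all classes")
      return(list(train = train, test = test))
    }
  }
  stop("could not produce a split containing every class on both sides")
}

#' Jointly fine-tune an encoder with a softmax head
#'
#' Supervised tuning step: the pretrained encoder stack and a softmax head
#' are trained together by full-batch gradient descent on the multinomial
#' cross-entropy, adjusting the hidden-unit weights according to the
#' classifier's performance. Backtracking keeps the loss nonincreasing.
#'
#' @param encoder list of encoder layers (from [train_autoencoder()]).
#' @param features n x M training matrix in \[0, 1\].
#' @param labels training labels (factor).
#' @param epochs,lr gradient descent settings.
#' @return list: `encoder` (tuned), `softmax` (head fit), `history`.
#' @export
finetune_encoder_softmax <- function(encoder, features, labels,
                                     epochs = 200L, lr = 0.5) {
  X <- as.matrix(features)
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  k <- nlevels(y); n <- nrow(X)
  Y <- matrix(0, n, k); Y[cbind(seq_len(n), as.integer(y))] <- 1
  code_dim <- nrow(encoder[[length(encoder)]]$W)
  # small random head init: a zero head has zero gradient into the encoder
  W <- matrix(stats::runif(k * code_dim, -0.5, 0.5), k, code_dim)
  b <- numeric(k)
  loss_of <- function(enc, W, b) {
    H <- .forward(X, enc)[[length(enc) + 1L]]
    .ce_loss(.softmax_prob(H, W, b), Y)
  }
  loss <- loss_of(encoder, W, b)
  history <- numeric(epochs)
  L <- length(encoder)
  step <- lr
  for (e in seq_len(epochs)) {
    acts <- .forward(X, encoder)
    H <- acts[[L + 1L]]
    P <- .softmax_prob(H, W, b)
    G <- (P - Y) / n
    gW_head <- crossprod(G, H); gb_head <- colSums(G)
    # backprop into encoder
    delta <- (G %*% W) * H * (1 - H)        # code layer is sigmoid
    grads <- vector("list", L)
    for (l in L:1) {
      grads[[l]] <- list(W = crossprod(delta, acts[[l]]), b = colSums(delta))
      if (l > 1L) {
        dA <- delta %*% encoder[[l]]$W
        a <- acts[[l]]
        delta <- dA * a * (1 - a)
      }
    }
    repeat {
      enc2 <- .apply_step(encoder, grads, step)
      W2 <- W - step * gW_head; b2 <- b - step * gb_head
      l2 <- loss_of(enc2, W2, b2)
      if (is.finite(l2) && l2 <= loss) {
        encoder <- enc2; W <- W2; b <- b2; loss <- l2
        step <- step * 1.1
        break
      }
      step <- step / 2
      if (step < 1e-14) break
    }
    history[e] <- loss
  }
  list(encoder = encoder,
       softmax = list(W = W, b = b, classes = levels(y), history = history),
       history = history)
}

#' Raw-versus-fine feature classifier comparison
#'
#' For each seed: split the data, train a linear SVM, an RBF SVM and a
#' softmax classifier on the raw features; pretrain a stacked autoencoder
#' on the training split only, tune it jointly with a softmax head on the
#' training labels, extract code-layer ("fine") features, and train the
#' same three classifiers on them; report held-out accuracies.
#'
#' @param feature_table n x M matrix in \[0, 1\] (or a data.frame).
#' @param labels class labels.
#' @param split_fraction held-out fraction (default 0.3).
#' @param seeds integer vector of split/initialization seeds.
#' @param layer_dims,pretrain_epochs,finetune_epochs autoencoder settings.
#' @return data.frame: seed, featureset ("raw"/"fine"), classifier
#'   ("softmax"/"linear_svm"/"rbf_svm"), accuracy, n_train, n_test.
#' @export
comparison_experiment <- function(feature_table, labels,
                                  split_fraction = 0.3, seeds = 1:20,
                                  layer_dims = NULL,
                                  pretrain_epochs = 300L,
                                  finetune_epochs = 1500L) {
  X <- as.matrix(feature_table)
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  out <- list()
  for (sd in seeds) {
    sp <- .class_safe_split(y, split_fraction, sd)
    Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
    Xte <- X[sp$test, , drop = FALSE]; yte <- y[sp$test]
    ae <- train_autoencoder(Xtr, layer_dims = layer_dims,
                            epochs = pretrain_epochs,
                            pretrain_epochs = pretrain_epochs, seed = sd)
    tuned <- finetune_encoder_softmax(ae$encoder, Xtr, ytr,
                                      epochs = finetune_epochs)
    sets <- list(raw = list(tr = Xtr, te = Xte),
                 fine = list(tr = .forward(Xtr, tuned$encoder)[[length(tuned$encoder) + 1L]],
                             te = .forward(Xte, tuned$encoder)[[length(tuned$encoder) + 1L]]))
    for (fs in names(sets)) {
      tr <- sets[[fs]]$tr; te <- sets[[fs]]$te
      acc <- c(
        softmax = {
          fit <- softmax_fit(tr, ytr, seed = sd)
          mean(softmax_predict(fit, te) == yte)
        },
        linear_svm = .svm_accuracy(tr, ytr, te, yte, "linear"),
        rbf_svm = .svm_accuracy(tr, ytr, te, yte, "radial"))
      out[[length(out) + 1L]] <- data.frame(
        seed = sd, featureset = fs, classifier = names(acc),
        accuracy = unname(acc), n_train = nrow(tr), n_test = nrow(te))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.svm_accuracy <- function(Xtr, ytr, Xte, yte, kernel) {
  fit <- e1071::svm(Xtr, ytr, kernel = kernel, scale = FALSE)
  mean(stats::predict(fit, Xte) == yte)
}
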
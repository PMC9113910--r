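test_that("encode and decode follow the layer equations", {
  # identity activation, W = I, b = 0: H = x
  id <- list(encoder = list(make_layer(3, 3, "identity", W = diag(3))))
  x <- c(0.2, 0.5, 0.9)
  expect_equal(encode(x, id), x)

  # sigmoid with zero weights: every component 0.5
  z <- list(encoder = list(make_layer(4, 2, "sigmoid",
                                      W = matrix(0, 2, 4))))
  expect_equal(encode(c(0.1, 0.2, 0.3, 0.4), z), c(0.5, 0.5))

  # hand case: W = [[1, -1]], b = 0, x = (1, 1) -> sigmoid(0) = 0.5
  h <- list(encoder = list(make_layer(2, 1, "sigmoid",
                                      W = matrix(c(1, -1), 1, 2))))
  expect_equal(encode(c(1, 1), h), 0.5)

  expect_error(encode(c(1, 2, 3), h), "components")

  # mirrored orthonormal linear construction: decode(encode(x)) = x
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mdl <- list(encoder = list(make_layer(2, 2, "identity", W = R)),
              decoder = list(make_layer(2, 2, "identity", W = t(R))))
  x2 <- c(0.3, -1.2)
  expect_equal(decode(encode(x2, mdl), mdl), x2, tolerance = 1e-10)

  # zero decoder weights: y = 0.5 * 1
  zd <- list(decoder = list(make_layer(2, 3, "sigmoid", W = matrix(0, 3, 2))))
  expect_equal(decode(c(0.4, 0.6), zd), rep(0.5, 3))
})

test_that("the reconstruction loss matches hand values and its gradient", {
  expect_identical(reconstruction_loss(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(reconstruction_loss(c(1, 0), c(0.5, 0.5)), 2 * log(2),
               tolerance = 1e-12)
  # perfectly wrong binary reconstruction needs clamping to stay finite
  expect_message(val <- reconstruction_loss(c(1, 0), c(0, 1)), "clamped")
  expect_equal(val, -2 * log(1e-12), tolerance = 1e-6)
  expect_error(reconstruction_loss(c(1.2, 0), c(0.5, 0.5)), "\\[0, 1\\]")

  # gradient wrt y against central finite differences
  set.seed(30)
  x <- runif(6); y <- runif(6, 0.1, 0.9)
  analytic <- -(x / y - (1 - x) / (1 - y))
  h <- 1e-6
  numeric <- vapply(seq_along(y), function(i) {
    yp <- y; ym <- y
    yp[i] <- y[i] + h; ym[i] <- y[i] - h
    (reconstruction_loss(x, yp) - reconstruction_loss(x, ym)) / (2 * h)
  }, 0)
  expect_equal(analytic, numeric, tolerance = 1e-6)
})

test_that("backprop gradients match finite differences on a random model", {
  set.seed(31)
  X <- matrix(runif(8 * 5), 8, 5)
  layers <- list(make_layer(5, 3), make_layer(3, 2),
                 make_layer(2, 3), make_layer(3, 5))
  fw <- phnalff:::.forward
  bm <- phnalff:::.bce_mean
  acts <- fw(X, layers)
  grads <- phnalff:::.bce_gradients(X, layers, acts)
  h <- 1e-6
  loss_at <- function(ls) {
    a <- fw(X, ls)
    bm(X, a[[length(ls) + 1L]])
  }
  for (l in seq_along(layers)) {
    # a few weight entries and one bias entry per layer
    for (pick in 1:3) {
      i <- sample(nrow(layers[[l]]$W), 1); j <- sample(ncol(layers[[l]]$W), 1)
      lp <- layers; lp[[l]]$W[i, j] <- lp[[l]]$W[i, j] + h
      lm <- layers; lm[[l]]$W[i, j] <- lm[[l]]$W[i, j] - h
      fd <- (loss_at(lp) - loss_at(lm)) / (2 * h)
      expect_equal(grads[[l]]$W[i, j], fd, tolerance = 1e-5)
    }
    i <- sample(length(layers[[l]]$b), 1)
    bp <- layers; bp[[l]]$b[i] <- bp[[l]]$b[i] + h
    bmn <- layers; bmn[[l]]$b[i] <- bmn[[l]]$b[i] - h
    fd <- (loss_at(bp) - loss_at(bmn)) / (2 * h)
    expect_equal(grads[[l]]$b[i], fd, tolerance = 1e-5)
  }
})

test_that("training reduces the loss monotonically and reproducibly", {
  set.seed(32)
  X <- matrix(runif(40 * 8), 40, 8)
  m1 <- train_autoencoder(X, epochs = 40, pretrain_epochs = 30, seed = 5)
  expect_true(all(diff(m1$history) <= 0))
  expect_lt(tail(m1$history, 1), m1$history[1])

  m2 <- train_autoencoder(X, epochs = 40, pretrain_epochs = 30, seed = 5)
  expect_identical(m1$encoder, m2$encoder)

  expect_error(train_autoencoder(X - 2, seed = 1), "\\[0, 1\\]")
  expect_error(train_autoencoder(X, layer_dims = c(4, 6), seed = 1),
               "strictly decreasing")
  expect_error(train_autoencoder(X[1, , drop = FALSE], seed = 1),
               "2 samples")
})

test_that("identical rows drive the loss to the entropy floor", {
  x <- c(0.2, 0.8, 0.5, 0.9)
  X <- matrix(x, 20, 4, byrow = TRUE)
  m <- train_autoencoder(X, layer_dims = c(3, 2), epochs = 400,
                         pretrain_epochs = 300, seed = 6)
  floor_ <- -sum(x * log(x) + (1 - x) * log(1 - x))
  expect_equal(tail(m$history, 1), floor_, tolerance = 0.05)

  # trained reconstruction beats an untrained model of the same shape
  set.seed(7)
  untrained <- list(
    encoder = list(make_layer(4, 3), make_layer(3, 2)),
    decoder = list(make_layer(2, 3), make_layer(3, 4)))
  rec_tr <- decode(encode(X, m), m)
  rec_un <- decode(encode(X, untrained), untrained)
  expect_lt(reconstruction_loss(X, rec_tr), reconstruction_loss(X, rec_un))
})

test_that("fine features have the code shape and differ from raw", {
  set.seed(33)
  X <- matrix(runif(30 * 10), 30, 10)
  m <- train_autoencoder(X, epochs = 30, pretrain_epochs = 30, seed = 2)
  H <- fine_features(X, m)
  expect_identical(dim(H), c(30L, tail(m$layer_dims, 1)))
  expect_identical(H, fine_features(X, m))
  expect_false(isTRUE(all.equal(dim(H), dim(X))))
})

test_that("the softmax classifier is a proper probabilistic classifier", {
  set.seed(34)
  lin <- simulate_feature_table(60, 5, "linear", seed = 8, separation = 5)
  res <- train_softmax(lin$features, lin$labels, seed = 3)
  expect_gte(res$accuracy, 0.95)
  P <- softmax_prob(res$fit, lin$features)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-10)
  expect_error(train_softmax(lin$features, rep("A", 120)), "2 classes")
})

test_that("the classifier comparison behaves at its reference points", {
  # large-margin linear structure: both feature sets near-perfect
  lin <- simulate_feature_table(60, 6, "linear", seed = 9, separation = 6)
  rep_lin <- comparison_experiment(lin$features, lin$labels, seeds = 1:2,
                                   pretrain_epochs = 150L,
                                   finetune_epochs = 400L)
  expect_true(all(rep_lin$accuracy >= 0.9))
  expect_identical(sort(unique(rep_lin$classifier)),
                   c("linear_svm", "rbf_svm", "softmax"))

  # permuted labels: all accuracies near chance (2 classes)
  set.seed(35)
  nl <- simulate_feature_table(100, 8, "nonlinear", seed = 10)
  shuffled <- sample(nl$labels)
  rep_null <- comparison_experiment(nl$features, shuffled, seeds = 1:3,
                                    pretrain_epochs = 100L,
                                    finetune_epochs = 200L)
  agg <- aggregate(accuracy ~ featureset, rep_null, mean)
  expect_true(all(abs(agg$accuracy - 0.5) < 0.15))
})
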
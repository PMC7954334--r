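test_that("model parameter counts match the closed-form layer formulas", {
  v <- 50L; d <- 8L; f <- 6L; k <- 3L; h <- 5L
  spec <- model_spec("cnn", embedding_dim = d, conv_filters = f,
                     conv_kernel = k, hidden_units = h)
  m <- build_model(spec, v, seed = 1)
  n_params <- sum(vapply(m$params, length, integer(1)))
  expect_equal(n_params,
               v * d + (k * d * f + f) + (f * h + h) + (h + 1))

  u <- 7L
  spec_l <- model_spec("lstm", embedding_dim = d, lstm_units = u)
  ml <- build_model(spec_l, v, seed = 1)
  expect_equal(sum(vapply(ml$params, length, integer(1))),
               v * d + (d * 4 * u + u * 4 * u + 4 * u) + (u + 1))

  expect_error(build_model(spec, 1L), "at least 2")
})

test_that("builds are deterministic and outputs are valid probabilities", {
  spec <- model_spec("cnn", embedding_dim = 4, conv_filters = 3,
                     conv_kernel = 2, hidden_units = 3)
  m1 <- build_model(spec, 20L, seed = 7)
  m2 <- build_model(spec, 20L, seed = 7)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(spec, 20L, seed = 8)
  expect_false(identical(m1$params, m3$params))

  X <- matrix(sample(0:19, 30, replace = TRUE), nrow = 5)
  for (kind in c("cnn", "lstm")) {
    sp <- model_spec(kind, embedding_dim = 4, conv_filters = 3,
                     conv_kernel = 2, hidden_units = 3, lstm_units = 4)
    mm <- build_model(sp, 20L, seed = 1)
    p <- traitminer:::.nn_forward(mm$params, X, mm$spec)$prob
    expect_length(p, 5)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("backpropagated gradients match numerical differentiation", {
  set.seed(3)
  X <- matrix(sample(0:9, 24, replace = TRUE), nrow = 4)
  y <- c(1, 0, 1, 0)
  for (kind in c("cnn", "lstm")) {
    spec <- model_spec(kind, embedding_dim = 3, conv_filters = 3,
                       conv_kernel = 2, hidden_units = 3, lstm_units = 3,
                       dropout = 0)
    params <- traitminer:::.nn_init(spec, 10L)
    fwd <- traitminer:::.nn_forward(params, X, spec, training = FALSE)
    grads <- traitminer:::.nn_backward(params, fwd$cache,
                                       matrix(y, ncol = 1), spec)
    loss_at <- function(p) {
      traitminer:::.bce(traitminer:::.nn_forward(p, X, spec)$prob, y)
    }
    eps <- 1e-5
    for (nm in names(params)) {
      idx <- sample(length(params[[nm]]), min(5, length(params[[nm]])))
      for (i in idx) {
        up <- params; up[[nm]][i] <- up[[nm]][i] + eps
        dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
        numeric_grad <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        expect_equal(grads[[nm]][i], numeric_grad, tolerance = 1e-4,
                     label = sprintf("%s grad %s[%d]", kind, nm, i))
      }
    }
  }
})

test_that("train/eval splits partition the corpus reproducibly", {
  sp <- split_train_eval(1200L, 1000L, seed = 4)
  expect_length(sp$eval, 200L)
  expect_identical(sp, split_train_eval(1200L, 1000L, seed = 4))
  expect_length(intersect(sp$train, sp$eval), 0L)
  expect_setequal(c(sp$train, sp$eval), 1:1200)
  expect_error(split_train_eval(10L, 10L), "smaller")
})

test_that("training minimizes the loss and beats the keyword baseline", {
  sc <- small_corpus()
  tr <- trait_fermentation()
  y <- as.integer(sc$manifest$trait1_label == "positive")
  texts <- vapply(sc$corpus$text, winnow, character(1), trait = tr,
                  config = text_prep_config(), USE.NAMES = FALSE)
  sp <- split_train_eval(length(texts), 80L, seed = 2)
  v <- fit_vocabulary(texts[sp$train], 3000)
  m <- build_model(model_spec("cnn"), v, seed = 2)
  m <- train_model(m, tokenize_texts(texts[sp$train], v), y[sp$train],
                   train_config(seed = 2))
  expect_lt(utils::tail(m$history, 1), m$history[1])
  pred <- predict(m, tokenize_texts(texts[sp$eval], v), vocab = v)
  acc <- mean(pred$label == y[sp$eval])
  base_acc <- mean(keyword_baseline(texts[sp$eval], tr) == y[sp$eval])
  expect_gte(acc, 0.9)
  expect_gt(acc, base_acc)
})

test_that("training is label-symmetric on the separable corpus", {
  # symmetry holds for species whose winnowed text reaches the network;
  # empty-text species are short-circuited to negative by design, so they
  # are excluded from the comparison
  sc <- small_corpus()
  tr <- trait_fermentation()
  y <- as.integer(sc$manifest$trait1_label == "positive")
  texts <- vapply(sc$corpus$text, winnow, character(1), trait = tr,
                  config = text_prep_config(), USE.NAMES = FALSE)
  sp <- split_train_eval(length(texts), 80L, seed = 3)
  v <- fit_vocabulary(texts[sp$train], 3000)
  seq_tr <- tokenize_texts(texts[sp$train], v)
  seq_ev <- tokenize_texts(texts[sp$eval], v)
  nonempty <- nzchar(texts[sp$eval])
  accs <- vapply(list(y, 1L - y), function(lab) {
    m <- train_model(build_model(model_spec("cnn"), v, seed = 3),
                     seq_tr, lab[sp$train], train_config(seed = 3))
    mean((predict(m, seq_ev, vocab = v)$label == lab[sp$eval])[nonempty])
  }, numeric(1))
  expect_equal(accs[1], accs[2], tolerance = 0.05)
})

test_that("degenerate training inputs are rejected or inert", {
  v <- fit_vocabulary("a b c d", 10)
  m <- build_model(model_spec("cnn"), v, seed = 1)
  expect_error(train_model(m, list(), integer(0)), "empty")
  expect_error(train_model(m, list(1L, 2L), c(1L, 1L)), "single class")

  # epochs = 0: untrained model, majority-class behaviour near chance
  m0 <- train_model(m, list(1L, 2L, c(1L, 2L), 3L), c(1L, 0L, 1L, 0L),
                    train_config(epochs = 0L, seed = 1))
  expect_length(m0$history, 0L)
  p <- predict(m0, list(c(1L, 2L)), vocab = v)
  expect_true(p$prob > 0.2 & p$prob < 0.8)  # near the sigmoid's center
})

test_that("prediction short-circuits empty sequences and checks tokenizer", {
  v1 <- fit_vocabulary("ferments glucose to acetate", 10)
  v2 <- fit_vocabulary("completely different words here", 10)
  m <- build_model(model_spec("cnn"), v1, seed = 1)
  m <- train_model(m, list(c(1L, 2L), 3L, c(2L, 3L), 1L), c(1L, 0L, 1L, 0L),
                   train_config(epochs = 1L, seed = 1))
  out <- predict(m, list(integer(0), c(1L, 2L)), vocab = v1)
  expect_identical(out$label[1], 0L)
  expect_true(is.na(out$prob[1]))
  expect_false(is.na(out$prob[2]))
  expect_error(predict(m, list(1L), vocab = v2), "tokenizer mismatch")

  # threshold 0 labels every non-empty sequence positive
  out0 <- predict(m, list(integer(0), 1L, 2L), threshold = 0, vocab = v1)
  expect_identical(out0$label, c(0L, 1L, 1L))
})

test_that("replicate runs are reproducible and report per-cell metrics", {
  sc <- small_corpus()
  tr <- trait_fermentation()
  y <- as.integer(sc$manifest$trait1_label == "positive")
  texts <- vapply(sc$corpus$text, winnow, character(1), trait = tr,
                  config = text_prep_config(), USE.NAMES = FALSE)
  cfg <- train_config(replicates = 2L, seed = 5)
  run <- run_replicates(texts, y, sizes = c(40L, 80L),
                        config = cfg, trait_name = "fermentation")
  expect_equal(nrow(run$metrics), 2 * 2 * 4)  # sizes x reps x metrics
  expect_setequal(unique(run$metrics$metric),
                  c("accuracy", "f1", "precision", "sensitivity"))
  run2 <- run_replicates(texts, y, sizes = c(40L, 80L),
                         config = cfg, trait_name = "fermentation")
  expect_identical(run$metrics, run2$metrics)
  # each run records its split for downstream tree exclusion
  r1 <- run$runs[["n40_r1"]]
  expect_length(r1$train, 40L)
  expect_length(intersect(r1$train, r1$eval), 0L)
  expect_error(run_replicates(texts, y, sizes = length(texts)),
               "smaller than the corpus")
})
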
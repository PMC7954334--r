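#' Specify a classifier architecture
#'
#' Two small binary text classifiers are available. The convolutional model
#' is embedding -> 1-D convolution (ReLU) -> global average pooling ->
#' dense hidden layer (ReLU) -> single sigmoid output, with dropout (rate
#' 0.2 by default) on the embedding and hidden dense layers. The LSTM model
#' is embedding -> LSTM layer (dropout on its inputs) -> single sigmoid
#' output. The default layer widths are the smallest that saturate the
#' synthetic classification task; all are overridable.
#'
#' @param kind `"cnn"` or `"lstm"`.
#' @param embedding_dim Embedding dimension.
#' @param conv_filters,conv_kernel Convolution width and kernel size (cnn).
#' @param hidden_units Hidden dense width (cnn).
#' @param lstm_units LSTM state size (lstm).
#' @param dropout Dropout rate in \[0,1).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(kind = c("cnn", "lstm"), embedding_dim = 16L,
                       conv_filters = 16L, conv_kernel = 5L,
                       hidden_units = 16L, lstm_units = 32L,
                       dropout = 0.2) {
  kind <- match.arg(kind)
  stopifnot(embedding_dim > 0, conv_filters > 0, conv_kernel > 0,
            hidden_units > 0, lstm_units > 0,
            dropout >= 0, dropout < 1)
  structure(list(kind = kind,
                 embedding_dim = as.integer(embedding_dim),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 hidden_units = as.integer(hidden_units),
                 lstm_units = as.integer(lstm_units),
                 dropout = dropout),
            class = "model_spec")
}

#' Training configuration
#'
#' Defaults follow the training regime that works well for this task:
#' mini-batches of 32, Adam, binary cross-entropy, 10 epochs — escalated to
#' 40 epochs when the training set is small (`n_train <= small_n`), where
#' more passes are needed to minimize the loss. Five replicate trainings
#' per training-set size give the mean and SEM of each metric.
#'
#' @param batch_size Mini-batch size.
#' @param epochs Number of epochs, or `NULL` for the size-dependent rule.
#' @param small_n Training-set size at or below which `epochs_small` is used.
#' @param epochs_small Epochs for small training sets.
#' @param replicates Independent trainings per training-set size.
#' @param seed Integer seed governing splits, initialization, shuffling and
#'   dropout.
#' @param threshold Decision threshold on the sigmoid output.
#' @param learning_rate Adam step size.
#' @param resample_split If `TRUE` (default) each replicate draws a fresh
#'   train/eval split as well as fresh weights; if `FALSE` the split is
#'   fixed across replicates and only initialization/shuffling vary.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, epochs = NULL, small_n = 250L,
                         epochs_small = 40L, replicates = 5L, seed = 1L,
                         threshold = 0.5, learning_rate = 0.001,
                         resample_split = TRUE) {
  stopifnot(batch_size >= 1, replicates >= 1,
            threshold >= 0, threshold <= 1, learning_rate > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = if (is.null(epochs)) NULL else as.integer(epochs),
                 small_n = as.integer(small_n),
                 epochs_small = as.integer(epochs_small),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), threshold = threshold,
                 learning_rate = learning_rate,
                 resample_split = isTRUE(resample_split)),
            class = "train_config")
}

.epochs_for <- function(config, n_train) {
  config$epochs %||%
    (if (n_train <= config$small_n) config$epochs_small else 10L)
}

#' Build an untrained classifier
#'
#' Initializes weights deterministically from `seed` (uniform embedding,
#' Glorot-uniform kernels, zero biases, LSTM forget-gate bias 1).
#'
#' @param spec A [model_spec()].
#' @param vocab Either a fitted [fit_vocabulary()] object (preferred; its
#'   `num_words` bound sizes the embedding and its fingerprint is stored so
#'   prediction can detect tokenizer mismatch) or an integer vocabulary
#'   size.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `trait_model`.
#' @export
build_model <- function(spec, vocab, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  if (inherits(vocab, "trait_vocabulary")) {
    vocab_size <- vocab$num_words
    vhash <- .vocab_hash(vocab)
  } else {
    vocab_size <- as.integer(vocab)
    vhash <- NA_real_
  }
  if (is.na(vocab_size) || vocab_size < 2)
    stop("vocabulary size must be at least 2", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  structure(list(spec = spec, params = .nn_init(spec, vocab_size),
                 vocab_size = vocab_size, vocab_hash = vhash,
                 max_len = NA_integer_, history = numeric(0),
                 trained = FALSE),
            class = "trait_model")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.trait_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<trait_model> %s, vocab %d, %d parameters, %s\n",
              x$spec$kind, x$vocab_size, np,
              if (x$trained) sprintf("trained (%d epochs, final loss %.4f)",
                                     length(x$history),
                                     utils::tail(x$history, 1))
              else "untrained"))
  invisible(x)
}

#' Split a corpus into training and evaluation sets
#'
#' A simple random sample without replacement of `n_train` species forms
#' the training set; all remaining species form the evaluation set. The
#' returned indices are also what the phylogenetic comparison uses to
#' exclude training species from trait trees.
#'
#' @param n_species Number of species (or a corpus data frame).
#' @param n_train Training-set size, strictly less than `n_species`.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `eval`.
#' @export
split_train_eval <- function(n_species, n_train, seed = 1L) {
  if (is.data.frame(n_species)) n_species <- nrow(n_species)
  n_species <- as.integer(n_species)
  if (n_train >= n_species)
    stop("`n_train` must be smaller than the corpus size", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  train <- sort(sample.int(n_species, n_train))
  list(train = train, eval = setdiff(seq_len(n_species), train))
}

#' Train a classifier
#'
#' Minimizes binary cross-entropy with mini-batch Adam. The training
#' sequences must already be tokenized against the vocabulary the model was
#' built with. Per-epoch mean training loss is recorded in the returned
#' model's `history`. With `epochs = 0` the model is returned untrained.
#'
#' @param model An untrained (or previously trained) [build_model()] result.
#' @param sequences List of integer token sequences (training set).
#' @param labels 0/1 vector aligned with `sequences`.
#' @param config A [train_config()].
#' @return The trained `trait_model`.
#' @export
train_model <- function(model, sequences, labels, config = train_config()) {
  stopifnot(inherits(model, "trait_model"), inherits(config, "train_config"))
  labels <- as.integer(labels)
  n <- length(sequences)
  if (n == 0L) stop("empty training set", call. = FALSE)
  if (length(labels) != n)
    stop("`labels` must align with `sequences`", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class; loss is degenerate",
         call. = FALSE)
  epochs <- .epochs_for(config, n)
  batch <- pad_batch(sequences)
  model$max_len <- ncol(batch$tokens)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  params <- model$params
  state <- .adam_init(params)
  history <- numeric(0)
  if (epochs > 0) {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (b0 in seq(1L, n, by = config$batch_size)) {
        take <- ord[b0:min(b0 + config$batch_size - 1L, n)]
        Xb <- batch$tokens[take, , drop = FALSE]
        yb <- matrix(labels[take], ncol = 1)
        fwd <- .nn_forward(params, Xb, model$spec, training = TRUE)
        losses <- c(losses, .bce(fwd$prob, labels[take]))
        grads <- .nn_backward(params, fwd$cache, yb, model$spec)
        upd <- .adam_step(params, grads, state, lr = config$learning_rate)
        params <- upd$params; state <- upd$state
      }
      history <- c(history, mean(losses))
    }
  }
  model$params <- params
  model$history <- history
  model$trained <- TRUE
  model
}

#' Predict trait labels for tokenized texts
#'
#' Applies the trained network and thresholds its sigmoid outputs. Species
#' whose (winnowed) text tokenized to an empty sequence never reach the
#' network: they carry no trait evidence and are predicted negative
#' directly, with `NA` probability.
#'
#' @param object A trained `trait_model`.
#' @param sequences List of integer token sequences, tokenized with the
#'   model's own vocabulary.
#' @param threshold Decision threshold; label is positive when probability
#'   >= threshold.
#' @param vocab Optional: the vocabulary used to tokenize `sequences`. If
#'   supplied and the model was built from a fitted vocabulary, a
#'   fingerprint mismatch is an error.
#' @param ... Unused.
#' @return List with `prob` (numeric, `NA` for empty sequences) and `label`
#'   (integer 0/1).
#' @export
predict.trait_model <- function(object, sequences, threshold = 0.5,
                                vocab = NULL, ...) {
  if (!is.null(vocab) && inherits(vocab, "trait_vocabulary") &&
      !is.na(object$vocab_hash) &&
      .vocab_hash(vocab) != object$vocab_hash)
    stop("tokenizer mismatch: `sequences` were tokenized with a different ",
         "vocabulary than the model was trained with", call. = FALSE)
  n <- length(sequences)
  prob <- rep(NA_real_, n)
  lab <- integer(n)
  nonempty <- which(lengths(sequences) > 0L)
  if (length(nonempty)) {
    L <- if (is.na(object$max_len)) NULL else object$max_len
    padded <- pad_batch(sequences[nonempty], max_len = L)
    bad <- padded$tokens >= object$vocab_size
    if (any(bad))
      stop("token index out of range for this model's vocabulary",
           call. = FALSE)
    # chunk to bound memory on large evaluation sets
    for (b0 in seq(1L, length(nonempty), by = 512L)) {
      take <- b0:min(b0 + 511L, length(nonempty))
      fwd <- .nn_forward(object$params,
                         padded$tokens[take, , drop = FALSE],
                         object$spec, training = FALSE)
      prob[nonempty[take]] <- fwd$prob
    }
    lab[nonempty] <- as.integer(prob[nonempty] >= threshold)
  }
  list(prob = prob, label = lab)
}

#' Keyword-only baseline classifier
#'
#' Predicts positive exactly when a description satisfies the trait's
#' keyword rule. This is the baseline a trained network must beat: keyword
#' search cannot tell "ferments glucose" from "non-fermentative", so every
#' negated keyword is a false positive for it.
#'
#' @param texts Character vector of descriptions.
#' @param trait A [trait_definition()].
#' @return Integer 0/1 predictions.
#' @export
keyword_baseline <- function(texts, trait) {
  as.integer(matches_trait(texts, trait))
}

#' Learning curve over training-set sizes with replicate trainings
#'
#' For every training-set size and replicate: draw a fresh train/eval
#' split, fit the vocabulary on the training texts only, tokenize both
#' sets, build a freshly initialized model, train it, and evaluate
#' accuracy, F1, precision and sensitivity on the held-out set. Replicate
#' seeds are derived deterministically from `config$seed`, so the whole run
#' is reproducible.
#'
#' @param texts Character vector of prepared (winnowed or full) texts.
#' @param labels 0/1 vector aligned with `texts`.
#' @param sizes Integer vector of training-set sizes.
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @param prep A [text_prep_config()]; supplies `num_words` and the
#'   vocabulary-fitting policy.
#' @param model_name,trait_name Labels for the output table.
#' @return Object of class `learning_run`: list with `metrics` (long tibble:
#'   model, trait, n_train, replicate, metric, value), `runs` (per
#'   size x replicate: split indices, predictions on the evaluation set) and
#'   `summary` (via [summarize_curve()]).
#' @export
run_replicates <- function(texts, labels, sizes, spec = model_spec("cnn"),
                           config = train_config(),
                           prep = text_prep_config(),
                           model_name = spec$kind, trait_name = "trait") {
  labels <- as.integer(labels)
  stopifnot(length(texts) == length(labels))
  if (max(sizes) >= length(texts))
    stop("every training size must be smaller than the corpus", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  cell_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                  length(sizes) * config$replicates),
                       nrow = length(sizes))
  rows <- list(); runs <- list()
  for (si in seq_along(sizes)) {
    n_train <- sizes[si]
    for (r in seq_len(config$replicates)) {
      seed_r <- cell_seeds[si, r]
      split_seed <- if (config$resample_split) seed_r else cell_seeds[si, 1]
      sp <- split_train_eval(length(texts), n_train, seed = split_seed)
      fit_texts <- if (prep$fit_on == "all") texts else texts[sp$train]
      vocab <- fit_vocabulary(fit_texts, num_words = prep$num_words)
      seq_train <- tokenize_texts(texts[sp$train], vocab)
      seq_eval <- tokenize_texts(texts[sp$eval], vocab)
      model <- build_model(spec, vocab, seed = seed_r)
      cfg_r <- config; cfg_r$seed <- seed_r
      model <- train_model(model, seq_train, labels[sp$train], cfg_r)
      pred <- predict(model, seq_eval, threshold = config$threshold,
                      vocab = vocab)
      met <- metric_report(confusion(pred$label, labels[sp$eval]))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = model_name, trait = trait_name, n_train = n_train,
        replicate = r, metric = names(met), value = unname(met))
      runs[[sprintf("n%d_r%d", n_train, r)]] <-
        list(n_train = n_train, replicate = r, seed = seed_r,
             train = sp$train, eval = sp$eval,
             prob = pred$prob, label = pred$label)
    }
  }
  metrics <- do.call(rbind, rows)
  structure(list(metrics = metrics, runs = runs,
                 summary = summarize_curve(metrics)),
            class = "learning_run")
}

#' @export
print.learning_run <- function(x, ...) {
  cat("<learning_run> ", length(x$runs), " trainings\n", sep = "")
  print(x$summary)
  invisible(x)
}
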
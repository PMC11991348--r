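# Per-region binary PPE classifier head: dropout(0.2) -> dense(hidden) ->
# ReLU -> dense(1) -> sigmoid, trained with Adam on binary cross-entropy.
# The scalar output layer before the sigmoid is required to obtain a
# probability and is documented as an interpretation of the published
# architecture sentence.

#' Training configuration for a classifier head
#'
#' @param epochs Training epochs (default 10).
#' @param learning_rate Adam step size (default 1e-3; Adam's standard
#'   default, with beta1 = 0.9, beta2 = 0.999, eps = 1e-8).
#' @param batch_size Mini-batch size (default 32; recorded in run
#'   metadata).
#' @param validation_fraction Held-out fraction, a seeded shuffle taking
#'   this share of the data (default 0.2).
#' @param seed Seed controlling the split, shuffling and dropout.
#' @return A `ppe_train_config` list.
#' @export
train_config <- function(epochs = 10L, learning_rate = 1e-3, batch_size = 32L,
                         validation_fraction = 0.2, seed = 1L) {
  stopifnot(
    epochs >= 1, learning_rate > 0, batch_size >= 1,
    validation_fraction > 0, validation_fraction < 1
  )
  structure(
    list(
      epochs = as.integer(epochs), learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      validation_fraction = validation_fraction, seed = as.integer(seed)
    ),
    class = "ppe_train_config"
  )
}

#' Create an untrained classifier head
#'
#' @param input_dim Feature length F the head consumes (default 712).
#' @param hidden_dim Hidden layer width (default 712).
#' @param dropout_rate Input dropout rate, active only during training
#'   (default 0.2).
#' @param decision_threshold Probability cut-off for the boolean prediction
#'   (default 0.5).
#' @param init `"glorot"` (seeded uniform) or `"zero"`.
#' @param seed Seed for weight initialisation.
#' @return A `ppe_head` object.
#' @export
classifier_head <- function(input_dim = 712L, hidden_dim = 712L,
                            dropout_rate = 0.2, decision_threshold = 0.5,
                            init = c("glorot", "zero"), seed = 1L) {
  init <- match.arg(init)
  stopifnot(dropout_rate >= 0, dropout_rate < 1, input_dim >= 1, hidden_dim >= 1)
  if (init == "glorot") {
    lim1 <- sqrt(6 / (input_dim + hidden_dim))
    lim2 <- sqrt(6 / (hidden_dim + 1))
    w <- withr::with_seed(seed, list(
      W1 = matrix(runif(input_dim * hidden_dim, -lim1, lim1), input_dim, hidden_dim),
      b1 = rep(0, hidden_dim),
      w2 = runif(hidden_dim, -lim2, lim2),
      b2 = 0
    ))
  } else {
    w <- list(
      W1 = matrix(0, input_dim, hidden_dim), b1 = rep(0, hidden_dim),
      w2 = rep(0, hidden_dim), b2 = 0
    )
  }
  structure(
    list(
      input_dim = as.integer(input_dim), hidden_dim = as.integer(hidden_dim),
      dropout_rate = dropout_rate, decision_threshold = decision_threshold,
      weights = w, trained = identical(init, "zero"), history = NULL
    ),
    class = "ppe_head"
  )
}

head_forward <- function(head, X) {
  w <- head$weights
  H <- X %*% w$W1
  H <- sweep(H, 2, w$b1, "+")
  A <- pmax(H, 0)
  z <- as.numeric(A %*% w$w2 + w$b2)
  list(A = A, H = H, p = 1 / (1 + exp(-z)))
}

#' Predict PPE presence from feature vectors
#'
#' Inference-mode forward pass: dropout disabled, fully deterministic.
#' Probability = sigmoid of the scalar output; the boolean prediction is
#' `probability >= decision_threshold`.
#'
#' @param head A trained `ppe_head`.
#' @param features Numeric vector of length F, or an n x F matrix.
#' @return Tibble with columns `probability` and `prediction`.
#' @export
predict_head <- function(head, features) {
  stopifnot(inherits(head, "ppe_head"))
  if (!isTRUE(head$trained)) abort("head is untrained; call train_head() first")
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(X) != head$input_dim) abort("feature length does not match head input_dim")
  p <- head_forward(head, X)$p
  tibble::tibble(probability = p, prediction = p >= head$decision_threshold)
}

bce_loss <- function(p, y) {
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_new <- function(w) list(m = lapply(w, function(x) x * 0), v = lapply(w, function(x) x * 0), t = 0)

adam_step <- function(w, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  for (k in names(w)) {
    st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g[[k]]
    st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * g[[k]]^2
    mhat <- st$m[[k]] / (1 - b1^st$t)
    vhat <- st$v[[k]] / (1 - b2^st$t)
    w[[k]] <- w[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, st = st)
}

#' Train a classifier head
#'
#' Splits the data with a seeded shuffle (the stated fraction held out for
#' validation), then runs mini-batch Adam on binary cross-entropy for the
#' configured number of epochs, with inverted input dropout active during
#' training only. Fully deterministic given the config seed.
#'
#' @param head An untrained or previously trained `ppe_head`.
#' @param features n x F feature matrix.
#' @param labels Logical or 0/1 vector of length n; both classes must be
#'   present.
#' @param config A [train_config()].
#' @return The trained head, with a `history` tibble (`epoch`,
#'   `train_loss`, `val_loss`, `val_acc`).
#' @export
train_head <- function(head, features, labels, config = train_config()) {
  stopifnot(inherits(head, "ppe_head"), inherits(config, "ppe_train_config"))
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) abort("labels must be boolean or 0/1")
  if (length(unique(y)) < 2) {
    abort("training data contains a single class; both classes are required")
  }
  if (nrow(X) != length(y)) abort("features and labels disagree in length")
  if (ncol(X) != head$input_dim) abort("feature length does not match head input_dim")

  n <- nrow(X)
  n_val <- max(1L, floor(config$validation_fraction * n))
  w <- head$weights
  st <- adam_new(w)
  keep <- head$dropout_rate

  history <- withr::with_seed(config$seed, {
    perm <- sample.int(n)
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[-seq_len(n_val)]
    Xtr <- X[tr_idx, , drop = FALSE]
    ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]
    yval <- y[val_idx]
    ntr <- length(tr_idx)

    rows <- vector("list", config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(ntr)
      losses <- c()
      for (b0 in seq(1, ntr, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, ntr)]
        Xb <- Xtr[idx, , drop = FALSE]
        yb <- ytr[idx]
        if (keep > 0) {
          drop_mask <- matrix(
            (runif(length(Xb)) >= keep) / (1 - keep),
            nrow(Xb), ncol(Xb)
          )
          Xb <- Xb * drop_mask
        }
        fw <- head_forward(list(weights = w), Xb)
        losses <- c(losses, bce_loss(fw$p, yb))
        m <- length(yb)
        d2 <- (fw$p - yb) / m
        gA <- outer(d2, w$w2) * (fw$H > 0)
        g <- list(
          W1 = crossprod(Xb, gA),
          b1 = colSums(gA),
          w2 = as.numeric(crossprod(fw$A, d2)),
          b2 = sum(d2)
        )
        upd <- adam_step(w, g, st, config$learning_rate)
        w <- upd$w
        st <- upd$st
      }
      vp <- head_forward(list(weights = w), Xval)$p
      rows[[ep]] <- tibble::tibble(
        epoch = ep,
        train_loss = mean(losses),
        val_loss = bce_loss(vp, yval),
        val_acc = mean((vp >= head$decision_threshold) == (yval == 1))
      )
    }
    dplyr::bind_rows(rows)
  })

  head$weights <- w
  head$trained <- TRUE
  head$history <- history
  head$train_meta <- list(
    n_train = n - n_val, n_val = n_val, batch_size = config$batch_size,
    epochs = config$epochs, seed = config$seed
  )
  head
}

#' Evaluate a head on labelled feature vectors
#'
#' @param head A trained `ppe_head`.
#' @param features n x F feature matrix.
#' @param labels Logical or 0/1 vector.
#' @return A [confusion_2x2()] (ground truth on rows, prediction on
#'   columns).
#' @export
evaluate_head <- function(head, features, labels) {
  y <- as.logical(labels)
  if (length(y) == 0) abort("cannot evaluate on an empty dataset")
  pred <- predict_head(head, as.matrix(features))$prediction
  confusion_2x2(
    a = sum(y & pred), b = sum(y & !pred),
    c = sum(!y & pred), d = sum(!y & !pred)
  )
}

#' @method tidy ppe_head
#' @export
tidy.ppe_head <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(
      epoch = integer(), train_loss = double(),
      val_loss = double(), val_acc = double()
    ))
  }
  x$history
}

#' @method glance ppe_head
#' @export
glance.ppe_head <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    trained = isTRUE(x$trained),
    epochs = if (is.null(h)) 0L else nrow(h),
    final_train_loss = if (is.null(h)) NA_real_ else h$train_loss[nrow(h)],
    final_val_loss = if (is.null(h)) NA_real_ else h$val_loss[nrow(h)],
    final_val_acc = if (is.null(h)) NA_real_ else h$val_acc[nrow(h)],
    input_dim = x$input_dim, hidden_dim = x$hidden_dim,
    dropout_rate = x$dropout_rate
  )
}

#' @export
print.ppe_head <- function(x, ...) {
  cat(sprintf(
    "<ppe_head> %d -> %d -> 1, dropout %.2f, %s\n",
    x$input_dim, x$hidden_dim, x$dropout_rate,
    if (isTRUE(x$trained)) "trained" else "untrained"
  ))
  if (!is.null(x$history)) {
    cat(sprintf(
      "  %d epochs, final val_acc %.3f\n",
      nrow(x$history), x$history$val_acc[nrow(x$history)]
    ))
  }
  invisible(x)
}

#' Save / load a trained head as a JSON weight bundle
#'
#' @param head A `ppe_head`.
#' @param path File path (.json).
#' @export
write_head <- function(head, path) {
  obj <- list(
    format = "ppe_head_v1",
    input_dim = head$input_dim, hidden_dim = head$hidden_dim,
    dropout_rate = head$dropout_rate,
    decision_threshold = head$decision_threshold,
    trained = head$trained,
    weights = list(
      W1 = as.vector(head$weights$W1), b1 = head$weights$b1,
      w2 = head$weights$w2, b2 = head$weights$b2
    ),
    history = head$history
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_head
#' @export
read_head <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "ppe_head_v1")) abort("not a ppe_head bundle")
  head <- classifier_head(
    input_dim = obj$input_dim, hidden_dim = obj$hidden_dim,
    dropout_rate = obj$dropout_rate,
    decision_threshold = obj$decision_threshold, init = "zero"
  )
  head$weights <- list(
    W1 = matrix(obj$weights$W1, obj$input_dim, obj$hidden_dim),
    b1 = obj$weights$b1, w2 = obj$weights$w2, b2 = obj$weights$b2
  )
  head$trained <- isTRUE(obj$trained)
  if (!is.null(obj$history) && length(obj$history)) {
    head$history <- tibble::as_tibble(obj$history)
  }
  head
}
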
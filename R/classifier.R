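## Per-window fatigue classifier: feed-forward network with 3 inputs
## (longest eye closure, yawn count, PERCLOS), one hidden layer, 1 output,
## trained by back-propagation with the Adam optimizer on binary
## cross-entropy. Written in plain matrix R so the stated training regime
## (mini-batches, epoch histories, per-node-count comparisons) is fully
## controllable and reproducible.

FEATURE_COLS <- c("longest_closure", "yawn_count", "perclos")

#' Empirical candidates for the hidden-layer size
#'
#' The usual single-hidden-layer sizing rule `m = sqrt(i + j) + c` with the
#' constant `c` ranging over 1..10, for `i` input and `j` output nodes. The
#' additive variant `m = i + j + c` is also available.
#'
#' @param i,j Positive integer input/output layer sizes.
#' @param form `"sqrt"` (default) or `"linear"`.
#' @param constants Integer vector of constants `c` (default `1:10`).
#' @return Integer vector of candidate hidden-node counts.
#' @export
#' @examples
#' hidden_node_candidates(3, 1)  # 3..12; sizes 3..8 are the usual test range
hidden_node_candidates <- function(i, j, form = c("sqrt", "linear"),
                                   constants = 1:10) {
  form <- match.arg(form)
  if (!is.numeric(i) || !is.numeric(j) || i < 1 || j < 1)
    stop("layer sizes must be positive integers", call. = FALSE)
  base <- if (form == "sqrt") round(sqrt(i + j)) else i + j
  as.integer(base + constants)
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (all(FEATURE_COLS %in% names(x))) x <- x[, FEATURE_COLS]
    x <- as.matrix(x)
  }
  stopifnot(is.matrix(x), is.numeric(x))
  x
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

sigmoid_ <- function(z) 1 / (1 + exp(-z))

#' Fit the per-window fatigue classifier
#'
#' Trains a feed-forward network (logistic hidden and output activations)
#' on labelled window features by mini-batch back-propagation with the Adam
#' optimizer and binary cross-entropy loss. Features are standardized
#' (z-score) using statistics of the training split; the scaling is stored
#' in the model so prediction is invariant to consistent affine re-encoding
#' of the raw feature units.
#'
#' @param x Feature matrix or data frame; columns `longest_closure`,
#'   `yawn_count`, `perclos` are used if present, otherwise all numeric
#'   columns.
#' @param y 0/1 or logical labels (1 = fatigue); both classes must occur.
#' @param hidden Hidden-layer size (default 4; see
#'   [hidden_node_candidates()]).
#' @param epochs Training epochs (default 4000).
#' @param batch_size Mini-batch size (default 8).
#' @param learning_rate Adam step size (default 1e-3).
#' @param validation_split Fraction held out for validation (default 0.1,
#'   i.e. a 90/10 split).
#' @param seed Integer RNG seed for split, initialization and batch
#'   shuffling (default 0); identical seed, data and settings reproduce
#'   identical weights.
#' @return Object of class `"fatigue_net"`: weights (`w1`, `b1`, `w2`,
#'   `b2`), scaling (`center`, `scale`), `history` (per-epoch data frame
#'   with train/validation loss and accuracy), and the call settings.
#' @seealso [predict.fatigue_net()], [compare_hidden_nodes()]
#' @export
fatigue_net <- function(x, y, hidden = 4, epochs = 4000, batch_size = 8,
                        learning_rate = 1e-3, validation_split = 0.1,
                        seed = 0) {
  x <- as_feature_matrix(x)
  y <- as.numeric(as.logical(y))
  stopifnot(nrow(x) == length(y), hidden >= 1, epochs >= 1, batch_size >= 1,
            validation_split >= 0, validation_split < 1)
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training data contains a single class", call. = FALSE)

  with_seed(seed, {
    n <- nrow(x); d <- ncol(x)
    n_val <- floor(n * validation_split)
    perm <- sample.int(n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)
    center <- colMeans(x[tr_idx, , drop = FALSE])
    scale <- apply(x[tr_idx, , drop = FALSE], 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    xs <- sweep(sweep(x, 2, center), 2, scale, "/")
    xtr <- xs[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    xva <- xs[val_idx, , drop = FALSE]; yva <- y[val_idx]

    w1 <- matrix(stats::rnorm(d * hidden, sd = 1 / sqrt(d)), d, hidden)
    b1 <- rep(0, hidden)
    w2 <- matrix(stats::rnorm(hidden, sd = 1 / sqrt(hidden)), hidden, 1)
    b2 <- 0
    pars <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
    adam_m <- lapply(pars, function(p) p * 0)
    adam_v <- lapply(pars, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0

    forward <- function(p, xm) {
      h <- sigmoid_(sweep(xm %*% p$w1, 2, p$b1, "+"))
      list(h = h, out = drop(sigmoid_(h %*% p$w2 + p$b2)))
    }
    bce <- function(prob, lab) {
      prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
      -mean(lab * log(prob) + (1 - lab) * log(1 - prob))
    }
    hist_rows <- matrix(NA_real_, epochs, 4,
                        dimnames = list(NULL, c("train_loss", "train_acc",
                                                "val_loss", "val_acc")))
    ntr <- nrow(xtr)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(ntr)
      for (start in seq(1, ntr, by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1L, ntr)]
        xb <- xtr[bi, , drop = FALSE]; yb <- ytr[bi]
        fw <- forward(pars, xb)
        # gradient of mean BCE with sigmoid output: delta = (p - y)/B
        dout <- matrix((fw$out - yb) / length(bi), ncol = 1)
        g <- list(
          w1 = NULL, b1 = NULL,
          w2 = t(fw$h) %*% dout,
          b2 = sum(dout)
        )
        dh <- (dout %*% t(pars$w2)) * fw$h * (1 - fw$h)
        g$w1 <- t(xb) %*% dh
        g$b1 <- colSums(dh)
        t_step <- t_step + 1
        for (nm in names(pars)) {
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g[[nm]]
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g[[nm]]^2
          mhat <- adam_m[[nm]] / (1 - beta1^t_step)
          vhat <- adam_v[[nm]] / (1 - beta2^t_step)
          pars[[nm]] <- pars[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      ftr <- forward(pars, xtr)
      hist_rows[ep, 1] <- bce(ftr$out, ytr)
      hist_rows[ep, 2] <- mean((ftr$out > 0.5) == ytr)
      if (length(yva)) {
        fva <- forward(pars, xva)
        hist_rows[ep, 3] <- bce(fva$out, yva)
        hist_rows[ep, 4] <- mean((fva$out > 0.5) == yva)
      }
    }
    structure(list(
      w1 = pars$w1, b1 = pars$b1, w2 = pars$w2, b2 = pars$b2,
      center = center, scale = scale,
      feature_names = colnames(x),
      history = data.frame(epoch = seq_len(epochs), hist_rows),
      settings = list(hidden = hidden, epochs = epochs,
                      batch_size = batch_size,
                      learning_rate = learning_rate,
                      validation_split = validation_split, seed = seed)
    ), class = "fatigue_net")
  })
}

#' Predict fatigue state for window features
#'
#' @param object A fitted [fatigue_net()].
#' @param newdata Feature matrix/data frame (columns as at fit time) or a
#'   [window_features()] row.
#' @param ... Unused.
#' @return Data frame with `probability` (network output in `[0, 1]`) and
#'   `state` (1 = fatigue iff probability > 0.5; exactly 0.5 counts awake).
#'   For a single row, a list with scalar `probability` and `state`.
#' @export
predict.fatigue_net <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  if (ncol(x) != length(object$center))
    stop("feature dimension mismatch", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  h <- sigmoid_(sweep(xs %*% object$w1, 2, object$b1, "+"))
  prob <- drop(sigmoid_(h %*% object$w2 + object$b2))
  state <- as.integer(prob > 0.5)
  if (length(prob) == 1L) list(probability = prob, state = state)
  else data.frame(probability = prob, state = state)
}

#' @export
print.fatigue_net <- function(x, ...) {
  s <- x$settings
  cat(sprintf("fatigue_net: %d-%d-1 feed-forward classifier\n",
              length(x$center), s$hidden))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  %d epochs (batch %d, Adam lr %g); final train acc %.3f",
              s$epochs, s$batch_size, s$learning_rate, h$train_acc))
  if (!is.na(h$val_acc)) cat(sprintf(", val acc %.3f", h$val_acc))
  cat("\n")
  invisible(x)
}

#' @export
summary.fatigue_net <- function(object, ...) {
  out <- list(settings = object$settings,
              n_parameters = length(object$w1) + length(object$b1) +
                length(object$w2) + 1L,
              final = object$history[nrow(object$history), ])
  class(out) <- "summary.fatigue_net"
  out
}

#' @export
print.summary.fatigue_net <- function(x, ...) {
  cat(sprintf("Feed-forward fatigue classifier, hidden = %d (%d parameters)\n",
              x$settings$hidden, x$n_parameters))
  print(x$final, row.names = FALSE)
  invisible(x)
}

#' @export
coef.fatigue_net <- function(object, ...) {
  list(w1 = object$w1, b1 = object$b1, w2 = object$w2, b2 = object$b2)
}

#' Plot training history of a fatigue classifier
#'
#' @param x A fitted [fatigue_net()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fatigue_net <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, h[, c("train_loss", "val_loss")], type = "l",
                    lty = 1:2, col = c("black", "red"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Compare hidden-layer sizes
#'
#' Trains one model per candidate hidden-node count under a fixed seed and
#' tabulates final train/validation loss and accuracy — the harness used to
#' choose the hidden-layer size.
#'
#' @inheritParams fatigue_net
#' @param node_list Integer vector of hidden sizes to try.
#' @param ... Passed to [fatigue_net()].
#' @return Data frame with one row per size: `hidden`, `train_loss`,
#'   `train_acc`, `val_loss`, `val_acc`.
#' @export
compare_hidden_nodes <- function(x, y, node_list, ...) {
  stopifnot(length(node_list) >= 1)
  rows <- lapply(node_list, function(m) {
    fit <- fatigue_net(x, y, hidden = m, ...)
    h <- fit$history[nrow(fit$history), ]
    data.frame(hidden = m, train_loss = h$train_loss,
               train_acc = h$train_acc, val_loss = h$val_loss,
               val_acc = h$val_acc)
  })
  do.call(rbind, rows)
}

#' Serialize / restore a fatigue classifier as JSON
#'
#' Stores shapes, weights, scaling parameters and settings; restoring yields
#' a model whose predictions match the original bit-for-bit.
#'
#' @param model A [fatigue_net()].
#' @param path File path.
#' @return `read_fatigue_net()` returns the restored `"fatigue_net"`.
#' @export
write_fatigue_net <- function(model, path) {
  stopifnot(inherits(model, "fatigue_net"))
  payload <- list(
    class = "fatigue_net",
    w1 = model$w1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
    center = model$center, scale = model$scale,
    feature_names = model$feature_names,
    settings = model$settings
  )
  # 17 significant digits guarantee exact double round-trip
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fatigue_net
#' @export
read_fatigue_net <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$class, "fatigue_net"))
    stop("not a serialized fatigue_net model", call. = FALSE)
  structure(list(
    w1 = as.matrix(p$w1), b1 = as.numeric(p$b1),
    w2 = as.matrix(p$w2), b2 = as.numeric(p$b2),
    center = stats::setNames(as.numeric(p$center), p$feature_names),
    scale = stats::setNames(as.numeric(p$scale), p$feature_names),
    feature_names = p$feature_names,
    history = NULL, settings = p$settings
  ), class = "fatigue_net")
}
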
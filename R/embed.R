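#' Autoencoder configuration
#'
#' A fully connected encoder-decoder: encoder widths are
#' `input -> hidden_dims`, the last entry being the bottleneck; the decoder
#' mirrors the encoder. Defaults follow the reference architecture
#' (hidden widths 4000/1500/800/400, bottleneck 400) with ReLU activations,
#' identity output (inputs mix \[0, 1\] and unscaled values, so a squashing
#' output would bias reconstruction), mean-squared-error loss, Adam at
#' learning rate 0.001, batch size 32, up to 200 epochs with early stopping
#' at patience 5 on a 10% validation split.
#'
#' @param hidden_dims encoder hidden widths; last entry is the bottleneck.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size; clamped (with a warning) to the
#'   training-set size.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without strict validation improvement before
#'   stopping.
#' @param val_fraction fraction of samples held out for validation.
#' @param seed RNG seed driving the split, weight init and batch shuffling.
#' @return an `ae_config` list.
#' @export
ae_config <- function(hidden_dims = c(4000, 1500, 800, 400),
                      learning_rate = 0.001,
                      batch_size = 32,
                      max_epochs = 200,
                      patience = 5,
                      val_fraction = 0.1,
                      seed = 1) {
  stopifnot(length(hidden_dims) >= 1, all(hidden_dims >= 1),
            val_fraction > 0, val_fraction < 1,
            patience >= 1, batch_size >= 1, max_epochs >= 1,
            learning_rate >= 0)
  structure(list(hidden_dims = as.integer(hidden_dims),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = seed),
            class = "ae_config")
}

relu <- function(z) pmax(z, 0)

# act_relu: logical per layer; the bottleneck and output layers are linear
# (a rectified bottleneck could not carry signed latent coordinates)
ae_forward <- function(weights, biases, x, act_relu) {
  acts <- vector("list", length(weights) + 1L)
  acts[[1]] <- x
  for (l in seq_along(weights)) {
    z <- acts[[l]] %*% weights[[l]]
    z <- sweep(z, 2, biases[[l]], "+")
    acts[[l + 1]] <- if (act_relu[l]) relu(z) else z
  }
  acts
}

#' Train a fully connected autoencoder
#'
#' Splits samples into training and validation sets, trains with
#' minibatch Adam on MSE reconstruction loss, and retains the weights of
#' the best validation epoch (training never returns weights with a worse
#' validation loss than the best epoch seen). Training stops at
#' `max_epochs` or once the validation loss has failed to improve strictly
#' for `patience` consecutive epochs. Fully reproducible given
#' `config$seed`.
#'
#' @param joint complete numeric matrix, samples in rows.
#' @param config an [ae_config()].
#' @return a `trained_encoder` with the learned weights, the per-epoch loss
#'   history and the stopping epoch.
#' @export
train_autoencoder <- function(joint, config = ae_config()) {
  stopifnot(is.matrix(joint), nrow(joint) >= 2)
  if (!all(is.finite(joint))) stop("input contains non-finite values")
  p <- ncol(joint)
  dims <- c(p, config$hidden_dims, rev(config$hidden_dims)[-1], p)
  n_layers <- length(dims) - 1L
  n_enc <- length(config$hidden_dims)
  act_relu <- rep(TRUE, n_layers)
  act_relu[c(n_enc, n_layers)] <- FALSE   # linear bottleneck and output

  withr::with_seed(config$seed, {
    n <- nrow(joint)
    n_val <- max(1L, round(config$val_fraction * n))
    if (n_val >= n) stop("validation split leaves no training samples")
    val_idx <- sample.int(n, n_val)
    x_tr <- joint[-val_idx, , drop = FALSE]
    x_val <- joint[val_idx, , drop = FALSE]
    bs <- config$batch_size
    if (bs > nrow(x_tr)) {
      warning("batch_size > training-set size; clamping to ", nrow(x_tr))
      bs <- nrow(x_tr)
    }

    # He (fan-in) initialization
    weights <- biases <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      weights[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1],
                                          sd = sqrt(2 / dims[l])),
                             dims[l], dims[l + 1])
      biases[[l]] <- numeric(dims[l + 1])
    }
    m_w <- lapply(weights, function(w) w * 0); v_w <- m_w
    m_b <- lapply(biases, function(b) b * 0); v_b <- m_b
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0L

    mse <- function(w, b, x) {
      acts <- ae_forward(w, b, x, act_relu)
      mean((acts[[n_layers + 1]] - x)^2)
    }

    best <- list(weights = weights, biases = biases, val = Inf, epoch = 0L)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    wait <- 0L
    stopped <- config$max_epochs
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(nrow(x_tr))
      for (start in seq(1, nrow(x_tr), by = bs)) {
        idx <- ord[start:min(start + bs - 1, nrow(x_tr))]
        xb <- x_tr[idx, , drop = FALSE]
        acts <- ae_forward(weights, biases, xb, act_relu)
        delta <- 2 * (acts[[n_layers + 1]] - xb) / length(xb)
        t_step <- t_step + 1L
        for (l in rev(seq_len(n_layers))) {
          gw <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(weights[[l]])
            if (act_relu[l - 1])
              delta <- delta * (acts[[l]] > 0)   # ReLU derivative
          }
          m_w[[l]] <- b1 * m_w[[l]] + (1 - b1) * gw
          v_w[[l]] <- b2 * v_w[[l]] + (1 - b2) * gw^2
          m_b[[l]] <- b1 * m_b[[l]] + (1 - b1) * gb
          v_b[[l]] <- b2 * v_b[[l]] + (1 - b2) * gb^2
          mh_w <- m_w[[l]] / (1 - b1^t_step); vh_w <- v_w[[l]] / (1 - b2^t_step)
          mh_b <- m_b[[l]] / (1 - b1^t_step); vh_b <- v_b[[l]] / (1 - b2^t_step)
          weights[[l]] <- weights[[l]] - config$learning_rate * mh_w / (sqrt(vh_w) + eps)
          biases[[l]] <- biases[[l]] - config$learning_rate * mh_b / (sqrt(vh_b) + eps)
        }
      }
      tr_loss <- mse(weights, biases, x_tr)
      val_loss <- mse(weights, biases, x_val)
      history <- rbind(history, data.frame(epoch = epoch, train_loss = tr_loss,
                                           val_loss = val_loss))
      if (val_loss < best$val) {
        best <- list(weights = weights, biases = biases, val = val_loss,
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) { stopped <- epoch; break }
      }
      stopped <- epoch
    }

    structure(list(weights = best$weights, biases = best$biases,
                   dims = dims, act_relu = act_relu,
                   bottleneck_layer = length(config$hidden_dims) + 1L,
                   input_width = p, config = config,
                   train_history = history, stopped_epoch = stopped,
                   best_val_loss = best$val, best_epoch = best$epoch),
              class = "trained_encoder")
  })
}

#' @export
print.trained_encoder <- function(x, ...) {
  cat(sprintf("<trained_encoder> %s; stopped epoch %d (best val MSE %.4g at epoch %d)\n",
              paste(x$dims, collapse = "-"), x$stopped_epoch,
              x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' Reconstruct inputs through a trained autoencoder
#'
#' @param model a `trained_encoder`.
#' @param matrix numeric matrix with `model$input_width` columns.
#' @return the reconstructed matrix.
#' @export
reconstruct <- function(model, matrix) {
  stopifnot(inherits(model, "trained_encoder"))
  if (ncol(matrix) != model$input_width)
    stop("input width ", ncol(matrix), " != model input width ",
         model$input_width)
  acts <- ae_forward(model$weights, model$biases, matrix, model$act_relu)
  out <- acts[[length(acts)]]
  dimnames(out) <- dimnames(matrix)
  out
}

#' Extract bottleneck embeddings
#'
#' Deterministic forward pass through the encoder half of a trained
#' autoencoder.
#'
#' @param model a `trained_encoder` from [train_autoencoder()].
#' @param matrix numeric matrix with the model's input width.
#' @return an `embedding_result` with the latent samples-by-bottleneck
#'   matrix and the training history.
#' @export
encode <- function(model, matrix) {
  stopifnot(inherits(model, "trained_encoder"))
  if (ncol(matrix) != model$input_width)
    stop("input width ", ncol(matrix), " != model input width ",
         model$input_width)
  acts <- ae_forward(model$weights, model$biases, matrix, model$act_relu)
  latent <- acts[[model$bottleneck_layer]]
  rownames(latent) <- rownames(matrix)
  colnames(latent) <- sprintf("L%03d", seq_len(ncol(latent)))
  structure(list(latent = latent, train_history = model$train_history,
                 stopped_epoch = model$stopped_epoch, method = "ae",
                 config_echo = model$config),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d samples x %d latent dims (%s)\n",
              nrow(x$latent), ncol(x$latent), x$method))
  invisible(x)
}

#' Deterministic PCA embedding
#'
#' Projection onto the top-d principal axes (centred, unscaled). The sign of
#' each axis is fixed by making its largest-magnitude loading positive, so
#' the embedding is fully deterministic. Serves as a fast, training-free
#' stand-in for the autoencoder when exercising the clustering stage.
#'
#' @param matrix complete numeric matrix, samples in rows.
#' @param d number of components, `d <= min(nrow - 1, ncol)`.
#' @return an `embedding_result` with a `variance_explained` field.
#' @export
pca_embed <- function(matrix, d) {
  stopifnot(is.matrix(matrix))
  if (d < 1 || d > min(nrow(matrix) - 1, ncol(matrix)))
    stop("d must be in [1, min(samples - 1, features)]")
  pc <- stats::prcomp(matrix, center = TRUE, scale. = FALSE, rank. = d)
  rot <- pc$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  latent <- sweep(pc$x[, seq_len(d), drop = FALSE], 2, flip, "*")
  colnames(latent) <- sprintf("L%03d", seq_len(d))
  total_var <- sum(apply(matrix, 2, stats::var))
  structure(list(latent = latent, train_history = NULL,
                 stopped_epoch = NA_integer_, method = "pca",
                 variance_explained = sum(pc$sdev[seq_len(d)]^2) / total_var,
                 config_echo = list(d = d)),
            class = "embedding_result")
}
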
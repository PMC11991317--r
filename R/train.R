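#' Mean cross-entropy loss
#'
#' `L = -(1/N) * sum_i y_i log(yhat_i)` over a batch, with predicted
#' probabilities clipped to `[1e-12, 1]`. `y_true` rows are one-hot targets,
#' `y_prob` rows are predicted class probabilities.
#'
#' @param y_true `N x K` one-hot matrix.
#' @param y_prob `N x K` probability matrix (rows sum to 1).
#' @return nonnegative scalar loss.
#' @export
cross_entropy <- function(y_true, y_prob) {
  if (!all(dim(y_true) == dim(y_prob)))
    stopf("shape mismatch: y_true %s vs y_prob %s",
          paste(dim(y_true), collapse = "x"), paste(dim(y_prob), collapse = "x"))
  -sum(y_true * log(pmax(y_prob, 1e-12))) / nrow(y_true)
}

onehot <- function(labels, k = 2) {
  y <- matrix(0, k, length(labels))
  y[cbind(labels + 1L, seq_along(labels))] <- 1
  y
}

#' Training hyperparameters
#'
#' `preset = "deap"` and `"dreamer"` are the published full-scale protocols
#' (SGD, learning rate 1e-5, batch 64, 40 or 30 epochs). `preset = "reduced"`
#' is this package's default for the small synthetic problems the test suite
#' and examples run (larger learning rate, fewer epochs, sized so a reduced
#' model converges on strongly separable data in minutes of CPU).
#'
#' @param lr learning rate.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param momentum SGD momentum (0 in the published protocol).
#' @param seed seed governing shuffling and dropout.
#' @param preset `"deap"`, `"dreamer"` or `"reduced"`; explicit arguments
#'   override preset values.
#' @return a `hyper_config` list.
#' @export
hyper_config <- function(lr = 1e-5, batch_size = 64, epochs = 40,
                         momentum = 0, seed = 1L, preset = NULL) {
  h <- list(lr = lr, batch_size = batch_size, epochs = epochs,
            momentum = momentum, seed = as.integer(seed))
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("deap", "dreamer", "reduced"))
    override <- switch(preset,
      deap = list(lr = 1e-5, batch_size = 64, epochs = 40, momentum = 0),
      dreamer = list(lr = 1e-5, batch_size = 64, epochs = 30, momentum = 0),
      reduced = list(lr = 0.05, batch_size = 32, epochs = 8, momentum = 0.9))
    called <- names(match.call())[-1]
    h <- utils::modifyList(h, override[setdiff(names(override), called)])
  }
  structure(h, class = "hyper_config")
}

## in-place SGD step on the nested parameter list
sgd_step <- function(params, grads, vel, lr, momentum) {
  for (nm in names(params)) {
    if (is.null(params[[nm]])) next
    if (is.list(params[[nm]])) {
      upd <- sgd_step(params[[nm]], grads[[nm]], vel[[nm]], lr, momentum)
      params[[nm]] <- upd$params
      vel[[nm]] <- upd$vel
    } else {
      g <- grads[[nm]]
      if (momentum > 0) {
        v <- (vel[[nm]] %||% 0) * momentum - lr * g
        vel[[nm]] <- v
        params[[nm]] <- params[[nm]] + v
      } else {
        params[[nm]] <- params[[nm]] - lr * g
      }
    }
  }
  list(params = params, vel = vel)
}

#' Train a model by mini-batch stochastic gradient descent
#'
#' Minimizes the softmax cross-entropy by SGD, reshuffling the samples every
#' epoch. Training is fully seeded (shuffling, dropout), so identical seeds
#' and data reproduce identical weights.
#'
#' @param model an untrained or partially trained [msdsanet_model()].
#' @param samples a training `sample_set`.
#' @param hyper a [hyper_config()].
#' @param verbose print the per-epoch loss.
#' @return list with the trained `model` and the per-epoch mean `loss` trace.
#' @export
train_model <- function(model, samples, hyper = hyper_config(preset = "reduced"),
                        verbose = FALSE) {
  n <- n_samples(samples)
  if (n < 1) stopf("empty training set")
  y_all <- onehot(samples$label, model$cfg$n_classes)
  vel <- list()
  trace <- numeric(hyper$epochs)
  with_seed(hyper$seed, {
    for (ep in seq_len(hyper$epochs)) {
      perm <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = hyper$batch_size)) {
        idx <- perm[start:min(n, start + hyper$batch_size - 1)]
        fw <- forward_batch(model, sample_batch(samples, idx), training = TRUE)
        loss <- ad_softmax_ce(fw$tape, fw$logits, y_all[, idx, drop = FALSE])
        ad_backward(fw$tape, loss)
        grads <- collect_grads(fw$leaves)
        upd <- sgd_step(model$params, grads, vel, hyper$lr, hyper$momentum)
        model$params <- upd$params
        vel <- upd$vel
        losses <- c(losses, loss$value)
      }
      trace[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %d/%d: loss %.4f", ep, hyper$epochs,
                                   trace[ep]))
    }
  })
  list(model = model, loss = trace)
}
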
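# Optional deep-residual-network backend: a fully connected network of
# width-256 pre-activation residual units with a softmax binary head,
# trained by minibatch SGD with momentum and a 1/(1 + decay * epoch)
# learning-rate schedule.  Pure matrix arithmetic; desk-scale by design.
# The tree ensembles remain the reference backend.

#' Hyperparameter grid for the deep residual network
#'
#' The option sets searched: number of width-256 layers (2, 3 or 4),
#' dropout rate, learning rate, epochs, SGD momentum, learning-rate decay
#' and minibatch size.  A randomized subset of the full grid of size
#' `n_search_draws` is scored (the full grid has 1728 cells).
#'
#' @param layer_sizes,dropout,learning_rate,epochs,momentum,decay,batch_size
#'   Candidate values for each hyperparameter.
#' @param n_search_draws Number of grid cells drawn at random.
#' @param cv_folds Folds for the ROC-AUC search score.
#' @param seed Integer seed.
#' @return A `bbb_drn_space` list.
#' @export
drn_search_space <- function(layer_sizes = c(2L, 3L, 4L),
                             dropout = c(0.0, 0.1),
                             learning_rate = c(0.005, 0.0035, 0.0025, 0.0010),
                             epochs = c(5L, 10L, 20L, 30L, 40L, 50L),
                             momentum = c(0.0, 0.9),
                             decay = c(0.0, 0.1),
                             batch_size = c(32L, 64L, 128L),
                             n_search_draws = 8L, cv_folds = 5L, seed = 1L) {
  structure(list(
    layer_sizes = as.integer(layer_sizes), dropout = dropout,
    learning_rate = learning_rate, epochs = as.integer(epochs),
    momentum = momentum, decay = decay, batch_size = as.integer(batch_size),
    n_search_draws = as.integer(n_search_draws),
    cv_folds = as.integer(cv_folds), seed = as.integer(seed)
  ), class = "bbb_drn_space")
}

relu <- function(z) pmax(z, 0)

drn_init <- function(d, layers, width, seed) {
  with_seed(seed, {
    p <- list(W0 = matrix(rnorm(d * width, sd = sqrt(2 / d)), d, width),
      b0 = rep(0, width)
    )
    for (l in seq_len(layers)) {
      p[[paste0("W", l)]] <- matrix(rnorm(width * width, sd = sqrt(2 / width)), width, width)
      p[[paste0("b", l)]] <- rep(0, width)
    }
    p$Wh <- matrix(rnorm(width * 2, sd = sqrt(2 / width)), width, 2)
    p$bh <- rep(0, 2)
    p
  })
}

drn_forward <- function(p, x, layers, dropout = 0, train = FALSE) {
  z <- sweep(x %*% p$W0, 2, p$b0, "+")
  acts <- list(z)
  masks <- list()
  for (l in seq_len(layers)) {
    a <- relu(z)
    h <- sweep(a %*% p[[paste0("W", l)]], 2, p[[paste0("b", l)]], "+")
    if (train && dropout > 0) {
      m <- matrix(runif(length(h)) >= dropout, nrow(h), ncol(h)) / (1 - dropout)
      h <- h * m
      masks[[l]] <- m
    }
    z <- z + h # pre-activation residual unit
    acts[[l + 1L]] <- z
  }
  logits <- sweep(relu(z) %*% p$Wh, 2, p$bh, "+")
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  list(probs = probs, acts = acts, masks = masks, z = z)
}

drn_train_one <- function(x, y, layers, dropout, lr, epochs, momentum, decay,
                          batch_size, seed, width = 256L) {
  d <- ncol(x)
  p <- drn_init(d, layers, width, derive_seed(seed, "init"))
  vel <- lapply(p, function(w) w * 0)
  n <- nrow(x)
  with_seed(derive_seed(seed, "sgd"), {
    for (ep in seq_len(epochs)) {
      lr_ep <- lr / (1 + decay * (ep - 1))
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        fw <- drn_forward(p, xb, layers, dropout, train = TRUE)
        m <- length(idx)
        # softmax cross-entropy gradient
        dlogits <- fw$probs
        dlogits[cbind(seq_len(m), yb + 1L)] <- dlogits[cbind(seq_len(m), yb + 1L)] - 1
        dlogits <- dlogits / m
        grads <- list()
        a_last <- relu(fw$z)
        grads$Wh <- t(a_last) %*% dlogits
        grads$bh <- colSums(dlogits)
        dz <- (dlogits %*% t(p$Wh)) * (fw$z > 0)
        for (l in rev(seq_len(layers))) {
          dh <- dz
          if (dropout > 0 && length(fw$masks) >= l && !is.null(fw$masks[[l]])) {
            dh <- dh * fw$masks[[l]]
          }
          a <- relu(fw$acts[[l]])
          grads[[paste0("W", l)]] <- t(a) %*% dh
          grads[[paste0("b", l)]] <- colSums(dh)
          dz <- dz + (dh %*% t(p[[paste0("W", l)]])) * (fw$acts[[l]] > 0)
        }
        grads$W0 <- t(xb) %*% dz
        grads$b0 <- colSums(dz)
        for (nm in names(grads)) {
          vel[[nm]] <- momentum * vel[[nm]] - lr_ep * grads[[nm]]
          p[[nm]] <- p[[nm]] + vel[[nm]]
        }
      }
    }
  })
  list(params = p, layers = layers, width = width)
}

#' Train the deep residual network with randomized grid search
#'
#' Draws `n_search_draws` cells from the hyperparameter grid, scores each
#' by mean cross-validated ROC-AUC, and refits the best cell on all
#' training data.  Returns class probabilities through the same
#' [predict_proba()] contract as the tree backends.
#'
#' @param x Training feature matrix.
#' @param labels Binary 0/1 labels (both classes required).
#' @param space A [drn_search_space()].
#' @return A `bbb_drn` model object with `best_params` and `cv_results`.
#' @export
train_residual_network <- function(x, labels, space = drn_search_space()) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop_config("train_residual_network(): training labels contain a single class")
  }
  x <- as.matrix(x)
  draws <- with_seed(derive_seed(space$seed, "drn_draws"), tibble::tibble(
    layers = sample(space$layer_sizes, space$n_search_draws, replace = TRUE),
    dropout = sample(space$dropout, space$n_search_draws, replace = TRUE),
    learning_rate = sample(space$learning_rate, space$n_search_draws, replace = TRUE),
    epochs = sample(space$epochs, space$n_search_draws, replace = TRUE),
    momentum = sample(space$momentum, space$n_search_draws, replace = TRUE),
    decay = sample(space$decay, space$n_search_draws, replace = TRUE),
    batch_size = sample(space$batch_size, space$n_search_draws, replace = TRUE)
  ))
  folds <- kfold_indices(nrow(x), space$cv_folds, derive_seed(space$seed, "drn_folds"))
  fit_cell <- function(i, rows) {
    drn_train_one(
      x[rows, , drop = FALSE], labels[rows],
      layers = draws$layers[i], dropout = draws$dropout[i],
      lr = draws$learning_rate[i], epochs = draws$epochs[i],
      momentum = draws$momentum[i], decay = draws$decay[i],
      batch_size = draws$batch_size[i],
      seed = derive_seed(space$seed, paste0("drn_fit", i))
    )
  }
  draws$cv_roc_auc <- vapply(seq_len(nrow(draws)), function(i) {
    aucs <- vapply(folds, function(hold) {
      tr <- setdiff(seq_len(nrow(x)), hold)
      if (length(unique(labels[tr])) < 2L || length(unique(labels[hold])) < 2L) {
        return(NA_real_)
      }
      net <- fit_cell(i, tr)
      p <- drn_forward(net$params, x[hold, , drop = FALSE], net$layers)$probs[, 2L]
      suppressWarnings(roc_auc(labels[hold], p))
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(draws$cv_roc_auc)
  net <- fit_cell(best, seq_len(nrow(x)))
  structure(list(
    kind = "drn", net = net,
    best_params = as.list(draws[best, setdiff(names(draws), "cv_roc_auc")]),
    cv_results = draws, seed = space$seed
  ), class = "bbb_drn")
}

#' @export
predict_proba.bbb_drn <- function(model, x) {
  drn_forward(model$net$params, as.matrix(x), model$net$layers)$probs[, 2L]
}

#' Class-probability matrix of the residual network
#'
#' @param model A `bbb_drn` model.
#' @param x Feature matrix.
#' @return An n x 2 matrix of class probabilities; rows sum to 1.
#' @export
predict_proba_matrix <- function(model, x) {
  stopifnot(inherits(model, "bbb_drn"))
  p <- drn_forward(model$net$params, as.matrix(x), model$net$layers)$probs
  colnames(p) <- c("0", "1")
  p
}

#' @export
print.bbb_drn <- function(x, ...) {
  cat(sprintf(
    "<bbb_drn> %d residual layers x 256 (cv ROC-AUC %.3f over %d draws)\n",
    x$best_params$layers, max(x$cv_results$cv_roc_auc, na.rm = TRUE),
    nrow(x$cv_results)
  ))
  invisible(x)
}
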
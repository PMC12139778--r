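## 1-D convolutional network for photobleaching-trace classification.
##
## Implemented directly on BLAS matrix products (im2col convolution) so the
## whole training path is plain R, deterministic under a seed, and fast
## enough for trace-length-1000 inputs on one CPU. Feature maps are stored
## as (batch * length) x channels matrices, position-major within sample.

#' Model configuration for a 1-D CNN trace classifier
#'
#' @param conv_blocks List of `c(kernel_size, n_filters)` pairs; each block
#'   is convolution + ReLU + max-pool. Kernel sizes must be odd and >= 3.
#' @param pool Pool width per block (scalar recycled).
#' @param dense Integer vector of hidden dense-layer widths (may be empty).
#' @param n_classes 2 (green) or 4 (far-red).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Training epochs.
#' @param input_length Fixed trace length (default 1000 frames).
#' @param seed Integer seed for initialization and shuffling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(conv_blocks = list(c(9, 16), c(9, 16)),
                         pool = 5, dense = 32, n_classes = 4,
                         learning_rate = 1e-3, batch_size = 64,
                         max_epochs = 8, input_length = 1000, seed = 1) {
  for (blk in conv_blocks) {
    if (length(blk) != 2 || blk[1] %% 2 != 1 || blk[1] < 3 || blk[2] < 1) {
      stop("each conv block must be c(odd kernel >= 3, n_filters >= 1)", call. = FALSE)
    }
  }
  if (!n_classes %in% c(2L, 4L)) stop("'n_classes' must be 2 or 4", call. = FALSE)
  stop_if_not_scalar(learning_rate, "learning_rate", positive = TRUE)
  pool <- rep_len(as.integer(pool), length(conv_blocks))
  structure(list(conv_blocks = conv_blocks, pool = pool,
                 dense = as.integer(dense), n_classes = as.integer(n_classes),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 input_length = as.integer(input_length),
                 seed = as.integer(seed)),
            class = "model_config")
}

## Layer dimensions through the network.
cnn_dims <- function(config) {
  L <- config$input_length; C <- 1L
  dims <- list()
  for (i in seq_along(config$conv_blocks)) {
    blk <- config$conv_blocks[[i]]
    dims[[i]] <- list(L_in = L, C_in = C, k = blk[1], F = blk[2],
                      pool = config$pool[i], L_out = L %/% config$pool[i])
    L <- L %/% config$pool[i]; C <- blk[2]
  }
  list(conv = dims, flat = L * C, L_final = L, C_final = C)
}

## He-initialized parameter set.
cnn_init <- function(config) {
  dims <- cnn_dims(config)
  params <- list()
  for (i in seq_along(dims$conv)) {
    d <- dims$conv[[i]]
    fan_in <- d$k * d$C_in
    params[[paste0("convW", i)]] <- matrix(stats::rnorm(fan_in * d$F, 0,
                                                        sqrt(2 / fan_in)),
                                           fan_in, d$F)
    params[[paste0("convb", i)]] <- numeric(d$F)
  }
  widths <- c(dims$flat, config$dense, config$n_classes)
  for (j in seq_len(length(widths) - 1)) {
    fan_in <- widths[j]
    params[[paste0("denseW", j)]] <- matrix(stats::rnorm(fan_in * widths[j + 1], 0,
                                                         sqrt(2 / fan_in)),
                                            fan_in, widths[j + 1])
    params[[paste0("denseb", j)]] <- numeric(widths[j + 1])
  }
  params
}

## im2col indices for one (B, L, k) geometry.
conv_indices <- function(B, L, k) {
  h <- (k - 1) %/% 2
  Lp <- L + 2 * h
  base <- rep((0:(B - 1)) * Lp, each = L)
  list(h = h, Lp = Lp,
       orig = base + h + seq_len(L),
       offsets = lapply(seq_len(k), function(j) base + (j - 1) + seq_len(L)))
}

conv_forward <- function(Fin, B, L, C, W, bvec, k, idx) {
  pad <- matrix(0, B * idx$Lp, C)
  pad[idx$orig, ] <- Fin
  M <- matrix(0, B * L, k * C)
  for (j in seq_len(k)) {
    M[, ((j - 1) * C + 1):(j * C)] <- pad[idx$offsets[[j]], , drop = FALSE]
  }
  out <- M %*% W
  out <- sweep(out, 2, bvec, "+")
  list(out = out, M = M)
}

conv_backward <- function(dOut, M, W, B, L, C, k, idx) {
  dW <- crossprod(M, dOut)
  db <- colSums(dOut)
  dM <- tcrossprod(dOut, W)
  dpad <- matrix(0, B * idx$Lp, C)
  for (j in seq_len(k)) {
    cols <- ((j - 1) * C + 1):(j * C)
    dpad[idx$offsets[[j]], ] <- dpad[idx$offsets[[j]], , drop = FALSE] +
      dM[, cols, drop = FALSE]
  }
  list(dW = dW, db = db, dFin = dpad[idx$orig, , drop = FALSE])
}

pool_forward <- function(Fin, B, L, C, p) {
  Lo <- L %/% p
  keep <- rep((0:(B - 1)) * L, each = Lo * p) + seq_len(Lo * p)
  X <- Fin[keep, , drop = FALSE]
  ng <- B * Lo
  out <- matrix(0, ng, C)
  arg <- matrix(0L, ng, C)
  for (c in seq_len(C)) {
    m <- matrix(X[, c], nrow = p)
    am <- max.col(t(m), ties.method = "first")
    out[, c] <- m[cbind(am, seq_len(ng))]
    arg[, c] <- am
  }
  list(out = out, arg = arg, keep = keep, Lo = Lo)
}

pool_backward <- function(dOut, cache, B, L, C, p) {
  ng <- B * cache$Lo
  dkept <- matrix(0, ng * p, C)
  base <- (seq_len(ng) - 1) * p
  for (c in seq_len(C)) {
    dkept[base + cache$arg[, c], c] <- dOut[, c]
  }
  dFin <- matrix(0, B * L, C)
  dFin[cache$keep, ] <- dkept
  dFin
}

flatten_forward <- function(Fin, B, Lo, C) {
  matrix(aperm(array(Fin, c(Lo, B, C)), c(2, 1, 3)), nrow = B)
}

flatten_backward <- function(dFlat, B, Lo, C) {
  matrix(aperm(array(dFlat, c(B, Lo, C)), c(2, 1, 3)), nrow = B * Lo, ncol = C)
}

## Full forward pass. X: B x L matrix of z-scored traces.
cnn_forward <- function(params, config, X, cache = FALSE) {
  dims <- cnn_dims(config)
  B <- nrow(X)
  Fin <- matrix(as.vector(t(X)), ncol = 1)  # (B*L) x 1, position-major
  caches <- list()
  for (i in seq_along(dims$conv)) {
    d <- dims$conv[[i]]
    idx <- conv_indices(B, d$L_in, d$k)
    cf <- conv_forward(Fin, B, d$L_in, d$C_in, params[[paste0("convW", i)]],
                       params[[paste0("convb", i)]], d$k, idx)
    act <- pmax(cf$out, 0)
    pf <- pool_forward(act, B, d$L_in, d$F, d$pool)
    if (cache) caches[[i]] <- list(idx = idx, M = cf$M, pre = cf$out, pool = pf)
    Fin <- pf$out
  }
  H <- flatten_forward(Fin, B, dims$L_final, dims$C_final)
  nd <- length(config$dense) + 1L
  dense_in <- list()
  for (j in seq_len(nd)) {
    dense_in[[j]] <- H
    Z <- sweep(H %*% params[[paste0("denseW", j)]], 2,
               params[[paste0("denseb", j)]], "+")
    H <- if (j < nd) pmax(Z, 0) else Z
  }
  logits <- H
  ## softmax (row-wise, stabilized)
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  list(logits = logits, probs = probs, caches = caches, dense_in = dense_in,
       dims = dims, B = B)
}

## Backward pass + weighted cross-entropy gradient.
cnn_backward <- function(params, config, fwd, y_int, sample_w) {
  dims <- fwd$dims
  B <- fwd$B
  grads <- list()
  Y <- matrix(0, B, config$n_classes)
  Y[cbind(seq_len(B), y_int)] <- 1
  wsum <- sum(sample_w)
  dZ <- (fwd$probs - Y) * (sample_w / wsum)
  nd <- length(config$dense) + 1L
  for (j in rev(seq_len(nd))) {
    Xj <- fwd$dense_in[[j]]
    grads[[paste0("denseW", j)]] <- crossprod(Xj, dZ)
    grads[[paste0("denseb", j)]] <- colSums(dZ)
    dX <- tcrossprod(dZ, params[[paste0("denseW", j)]])
    if (j > 1) dZ <- dX * (Xj > 0)
  }
  dFin <- flatten_backward(dX, B, dims$L_final, dims$C_final)
  for (i in rev(seq_along(dims$conv))) {
    d <- dims$conv[[i]]
    ch <- fwd$caches[[i]]
    dAct <- pool_backward(dFin, ch$pool, B, d$L_in, d$F, d$pool)
    dPre <- dAct * (ch$pre > 0)
    cb <- conv_backward(dPre, ch$M, params[[paste0("convW", i)]],
                        B, d$L_in, d$C_in, d$k, ch$idx)
    grads[[paste0("convW", i)]] <- cb$dW
    grads[[paste0("convb", i)]] <- cb$db
    dFin <- cb$dFin
  }
  grads
}

## One Adam update over all parameter matrices (in place on the state list).
adam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(state$params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    state$params[[nm]] <- state$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

#' Inverse-class-frequency loss weights
#'
#' Assigns each class the weight `w_c = N / (K * n_c)`, where `N` is the
#' total count and `K` the number of classes, so underrepresented classes
#' contribute more to the training loss. Satisfies the identity
#' `sum(n_c * w_c) = N` exactly.
#'
#' @param counts Named vector of per-class counts (all >= 1).
#' @return Named numeric weights.
#' @export
compute_class_weights <- function(counts) {
  counts <- unlist(counts)
  if (any(counts < 1)) stop("every class must have count >= 1", call. = FALSE)
  N <- sum(counts)
  K <- length(counts)
  w <- N / (K * counts)
  names(w) <- names(counts)
  w
}

#' Stratified train/validation split
#'
#' Partitions indices so that per-class proportions in each split match the
#' whole set within one trace; deterministic given `seed`.
#'
#' @param labels Factor or character vector of class labels.
#' @param train_frac Fraction assigned to training (default 0.8).
#' @param seed Integer seed.
#' @return List of integer index vectors `train` and `validation`.
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed = 1) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("every class must have >= 2 members for a stratified split", call. = FALSE)
  }
  with_seed(seed, {
    train <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      n_tr <- min(max(round(length(idx) * train_frac), 1L), length(idx) - 1L)
      train <- c(train, idx[seq_len(n_tr)])
    }
    train <- sort(train)
    list(train = train, validation = setdiff(seq_along(labels), train))
  })
}

## Per-class one-vs-rest F1, macro-averaged. Absent-class F1 counts as 0
## unless the class is absent from both truth and prediction.
macro_f1 <- function(truth, pred, levels) {
  f1 <- vapply(levels, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp + fp + fn == 0) return(NA_real_)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1, na.rm = TRUE)
}

#' Train a 1-D CNN trace classifier
#'
#' Minimizes class-weighted cross-entropy with Adam on minibatches of
#' z-scored traces. All randomness (initialization, shuffling) derives from
#' `config$seed`, so identical inputs give identical models.
#'
#' @param x Matrix of z-scored traces, one row per trace, `config$input_length`
#'   columns.
#' @param y Factor (or character) of class labels; its levels define the
#'   class order.
#' @param config A [model_config()].
#' @param class_weights Named weights per class; default
#'   [compute_class_weights()] on the training label counts.
#' @param validation Optional list `list(x =, y =)` of held-out traces;
#'   validation accuracy and macro-F1 are reported when supplied, training
#'   metrics otherwise.
#' @param verbose Print per-epoch loss.
#' @return Object of class `simpull_cnn`: `params`, `config`, `classes`,
#'   `class_weights`, `history` (per-epoch mean loss), `metrics`
#'   (`accuracy`, `macro_f1`, `on`).
#' @export
train_cnn <- function(x, y, config, class_weights = NULL, validation = NULL,
                      verbose = FALSE) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("at least 2 classes required for training", call. = FALSE)
  if (nlevels(y) != config$n_classes) {
    stop(sprintf("config expects %d classes but labels have %d",
                 config$n_classes, nlevels(y)), call. = FALSE)
  }
  if (ncol(x) != config$input_length) {
    stop("trace length does not match config$input_length", call. = FALSE)
  }
  if (is.null(class_weights)) class_weights <- compute_class_weights(table(y))
  class_weights <- class_weights[levels(y)]
  y_int <- as.integer(y)
  n <- nrow(x)
  model <- with_seed(config$seed, {
    state <- list(params = cnn_init(config))
    state$m <- lapply(state$params, function(p) p * 0)
    state$v <- state$m
    t_step <- 0L
    history <- numeric(config$max_epochs)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1, n)]
        fwd <- cnn_forward(state$params, config, x[bi, , drop = FALSE], cache = TRUE)
        sw <- as.numeric(class_weights[y_int[bi]])
        p_true <- fwd$probs[cbind(seq_along(bi), y_int[bi])]
        loss <- -sum(sw * log(pmax(p_true, 1e-12))) / sum(sw)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d (lr=%g); try a lower learning rate",
                       epoch, config$learning_rate), call. = FALSE)
        }
        losses <- c(losses, loss)
        grads <- cnn_backward(state$params, config, fwd, y_int[bi], sw)
        t_step <- t_step + 1L
        state <- adam_step(state, grads, config$learning_rate, t_step)
      }
      history[epoch] <- mean(losses)
      if (verbose) message(sprintf("epoch %d/%d  loss %.4f", epoch,
                                   config$max_epochs, history[epoch]))
    }
    structure(list(params = state$params, config = config,
                   classes = levels(y), class_weights = class_weights,
                   history = history),
              class = "simpull_cnn")
  })
  eval_x <- if (!is.null(validation)) validation$x else x
  eval_y <- if (!is.null(validation)) validation$y else y
  pred <- predict(model, eval_x)
  model$metrics <- list(
    accuracy = mean(as.character(pred) == as.character(eval_y)),
    macro_f1 = macro_f1(as.character(eval_y), as.character(pred), model$classes),
    on = if (!is.null(validation)) "validation" else "training")
  model
}

#' Predict classes for z-scored traces
#'
#' Deterministic argmax inference. Traces shorter than the model input
#' length are zero-padded, longer ones truncated; either adjustment sets
#' the `adjusted` attribute.
#'
#' @param object A `simpull_cnn`.
#' @param x Matrix of z-scored traces (rows) or a single trace vector.
#' @param type `"class"` for labels, `"prob"` for class probabilities.
#' @param batch Inference batch size.
#' @param ... Unused.
#' @return Factor of labels or a probability matrix, with attribute
#'   `adjusted` if pad/truncate was applied.
#' @export
predict.simpull_cnn <- function(object, x, type = c("class", "prob"),
                                batch = 256L, ...) {
  type <- match.arg(type)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  L <- object$config$input_length
  adjusted <- FALSE
  if (ncol(x) != L) {
    adjusted <- TRUE
    if (ncol(x) < L) {
      x <- cbind(x, matrix(0, nrow(x), L - ncol(x)))
    } else {
      x <- x[, seq_len(L), drop = FALSE]
    }
    warning(sprintf("traces adjusted to model input length %d", L), call. = FALSE)
  }
  probs <- matrix(0, nrow(x), object$config$n_classes)
  for (start in seq(1, nrow(x), by = batch)) {
    bi <- start:min(start + batch - 1, nrow(x))
    probs[bi, ] <- cnn_forward(object$params, object$config,
                               x[bi, , drop = FALSE])$probs
  }
  colnames(probs) <- object$classes
  out <- if (type == "prob") probs else {
    factor(object$classes[max.col(probs, ties.method = "first")],
           levels = object$classes)
  }
  attr(out, "adjusted") <- adjusted
  out
}

#' Number of trainable parameters
#' @param config A [model_config()].
#' @return Integer parameter count.
#' @export
n_params <- function(config) {
  with_seed(1, sum(vapply(cnn_init(config), length, numeric(1))))
}

#' Stratified k-fold cross-validation of a CNN configuration
#'
#' Assigns traces to `k` folds stratified by class (per-fold class
#' proportions within one trace of the global proportions), retrains the
#' model from fresh initialization on each training split, and reports
#' per-fold accuracy and macro-F1 with their mean and standard deviation.
#'
#' @param x Trace matrix (rows = traces).
#' @param y Labels.
#' @param config A [model_config()].
#' @param k Number of folds (default 5); every class must have >= k members.
#' @param seed Integer seed for fold assignment.
#' @param class_weights Optional fixed class weights.
#' @return List of class `cv_report`: `folds` data frame (`fold`,
#'   `accuracy`, `macro_f1`, `n_validation`), `mean_accuracy`,
#'   `sd_accuracy`, `mean_macro_f1`, `sd_macro_f1`, `fold_assignment`.
#' @export
cross_validate <- function(x, y, config, k = 5, seed = 1, class_weights = NULL) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  tab <- table(y)
  if (any(tab < k)) {
    stop(sprintf("every class needs >= %d members for %d-fold CV", k, k),
         call. = FALSE)
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  res <- lapply(seq_len(k), function(f) {
    tr <- which(fold != f); va <- which(fold == f)
    cfg <- config
    cfg$seed <- as.integer(derive_seed(config$seed, f) %% .Machine$integer.max)
    fit <- train_cnn(x[tr, , drop = FALSE], y[tr], cfg,
                     class_weights = class_weights,
                     validation = list(x = x[va, , drop = FALSE], y = y[va]))
    data.frame(fold = f, accuracy = fit$metrics$accuracy,
               macro_f1 = fit$metrics$macro_f1, n_validation = length(va))
  })
  folds <- do.call(rbind, res)
  structure(list(folds = folds,
                 mean_accuracy = mean(folds$accuracy),
                 sd_accuracy = stats::sd(folds$accuracy),
                 mean_macro_f1 = mean(folds$macro_f1),
                 sd_macro_f1 = stats::sd(folds$macro_f1),
                 fold_assignment = fold),
            class = "cv_report")
}

#' Architecture search over a grid of model configurations
#'
#' Each candidate is trained once on the same stratified 80/20
#' train-validation split and ranked by validation accuracy (ties broken by
#' higher macro-F1, then smaller parameter count). The top `top_k`
#' configurations go to k-fold cross-validation; the final pick is the one
#' with the best mean CV accuracy.
#'
#' @param x Trace matrix.
#' @param y Labels.
#' @param grid List of [model_config()] objects.
#' @param seed Integer seed (split and per-config training seeds derive
#'   from it).
#' @param top_k Number of finalists cross-validated (default 5).
#' @param cv_k Folds in the final cross-validation.
#' @return List: `ranking` data frame, `top` (finalist indices),
#'   `cv_reports` (per finalist), `best_config`, `best_index`.
#' @export
architecture_search <- function(x, y, grid, seed = 1, top_k = 5, cv_k = 5) {
  if (length(grid) == 0) stop("empty configuration grid", call. = FALSE)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  split <- stratified_split(y, 0.8, seed = derive_seed(seed, 0))
  rows <- lapply(seq_along(grid), function(i) {
    cfg <- grid[[i]]
    cfg$seed <- as.integer(derive_seed(seed, i) %% .Machine$integer.max)
    fit <- train_cnn(x[split$train, , drop = FALSE], y[split$train], cfg,
                     validation = list(x = x[split$validation, , drop = FALSE],
                                       y = y[split$validation]))
    data.frame(config = i, val_accuracy = fit$metrics$accuracy,
               val_macro_f1 = fit$metrics$macro_f1, n_params = n_params(cfg))
  })
  ranking <- do.call(rbind, rows)
  ord <- order(-ranking$val_accuracy, -ranking$val_macro_f1, ranking$n_params,
               ranking$config)
  ranking <- ranking[ord, ]
  rownames(ranking) <- NULL
  top <- ranking$config[seq_len(min(top_k, nrow(ranking)))]
  cv_reports <- lapply(top, function(i) {
    cross_validate(x, y, grid[[i]], k = cv_k, seed = derive_seed(seed, 1000 + i))
  })
  best <- top[which.max(vapply(cv_reports, `[[`, numeric(1), "mean_accuracy"))]
  list(ranking = ranking, top = top, cv_reports = cv_reports,
       best_config = grid[[best]], best_index = best)
}

#' Default demonstration search grid (39 configurations)
#'
#' Spans the three axes typically explored for this classifier: kernel size
#' (5, 9, 15), filter count (8, 16, 32), and dense-layer configuration
#' ((32), (64), (64, 32)), at learning rate 1e-3, plus a reduced sweep of
#' the same kernels and the two larger filter counts over dense (32) and
#' (64) at learning rate 1e-4 — 39 configurations in total.
#'
#' @param n_classes 2 or 4.
#' @param input_length Trace length.
#' @param max_epochs Epochs per candidate (kept small for search).
#' @return List of 39 [model_config()] objects.
#' @export
default_search_grid <- function(n_classes = 4, input_length = 1000,
                                max_epochs = 4) {
  grid <- list()
  denses <- list(32L, 64L, c(64L, 32L))
  for (kern in c(5, 9, 15)) {
    for (filt in c(8, 16, 32)) {
      for (d in denses) {
        grid[[length(grid) + 1]] <- model_config(
          conv_blocks = list(c(kern, filt), c(kern, filt)), pool = 5,
          dense = d, n_classes = n_classes, learning_rate = 1e-3,
          input_length = input_length, max_epochs = max_epochs)
      }
    }
  }
  for (kern in c(5, 9, 15)) {
    for (filt in c(16, 32)) {
      for (d in denses[1:2]) {
        grid[[length(grid) + 1]] <- model_config(
          conv_blocks = list(c(kern, filt), c(kern, filt)), pool = 5,
          dense = d, n_classes = n_classes, learning_rate = 1e-4,
          input_length = input_length, max_epochs = max_epochs)
      }
    }
  }
  grid
}

#' Serialize a trained CNN to JSON
#'
#' Writes a single JSON file holding the configuration, class map, class
#' weights, training history, and all weight matrices (with shapes), so a
#' model round-trips losslessly through text.
#'
#' @param model A `simpull_cnn`.
#' @param path Output path.
#' @export
save_cnn <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    classes = model$classes,
    class_weights = as.list(model$class_weights),
    history = model$history,
    metrics = model$metrics,
    params = lapply(model$params, function(p) {
      list(dim = if (is.matrix(p)) dim(p) else length(p), values = as.numeric(p))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a CNN saved by [save_cnn()]
#' @param path JSON path.
#' @return A `simpull_cnn`.
#' @export
load_cnn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- model_config(
    conv_blocks = if (is.matrix(cfg$conv_blocks)) {
      lapply(seq_len(nrow(cfg$conv_blocks)), function(i) cfg$conv_blocks[i, ])
    } else cfg$conv_blocks,
    pool = cfg$pool, dense = cfg$dense, n_classes = cfg$n_classes,
    learning_rate = cfg$learning_rate, batch_size = cfg$batch_size,
    max_epochs = cfg$max_epochs, input_length = cfg$input_length,
    seed = cfg$seed)
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) == 2) matrix(p$values, p$dim[1], p$dim[2]) else p$values
  })
  structure(list(params = params, config = config, classes = payload$classes,
                 class_weights = unlist(payload$class_weights),
                 history = payload$history, metrics = payload$metrics),
            class = "simpull_cnn")
}
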
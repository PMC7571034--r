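#' Feed-forward softmax classifier for activity recognition
#'
#' Fits a small fully connected network mapping the 120-element feature
#' vector to the 8 activity classes: one or two ReLU hidden layers followed
#' by a softmax output layer. Training minimises the multinomial
#' cross-entropy by seeded mini-batch gradient descent with early stopping on
#' cross-validation accuracy, using a fixed 60/20/20
#' train/cross-validation/test split of the supplied data. The returned
#' object is the unit the online-learning rules ([pg_update()],
#' [il_observe()], [run_adaptation()]) operate on: they touch only its
#' output-layer weights.
#'
#' @param x Numeric feature matrix (rows = segments, 120 columns). Raw
#'   features are standardized internally; the fitted normalizer is stored in
#'   the model and applied by `predict()`.
#' @param y Character or factor vector of activity labels (levels from
#'   [har_activities()]).
#' @param hidden Integer vector of hidden-layer sizes: length 1 or 2.
#' @param learning_rate Gradient-descent step size.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience: training stops when the
#'   cross-validation accuracy has not improved for this many epochs, and the
#'   best weights are restored.
#' @param split Train/cv/test fractions (must sum to 1).
#' @param seed Integer seed controlling the split, weight initialisation and
#'   batch order.
#' @param normalize Standardize features internally (disable when `x` is
#'   already standardized).
#' @return An object of class `"har_mlp"` with components `weights` (list of
#'   weight matrices, each with a trailing bias row), `classes`, `normalizer`,
#'   `metrics` (train/cv/test accuracies), `confusion` (test confusion matrix,
#'   rows = truth, columns = prediction) and `history` (per-epoch accuracies).
#' @export
har_mlp <- function(x, y, hidden = c(4L, 8L), learning_rate = 0.1,
                    batch_size = 32L, max_epochs = 500L, patience = 60L,
                    split = c(train = 0.6, cv = 0.2, test = 0.2),
                    seed = 1L, normalize = TRUE) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (abs(sum(split) - 1) > 1e-9) stop_validation("split fractions must sum to 1")
  if (length(hidden) < 1L || length(hidden) > 2L || any(hidden < 1L))
    stop_validation("`hidden` must hold 1 or 2 positive layer sizes")
  classes <- intersect(har_activities(), unique(y))
  if (length(classes) < 2L)
    stop_validation("need at least 2 classes to train a classifier")
  yi <- match(y, classes)
  if (anyNA(yi)) stop_validation("labels outside the known activity set")

  norm <- NULL
  if (normalize) {
    norm <- fit_normalizer(x)
    x <- apply_normalizer(x, norm)
  }

  n <- nrow(x)
  fit <- with_seed(seed, {
    idx <- sample.int(n)
    n_tr <- floor(split[[1]] * n)
    n_cv <- floor(split[[2]] * n)
    i_tr <- idx[seq_len(n_tr)]
    i_cv <- idx[n_tr + seq_len(n_cv)]
    i_te <- idx[(n_tr + n_cv + 1L):n]
    w <- init_weights(ncol(x), hidden, length(classes))
    tr <- train_sgd(x[i_tr, , drop = FALSE], yi[i_tr],
                    x[i_cv, , drop = FALSE], yi[i_cv],
                    w, learning_rate, batch_size, max_epochs, patience)
    list(tr = tr, i_tr = i_tr, i_cv = i_cv, i_te = i_te)
  })

  w <- fit$tr$weights
  acc_of <- function(i) {
    if (!length(i)) return(NA_real_)
    mean(mlp_predict_idx(x[i, , drop = FALSE], w) == yi[i])
  }
  pred_te <- mlp_predict_idx(x[fit$i_te, , drop = FALSE], w)
  conf <- table(truth = factor(classes[yi[fit$i_te]], levels = classes),
                prediction = factor(classes[pred_te], levels = classes))
  structure(list(weights = w, hidden = as.integer(hidden), classes = classes,
                 normalizer = norm,
                 metrics = c(train = acc_of(fit$i_tr), cv = acc_of(fit$i_cv),
                             test = acc_of(fit$i_te)),
                 confusion = conf, history = fit$tr$history,
                 epochs_run = fit$tr$epochs, seed = seed,
                 call = match.call()),
            class = "har_mlp")
}

# Glorot-uniform initial weights; each matrix has a trailing bias row.
init_weights <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    rbind(matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
          0)  # bias row
  })
}

relu <- function(z) z * (z > 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

add_bias <- function(x) cbind(x, 1)

# Batched forward pass; returns activations of every layer.
mlp_forward_batch <- function(x, w) {
  acts <- list()
  h <- x
  n_layers <- length(w)
  for (l in seq_len(n_layers)) {
    z <- add_bias(h) %*% w[[l]]
    h <- if (l < n_layers) relu(z) else z
    acts[[l]] <- h
  }
  acts[[n_layers]] <- softmax_rows(acts[[n_layers]])
  acts
}

mlp_predict_idx <- function(x, w) {
  p <- mlp_forward_batch(x, w)[[length(w)]]
  max.col(p, ties.method = "first")
}

# Mini-batch gradient descent on the softmax cross-entropy with early
# stopping on cross-validation accuracy (best weights kept).
train_sgd <- function(xt, yt, xc, yc, w, lr, batch, max_epochs, patience) {
  n <- nrow(xt)
  n_out <- ncol(w[[length(w)]])
  best_w <- w
  best_acc <- -Inf
  since_best <- 0L
  hist <- data.frame(epoch = integer(0), train_acc = numeric(0),
                     cv_acc = numeric(0))
  epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    ord <- sample.int(n)
    for (b0 in seq(1L, n, by = batch)) {
      bi <- ord[b0:min(b0 + batch - 1L, n)]
      w <- sgd_step(xt[bi, , drop = FALSE], yt[bi], w, lr, n_out)
    }
    tr_acc <- mean(mlp_predict_idx(xt, w) == yt)
    cv_acc <- if (nrow(xc)) mean(mlp_predict_idx(xc, w) == yc) else tr_acc
    hist <- rbind(hist, data.frame(epoch = epoch, train_acc = tr_acc,
                                   cv_acc = cv_acc))
    if (cv_acc > best_acc + 1e-12) {
      best_acc <- cv_acc
      best_w <- w
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= patience) break
    }
  }
  list(weights = best_w, history = hist, epochs = epoch)
}

# One gradient step on a mini-batch (backpropagation through all layers).
sgd_step <- function(xb, yb, w, lr, n_out) {
  m <- nrow(xb)
  n_layers <- length(w)
  inputs <- vector("list", n_layers)   # with bias column
  h <- xb
  zs <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    inputs[[l]] <- add_bias(h)
    z <- inputs[[l]] %*% w[[l]]
    zs[[l]] <- z
    h <- if (l < n_layers) relu(z) else z
  }
  p <- softmax_rows(h)
  yhot <- matrix(0, m, n_out)
  yhot[cbind(seq_len(m), yb)] <- 1
  delta <- (p - yhot) / m
  for (l in rev(seq_len(n_layers))) {
    grad <- crossprod(inputs[[l]], delta)
    if (l > 1L) {
      back <- delta %*% t(w[[l]][-nrow(w[[l]]), , drop = FALSE])
      delta <- back * (zs[[l - 1L]] > 0)
    }
    w[[l]] <- w[[l]] - lr * grad
  }
  w
}

#' Single-sample forward pass
#'
#' Propagates one feature vector through a fitted network and returns every
#' intermediate activation. The output activations are the inner products of
#' the last hidden layer (plus bias) with the output weights, and the class
#' probabilities are their softmax.
#'
#' @param x Numeric feature vector (already standardized if the model was fit
#'   on standardized features; [predict.har_mlp()] handles this for you).
#' @param model A fitted [har_mlp()] (or a bare weight list).
#' @return List with `h1`, `h2` (hidden activations; `h2` is `NULL` for a
#'   single-hidden-layer net), `activations` (pre-softmax outputs) and `prob`
#'   (softmax probabilities, summing to 1).
#' @export
mlp_forward <- function(x, model) {
  w <- if (inherits(model, "har_mlp")) model$weights else model
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop_validation("input features must be finite")
  acts <- mlp_forward_batch(matrix(x, 1L), w)
  n_layers <- length(w)
  pre_soft <- add_bias(if (n_layers > 1L) acts[[n_layers - 1L]] else matrix(x, 1L)) %*%
    w[[n_layers]]
  list(h1 = if (n_layers >= 2L) drop(acts[[1]]) else NULL,
       h2 = if (n_layers == 3L) drop(acts[[2]]) else
            if (n_layers == 2L) drop(acts[[1]]) else NULL,
       activations = drop(pre_soft),
       prob = drop(acts[[n_layers]]))
}

#' @export
print.har_mlp <- function(x, ...) {
  arch <- paste(c(nrow(x$weights[[1]]) - 1L, x$hidden, length(x$classes)),
                collapse = " -> ")
  cat(sprintf("<har_mlp> %s (ReLU hidden, softmax output)\n", arch))
  cat(sprintf("  accuracies: train %.1f%%, cv %.1f%%, test %.1f%% (%d epochs)\n",
              100 * x$metrics[["train"]], 100 * x$metrics[["cv"]],
              100 * x$metrics[["test"]], x$epochs_run))
  invisible(x)
}

#' @export
summary.har_mlp <- function(object, ...) {
  print(object)
  cost <- cost_model(object$hidden)
  cat(sprintf("  cost: %d multiplications, %d weights, %d bytes (float32)\n",
              cost[["multiplications"]], cost[["weights"]],
              cost[["memory_bytes"]]))
  cat("  test confusion matrix (rows = truth):\n")
  print(object$confusion)
  invisible(object)
}

#' @export
coef.har_mlp <- function(object, ...) object$weights

#' Predict activities for new segments
#'
#' @param object A fitted [har_mlp()].
#' @param newdata Feature matrix or vector on the raw feature scale.
#' @param type `"class"` for activity tags (ties broken toward the lower
#'   class index), `"prob"` for the softmax probability matrix.
#' @param ... Unused.
#' @return Character vector of activity tags, or a probability matrix.
#' @export
predict.har_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (is.null(dim(newdata))) matrix(as.numeric(newdata), 1L)
       else as.matrix(newdata)
  if (!is.null(object$normalizer)) x <- apply_normalizer(x, object$normalizer)
  p <- mlp_forward_batch(x, object$weights)[[length(object$weights)]]
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  object$classes[max.col(p, ties.method = "first")]
}

#' Serialize a fitted network to a flat text file
#'
#' The format is line-oriented and human-readable: a header with the layer
#' sizes and class names, the optional feature-normalizer statistics, then
#' one line per weight-matrix row (row-major, full precision). `read_mlp()`
#' inverts it.
#'
#' @param model A fitted [har_mlp()].
#' @param path Output file path.
#' @return `path` invisibly (writer); a `"har_mlp"` object (reader).
#' @export
write_mlp <- function(model, path) {
  w <- model$weights
  sizes <- c(nrow(w[[1]]) - 1L, vapply(w, ncol, integer(1)))
  num <- function(v) paste(formatC(v, format = "g", digits = 17),
                           collapse = " ")
  lines <- c(paste("layers", paste(sizes, collapse = " ")),
             paste("classes", paste(model$classes, collapse = " ")))
  if (!is.null(model$normalizer)) {
    lines <- c(lines,
               paste("center", num(model$normalizer$center)),
               paste("scale", num(model$normalizer$scale)))
  }
  for (l in seq_along(w))
    for (r in seq_len(nrow(w[[l]])))
      lines <- c(lines, num(w[[l]][r, ]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  lines <- readLines(path)
  toks <- strsplit(lines, " +")
  stopifnot(toks[[1]][1] == "layers")
  sizes <- as.integer(toks[[1]][-1])
  classes <- toks[[2]][-1]
  i <- 3L
  norm <- NULL
  if (toks[[i]][1] == "center") {
    norm <- list(center = as.numeric(toks[[i]][-1]),
                 scale = as.numeric(toks[[i + 1L]][-1]))
    class(norm) <- "har_normalizer"
    i <- i + 2L
  }
  w <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    nr <- sizes[l] + 1L
    m <- t(vapply(seq_len(nr), function(r) as.numeric(toks[[i + r - 1L]]),
                  numeric(sizes[l + 1L])))
    i <- i + nr
    w[[l]] <- m
  }
  structure(list(weights = w,
                 hidden = sizes[-c(1L, length(sizes))],
                 classes = classes, normalizer = norm),
            class = "har_mlp")
}

#' Resource cost of a network configuration
#'
#' Multiplication count and weight memory of the classifier on a
#' microcontroller. A two-hidden-layer net with `Nh1`, `Nh2` neurons and
#' `NA` outputs performs `121*Nh1 + (Nh1+1)*(Nh2+1) + (Nh2+1)*NA`
#' multiplications per inference (the 121 counts the 120 inputs plus bias);
#' a single-hidden-layer net stores `121*Nh + Nh*8` weights. Memory is 4
#' bytes per weight in single precision, or 2 with 16-bit integer weights.
#'
#' @param hidden Integer vector of hidden sizes (length 1 or 2).
#' @param n_classes Number of output classes.
#' @param n_features Input dimension.
#' @param bytes_per_weight 4 (float32, default) or 2 (int16).
#' @return Named numeric vector: `multiplications`, `weights`,
#'   `memory_bytes`.
#' @export
cost_model <- function(hidden, n_classes = 8L, n_features = 120L,
                       bytes_per_weight = 4L) {
  if (any(hidden < 1L)) stop_validation("hidden layer sizes must be >= 1")
  if (length(hidden) == 2L) {
    mult <- (n_features + 1L) * hidden[1] +
      (hidden[1] + 1L) * (hidden[2] + 1L) + (hidden[2] + 1L) * n_classes
    wts <- (n_features + 1L) * hidden[1] + (hidden[1] + 1L) * hidden[2] +
      (hidden[2] + 1L) * n_classes
  } else if (length(hidden) == 1L) {
    wts <- (n_features + 1L) * hidden[1] + hidden[1] * n_classes
    mult <- wts
  } else stop_validation("hidden must have length 1 or 2")
  c(multiplications = mult, weights = wts,
    memory_bytes = wts * bytes_per_weight)
}

#' Design-space exploration over network architectures
#'
#' Trains and tests every candidate architecture `repeats` times with
#' distinct seeds, records mean and standard deviation of test accuracy plus
#' the cost-model figures, and selects the cheapest configuration whose mean
#' accuracy lies within `tolerance` of the grid maximum (the
#' accuracy/resource trade-off rule).
#'
#' @param x,y Features and labels as in [har_mlp()].
#' @param grid List of hidden-size vectors, e.g.
#'   `list(4, 8, c(4, 4), c(4, 8))`.
#' @param repeats Training repetitions per configuration.
#' @param tolerance Accuracy band (fraction, default 0.01 = 1 percentage
#'   point) around the best mean accuracy.
#' @param seed Base seed; repetition `r` of configuration `c` derives its
#'   own seed from it.
#' @param ... Further arguments to [har_mlp()] (e.g. `max_epochs`).
#' @return An object of class `"har_dse"`: a list with `table` (one row per
#'   configuration), `chosen` (hidden sizes of the selected configuration)
#'   and `accuracies` (matrix of the raw repeat accuracies).
#' @export
run_dse <- function(x, y, grid = list(4L, 8L, c(4L, 4L), c(4L, 8L), c(8L, 8L)),
                    repeats = 10L, tolerance = 0.01, seed = 1L, ...) {
  if (!length(grid)) stop_validation("DSE grid is empty")
  acc <- matrix(NA_real_, length(grid), repeats)
  rows <- lapply(seq_along(grid), function(g) {
    hid <- as.integer(grid[[g]])
    for (r in seq_len(repeats)) {
      fit <- har_mlp(x, y, hidden = hid,
                     seed = child_seed(seed, g * 1000L + r), ...)
      acc[g, r] <<- fit$metrics[["test"]]
    }
    cost <- cost_model(hid)
    data.frame(config = paste(hid, collapse = "x"),
               n_layers = length(hid),
               mean_acc = mean(acc[g, ]), sd_acc = stats::sd(acc[g, ]),
               multiplications = cost[["multiplications"]],
               memory_bytes = cost[["memory_bytes"]])
  })
  tab <- do.call(rbind, rows)
  best <- max(tab$mean_acc)
  eligible <- which(tab$mean_acc >= best - tolerance)
  chosen <- eligible[which.min(tab$multiplications[eligible])]
  structure(list(table = tab, chosen = grid[[chosen]],
                 chosen_config = tab$config[chosen],
                 accuracies = acc, tolerance = tolerance),
            class = "har_dse")
}

#' @export
print.har_dse <- function(x, ...) {
  cat("<har_dse> architecture exploration\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("chosen: %s (cheapest within %.1f points of the best)\n",
              x$chosen_config, 100 * x$tolerance))
  invisible(x)
}
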
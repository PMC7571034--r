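#' User feedback and its reward
#'
#' Converts runtime feedback into the scalar reward driving the
#' policy-gradient update: +1 when the predicted activity was correct, -1
#' when it was wrong. Feedback may be binary (`correct`/`wrong`) or a true
#' activity label, in which case correctness is judged against the
#' prediction. `NULL` feedback means the wearer gave none, and no update
#' signal is produced (returns `NA`).
#'
#' @param predicted Predicted activity tag.
#' @param feedback `"correct"`, `"wrong"`, a true activity tag, or `NULL`.
#' @return `+1`, `-1`, or `NA` when there is no feedback.
#' @export
compute_reward <- function(predicted, feedback) {
  if (is.null(feedback) || (length(feedback) == 1L && is.na(feedback)))
    return(NA_real_)
  if (feedback %in% c("correct", "wrong"))
    return(if (feedback == "correct") 1 else -1)
  if (!feedback %in% har_activities())
    stop_validation("feedback must be correct/wrong or a valid activity tag")
  if (identical(feedback, predicted)) 1 else -1
}

#' Policy-gradient update of the output layer
#'
#' REINFORCE-style update of the output-layer weights only, using the last
#' hidden layer's activations as the state representation. Writing `St` for
#' the weights feeding the neuron of the chosen activity `at` and `S̄t` for
#' all other output weights, the update is
#' `theta[j, at] += alpha * r * (1 - pi[at]) * h2[j]` for `St` and
#' `theta[j, i] -= alpha * r * pi[i] * h2[j]` for `S̄t`, which equals
#' `alpha * r` times the gradient of `log pi(at)` with respect to the output
#' weights. Hidden-layer weights are never touched: the offline-trained
#' hidden layers provide general features, and updating only the output
#' layer keeps the runtime cost at a few hundred multiplications.
#'
#' @param model A fitted [har_mlp()].
#' @param h2 Activations of the last hidden layer for the segment that was
#'   classified (from [mlp_forward()]; without the bias term).
#' @param action Index (1-based) of the predicted class.
#' @param reward `+1` or `-1` (an `NA` reward leaves the model unchanged).
#' @param alpha Learning rate (> 0).
#' @return The model with updated output-layer weights.
#' @export
pg_update <- function(model, h2, action, reward, alpha = 1e-4) {
  if (alpha <= 0) stop_validation("alpha must be positive")
  if (is.na(reward)) return(model)
  w <- model$weights
  L <- length(w)
  h2b <- c(h2, 1)  # bias input
  pre <- drop(h2b %*% w[[L]])
  p <- exp(pre - max(pre)); p <- p / sum(p)
  grad_log <- -outer(h2b, p)          # S̄t part: -pi_i * h2_j
  grad_log[, action] <- h2b * (1 - p[action])  # St part
  w[[L]] <- w[[L]] + alpha * reward * grad_log
  model$weights <- w
  model
}

#' Incremental-learning state
#'
#' Holds the misclassification buffer of the incremental supervised learner:
#' up to `capacity` (feature vector, true label) pairs, plus the
#' gradient-descent settings applied when the buffer fills.
#'
#' @param capacity Buffer size `M` (default 16).
#' @param flush_epochs Full-buffer gradient steps per flush (default 10).
#' @param flush_rate Learning rate used during a flush.
#' @return An object of class `"har_il_state"`.
#' @export
il_state <- function(capacity = 16L, flush_epochs = 10L, flush_rate = 0.1) {
  structure(list(x = list(), y = integer(0), capacity = as.integer(capacity),
                 flush_epochs = as.integer(flush_epochs),
                 flush_rate = flush_rate, n_flushes = 0L),
            class = "har_il_state")
}

#' One step of buffered incremental supervised learning
#'
#' If the prediction matches the true label, nothing happens. Otherwise the
#' (standardized feature vector, true label) pair joins the buffer; when the
#' buffer reaches capacity, the output-layer weights are updated by
#' cross-entropy gradient descent on the buffered examples and the buffer is
#' cleared so new data reflects the updated network.
#'
#' @param model A fitted [har_mlp()].
#' @param x Standardized feature vector of the segment.
#' @param predicted Predicted activity tag.
#' @param true_label True activity tag provided by the wearer.
#' @param state A [il_state()].
#' @return List with updated `model` and `state`.
#' @export
il_observe <- function(model, x, predicted, true_label, state) {
  if (!true_label %in% model$classes)
    stop_validation("unknown true label `%s`", true_label)
  if (identical(predicted, true_label))
    return(list(model = model, state = state))
  state$x[[length(state$x) + 1L]] <- x
  state$y <- c(state$y, match(true_label, model$classes))
  if (length(state$y) >= state$capacity) {
    model <- il_flush(model, state)
    state$x <- list()
    state$y <- integer(0)
    state$n_flushes <- state$n_flushes + 1L
  }
  list(model = model, state = state)
}

# Cross-entropy gradient descent on the buffered examples, output layer only.
il_flush <- function(model, state) {
  w <- model$weights
  L <- length(w)
  xb <- do.call(rbind, state$x)
  m <- nrow(xb)
  # hidden activations are fixed: hidden weights are frozen
  h2 <- if (L > 1L) {
    acts <- mlp_forward_batch(xb, w)
    add_bias(acts[[L - 1L]])
  } else add_bias(xb)
  yhot <- matrix(0, m, ncol(w[[L]]))
  yhot[cbind(seq_len(m), state$y)] <- 1
  for (e in seq_len(state$flush_epochs)) {
    p <- softmax_rows(h2 %*% w[[L]])
    w[[L]] <- w[[L]] - state$flush_rate * crossprod(h2, p - yhot) / m
  }
  model$weights <- w
  model
}

#' Online adaptation of a trained classifier to a new wearer
#'
#' Replays a new user's segment stream for `episodes` passes. In each
#' episode every segment is classified with the current weights; feedback is
#' simulated from the ground-truth labels (binary correct/wrong for the
#' policy-gradient method, true labels for incremental learning) and the
#' chosen update rule is applied after each segment. Only output-layer
#' weights change. When an episode ends with a partially full incremental
#' buffer, the buffer is flushed if at least half full and discarded
#' otherwise.
#'
#' @param model A fitted [har_mlp()].
#' @param features Raw feature matrix of the new user's segments.
#' @param labels True activity tags of those segments.
#' @param method `"pg"` (policy gradient, binary feedback) or `"il"`
#'   (incremental supervised learning, labeled feedback).
#' @param episodes Number of replay episodes (default 100).
#' @param alpha Policy-gradient learning rate (initial value).
#' @param buffer Buffer capacity `M` for incremental learning.
#' @param flush_epochs,flush_rate Flush settings for incremental learning
#'   (`flush_rate` is the initial value).
#' @param decay_episodes Learning-rate decay time constant: both update
#'   rules anneal their step size by `1 / (1 + (episode - 1) / decay_episodes)`,
#'   so early episodes make large corrections while late episodes suppress
#'   the gradient noise injected by irreducibly ambiguous segments that
#'   re-enter the feedback stream forever. `Inf` disables annealing.
#' @param seed Unused source of randomness reserved for subsampling streams;
#'   the replay itself is deterministic.
#' @return An object of class `"har_episode_log"`: list with `accuracy`
#'   (per-episode accuracy), `cumulative_reward` (per-episode summed reward),
#'   `initial_accuracy`, `final_accuracy` and the adapted `model`.
#' @export
run_adaptation <- function(model, features, labels, method = c("il", "pg"),
                           episodes = 100L, alpha = 1e-4, buffer = 16L,
                           flush_epochs = 10L, flush_rate = 0.1,
                           decay_episodes = 10, seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(features)
  if (!nrow(x)) stop_validation("empty segment stream")
  if (!is.null(model$normalizer)) x <- apply_normalizer(x, model$normalizer)
  yi <- match(as.character(labels), model$classes)
  if (anyNA(yi)) stop_validation("labels outside the model's class set")
  L <- length(model$weights)
  n <- nrow(x)
  acc <- numeric(episodes)
  rew <- numeric(episodes)
  state <- il_state(buffer, flush_epochs, flush_rate)
  for (ep in seq_len(episodes)) {
    anneal <- 1 / (1 + (ep - 1) / decay_episodes)
    state$flush_rate <- flush_rate * anneal
    correct <- 0L
    for (t in seq_len(n)) {
      fw <- mlp_forward(x[t, ], model)
      at <- which.max(fw$prob)
      ok <- at == yi[t]
      correct <- correct + ok
      if (method == "pg") {
        r <- if (ok) 1 else -1
        rew[ep] <- rew[ep] + r
        model <- pg_update(model, fw$h2, at, r, alpha * anneal)
      } else {
        rew[ep] <- rew[ep] + if (ok) 1 else -1
        st <- il_observe(model, x[t, ], model$classes[at],
                         model$classes[yi[t]], state)
        model <- st$model
        state <- st$state
      }
    }
    if (method == "il" && length(state$y)) {
      if (length(state$y) >= state$capacity / 2)
        model <- il_flush(model, state)
      state$x <- list()
      state$y <- integer(0)
    }
    acc[ep] <- correct / n
  }
  structure(list(accuracy = acc, cumulative_reward = rew,
                 initial_accuracy = acc[1], final_accuracy = acc[episodes],
                 method = method, model = model),
            class = "har_episode_log")
}

#' @export
print.har_episode_log <- function(x, ...) {
  cat(sprintf("<har_episode_log> %s: %d episodes, accuracy %.1f%% -> %.1f%%\n",
              x$method, length(x$accuracy), 100 * x$initial_accuracy,
              100 * x$final_accuracy))
  invisible(x)
}
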
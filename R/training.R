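#' Training configuration
#'
#' Standard defaults for the desk-scale training runs: Adam with binary
#' cross-entropy (pose) or mean squared error (affinity), a group-aware
#' validation split (all examples sharing a `group_id` land on the same
#' side, so decoys of a system can never leak across the split), and early
#' stopping on validation loss.
#'
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size (graphs per step).
#' @param learning_rate Adam step size.
#' @param seed Seed for shuffling and the split.
#' @param validation_fraction Fraction of groups held out.
#' @param patience Early-stopping patience in epochs (`Inf` to disable).
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 60L, batch_size = 32L, learning_rate = 5e-3,
                         seed = 1L, validation_fraction = 0.2, patience = 25L) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate >= 0,
            validation_fraction > 0, validation_fraction < 1, patience >= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 validation_fraction = validation_fraction, patience = patience),
            class = "train_config")
}

#' Bundle a graph with a training label
#'
#' @param graph A `complex_graph`.
#' @param label Binary (pose task) or nonnegative real (affinity task).
#' @param group_id String tying together poses of one system.
#' @return A `labeled_example`.
#' @export
labeled_example <- function(graph, label, group_id) {
  structure(list(graph = graph, label = label, group_id = group_id),
            class = "labeled_example")
}

split_by_group <- function(dataset, fraction, seed) {
  groups <- vapply(dataset, function(e) e$group_id, character(1))
  ug <- unique(groups)
  with_seed(seed, {
    n_val <- max(1L, round(fraction * length(ug)))
    val_groups <- sample(ug, n_val)
  })
  val <- groups %in% val_groups
  list(train = which(!val), val = which(val))
}

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

eval_split <- function(params, dataset, idx, chunk = 64L) {
  labels <- vapply(dataset[idx], function(e) e$label, numeric(1))
  outs <- numeric(0)
  for (start in seq(1, length(idx), by = chunk)) {
    take <- idx[start:min(start + chunk - 1L, length(idx))]
    batch <- combine_graphs(lapply(dataset[take], function(e) e$graph))
    outs <- c(outs, egnn_forward(params, batch)$output)
  }
  if (params$config$head == "pose") {
    p <- pmin(pmax(outs, 1e-12), 1 - 1e-12)
    list(loss = -mean(labels * log(p) + (1 - labels) * log(1 - p)),
         accuracy = mean((outs > 0.5) == (labels > 0.5)),
         pearson = NA_real_, output = outs)
  } else {
    r <- if (stats::sd(outs) > 0 && stats::sd(labels) > 0) {
      stats::cor(outs, labels)
    } else NA_real_
    list(loss = mean((outs - labels)^2), accuracy = NA_real_,
         pearson = r, output = outs)
  }
}

train_loop <- function(params, dataset, config) {
  split <- split_by_group(dataset, config$validation_fraction, config$seed)
  theta <- flatten_params(params)
  st <- adam_state(length(theta))
  history <- list()
  best <- list(theta = theta, val_loss = Inf, epoch = 0L)
  n_train <- length(split$train)
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(config$seed * 10000L + epoch, sample(split$train))
    ep_loss <- 0; n_batches <- 0L
    ep_out <- ep_lab <- numeric(0)
    for (start in seq(1, n_train, by = config$batch_size)) {
      take <- ord[start:min(start + config$batch_size - 1L, n_train)]
      batch <- combine_graphs(lapply(dataset[take], function(e) e$graph))
      labels <- vapply(dataset[take], function(e) e$label, numeric(1))
      params <- unflatten_params(theta, params)
      lg <- batch_loss_grad(params, batch, labels)
      stepped <- adam_step(theta, flatten_grads(lg$grads), st, config$learning_rate)
      theta <- stepped$theta; st <- stepped$state
      ep_loss <- ep_loss + lg$loss * length(take); n_batches <- n_batches + 1L
      ep_out <- c(ep_out, lg$output); ep_lab <- c(ep_lab, labels)
    }
    params <- unflatten_params(theta, params)
    va <- eval_split(params, dataset, split$val)
    # train metrics are running minibatch averages (pre-update outputs)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = ep_loss / n_train, val_loss = va$loss,
      train_accuracy = if (params$config$head == "pose")
        mean((ep_out > 0.5) == (ep_lab > 0.5)) else NA_real_,
      val_accuracy = va$accuracy,
      val_pearson = va$pearson
    )
    if (va$loss < best$val_loss) {
      best <- list(theta = theta, val_loss = va$loss, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  if (config$epochs == 0L) {
    va0 <- eval_split(params, dataset, split$val)
    best <- list(theta = theta, val_loss = va0$loss, epoch = 0L)
  }
  params <- unflatten_params(best$theta, params)
  history <- if (length(history)) dplyr::bind_rows(history) else
    tibble::tibble(epoch = integer(), train_loss = numeric(), val_loss = numeric(),
                   train_accuracy = numeric(), val_accuracy = numeric(),
                   val_pearson = numeric())
  structure(list(params = params, history = history, split = split,
                 best_epoch = best$epoch, config = config),
            class = "egnn_fit")
}

#' Train the pose classifier
#'
#' Stage one of the two-stage scheme: binary classification of poses into
#' binders and nonbinders under binary cross-entropy, learning the geometry
#' of binding before any affinity data is seen.
#'
#' @param dataset List of [labeled_example()]s with binary labels.
#' @param config A [model_config()] with `head = "pose"`.
#' @param train A [train_config()].
#' @return An `egnn_fit`: list with `params` (the selected checkpoint),
#'   `history` (per-epoch tibble), `split` and `best_epoch`.
#' @export
train_pose_classifier <- function(dataset, config = model_config(head = "pose"),
                                  train = train_config()) {
  labels <- vapply(dataset, function(e) e$label, numeric(1))
  if (!all(labels %in% c(0, 1))) {
    stop("pose labels must be binary 0/1", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("pose dataset must contain both classes", call. = FALSE)
  }
  if (config$head != "pose") {
    config$head <- "pose"
  }
  params <- init_params(config)
  train_loop(params, dataset, train)
}

#' Finetune on binding affinity
#'
#' Stage two: the sigmoid pose head is replaced by a freshly initialized
#' fully connected layer with ReLU activation, the network body is kept from
#' pretraining, and training continues under squared-error loss on
#' nonnegative affinity labels.
#'
#' @param pretrained An `egnn_model` with a pose head (e.g.
#'   `fit$params` from [train_pose_classifier()]).
#' @param dataset List of [labeled_example()]s with nonnegative real labels.
#' @param train A [train_config()].
#' @param head_seed Seed for the new head's initialization.
#' @return An `egnn_fit`; `params$head_replaced` is `TRUE` and the history
#'   carries per-epoch validation Pearson correlation.
#' @export
finetune_affinity <- function(pretrained, dataset, train = train_config(),
                              head_seed = 999L) {
  stopifnot(inherits(pretrained, "egnn_model"))
  if (pretrained$config$head != "pose") {
    stop("expected a pose-head pretrained model", call. = FALSE)
  }
  labels <- vapply(dataset, function(e) e$label, numeric(1))
  if (any(labels < 0)) stop("affinity labels must be nonnegative", call. = FALSE)
  params <- pretrained
  params$config$head <- "affinity"
  d <- params$config$hidden_width
  with_seed(head_seed, {
    params$head <- list(w = as.numeric(glorot(d, 1)), b = 1.0)
  })
  params$head_replaced <- TRUE
  train_loop(params, dataset, train)
}

#' @export
print.egnn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<egnn_fit> %s head, %d epochs (best %d)\n",
              x$params$config$head, nrow(h), x$best_epoch))
  if (nrow(h)) print(utils::tail(h, 3))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fit
#'
#' @param x An `egnn_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @method tidy egnn_fit
#' @export
tidy.egnn_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x An `egnn_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the head type, best epoch and the
#'   validation metrics at the selected checkpoint.
#' @method glance egnn_fit
#' @export
glance.egnn_fit <- function(x, ...) {
  h <- x$history
  row <- if (x$best_epoch >= 1 && nrow(h)) h[h$epoch == x$best_epoch, ] else
    tibble::tibble(val_loss = NA_real_, val_accuracy = NA_real_, val_pearson = NA_real_)
  tibble::tibble(
    head = x$params$config$head,
    n_layers = x$params$config$n_layers,
    hidden_width = x$params$config$hidden_width,
    epochs_run = nrow(h),
    best_epoch = x$best_epoch,
    val_loss = row$val_loss,
    val_accuracy = row$val_accuracy,
    val_pearson = row$val_pearson
  )
}

#' Plot a training history
#'
#' @param fit An `egnn_fit`.
#' @return A ggplot object of train/validation loss per epoch.
#' @export
plot_history <- function(fit) {
  h <- tidyr::pivot_longer(fit$history, c("train_loss", "val_loss"),
                           names_to = "split", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
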
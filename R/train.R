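#' @title Two-stage training with knowledge transfer
#' @name train
#' @description Stage I pretrains the full network on censoring-aware
#'   binary vital-status labels (binary cross-entropy). Stage II transfers
#'   the expression- and drug-encoder weights of the best stage-I
#'   checkpoint, attaches a fresh regression head, and fine-tunes on log
#'   months-to-death of deceased patients (mean squared error). Both stages
#'   checkpoint the best validation metric and stop early.
NULL

#' Training configuration
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 64).
#' @param max_epochs Epoch budget (default 100).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param weight_decay Decoupled weight decay applied to weight matrices
#'   (not biases or normalization parameters); default 0.1.
#' @param input_noise_sd Gaussian jitter added to the standardized
#'   expression inputs during training only (augmentation against
#'   patient-level memorization; inputs are z-scored so this is in SD
#'   units); default 0.5.
#' @param seed Integer seed covering shuffling and any fresh initialization.
#' @return A \code{train_config} list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 100L, patience = 10L,
                         weight_decay = 0.1, input_noise_sd = 0.5,
                         seed = 1L) {
  stopifnot(learning_rate > 0, batch_size > 1, max_epochs > 0, patience > 0,
            weight_decay >= 0, input_noise_sd >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 weight_decay = weight_decay,
                 input_noise_sd = input_noise_sd,
                 seed = as.integer(seed)),
            class = "train_config")
}

.make_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  starts <- seq(1L, n, by = batch_size)
  batches <- lapply(starts, function(s) idx[s:min(s + batch_size - 1L, n)])
  nb <- length(batches)
  if (nb > 1L && length(batches[[nb]]) < 2L) {
    batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
    batches[[nb]] <- NULL
  }
  batches
}

.metric_of <- function(stage, pred, y) {
  if (stage == "stage1") {
    mean((pred > 0.5) == (y == 1))
  } else {
    if (stats::sd(pred) < 1e-12 || stats::sd(y) < 1e-12) {
      return(NA_real_)
    }
    stats::cor(pred, y)
  }
}

.eval_loss <- function(stage, pred, y) {
  if (stage == "stage1") {
    eps <- 1e-12
    -mean(y * log(pred + eps) + (1 - y) * log(1 - pred + eps))
  } else {
    mean((pred - y)^2)
  }
}

.with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

.train_loop <- function(model, train, val, config, checkpoint = "best") {
  .with_seed(config$seed, {
    state <- adam_init(model$par)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0), train_metric = numeric(0),
                          val_metric = numeric(0))
    best <- list(metric = -Inf, epoch = 0L, par = model$par,
                 buffers = model$buffers)
    stale <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      batches <- .make_batches(nrow(train$X), config$batch_size)
      for (b in batches) {
        Xb <- train$X[b, , drop = FALSE]
        if (config$input_noise_sd > 0) {
          Xb <- Xb + stats::rnorm(length(Xb), 0, config$input_noise_sd)
        }
        fw <- vnn_forward(model, Xb, train$FP[b, , drop = FALSE],
                          training = TRUE, cache = TRUE)
        model$buffers <- fw$enc$buffers
        bw <- vnn_backward(model, fw, train$label[b])
        upd <- adam_step(model$par, bw$grads, state,
                         lr = config$learning_rate,
                         weight_decay = config$weight_decay)
        model$par <- upd$par
        state <- upd$state
      }
      # recalibrate normalization statistics on the clean training inputs
      # (minibatch statistics are inflated by the input-noise augmentation)
      recal <- .encoder_forward(model, train$X, training = TRUE,
                                bn_update = "replace")
      model$buffers <- recal$buffers
      pred_tr <- predict_training_set(model, train)
      pred_va <- predict_training_set(model, val)
      m_tr <- .metric_of(model$stage, pred_tr, train$label)
      m_va <- .metric_of(model$stage, pred_va, val$label)
      history <- rbind(history, data.frame(
        epoch = epoch,
        train_loss = .eval_loss(model$stage, pred_tr, train$label),
        val_loss = .eval_loss(model$stage, pred_va, val$label),
        train_metric = m_tr, val_metric = m_va))
      if (!is.na(m_va) && m_va > best$metric) {
        best <- list(metric = m_va, epoch = epoch, par = model$par,
                     buffers = model$buffers)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
    if (checkpoint == "best") {
      model$par <- best$par
      model$buffers <- best$buffers
    }
    model$meta$trained <- list(seed = config$seed, epochs = nrow(history),
                               best_epoch = best$epoch,
                               best_metric = best$metric)
    structure(list(model = model, history = history,
                   best_epoch = best$epoch, best_metric = best$metric),
              class = "stage_result")
  })
}

#' @export
print.stage_result <- function(x, ...) {
  cat("stage_result (", x$model$stage, "): best epoch ", x$best_epoch,
      ", best validation metric ", round(x$best_metric, 4L), "\n", sep = "")
  invisible(x)
}

#' Stage-I training: binary vital-status classification
#'
#' @param model A \code{vnn_model} built with \code{stage = "stage1"}.
#' @param train,val \code{training_set}s with binary labels.
#' @param config A [train_config()].
#' @return A \code{stage_result} with the best-validation-accuracy model,
#'   the per-epoch history, and the best epoch/metric.
#' @export
train_stage1 <- function(model, train, val, config = train_config()) {
  stopifnot(inherits(model, "vnn_model"), model$stage == "stage1")
  if (!all(train$label %in% c(0, 1))) stop("stage-1 labels must be 0/1")
  if (length(unique(train$label)) < 2L) {
    stop("stage-1 training set contains a single class")
  }
  .train_loop(model, train, val, config)
}

#' Stage-II training with knowledge transfer
#'
#' Initializes the expression encoder and drug encoder exactly with the
#' best stage-I weights (including batch-norm running statistics), discards
#' the classification head, attaches a freshly initialized regression head,
#' and fine-tunes on log months-to-death. With \code{single_stage = TRUE}
#' all weights are instead freshly initialized — the no-pretraining
#' ablation baseline.
#'
#' @param stage1 A \code{stage_result} from [train_stage1()].
#' @param train,val \code{training_set}s with log-months labels.
#' @param config A [train_config()].
#' @param single_stage Skip knowledge transfer (default \code{FALSE}).
#' @return A \code{stage_result} checkpointed at the best validation
#'   Pearson r.
#' @export
transfer_and_train_stage2 <- function(stage1, train, val,
                                      config = train_config(),
                                      single_stage = FALSE) {
  stopifnot(inherits(stage1, "stage_result"))
  s1_model <- stage1$model
  if (ncol(train$X) != length(s1_model$gene_order) ||
      ncol(train$FP) != s1_model$config$n_bits) {
    stop("stage-2 data do not match the stage-1 model ",
         "(DAG/config hash ", s1_model$meta$dag_hash, ")")
  }
  model <- transfer_model(stage1, seed = config$seed,
                          single_stage = single_stage)
  .train_loop(model, train, val, config)
}

#' Initialize the stage-II model from a stage-I result
#'
#' The returned model is the exact epoch-0 state of stage-II training:
#' encoder and drug-encoder weights (and normalization statistics) are the
#' stage-I best checkpoint, bitwise; the head is freshly initialized.
#'
#' @param stage1 A \code{stage_result} from [train_stage1()].
#' @param seed Seed for the fresh head (and, with
#'   \code{single_stage = TRUE}, the whole network).
#' @param single_stage Initialize everything from scratch instead.
#' @return A \code{vnn_model} with \code{stage = "stage2"}.
#' @export
transfer_model <- function(stage1, seed = 1L, single_stage = FALSE) {
  stopifnot(inherits(stage1, "stage_result"))
  s1_model <- stage1$model
  if (single_stage) {
    cfg2 <- s1_model$config
    cfg2$seed <- as.integer(seed)
    return(build_model(s1_model$dag, cfg2, stage = "stage2"))
  }
  model <- s1_model
  model$stage <- "stage2"
  # fresh regression head, seeded by the stage-2 training seed
  .with_seed(seed, {
    head_in <- model$config$k_term_neurons +
      utils::tail(model$config$drug_layer_sizes, 1L)
    model$par[["head.Wh"]] <- .glorot(head_in, model$config$head_hidden)
    model$par[["head.bh"]] <- numeric(model$config$head_hidden)
    model$par[["head.Wo"]] <- .glorot(model$config$head_hidden, 1L)
    model$par[["head.bo"]] <- 0
  })
  model
}

#' Evaluate a model on a set of examples
#'
#' @param model A \code{vnn_model}.
#' @param examples A \code{training_set}.
#' @return Accuracy at threshold 0.5 (stage 1) or Pearson correlation
#'   between predicted and true log months (stage 2).
#' @export
evaluate <- function(model, examples) {
  if (!nrow(examples$X)) stop("empty example list")
  pred <- predict_training_set(model, examples)
  m <- .metric_of(model$stage, pred, examples$label)
  if (model$stage == "stage2" && is.na(m)) {
    stop("correlation undefined: zero-variance predictions or labels")
  }
  m
}
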
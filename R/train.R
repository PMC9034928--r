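#' Construct an optimizer
#'
#' SGD (the default training regime: initial rate 0.015 decayed per epoch as
#' \code{lr_e = lr_0 / (1 + decay * e)}, global gradient-norm clipping at 5.0)
#' plus the adaptive alternatives AdaGrad, Adadelta, RMSProp and Adam for
#' optimizer comparisons.
#'
#' @param name one of "sgd", "adagrad", "adadelta", "rmsprop", "adam".
#' @param config a \code{\link{run_config}} supplying initial_lr, decay_rate
#'   and gradient_clip.
#' @return an object of class \code{drugner_optimizer}.
#' @export
make_optimizer <- function(name, config = run_config()) {
  valid <- c("sgd", "adagrad", "adadelta", "rmsprop", "adam")
  name <- tolower(name)
  if (!name %in% valid)
    stop("unknown optimizer '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  structure(list(name = name, lr0 = config$initial_lr,
                 decay = config$decay_rate, clip = config$gradient_clip,
                 state = new.env(parent = emptyenv())),
            class = "drugner_optimizer")
}

#' Effective learning rate at an epoch
#' @param opt optimizer.
#' @param epoch 0-based epoch index.
#' @return \code{lr_0 / (1 + decay * epoch)} for SGD; \code{lr_0} otherwise.
#' @export
optimizer_lr <- function(opt, epoch) {
  if (opt$name == "sgd") opt$lr0 / (1 + opt$decay * epoch) else opt$lr0
}

#' Clip a gradient set to a global norm bound
#'
#' @param grads named list of gradient arrays.
#' @param clip maximum global L2 norm; values above it rescale every gradient
#'   so the applied global norm is exactly \code{clip}.
#' @return the (possibly rescaled) gradient list.
#' @export
clip_gradients <- function(grads, clip) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(nrm) && nrm > clip)
    grads <- lapply(grads, function(g) g * (clip / nrm))
  grads
}

# Apply one optimizer update to the parameter list. grads holds arrays shaped
# like the corresponding params entries (absent entries are untouched).
optimizer_step <- function(opt, params, grads, epoch) {
  grads <- clip_gradients(grads, opt$clip)
  lr <- optimizer_lr(opt, epoch)
  eps <- 1e-8
  st <- opt$state
  for (nm in names(grads)) {
    g <- grads[[nm]]
    params[[nm]] <- switch(opt$name,
      sgd = params[[nm]] - lr * g,
      adagrad = {
        key <- paste0("acc.", nm)
        acc <- if (is.null(st[[key]])) g^2 else st[[key]] + g^2
        st[[key]] <- acc
        params[[nm]] - lr * g / (sqrt(acc) + eps)
      },
      adadelta = {
        rho <- 0.95
        kg <- paste0("Eg.", nm); kx <- paste0("Ex.", nm)
        Eg <- if (is.null(st[[kg]])) (1 - rho) * g^2
              else rho * st[[kg]] + (1 - rho) * g^2
        Ex <- if (is.null(st[[kx]])) array(0, dim = dim(g) %||% length(g))
              else st[[kx]]
        dx <- -sqrt(Ex + eps) / sqrt(Eg + eps) * g
        st[[kg]] <- Eg
        st[[kx]] <- rho * Ex + (1 - rho) * dx^2
        params[[nm]] + dx
      },
      rmsprop = {
        rho <- 0.9
        key <- paste0("Eg.", nm)
        Eg <- if (is.null(st[[key]])) (1 - rho) * g^2
              else rho * st[[key]] + (1 - rho) * g^2
        st[[key]] <- Eg
        params[[nm]] - lr * g / (sqrt(Eg) + eps)
      },
      adam = {
        b1 <- 0.9; b2 <- 0.999
        km <- paste0("m.", nm); kv <- paste0("v.", nm); kt <- paste0("t.", nm)
        t <- (if (is.null(st[[kt]])) 0L else st[[kt]]) + 1L
        m <- if (is.null(st[[km]])) (1 - b1) * g
             else b1 * st[[km]] + (1 - b1) * g
        v <- if (is.null(st[[kv]])) (1 - b2) * g^2
             else b2 * st[[kv]] + (1 - b2) * g^2
        st[[km]] <- m; st[[kv]] <- v; st[[kt]] <- t
        mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
        params[[nm]] - lr * mh / (sqrt(vh) + eps)
      })
  }
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- loss and gradients for one sentence ---------------------------------

# Forward + backward for one instance on one task. Returns the sentence loss
# and a named gradient list. Feedback (when active) uses the current model's
# own first-pass predictions on the same shared representation, with no
# gradient through the feedback labels.
sentence_grads <- function(model, inst, task, training = TRUE) {
  cfg <- model$config
  s <- cfg$state_size
  enc <- encoder_forward(model, inst, training = training)
  n <- enc$n
  Y <- NULL
  if (cfg$feedback) {
    other <- if (task == "ner") "nen" else "ner"
    Y <- first_pass_dist(model, enc$H, other,
                         onehot = (cfg$feedback_y == "onehot"))
  }
  hf <- head_forward(model, enc$H, task, Y)
  grads <- list()
  if (task == "ner") {
    if (any(inst$ner_z < 1L))
      stop("training sentence contains a label outside the label alphabet")
    cg <- crf_grad(hf$scores, model$params$ner.A, inst$ner_z)
    loss <- cg$nll
    dScores <- cg$dP
    grads$ner.A <- cg$dA
  } else {
    if (any(inst$norm_z < 1L))
      stop("training sentence contains a normalization ID outside the alphabet")
    Pm <- row_softmax(hf$scores)
    loss <- -sum(log(Pm[cbind(seq_len(n), inst$norm_z)]))
    dScores <- Pm
    dScores[cbind(seq_len(n), inst$norm_z)] <-
      dScores[cbind(seq_len(n), inst$norm_z)] - 1
  }
  Wname <- paste0(task, ".W"); bname <- paste0(task, ".b")
  grads[[Wname]] <- crossprod(dScores, hf$Vrep)
  grads[[bname]] <- colSums(dScores)
  dVrep <- dScores %*% model$params[[Wname]]
  if (cfg$feedback_mode == "concat") {
    dv_direct <- dVrep[, 1:(2 * s), drop = FALSE]
    dv_corr <- dVrep[, (2 * s + 1):(4 * s), drop = FALSE]
  } else {
    dv_direct <- matrix(0, n, 2 * s)
    dv_corr <- dVrep
  }
  dH <- dv_direct + dv_corr
  if (!is.null(Y))
    grads[[if (task == "ner") "U" else "V"]] <- crossprod(Y, dv_corr)
  bb <- bilstm_backward(dH, enc$fw, lstm_view(model, "fwd"),
                        lstm_view(model, "bwd"))
  grads$fwd.Wx <- bb$fwd$Wx; grads$fwd.Wh <- bb$fwd$Wh; grads$fwd.b <- bb$fwd$b
  grads$bwd.Wx <- bb$bwd$Wx; grads$bwd.Wh <- bb$bwd$Wh; grads$bwd.b <- bb$bwd$b
  dX <- bb$dX
  col0 <- 0L
  if (cfg$use_word) {
    dXw <- dX[, col0 + 1:cfg$word_dim, drop = FALSE]
    dE <- matrix(0, nrow(model$params$word.E), cfg$word_dim)
    for (t in seq_len(n)) {
      id <- inst$word_ids[t]
      if (id != 1L) dE[id, ] <- dE[id, ] + dXw[t, ]
    }
    grads$word.E <- dE
    col0 <- col0 + cfg$word_dim
  }
  if (cfg$use_char) {
    dXc <- dX[, col0 + 1:cfg$num_filters, drop = FALSE]
    cb <- char_batch_backward(dXc, enc$char_caches, char_cnn_view(model),
                              nrow(model$params$char.E))
    grads$char.W <- cb$W; grads$char.b <- cb$b; grads$char.E <- cb$E
    col0 <- col0 + cfg$num_filters
  }
  if (cfg$use_elmo) {
    dXe <- dX[, col0 + 1:(2 * s), drop = FALSE]
    w <- softmax(model$params$elmo.logits)
    raw <- vapply(enc$ctx_cache, function(Lj) sum(dXe * Lj), numeric(1))
    grads$elmo.logits <- w * (raw - sum(w * raw))
  }
  list(loss = loss, grads = grads)
}

# Sum gradient lists elementwise.
add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]]
    else a[[nm]] + b[[nm]]
  a
}

# ---- the asynchronous multitask loop -------------------------------------

#' Train the model (single task or asynchronous multitask)
#'
#' Each step samples a task from the schedule, draws the next minibatch of
#' that task's dataset, computes the task loss (CRF negative log-likelihood
#' for recognition; summed per-token cross-entropy for normalization),
#' backpropagates through that task's head, its feedback matrix and the whole
#' shared encoder, and applies one optimizer update. The other task's head is
#' untouched by the step. An epoch draws as many instances in expectation as
#' the scheduled datasets contain. Batch loss is the mean per-sentence loss.
#'
#' All randomness (shuffling, task sampling, dropout) is drawn from a single
#' stream derived from the configuration seed, so training is exactly
#' reproducible.
#'
#' @param model a \code{\link{init_model}} model.
#' @param d_dner recognition dataset: list of \code{\link{annotated_sentence}}
#'   or prepared instances.
#' @param d_dnen normalization dataset; defaults to the same sentences.
#' @param epochs number of epochs (default from the config).
#' @param schedule named task-sampling probabilities
#'   \code{c(dner = , dnen = )}; default proportional to dataset sizes for
#'   multitask, degenerate for single-task configs.
#' @param early_stop_f1 optional strict-matching F1 threshold on \code{d_dner}
#'   evaluated after each epoch; training stops once reached.
#' @param verbose print per-epoch losses.
#' @return list of class \code{drugner_fit}: \code{model} (trained) and
#'   \code{history} (one row per completed epoch: per-task mean losses,
#'   effective learning rate, and F1 when evaluated).
#' @export
multitask_train <- function(model, d_dner, d_dnen = d_dner,
                            epochs = model$config$epochs, schedule = NULL,
                            early_stop_f1 = NULL, verbose = FALSE) {
  cfg <- model$config
  if (is.null(schedule)) {
    schedule <- switch(cfg$task,
      dner = c(dner = 1, dnen = 0),
      dnen = c(dner = 0, dnen = 1),
      multitask = {
        n1 <- length(d_dner); n2 <- length(d_dnen)
        if (n1 == 0L || n2 == 0L)
          stop("multitask training needs a non-empty dataset for both tasks; ",
               "got ", n1, " recognition and ", n2,
               " normalization instances (dataset is empty)")
        c(dner = n1, dnen = n2) / (n1 + n2)
      })
  }
  if (schedule["dner"] > 0 && length(d_dner) == 0L)
    stop("recognition task is scheduled but its dataset is empty")
  if (schedule["dnen"] > 0 && length(d_dnen) == 0L)
    stop("normalization task is scheduled but its dataset is empty")
  is_inst <- function(d) length(d) > 0L && !is.null(d[[1]]$word_ids)
  gold_dner <- if (!is_inst(d_dner)) d_dner else NULL
  inst_dner <- if (is_inst(d_dner)) d_dner else prepare_instances(d_dner, model)
  inst_dnen <- if (is_inst(d_dnen)) d_dnen else prepare_instances(d_dnen, model)
  opt <- make_optimizer(cfg$optimizer, cfg)
  n_active <- (schedule["dner"] > 0) * length(inst_dner) +
    (schedule["dnen"] > 0) * length(inst_dnen)
  steps_per_epoch <- max(1L, ceiling(n_active / cfg$batch_size))
  history <- data.frame()
  with_seed(derive_seed(cfg$seed, "train"), {
    cursor <- c(dner = 0L, dnen = 0L)
    order_d <- list(dner = integer(0), dnen = integer(0))
    datasets <- list(dner = inst_dner, dnen = inst_dnen)
    next_batch <- function(task) {
      N <- length(datasets[[task]])
      idx <- integer(0)
      need <- min(cfg$batch_size, N)
      while (length(idx) < need) {
        if (cursor[[task]] >= length(order_d[[task]])) {
          order_d[[task]] <<- sample.int(N)
          cursor[[task]] <<- 0L
        }
        take <- min(need - length(idx),
                    length(order_d[[task]]) - cursor[[task]])
        idx <- c(idx, order_d[[task]][cursor[[task]] + seq_len(take)])
        cursor[[task]] <<- cursor[[task]] + take
      }
      datasets[[task]][idx]
    }
    for (ep in seq_len(epochs) - 1L) {
      loss_sum <- c(dner = 0, dnen = 0); loss_n <- c(dner = 0L, dnen = 0L)
      for (step in seq_len(steps_per_epoch)) {
        u <- stats::runif(1)     # one draw per step, schedule-independent
        task <- if (u < schedule["dner"]) "dner" else "dnen"
        if (schedule["dner"] >= 1) task <- "dner"
        if (schedule["dnen"] >= 1) task <- "dnen"
        batch <- next_batch(task)
        head_task <- if (task == "dner") "ner" else "nen"
        grads <- list(); loss <- 0
        for (inst in batch) {
          sg <- sentence_grads(model, inst, head_task, training = TRUE)
          grads <- add_grads(grads, sg$grads)
          loss <- loss + sg$loss
        }
        loss <- loss / length(batch)
        grads <- lapply(grads, function(g) g / length(batch))
        model$params <- optimizer_step(opt, model$params, grads, ep)
        loss_sum[task] <- loss_sum[task] + loss
        loss_n[task] <- loss_n[task] + 1L
      }
      f1 <- NA_real_
      if (!is.null(early_stop_f1) && !is.null(gold_dner)) {
        pred <- predict_corpus(gold_dner, model)
        f1 <- evaluate_corpus(gold_dner, pred, "strict")$micro$f1
      }
      history <- rbind(history, data.frame(
        epoch = ep,
        dner_loss = if (loss_n["dner"] > 0) loss_sum["dner"] / loss_n["dner"]
          else NA_real_,
        dnen_loss = if (loss_n["dnen"] > 0) loss_sum["dnen"] / loss_n["dnen"]
          else NA_real_,
        lr = optimizer_lr(opt, ep), f1 = f1, row.names = NULL))
      if (verbose)
        message(sprintf("epoch %d: dner %.4f dnen %.4f lr %.5f f1 %s", ep,
                        history$dner_loss[nrow(history)],
                        history$dnen_loss[nrow(history)],
                        history$lr[nrow(history)],
                        ifelse(is.na(f1), "-", sprintf("%.3f", f1))))
      if (!is.null(early_stop_f1) && !is.na(f1) && f1 >= early_stop_f1) break
    }
  })
  structure(list(model = model, history = history), class = "drugner_fit")
}

#' @export
print.drugner_fit <- function(x, ...) {
  cat(sprintf("<drugner fit: %d epochs>\n", nrow(x$history)))
  print(x$history)
  invisible(x)
}

#' Single-entry training dispatch
#'
#' Trains according to \code{config$task}: single-task training is exactly the
#' multitask loop with a degenerate schedule, so the two regimes are
#' step-for-step comparable.
#'
#' @param model the model.
#' @param corpus annotated training corpus (used for both task datasets in
#'   multitask mode).
#' @param ... passed to \code{\link{multitask_train}}.
#' @return a \code{drugner_fit}.
#' @export
train_model <- function(model, corpus, ...) {
  multitask_train(model, corpus, corpus, ...)
}
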
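#' Run configuration
#'
#' All tunable hyperparameters with the package's default training regime:
#' char-CNN window 3 and 30 filters, LSTM state size 200 with zero initial
#' state and no peepholes, dropout 0.5, batch size 10, initial learning rate
#' 0.015 with per-epoch decay rate 0.05, gradient clipping 5.0, BIO labeling,
#' contextual-channel width 1024. Word/char/contextual embedding widths
#' default to 100/30/1024 (the character width matching the character-CNN
#' initialization convention); either pairing of the word/char widths is
#' configurable.
#'
#' @param window_size char-CNN window width.
#' @param num_filters char-CNN filter count.
#' @param state_size LSTM hidden state size.
#' @param dropout_rate dropout probability on character embeddings (training).
#' @param batch_size minibatch size.
#' @param initial_lr initial SGD learning rate.
#' @param gradient_clip global gradient-norm clip.
#' @param decay_rate learning-rate decay: lr_e = lr_0 / (1 + decay_rate * e).
#' @param labeling_schema only "BIO" is supported.
#' @param word_dim,char_dim,elmo_dim channel widths.
#' @param use_word,use_char,use_elmo active representation channels.
#' @param lstm_variant "standard" (training default) or "cifg".
#' @param task "multitask", "dner" or "dnen".
#' @param feedback cross-task explicit feedback on/off (requires multitask).
#' @param feedback_mode "concat" (head sees the shared vector alongside the
#'   feedback-corrected vector) or "corrected" (corrected vector only).
#' @param feedback_y "distribution" (softmax feedback during training) or
#'   "onehot"; inference always uses the predicted label's one-hot.
#' @param bio_mask hard BIO transition masking at decode time.
#' @param optimizer one of "sgd", "adagrad", "adadelta", "rmsprop", "adam".
#' @param epochs training epochs.
#' @param seed master seed fanned out to derived streams.
#' @param elmo_layers biLM layer count when the contextual channel is active.
#' @return an object of class \code{drugner_config}.
#' @export
run_config <- function(window_size = 3L, num_filters = 30L,
                       state_size = 200L, dropout_rate = 0.5,
                       batch_size = 10L, initial_lr = 0.015,
                       gradient_clip = 5.0, decay_rate = 0.05,
                       labeling_schema = "BIO",
                       word_dim = 100L, char_dim = 30L, elmo_dim = 1024L,
                       use_word = TRUE, use_char = TRUE, use_elmo = FALSE,
                       lstm_variant = "standard",
                       task = c("multitask", "dner", "dnen"),
                       feedback = (task == "multitask"),
                       feedback_mode = c("concat", "corrected"),
                       feedback_y = c("distribution", "onehot"),
                       bio_mask = FALSE,
                       optimizer = "sgd", epochs = 10L, seed = 1L,
                       elmo_layers = 1L) {
  task <- match.arg(task)
  feedback_mode <- match.arg(feedback_mode)
  feedback_y <- match.arg(feedback_y)
  if (labeling_schema != "BIO")
    stop("labeling_schema: only \"BIO\" is supported")
  if (feedback && task != "multitask")
    stop("feedback requires task = \"multitask\"; single-task '", task,
         "' has no other task to feed back from")
  check_variant(lstm_variant)
  if (!any(use_word, use_char, use_elmo))
    stop("at least one of use_word, use_char, use_elmo must be TRUE")
  structure(list(window_size = as.integer(window_size),
                 num_filters = as.integer(num_filters),
                 state_size = as.integer(state_size),
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, gradient_clip = gradient_clip,
                 decay_rate = decay_rate, labeling_schema = labeling_schema,
                 word_dim = as.integer(word_dim),
                 char_dim = as.integer(char_dim),
                 elmo_dim = as.integer(elmo_dim),
                 use_word = use_word, use_char = use_char,
                 use_elmo = use_elmo, lstm_variant = lstm_variant,
                 task = task, feedback = feedback,
                 feedback_mode = feedback_mode, feedback_y = feedback_y,
                 bio_mask = bio_mask, optimizer = optimizer,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 elmo_layers = as.integer(elmo_layers)),
            class = "drugner_config")
}

#' Read a flat key/value configuration file
#'
#' One \code{key = value} (or \code{key: value}) pair per line; \code{#}
#' starts a comment. Keys must be arguments of \code{\link{run_config}};
#' unknown keys raise an error naming the key.
#'
#' @param path file path.
#' @param ... overrides applied after the file.
#' @return a \code{drugner_config}.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  vals <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", perl = TRUE)[[1]]
    if (length(kv) != 2L) stop("config line not key = value: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(run_config)))
      stop("unknown configuration key: '", key, "'")
    num <- suppressWarnings(as.numeric(val))
    vals[[key]] <- if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(val)
      else val
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' @export
print.drugner_config <- function(x, ...) {
  cat("<run config>\n")
  for (k in names(x)) cat(sprintf("  %-15s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Initialize a multitask DNER/DNEN model
#'
#' A shared encoder (word embedding + char-CNN + optional contextual channel,
#' then a BiLSTM) feeding two task heads: a linear layer + linear-chain CRF
#' for BIO entity tagging, and a per-token softmax classifier over the
#' normalization vocabulary. The feedback matrices U (normalization label
#' space to the shared-representation space, feeding the recognition head) and
#' V (recognition labels to the normalization head) start at zero, so an
#' untrained model's feedback term is inert.
#'
#' @param alphabets from \code{\link{build_alphabets}}, frozen or not.
#' @param config a \code{\link{run_config}}.
#' @param word_vectors optional pretrained word-embedding matrix from
#'   \code{\link{load_word_vectors}} (overrides random initialization).
#' @return an object of class \code{drugner_model}.
#' @export
init_model <- function(alphabets, config = run_config(),
                       word_vectors = NULL) {
  for (a in alphabets) alphabet_freeze(a)
  ner_labels <- alphabet_entries(alphabets$label)
  norm_labels <- alphabet_entries(alphabets$norm)
  if (length(ner_labels) == 0L) stop("label alphabet has no entries")
  s <- config$state_size
  input_dim <- (if (config$use_word) config$word_dim else 0L) +
    (if (config$use_char) config$num_filters else 0L) +
    (if (config$use_elmo) 2L * config$state_size else 0L)
  with_seed(derive_seed(config$seed, "init"), {
    params <- list()
    if (config$use_word) {
      params$word.E <- if (!is.null(word_vectors)) word_vectors
        else embedding_table(alphabet_size(alphabets$word), config$word_dim)
    }
    bilm <- NULL
    if (config$use_char) {
      cc <- init_char_cnn(alphabet_size(alphabets$char), config$char_dim,
                          config$window_size, config$num_filters,
                          config$dropout_rate)
      params$char.E <- cc$E; params$char.W <- cc$W; params$char.b <- cc$b
    }
    if (config$use_elmo) {
      bilm <- init_bilm(alphabet_size(alphabets$word), config$state_size,
                        config$elmo_layers)
      params$elmo.logits <- numeric(config$elmo_layers + 1L)
    }
    params$fwd.Wx <- runif_matrix(4 * s, input_dim, sqrt(3 / input_dim))
    params$fwd.Wh <- runif_matrix(4 * s, s, sqrt(3 / s))
    params$fwd.b <- numeric(4 * s)
    params$bwd.Wx <- runif_matrix(4 * s, input_dim, sqrt(3 / input_dim))
    params$bwd.Wh <- runif_matrix(4 * s, s, sqrt(3 / s))
    params$bwd.b <- numeric(4 * s)
    head_in <- 2L * s * (if (config$feedback_mode == "concat") 2L else 1L)
    k_ner <- length(ner_labels); k_nen <- length(norm_labels)
    params$ner.W <- runif_matrix(k_ner, head_in, sqrt(3 / head_in))
    params$ner.b <- numeric(k_ner)
    params$ner.A <- init_transitions(k_ner)
    params$nen.W <- runif_matrix(k_nen, head_in, sqrt(3 / head_in))
    params$nen.b <- numeric(k_nen)
    params$U <- matrix(0, k_nen, 2L * s)
    params$V <- matrix(0, k_ner, 2L * s)
    structure(list(version = 1L, config = config, alphabets = alphabets,
                   ner_labels = ner_labels, norm_labels = norm_labels,
                   input_dim = input_dim, params = params, bilm = bilm),
              class = "drugner_model")
  })
}

#' @export
print.drugner_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<drugner model: %d NER labels, %d norm IDs, state %d, input width %d, %d parameters, task %s%s>\n",
    length(x$ner_labels), length(x$norm_labels), x$config$state_size,
    x$input_dim, np, x$config$task,
    if (x$config$feedback) " + feedback" else ""))
  invisible(x)
}

# LSTM parameter view over the flat parameter list.
lstm_view <- function(model, dir) {
  list(variant = "standard", state = model$config$state_size,
       input_dim = model$input_dim,
       Wx = model$params[[paste0(dir, ".Wx")]],
       Wh = model$params[[paste0(dir, ".Wh")]],
       b = model$params[[paste0(dir, ".b")]])
}

char_cnn_view <- function(model) {
  list(E = model$params$char.E, W = model$params$char.W,
       b = model$params$char.b, window = model$config$window_size,
       filters = model$config$num_filters, char_dim = model$config$char_dim,
       dropout_rate = model$config$dropout_rate)
}

# Encode one instance (word_ids + char_ids) through the shared encoder.
# Returns the hidden sequence H (n x 2s) plus every cache backprop needs.
encoder_forward <- function(model, inst, training = FALSE) {
  cfg <- model$config
  n <- length(inst$word_ids)
  chan_word <- chan_char <- chan_ctx <- NULL
  char_caches <- NULL; ctx_cache <- NULL
  if (cfg$use_word)
    chan_word <- model$params$word.E[inst$word_ids, , drop = FALSE]
  if (cfg$use_char) {
    ccp <- char_cnn_view(model)
    cb <- char_batch_forward(inst$char_ids, ccp, training = training)
    chan_char <- cb$out
    char_caches <- cb$cache
  }
  if (cfg$use_elmo) {
    st <- bilm_states(inst$word_ids, model$bilm)
    chan_ctx <- elmo_mix(st, model$params$elmo.logits)
    ctx_cache <- st$layers
  }
  X <- concat_token_features(word = chan_word, char = chan_char,
                             contextual = chan_ctx)
  fw <- bilstm_forward(X, lstm_view(model, "fwd"), lstm_view(model, "bwd"))
  list(H = fw$H, fw = fw, X = X, n = n,
       char_caches = char_caches, ctx_cache = ctx_cache)
}

#' Feedback-augmented head input
#'
#' Builds the input of a task head from the shared representation v and the
#' other task's output labels y mapped through matrix M: the concatenation of
#' v with (v + yM) — the head always sees the uncorrected representation
#' alongside the feedback-corrected one. With \code{y = NULL} (feedback
#' disabled) the corrected half equals v, preserving the width contract. With
#' \code{mode = "corrected"} only (v + yM) is returned.
#'
#' @param v n x d matrix (or length-d vector) of shared representations.
#' @param y n x m matrix (or length-m vector) of other-task label
#'   distributions or one-hots, or NULL.
#' @param M m x d mapping matrix.
#' @param mode "concat" or "corrected".
#' @return the head-input matrix.
#' @export
feedback_input <- function(v, y = NULL, M = NULL,
                           mode = c("concat", "corrected")) {
  mode <- match.arg(mode)
  if (is.vector(v)) v <- matrix(v, nrow = 1L)
  corrected <- v
  if (!is.null(y)) {
    if (is.vector(y)) y <- matrix(y, nrow = 1L)
    if (ncol(y) != nrow(M) || ncol(M) != ncol(v))
      stop("feedback width mismatch: y is n x ", ncol(y), ", M is ",
           nrow(M), " x ", ncol(M), ", v is n x ", ncol(v))
    corrected <- v + y %*% M
  }
  if (mode == "concat") cbind(v, corrected) else corrected
}

# Head scores for one task. task is "ner" or "nen"; Y is the gradient-stopped
# other-task output (or NULL). Returns scores (n x k) and the head input.
head_forward <- function(model, H, task, Y = NULL) {
  M <- if (task == "ner") model$params$U else model$params$V
  Vrep <- feedback_input(H, Y, M, mode = model$config$feedback_mode)
  W <- model$params[[paste0(task, ".W")]]
  b <- model$params[[paste0(task, ".b")]]
  scores <- Vrep %*% t(W) + rep(b, each = nrow(Vrep))
  list(scores = scores, Vrep = Vrep)
}

# First-pass (feedback-free) softmax distributions of the other task, used as
# gradient-stopped feedback. Returns an n x k matrix.
first_pass_dist <- function(model, H, task, onehot = FALSE) {
  hf <- head_forward(model, H, task, Y = NULL)
  D <- row_softmax(hf$scores)
  if (onehot) {
    oh <- matrix(0, nrow(D), ncol(D))
    oh[cbind(seq_len(nrow(D)), max.col(D, ties.method = "first"))] <- 1
    oh
  } else D
}

# For the recognition first pass the natural label output is the CRF decode;
# per-token softmax over emissions is used for distribution-style feedback.
prepare_instance <- function(sent, model) {
  word_ids <- alphabet_index(model$alphabets$word, sent$tokens)
  char_ids <- lapply(sent$tokens, function(w)
    alphabet_index(model$alphabets$char, strsplit(w, "", fixed = TRUE)[[1]]))
  ner_z <- alphabet_index(model$alphabets$label, sent$ner) - 2L
  norm_z <- alphabet_index(model$alphabets$norm, sent$norm) - 2L
  list(word_ids = word_ids, char_ids = char_ids,
       ner_z = ner_z, norm_z = norm_z, tokens = sent$tokens)
}

#' Prepare a corpus for training or prediction
#'
#' Encodes each sentence against the model's frozen alphabets into the index
#' lists the encoder consumes. Gold labels outside the alphabets (possible
#' only on non-training data) map to the unknown entry.
#'
#' @param corpus list of \code{\link{annotated_sentence}}.
#' @param model a \code{\link{init_model}} model.
#' @return list of instances.
#' @export
prepare_instances <- function(corpus, model) {
  lapply(corpus, prepare_instance, model = model)
}

#' Predict BIO entity tags for one sentence
#'
#' Emissions come from the recognition head applied to the (optionally
#' feedback-augmented) shared representation; the label sequence is decoded
#' with the CRF by Viterbi. With feedback active, the normalization head's
#' feedback-free predictions (one-hot) are injected first. The returned
#' sequence is BIO-repaired, so it is always legal.
#'
#' @param sent an \code{\link{annotated_sentence}} (labels ignored) or a
#'   prepared instance.
#' @param model the model.
#' @return character vector of BIO tags.
#' @export
predict_dner <- function(sent, model) {
  inst <- if (is.null(sent$word_ids)) prepare_instance(sent, model) else sent
  enc <- encoder_forward(model, inst, training = FALSE)
  Y <- if (model$config$feedback)
    first_pass_dist(model, enc$H, "nen", onehot = TRUE) else NULL
  hf <- head_forward(model, enc$H, "ner", Y)
  mask <- if (model$config$bio_mask)
    bio_transition_mask(model$ner_labels) else NULL
  dec <- viterbi_decode(hf$scores, model$params$ner.A, mask)
  labels <- model$ner_labels[dec$path]
  spans_to_bio(bio_to_spans(labels), length(labels))   # repair to legal BIO
}

#' Predict normalization IDs for one sentence
#'
#' Per-token argmax over the normalization vocabulary (ties to the lowest
#' index); with feedback active, the recognition head's feedback-free one-hot
#' predictions are injected first. Non-entity tokens are expected to receive
#' the reserved NIL label.
#'
#' @inheritParams predict_dner
#' @return character vector of normalization IDs.
#' @export
predict_dnen <- function(sent, model) {
  inst <- if (is.null(sent$word_ids)) prepare_instance(sent, model) else sent
  enc <- encoder_forward(model, inst, training = FALSE)
  Y <- if (model$config$feedback)
    first_pass_dist(model, enc$H, "ner", onehot = TRUE) else NULL
  hf <- head_forward(model, enc$H, "nen", Y)
  model$norm_labels[apply(hf$scores, 1L, which.max)]
}

# Both task outputs from a single encoder pass.
predict_instance <- function(model, inst) {
  cfg <- model$config
  enc <- encoder_forward(model, inst, training = FALSE)
  Yn <- Yr <- NULL
  if (cfg$feedback) {
    Yn <- first_pass_dist(model, enc$H, "nen", onehot = TRUE)
    Yr <- first_pass_dist(model, enc$H, "ner", onehot = TRUE)
  }
  hf <- head_forward(model, enc$H, "ner", Yn)
  mask <- if (cfg$bio_mask) bio_transition_mask(model$ner_labels) else NULL
  dec <- viterbi_decode(hf$scores, model$params$ner.A, mask)
  labels <- model$ner_labels[dec$path]
  ner <- spans_to_bio(bio_to_spans(labels), length(labels))
  norm <- if (cfg$task %in% c("multitask", "dnen")) {
    hn <- head_forward(model, enc$H, "nen", Yr)
    model$norm_labels[apply(hn$scores, 1L, which.max)]
  } else rep(NIL_LABEL, length(ner))
  list(ner = ner, norm = norm)
}

#' Predict a whole corpus
#'
#' @param corpus list of \code{\link{annotated_sentence}} or prepared
#'   instances.
#' @param model the model.
#' @return list of \code{\link{annotated_sentence}} carrying predicted labels
#'   (normalization IDs only when the model is multitask).
#' @export
predict_corpus <- function(corpus, model) {
  lapply(corpus, function(sent) {
    inst <- if (is.null(sent$word_ids)) prepare_instance(sent, model)
      else sent
    out <- predict_instance(model, inst)
    annotated_sentence(inst$tokens, out$ner, out$norm)
  })
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a versioned container holding every parameter array, the
#' alphabets and the full configuration; loading reproduces predictions
#' bit-for-bit.
#'
#' @param model the model.
#' @param path checkpoint file path.
#' @export
save_model <- function(model, path) {
  # alphabets are environments; serialize their plain contents
  ab <- lapply(model$alphabets, function(a)
    list(name = a$name, instances = a$instances, frozen = a$frozen))
  obj <- unclass(model)
  obj$alphabets <- ab
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @return \code{load_model}: the restored model.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  obj$alphabets <- lapply(obj$alphabets, function(a) {
    out <- alphabet(a$name)
    for (ins in a$instances[-(1:2)]) alphabet_index(out, ins)
    if (a$frozen) alphabet_freeze(out)
    out
  })
  structure(obj, class = "drugner_model")
}
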
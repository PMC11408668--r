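# Multi-label sentence classifier.
#
# Architecture: pooled encoder representation (optionally concatenated with
# a one-hot sentence-position encoding) -> dropout -> fully connected layer
# -> sigmoid per label. Training minimizes mean binary cross-entropy with
# AdamW (decoupled weight decay), mini-batches of `batch_size`, a fixed
# number of epochs, and no scheduler or early stopping. Two parameter
# groups are configured (encoder and head learning rates); the reference
# encoder has no trainable parameters, so only the head group updates
# under it.

#' Classifier configuration
#'
#' Collects the model and training settings. Defaults follow the training
#' recipe the package implements: batch size 4, encoder learning rate 1e-5,
#' head learning rate 1e-3, dropout 0.1 on the pooled representation,
#' 20 epochs, sigmoid decision threshold 0.5.
#'
#' @param label_set Ordered character vector of item codes the model
#'   predicts; defaults to the 34 sentence-level checklist items.
#' @param encoder_id Encoder selector; `"reference"` (default) or a custom
#'   encoder object (see [resolve_encoder()]).
#' @param context Logical; use the preceding and trailing sentence (default
#'   `TRUE`).
#' @param header_mode Section-header prefixing: `"all"`, `"innermost"`,
#'   `"outermost"` or `"none"`.
#' @param position_kind Sentence position feature: `"none"`, `"absolute"`
#'   or `"relative"`.
#' @param position_cap Clipping cap for absolute positions.
#' @param batch_size,encoder_learning_rate,head_learning_rate,dropout,epochs
#'   Training hyperparameters.
#' @param weight_decay Decoupled weight decay coefficient.
#' @param threshold Probability threshold for label assignment (labels with
#'   probability >= threshold are predicted).
#' @param encoder_dim Width of the reference encoder.
#' @param seed Integer seed making training reproducible.
#' @return A list of class `consort_config`.
#' @export
consort_config <- function(label_set = NULL,
                           encoder_id = "reference",
                           context = TRUE,
                           header_mode = c("all", "none", "innermost", "outermost"),
                           position_kind = c("none", "absolute", "relative"),
                           position_cap = 512L,
                           batch_size = 4L,
                           encoder_learning_rate = 1e-5,
                           head_learning_rate = 1e-3,
                           dropout = 0.1,
                           epochs = 20L,
                           weight_decay = 0.01,
                           threshold = 0.5,
                           encoder_dim = 1024L,
                           seed = 1L) {
  header_mode <- match.arg(header_mode)
  position_kind <- match.arg(position_kind)
  if (is.null(label_set)) label_set <- sentence_level_items()$code
  label_set <- normalize_code(label_set)
  if (!length(label_set)) stopf("label_set must be non-empty")
  if (anyDuplicated(label_set)) stopf("label_set contains duplicate codes")
  if (!(threshold > 0 && threshold < 1)) stopf("threshold must be in (0, 1)")
  if (encoder_learning_rate <= 0 || head_learning_rate <= 0) {
    stopf("learning rates must be positive")
  }
  structure(list(
    label_set = label_set, encoder_id = encoder_id, context = isTRUE(context),
    header_mode = header_mode, position_kind = position_kind,
    position_cap = as.integer(position_cap), batch_size = as.integer(batch_size),
    encoder_learning_rate = encoder_learning_rate,
    head_learning_rate = head_learning_rate, dropout = dropout,
    epochs = as.integer(epochs), weight_decay = weight_decay,
    threshold = threshold, encoder_dim = as.integer(encoder_dim),
    seed = as.integer(seed)
  ), class = "consort_config")
}

# Value given to the active position indicator column (standardization in
# the head puts position and token features on a common scale).
POSITION_SCALE <- 1

# Gain applied to standardized head inputs. Sets the evidence-per-feature
# scale the fully connected layer sees, so that informative features are
# resolvable at the configured head learning rate within the fixed epoch
# budget.
FEATURE_GAIN <- 3

position_width <- function(config) {
  switch(config$position_kind,
         none = 0L, relative = 10L, absolute = config$position_cap + 1L)
}

# Design matrix: pooled encoder features, then one-hot position block.
design_matrix <- function(corpus, config, encoder) {
  asm <- assemble_corpus_inputs(corpus, config$context, config$header_mode,
                                config$position_kind, config$position_cap)
  E <- encoder$encode(asm$segments)
  pw <- position_width(config)
  if (pw > 0L) {
    P <- matrix(0, nrow = nrow(E), ncol = pw)
    P[cbind(seq_len(nrow(E)), asm$position + 1L)] <- POSITION_SCALE
    E <- cbind(E, P)
  }
  list(X = E, corpus = asm$corpus, encoder_dim = encoder$dim)
}

label_matrix <- function(labels, label_set) {
  labs <- split_labels(labels)
  Y <- matrix(0, nrow = length(labs), ncol = length(label_set))
  for (i in seq_along(labs)) {
    Y[i, match(intersect(labs[[i]], label_set), label_set)] <- 1
  }
  Y
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit the multi-label CONSORT sentence classifier
#'
#' Trains the classification head (and, for trainable encoders, the encoder)
#' on a labelled sentence corpus. Sentences are embedded through the
#' configured encoder using header-prefixed context windows; the pooled
#' representation, concatenated with the sentence-position encoding when
#' enabled, feeds a fully connected layer with per-label sigmoid outputs.
#'
#' @param corpus A labelled `consort_corpus` data frame. Every label must
#'   be in `config$label_set`.
#' @param config A [consort_config()].
#' @param augmented Optional data frame of augmentation instances (from
#'   [eda_augment()] / [parse_augmentation_response()]); each instance is
#'   trained on as its own three-sentence window.
#' @return An object of class `consort_model` with `print`, `summary`,
#'   `coef` and `predict` methods.
#' @seealso [predict.consort_model()], [cross_validate()]
#' @export
consort_fit <- function(corpus, config = consort_config(), augmented = NULL) {
  validate_corpus(corpus)
  if (!nrow(corpus)) stopf("training corpus is empty")
  used <- unique(unlist(split_labels(corpus$labels)))
  bad <- setdiff(used, config$label_set)
  if (length(bad)) {
    stopf("training labels outside config$label_set: %s",
          paste(bad, collapse = ", "))
  }
  encoder <- resolve_encoder(config$encoder_id, config$encoder_dim)

  dm <- design_matrix(corpus, config, encoder)
  X <- dm$X
  Y <- label_matrix(dm$corpus$labels, config$label_set)

  if (!is.null(augmented) && nrow(augmented)) {
    aug <- augmented_design(augmented, config, encoder)
    X <- rbind(X, aug$X)
    Y <- rbind(Y, label_matrix(aug$labels, config$label_set))
  }

  # standardize head inputs on the training set (stored for prediction)
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[!is.finite(scale) | scale < 1e-8] <- 1
  X <- FEATURE_GAIN * sweep(sweep(X, 2, center), 2, scale, "/")

  par <- with_seed(config$seed,
                   train_head(X, Y, config, encoder_dim = encoder$dim))

  structure(list(
    W = par$W, b = par$b, center = center, scale = scale,
    config = config, label_set = config$label_set,
    encoder = encoder, n_train = nrow(X),
    loss_trace = par$loss_trace
  ), class = "consort_model")
}

# Augmentation instances become standalone three-sentence windows; their
# stored section path is prefixed onto each non-empty segment.
augmented_design <- function(augmented, config, encoder) {
  needed <- c("preceding", "target", "trailing", "label", "section_path")
  missing <- setdiff(needed, names(augmented))
  if (length(missing)) {
    stopf("augmented instances are missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  n <- nrow(augmented)
  nseg <- if (config$context) 3L else 1L
  segs <- matrix("", nrow = n, ncol = nseg)
  for (i in seq_len(n)) {
    w <- list(preceding = augmented$preceding[i],
              target = augmented$target[i],
              trailing = augmented$trailing[i],
              preceding_path = augmented$section_path[i],
              target_path = augmented$section_path[i],
              trailing_path = augmented$section_path[i])
    segs[i, ] <- assemble_input(w, context = config$context,
                                header_mode = config$header_mode)$segments
  }
  E <- encoder$encode(segs)
  pw <- position_width(config)
  if (pw > 0L) E <- cbind(E, matrix(0, nrow = n, ncol = pw))
  list(X = E, labels = augmented$label)
}

# AdamW training of the fully connected head. Per-label biases start at the
# label's training log-odds (the standard initialization for rare-class
# sigmoid heads: the base rate lives in the intercept from step one instead
# of drifting into the feature weights).
train_head <- function(X, Y, config, encoder_dim) {
  n <- nrow(X); d <- ncol(X); L <- ncol(Y)
  W <- matrix(0, nrow = d, ncol = L)
  prior <- pmin(pmax(colMeans(Y), 1e-3), 1 - 1e-3)
  b <- log(prior / (1 - prior))
  mW <- vW <- matrix(0, d, L); mb <- vb <- numeric(L)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$head_learning_rate; wd <- config$weight_decay
  t <- 0L
  keep <- 1 - config$dropout
  loss_trace <- numeric(config$epochs)
  enc_cols <- seq_len(encoder_dim)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      if (config$dropout > 0) {
        mask <- matrix(rbinom(length(idx) * encoder_dim, 1L, keep) / keep,
                       nrow = length(idx))
        Xb[, enc_cols] <- Xb[, enc_cols] * mask
      }
      Z <- Xb %*% W + matrix(b, nrow(Xb), L, byrow = TRUE)
      P <- sigmoid(Z)
      Yb <- Y[idx, , drop = FALSE]
      eps_p <- 1e-12
      epoch_loss <- epoch_loss -
        sum(Yb * log(P + eps_p) + (1 - Yb) * log(1 - P + eps_p))
      G <- (P - Yb) / (nrow(Xb) * L)
      gW <- crossprod(Xb, G)
      gb <- colSums(G)
      t <- t + 1L
      mW <- beta1 * mW + (1 - beta1) * gW
      vW <- beta2 * vW + (1 - beta2) * gW^2
      mb <- beta1 * mb + (1 - beta1) * gb
      vb <- beta2 * vb + (1 - beta2) * gb^2
      bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
      W <- W - lr * ((mW / bc1) / (sqrt(vW / bc2) + eps) + wd * W)
      b <- b - lr * (mb / bc1) / (sqrt(vb / bc2) + eps)
    }
    loss_trace[epoch] <- epoch_loss / (n * L)
  }
  list(W = W, b = b, loss_trace = loss_trace)
}

#' Predict checklist items for sentences
#'
#' @param object A fitted `consort_model`.
#' @param corpus A `consort_corpus` data frame (labels may be empty or
#'   absent from gold).
#' @param threshold Probability threshold; defaults to the model's
#'   configured threshold. Labels with probability >= threshold are
#'   predicted.
#' @param ... Unused.
#' @return A `consort_predictions` data frame: `article_id`,
#'   `sentence_index`, `predicted` (codes joined with `|`), and one
#'   probability column `p_<code>` per label.
#' @export
predict.consort_model <- function(object, corpus, threshold = NULL, ...) {
  validate_corpus(corpus)
  threshold <- threshold %||% object$config$threshold
  dm <- design_matrix(corpus, object$config, object$encoder)
  if (ncol(dm$X) != nrow(object$W)) {
    stopf(paste0("representation mismatch: model expects %d features but the ",
                 "assembled inputs have %d (check context/header/position ",
                 "settings)"), nrow(object$W), ncol(dm$X))
  }
  Xs <- FEATURE_GAIN *
    sweep(sweep(dm$X, 2, object$center), 2, object$scale, "/")
  Z <- Xs %*% object$W +
    matrix(object$b, nrow(Xs), length(object$b), byrow = TRUE)
  P <- sigmoid(Z)
  colnames(P) <- paste0("p_", object$label_set)
  predicted <- apply(P, 1L, function(p)
    paste(object$label_set[p >= threshold], collapse = "|"))
  df <- data.frame(article_id = dm$corpus$article_id,
                   sentence_index = dm$corpus$sentence_index,
                   predicted = predicted, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(P))
  new_predictions(df, object$label_set, threshold)
}

#' Threshold a probability vector into a label set
#'
#' @param probabilities Named numeric vector (names are item codes) or a
#'   numeric vector with `labels` supplied.
#' @param threshold Decision threshold in (0, 1); labels with probability
#'   >= threshold are returned. Lowering the threshold never removes labels.
#' @param labels Item codes aligned with `probabilities` (defaults to its
#'   names).
#' @return Character vector of predicted codes.
#' @export
binarize <- function(probabilities, threshold = 0.5, labels = names(probabilities)) {
  if (!(threshold > 0 && threshold < 1)) stopf("threshold must be in (0, 1)")
  if (is.null(labels) || length(labels) != length(probabilities)) {
    stopf("labels must align with probabilities")
  }
  labels[probabilities >= threshold]
}

#' @export
print.consort_model <- function(x, ...) {
  cfg <- x$config
  cat("CONSORT sentence classifier (consort_model)\n")
  cat(sprintf("  encoder     : %s (dim %d)\n",
              if (is.list(cfg$encoder_id)) cfg$encoder_id$id else cfg$encoder_id,
              x$encoder$dim))
  cat(sprintf("  labels      : %d items\n", length(x$label_set)))
  cat(sprintf("  context     : %s; headers: %s; position: %s\n",
              cfg$context, cfg$header_mode, cfg$position_kind))
  cat(sprintf("  trained on  : %d windows, %d epochs, batch %d\n",
              x$n_train, cfg$epochs, cfg$batch_size))
  cat(sprintf("  final loss  : %.4f (mean BCE)\n",
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' @export
summary.consort_model <- function(object, ...) {
  w_norm <- sqrt(colSums(object$W^2))
  out <- data.frame(code = object$label_set,
                    bias = object$b,
                    weight_norm = w_norm,
                    stringsAsFactors = FALSE)
  structure(list(model = object, per_label = out),
            class = "summary.consort_model")
}

#' @export
print.summary.consort_model <- function(x, ...) {
  print(x$model)
  cat("\nPer-label head parameters:\n")
  print(x$per_label, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.consort_model <- function(object, ...) {
  W <- object$W
  colnames(W) <- object$label_set
  rbind(`(bias)` = object$b, W)
}

#' Fit a section-specific classifier
#'
#' Restricts training to sentences of one article section (Methods, Results
#' or Discussion) and to the checklist items of that section group. There is
#' no Introduction-specific model (the Introduction carries a single relevant
#' item, 2b).
#'
#' @param corpus A labelled `consort_corpus`.
#' @param group `"Methods"`, `"Results"` or `"Discussion"`.
#' @param config A [consort_config()]; its `label_set` is replaced by the
#'   group's items.
#' @param section_map Function mapping an outermost section header to a
#'   section group name (defaults to [guess_section_group()]).
#' @return A `consort_model` whose label set is the group's items.
#' @export
fit_section_model <- function(corpus, group, config = consort_config(),
                              section_map = guess_section_group) {
  if (!is_string(group) || !(group %in% c("Methods", "Results", "Discussion"))) {
    if (identical(group, "Introduction")) {
      stopf("no Introduction-specific model is supported (single relevant item 2b)")
    }
    stopf("group must be one of Methods, Results, Discussion")
  }
  items <- items_for_section_group(group)
  outer <- vapply(split_path(corpus$section_path), function(p)
    if (length(p)) p[1] else "", character(1))
  keep <- vapply(outer, function(h) identical(section_map(h), group), logical(1))
  sub <- corpus[keep, , drop = FALSE]
  if (!nrow(sub)) stopf("no sentences map to section group %s", group)
  sub$labels <- join_labels(lapply(split_labels(sub$labels),
                                   function(l) intersect(l, items$code)))
  config$label_set <- items$code
  consort_fit(new_corpus(sub), config)
}

#' Map a section header to a checklist section group
#'
#' Heuristic used to route sentences to section-specific models: matches
#' common IMRaD header wordings (e.g., "Materials and methods" ->
#' `"Methods"`).
#'
#' @param header Outermost section header string.
#' @return A section group name, or `NA_character_` if unrecognized.
#' @export
guess_section_group <- function(header) {
  h <- tolower(trim(header))
  if (!nzchar(h)) return(NA_character_)
  if (grepl("method|material|design|procedure", h)) return("Methods")
  if (grepl("result|finding", h)) return("Results")
  if (grepl("discussion|comment|limitation", h)) return("Discussion")
  if (grepl("introduction|background", h)) return("Introduction")
  if (grepl("other information|registration|funding|acknowledg|supplement|declaration", h)) {
    return("OtherInformation")
  }
  NA_character_
}

#' Save a fitted model to a directory
#'
#' Writes `config.json` plus the head parameters as full-precision text so a
#' reloaded model produces bitwise-identical predictions.
#'
#' @param model A `consort_model`.
#' @param dir Directory to create/overwrite.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  if (is.list(cfg$encoder_id)) {
    stopf("models with custom encoder objects cannot be serialized")
  }
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- c(nrow(model$W), ncol(model$W), model$n_train,
            length(model$loss_trace))
  writeLines(c(paste(meta, collapse = " "),
               paste(model$label_set, collapse = " "),
               sprintf("%.17g", model$b),
               sprintf("%.17g", as.numeric(model$W)),
               sprintf("%.17g", model$center),
               sprintf("%.17g", model$scale),
               sprintf("%.17g", model$loss_trace)),
             file.path(dir, "parameters.txt"))
  invisible(dir)
}

#' Load a model saved by [save_model()]
#'
#' @param dir Model directory.
#' @return A `consort_model`.
#' @export
load_model <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  par_path <- file.path(dir, "parameters.txt")
  if (!file.exists(cfg_path) || !file.exists(par_path)) {
    stopf("%s is not a saved model directory", dir)
  }
  raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  config <- consort_config(
    label_set = raw$label_set, encoder_id = raw$encoder_id,
    context = raw$context, header_mode = raw$header_mode,
    position_kind = raw$position_kind, position_cap = raw$position_cap,
    batch_size = raw$batch_size,
    encoder_learning_rate = raw$encoder_learning_rate,
    head_learning_rate = raw$head_learning_rate, dropout = raw$dropout,
    epochs = raw$epochs, weight_decay = raw$weight_decay,
    threshold = raw$threshold, encoder_dim = raw$encoder_dim,
    seed = raw$seed)
  lines <- readLines(par_path)
  meta <- as.integer(strsplit(lines[1], " ")[[1]])
  d <- meta[1]; L <- meta[2]
  label_set <- strsplit(lines[2], " ")[[1]]
  at <- 2L
  take <- function(k) {
    vals <- as.numeric(lines[(at + 1L):(at + k)])
    at <<- at + k
    vals
  }
  b <- take(L)
  W <- matrix(take(d * L), nrow = d, ncol = L)
  center <- take(d)
  scale <- take(d)
  loss_trace <- take(meta[4])
  structure(list(
    W = W, b = b, center = center, scale = scale,
    config = config, label_set = label_set,
    encoder = resolve_encoder(config$encoder_id, config$encoder_dim),
    n_train = meta[3], loss_trace = loss_trace
  ), class = "consort_model")
}
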
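# Small token-level transformer classifier over SMILES tokens, written with
# explicit forward/backward passes. The backward pass doubles as the
# gradient engine for integrated-gradients attribution (gradients with
# respect to the input embedding matrix are returned alongside parameter
# gradients). Architecture: learned token embeddings + sinusoidal positions,
# n_layers single-head self-attention blocks with residual connections and a
# ReLU feed-forward, mean pooling, linear classifier head. Training:
# cross-entropy, AdamW-style decoupled weight decay, minibatches, per-epoch
# evaluation loss with best-checkpoint retention.

.TLM_MAX_LEN <- 256L

.tlm_positions <- function(max_len, d) {
  p <- matrix(0, max_len, d)
  pos <- seq_len(max_len)
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / (10000^((2 * (i - 1)) / d))
    p[, 2 * i - 1] <- sin(pos * freq)
    if (2 * i <= d) p[, 2 * i] <- cos(pos * freq)
  }
  p
}

.tlm_init_params <- function(vocab_size, d, d_ff, n_layers, n_classes = 5L) {
  sd0 <- 0.02
  layer <- function() list(
    Wq = matrix(rnorm(d * d, 0, sd0), d, d),
    Wk = matrix(rnorm(d * d, 0, sd0), d, d),
    Wv = matrix(rnorm(d * d, 0, sd0), d, d),
    Wo = matrix(rnorm(d * d, 0, sd0), d, d),
    W1 = matrix(rnorm(d * d_ff, 0, sd0), d, d_ff),
    b1 = numeric(d_ff),
    W2 = matrix(rnorm(d_ff * d, 0, sd0), d_ff, d),
    b2 = numeric(d)
  )
  list(
    E = matrix(rnorm(vocab_size * d, 0, sd0), vocab_size, d),
    layers = lapply(seq_len(n_layers), function(i) layer()),
    Wc = matrix(rnorm(d * n_classes, 0, sd0), d, n_classes),
    bc = numeric(n_classes)
  )
}

# forward pass; ids may be NULL when x_override (T x d input representation,
# embeddings + positions already summed) is supplied
.tlm_forward <- function(params, pos, ids = NULL, x_override = NULL) {
  if (is.null(x_override)) {
    X <- params$E[ids, , drop = FALSE] + pos[seq_along(ids), , drop = FALSE]
  } else {
    X <- x_override
  }
  X0 <- X
  d <- ncol(X)
  caches <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    w <- params$layers[[l]]
    Q <- X %*% w$Wq; K <- X %*% w$Wk; V <- X %*% w$Wv
    S <- (Q %*% t(K)) / sqrt(d)
    S <- S - apply(S, 1, max)
    A <- exp(S); A <- A / rowSums(A)
    C <- A %*% V
    H <- C %*% w$Wo
    X1 <- X + H
    U <- sweep(X1 %*% w$W1, 2, w$b1, `+`)
    R <- U * (U > 0)
    Fo <- sweep(R %*% w$W2, 2, w$b2, `+`)
    X2 <- X1 + Fo
    caches[[l]] <- list(X = X, Q = Q, K = K, V = V, A = A, C = C,
                        X1 = X1, U = U, R = R)
    X <- X2
  }
  m <- colMeans(X)
  logits <- drop(m %*% params$Wc) + params$bc
  list(logits = logits, m = m, Xout = X, X0 = X0, caches = caches)
}

# backward pass from a gradient on the logits; returns parameter gradients
# (same shape as params) and the gradient on the input representation X0
.tlm_backward <- function(params, fw, dlogits) {
  d <- ncol(params$E)
  Tn <- nrow(fw$X0)
  g <- list(
    E = NULL,  # filled by caller for embedding rows
    layers = vector("list", length(params$layers)),
    Wc = outer(fw$m, dlogits),
    bc = dlogits
  )
  dm <- drop(params$Wc %*% dlogits)
  dX <- matrix(rep(dm / Tn, each = Tn), Tn, d)
  for (l in rev(seq_along(params$layers))) {
    w <- params$layers[[l]]
    cc <- fw$caches[[l]]
    dX2 <- dX
    # feed-forward block: X2 = X1 + relu(X1 W1 + b1) W2 + b2
    dFo <- dX2
    dW2 <- t(cc$R) %*% dFo
    db2 <- colSums(dFo)
    dR <- dFo %*% t(w$W2)
    dU <- dR * (cc$U > 0)
    dW1 <- t(cc$X1) %*% dU
    db1 <- colSums(dU)
    dX1 <- dX2 + dU %*% t(w$W1)
    # attention block: X1 = X + (A (X Wv)) Wo
    dH <- dX1
    dWo <- t(cc$C) %*% dH
    dC <- dH %*% t(w$Wo)
    dA <- dC %*% t(cc$V)
    dV <- t(cc$A) %*% dC
    dS <- cc$A * (dA - rowSums(dA * cc$A))
    dQ <- (dS %*% cc$K) / sqrt(d)
    dK <- (t(dS) %*% cc$Q) / sqrt(d)
    dXl <- dX1 + dQ %*% t(w$Wq) + dK %*% t(w$Wk) + dV %*% t(w$Wv)
    g$layers[[l]] <- list(
      Wq = t(cc$X) %*% dQ, Wk = t(cc$X) %*% dK, Wv = t(cc$X) %*% dV,
      Wo = dWo, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2
    )
    dX <- dXl
  }
  list(grads = g, dX0 = dX)
}

.tlm_softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# tokens -> vocabulary ids; unseen tokens map to <unk> (id 1)
.tlm_ids <- function(fit_or_vocab, smiles) {
  vocab <- if (is.list(fit_or_vocab)) fit_or_vocab$vocab else fit_or_vocab
  toks <- tokenize_smiles(smiles)$token
  if (length(toks) > .TLM_MAX_LEN) {
    abort(paste0("SMILES longer than the model's context window (",
                 .TLM_MAX_LEN, " tokens)"), class = "tastekit_token_error")
  }
  ids <- match(toks, vocab)
  ids[is.na(ids)] <- 1L
  ids
}

# flat iteration over parameter tensors for the optimizer
.tlm_param_paths <- function(params) {
  paths <- list(list("E"), list("Wc"), list("bc"))
  for (l in seq_along(params$layers)) {
    for (nm in names(params$layers[[l]])) {
      paths[[length(paths) + 1L]] <- list("layers", l, nm)
    }
  }
  paths
}

.tlm_get <- function(obj, path) {
  for (p in path) obj <- obj[[p]]
  obj
}

.tlm_set <- function(obj, path, value) {
  if (length(path) == 1) obj[[path[[1]]]] <- value
  else if (length(path) == 3) obj[[path[[1]]]][[path[[2]]]][[path[[3]]]] <- value
  obj
}

.tlm_train <- function(smiles, y, config) {
  toks <- lapply(smiles, function(s) tokenize_smiles(s)$token)
  # radix sort gives locale-independent vocabulary order, so training is
  # bit-reproducible across systems
  vocab <- c("<unk>", sort(unique(unlist(toks)), method = "radix"))
  ids <- lapply(toks, function(tt) {
    v <- match(tt, vocab); v[is.na(v)] <- 1L; v
  })
  too_long <- lengths(ids) > .TLM_MAX_LEN
  if (any(too_long)) {
    abort("training SMILES exceed the model's context window",
          class = "tastekit_token_error")
  }
  yidx <- as.integer(y)
  n <- length(ids)
  pos <- .tlm_positions(.TLM_MAX_LEN, config$d_model)

  withr::with_seed(config$seed, {
    params <- .tlm_init_params(length(vocab), config$d_model, config$d_ff,
                               config$n_layers)
    n_eval <- floor(config$eval_fraction * n)
    eval_idx <- if (n_eval >= 1) sample(n, n_eval) else integer(0)
    train_idx <- setdiff(seq_len(n), eval_idx)

    paths <- .tlm_param_paths(params)
    adam_m <- lapply(paths, function(p) .tlm_get(params, p) * 0)
    adam_v <- adam_m
    step <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

    seq_loss <- function(i) {
      fw <- .tlm_forward(params, pos, ids[[i]])
      -log(max(.tlm_softmax(fw$logits)[yidx[i]], 1e-12))
    }
    eval_loss <- function() {
      idx <- if (length(eval_idx)) eval_idx else train_idx
      mean(vapply(idx, seq_loss, 0))
    }

    best <- list(loss = Inf, params = params, epoch = 0L)
    history <- tibble(epoch = integer(0), train_loss = numeric(0),
                      eval_loss = numeric(0))
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample(train_idx)
      batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
      epoch_loss <- 0
      for (batch in batches) {
        acc <- NULL
        dE_rows <- list()
        bl <- 0
        for (i in batch) {
          fw <- .tlm_forward(params, pos, ids[[i]])
          p <- .tlm_softmax(fw$logits)
          bl <- bl - log(max(p[yidx[i]], 1e-12))
          dlogits <- p
          dlogits[yidx[i]] <- dlogits[yidx[i]] - 1
          bw <- .tlm_backward(params, fw, dlogits)
          dE_rows[[length(dE_rows) + 1L]] <- list(ids = ids[[i]], g = bw$dX0)
          if (is.null(acc)) acc <- bw$grads
          else {
            for (pp in seq_along(paths)) {
              pa <- paths[[pp]]
              if (identical(pa[[1]], "E")) next
              acc <- .tlm_set(acc, pa, .tlm_get(acc, pa) + .tlm_get(bw$grads, pa))
            }
          }
        }
        epoch_loss <- epoch_loss + bl
        nb <- length(batch)
        # embedding gradient: scatter-add token-position gradients
        dE <- params$E * 0
        for (r in dE_rows) {
          for (t in seq_along(r$ids)) {
            dE[r$ids[t], ] <- dE[r$ids[t], ] + r$g[t, ]
          }
        }
        acc$E <- dE
        step <- step + 1L
        lr <- config$learning_rate
        for (pp in seq_along(paths)) {
          pa <- paths[[pp]]
          gcur <- .tlm_get(acc, pa) / nb
          m_ <- b1 * adam_m[[pp]] + (1 - b1) * gcur
          v_ <- b2 * adam_v[[pp]] + (1 - b2) * gcur^2
          adam_m[[pp]] <- m_
          adam_v[[pp]] <- v_
          mh <- m_ / (1 - b1^step)
          vh <- v_ / (1 - b2^step)
          cur <- .tlm_get(params, pa)
          upd <- cur - lr * (mh / (sqrt(vh) + eps) + config$weight_decay * cur)
          params <- .tlm_set(params, pa, upd)
        }
      }
      el <- eval_loss()
      history <- bind_rows(history, tibble(
        epoch = epoch,
        train_loss = epoch_loss / length(order_idx),
        eval_loss = el
      ))
      if (el < best$loss) best <- list(loss = el, params = params, epoch = epoch)
    }
  })
  list(
    vocab = vocab, params = best$params, pos = pos,
    d_model = config$d_model, best_eval_loss = best$loss,
    best_epoch = best$epoch, history = history
  )
}

.tlm_predict_proba <- function(fit, smiles) {
  out <- matrix(0, length(smiles), 5)
  for (i in seq_along(smiles)) {
    ids <- .tlm_ids(fit, smiles[i])
    fw <- .tlm_forward(fit$params, fit$pos, ids)
    out[i, ] <- .tlm_softmax(fw$logits)
  }
  out
}

# scoring function + input-gradient closure used by integrated gradients.
# against = "logit" differentiates the raw class logit, "probability" the
# softmax output for the class.
.tlm_scorer <- function(fit, target_idx, against = "logit") {
  list(
    value = function(x) {
      fw <- .tlm_forward(fit$params, fit$pos, x_override = x)
      if (against == "logit") fw$logits[target_idx]
      else .tlm_softmax(fw$logits)[target_idx]
    },
    grad = function(x) {
      fw <- .tlm_forward(fit$params, fit$pos, x_override = x)
      if (against == "logit") {
        dlogits <- numeric(length(fw$logits))
        dlogits[target_idx] <- 1
      } else {
        p <- .tlm_softmax(fw$logits)
        dlogits <- -p[target_idx] * p
        dlogits[target_idx] <- dlogits[target_idx] + p[target_idx]
      }
      .tlm_backward(fit$params, fw, dlogits)$dX0
    }
  )
}

# input representation (embeddings + positions) for a SMILES string
.tlm_input_rep <- function(fit, smiles) {
  ids <- .tlm_ids(fit, smiles)
  fit$params$E[ids, , drop = FALSE] + fit$pos[seq_along(ids), , drop = FALSE]
}
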
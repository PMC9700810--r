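#' Hyperparameters of the sequence generator
#'
#' Configuration for the embedding + LSTM + softmax generative model of a
#' discretized time series. The architecture follows the standard LSTM cell:
#' one-hot states are embedded into `embed_dim` dense vectors, passed through
#' `n_layers` recurrent layers of `hidden_dim` units, and a dense softmax head
#' emits the next-state distribution. Training minimizes the next-state
#' cross-entropy (the negative log path probability of the training series).
#'
#' @param n_states vocabulary size N (must match the data's binning).
#' @param embed_dim embedding dimension M.
#' @param hidden_dim LSTM units L per layer.
#' @param n_layers number of stacked recurrent layers.
#' @param learning_rate Adam step size.
#' @param batch_len training window length (contiguous subsequences; hidden
#'   state is reset at each window start).
#' @param batch_size windows per gradient step.
#' @param epochs passes over the set of windows.
#' @param lr_schedule `"constant"`, or `"step"` to decay the rate to 0.3x
#'   after 60% and 0.1x after 85% of the epochs (settles the optimizer onto
#'   the loss plateau, which stabilizes observables that are hypersensitive
#'   to small weight changes, such as stationary population ratios).
#' @param swa Polyak/stochastic weight averaging: average the weights over
#'   the final 40% of epochs and return the averaged model. Another
#'   stabilizer for plateau wobble; off by default.
#' @param seed RNG seed for initialization and window shuffling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_states, embed_dim = 8L, hidden_dim = 64L,
                         n_layers = 1L, learning_rate = 3e-3,
                         batch_len = 100L, batch_size = 32L,
                         epochs = 25L, lr_schedule = c("constant", "step"),
                         swa = FALSE, seed = 1L) {
  cfg <- list(n_states = as.integer(n_states), embed_dim = as.integer(embed_dim),
              hidden_dim = as.integer(hidden_dim), n_layers = as.integer(n_layers),
              learning_rate = learning_rate, batch_len = as.integer(batch_len),
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              lr_schedule = match.arg(lr_schedule), swa = isTRUE(swa),
              seed = as.integer(seed))
  with(cfg, {
    if (n_states < 2L || embed_dim < 1L || hidden_dim < 1L || n_layers < 1L ||
        batch_len < 1L || batch_size < 1L || epochs < 1L)
      stop("all model dimensions and sizes must be positive (n_states >= 2)")
    if (!is.finite(learning_rate) || learning_rate <= 0)
      stop("learning_rate must be positive")
  })
  structure(cfg, class = "model_config")
}

# Run `code` under a fixed seed, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Derive a reproducible child seed from a master seed (kept within 32-bit range).
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * as.numeric(k)) %% 2147483629) + 1L
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Uniform(-r, r) init with r = 1/sqrt(fan-in); forget-gate bias starts at 1.
.lstm_init <- function(cfg) {
  N <- cfg$n_states; M <- cfg$embed_dim; L <- cfg$hidden_dim
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -1, 1) / sqrt(nc), nr, nc)
  W <- vector("list", cfg$n_layers); b <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    din <- if (l == 1L) M else L
    W[[l]] <- matrix(stats::runif((din + L) * 4L * L, -1, 1) / sqrt(din + L),
                     din + L, 4L * L)
    b[[l]] <- c(rep(0, L), rep(1, L), rep(0, 2L * L))  # i, f, g, o
  }
  list(Emb = u(N, M), W = W, b = b, V = u(L, N) * sqrt(cfg$n_states) / sqrt(L),
       c_out = rep(0, N))
}

# Forward + backward over one minibatch of windows.
# S: B x (K+1) matrix of 1-based labels. Returns summed loss and gradients.
.lstm_batch_grad <- function(par, cfg, S) {
  B <- nrow(S); K <- ncol(S) - 1L
  L <- cfg$hidden_dim; M <- cfg$embed_dim; NL <- cfg$n_layers
  N <- cfg$n_states
  iL <- 1:L; fL <- L + iL; gL <- 2L * L + iL; oL <- 3L * L + iL
  h <- rep(list(matrix(0, B, L)), NL)
  cc <- rep(list(matrix(0, B, L)), NL)
  cache <- vector("list", K)
  probs <- vector("list", K)
  loss <- 0
  for (t in seq_len(K)) {
    inp <- par$Emb[S[, t], , drop = FALSE]
    ct <- vector("list", NL)
    for (l in seq_len(NL)) {
      z <- cbind(inp, h[[l]]) %*% par$W[[l]]
      z <- sweep(z, 2L, par$b[[l]], "+")
      ig <- .sigmoid(z[, iL, drop = FALSE]); fg <- .sigmoid(z[, fL, drop = FALSE])
      gg <- tanh(z[, gL, drop = FALSE]);     og <- .sigmoid(z[, oL, drop = FALSE])
      cn <- fg * cc[[l]] + ig * gg
      tc <- tanh(cn)
      hn <- og * tc
      ct[[l]] <- list(inp = inp, h_prev = h[[l]], c_prev = cc[[l]],
                      i = ig, f = fg, g = gg, o = og, tc = tc)
      h[[l]] <- hn; cc[[l]] <- cn
      inp <- hn
    }
    cache[[t]] <- ct
    z_out <- sweep(inp %*% par$V, 2L, par$c_out, "+")
    p <- .softmax_rows(z_out)
    probs[[t]] <- p
    tgt <- S[, t + 1L]
    loss <- loss - sum(log(pmax(p[cbind(seq_len(B), tgt)], 1e-300)))
  }
  # backward
  g <- list(Emb = matrix(0, N, M),
            W = lapply(par$W, function(w) array(0, dim(w))),
            b = lapply(par$b, function(bb) numeric(length(bb))),
            V = matrix(0, L, N), c_out = numeric(N))
  dh_next <- rep(list(matrix(0, B, L)), NL)
  dc_next <- rep(list(matrix(0, B, L)), NL)
  dx_rows <- vector("list", K)
  for (t in rev(seq_len(K))) {
    p <- probs[[t]]
    p[cbind(seq_len(B), S[, t + 1L])] <- p[cbind(seq_len(B), S[, t + 1L])] - 1
    top_h <- if (NL == 1L) cache[[t]][[1L]]$o * cache[[t]][[1L]]$tc else NULL
    h_top <- cache[[t]][[NL]]$o * cache[[t]][[NL]]$tc
    g$V <- g$V + crossprod(h_top, p)
    g$c_out <- g$c_out + colSums(p)
    dtop <- p %*% t(par$V)
    for (l in rev(seq_len(NL))) {
      cb <- cache[[t]][[l]]
      dh <- dtop + dh_next[[l]]
      do <- dh * cb$tc
      dc <- dh * cb$o * (1 - cb$tc^2) + dc_next[[l]]
      di <- dc * cb$g; df <- dc * cb$c_prev; dg <- dc * cb$i
      dc_next[[l]] <- dc * cb$f
      dz <- cbind(di * cb$i * (1 - cb$i), df * cb$f * (1 - cb$f),
                  dg * (1 - cb$g^2), do * cb$o * (1 - cb$o))
      g$W[[l]] <- g$W[[l]] + crossprod(cbind(cb$inp, cb$h_prev), dz)
      g$b[[l]] <- g$b[[l]] + colSums(dz)
      dxh <- dz %*% t(par$W[[l]])
      din <- ncol(cb$inp)
      dinp <- dxh[, seq_len(din), drop = FALSE]
      dh_next[[l]] <- dxh[, din + seq_len(ncol(cb$h_prev)), drop = FALSE]
      dtop <- dinp  # becomes dh for layer below (or dx for embedding)
    }
    dx_rows[[t]] <- dtop
  }
  ids <- as.vector(S[, seq_len(K)])
  dx_all <- do.call(rbind, dx_rows)
  acc <- rowsum(dx_all, group = ids)
  g$Emb[as.integer(rownames(acc)), ] <- g$Emb[as.integer(rownames(acc)), ] + acc
  list(loss = loss, grad = g, n_targets = B * K)
}

.flatten_params <- function(p) {
  c(list(p$Emb), p$W, p$b, list(p$V), list(p$c_out))
}

.unflatten_into <- function(p, flat) {
  k <- 1L
  p$Emb <- flat[[k]]; k <- k + 1L
  for (l in seq_along(p$W)) { p$W[[l]] <- flat[[k]]; k <- k + 1L }
  for (l in seq_along(p$b)) { p$b[[l]] <- flat[[k]]; k <- k + 1L }
  p$V <- flat[[k]]; k <- k + 1L
  p$c_out <- flat[[k]]
  p
}

# One Adam update; state carries first/second moments and step count.
.adam_step <- function(par, grad, state, lr, clip = 5) {
  fp <- .flatten_params(par); fg <- .flatten_params(grad)
  gn <- sqrt(sum(vapply(fg, function(x) sum(x^2), numeric(1))))
  if (is.finite(gn) && gn > clip) fg <- lapply(fg, function(x) x * (clip / gn))
  if (is.null(state)) {
    state <- list(m = lapply(fg, function(x) x * 0),
                  v = lapply(fg, function(x) x * 0), t = 0L)
  }
  state$t <- state$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (k in seq_along(fp)) {
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * fg[[k]]
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * fg[[k]]^2
    fp[[k]] <- fp[[k]] - lr * (state$m[[k]] / corr1) /
      (sqrt(state$v[[k]] / corr2) + eps)
  }
  list(par = .unflatten_into(par, fp), state = state)
}

.as_state_matrix <- function(data) {
  if (inherits(data, "discrete_trajectory")) {
    matrix(data$states, nrow = 1L)
  } else if (inherits(data, "path_ensemble")) {
    data$states
  } else stop("data must be a discrete_trajectory or path_ensemble")
}

#' Train the generative sequence model
#'
#' Minimizes the next-state cross-entropy `J = -sum_t v(t+1) . ln yhat(t)`
#' over the training series (summed over member trajectories for an ensemble,
#' each keeping its own temporal order) with Adam on contiguous overlapping
#' windows of length `batch_len`; hidden state is reset at each window start.
#' The optimum of this loss is the true conditional next-state distribution
#' of the data-generating process, which is what makes the trained network a
#' sampler of the underlying path ensemble.
#'
#' @param data a [discrete_trajectory()] or [path_ensemble()].
#' @param config a [model_config()]; `n_states` must cover all labels.
#' @return An object of class `sequence_model` with elements `config`,
#'   `parameters` and `loss_history` (mean per-step loss by epoch).
#' @export
train_lstm <- function(data, config) {
  stopifnot(inherits(config, "model_config"))
  S <- .as_state_matrix(data) + 1L
  if (any(S > config$n_states))
    stop("state label >= n_states; enlarge n_states or rebin the data")
  Tn <- ncol(S)
  if (Tn < 2L) stop("training data must contain at least one transition")
  K <- min(config$batch_len, Tn - 1L)
  stride <- max(1L, K %/% 2L)
  starts <- unique(c(seq(1L, Tn - K, by = stride), Tn - K))
  windows <- expand.grid(row = seq_len(nrow(S)), start = starts)
  dtb <- if (inherits(data, "path_ensemble") || inherits(data, "discrete_trajectory"))
    list(dt = data$dt, binning = data$binning) else list(dt = 1, binning = NULL)
  lr_schedule <- config$lr_schedule %||% "constant"
  use_swa <- isTRUE(config$swa)
  swa_from <- max(1L, ceiling(0.6 * config$epochs) + 1L)
  .with_seed(config$seed, {
    par <- .lstm_init(config)
    state <- NULL
    swa_acc <- NULL; swa_n <- 0L
    history <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      lr <- config$learning_rate * if (lr_schedule == "step") {
        if (ep > 0.85 * config$epochs) 0.1
        else if (ep > 0.6 * config$epochs) 0.3
        else 1
      } else 1
      ord <- sample.int(nrow(windows))
      ep_loss <- 0; ep_n <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        Sb <- t(vapply(bs, function(i) {
          S[windows$row[i], windows$start[i] + 0:K]
        }, integer(K + 1L)))
        res <- .lstm_batch_grad(par, config, Sb)
        if (!is.finite(res$loss))
          stop("non-finite training loss at epoch ", ep,
               "; reduce learning_rate or check the data")
        upd <- .adam_step(par, res$grad, state, lr)
        par <- upd$par; state <- upd$state
        ep_loss <- ep_loss + res$loss; ep_n <- ep_n + res$n_targets
      }
      history[ep] <- ep_loss / ep_n
      if (use_swa && ep >= swa_from) {
        flat <- .flatten_params(par)
        swa_acc <- if (is.null(swa_acc)) flat
                   else Map(`+`, swa_acc, flat)
        swa_n <- swa_n + 1L
      }
    }
    if (use_swa && swa_n > 0L)
      par <- .unflatten_into(par, lapply(swa_acc, function(x) x / swa_n))
    structure(list(config = config, parameters = par,
                   loss_history = history, dt = dtb$dt, binning = dtb$binning),
              class = "sequence_model")
  })
}

#' @export
print.sequence_model <- function(x, ...) {
  cat(sprintf(paste0("<sequence_model> N=%d states, M=%d embed, L=%d hidden, ",
                     "%d layer(s); final loss %.4f\n"),
              x$config$n_states, x$config$embed_dim, x$config$hidden_dim,
              x$config$n_layers, utils::tail(x$loss_history, 1)))
  invisible(x)
}

# Forward a batch of label matrices through the net without caching;
# returns final hidden/cell state and (optionally) all per-step probabilities.
.lstm_forward_probs <- function(par, cfg, S, h = NULL, cc = NULL) {
  B <- nrow(S); K <- ncol(S)
  L <- cfg$hidden_dim; NL <- cfg$n_layers
  iL <- 1:L; fL <- L + iL; gL <- 2L * L + iL; oL <- 3L * L + iL
  if (is.null(h)) h <- rep(list(matrix(0, B, L)), NL)
  if (is.null(cc)) cc <- rep(list(matrix(0, B, L)), NL)
  probs <- vector("list", K)
  for (t in seq_len(K)) {
    inp <- par$Emb[S[, t], , drop = FALSE]
    for (l in seq_len(NL)) {
      z <- sweep(cbind(inp, h[[l]]) %*% par$W[[l]], 2L, par$b[[l]], "+")
      cn <- .sigmoid(z[, fL, drop = FALSE]) * cc[[l]] +
        .sigmoid(z[, iL, drop = FALSE]) * tanh(z[, gL, drop = FALSE])
      hn <- .sigmoid(z[, oL, drop = FALSE]) * tanh(cn)
      h[[l]] <- hn; cc[[l]] <- cn; inp <- hn
    }
    probs[[t]] <- .softmax_rows(sweep(inp %*% par$V, 2L, par$c_out, "+"))
  }
  list(h = h, c = cc, probs = probs)
}

#' Next-state probability distribution after a given context
#'
#' @param model a trained [sequence_model].
#' @param context integer vector of 0-based state labels (the prefix).
#' @return probability vector over the `n_states` states (sums to 1).
#' @export
next_state_probs <- function(model, context) {
  stopifnot(inherits(model, "sequence_model"))
  S <- matrix(as.integer(context) + 1L, nrow = 1L)
  if (any(S < 1L | S > model$config$n_states)) stop("context label out of range")
  fw <- .lstm_forward_probs(model$parameters, model$config, S)
  as.numeric(fw$probs[[ncol(S)]])
}

#' Autoregressively generate a path ensemble from a trained model
#'
#' Each path is sampled state by state: the model's next-state distribution is
#' sampled multinomially (never argmax) and the draw fed back as input. All
#' paths share the initial label (or teacher-forced prefix) and evolve
#' independently; the result is reproducible for a fixed seed.
#'
#' When `model` is a *list* of trained models (a deep ensemble), each step
#' samples from the average of their predictive distributions. Averaging in
#' probability space cancels independent fitting noise in the learned
#' transition probabilities before it compounds into stationary-population
#' error, which matters for observables that depend exponentially on
#' transition-rate ratios (see the methods vignette).
#'
#' @param model a trained [sequence_model], or a list of them sharing one
#'   state space (mixture generation).
#' @param n_paths number of trajectories to generate (> 0).
#' @param length samples per trajectory (>= 2, including the prefix).
#' @param init a single 0-based state label or a prefix vector of labels.
#' @param seed RNG seed.
#' @return A [path_ensemble()] carrying the model's dt/binning metadata.
#' @export
generate_paths <- function(model, n_paths, length, init, seed = 1L) {
  models <- if (inherits(model, "sequence_model")) list(model) else model
  stopifnot(is.list(models), base::length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "sequence_model")))
  N <- models[[1L]]$config$n_states
  if (any(vapply(models, function(m) m$config$n_states, integer(1)) != N))
    stop("all models in a mixture must share n_states")
  n_paths <- as.integer(n_paths)
  if (is.na(n_paths) || n_paths <= 0L) stop("n_paths must be positive")
  length <- as.integer(length)
  init <- as.integer(init)
  if (length < 2L) stop("length must be >= 2")
  if (length(init) >= length) stop("init prefix must be shorter than length")
  if (any(init < 0L | init >= N)) stop("init label out of range")
  R <- base::length(models)
  Ucum <- upper.tri(matrix(0, N, N), diag = TRUE) * 1  # row-cumsum helper
  .with_seed(seed, {
    states <- matrix(0L, n_paths, length)
    states[, seq_along(init)] <- matrix(init, n_paths, length(init), byrow = TRUE)
    h <- vector("list", R); cc <- vector("list", R)
    p <- matrix(0, n_paths, N)
    for (r in seq_len(R)) {
      fw <- .lstm_forward_probs(models[[r]]$parameters, models[[r]]$config,
                                states[, seq_along(init), drop = FALSE] + 1L)
      h[[r]] <- fw$h; cc[[r]] <- fw$c
      p <- p + fw$probs[[length(init)]] / R
    }
    for (t in (length(init) + 1L):length) {
      cs <- p %*% Ucum
      u <- stats::runif(n_paths) * cs[, N]
      nxt <- rowSums(cs < u) + 1L
      states[, t] <- nxt - 1L
      if (t == length) break
      p <- matrix(0, n_paths, N)
      for (r in seq_len(R)) {
        par <- models[[r]]$parameters; cfg <- models[[r]]$config
        L <- cfg$hidden_dim; NL <- cfg$n_layers
        iL <- 1:L; fL <- L + iL; gL <- 2L * L + iL; oL <- 3L * L + iL
        inp <- par$Emb[nxt, , drop = FALSE]
        for (l in seq_len(NL)) {
          z <- sweep(cbind(inp, h[[r]][[l]]) %*% par$W[[l]], 2L, par$b[[l]], "+")
          cn <- .sigmoid(z[, fL, drop = FALSE]) * cc[[r]][[l]] +
            .sigmoid(z[, iL, drop = FALSE]) * tanh(z[, gL, drop = FALSE])
          hn <- .sigmoid(z[, oL, drop = FALSE]) * tanh(cn)
          h[[r]][[l]] <- hn; cc[[r]][[l]] <- cn; inp <- hn
        }
        p <- p + .softmax_rows(sweep(inp %*% par$V, 2L, par$c_out, "+")) / R
      }
    }
    path_ensemble(states, dt = models[[1L]]$dt, binning = models[[1L]]$binning)
  })
}

#' Log path probability of a trajectory under the model
#'
#' Returns `sum_t ln yhat(t)[v(t+1)]` conditioned on the trajectory's first
#' state, i.e. the log of the path probability the generator assigns to the
#' realized sequence. Always <= 0. If any step has predicted probability 0
#' the function returns `-Inf` with attribute `flagged = TRUE`.
#'
#' @param model a trained [sequence_model].
#' @param traj a [discrete_trajectory()] with labels `< n_states`.
#' @export
path_log_probability <- function(model, traj) {
  stopifnot(inherits(model, "sequence_model"),
            inherits(traj, "discrete_trajectory"))
  s <- traj$states + 1L
  if (any(s > model$config$n_states)) stop("trajectory label >= n_states")
  Tn <- length(s)
  fw <- .lstm_forward_probs(model$parameters, model$config,
                            matrix(s[-Tn], nrow = 1L))
  p_step <- vapply(seq_len(Tn - 1L), function(t) fw$probs[[t]][1L, s[t + 1L]],
                   numeric(1))
  if (any(p_step == 0)) {
    out <- -Inf; attr(out, "flagged") <- TRUE
    return(out)
  }
  sum(log(p_step))
}

#' Save / load a trained sequence model
#'
#' The weights and configuration are stored together in a single serialized
#' archive so that generation is reproducible across sessions.
#'
#' @param model a [sequence_model].
#' @param path file path for the archive.
#' @export
save_sequence_model <- function(model, path) {
  stopifnot(inherits(model, "sequence_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_sequence_model
#' @export
load_sequence_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sequence_model")) stop("not a sequence_model archive")
  model
}
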
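#' Training configuration
#'
#' Bundles the optimisation hyper-parameters: the initial learning rate is
#' reduced by `plateau_factor` whenever the best validation loss has not
#' improved for `plateau_patience` consecutive epochs, and training stops when
#' the difference between consecutive learning rates falls below `stop_delta`
#' (or `max_epochs` is reached). Defaults follow the published schedule
#' (1e-3, factor 0.8, patience 10 epochs, threshold 1e-8).
#'
#' @param lr_init initial learning rate.
#' @param plateau_factor multiplicative learning-rate reduction in (0, 1).
#' @param plateau_patience epochs of stagnation before a reduction.
#' @param stop_delta stop once `lr_prev - lr_new` is positive but smaller
#'   than this.
#' @param weights a [loss_weights()]; `beta` is forced to zero for the
#'   feed-forward variant.
#' @param max_epochs hard epoch cap.
#' @param seed master seed for shuffling, pair sampling and initialisation.
#' @param validation_fraction fraction of sequences held out for the
#'   plateau criterion.
#' @param variant `"usenet"` or `"reusenet"`.
#' @param window optional temporal window: long sequences are chopped into
#'   consecutive windows of this many frames for the recurrent variant.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param pairs_per_sequence frame pairs drawn per sequence per epoch for the
#'   feed-forward variant (default: frames - 1).
#' @param clip_norm global gradient-norm ceiling applied before each update
#'   (the L1 strain-gradient penalty has a non-vanishing subgradient, so
#'   unclipped steps can overshoot badly; clipping is the standard remedy).
#' @param warmup_steps optimiser steps over which the learning rate ramps
#'   linearly from zero; the zero-initialised displacement heads have very
#'   small but spatially coherent first gradients, and adaptive optimisers
#'   would otherwise take full-size first steps with enormous leverage on the
#'   multi-scale field.
#' @export
train_config <- function(lr_init = 1e-3, plateau_factor = 0.8,
                         plateau_patience = 10L, stop_delta = 1e-8,
                         weights = loss_weights(), max_epochs = 100L,
                         seed = 1L, validation_fraction = 0.2,
                         variant = c("reusenet", "usenet"),
                         window = NULL, optimizer = c("adam", "sgd"),
                         pairs_per_sequence = NULL, clip_norm = 5,
                         warmup_steps = 60L) {
  variant <- match.arg(variant)
  optimizer <- match.arg(optimizer)
  stopifnot(plateau_factor > 0, plateau_factor < 1, stop_delta > 0,
            lr_init > 0, plateau_patience >= 1)
  if (variant == "usenet" && weights$beta != 0)
    weights$beta <- 0            # no previous strain exists for single pairs
  structure(list(lr_init = lr_init, plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 stop_delta = stop_delta, weights = weights,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 validation_fraction = validation_fraction, variant = variant,
                 window = window, optimizer = optimizer,
                 pairs_per_sequence = pairs_per_sequence,
                 clip_norm = clip_norm, warmup_steps = as.integer(warmup_steps)),
            class = "train_config")
}

#' Assemble training items from RF sequences
#'
#' The feed-forward variant trains on frame pairs whose interframe interval is
#' drawn uniformly from 1 to `length - 1` (random start frame); the recurrent
#' variant consumes whole sequences, or consecutive non-overlapping windows of
#' `window` frames when a sequence is longer (the protocol used for long
#' free-hand acquisitions).
#'
#' @param sequences list of sequences (each an `rf_sequence`, list of frames,
#'   or 3D array).
#' @param variant `"usenet"` or `"reusenet"`.
#' @param seed integer; the draw is deterministic given the seed.
#' @param pairs_per_sequence pairs drawn per sequence (`usenet`; default
#'   frames - 1).
#' @param window optional window length (`reusenet`).
#' @return list of items, each `list(frames = <list of 2+ frames>)`.
#' @export
make_training_batches <- function(sequences, variant = c("usenet", "reusenet"),
                                  seed = 1L, pairs_per_sequence = NULL,
                                  window = NULL) {
  variant <- match.arg(variant)
  if (length(sequences) == 0) stop("make_training_batches: no sequences")
  frames_of <- lapply(sequences, sequence_frames)
  with_seed(seed, {
    items <- list()
    for (fr in frames_of) {
      n <- length(fr)
      if (n < 2) stop("make_training_batches: sequence shorter than 2 frames")
      if (variant == "usenet") {
        np <- if (is.null(pairs_per_sequence)) n - 1L else pairs_per_sequence
        for (q in seq_len(np)) {
          gap <- sample.int(n - 1L, 1L)
          i <- sample.int(n - gap, 1L)
          items[[length(items) + 1L]] <- list(frames = fr[c(i, i + gap)],
                                              interval = gap)
        }
      } else {
        if (!is.null(window) && n > window) {
          starts <- seq(1L, n - window + 1L, by = window)
          starts <- starts[starts + window - 1L <= n]
          for (s in starts)
            items[[length(items) + 1L]] <- list(frames = fr[s:(s + window - 1L)])
        } else {
          items[[length(items) + 1L]] <- list(frames = fr)
        }
      }
    }
    if (variant == "usenet") items <- items[sample.int(length(items))]
    items
  })
}

#' Plateau learning-rate schedule
#'
#' Replays the validation-loss history: whenever the best-so-far validation
#' loss has not improved (absolute comparison) for `plateau_patience`
#' consecutive epochs, the learning rate is multiplied by `plateau_factor` and
#' the stagnation counter resets. Returns the learning rate in force after the
#' last recorded epoch.
#'
#' @param history a data frame with a `val_loss` column (one row per epoch),
#'   or a numeric vector of validation losses.
#' @param current_lr learning rate before this epoch's decision.
#' @param config a [train_config()].
#' @export
lr_schedule_step <- function(history, current_lr, config = train_config()) {
  val <- if (is.data.frame(history)) history$val_loss else as.numeric(history)
  if (length(val) < 1) stop("lr_schedule_step: empty history")
  best <- Inf; stag <- 0L; k <- 0L
  for (v in val) {
    if (v < best) { best <- v; stag <- 0L } else stag <- stag + 1L
    if (stag >= config$plateau_patience) { k <- k + 1L; stag <- 0L }
  }
  config$lr_init * config$plateau_factor^k
}

#' Stopping rule on the learning-rate sequence
#'
#' Training stops when a reduction has just occurred and the difference
#' between the previous and new learning rate is smaller than `stop_delta`.
#' From 1e-3 with factor 0.8 and threshold 1e-8 this permits at most 45
#' reductions.
#'
#' @param lr_prev,lr_new learning rates before and after the schedule step.
#' @param config a [train_config()].
#' @export
should_stop <- function(lr_prev, lr_new, config = train_config()) {
  d <- lr_prev - lr_new
  d > 0 && d < config$stop_delta
}

# ---------------------------------------------------------------------------
# loss + gradient for one training item

# dU accumulation helper: similarity + alpha * smoothness (+ beta * consistency)
pair_loss_and_dU <- function(U, pre_n, post_n, weights, prev_strain = NULL) {
  d <- displacement_field(U[, , 1], U[, , 2])
  sg <- similarity_loss_grad(pre_n, post_n, d, weights)
  rg <- smoothness_loss_grad(d$axial)
  dU <- array(0, dim(U))
  dU[, , 1] <- sg$g_axial + weights$alpha * rg$grad
  dU[, , 2] <- sg$g_lateral
  cons <- NULL
  strain <- if (weights$beta > 0) lsq_strain(d$axial, weights$strain_window)
            else NULL
  if (!is.null(prev_strain) && weights$beta > 0) {
    # constant strain maps (e.g. the identity-transform start) have no valid
    # NCC window; the term is undefined there and is skipped for that pair
    cg <- tryCatch(consistency_loss_grad(prev_strain, strain, d, weights),
                   error = function(e) NULL)
    if (!is.null(cg)) {
      cons <- cg$value
      dU[, , 1] <- dU[, , 1] + weights$beta *
        (cg$g_axial + lsq_strain_adj(cg$g_strain, weights$strain_window))
      dU[, , 2] <- dU[, , 2] + weights$beta * cg$g_lateral
    }
  }
  wts_here <- weights
  if (is.null(cons)) wts_here$beta <- 0
  list(breakdown = total_loss(sg$value, rg$value, cons, wts_here),
       dU = dU, strain = strain)
}

item_grad_usenet <- function(P, cfg, item, weights) {
  pre_n <- normalize_frame(item$frames[[1]])
  post_n <- normalize_frame(item$frames[[2]])
  x0 <- array(c(pre_n, post_n), c(dim(pre_n), 2L))
  fw <- usenet_fwd(P, cfg, x0)
  pl <- pair_loss_and_dU(fw$U, pre_n, post_n, weights)
  G <- new.env(parent = emptyenv())
  usenet_bwd(P, cfg, fw, pl$dU, G)
  list(loss = pl$breakdown, G = G)
}

item_grad_reusenet <- function(P, cfg, item, weights) {
  fr <- lapply(item$frames, normalize_frame)
  n <- length(fr)
  fws <- vector("list", n - 1L)
  dUs <- vector("list", n - 1L)
  state <- vector("list", 5L)
  prev_strain <- NULL
  sims <- regs <- cons <- totals <- numeric(0)
  for (t in seq_len(n - 1L)) {
    x0 <- array(c(fr[[t]], fr[[t + 1L]]), c(dim(fr[[t]]), 2L))
    fws[[t]] <- reusenet_step_fwd(P, cfg, x0, state)
    state <- fws[[t]]$state
    pl <- pair_loss_and_dU(fws[[t]]$U, fr[[t]], fr[[t + 1L]], weights,
                           prev_strain)
    dUs[[t]] <- pl$dU
    prev_strain <- pl$strain      # detached target for the next step
    sims <- c(sims, pl$breakdown$sim); regs <- c(regs, pl$breakdown$reg)
    cons <- c(cons, pl$breakdown$cons); totals <- c(totals, pl$breakdown$total)
  }
  G <- new.env(parent = emptyenv())
  dh <- vector("list", 5L); dc <- vector("list", 5L)
  for (t in (n - 1L):1L) {
    # average the per-pair losses: scale each pair's dU by 1/(n-1)
    r <- reusenet_step_bwd(P, cfg, fws[[t]], dUs[[t]] / (n - 1L), dh, dc, G)
    dh <- r$dh_prev; dc <- r$dc_prev
  }
  list(loss = structure(list(sim = mean(sims), reg = mean(regs),
                             cons = mean(cons), total = mean(totals)),
                        class = "loss_breakdown"),
       G = G)
}

item_loss_only <- function(P, cfg, variant, item, weights) {
  fr <- lapply(item$frames, normalize_frame)
  totals <- numeric(0)
  if (variant == "usenet") {
    x0 <- array(c(fr[[1]], fr[[2]]), c(dim(fr[[1]]), 2L))
    U <- usenet_fwd(P, cfg, x0)$U
    d <- displacement_field(U[, , 1], U[, , 2])
    return(similarity_loss(fr[[1]], fr[[2]], d, weights) +
             weights$alpha * smoothness_loss(d, weights))
  }
  state <- vector("list", 5L)
  prev_strain <- NULL
  for (t in seq_len(length(fr) - 1L)) {
    x0 <- array(c(fr[[t]], fr[[t + 1L]]), c(dim(fr[[t]]), 2L))
    fw <- reusenet_step_fwd(P, cfg, x0, state)
    state <- fw$state
    d <- displacement_field(fw$U[, , 1], fw$U[, , 2])
    tot <- similarity_loss(fr[[t]], fr[[t + 1L]], d, weights) +
      weights$alpha * smoothness_loss(d, weights)
    strain <- lsq_strain(d$axial, weights$strain_window)
    if (!is.null(prev_strain) && weights$beta > 0)
      tot <- tot + weights$beta * tryCatch(
        consistency_loss(prev_strain, strain, d, weights),
        error = function(e) 0)
    prev_strain <- strain
    totals <- c(totals, tot)
  }
  mean(totals)
}

# ---------------------------------------------------------------------------
# optimiser

adam_init <- function(P) {
  list(m = lapply(P, function(x) array(0, dim(x) %||% length(x))),
       v = lapply(P, function(x) array(0, dim(x) %||% length(x))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(P, G, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in names(P)) {
    g <- G[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    P[[nm]] <- P[[nm]] - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(P = P, st = st)
}

# rescale the whole gradient so its global L2 norm is at most max_norm
clip_grads <- function(G, max_norm) {
  if (!is.finite(max_norm) || max_norm <= 0) return(G)
  tot <- 0
  for (nm in ls(G)) tot <- tot + sum(G[[nm]]^2)
  nrm <- sqrt(tot)
  if (nrm > max_norm) {
    sc <- max_norm / nrm
    for (nm in ls(G)) G[[nm]] <- G[[nm]] * sc
  }
  G
}

sgd_step <- function(P, G, lr) {
  for (nm in names(P)) {
    g <- G[[nm]]
    if (is.null(g)) next
    P[[nm]] <- P[[nm]] - lr * g
  }
  P
}

#' Train a displacement-estimation model without labels
#'
#' Minimises the unsupervised objective over the training sequences. Each
#' epoch iterates the training items (frame pairs for `usenet`, whole
#' sequences with backpropagation through time for `reusenet`) with one
#' optimiser update per item; validation items (a held-out fraction of the
#' sequences) drive the plateau learning-rate schedule and the stopping rule.
#' The consistency weight `beta` is active only from the second pair of a
#' recurrent sequence onward.
#'
#' @param model an `elastnet_model`.
#' @param sequences list of training sequences.
#' @param config a [train_config()] (its `variant` must match the model).
#' @param verbose print one line per epoch.
#' @return list with the trained `model` and `history` (one row per epoch:
#'   loss breakdown, validation loss, learning rate, wall time).
#' @export
train <- function(model, sequences, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "elastnet_model"))
  if (config$variant != model$config$variant)
    stop("train: config/model variant mismatch")
  P <- model$params; cfg <- model$config
  weights <- config$weights
  nseq <- length(sequences)
  with_seed(config$seed, {
    ord <- sample.int(nseq)
  })
  nval <- if (nseq >= 2) max(0L, round(config$validation_fraction * nseq)) else 0L
  val_idx <- if (nval > 0) ord[seq_len(nval)] else integer(0)
  tr_idx <- setdiff(ord, val_idx)
  if (length(tr_idx) == 0) stop("train: no training sequences left after split")
  val_items <- if (nval > 0)
    make_training_batches(sequences[val_idx], config$variant,
                          seed = config$seed + 10000L,
                          window = config$window) else list()
  st <- adam_init(P)
  hist <- list()
  gstep <- 0L
  lr <- config$lr_init
  for (epoch in seq_len(config$max_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    items <- make_training_batches(sequences[tr_idx], config$variant,
                                   seed = config$seed + epoch,
                                   pairs_per_sequence = config$pairs_per_sequence,
                                   window = config$window)
    sims <- regs <- conss <- tots <- numeric(0)
    for (it in items) {
      r <- if (config$variant == "usenet")
        item_grad_usenet(P, cfg, it, weights)
      else item_grad_reusenet(P, cfg, it, weights)
      if (!is.finite(r$loss$total))
        stop(sprintf(paste0("train: non-finite loss at epoch %d ",
                            "(sim %.4g, reg %.4g, cons %.4g)"),
                     epoch, r$loss$sim, r$loss$reg, r$loss$cons))
      r$G <- clip_grads(r$G, config$clip_norm)
      gstep <- gstep + 1L
      lr_eff <- if (gstep <= config$warmup_steps)
        lr * gstep / config$warmup_steps else lr
      if (config$optimizer == "adam") {
        up <- adam_step(P, r$G, st, lr_eff)
        P <- up$P; st <- up$st
      } else {
        P <- sgd_step(P, r$G, lr_eff)
      }
      sims <- c(sims, r$loss$sim); regs <- c(regs, r$loss$reg)
      conss <- c(conss, r$loss$cons); tots <- c(tots, r$loss$total)
    }
    val <- if (length(val_items))
      mean(vapply(val_items, function(it)
        item_loss_only(P, cfg, config$variant, it, weights), numeric(1)))
    else mean(tots)
    hist[[epoch]] <- data.frame(
      epoch = epoch, loss_sim = mean(sims), loss_reg = mean(regs),
      loss_cons = mean(conss, na.rm = TRUE), loss_total = mean(tots),
      val_loss = val, lr = lr,
      seconds = proc.time()[["elapsed"]] - t0)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val %.4f  lr %.2e",
                      epoch, mean(tots), val, lr))
    hdf <- do.call(rbind, hist)
    lr_new <- lr_schedule_step(hdf, lr, config)
    if (should_stop(lr, lr_new, config)) { lr <- lr_new; break }
    lr <- lr_new
  }
  model$params <- P
  list(model = model, history = do.call(rbind, hist))
}

#' Predict displacements (and strains) for a sequence
#'
#' Runs the model over consecutive frame pairs: `N` frames give `N - 1`
#' displacement fields, each mapping the earlier frame's grid into the later
#' frame. Strain maps are derived with [lsq_strain()].
#'
#' @param model a trained `elastnet_model`.
#' @param frames a sequence (list of matrices, `rf_sequence`, or 3D array).
#' @param strain_window LSQSE window (samples).
#' @return list with `displacements` and `strains` (lists of length `N - 1`).
#' @export
infer_sequence <- function(model, frames, strain_window = 43L) {
  fr <- sequence_frames(frames)
  if (model$config$variant == "reusenet") {
    disp <- reusenet_forward(model, fr)$displacements
  } else {
    disp <- lapply(seq_len(length(fr) - 1L), function(t)
      usenet_forward(model, fr[[t]], fr[[t + 1L]]))
  }
  strains <- lapply(disp, function(d) lsq_strain(d$axial, strain_window))
  list(displacements = disp, strains = strains)
}

config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1))
}

#' Save / load a model checkpoint
#'
#' A checkpoint holds the network configuration, the named weight tensors,
#' the input-normalisation convention and optionally the training history and
#' configuration. Loading validates the stored configuration hash.
#'
#' @param model an `elastnet_model`.
#' @param path file path.
#' @param history,train_config optional training metadata to embed.
#' @export
save_checkpoint <- function(model, path, history = NULL, train_config = NULL) {
  obj <- list(config = model$config, params = model$params,
              config_hash = config_hash(model$config),
              normalization = "per-frame z-score",
              history = history, train_config = train_config,
              package_version = as.character(utils::packageVersion("elastnet")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("load_checkpoint: no such file: ", path)
  obj <- readRDS(path)
  if (!identical(config_hash(obj$config), obj$config_hash))
    stop("load_checkpoint: configuration hash mismatch (corrupt checkpoint?)")
  model <- structure(list(config = obj$config, params = obj$params),
                     class = "elastnet_model")
  attr(model, "history") <- obj$history
  attr(model, "train_config") <- obj$train_config
  model
}
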
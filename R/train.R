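#' @title Training loop
#' @description
#' Prepares training examples from synthetic spectrum sets, assembles the
#' three-part loss and its hand-derived gradients, and optimizes the network
#' with ADAM under the warm-up/decay learning-rate schedule.
#' @name training
NULL

#' Prepare a spectrum set for training
#'
#' Packs the two input planes into the network layout and computes the
#' frequency-domain target via the model's fixed transform. The whole set is
#' scaled so the frequency-domain maximum absolute value of the no-coupling
#' input plane is 1 (inference applies the same convention). The target used
#' by the losses is additionally convolved with the loss-domain sine-bell
#' operator.
#'
#' @param set A [generate_training_set()] result.
#' @param model The model whose transforms and grid sizes to use.
#' @return List with `x` (internal `(H, C, 2)` input), `target_freq`
#'   (unconvolved), `target_loss` (convolved) and `scale`.
#' @export
prepare_training_example <- function(set, model) {
  stopifnot(inherits(set, "spectrum_set"), inherits(model, "enhancer_model"))
  cfg <- model$config
  acq <- set$params$acq
  if (acq$zf_c != cfg$zf_c || acq$zf_h != cfg$zf_h)
    stop("set zero-fill targets do not match the model configuration")
  x <- array(0, dim = c(2L * cfg$zf_h, 2L * cfg$zf_c, 2L))
  x[, , 1] <- pack_plane(set$input_nocoup, cfg$zf_h, cfg$zf_c)
  x[, , 2] <- pack_plane(set$input_coup, cfg$zf_h, cfg$zf_c)
  tpk <- pack_plane(set$target, cfg$zf_h, cfg$zf_c)
  tf <- model$Mh %*% tpk %*% t(model$Mc)
  f0 <- model$Mh %*% x[, , 1] %*% t(model$Mc)
  scale <- 1 / max(abs(f0))
  if (!is.finite(scale)) scale <- 1
  list(x = x * scale,
       target_freq = tf * scale,
       target_loss = apply_sep(tf * scale, model$Ah, model$Ac),
       scale = scale)
}

# gradient of loss2 w.r.t. chi (elementwise); moments Am precomputed
loss2_chi_grad <- function(chi, Am) {
  N <- length(chi)
  g <- numeric(N)
  zc <- as.complex(as.numeric(chi))
  small <- Mod(zc) < 1e-6
  for (k in seq_along(moment_orders())) {
    m <- moment_orders()[k]
    d <- Am[k] - gaussian_moment_reference(m)
    pw <- zc^(m - 1)
    pw[small & m < 1] <- 0  # guard the singular fractional derivative at 0
    g <- g + 2 * Re(Conj(d) * m * pw) / N
  }
  # note d/dchi |mean(chi^m) - M|^2 = 2 Re[(mean(chi^m) - M)* m chi^(m-1)]/N
  dim(g) <- dim(chi)
  g
}

# losses and gradients w.r.t. the network output (intensity, confidence),
# all in the convolved loss domain. Returns losses plus gradient array gout.
loss_and_grad <- function(model, out, target_loss, n_bins = 200,
                          phase1 = FALSE, scaling_override = NULL) {
  Ah <- model$Ah; Ac <- model$Ac
  I <- out[, , 1]; conf <- out[, , 2]
  Ic <- apply_sep(I, Ah, Ac)
  sig <- sigma_from_confidence(conf)
  sigc <- apply_sep(sig, Ah, Ac)
  floor_mask <- sigc > 1e-8
  sigc <- pmax(sigc, 1e-8)
  r <- target_loss - Ic
  N <- length(r)

  l1 <- mean(r^2)
  if (phase1) {
    l2 <- 0; l3 <- 0; S <- 0
    gIc <- -2 * r / N * 2          # d[(2 - S) l1]/dIc with S = 0
    gsigc <- array(0, dim(sigc))
  } else {
    chi <- r / sigc
    Am <- vapply(moment_orders(), function(m) empirical_moment(chi, m),
                 complex(1))
    l2 <- sum(Mod(Am - vapply(moment_orders(), gaussian_moment_reference,
                              complex(1)))^2)
    # loss3 on the linear sigma bins
    b <- sigma_bins(sigc, n_bins)
    Nb <- tabulate(b, n_bins)
    occ <- Nb > 0
    sums <- rowsum(as.numeric(sigc), b)
    sums2 <- rowsum(as.numeric(r^2), b)
    ubins <- as.integer(rownames(sums))
    means <- numeric(n_bins); means[ubins] <- sums[, 1] / Nb[ubins]
    rmsd <- numeric(n_bins); rmsd[ubins] <- sqrt(sums2[, 1] / Nb[ubins])
    eb <- means - rmsd
    l3 <- sum(eb[occ]^2)

    S <- if (is.null(scaling_override)) loss_scaling(l1) else scaling_override

    gchi <- loss2_chi_grad(chi, Am)
    # per-element bin quantities
    ebi <- eb[b]; Nbi <- Nb[b]; rmsdi <- rmsd[b]
    g3_sig <- 2 * ebi / Nbi
    g3_I <- ifelse(rmsdi > 0, 2 * ebi * as.numeric(r) / (Nbi * rmsdi), 0)
    dim(g3_sig) <- dim(sigc); dim(g3_I) <- dim(sigc)

    gIc <- (2 - S) * (-2 * r / N) +
      S * (gchi * (-1 / sigc) + g3_I)
    gsigc <- S * (gchi * (-r / sigc^2) + g3_sig)
  }
  tl <- if (phase1) list(total = 2 * l1, scaling = 0) else
    list(total = (2 - S) * l1 + S * (l2 + l3), scaling = S)

  gI <- apply_sep(gIc, t(Ah), t(Ac))
  gsig <- apply_sep(gsigc * floor_mask, t(Ah), t(Ac))
  gconf <- gsig * sigma_from_confidence_grad(conf)
  gout <- array(0, dim(out))
  gout[, , 1] <- gI
  gout[, , 2] <- gconf
  list(l1 = l1, l2 = l2, l3 = l3, total = tl$total, scaling = tl$scaling,
       gout = gout)
}

# ---- ADAM -------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$type != "conv") return(list())
    list(mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
         mb = rep(0, length(l$b)), vb = rep(0, length(l$b)))
  })
}

adam_update <- function(layers, grads, state, t, lr, b1, b2, eps) {
  for (li in seq_along(layers)) {
    if (layers[[li]]$type != "conv") next
    g <- grads[[li]]; s <- state[[li]]
    s$mW <- b1 * s$mW + (1 - b1) * g$gW
    s$vW <- b2 * s$vW + (1 - b2) * g$gW^2
    s$mb <- b1 * s$mb + (1 - b1) * g$gb
    s$vb <- b2 * s$vb + (1 - b2) * g$gb^2
    mhW <- s$mW / (1 - b1^t); vhW <- s$vW / (1 - b2^t)
    mhb <- s$mb / (1 - b1^t); vhb <- s$vb / (1 - b2^t)
    layers[[li]]$W <- layers[[li]]$W - lr * mhW / (sqrt(vhW) + eps)
    layers[[li]]$b <- layers[[li]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[li]] <- s
  }
  list(layers = layers, state = state)
}

#' Train the enhancement model
#'
#' Mini-batch ADAM training against prepared examples. During the initial
#' phase only the intensity mean-squared error drives the weights; once it
#' falls below 0.03 the calibration terms are mixed in through the
#' [loss_scaling()] schedule (this happens automatically through
#' [total_loss()]; `phase = "loss1"` forces the pure phase-1 objective).
#'
#' @param model A [build_model()] model.
#' @param data Either a list of examples from [prepare_training_example()]
#'   or a function `function(step)` returning a list (mini-batch) of such
#'   examples.
#' @param steps Number of optimization steps (mini-batches).
#' @param lr_fn Learning-rate schedule, a function of the integer step;
#'   defaults to [learning_rate()]. Scaled-down demonstration runs may pass
#'   a constant.
#' @param phase `"auto"` (default: full objective with the mixing schedule)
#'   or `"loss1"` (reconstruction error only).
#' @param checkpoint_dir Optional directory; the model is saved there every
#'   `config$checkpoint_interval` steps and at the end.
#' @param log_path Optional JSON-lines file receiving one record per step
#'   (step, lr, losses, scaling).
#' @param step_offset Continue counting from a previous run (affects the
#'   schedule and ADAM bias correction).
#' @param smooth_scaling Exponential smoothing factor in `[0, 1)` for the
#'   loss1 estimate that drives the [loss_scaling()] schedule (the schedule
#'   is a stop-gradient, so this only stabilizes the mixing weight against
#'   mini-batch fluctuations; 0 uses the instantaneous per-example loss1).
#' @param verbose Print a progress line every `verbose` steps (0 = quiet).
#' @return The trained model, with the training log attached as attribute
#'   `log` (a data.frame).
#' @export
train_model <- function(model, data, steps,
                        lr_fn = learning_rate,
                        phase = c("auto", "loss1"),
                        checkpoint_dir = NULL, log_path = NULL,
                        step_offset = 0L, smooth_scaling = 0.95, verbose = 0) {
  stopifnot(inherits(model, "enhancer_model"), steps >= 1)
  phase <- match.arg(phase)
  cfg <- model$config
  state <- adam_init(model$layers)
  if (is.function(data)) {
    get_batch <- data
  } else {
    stopifnot(length(data) >= 1)
    get_batch <- function(step) {
      idx <- ((step - 1L) * cfg$batch_size + seq_len(cfg$batch_size) - 1L) %%
        length(data) + 1L
      data[idx]
    }
  }
  log <- vector("list", steps)
  con <- if (!is.null(log_path)) file(log_path, open = "a") else NULL
  on.exit(if (!is.null(con)) close(con), add = TRUE)

  l1_ema <- NULL  # smoothed reconstruction loss driving the mixing schedule
  for (s in seq_len(steps)) {
    step <- s + step_offset
    batch <- get_batch(step)
    acc <- NULL
    tots <- c(l1 = 0, l2 = 0, l3 = 0, total = 0, scaling = 0)
    s_over <- if (smooth_scaling > 0 && !is.null(l1_ema))
      loss_scaling(l1_ema) else NULL
    for (ex in batch) {
      fw <- forward_net(model, ex$x, keep_cache = TRUE)
      lg <- loss_and_grad(model, fw$out, ex$target_loss,
                          phase1 = (phase == "loss1"),
                          scaling_override = s_over)
      if (!all(is.finite(lg$gout)) || !is.finite(lg$total))
        stop(sprintf("training diverged at step %d (non-finite loss/gradient)", step))
      g <- backward_net(model, fw$caches, lg$gout / length(batch))
      if (is.null(acc)) {
        acc <- g
      } else {
        for (li in seq_along(acc)) {
          if (model$layers[[li]]$type != "conv") next
          acc[[li]]$gW <- acc[[li]]$gW + g[[li]]$gW
          acc[[li]]$gb <- acc[[li]]$gb + g[[li]]$gb
        }
      }
      tots <- tots + c(lg$l1, lg$l2, lg$l3, lg$total, lg$scaling) / length(batch)
    }
    l1_ema <- if (is.null(l1_ema)) tots[["l1"]] else
      smooth_scaling * l1_ema + (1 - smooth_scaling) * tots[["l1"]]
    lr <- lr_fn(step)
    up <- adam_update(model$layers, acc, state, step, lr,
                      cfg$beta1, cfg$beta2, cfg$eps)
    model$layers <- up$layers
    state <- up$state
    rec <- c(list(step = step, lr = lr), as.list(tots))
    log[[s]] <- rec
    if (!is.null(con))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    if (verbose > 0 && s %% verbose == 0)
      message(sprintf("step %d: lr %.3g loss1 %.4g loss2 %.4g loss3 %.4g total %.4g",
                      step, lr, tots["l1"], tots["l2"], tots["l3"], tots["total"]))
    if (!is.null(checkpoint_dir) && step %% cfg$checkpoint_interval == 0) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(model, file.path(checkpoint_dir, sprintf("model_step%06d.rds", step)))
    }
  }
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(model, file.path(checkpoint_dir, "model_final.rds"))
  }
  attr(model, "log") <- do.call(rbind, lapply(log, as.data.frame))
  model
}

#' Evaluate the reconstruction loss on held-out examples
#'
#' Mean of [loss1()] (in the convolved loss domain) over a list of prepared
#' examples; no weights are updated.
#'
#' @param model An `enhancer_model`.
#' @param examples List from [prepare_training_example()].
#' @return Mean loss1.
#' @export
evaluate_loss1 <- function(model, examples) {
  mean(vapply(examples, function(ex) {
    fw <- forward_net(model, ex$x, keep_cache = FALSE)
    Ic <- apply_sep(fw$out[, , 1], model$Ah, model$Ac)
    mean((ex$target_loss - Ic)^2)
  }, numeric(1)))
}

#' Calibration diagnostics of a model on held-out sets
#'
#' Runs the model on each prepared example and pools the standardized
#' residuals (in the convolved loss domain) into a [calibration_report()].
#'
#' @param model An `enhancer_model`.
#' @param examples List from [prepare_training_example()].
#' @param n_bins Sigma bins for the report table.
#' @return A [calibration_report()].
#' @export
evaluate_calibration <- function(model, examples, n_bins = 200) {
  targets <- list(); preds <- list(); sigmas <- list()
  for (k in seq_along(examples)) {
    ex <- examples[[k]]
    fw <- forward_net(model, ex$x, keep_cache = FALSE)
    preds[[k]] <- apply_sep(fw$out[, , 1], model$Ah, model$Ac)
    sigmas[[k]] <- pmax(apply_sep(sigma_from_confidence(fw$out[, , 2]),
                                  model$Ah, model$Ac), 1e-8)
    targets[[k]] <- ex$target_loss
  }
  calibration_report(targets, preds, sigmas, n_bins)
}
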
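#' Training configuration
#'
#' Defaults are the full-scale settings: ADAM over 40 epochs at an
#' effective batch size of 256 reference cells per optimizer step, linear
#' warmup over 500 steps to a peak learning rate of 1e-3 followed by
#' inverse-square-root decay, and decoupled weight decay of 5e-5 (not
#' warmed up) on all weights except norms, embeddings and biases. For
#' desk-scale runs shrink `batch_size`/`warmup_steps` in proportion to
#' the number of optimizer steps.
#'
#' @param epochs training epochs
#' @param batch_size reference cells per optimizer step
#' @param warmup_steps linear warmup length in steps
#' @param peak_lr learning rate at the end of warmup
#' @param weight_decay decoupled weight-decay coefficient
#' @param seed integer seed controlling shuffling (and nothing else)
#' @param beta1,beta2,adam_eps ADAM moment coefficients
#' @return a `train_config` list
#' @export
train_config <- function(epochs = 40L, batch_size = 256L, warmup_steps = 500L,
                         peak_lr = 1e-3, weight_decay = 5e-5, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  stopifnot(epochs >= 1, batch_size >= 1, warmup_steps >= 1, peak_lr > 0,
            weight_decay >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 warmup_steps = as.integer(warmup_steps), peak_lr = peak_lr,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Linear warmup to the peak rate, then continuous inverse-square-root
#' decay: `lr(t) = peak_lr * min(t / warmup, sqrt(warmup / t))`. The two
#' branches meet at `t = warmup`, so the schedule is continuous and peaks
#' exactly there.
#'
#' @param step optimizer step, `>= 1` (vectorized)
#' @param cfg a [train_config()]
#' @return learning rate(s)
#' @export
lr_schedule <- function(step, cfg = train_config()) {
  stopifnot(all(step >= 1))
  w <- cfg$warmup_steps
  cfg$peak_lr * pmin(step / w, sqrt(w / step))
}

# names of parameters exempt from weight decay: norms, embeddings, biases,
# and the free token/query vectors
no_decay_param <- function(name) {
  grepl("_b$|_b[0-9]*$|_ln[0-9]?_[gb]$|embed|^cls$|^pool_q$|_bq$|_bk$|_bv$|head_.*_b$",
        name) | grepl("_g$", name)
}

#' Train the model by masked-cell prediction
#'
#' Self-supervised loop: each epoch visits every training reference cell
#' once in shuffled order; for each minibatch the neighborhoods are
#' assembled, the masked reference cell's counts are predicted from its
#' context, and the mean ZINB NLL is minimized with ADAM under
#' [lr_schedule()]. Output heads are calibrated from the training data
#' before the first step (mean-head bias at the global log gene
#' proportions, scale bias at the median depth) so optimization starts at
#' the dataset-mean predictor. Fully reproducible given `cfg$seed`.
#'
#' @param model a [nichescope_model()]
#' @param table a [cell_table()]
#' @param index a [build_neighborhood_index()] on the same table
#' @param split list with `train`/`test` integer indices, e.g. from
#'   [split_train_test()]
#' @param cfg a [train_config()]
#' @param checkpoint_dir optional directory; when set a checkpoint is
#'   written after every epoch
#' @param verbose print one line per epoch
#' @return the trained model, with `$train_state` holding the per-epoch
#'   `trace` (train/test NLL), the step counter, and the config
#' @export
train_model <- function(model, table, index, split, cfg = train_config(),
                        checkpoint_dir = NULL, verbose = FALSE) {
  P <- model$params
  P <- calibrate_heads(P, table, split$train)
  adam_m <- lapply(P, function(p) p * 0)
  adam_v <- lapply(P, function(p) p * 0)
  no_decay <- vapply(names(P), no_decay_param, logical(1))
  step <- 0L
  trace <- data.frame(epoch = integer(), train_nll = numeric(),
                      test_nll = numeric())
  epoch_orders <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$epochs), function(e) sample(split$train))
  })
  for (epoch in seq_len(cfg$epochs)) {
    ord <- epoch_orders[[epoch]]
    nb_batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    epoch_loss <- 0
    n_seen <- 0L
    for (bidx in nb_batches) {
      step <- step + 1L
      batch <- batch_neighborhoods(index, bidx, table)
      lg <- model_loss_grads(structure(list(config = model$config, params = P),
                                       class = "nichescope_model"),
                             batch, table)
      if (!is.finite(lg$loss)) {
        stop2("non-finite loss at step ", step, " (lr ",
              signif(lr_schedule(step, cfg), 3), "); batch refs: ",
              paste(utils::head(bidx, 5), collapse = ", "))
      }
      lr <- lr_schedule(step, cfg)
      for (nm in names(lg$grads)) {
        gmat <- lg$grads[[nm]]
        adam_m[[nm]] <- cfg$beta1 * adam_m[[nm]] + (1 - cfg$beta1) * gmat
        adam_v[[nm]] <- cfg$beta2 * adam_v[[nm]] + (1 - cfg$beta2) * gmat^2
        mhat <- adam_m[[nm]] / (1 - cfg$beta1^step)
        vhat <- adam_v[[nm]] / (1 - cfg$beta2^step)
        upd <- mhat / (sqrt(vhat) + cfg$adam_eps)
        if (!no_decay[[nm]] && cfg$weight_decay > 0) {
          upd <- upd + cfg$weight_decay * P[[nm]]
        }
        P[[nm]] <- P[[nm]] - lr * upd
      }
      epoch_loss <- epoch_loss + lg$loss * length(bidx)
      n_seen <- n_seen + length(bidx)
    }
    cur <- structure(list(config = model$config, params = P),
                     class = "nichescope_model")
    test_nll <- evaluate_nll(cur, table, index, split$test,
                             batch_size = cfg$batch_size)
    trace <- rbind(trace, data.frame(epoch = epoch,
                                     train_nll = epoch_loss / n_seen,
                                     test_nll = test_nll))
    if (verbose) {
      message(sprintf("epoch %d/%d | train NLL %.4f | test NLL %.4f",
                      epoch, cfg$epochs, epoch_loss / n_seen, test_nll))
    }
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      cur$train_state <- list(trace = trace, step = step, config = cfg)
      save_model(cur, file.path(checkpoint_dir,
                                sprintf("epoch_%03d.rds", epoch)))
    }
  }
  model$params <- P
  model$train_state <- list(trace = trace, step = step, config = cfg)
  model
}

# data-dependent init of the output heads: start at the dataset-mean
# predictor so early optimization refines rather than rescales
calibrate_heads <- function(P, table, train_idx) {
  depth <- Matrix::rowSums(table$counts[train_idx, , drop = FALSE])
  gene_tot <- Matrix::colSums(table$counts[train_idx, , drop = FALSE])
  prop <- (gene_tot + 1e-8) / sum(gene_tot + 1e-8)
  P$head_mean_b <- as.numeric(log(prop) - mean(log(prop)))
  P$head_scale_b <- inv_softplus(max(stats::median(depth), 1))
  P
}

#' Held-out negative log-likelihood of the masked-cell model
#'
#' Mean over cells of the per-cell mean-over-genes ZINB NLL, computed in
#' evaluation mode (no gradients, deterministic).
#'
#' @param model a trained [nichescope_model()]
#' @param table,index data and neighborhood index
#' @param cells integer indices of reference cells to evaluate
#' @param batch_size forward-pass batch size (does not affect values)
#' @return scalar mean NLL
#' @export
evaluate_nll <- function(model, table, index, cells, batch_size = 256L) {
  tot <- 0
  for (chunk in split(cells, ceiling(seq_along(cells) / batch_size))) {
    batch <- batch_neighborhoods(index, chunk, table)
    fwd <- model_forward(model, batch, table)
    y <- as.matrix(table$counts[chunk, , drop = FALSE])
    nll <- zinb_nll(y, fwd$params$mu, fwd$params$dispersion,
                    fwd$params$zero_inflation_logit)
    tot <- tot + sum(nll)
  }
  tot / length(cells)
}

#' Mean-expression baseline negative log-likelihood
#'
#' The no-context reference point: each held-out cell's counts are scored
#' under a negative binomial whose mean is the training-set average
#' expression (optionally conditioned on the cell's type, the stronger
#' baseline) with per-gene moment-matched dispersion. Comparing this to
#' [evaluate_nll()] quantifies what spatial context adds.
#'
#' @param table a [cell_table()]
#' @param split list with `train`/`test` indices
#' @param type_conditional condition means (and dispersions) on cell type
#' @return scalar mean NLL over the test cells
#' @export
baseline_expression_nll <- function(table, split, type_conditional = TRUE) {
  tr <- split$train; te <- split$test
  Y_te <- as.matrix(table$counts[te, , drop = FALSE])
  moment_theta <- function(m, v) {
    th <- m^2 / pmax(v - m, 1e-8)
    pmin(pmax(th, 1e-3), 1e6)
  }
  if (type_conditional) {
    types_tr <- table$obs$cell_type[tr]
    types_te <- table$obs$cell_type[te]
    Y_tr <- table$counts[tr, , drop = FALSE]
    nll <- numeric(length(te))
    for (t in unique(types_te)) {
      rows_tr <- which(types_tr == t)
      if (length(rows_tr) < 2) rows_tr <- seq_along(tr) # fallback: pool
      m <- Matrix::colMeans(Y_tr[rows_tr, , drop = FALSE])
      v <- apply(as.matrix(Y_tr[rows_tr, , drop = FALSE]), 2, stats::var)
      rows_te <- which(types_te == t)
      nll[rows_te] <- zinb_nll(Y_te[rows_te, , drop = FALSE],
                               pmax(m, 1e-8), moment_theta(m, v))
    }
    mean(nll)
  } else {
    m <- Matrix::colMeans(table$counts[tr, , drop = FALSE])
    v <- apply(as.matrix(table$counts[tr, , drop = FALSE]), 2, stats::var)
    mean(zinb_nll(Y_te, pmax(m, 1e-8), moment_theta(m, v)))
  }
}
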
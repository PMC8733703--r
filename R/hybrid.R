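## Serial hybrid assembly: interpolated process inputs -> z-score scaler ->
## rate network -> fed-batch mass balances.  Because the measured inputs do
## not feed back on the propagated states, the balances are linear in (X, P)
## given the rate trajectories, and prediction reduces to quadrature:
##   X(t) = X0 Phi(t) exp(A(t)),  A = int mu dt,
##   P(t) = Phi(t) (P0 + X0 int v exp(A) dt),
## where Phi(t) is the dilution response of the feed schedule (continuous
## dilution and bolus jumps alike).  This also yields closed-form weight
## sensitivities used by the Levenberg-Marquardt trainer.

#' Construct a hybrid model
#'
#' @param network an \code{hd_network} (its input names define the model
#'   inputs and their order).
#' @param scaler an \code{hd_scaler} fitted on training inputs.
#' @param mu_ref,v_ref rate scaling constants: the network is trained in
#'   scaled rate units, and its two outputs are multiplied by these
#'   references (1/h and g/L/h per 1e6 cells/mL) to give mu and v_px.
#' @return object of class \code{hd_hybrid}.
#' @export
hybrid_model <- function(network, scaler, mu_ref = 0.03, v_ref = 5e-4) {
  stopifnot(inherits(network, "hd_network"), inherits(scaler, "hd_scaler"))
  if (length(scaler$mean) != length(network$input_names))
    stopf("hybrid_model: scaler and network dimensions disagree")
  structure(list(network = network, scaler = scaler,
                 input_names = network$input_names,
                 mu_ref = mu_ref, v_ref = v_ref),
            class = "hd_hybrid")
}

## Precompute everything about a run that training and prediction reuse:
## an integration grid with duplicated nodes at input/dilution
## discontinuities (bolus times, CPP shift times), the raw input matrix on
## that grid, the dilution response, and the sample-row indices (last
## occurrence = post-bolus state, matching the sampling convention).
run_cache <- function(run, input_names = MODEL_INPUTS, step = 1,
                      extra_times = NULL) {
  end <- max(run$samples$time)
  tb <- bolus_times(run, end)
  seg <- run$design$segments$start_time
  dup <- sort(unique(c(tb, seg[seg > 0 & seg < end])))
  base <- sort(unique(c(seq(0, end, by = step), end, run$samples$time,
                        extra_times, dup)))
  t_eval <- base                       # where inputs are evaluated
  is_post <- rep(FALSE, length(base))
  for (d in dup) {
    i <- match(d, base)
    base <- append(base, d, after = i)
    t_eval <- append(t_eval, d, after = i)
    is_post <- append(is_post, TRUE, after = i)
    t_eval[i] <- d - 1e-9              # pre copy: left limit of step inputs
  }
  phi <- dilution_response(run, base)  # post-bolus values at bolus nodes
  pre_b <- !is_post & base %in% tb     # pre copy: undo the bolus dilution
  phi[pre_b] <- phi[pre_b] * (1 + run$feed$bolus_fraction)
  U <- t(interpolate_inputs(run, pmin(pmax(t_eval, 0), end), input_names))
  last_idx <- vapply(run$samples$time, function(ts)
    max(which(abs(base - ts) < 1e-9)), integer(1))
  list(run_id = run$run_id, t = base, U = U, phi = phi,
       X0 = run$seeding_density, P0 = 0, sample_idx = last_idx,
       vcc = run$samples$vcc, titer = run$samples$titer,
       n_samples = nrow(run$samples))
}

## Forward pass + quadrature on a cache for a given weight vector.
## Returns X, P on the grid plus intermediates for the sensitivity pass.
cache_forward <- function(w, cache, scaler, net_template, mu_ref, v_ref) {
  net <- net_set_weights(net_template, w)
  Z <- (cache$U - scaler$mean) / scaler$sd
  H <- tanh(net$W1 %*% Z + net$b1)
  mu <- mu_ref * as.numeric(net$W2[1, ] %*% H + net$b2[1])
  v <- v_ref * as.numeric(net$W2[2, ] %*% H + net$b2[2])
  A <- as.numeric(cumtrapz(cache$t, mu))
  eA <- exp(pmin(A, 50))
  X <- cache$X0 * cache$phi * eA
  B <- as.numeric(cumtrapz(cache$t, v * eA))
  P <- cache$phi * (cache$P0 + cache$X0 * B)
  list(X = X, P = P, H = H, Z = Z, mu = mu, v = v, A = A, eA = eA, net = net)
}

#' Predict the state trajectory of a run with a hybrid model
#'
#' Composes input interpolation, the scaler, the rate network and the mass
#' balances from the run's initial conditions (X0 = seeding density,
#' P0 = 0).  Deterministic.
#'
#' @param model an \code{hd_hybrid}.
#' @param run an \code{hd_run} (its measured analytes provide the inputs).
#' @param times optional extra times to include on the output grid.
#' @param step dense grid spacing (h).
#' @return data.frame (class \code{hd_trajectory}) with time, X, P; rows at
#'   bolus/shift times report the post-event state.
#' @export
predict_run <- function(model, run, times = NULL, step = 1) {
  miss <- setdiff(intersect(model$input_names, ANALYTE_NAMES),
                  names(run$samples))
  if (length(miss))
    stopf("predict_run: run '%s' lacks analyte '%s'", run$run_id, miss[1])
  cache <- run_cache(run, model$input_names, step = step,
                     extra_times = times)
  fw <- cache_forward(net_weights(model$network), cache, model$scaler,
                      model$network, model$mu_ref, model$v_ref)
  keep <- !duplicated(cache$t, fromLast = TRUE)  # post-event rows
  out <- data.frame(time = cache$t[keep], X = fw$X[keep], P = fw$P[keep])
  out$V <- volume_at(run, out$time)
  class(out) <- c("hd_trajectory", "data.frame")
  out
}

#' Normalized root mean square error (percent)
#'
#' 100 * sqrt(mean((y - y_hat)^2)) / mean(y).
#'
#' @param y measured values.
#' @param y_hat estimated values, same length.
#' @return NRMSE in percent.
#' @export
nrmse <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 1)
    stopf("nrmse: series must have equal positive length")
  if (mean(y) == 0) stopf("nrmse: mean of measured series is zero")
  100 * sqrt(mean((y - y_hat)^2)) / mean(y)
}

#' Residual vector of a hybrid model on a set of runs
#'
#' Concatenates (measured - predicted) at the sampling times for VCC and
#' titer, each block divided by its (training-set) mean so both targets
#' contribute on the NRMSE scale.
#'
#' @param model an \code{hd_hybrid}.
#' @param runs list of \code{hd_run}.
#' @param norm named list/vector with elements \code{vcc} and \code{titer};
#'   defaults to the means over \code{runs}.
#' @return numeric residual vector of length
#'   \code{2 * sum(sampling times per run)}.
#' @export
hybrid_residuals <- function(model, runs, norm = NULL) {
  norm <- norm %||% list(vcc = mean(unlist(lapply(runs, function(r) r$samples$vcc))),
                         titer = mean(unlist(lapply(runs, function(r) r$samples$titer))))
  unlist(lapply(runs, function(r) {
    pr <- tryCatch(predict_run(model, r),
                   error = function(e) stopf("prediction failed for run '%s': %s",
                                             r$run_id, conditionMessage(e)))
    at <- match(r$samples$time, pr$time)
    c((r$samples$vcc - pr$X[at]) / norm$vcc,
      (r$samples$titer - pr$P[at]) / norm$titer)
  }), use.names = FALSE)
}

## Residuals over precomputed caches (training hot path).
cache_residuals <- function(w, caches, scaler, net_template, mu_ref, v_ref,
                            norm) {
  unlist(lapply(caches, function(ca) {
    fw <- cache_forward(w, ca, scaler, net_template, mu_ref, v_ref)
    i <- ca$sample_idx
    c((ca$vcc - fw$X[i]) / norm$vcc, (ca$titer - fw$P[i]) / norm$titer)
  }), use.names = FALSE)
}

## Analytic Jacobian of cache_residuals w.r.t. the weight vector, via the
## closed-form sensitivities of the quadrature predictor (forward
## sensitivities through the ODE).
cache_jacobian <- function(w, caches, scaler, net_template, mu_ref, v_ref,
                           norm) {
  k <- length(net_template$input_names); h <- net_template$n_hidden
  nw <- length(w)
  do.call(rbind, lapply(caches, function(ca) {
    fw <- cache_forward(w, ca, scaler, net_template, mu_ref, v_ref)
    G <- length(ca$t)
    H <- fw$H; Hp <- 1 - H^2; Z <- fw$Z
    W2 <- fw$net$W2
    build_grad <- function(out_row) {
      Arow <- W2[out_row, ] * Hp                       # h x G
      w1 <- Arow[rep(seq_len(h), k), , drop = FALSE] *
        Z[rep(seq_len(k), each = h), , drop = FALSE]   # h*k x G
      w2 <- matrix(0, 2 * h, G)
      w2[seq(out_row, 2 * h, by = 2), ] <- H
      b2 <- matrix(0, 2, G); b2[out_row, ] <- 1
      rbind(w1, Arow, w2, b2)                          # nw x G
    }
    Gmu <- mu_ref * build_grad(1)
    Gv <- v_ref * build_grad(2)
    dA <- cumtrapz(ca$t, t(Gmu))               # G x nw
    dX <- dA * fw$X                                    # row-scaled
    intg <- t(Gv) * fw$eA + (fw$v * fw$eA) * dA
    dB <- cumtrapz(ca$t, intg)
    dP <- (ca$phi * ca$X0) * dB
    i <- ca$sample_idx
    rbind(-dX[i, , drop = FALSE] / norm$vcc,
          -dP[i, , drop = FALSE] / norm$titer)
  }))
}

#' Cross-validation configuration
#'
#' @param split_ratio fraction of runs in the training partition for random
#'   run-level splits (0.6).
#' @param n_repeats number of random-split repetitions (40).
#' @param mode "random_split" or "leave_one_run_out".
#' @param seed master seed (spawns per-partition split and init seeds).
#' @return list of class \code{hd_cv_config}.
#' @export
cv_config <- function(split_ratio = 0.6, n_repeats = 40,
                      mode = c("random_split", "leave_one_run_out"),
                      seed = 1) {
  mode <- match.arg(mode)
  stopifnot(split_ratio > 0, split_ratio < 1, n_repeats >= 1)
  structure(list(split_ratio = split_ratio, n_repeats = n_repeats,
                 mode = mode, seed = seed), class = "hd_cv_config")
}

## Pooled validation NRMSE (mean of the two targets) for a weight vector.
val_nrmse <- function(w, caches, scaler, net_template, mu_ref, v_ref) {
  vcc_m <- unlist(lapply(caches, `[[`, "vcc"))
  tit_m <- unlist(lapply(caches, `[[`, "titer"))
  pred <- lapply(caches, function(ca) {
    fw <- cache_forward(w, ca, scaler, net_template, mu_ref, v_ref)
    i <- ca$sample_idx
    list(X = fw$X[i], P = fw$P[i])
  })
  (nrmse(vcc_m, unlist(lapply(pred, `[[`, "X"))) +
     nrmse(tit_m, unlist(lapply(pred, `[[`, "P")))) / 2
}

#' Fit a hybrid-model ensemble by cross-validation
#'
#' For each partition the runs are split at run level (never by time
#' points), a network is initialized from a partition-specific seed and
#' trained by Levenberg-Marquardt on the training-partition residuals with
#' a ridge (weight decay) penalty, and the weights minimizing the
#' validation NRMSE (mean of the VCC and titer NRMSE) along the accepted
#' iterates are kept; training stops when the validation error stops
#' improving.  The ensemble gathers one model per partition.  The default
#' ridge strength for hybrid fitting (0.3) is deliberately much stronger
#' than the generic \code{\link{train_config}} default: with ~20 runs the
#' 38-weight network otherwise learns steep surfaces in sparsely observed
#' corners of the input space, and the exponential state propagation
#' amplifies them.
#'
#' @param runs named list of \code{hd_run} (>= 3 for random splits, >= 2
#'   for leave-one-run-out).
#' @param cv a \code{\link{cv_config}}.
#' @param train a \code{\link{train_config}}.
#' @param input_names model inputs.
#' @param mu_ref,v_ref rate scaling constants.
#' @param step integration grid spacing for training (h).
#' @param val_patience stop a partition's training once this many accepted
#'   steps pass without a new validation minimum.
#' @param n_starts random restarts per partition; the start reaching the
#'   lowest validation error provides the partition's member.
#' @return object of class \code{hd_ensemble}: members, partition records,
#'   per-member validation errors, seeds.
#' @export
fit_hybrid <- function(runs, cv = cv_config(),
                       train = train_config(weight_decay = 0.3,
                                            max_iter = 200, patience = 12),
                       input_names = MODEL_INPUTS, mu_ref = 0.03,
                       v_ref = 5e-4, step = 1, val_patience = 15,
                       n_starts = 3) {
  n <- length(runs)
  if (cv$mode == "random_split" && n < 3)
    stopf("fit_hybrid: random_split needs >= 3 runs")
  if (cv$mode == "leave_one_run_out" && n < 2)
    stopf("fit_hybrid: leave_one_run_out needs >= 2 runs")
  ids <- names(runs) %||% as.character(seq_len(n))
  names(runs) <- ids
  caches <- lapply(runs, run_cache, input_names = input_names, step = step)
  n_part <- if (cv$mode == "random_split") cv$n_repeats else n
  seeds <- matrix(spawn_seeds(cv$seed, (1 + n_starts) * n_part),
                  ncol = 1 + n_starts)
  net0 <- init_network(input_names, seed = 1)
  members <- list(); partitions <- list(); val_errors <- numeric(0)
  for (p in seq_len(n_part)) {
    train_ids <- if (cv$mode == "random_split") {
      with_seed(seeds[p, 1],
                sample(ids, ceiling(cv$split_ratio * n)))
    } else ids[-p]
    val_ids <- setdiff(ids, train_ids)
    res <- tryCatch({
      tr_runs <- runs[train_ids]
      inmat <- do.call(rbind, lapply(tr_runs, function(r)
        interpolate_inputs(r, r$samples$time, input_names)))
      scaler <- fit_scaler(inmat)
      norm <- list(vcc = mean(unlist(lapply(tr_runs, function(r) r$samples$vcc))),
                   titer = mean(unlist(lapply(tr_runs, function(r) r$samples$titer))))
      obj <- function(w) cache_residuals(w, caches[train_ids], scaler, net0,
                                         mu_ref, v_ref, norm)
      jac <- function(w) cache_jacobian(w, caches[train_ids], scaler, net0,
                                        mu_ref, v_ref, norm)
      best <- NULL; hist_best <- NULL
      for (s in seq_len(n_starts)) {
        net <- init_network(input_names, seed = seeds[p, 1 + s])
        cur <- list(err = val_nrmse(net_weights(net), caches[val_ids],
                                    scaler, net0, mu_ref, v_ref),
                    w = net_weights(net), iter = 0L)
        ## stop once the validation partition stops improving
        cb <- function(w, iter) {
          e <- val_nrmse(w, caches[val_ids], scaler, net0, mu_ref, v_ref)
          if (e < cur$err) cur <<- list(err = e, w = w, iter = iter)
          iter - cur$iter < val_patience
        }
        fit <- train_lm(obj, net, train, jacobian = jac, callback = cb)
        if (is.null(best) || cur$err < best$err) {
          best <- cur; hist_best <- fit$history
        }
      }
      list(model = hybrid_model(net_set_weights(net0, best$w), scaler,
                                mu_ref, v_ref),
           err = best$err, history = hist_best)
    }, error = function(e) {
      warnf("fit_hybrid: partition %d failed to train (%s)", p,
            conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      members[[length(members) + 1]] <- res$model
      partitions[[length(partitions) + 1]] <-
        list(train = train_ids, validation = val_ids,
             split_seed = seeds[p, 1], init_seeds = seeds[p, -1],
             history = res$history)
      val_errors <- c(val_errors, res$err)
    }
  }
  if (length(members) < 2)
    stopf("fit_hybrid: fewer than 2 partitions trained successfully")
  structure(list(members = members, partitions = partitions,
                 val_errors = val_errors, cv = cv, train = train,
                 input_names = input_names, seed = cv$seed),
            class = "hd_ensemble")
}

#' @export
print.hd_ensemble <- function(x, ...) {
  cat(sprintf("<hybrid ensemble: %d members (%s), validation NRMSE %.2f%% (mean)>\n",
              length(x$members), x$cv$mode, mean(x$val_errors)))
  invisible(x)
}

#' Ensemble-average prediction with SD and confidence band
#'
#' The averaged estimate is the mean over member predictions at each time;
#' the SD is the member spread sqrt(sum((mean - member)^2)/(n-1)) and the
#' confidence band is mean +/- SD, per target per time.
#'
#' @param ensemble an \code{hd_ensemble} (>= 2 members).
#' @param run an \code{hd_run}.
#' @param times optional extra times on the output grid.
#' @param step dense grid spacing (h).
#' @param max_vcc physiological plausibility bound (1e6 cells/mL): a member
#'   whose VCC prediction exceeds it anywhere is excluded with a warning
#'   (fed-batch CHO cultures stay well below 40e6 cells/mL).
#' @return data.frame (class \code{hd_prediction}): time, x_hat, p_hat,
#'   sd_x, sd_p, ci bounds per target.
#' @export
average_predict <- function(ensemble, run, times = NULL, step = 1,
                            max_vcc = 40) {
  preds <- list()
  for (m in ensemble$members) {
    p <- tryCatch({
      pr <- predict_run(m, run, times = times, step = step)
      if (any(!is.finite(pr$X)) || max(pr$X) > max_vcc)
        stopf("implausible VCC prediction (max %.3g)", max(pr$X))
      pr
    }, error = function(e) {
      warnf("average_predict: member excluded for run '%s' (%s)",
            run$run_id, conditionMessage(e))
      NULL
    })
    if (!is.null(p)) preds[[length(preds) + 1]] <- p
  }
  n <- length(preds)
  if (n < 2) stopf("average_predict: fewer than 2 member predictions")
  Xs <- sapply(preds, `[[`, "X")
  Ps <- sapply(preds, `[[`, "P")
  x_hat <- rowMeans(Xs); p_hat <- rowMeans(Ps)
  sd_x <- sqrt(rowSums((Xs - x_hat)^2) / (n - 1))
  sd_p <- sqrt(rowSums((Ps - p_hat)^2) / (n - 1))
  out <- data.frame(time = preds[[1]]$time, x_hat = x_hat, p_hat = p_hat,
                    sd_x = sd_x, sd_p = sd_p,
                    ci_lower_x = x_hat - sd_x, ci_upper_x = x_hat + sd_x,
                    ci_lower_p = p_hat - sd_p, ci_upper_p = p_hat + sd_p)
  class(out) <- c("hd_prediction", "data.frame")
  out
}

#' Evaluate an ensemble on a set of runs
#'
#' NRMSE per target, pooling all sampling points of all runs, on the
#' ensemble-average prediction; per-run values are also reported.
#'
#' @param ensemble an \code{hd_ensemble}.
#' @param runs list of \code{hd_run}.
#' @return list with \code{nrmse} (named: vcc, titer) and \code{per_run}
#'   data.frame.
#' @export
evaluate_ensemble <- function(ensemble, runs) {
  per <- lapply(runs, function(r) {
    pr <- average_predict(ensemble, r)
    at <- match(r$samples$time, pr$time)
    list(id = r$run_id, vcc_m = r$samples$vcc, vcc_p = pr$x_hat[at],
         tit_m = r$samples$titer, tit_p = pr$p_hat[at])
  })
  pooled <- c(vcc = nrmse(unlist(lapply(per, `[[`, "vcc_m")),
                          unlist(lapply(per, `[[`, "vcc_p"))),
              titer = nrmse(unlist(lapply(per, `[[`, "tit_m")),
                            unlist(lapply(per, `[[`, "tit_p"))))
  per_run <- do.call(rbind, lapply(per, function(x)
    data.frame(run_id = x$id,
               nrmse_vcc = nrmse(x$vcc_m, x$vcc_p),
               nrmse_titer = nrmse(x$tit_m, x$tit_p))))
  rownames(per_run) <- NULL
  list(nrmse = pooled, per_run = per_run)
}

#' Serialize an ensemble to a directory (member JSONs + ensemble.yaml)
#'
#' @param ensemble an \code{hd_ensemble}.
#' @param path directory.
#' @return \code{path} / the reconstructed \code{hd_ensemble}.
#' @export
write_ensemble <- function(ensemble, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ensemble$members)) {
    m <- ensemble$members[[i]]
    write_network(m$network, file.path(path, sprintf("member_%02d.json", i)),
                  extra = list(scaler_mean = m$scaler$mean,
                               scaler_sd = m$scaler$sd,
                               mu_ref = m$mu_ref, v_ref = m$v_ref))
  }
  yaml::write_yaml(list(n_members = length(ensemble$members),
                        input_names = ensemble$input_names,
                        seed = ensemble$seed,
                        cv = unclass(ensemble$cv),
                        val_errors = ensemble$val_errors,
                        partitions = lapply(ensemble$partitions, function(p)
                          p[c("train", "validation", "split_seed", "init_seed")])),
                   file.path(path, "ensemble.yaml"))
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  meta <- yaml::read_yaml(file.path(path, "ensemble.yaml"))
  members <- lapply(seq_len(meta$n_members), function(i) {
    net <- read_network(file.path(path, sprintf("member_%02d.json", i)))
    ex <- attr(net, "extra")
    sc <- structure(list(mean = stats::setNames(as.numeric(ex$scaler_mean),
                                                net$input_names),
                         sd = stats::setNames(as.numeric(ex$scaler_sd),
                                              net$input_names)),
                    class = "hd_scaler")
    hybrid_model(net, sc, mu_ref = ex$mu_ref, v_ref = ex$v_ref)
  })
  structure(list(members = members, partitions = meta$partitions,
                 val_errors = as.numeric(meta$val_errors),
                 cv = do.call(cv_config, meta$cv[c("split_ratio", "n_repeats",
                                                   "mode", "seed")]),
                 input_names = unlist(meta$input_names), seed = meta$seed),
            class = "hd_ensemble")
}
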
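## Data-driven half of the hybrid: z-score input scaling, a one-hidden-layer
## tanh network producing the two specific rates (in scaled rate units), and
## a Levenberg-Marquardt trainer with an L2 weight-decay penalty.

#' Fit a z-score input scaler
#'
#' @param x numeric matrix of training inputs (rows = observations).
#' @return list with per-column \code{mean} and \code{sd}
#'   (class \code{hd_scaler}).
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  m <- colMeans(x)
  s <- apply(x, 2, sd)
  if (any(s <= 0 | !is.finite(s))) {
    bad <- colnames(x)[which(s <= 0 | !is.finite(s))[1]] %||% "<unnamed>"
    stopf("fit_scaler: input '%s' is constant in the training set", bad)
  }
  structure(list(mean = m, sd = s), class = "hd_scaler")
}

#' Apply a fitted z-score scaler
#'
#' @param stats an \code{hd_scaler}.
#' @param x matrix (rows = observations) or vector of raw inputs.
#' @return scaled inputs, same shape as \code{x}.
#' @export
apply_scaler <- function(stats, x) {
  if (is.null(dim(x))) return((x - stats$mean) / stats$sd)
  sweep(sweep(as.matrix(x), 2, stats$mean, "-"), 2, stats$sd, "/")
}

#' Initialize a rate network
#'
#' One hidden layer of \code{n_hidden} tanh units and a linear 2-output
#' layer (scaled specific growth and production rates).  Weights are drawn
#' uniformly from [-0.5, 0.5] so the tanh units start near their linear
#' range; the draw is reproducible from the seed.
#'
#' @param input_names character vector naming the network inputs.
#' @param n_hidden hidden layer width (4).
#' @param seed integer seed.
#' @return An object of class \code{hd_network}.
#' @export
init_network <- function(input_names = MODEL_INPUTS, n_hidden = 4,
                         seed = 1) {
  k <- length(input_names)
  w <- with_seed(seed, runif(n_hidden * k + n_hidden + 2 * n_hidden + 2,
                             -0.5, 0.5))
  ## output layer starts an order of magnitude smaller, so the initial rates
  ## are near zero and the propagated states stay bounded
  structure(list(input_names = input_names, n_hidden = n_hidden,
                 W1 = matrix(w[seq_len(n_hidden * k)], n_hidden, k),
                 b1 = w[n_hidden * k + seq_len(n_hidden)],
                 W2 = 0.1 * matrix(w[n_hidden * k + n_hidden +
                                       seq_len(2 * n_hidden)], 2, n_hidden),
                 b2 = 0.1 * w[n_hidden * k + 3 * n_hidden + 1:2]),
            class = "hd_network")
}

## Flatten/unflatten the trainable weights (column-major, W1 | b1 | W2 | b2).
net_weights <- function(net) c(as.vector(net$W1), net$b1,
                               as.vector(net$W2), net$b2)

net_set_weights <- function(net, w) {
  k <- length(net$input_names); h <- net$n_hidden
  stopifnot(length(w) == h * k + h + 2 * h + 2)
  net$W1 <- matrix(w[seq_len(h * k)], h, k)
  net$b1 <- w[h * k + seq_len(h)]
  net$W2 <- matrix(w[h * k + h + seq_len(2 * h)], 2, h)
  net$b2 <- w[h * k + 3 * h + 1:2]
  net
}

#' Forward pass of the rate network
#'
#' @param net an \code{hd_network}.
#' @param x_scaled scaled input vector (length = number of inputs) or matrix
#'   with one column per evaluation point.
#' @return numeric vector \code{c(mu, vpx)} in scaled rate units, or a
#'   2-row matrix for matrix input.
#' @export
ann_forward <- function(net, x_scaled) {
  vec <- is.null(dim(x_scaled))
  Z <- if (vec) matrix(x_scaled, ncol = 1) else as.matrix(x_scaled)
  if (nrow(Z) != length(net$input_names))
    stopf("ann_forward: expected %d inputs, got %d",
          length(net$input_names), nrow(Z))
  H <- tanh(net$W1 %*% Z + net$b1)
  out <- net$W2 %*% H + net$b2
  if (vec) c(mu = out[1, 1], vpx = out[2, 1]) else out
}

#' Serialize / deserialize a network (with optional scaler) to JSON
#'
#' @param net an \code{hd_network}.
#' @param path file path.
#' @param extra named list of extra fields to store alongside (e.g. scaler
#'   statistics, rate scaling constants).
#' @return \code{path} (write) / reconstructed list (read).
#' @export
write_network <- function(net, path, extra = NULL) {
  ## weight matrices stored as flat column-major vectors (shape is implied
  ## by input_names and n_hidden), which round-trips bit-exactly
  obj <- c(list(input_names = net$input_names, n_hidden = net$n_hidden,
                W1 = as.vector(net$W1), b1 = net$b1,
                W2 = as.vector(net$W2), b2 = net$b2),
           extra %||% list())
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- o$n_hidden; k <- length(o$input_names)
  net <- structure(list(input_names = o$input_names, n_hidden = h,
                        W1 = matrix(as.numeric(o$W1), h, k),
                        b1 = as.numeric(o$b1),
                        W2 = matrix(as.numeric(o$W2), 2, h),
                        b2 = as.numeric(o$b2)),
                   class = "hd_network")
  attr(net, "extra") <- o[setdiff(names(o),
                                  c("input_names", "n_hidden", "W1", "b1",
                                    "W2", "b2"))]
  net
}

#' Training configuration for the Levenberg-Marquardt loop
#'
#' @param damping_init initial damping factor lambda.
#' @param damping_up,damping_down multiplicative damping updates on
#'   rejected/accepted steps.
#' @param weight_decay L2 penalty coefficient on the weights.
#' @param max_iter maximum accepted iterations.
#' @param patience stop after this many consecutive iterations without
#'   improvement of the penalized objective.
#' @param max_escalations damping escalations allowed within one iteration
#'   before giving up.
#' @param seed integer seed recorded with the config.
#' @return list of class \code{hd_train_config}.
#' @export
train_config <- function(damping_init = 1e-2, damping_up = 10,
                         damping_down = 0.1, weight_decay = 1e-4,
                         max_iter = 100, patience = 8,
                         max_escalations = 30, seed = 1) {
  stopifnot(damping_init > 0, patience >= 1)
  structure(list(damping_init = damping_init, damping_up = damping_up,
                 damping_down = damping_down, weight_decay = weight_decay,
                 max_iter = max_iter, patience = patience,
                 max_escalations = max_escalations, seed = seed),
            class = "hd_train_config")
}

#' Jacobian of a residual function by central finite differences
#'
#' @param objective function mapping a weight vector to a residual vector.
#' @param weights point at which to differentiate.
#' @param eps base step size (scaled by \code{max(1, |w_i|)} per coordinate).
#' @return matrix, one row per residual, one column per weight.
#' @export
residual_jacobian <- function(objective, weights, eps = 1e-6) {
  r0 <- objective(weights)
  if (any(!is.finite(r0)))
    stopf("residual_jacobian: non-finite residuals at the evaluation point")
  J <- matrix(0, length(r0), length(weights))
  for (i in seq_along(weights)) {
    h <- eps * max(1, abs(weights[i]))
    wp <- weights; wp[i] <- wp[i] + h
    wm <- weights; wm[i] <- wm[i] - h
    J[, i] <- (objective(wp) - objective(wm)) / (2 * h)
  }
  J
}

#' Train by Levenberg-Marquardt with L2 weight decay
#'
#' Classic damped Gauss-Newton loop on the penalized sum of squares
#' \code{||r(w)||^2 + weight_decay * ||w||^2} (implemented through residual
#' augmentation): a step is accepted only if the penalized objective
#' decreases, otherwise the damping is raised and the step recomputed.  The
#' recorded history over accepted steps is therefore non-increasing.
#'
#' @param objective function weight vector -> residual vector.
#' @param start starting point: an \code{hd_network} or a numeric weight
#'   vector.
#' @param cfg an \code{\link{train_config}}.
#' @param jacobian optional function weight vector -> Jacobian matrix;
#'   defaults to \code{\link{residual_jacobian}} (finite differences).
#' @param callback optional function \code{(w, iter)} invoked after every
#'   accepted step (used e.g. to track validation error); returning
#'   \code{FALSE} stops training early.
#' @return list with \code{weights} (or \code{network} when \code{start}
#'   was one), \code{history} (penalized SSE at start and after each
#'   accepted step), and \code{iterations}.
#' @export
train_lm <- function(objective, start, cfg = train_config(),
                     jacobian = NULL, callback = NULL) {
  is_net <- inherits(start, "hd_network")
  w <- if (is_net) net_weights(start) else as.numeric(start)
  jac <- jacobian %||% function(wv) residual_jacobian(objective, wv)
  wd <- sqrt(cfg$weight_decay)
  pen_sse <- function(r, wv) sum(r^2) + cfg$weight_decay * sum(wv^2)
  r <- objective(w)
  if (any(!is.finite(r)))
    stopf("train_lm: objective returned non-finite residuals at the start")
  sse <- pen_sse(r, w)
  history <- sse
  lambda <- cfg$damping_init
  stall <- 0L
  iter <- 0L
  while (iter < cfg$max_iter && stall < cfg$patience) {
    if (sse <= .Machine$double.eps) break    # already at (numerically) zero
    J <- jac(w)
    Ja <- rbind(J, diag(wd, length(w)))
    ra <- c(r, wd * w)
    JtJ <- crossprod(Ja)
    g <- crossprod(Ja, ra)
    dscale <- pmax(diag(JtJ), 1e-12)
    accepted <- FALSE
    for (esc in seq_len(cfg$max_escalations)) {
      step <- tryCatch(
        solve(JtJ + lambda * diag(dscale, length(w)), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        w_new <- w + as.numeric(step)
        r_new <- objective(w_new)
        if (all(is.finite(r_new))) {
          sse_new <- pen_sse(r_new, w_new)
          if (sse_new < sse) {
            rel <- (sse - sse_new) / max(sse, 1e-300)
            w <- w_new; r <- r_new; sse <- sse_new
            lambda <- max(lambda * cfg$damping_down, 1e-12)
            accepted <- TRUE
            break
          }
        }
      }
      lambda <- lambda * cfg$damping_up
      if (lambda > 1e12) break
    }
    iter <- iter + 1L
    if (accepted) {
      history <- c(history, sse)
      stall <- if (rel < 1e-10) stall + 1L else 0L
      if (!is.null(callback) && isFALSE(callback(w, iter))) break
    } else {
      stall <- cfg$patience                 # no descent direction left
    }
  }
  out <- list(history = history, iterations = iter)
  if (is_net) out$network <- net_set_weights(start, w)
  out$weights <- w
  out
}
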
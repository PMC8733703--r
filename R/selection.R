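## Three-step input-identification workflow: PCA on autoscaled candidates,
## squared-correlation screening against the targets, collinearity
## exclusion, and backward elimination to the minimal-validation-error
## input set.

#' The eleven candidate model inputs of the selection workflow
#'
#' The two CPPs, the amino acids flagged by PCA (glutamine, asparagine,
#' aspartate, serine) and by correlation (glycine, alanine, tyrosine,
#' hydroxyproline), and the aspartate/glutamate ratio (prior knowledge).
#' @export
CANDIDATE_INPUTS <- c("temperature", "feed_glucose", "glutamine",
                      "asparagine", "aspartate", "serine", "glycine",
                      "alanine", "tyrosine", "hydroxyproline",
                      "asp_glu_ratio")

#' Pooled candidate/target matrices of a dataset
#'
#' Stacks the candidate inputs (at the sampling times, i.e. the measured
#' values) and the two targets over all runs.
#'
#' @param runs list of \code{hd_run}.
#' @param candidates candidate input names.
#' @return list with matrix \code{x} and data.frame \code{targets}
#'   (vcc, titer).
#' @export
candidate_matrix <- function(runs, candidates = CANDIDATE_INPUTS) {
  x <- do.call(rbind, lapply(runs, function(r)
    interpolate_inputs(r, r$samples$time, candidates)))
  targets <- do.call(rbind, lapply(runs, function(r)
    data.frame(vcc = r$samples$vcc, titer = r$samples$titer)))
  rownames(x) <- NULL; rownames(targets) <- NULL
  list(x = x, targets = targets)
}

#' PCA of autoscaled candidate inputs
#'
#' Columns are z-scored before the eigendecomposition, so the analysis acts
#' on the correlation structure; explained variances are reported in
#' percent (descending, summing to 100).
#'
#' @param x numeric matrix (>= 2 rows and columns, no missing values).
#' @return list with \code{variance_percent}, orthonormal \code{loadings}
#'   and \code{sdev}.
#' @export
pca_explained_variance <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stopf("pca_explained_variance: need >= 2 rows and >= 2 columns")
  if (anyNA(x)) stopf("pca_explained_variance: missing values")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stopf("pca_explained_variance: column '%s' is constant",
          (colnames(x) %||% seq_len(ncol(x)))[which(sds == 0)[1]])
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  list(variance_percent = 100 * p$sdev^2 / sum(p$sdev^2),
       loadings = p$rotation, sdev = p$sdev)
}

#' Squared Pearson correlation of candidates against targets
#'
#' @param candidates numeric matrix (columns = candidates).
#' @param targets numeric matrix or data.frame (columns = targets, e.g.
#'   vcc and titer), aligned by row.
#' @return matrix of R-squared values, candidates x targets.
#' @export
correlation_r2 <- function(candidates, targets) {
  candidates <- as.matrix(candidates); targets <- as.matrix(targets)
  if (nrow(candidates) != nrow(targets))
    stopf("correlation_r2: unaligned observations")
  if (any(apply(candidates, 2, sd) == 0) || any(apply(targets, 2, sd) == 0))
    stopf("correlation_r2: zero-variance series")
  cor(candidates, targets)^2
}

#' Flag collinear candidate pairs for exclusion
#'
#' For each pair with |r| above the threshold, the member with the lower
#' mean R-squared against the targets is excluded.
#'
#' @param candidates numeric matrix.
#' @param threshold absolute-correlation threshold (default 0.95).
#' @param targets optional target matrix for the tie-break; without it the
#'   later column of a pair is excluded.
#' @return character vector of excluded candidate names.
#' @export
flag_collinear <- function(candidates, threshold = 0.95, targets = NULL) {
  candidates <- as.matrix(candidates)
  nm <- colnames(candidates) %||% as.character(seq_len(ncol(candidates)))
  score <- if (!is.null(targets))
    rowMeans(correlation_r2(candidates, targets)) else
      stats::setNames(rev(seq_along(nm)), nm)  # fallback: keep earlier column
  names(score) <- nm
  cc <- cor(candidates)
  excluded <- character(0)
  for (i in seq_len(ncol(cc) - 1)) for (j in (i + 1):ncol(cc)) {
    if (nm[i] %in% excluded || nm[j] %in% excluded) next
    if (abs(cc[i, j]) > threshold) {
      drop <- if (score[nm[i]] >= score[nm[j]]) nm[j] else nm[i]
      excluded <- c(excluded, drop)
    }
  }
  excluded
}

#' Backward elimination of hybrid-model inputs
#'
#' Starting from the candidate set, repeatedly retrains a reduced hybrid
#' ensemble for every single-input-removed subset and removes the input
#' whose removal gives the lowest cross-validation error.  Exploration
#' stops once the best removal exceeds the lowest validation error seen so
#' far by more than \code{tol} percentage points of NRMSE, and the final
#' set is the one at that minimal validation error.  The full explored
#' path is reported.
#'
#' @param runs training dataset (list of \code{hd_run}).
#' @param candidates starting input set (>= 2).
#' @param cv a \code{\link{cv_config}} (reduced repeats are customary here).
#' @param train a \code{\link{train_config}}.
#' @param tol stopping tolerance, absolute NRMSE percentage points (1).
#' @param step integration grid spacing for training (h).
#' @param ... further arguments passed to \code{\link{fit_hybrid}}
#'   (e.g. \code{n_starts}).
#' @return list of class \code{hd_selection} with the elimination
#'   \code{path} (data.frame: step, removed, val_error), \code{final}
#'   input set and the starting error.
#' @export
backward_eliminate <- function(runs, candidates = CANDIDATE_INPUTS,
                               cv = cv_config(n_repeats = 8),
                               train = train_config(weight_decay = 0.3,
                                                    max_iter = 80,
                                                    patience = 8),
                               tol = 1, step = 1, ...) {
  if (length(candidates) < 2) {
    return(structure(list(path = data.frame(step = integer(0),
                                            removed = character(0),
                                            val_error = numeric(0)),
                          final = candidates, start_error = NA_real_),
                     class = "hd_selection"))
  }
  ## candidate sets within one step share split/init seeds, so removals are
  ## compared on identical partitions (paired comparisons)
  fit_err <- function(inputs, seed_shift) {
    cvp <- cv; cvp$seed <- cv$seed + seed_shift
    ens <- fit_hybrid(runs, cv = cvp, train = train, input_names = inputs,
                      step = step, ...)
    mean(ens$val_errors)
  }
  current <- candidates
  start_error <- fit_err(current, 0L)
  best_err <- start_error
  best_set <- current
  path <- data.frame(step = integer(0), removed = character(0),
                     val_error = numeric(0), stringsAsFactors = FALSE)
  stepno <- 0L
  while (length(current) > 2) {
    errs <- vapply(seq_along(current), function(i) {
      tryCatch(fit_err(current[-i], stepno),
               error = function(e) {
                 warnf("backward_eliminate: removal of '%s' failed (%s)",
                       current[i], conditionMessage(e))
                 Inf
               })
    }, numeric(1))
    best <- which.min(errs)
    if (!is.finite(errs[best]) || errs[best] > best_err + tol) break
    stepno <- stepno + 1L
    path <- rbind(path, data.frame(step = stepno, removed = current[best],
                                   val_error = errs[best],
                                   stringsAsFactors = FALSE))
    current <- current[-best]
    if (errs[best] < best_err) {
      best_err <- errs[best]
      best_set <- current
    }
  }
  structure(list(path = path, final = best_set, min_error = best_err,
                 start_error = start_error),
            class = "hd_selection")
}

#' Run the full input-selection workflow on one dataset
#'
#' PCA scree + loadings, R-squared screening, collinearity exclusions, then
#' backward elimination on the surviving candidates.
#'
#' @inheritParams backward_eliminate
#' @param collinearity_threshold absolute-correlation threshold.
#' @return list of class \code{hd_selection_report}: pca, r2, exclusions,
#'   elimination (an \code{hd_selection}), final input set.
#' @export
run_input_selection <- function(runs, candidates = CANDIDATE_INPUTS,
                                cv = cv_config(n_repeats = 8),
                                train = train_config(weight_decay = 0.3,
                                                     max_iter = 80,
                                                     patience = 8),
                                collinearity_threshold = 0.95, tol = 1,
                                step = 1, ...) {
  cm <- candidate_matrix(runs, candidates)
  pca <- pca_explained_variance(cm$x)
  r2 <- correlation_r2(cm$x, cm$targets)
  excl <- flag_collinear(cm$x, collinearity_threshold, cm$targets)
  surviving <- setdiff(candidates, excl)
  elim <- backward_eliminate(runs, surviving, cv = cv, train = train,
                             tol = tol, step = step, ...)
  structure(list(candidates = candidates, pca = pca, r2 = r2,
                 exclusions = excl, elimination = elim,
                 final = elim$final),
            class = "hd_selection_report")
}
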
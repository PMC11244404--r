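#' Whiten multichannel data
#'
#' Removes channel means and applies a PCA whitening matrix so the output
#' has identity covariance (population covariance of the sample, divisor
#' \code{n}).
#'
#' @param X Channels x samples numeric matrix.
#' @param n_components Number of components to retain (default: all
#'   channels).
#' @return List: \code{Z} (whitened n_components x samples), \code{K}
#'   (whitening matrix), \code{means} (per-channel means).
#' @export
whiten <- function(X, n_components = nrow(X)) {
  X <- as.matrix(X)
  if (n_components > nrow(X)) {
    stop("cannot extract ", n_components, " components from ", nrow(X),
         " channels", call. = FALSE)
  }
  means <- rowMeans(X)
  Xc <- X - means
  C <- Xc %*% t(Xc) / ncol(Xc)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[n_components] < 1e-12 * e$values[1]) {
    stop("covariance is (near) rank deficient; try fewer components",
         call. = FALSE)
  }
  K <- diag(1 / sqrt(e$values[1:n_components]), n_components) %*%
    t(e$vectors[, 1:n_components, drop = FALSE])
  list(Z = K %*% Xc, K = K, means = means)
}

## W <- (W W^T)^(-1/2) W : symmetric decorrelation
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(e$values), nrow(W)) %*% t(e$vectors) %*% W
}

#' Fixed-point FastICA on whitened data
#'
#' Parallel (symmetric) FastICA: every row of the weight matrix is updated
#' by the fixed-point rule
#' \eqn{w \leftarrow E\{z g(w^T z)\} - E\{g'(w^T z)\} w}
#' and the matrix is re-orthonormalized by symmetric decorrelation after
#' each sweep. Iteration stops when the largest row-wise
#' \eqn{|1 - |\langle w_{new}, w_{old}\rangle||} drops below \code{tol}.
#'
#' @param Z Whitened components x samples matrix (see \code{\link{whiten}}).
#' @param n_components Number of components (default: rows of \code{Z}).
#' @param g Contrast nonlinearity, \code{"tanh"} or \code{"pow3"}.
#' @param tol Convergence tolerance.
#' @param max_iter Maximum sweeps; non-convergence returns the best
#'   iterate with \code{converged = FALSE} and a warning.
#' @param seed RNG seed for the random orthonormal initialization.
#' @return List: \code{W} (orthonormal unmixing in whitened space),
#'   \code{iteration_log} (per-sweep convergence deltas),
#'   \code{converged}.
#' @export
fastica_fit <- function(Z, n_components = nrow(Z), g = c("tanh", "pow3"),
                        tol = 1e-4, max_iter = 200, seed = 1L) {
  g <- match.arg(g)
  stopifnot(tol > 0, max_iter >= 1)
  if (n_components != nrow(Z)) {
    stop("Z has ", nrow(Z), " rows; whiten() with the desired component",
         " count first", call. = FALSE)
  }
  m <- ncol(Z)
  set.seed(seed)
  W <- sym_decorrelate(matrix(stats::rnorm(n_components^2), n_components))
  log <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    if (g == "tanh") {
      G <- tanh(WX)
      W_new <- (G %*% t(Z)) / m - diag(rowMeans(1 - G^2)) %*% W
    } else {
      W_new <- ((WX^3) %*% t(Z)) / m - 3 * W
    }
    if (any(!is.finite(W_new))) {
      stop("FastICA update produced non-finite values", call. = FALSE)
    }
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    log <- c(log, delta)
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("FastICA did not converge in ", max_iter,
            " sweeps (last delta ", signif(log[length(log)], 3), ")")
  }
  list(W = W, iteration_log = log, converged = converged)
}

#' Fit an ICA unmixing model to a recording
#'
#' Whitening followed by \code{\link{fastica_fit}}; assembles the sensor
#' space unmixing and estimated mixing matrices.
#'
#' @param x An \code{\link{eeg_recording}} or channels x samples matrix.
#' @param n_components Number of independent components (default 8).
#' @param ... Passed to \code{\link{fastica_fit}} (\code{g}, \code{tol},
#'   \code{max_iter}, \code{seed}).
#' @return An \code{ica_model}: \code{W} (whitened-space unmixing),
#'   \code{K}, \code{means}, \code{unmixing} (\code{W K}, sensor space),
#'   \code{A} (estimated mixing, channels x components — the component
#'   scalp topographies), \code{channel_names}, \code{n_components},
#'   \code{excluded}, \code{iteration_log}, \code{converged}.
#' @export
ica_fit <- function(x, n_components = 8, ...) {
  X <- if (inherits(x, "eeg_recording")) x$data else as.matrix(x)
  ch <- if (inherits(x, "eeg_recording")) x$channel_names
        else rownames(X)
  wh <- whiten(X, n_components)
  fit <- fastica_fit(wh$Z, n_components, ...)
  U <- fit$W %*% wh$K                        # sensor-space unmixing
  A <- t(U) %*% solve(U %*% t(U))            # pseudo-inverse: mixing
  structure(list(W = fit$W, K = wh$K, means = wh$means, unmixing = U,
                 A = A, channel_names = ch,
                 n_components = n_components, excluded = integer(),
                 iteration_log = fit$iteration_log,
                 converged = fit$converged),
            class = "ica_model")
}

#' Recover component time series
#'
#' @param model An \code{ica_model}.
#' @param x Recording or matrix the model was (or could have been) fit on.
#' @return Components x samples matrix \code{S = W K (X - means)}.
#' @export
ica_sources <- function(model, x) {
  X <- if (inherits(x, "eeg_recording")) x$data else as.matrix(x)
  model$unmixing %*% (X - model$means)
}

excess_kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

## peak-to-RMS of the matched-filter output against a template, in units
## of the Gaussian expectation sqrt(2 log n)
template_peakiness <- function(s, tpl) {
  s <- (s - mean(s)) / stats::sd(s)
  tpl <- tpl / sqrt(sum(tpl^2))
  y <- conv_full(s, rev(tpl))
  (max(abs(y)) / stats::sd(y)) / sqrt(2 * log(length(s)))
}

#' Score and flag artifact components
#'
#' Combines three markers of ocular/cardiac interference per component:
#' concentration of the scalp topography on the frontal-pole (Fp)
#' channels, excess kurtosis of the component time series (blinks and QRS
#' pulses are sparse, hence strongly super-Gaussian, while band
#' oscillations are not), and peakiness of the matched-filter response to
#' stereotyped blink and cardiac templates. Band oscillations score near
#' zero on all three, so the default threshold separates cleanly.
#'
#' @param model An \code{ica_model}.
#' @param sources Components x samples matrix from
#'   \code{\link{ica_sources}}.
#' @param channel_names Channel names matching the model's rows (defaults
#'   to the names stored in the model).
#' @param threshold Components scoring above this are flagged (default 1).
#' @param fs Sampling rate (Hz) used to build the templates.
#' @return Data frame sorted by decreasing score: \code{component} (index),
#'   \code{score}, \code{frontal_ratio}, \code{kurtosis},
#'   \code{template_peak}, \code{flagged}.
#' @export
identify_artifact_components <- function(model, sources,
                                         channel_names = model$channel_names,
                                         threshold = 1, fs = 500) {
  stopifnot(inherits(model, "ica_model"))
  n_comp <- model$n_components
  is_fp <- grepl("^Fp", channel_names)
  tt <- seq(0, 0.3, by = 1 / fs)
  blink_tpl <- sin(2 * pi * tt / 0.3) * exp(-((tt - 0.15) / 0.1)^2)
  tt2 <- seq(0, 0.08, by = 1 / fs)
  card_tpl <- c(-0.2, diff(exp(-((tt2 - 0.04) / 0.012)^2))) * 40
  out <- data.frame(component = seq_len(n_comp), score = 0,
                    frontal_ratio = 0, kurtosis = 0, template_peak = 0)
  for (j in seq_len(n_comp)) {
    topo <- abs(model$A[, j])
    fr <- if (any(is_fp)) sum(topo[is_fp]) / sum(topo) else 0
    ku <- excess_kurtosis(sources[j, ])
    tp <- max(template_peakiness(sources[j, ], blink_tpl),
              template_peakiness(sources[j, ], card_tpl))
    out$frontal_ratio[j] <- fr
    out$kurtosis[j] <- ku
    out$template_peak[j] <- tp
    out$score[j] <- sqrt(max(ku, 0)) * (0.5 + fr) + max(0, tp - 1.5)
  }
  out <- out[order(-out$score), ]
  out$flagged <- out$score > threshold
  rownames(out) <- NULL
  out
}

#' Remove ICA components from a recording
#'
#' \eqn{X_{corrected} = X - A_{excluded} S_{excluded}}: the back-projection
#' of the excluded components is subtracted; retained components are
#' untouched.
#'
#' @param x Recording or channels x samples matrix.
#' @param model An \code{ica_model}.
#' @param excluded Integer component indices to remove (empty set is a
#'   no-op).
#' @return Same type as \code{x}, corrected.
#' @export
remove_components <- function(x, model, excluded) {
  stopifnot(inherits(model, "ica_model"))
  excluded <- as.integer(excluded)
  if (length(excluded) &&
      (min(excluded) < 1 || max(excluded) > model$n_components)) {
    stop("excluded indices out of range 1..", model$n_components,
         call. = FALSE)
  }
  X <- if (inherits(x, "eeg_recording")) x$data else as.matrix(x)
  if (length(excluded)) {
    S <- ica_sources(model, X)
    X <- X - model$A[, excluded, drop = FALSE] %*%
      S[excluded, , drop = FALSE]
  }
  if (inherits(x, "eeg_recording")) {
    out <- x
    out$data <- X
    return(append_history(out, sprintf("ica_remove(%s)",
                                       paste(excluded, collapse = ","))))
  }
  X
}

#' Match estimated sources to references
#'
#' Greedy assignment on the absolute correlation matrix; permutation- and
#' sign-invariant recovery score for blind source separation benchmarks.
#'
#' @param est,ref Components x samples matrices with equal row counts.
#' @return List: \code{pairs} (data frame est/ref index and \code{abs_cor})
#'   and \code{mean_abs_cor}.
#' @export
match_sources <- function(est, ref) {
  cm <- abs(stats::cor(t(est), t(ref)))
  k <- nrow(cm)
  pairs <- data.frame(est = integer(k), ref = integer(k), abs_cor = 0)
  for (i in seq_len(k)) {
    ij <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pairs[i, ] <- c(ij[1], ij[2], cm[ij[1], ij[2]])
    cm[ij[1], ] <- -1
    cm[, ij[2]] <- -1
  }
  list(pairs = pairs, mean_abs_cor = mean(pairs$abs_cor))
}
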
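#' Estimate the noise covariance of a cube by shift differences
#'
#' Noise is estimated from spectra of horizontally and vertically adjacent
#' pixel pairs lying fully inside the tissue mask: the covariance of the
#' difference spectra divided by 2, which for stationary noise with smooth
#' signal recovers the per-band noise covariance.
#'
#' Pairs straddling a tissue-class boundary carry signal, not noise, and
#' would dominate the estimate; they are trimmed by discarding pairs whose
#' difference norm exceeds `trim` times the median pair norm. By default the
#' multiplier adapts to the band count as `1 + 8 / sqrt(2B)`: the norm of a
#' genuine noise difference concentrates around its median with relative
#' spread of order `1 / sqrt(2B)`, so at high band counts the cut sits far
#' outside the noise distribution yet well below boundary-pair norms, while
#' at low band counts it loosens enough not to bias the estimate.
#'
#' @param cube A [hyper_cube()].
#' @param mask Logical matrix; defaults to the cube's tissue mask.
#' @param trim Multiple of the median difference norm above which a pair is
#'   treated as a boundary pair and discarded; `NULL` (default) uses the
#'   band-count-adaptive multiplier, `Inf` disables trimming.
#' @return Symmetric positive semi-definite `B x B` matrix.
#' @export
estimate_noise_covariance <- function(cube, mask = cube$tissue_mask,
                                      trim = NULL) {
  d <- dim(cube$data)
  H <- d[1]; W <- d[2]; B <- d[3]
  X <- matrix(cube$data, H * W, B)
  idx <- matrix(seq_len(H * W), H, W)
  pairs <- rbind(
    cbind(as.vector(idx[-H, ]), as.vector(idx[-1, ])),   # vertical
    cbind(as.vector(idx[, -W]), as.vector(idx[, -1]))    # horizontal
  )
  keep <- mask[pairs[, 1]] & mask[pairs[, 2]]
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 1)
    abort("no adjacent masked pixel pairs; cannot estimate noise")
  D <- X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE]
  if (is.null(trim)) trim <- 1 + 8 / sqrt(2 * B)
  if (is.finite(trim) && nrow(D) > 4) {
    nrm <- sqrt(rowSums(D^2))
    keep2 <- nrm <= trim * stats::median(nrm)
    if (sum(keep2) >= 2) D <- D[keep2, , drop = FALSE]
  }
  crossprod(D) / (2 * nrow(D))
}

#' Fit a Minimum Noise Fraction transform
#'
#' Solves the generalized eigenproblem of the data covariance against the
#' noise covariance by whitening: components are ordered by decreasing
#' signal-to-noise ratio, so truncating to the leading components and
#' inverting the transform denoises the cube. A ridge term
#' `1e-10 * trace / B` stabilizes near-singular noise covariances.
#'
#' @param cube A [hyper_cube()].
#' @param mask Logical matrix of pixels entering the fit.
#' @param noise_cov Optional precomputed noise covariance.
#' @return An object of class `mnf_model` with elements `noise_cov`,
#'   `data_cov`, `eigvals` (descending), `forward`, `inverse`,
#'   `mean_spectrum`.
#' @export
mnf_fit <- function(cube, mask = cube$tissue_mask, noise_cov = NULL) {
  B <- dim(cube$data)[3]
  X <- cube_spectra(cube, which(mask))
  if (nrow(X) < 2) abort("need at least 2 masked pixels")
  if (is.null(noise_cov)) noise_cov <- estimate_noise_covariance(cube, mask)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  data_cov <- crossprod(Xc) / (nrow(Xc) - 1)
  ridge <- 1e-10 * sum(diag(noise_cov)) / B
  if (ridge <= 0) ridge <- 1e-12
  Sn <- noise_cov + diag(ridge, B)
  en <- eigen(Sn, symmetric = TRUE)
  wvals <- pmax(en$values, ridge)
  Wm <- en$vectors %*% diag(1 / sqrt(wvals)) %*% t(en$vectors)  # whitener
  M <- Wm %*% data_cov %*% Wm
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  forward <- Wm %*% em$vectors                    # spectra %*% forward = scores
  inverse <- t(em$vectors) %*% en$vectors %*% diag(sqrt(wvals)) %*% t(en$vectors)
  structure(
    list(noise_cov = noise_cov, data_cov = data_cov,
         eigvals = em$values, forward = forward, inverse = inverse,
         mean_spectrum = mu),
    class = "mnf_model"
  )
}

#' Denoise a cube with the Minimum Noise Fraction transform
#'
#' Masked pixels are mean-centered, projected onto the top `k` MNF
#' components and transformed back; unmasked pixels pass through unchanged.
#'
#' @param cube A [hyper_cube()].
#' @param mask Logical pixel mask (default: tissue mask).
#' @param k Number of retained components (default 20, the count found
#'   optimal for reconstruction in this pipeline).
#' @param model Optional prefitted [mnf_fit()] model.
#' @return A denoised [hyper_cube()] of identical shape and axis.
#' @export
mnf_denoise <- function(cube, mask = cube$tissue_mask, k = 20, model = NULL) {
  B <- dim(cube$data)[3]
  if (k < 1 || k > B) abort(sprintf("k must lie in [1, %d]", B))
  if (is.null(model)) model <- mnf_fit(cube, mask)
  px <- which(mask)
  X <- cube_spectra(cube, px)
  Xc <- sweep(X, 2, model$mean_spectrum)
  scores <- Xc %*% model$forward[, seq_len(k), drop = FALSE]
  Xhat <- scores %*% model$inverse[seq_len(k), , drop = FALSE]
  Xhat <- sweep(Xhat, 2, model$mean_spectrum, `+`)
  d <- dim(cube$data)
  out <- matrix(cube$data, d[1] * d[2], B)
  out[px, ] <- Xhat
  res <- cube
  res$data <- array(out, d)
  res
}

#' @export
print.mnf_model <- function(x, ...) {
  cat(sprintf("<mnf_model> %d bands; leading SNR eigenvalues: %s\n",
              length(x$eigvals),
              paste(signif(head(x$eigvals, 5), 4), collapse = ", ")))
  invisible(x)
}
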
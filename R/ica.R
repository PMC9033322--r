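#' Contrast nonlinearity for the fixed-point ICA iteration
#'
#' Bundles the contrast function `G`, its derivative `g = G'` and second
#' derivative `g' = G''` used by the negentropy approximation and the
#' fixed-point update. The default — and the one the method is derived
#' with — is the logcosh family
#' `G(u) = log(cosh(a1 u)) / a1`, `g(u) = tanh(a1 u)`,
#' `g'(u) = a1 (1 - tanh(a1 u)^2)`, with shape parameter `a1` in `[1, 2]`.
#'
#' @param name contrast name; `"logcosh"` is the supported family.
#' @param a1 shape parameter, dimensionless, in `[1, 2]`.
#' @return A `nonlinearity` object with elementwise functions `G`, `g`,
#'   `gprime`, plus `EG_gauss`, the expectation of `G` under a standard
#'   Gaussian (computed once by Gauss–Hermite quadrature; used only by the
#'   negentropy diagnostic, not by the update).
#' @examples
#' nl <- nonlinearity()
#' nl$g(0) # tanh is odd: 0
#' @export
nonlinearity <- function(name = "logcosh", a1 = 1) {
  name <- match.arg(name, "logcosh")
  if (!is.numeric(a1) || length(a1) != 1 || a1 < 1 || a1 > 2) {
    stop("a1 must be a single number in [1, 2]")
  }
  G <- function(u) log(cosh(a1 * u)) / a1
  g <- function(u) tanh(a1 * u)
  gprime <- function(u) a1 * (1 - tanh(a1 * u)^2)
  gh <- pracma::gaussHermite(40)
  # E G(nu), nu ~ N(0,1): nodes are for exp(-x^2) so rescale by sqrt(2)
  EG <- sum(gh$w * G(sqrt(2) * gh$x)) / sqrt(pi)
  structure(list(name = name, a1 = a1, G = G, g = g, gprime = gprime,
                 EG_gauss = EG),
            class = "nonlinearity")
}

#' Fit a PCA whitening model
#'
#' Centers the data per channel and computes the eigendecomposition of the
#' sample covariance; the whitening matrix `V = D^{-1/2} E^T` maps centered
#' data to uncorrelated rows with unit variance. Components are ordered by
#' decreasing eigenvalue and the decomposition may be truncated to the
#' leading `n_keep` components.
#'
#' @param data numeric matrix, channels x samples (samples > channels).
#' @param n_keep number of components to retain, or `"all"`.
#' @param tol_rank eigenvalues below `tol_rank * max(eigenvalue)` are
#'   treated as zero when checking rank.
#' @return A `whitening_model` with fields `mean`, `E` (orthonormal
#'   eigenvectors, columns), `D` (eigenvalues, descending), `V`, `n_keep`.
#' @examples
#' X <- matrix(rnorm(3 * 500), nrow = 3)
#' wm <- fit_whitening(X)
#' Z <- whiten(wm, X)
#' max(abs(tcrossprod(Z) / (ncol(Z) - 1) - diag(3))) # ~ 0
#' @export
fit_whitening <- function(data, n_keep = "all", tol_rank = 1e-12) {
  stopifnot(is.matrix(data), is.numeric(data))
  p <- nrow(data); n <- ncol(data)
  if (n <= p) stop("need more samples than channels (", n, " <= ", p, ")")
  mu <- rowMeans(data)
  Xc <- data - mu
  C <- tcrossprod(Xc) / (n - 1)
  eg <- eigen(C, symmetric = TRUE)
  D <- eg$values; E <- eg$vectors
  keep <- if (identical(n_keep, "all")) p else as.integer(n_keep)
  if (keep < 1 || keep > p) stop("n_keep must be in 1..", p)
  bad <- which(D[seq_len(keep)] <= tol_rank * max(D))
  if (length(bad)) {
    stop(sprintf(
      "covariance is rank deficient: eigenvalue(s) %s are %s; lower n_keep to %d",
      paste(bad, collapse = ", "),
      paste(signif(D[bad], 3), collapse = ", "),
      min(bad) - 1L
    ))
  }
  E <- E[, seq_len(keep), drop = FALSE]
  D <- D[seq_len(keep)]
  V <- diag(1 / sqrt(D), nrow = keep) %*% t(E)
  structure(list(mean = mu, E = E, D = D, V = V, n_keep = keep),
            class = "whitening_model")
}

#' @rdname fit_whitening
#' @param model a fitted `whitening_model`.
#' @return [whiten()] returns the `n_keep` x samples whitened matrix.
#' @export
whiten <- function(model, data) {
  stopifnot(inherits(model, "whitening_model"))
  if (nrow(data) != length(model$mean)) {
    stop("data has ", nrow(data), " channels but model expects ",
         length(model$mean))
  }
  model$V %*% (data - model$mean)
}

#' One fixed-point update of a single unmixing direction
#'
#' Applies the approximate-Newton step that makes FastICA fast: with
#' whitened data `Z` and the current unit vector `w`,
#' `w+ = E[z g(w'z)] - E[g'(w'z)] w`, followed by renormalisation to unit
#' length. Expectations are sample means over the sample axis. At a fixed
#' point `w+` is parallel to `w`.
#'
#' @param w unit-norm numeric vector, length `nrow(Z)`.
#' @param Z whitened data matrix (components x samples).
#' @param nl a [nonlinearity()].
#' @return The updated unit vector. If the update collapses to the zero
#'   vector a condition of class `icafeat_degenerate_update` is signalled.
#' @export
one_unit_update <- function(w, Z, nl = nonlinearity()) {
  wz <- drop(crossprod(w, Z))      # w'z per sample
  w_new <- drop(Z %*% nl$g(wz)) / ncol(Z) - mean(nl$gprime(wz)) * w
  nrm <- sqrt(sum(w_new^2))
  if (nrm < .Machine$double.eps^0.5) {
    stop(structure(
      class = c("icafeat_degenerate_update", "error", "condition"),
      list(message = "fixed-point update collapsed to the zero vector",
           call = sys.call())
    ))
  }
  w_new / nrm
}

#' Negentropy contrast of a direction
#'
#' The non-Gaussianity objective maximised by the fixed-point iteration:
#' `|E G(w'z) - E G(nu)|` with `nu` standard Gaussian. Used as a diagnostic
#' (converged directions should beat random ones), not by the update.
#'
#' @inheritParams one_unit_update
#' @return Non-negative scalar.
#' @export
negentropy_contrast <- function(w, Z, nl = nonlinearity()) {
  wz <- drop(crossprod(w, Z))
  abs(mean(nl$G(wz)) - nl$EG_gauss)
}

#' Fit fixed-point ICA by deflation
#'
#' Whitens the data, then extracts `n_components` unmixing directions one at
#' a time with the approximate-Newton fixed-point update ([one_unit_update()]).
#' After every update the current direction is Gram–Schmidt-orthogonalised
#' against the previously accepted rows and renormalised (deflation), so the
#' final `W` has orthonormal rows. A component converges when successive
#' directions satisfy `|<w_new, w_old>| > 1 - tol` (the absolute value
#' absorbs sign flips between iterations). Symmetric (simultaneous)
#' orthogonalisation is available as an alternative.
#'
#' Each direction is initialised from a seeded standard-normal stream, so
#' the fit is reproducible given `seed`. After extraction each row of `W` is
#' sign-flipped so the recovered component has positive skewness (falling
#' back to the sign of its largest-magnitude sample when skewness is near
#' zero), giving deterministic output.
#'
#' @param data channels x samples numeric matrix.
#' @param n_components number of components to extract (defaults to the
#'   retained whitening dimension).
#' @param nl a [nonlinearity()].
#' @param tol convergence tolerance on `1 - |<w_new, w_old>|`.
#' @param max_iter maximum fixed-point iterations per component; a component
#'   still moving after `max_iter` is flagged unconverged with a warning but
#'   returned.
#' @param seed integer seed for the initial directions (required).
#' @param ortho `"deflation"` (default) or `"symmetric"`.
#' @param n_keep components retained by whitening (default `"all"`).
#' @return An `ica_fit` with the whitening model, orthonormal `W` (rows are
#'   unit vectors in whitened space), per-component iteration counts and
#'   convergence flags, and the settings used.
#' @examples
#' bench <- make_bss_benchmark(seed = 7)
#' fit <- fit_ica(bench$recording$data, seed = 7)
#' glance(fit)
#' @export
fit_ica <- function(data, n_components = NULL, nl = nonlinearity(),
                    tol = 1e-6, max_iter = 200, seed,
                    ortho = c("deflation", "symmetric"), n_keep = "all") {
  if (inherits(data, "recording")) data <- data$data
  ortho <- match.arg(ortho)
  if (missing(seed)) stop("`seed` is required for reproducible initialisation")
  wm <- fit_whitening(data, n_keep = n_keep)
  m <- wm$n_keep
  if (is.null(n_components)) n_components <- m
  if (n_components > m) {
    stop("n_components (", n_components, ") exceeds retained rank (", m, ")")
  }
  Z <- whiten(wm, data)
  rng <- local({ set.seed(seed); function(n) rnorm(n) })

  draw_unit <- function() {
    v <- rng(m)
    v / sqrt(sum(v^2))
  }
  gram_schmidt <- function(w, W_prev) {
    if (nrow(W_prev) > 0) w <- w - drop(crossprod(W_prev, W_prev %*% w))
    nrm <- sqrt(sum(w^2))
    if (nrm < .Machine$double.eps^0.5) return(NULL)
    w / nrm
  }

  W <- matrix(0, 0, m)
  n_iter <- integer(n_components)
  converged <- logical(n_components)

  if (ortho == "deflation") {
    for (k in seq_len(n_components)) {
      w <- gram_schmidt(draw_unit(), W)
      while (is.null(w)) w <- gram_schmidt(draw_unit(), W)
      it <- 0L; done <- FALSE
      while (it < max_iter && !done) {
        it <- it + 1L
        w_new <- tryCatch(one_unit_update(w, Z, nl),
                          icafeat_degenerate_update = function(e) NULL)
        if (is.null(w_new)) {
          message("component ", k, ": degenerate update, reinitialising")
          w <- gram_schmidt(draw_unit(), W)
          next
        }
        w_new <- gram_schmidt(w_new, W)
        if (is.null(w_new)) {
          w <- gram_schmidt(draw_unit(), W)
          next
        }
        done <- abs(sum(w_new * w)) > 1 - tol
        w <- w_new
      }
      if (!done) {
        warning("component ", k, " did not converge in ", max_iter,
                " iterations", call. = FALSE)
      }
      n_iter[k] <- it; converged[k] <- done
      W <- rbind(W, w)
    }
  } else {
    W <- t(replicate(n_components, draw_unit()))
    W <- sym_decorrelate(W)
    it <- 0L; done <- FALSE
    while (it < max_iter && !done) {
      it <- it + 1L
      W_new <- t(apply(W, 1, function(w) {
        wz <- drop(crossprod(w, Z))
        drop(Z %*% nl$g(wz)) / ncol(Z) - mean(nl$gprime(wz)) * w
      }))
      W_new <- sym_decorrelate(W_new)
      done <- max(1 - abs(rowSums(W_new * W))) < tol
      W <- W_new
    }
    if (!done) warning("symmetric iteration did not converge in ", max_iter,
                       " iterations", call. = FALSE)
    n_iter <- rep(it, n_components); converged <- rep(done, n_components)
  }
  W <- unname(W)

  # deterministic sign: positive skewness, else positive max-|value| sample
  S <- W %*% Z
  for (k in seq_len(n_components)) {
    s <- S[k, ]
    sk <- mean((s - mean(s))^3)
    flip <- if (abs(sk) > 1e-8) sk < 0 else s[which.max(abs(s))] < 0
    if (flip) W[k, ] <- -W[k, ]
  }

  structure(
    list(whitening = wm, W = W, n_iter = n_iter, converged = converged,
         nl = nl, tol = tol, max_iter = max_iter, seed = seed, ortho = ortho),
    class = "ica_fit"
  )
}

sym_decorrelate <- function(W) {
  # W <- (W W')^{-1/2} W
  sv <- eigen(tcrossprod(W), symmetric = TRUE)
  sv$vectors %*% diag(1 / sqrt(sv$values), nrow(W)) %*% t(sv$vectors) %*% W
}

#' @export
print.ica_fit <- function(x, ...) {
  cat(sprintf(
    "<ica_fit> %d component(s) from %d channel(s); %s orthogonalisation, %s(a1=%g), seed %d\n",
    nrow(x$W), length(x$whitening$mean), x$ortho, x$nl$name, x$nl$a1, x$seed
  ))
  cat(sprintf("  converged: %d/%d (tol %g, max_iter %d)\n",
              sum(x$converged), length(x$converged), x$tol, x$max_iter))
  invisible(x)
}

#' Recover source components from a fitted unmixing model
#'
#' Applies centering, whitening and the unmixing rows:
#' `S = W V (X - mean)`. Rows are ordered by extraction order and have unit
#' variance on the training data (the whitened-space convention); source
#' scale is not identifiable.
#'
#' @param model an `ica_fit`.
#' @param data channels x samples matrix or `recording` with the same
#'   channel count the model was fitted on.
#' @return Components matrix (n_components x samples), or a `recording` of
#'   components when `data` is a `recording`.
#' @export
unmix <- function(model, data) {
  stopifnot(inherits(model, "ica_fit"))
  rec <- NULL
  if (inherits(data, "recording")) { rec <- data; data <- data$data }
  S <- model$W %*% whiten(model$whitening, data)
  if (!is.null(rec)) {
    return(recording(S, fs = rec$fs,
                     channel_names = paste0("IC", seq_len(nrow(S))),
                     t0 = rec$t0))
  }
  S
}

#' Estimated mixing matrix of a fitted model
#'
#' The Moore–Penrose pseudo-inverse of the full unmixing transform `W V`,
#' mapping components back to (centered) channel space.
#'
#' @param model an `ica_fit`.
#' @return channels x components matrix.
#' @export
mixing_matrix <- function(model) {
  stopifnot(inherits(model, "ica_fit"))
  pracma::pinv(model$W %*% model$whitening$V)
}

#' Amari performance index of an unmixing solution
#'
#' Measures how far `P = (W V) A_true` is from a scaled permutation — the
#' residual indeterminacy of a perfect separation. For each row the absolute
#' entries are summed and divided by the row maximum (and likewise for
#' columns); the index is the normalised excess over 1, so it is 0 exactly
#' when `P` is a scaled permutation and at most 1.
#'
#' @param WV estimated unmixing transform (components x channels), e.g.
#'   `model$W %*% model$whitening$V`.
#' @param A_true true mixing matrix (channels x sources); `WV %*% A_true`
#'   must be square.
#' @return Scalar in `[0, 1]`.
#' @export
amari_index <- function(WV, A_true) {
  P <- abs(WV %*% A_true)
  if (nrow(P) != ncol(P)) {
    stop("product of unmixing and mixing must be square, got ",
         nrow(P), " x ", ncol(P))
  }
  n <- nrow(P)
  row_term <- sum(rowSums(P) / apply(P, 1, max) - 1)
  col_term <- sum(colSums(P) / apply(P, 2, max) - 1)
  (row_term + col_term) / (2 * n * (n - 1))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy an ICA fit
#'
#' @param x an `ica_fit`.
#' @param data optional channels x samples matrix; when supplied, each
#'   component's negentropy contrast on those data is added.
#' @param ... unused.
#' @return One row per component: `component`, `n_iter`, `converged`, and
#'   `contrast` when `data` is given.
#' @method tidy ica_fit
#' @export
tidy.ica_fit <- function(x, data = NULL, ...) {
  out <- tibble::tibble(
    component = paste0("IC", seq_len(nrow(x$W))),
    n_iter = x$n_iter,
    converged = x$converged
  )
  if (!is.null(data)) {
    if (inherits(data, "recording")) data <- data$data
    Z <- whiten(x$whitening, data)
    out$contrast <- vapply(seq_len(nrow(x$W)), function(k) {
      negentropy_contrast(x$W[k, ], Z, x$nl)
    }, numeric(1))
  }
  out
}

#' @rdname tidy.ica_fit
#' @method glance ica_fit
#' @export
glance.ica_fit <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$W),
    n_channels = length(x$whitening$mean),
    n_converged = sum(x$converged),
    max_iter_used = max(x$n_iter),
    nonlinearity = x$nl$name,
    a1 = x$nl$a1,
    tol = x$tol,
    ortho = x$ortho,
    seed = x$seed
  )
}

#' Serialise / restore an ICA fit as JSON
#'
#' Stores the centering vector, whitening matrix, unmixing rows and all
#' settings in a plain JSON file.
#'
#' @param model an `ica_fit`.
#' @param path output / input JSON path.
#' @return [write_ica()] returns `path` invisibly; [read_ica()] an `ica_fit`.
#' @export
write_ica <- function(model, path) {
  stopifnot(inherits(model, "ica_fit"))
  wm <- model$whitening
  jsonlite::write_json(
    list(
      mean = wm$mean, E = wm$E, D = wm$D, V = wm$V, n_keep = wm$n_keep,
      W = model$W, n_iter = model$n_iter, converged = model$converged,
      nonlinearity = model$nl$name, a1 = model$nl$a1,
      tol = model$tol, max_iter = model$max_iter, seed = model$seed,
      ortho = model$ortho
    ),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_ica
#' @export
read_ica <- function(path) {
  j <- jsonlite::fromJSON(path)
  wm <- structure(
    list(mean = j$mean, E = as.matrix(j$E), D = j$D, V = as.matrix(j$V),
         n_keep = j$n_keep),
    class = "whitening_model"
  )
  structure(
    list(whitening = wm, W = as.matrix(j$W), n_iter = j$n_iter,
         converged = j$converged, nl = nonlinearity(j$nonlinearity, j$a1),
         tol = j$tol, max_iter = j$max_iter, seed = j$seed, ortho = j$ortho),
    class = "ica_fit"
  )
}
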
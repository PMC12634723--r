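#' Quadratic feature expansion for the LLGMN
#'
#' The log of a Gaussian density is a quadratic form in the input, so the
#' log-linearized Gaussian mixture network operates on the expanded vector
#' `(1, x_1..x_D, x_i * x_j for i <= j)`, of length `1 + D + D(D+1)/2`.
#' Log-linear weights over this basis can represent any Gaussian component
#' (prior, mean and full covariance) exactly.
#'
#' @param x numeric vector of length D; all components must be finite.
#' @return expanded numeric vector.
#' @export
llgmn_expand <- function(x) {
  if (any(!is.finite(x))) stop("non-finite input")
  d <- length(x)
  cross <- numeric(d * (d + 1) / 2)
  k <- 1L
  for (i in seq_len(d)) {
    for (j in i:d) {
      cross[k] <- x[i] * x[j]
      k <- k + 1L
    }
  }
  c(1, x, cross)
}

#' Length of the expanded feature vector for input dimension D
#' @param d input dimension.
#' @export
llgmn_expanded_dim <- function(d) as.integer(1 + d + d * (d + 1) / 2)

#' Construct an LLGMN model
#'
#' The model holds one weight vector over the expanded features per
#' (class, component) pair; the last pair is pinned to zero for
#' identifiability (a global softmax is invariant to a common shift).
#'
#' @param input_dim D, dimension of the raw input vector.
#' @param classes character vector of class names (M >= 2).
#' @param n_components K, mixture components per class.
#' @param weights optional numeric array `(H, K, M)` with
#'   `H = llgmn_expanded_dim(input_dim)`; defaults to all zeros.
#' @return an object of class `llgmn`.
#' @export
llgmn_model <- function(input_dim, classes = c("hold", "release"),
                        n_components = 1L, weights = NULL) {
  h <- llgmn_expanded_dim(input_dim)
  m <- length(classes)
  k <- as.integer(n_components)
  if (m < 1L) stop("need at least one class")
  if (is.null(weights)) weights <- array(0, dim = c(h, k, m))
  weights <- array(as.numeric(weights), dim = c(h, k, m))
  weights[, k, m] <- 0  # reference pair pinned for identifiability
  structure(
    list(input_dim = as.integer(input_dim), classes = classes,
         n_components = k, weights = weights),
    class = "llgmn"
  )
}

#' @export
print.llgmn <- function(x, ...) {
  cat(sprintf("<llgmn> D=%d, classes=[%s], K=%d, %d free weights\n",
              x$input_dim, paste(x$classes, collapse = ", "),
              x$n_components,
              length(x$weights) - dim(x$weights)[1]))
  invisible(x)
}

# per-(class,component) softmax responsibilities and class posteriors
llgmn_forward_full <- function(model, x) {
  if (length(x) != model$input_dim) stop("input dimension mismatch")
  xe <- llgmn_expand(x)
  w <- model$weights
  scores <- apply(w, c(2, 3), function(wv) sum(wv * xe))  # K x M
  scores <- scores - max(scores)                           # overflow guard
  e <- exp(scores)
  r <- e / sum(e)
  list(resp = r, posterior = colSums(r))
}

#' Class posterior for one input
#'
#' Component scores are the inner products of the weights with the expanded
#' input; they are exponentiated and normalized over all (class, component)
#' pairs, and a class posterior is the sum of its components' normalized
#' scores.
#'
#' @param model an `llgmn` model.
#' @param x numeric input vector of length `model$input_dim`.
#' @return named numeric vector of class probabilities summing to 1.
#' @export
llgmn_forward <- function(model, x) {
  p <- llgmn_forward_full(model, x)$posterior
  names(p) <- model$classes
  p
}

#' Train an LLGMN by full-batch gradient ascent on the log-likelihood
#'
#' Weights are initialized at zero for K = 1 (the fit is then deterministic
#' without randomness) or with small seeded Gaussian noise for K > 1 to break
#' component symmetry. Training stops after `epochs` passes or when the
#' epoch log-likelihood improves by less than `tol`.
#'
#' @param x numeric matrix, one row per sample.
#' @param y vector of class labels; every class in `classes` must appear.
#' @param classes class names; defaults to the sorted unique labels.
#' @param n_components K per class.
#' @param lr learning rate.
#' @param epochs maximum epochs.
#' @param tol early-stopping threshold on log-likelihood gain.
#' @param seed RNG seed for the K > 1 initialization.
#' @return a trained `llgmn` with attribute `loglik` (per-epoch trace).
#' @export
llgmn_train <- function(x, y, classes = NULL, n_components = 1L,
                        lr = 0.05, epochs = 500L, tol = 1e-8, seed = 1L) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite features")
  if (is.null(classes)) classes <- sort(unique(as.character(y)))
  y <- as.character(y)
  if (!all(y %in% classes)) stop("labels outside `classes`")
  if (any(!(classes %in% y))) stop("a class with zero samples")
  n <- nrow(x); d <- ncol(x); m <- length(classes); k <- as.integer(n_components)
  h <- llgmn_expanded_dim(d)
  xe <- t(apply(x, 1L, llgmn_expand))                      # n x h
  yi <- match(y, classes)

  w <- if (k > 1L)
    array(withr_seed(seed, stats::rnorm(h * k * m, sd = 0.01)), dim = c(h, k, m))
  else array(0, dim = c(h, k, m))
  w[, k, m] <- 0

  wmat <- matrix(w, nrow = h)                              # h x (k*m)
  cls_of <- rep(seq_len(m), each = k)                      # class of each column
  batch_eval <- function(wm) {
    s <- xe %*% wm                                         # n x (k*m)
    s <- s - apply(s, 1L, max)
    e <- exp(s)
    r <- e / rowSums(e)                                    # responsibilities
    post <- vapply(seq_len(m), function(mm)
      rowSums(r[, cls_of == mm, drop = FALSE]), numeric(n))
    p_true <- post[cbind(seq_len(n), yi)]
    list(r = r, p_true = p_true, ll = sum(log(pmax(p_true, 1e-300))))
  }
  ll_trace <- numeric(0)
  cur <- batch_eval(wmat)
  for (ep in seq_len(epochs)) {
    ll_trace <- c(ll_trace, cur$ll)
    # dL/ds_{n,(m,k)} = 1{y_n=m} r/post_true - r
    r <- cur$r
    target <- r
    for (col in seq_len(ncol(r))) {
      mm <- cls_of[col]
      target[, col] <- ifelse(yi == mm, r[, col] / pmax(cur$p_true, 1e-300), 0)
    }
    grad <- t(xe) %*% (target - r) / n                     # h x (k*m)
    # backtracking step: halve the rate while the log-likelihood would drop
    step <- lr
    repeat {
      wnew <- wmat + step * grad
      wnew[, k * m] <- 0                                   # keep reference pinned
      nxt <- batch_eval(wnew)
      if (nxt$ll >= cur$ll || step < 1e-12) break
      step <- step / 2
    }
    if (nxt$ll - cur$ll < tol) { wmat <- wnew; cur <- nxt; break }
    wmat <- wnew
    cur <- nxt
  }
  ll_trace <- c(ll_trace, cur$ll)
  model <- llgmn_model(d, classes, k, array(wmat, dim = c(h, k, m)))
  attr(model, "loglik") <- ll_trace
  model
}

#' Predict class labels for a matrix of inputs
#'
#' Ties at equal posterior are broken toward `tie_break` (by default
#' "release": hold time is not accrued on ambiguity).
#'
#' @param object a trained `llgmn`.
#' @param x matrix of inputs, one row each.
#' @param tie_break class favoured at exact posterior ties.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.llgmn <- function(object, x, tie_break = "release", ...) {
  x <- as.matrix(x)
  apply(x, 1L, function(row) {
    p <- llgmn_forward(object, row)
    top <- which(p == max(p))
    if (length(top) > 1L && tie_break %in% names(p)[top]) tie_break
    else names(p)[top[1L]]
  })
}

#' Build LLGMN weights from explicit Gaussian components
#'
#' Maps a Gaussian mixture (per-class priors, means, covariances) into
#' log-linear weights over the quadratic expansion, so that the network
#' posterior equals the Bayes posterior of the generative model exactly.
#' Used to validate the forward pass against direct density evaluation and
#' to seed models from fitted mixtures.
#'
#' @param priors list (per class) of numeric component prior vectors
#'   (overall mixing proportions; need not be normalized per class).
#' @param means list (per class) of matrices, one component mean per row.
#' @param covs list (per class) of lists of covariance matrices.
#' @param classes class names.
#' @return an `llgmn` model.
#' @export
llgmn_from_gaussians <- function(priors, means, covs, classes) {
  m <- length(classes)
  d <- ncol(as.matrix(means[[1]]))
  h <- llgmn_expanded_dim(d)
  k <- max(vapply(priors, length, 1L))
  w <- array(0, dim = c(h, k, m))
  for (mm in seq_len(m)) {
    mu_m <- as.matrix(means[[mm]])
    for (kk in seq_along(priors[[mm]])) {
      mu <- mu_m[kk, ]
      sig <- covs[[mm]][[kk]]
      si <- solve(sig)
      a <- -0.5 * si                                       # quadratic coeff
      b <- si %*% mu                                       # linear coeff
      c0 <- log(priors[[mm]][kk]) - 0.5 * (d * log(2 * pi) +
            determinant(sig, logarithm = TRUE)$modulus[1] +
            drop(t(mu) %*% si %*% mu))
      # expanded basis stores x_i x_j once for i <= j: off-diagonal terms
      # of the symmetric quadratic form contribute twice
      quad <- numeric(d * (d + 1) / 2)
      pos <- 1L
      for (i in seq_len(d)) {
        for (j in i:d) {
          quad[pos] <- if (i == j) a[i, i] else 2 * a[i, j]
          pos <- pos + 1L
        }
      }
      w[, kk, mm] <- c(c0, as.numeric(b), quad)
    }
  }
  # shift so the reference pair is zero (softmax-invariant)
  w <- w - array(rep(w[, k, m], k * m), dim = c(h, k, m))
  llgmn_model(d, classes, k, w)
}

#' Serialize / deserialize an LLGMN model as JSON
#'
#' The JSON document stores shape metadata and a flat weight list in full
#' double precision; a write/read round trip reproduces the weights exactly.
#'
#' @param model an `llgmn`.
#' @param path file path.
#' @export
write_llgmn <- function(model, path) {
  doc <- list(input_dim = model$input_dim, classes = model$classes,
              n_components = model$n_components,
              weights = as.numeric(model$weights))
  # 17 significant digits reproduce every double exactly on re-parse
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_llgmn
#' @export
read_llgmn <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  llgmn_model(doc$input_dim, doc$classes, doc$n_components, doc$weights)
}
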
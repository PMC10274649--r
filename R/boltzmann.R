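# Fully visible Boltzmann model of motif presence given lectin features.
#
# The conditional log P(m | l) = sum_i A_i m_i + sum_ij m_i C_ij l_j - F(l)
# contains no motif-motif couplings, so it factorizes into independent
# per-motif logistic units with the closed-form normalizer
# F(l) = sum_i log(1 + exp(A_i + C_i . l)).  The log-likelihood is concave,
# so all training runs converge to the same optimum.

.softplus <- function(x) {
  # numerically stable log(1 + exp(x)), branch-free
  pmax(x, 0) + log1p(exp(-abs(x)))
}

.boltz_eta <- function(A, C, L) {
  eta <- L %*% t(C)
  eta + rep(A, each = nrow(eta))
}

.boltz_loss <- function(A, C, M, L, l2 = 0, eta = NULL) {
  if (is.null(eta)) eta <- .boltz_eta(A, C, L)
  # mean negative log-likelihood (nats per observation)
  nll <- (sum(.softplus(eta)) - sum(M * eta)) / nrow(M)
  nll + l2 * (sum(A^2) + sum(C^2)) / (2 * nrow(M))
}

#' Train the Boltzmann model
#'
#' Maximizes the mean conditional log-likelihood of the observed motif
#' vectors given lectin features by full-batch gradient ascent with step
#' size 0.1 and step-halving backtracking whenever a step would increase
#' the loss. The objective is concave; runs from any initialization reach
#' the same optimum.
#'
#' @param M Binary motif matrix (observations x motifs).
#' @param L Binary feature matrix (observations x features), row-aligned
#'   with `M`; a `feature_matrix` object is also accepted.
#' @param step Gradient step size (default 0.1).
#' @param max_iter Iteration cap (default 10000). On separable (noiseless)
#'   data weights diverge and the cap applies; candidate ordering is
#'   invariant to the cap.
#' @param tol Stop when the loss decreases by less than this (default 0,
#'   i.e. rely on the gradient criterion).
#' @param gtol Stop when the max absolute mean gradient falls below this
#'   (default 1e-7).
#' @param l2 Optional L2 penalty (default 0; regularization makes no
#'   meaningful difference on these data).
#' @param init Optional list with `A` (length K) and `C` (K x J) starting
#'   values; default zeros.
#' @param method `"gd"` for plain gradient ascent (default), `"nesterov"`
#'   for accelerated gradient ascent with adaptive restart, or `"newton"`
#'   for guarded per-motif Newton (IRLS) steps that exploit the
#'   factorization into independent logistic units. All methods converge
#'   to the same unique optimum of the concave objective; they differ only
#'   in iteration count.
#' @return A `boltzmann_params` object: list with bias vector `A`, weight
#'   matrix `C` (motifs x features), `loss` (final mean negative
#'   log-likelihood, nats), `iterations`, `converged`, `grad_max` and the
#'   motif/feature names.
#' @export
boltzmann_train <- function(M, L, step = 0.1, max_iter = 10000L, tol = 0,
                            gtol = 1e-7, l2 = 0, init = NULL,
                            method = c("gd", "nesterov", "newton")) {
  method <- match.arg(method)
  if (inherits(L, "feature_matrix")) L <- L$bits
  M <- as.matrix(M); L <- as.matrix(L)
  stopifnot(nrow(M) == nrow(L), nrow(M) >= 1L)
  n <- nrow(M); K <- ncol(M); J <- ncol(L)
  # motifs with identical presence patterns are identical independent
  # logistic units: train each distinct pattern once and expand (exact)
  key <- apply(M, 2, paste, collapse = "")
  if (anyDuplicated(key)) {
    uniq <- which(!duplicated(key))
    map <- match(key, key[uniq])
    init_u <- if (is.null(init)) NULL else {
      list(A = as.numeric(init$A)[uniq],
           C = matrix(as.numeric(init$C), K, J)[uniq, , drop = FALSE])
    }
    fit <- boltzmann_train(M[, uniq, drop = FALSE], L, step = step,
                           max_iter = max_iter, tol = tol, gtol = gtol,
                           l2 = l2, init = init_u, method = method)
    fit$A <- fit$A[map]
    fit$C <- fit$C[map, , drop = FALSE]
    fit$motif_ids <- colnames(M)
    fit$loss <- .boltz_loss(fit$A, fit$C, M, L, l2)
    return(fit)
  }
  A <- if (is.null(init)) rep(0, K) else as.numeric(init$A)
  C <- if (is.null(init)) matrix(0, K, J) else matrix(as.numeric(init$C), K, J)
  if (method == "newton") {
    return(.boltz_newton(M, L, A, C, max_iter, gtol, l2))
  }
  grad_at <- function(A, C) {
    R <- M - stats::plogis(.boltz_eta(A, C, L))
    gA <- colMeans(R) - l2 * A / n
    gC <- crossprod(R, L) / n - l2 * C / n
    if (any(!is.finite(gA)) || any(!is.finite(gC))) {
      stop("non-finite gradient (loss = ", format(.boltz_loss(A, C, M, L, l2)), ")")
    }
    list(gA = gA, gC = gC)
  }
  loss <- .boltz_loss(A, C, M, L, l2)
  grad_max <- Inf
  it <- 0L
  yA <- A; yC <- C  # lookahead point (nesterov)
  mom <- 0
  while (it < max_iter) {
    it <- it + 1L
    g <- grad_at(yA, yC)
    if (method == "gd") {
      grad_max <- max(abs(g$gA), abs(g$gC))
    } else if (it %% 10L == 1L) {  # periodic check at the iterate itself
      gx <- grad_at(A, C)
      grad_max <- max(abs(gx$gA), abs(gx$gC))
    }
    if (grad_max < gtol) { it <- it - 1L; break }
    s <- step
    repeat {
      A2 <- yA + s * g$gA
      C2 <- yC + s * g$gC
      loss2 <- .boltz_loss(A2, C2, M, L, l2)
      if (loss2 <= loss || s < step / 2^20) break
      s <- s / 2
    }
    if (method == "nesterov") {
      if (loss2 > loss) {  # adaptive restart: drop momentum
        mom <- 0
        yA <- A; yC <- C
        next
      }
      mom <- mom + 1
      beta <- (mom - 1) / (mom + 2)
      yA <- A2 + beta * (A2 - A)
      yC <- C2 + beta * (C2 - C)
    }
    dloss <- loss - loss2
    A <- A2; C <- C2; loss <- loss2
    if (method == "gd") { yA <- A; yC <- C }
    if (tol > 0 && dloss >= 0 && dloss < tol) break
  }
  converged <- grad_max < gtol
  if (!converged && it >= max_iter) {
    warning(sprintf("gradient ascent stopped at max_iter = %d (max |grad| = %.3g)",
                    max_iter, grad_max))
  }
  structure(list(A = as.numeric(A), C = C, loss = loss, iterations = it,
                 converged = converged, grad_max = grad_max,
                 motif_ids = colnames(M), feature_names = colnames(L)),
            class = "boltzmann_params")
}

# guarded Newton/IRLS over the K independent logistic units; backtracks on
# loss increase, so it is monotone and safe under separable data (where the
# iteration cap applies, as for gradient ascent)
.boltz_newton <- function(M, L, A, C, max_iter, gtol, l2) {
  n <- nrow(M); K <- ncol(M); J <- ncol(L)
  X <- cbind(1, L)
  grad_max_all <- 0
  total_it <- 0L
  capped <- FALSE
  for (k in seq_len(K)) {
    m <- M[, k]
    th <- c(A[k], C[k, ])
    eta <- as.numeric(X %*% th)
    nll <- (sum(.softplus(eta)) - sum(m * eta)) / n + l2 * sum(th^2) / (2 * n)
    it <- 0L
    gmax <- Inf
    while (it < max_iter) {
      it <- it + 1L
      p <- stats::plogis(eta)
      g <- as.numeric(crossprod(X, m - p)) / n - l2 * th / n
      gmax <- max(abs(g))
      if (gmax < gtol) { it <- it - 1L; break }
      w <- pmax(p * (1 - p), 1e-10)
      H <- crossprod(X * w, X) / n
      diag(H) <- diag(H) + l2 / n + 1e-12
      dir <- tryCatch(solve(H, g), error = function(e) g)
      s <- 1
      repeat {
        th2 <- th + s * dir
        eta2 <- as.numeric(X %*% th2)
        nll2 <- (sum(.softplus(eta2)) - sum(m * eta2)) / n +
          l2 * sum(th2^2) / (2 * n)
        if (nll2 <= nll || s < 2^-30) break
        s <- s / 2
      }
      th <- th2; eta <- eta2; nll <- nll2
    }
    if (it >= max_iter && gmax >= gtol) capped <- TRUE
    total_it <- max(total_it, it)
    grad_max_all <- max(grad_max_all, gmax)
    A[k] <- th[1]; C[k, ] <- th[-1]
  }
  if (capped) {
    warning(sprintf("Newton stopped at max_iter = %d for some motifs (max |grad| = %.3g)",
                    max_iter, grad_max_all))
  }
  structure(list(A = as.numeric(A), C = C,
                 loss = .boltz_loss(A, C, M, L, l2),
                 iterations = total_it, converged = grad_max_all < gtol,
                 grad_max = grad_max_all,
                 motif_ids = colnames(M), feature_names = colnames(L)),
            class = "boltzmann_params")
}

#' @export
print.boltzmann_params <- function(x, ...) {
  cat("<boltzmann_params> ", length(x$A), " motifs x ", ncol(x$C),
      " features; loss ", format(x$loss, digits = 6), " after ",
      x$iterations, " iterations",
      if (x$converged) " (converged)" else "", "\n", sep = "")
  invisible(x)
}

.check_feature_vec <- function(params, l) {
  l <- as.numeric(l)
  if (length(l) != ncol(params$C)) {
    stop("feature vector length ", length(l), " does not match schema (",
         ncol(params$C), " features)")
  }
  l
}

#' Per-motif posterior probabilities for a lectin profile
#'
#' `p_i = sigmoid(A_i + sum_j C_ij l_j)`.
#'
#' @param params A `boltzmann_params` object.
#' @param l Binary feature vector for one observation.
#' @return Numeric vector of motif probabilities in (0, 1).
#' @export
motif_posterior <- function(params, l) {
  l <- .check_feature_vec(params, l)
  p <- stats::plogis(params$A + as.numeric(params$C %*% l))
  names(p) <- params$motif_ids
  p
}

#' Log-likelihood of motif vectors given a lectin profile
#'
#' `log P(m | l) = sum_i m_i (A_i + C_i . l) - F(l)` with the closed-form
#' normalizer `F(l) = sum_i log(1 + exp(A_i + C_i . l))`; this is the exact
#' log-probability of the full motif vector (present and absent motifs)
#' under the factorized model, in nats.
#'
#' @param params A `boltzmann_params` object.
#' @param l Binary feature vector for one observation.
#' @param M Binary motif vector, or a matrix of motif vectors (rows).
#' @return Numeric vector of log-probabilities, one per row of `M`.
#' @export
glycan_loglik <- function(params, l, M) {
  l <- .check_feature_vec(params, l)
  theta <- params$A + as.numeric(params$C %*% l)
  F_l <- sum(.softplus(theta))
  M <- if (is.matrix(M)) M else matrix(M, nrow = 1)
  as.numeric(M %*% theta) - F_l
}

#' Rank candidate glycans for a lectin profile
#'
#' Sorts the candidate pool by `log P(m(glycan) | l)` descending; ties are
#' broken by canonical structure string ascending.
#'
#' @param params A `boltzmann_params` object.
#' @param l Binary feature vector for the profile.
#' @param pool Candidate pool tibble (from [build_candidate_pool()] or a
#'   corpus tibble).
#' @param catalog Motif catalog used to compute candidate motif vectors.
#' @param M Optional precomputed motif matrix for `pool` (rows aligned),
#'   to amortize enumeration across many profiles.
#' @param top_n Optionally truncate the ranking to the best `top_n`.
#' @return Tibble `rank`, `glycan_id`, `structure`, `loglik` (ordered).
#' @export
rank_candidates <- function(params, l, pool, catalog, M = NULL, top_n = NULL) {
  if (!nrow(pool)) stop("empty candidate pool")
  if (is.null(M)) M <- motif_matrix(pool, catalog)
  ll <- glycan_loglik(params, l, M)
  ord <- order(-ll, pool$structure, method = "radix")
  out <- tibble::tibble(rank = seq_along(ord),
                        glycan_id = pool$glycan_id[ord],
                        structure = pool$structure[ord],
                        loglik = ll[ord])
  if (!is.null(top_n)) out <- out[seq_len(min(top_n, nrow(out))), , drop = FALSE]
  out
}

# rank of one candidate structure without materializing the full ordering
.rank_of <- function(ll, structures, true_structure) {
  i <- match(true_structure, structures)
  if (is.na(i)) return(NA_integer_)
  ahead <- sum(ll > ll[i]) +
    sum(ll == ll[i] & structures < true_structure)
  ahead + 1L
}

#' Write Boltzmann parameters to JSON
#'
#' @param params A `boltzmann_params` object.
#' @param path Output path.
#' @param meta Optional named list of training metadata to embed.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path, meta = list()) {
  jsonlite::write_json(list(motif_ids = params$motif_ids,
                            feature_names = params$feature_names,
                            A = params$A,
                            C = apply(params$C, 1, identity, simplify = FALSE),
                            loss = params$loss,
                            iterations = params$iterations,
                            meta = meta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read Boltzmann parameters from JSON
#'
#' @param path File path.
#' @return A `boltzmann_params` object.
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  C <- if (is.list(x$C)) do.call(rbind, x$C) else matrix(x$C, nrow = length(x$A))
  structure(list(A = x$A, C = C, loss = x$loss, iterations = x$iterations,
                 converged = NA, grad_max = NA_real_,
                 motif_ids = x$motif_ids, feature_names = x$feature_names),
            class = "boltzmann_params")
}
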
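#' ELM hyperparameters
#'
#' @param L hidden-neuron count (>= 1).
#' @param activation activation function; only `"sigmoid"` (logistic) is used.
#' @param seed RNG seed for the random hidden layer.
#' @param ridge ridge regularization >= 0; `0` solves the least-squares
#'   problem by SVD pseudo-inverse, `> 0` solves
#'   `(H'H + ridge I)^-1 H'O` (useful for conditioning large hidden layers).
#' @return an object of class `elm_params`.
#' @export
elm_params <- function(L, activation = "sigmoid", seed = 1L, ridge = 0) {
  if (!is_scalar_num(L) || L < 1) stop_validation("L must be >= 1")
  activation <- match.arg(activation)
  if (!is_scalar_num(ridge) || ridge < 0) stop_validation("ridge must be >= 0")
  structure(list(L = as.integer(L), activation = activation,
                 seed = as.integer(seed), ridge = ridge),
            class = "elm_params")
}

#' Random hidden layer of an ELM
#'
#' Input weights and biases are drawn i.i.d. uniform on `[-1, 1]` from the
#' seeded RNG and are never trained afterwards.  Deterministic given the seed;
#' the caller's RNG state is left untouched.
#'
#' @param n input dimension.
#' @param params an [elm_params()].
#' @return list with `W` (`L x n`) and `b` (length `L`).
#' @export
elm_init_hidden <- function(n, params) {
  if (!is_scalar_num(n) || n < 1) stop_validation("input dimension must be >= 1")
  with_seed(params$seed, {
    W <- matrix(runif(params$L * n, -1, 1), nrow = params$L, ncol = n)
    b <- runif(params$L, -1, 1)
    list(W = W, b = b)
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Hidden-layer output matrix
#'
#' `H[j, i] = g(w_i . s_j + b_i)` with the logistic sigmoid `g`.
#'
#' @param hidden list with `W` (`L x n`) and `b` (an [elm_init_hidden()]
#'   result or a fitted `elm` model).
#' @param S input matrix, `N x n`.
#' @return `N x L` matrix.
#' @export
elm_hidden <- function(hidden, S) {
  S <- as.matrix(S)
  if (ncol(S) != ncol(hidden$W))
    stop("input dimension ", ncol(S), " does not match hidden layer (",
         ncol(hidden$W), ")")
  sigmoid(sweep(S %*% t(hidden$W), 2L, hidden$b, "+"))
}

# Moore-Penrose pseudo-inverse by SVD with relative cutoff
pinv_svd <- function(H, tol = 1e-12) {
  sv <- svd(H)
  keep <- sv$d > tol * sv$d[1L]
  if (!any(keep)) return(matrix(0, ncol(H), nrow(H)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Fit an ELM by Moore-Penrose pseudo-inverse
#'
#' The hidden layer is random and fixed; only the output weights are solved,
#' as the minimum-norm least-squares solution `B = H^+ O` (SVD pseudo-inverse)
#' or the ridge solution when `params$ridge > 0`.
#'
#' @param S input matrix, `N x n`.
#' @param O target matrix, `N x m` (a vector is treated as one column).
#' @param params an [elm_params()].
#' @param hidden optional pre-built hidden layer (shared across fits); built
#'   from `params` when omitted.
#' @return an object of class `elm`: list with `W`, `b`, `B`, `params`.
#' @export
elm_fit <- function(S, O, params, hidden = NULL) {
  S <- as.matrix(S)
  O <- as.matrix(O)
  if (nrow(S) < 1L) stop_validation("need at least one training instance")
  if (nrow(S) != nrow(O)) stop_validation("S and O must have the same number of rows")
  if (any(!is.finite(S)) || any(!is.finite(O)))
    stop_validation("non-finite training values")
  if (is.null(hidden)) hidden <- elm_init_hidden(ncol(S), params)
  H <- elm_hidden(hidden, S)
  B <- if (params$ridge > 0) {
    A <- crossprod(H)
    diag(A) <- diag(A) + params$ridge
    solve(A, crossprod(H, O))
  } else {
    pinv_svd(H) %*% O
  }
  structure(list(W = hidden$W, b = hidden$b, B = B, params = params),
            class = "elm")
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("<elm> %d inputs -> %d hidden (sigmoid) -> %d outputs, ridge=%g\n",
              ncol(x$W), nrow(x$W), ncol(x$B), x$params$ridge))
  invisible(x)
}

#' Predict with a fitted ELM
#' @param object a fitted `elm`.
#' @param newdata input matrix, `N x n`.
#' @param ... unused.
#' @return `N x m` output matrix.
#' @export
predict.elm <- function(object, newdata, ...) {
  elm_hidden(object, as.matrix(newdata)) %*% object$B
}

#' Save / load a fitted ELM
#' @param model a fitted `elm`.
#' @param path file path.
#' @return `read_elm` returns the model; `write_elm` returns `path` invisibly.
#' @export
write_elm <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  structure(readRDS(path), class = "elm")
}
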
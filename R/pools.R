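#' Fixed-capacity labelled sample pool
#'
#' Holds the feature vectors of one class: `S_pre` (preictal) or `S_inter`
#' (interictal).  Updates never change the capacity; every retained sample
#' comes from the union of the old pool and the observed set.
#'
#' @param features numeric matrix, one feature vector per row.
#' @param capacity maximum number of samples the pool may hold.
#' @param role `"pre"` or `"inter"`.
#' @return object of class `sample_pool` (fields `features`, `capacity`,
#'   `role`, `age`; lower age = older sample).
#' @export
sample_pool <- function(features, capacity = nrow(features), role = c("pre", "inter")) {
  role <- match.arg(role)
  features <- as.matrix(features)
  if (nrow(features) < 1L || nrow(features) > capacity)
    stop_validation("pool size must satisfy 0 < n <= capacity")
  if (any(!is.finite(features))) stop_validation("pool features must be finite")
  structure(list(features = features, capacity = as.integer(capacity),
                 role = role, age = seq_len(nrow(features))),
            class = "sample_pool")
}

#' @export
print.sample_pool <- function(x, ...) {
  cat(sprintf("<sample_pool:%s> %d/%d samples, dim %d\n",
              x$role, nrow(x$features), x$capacity, ncol(x$features)))
  invisible(x)
}

#' Mean, covariance and regularized inverse covariance of a pool
#'
#' The covariance uses the sample (`n - 1`) denominator.  Its inverse is
#' regularized with a ridge `eps = 1e-6 * trace(sigma) / dim`; when the trace
#' is zero (all samples identical) the Moore-Penrose pseudo-inverse is used
#' instead.
#'
#' @param pool a `sample_pool` or a feature matrix with >= 2 rows.
#' @return object of class `pool_stats` (fields `mu`, `sigma`, `sigma_inv`,
#'   `eps`).
#' @export
pool_stats <- function(pool) {
  X <- if (inherits(pool, "sample_pool")) pool$features else as.matrix(pool)
  if (nrow(X) < 2L) stop_validation("need at least 2 samples for pool statistics")
  mu <- colMeans(X)
  sigma <- stats::cov(X)
  tr <- sum(diag(sigma))
  if (tr > 0) {
    eps <- 1e-6 * tr / ncol(X)
    sigma_inv <- solve(sigma + diag(eps, ncol(X)))
  } else {
    eps <- 0
    sigma_inv <- MASS::ginv(sigma)
  }
  structure(list(mu = mu, sigma = sigma, sigma_inv = sigma_inv, eps = eps),
            class = "pool_stats")
}

#' Mahalanobis distance of one point to a pool
#'
#' `sqrt((x - mu)' sigma_inv (x - mu))`.  The square root of the printed
#' quadratic form is taken so the quantity is a distance; comparisons and
#' sorting are monotone in either convention.
#'
#' @param x numeric feature vector.
#' @param stats a [pool_stats()].
#' @return non-negative scalar distance.
#' @export
mahal_point <- function(x, stats) {
  x <- as.numeric(x)
  if (length(x) != length(stats$mu)) stop("dimension mismatch")
  d <- x - stats$mu
  sqrt(max(0, drop(t(d) %*% stats$sigma_inv %*% d)))
}

# vectorized over rows; identical to mahal_point per row
mahal_points <- function(X, stats) {
  X <- as.matrix(X)
  q <- stats::mahalanobis(X, stats$mu, stats$sigma_inv, inverted = TRUE)
  sqrt(pmax(0, q))
}

#' Mahalanobis distance of a sample set to a pool
#'
#' Set-to-pool distance is the arithmetic mean of the point distances of the
#' set's samples.
#'
#' @param S matrix of observed feature vectors (rows), or a `sample_pool`.
#' @param stats a [pool_stats()].
#' @return non-negative scalar.
#' @export
mahal_set <- function(S, stats) {
  X <- if (inherits(S, "sample_pool")) S$features else as.matrix(S)
  if (nrow(X) < 1L) stop_validation("empty observed set")
  mean(mahal_points(X, stats))
}

#' Abnormality test for an observed sample set
#'
#' The observed set is *normal* when its distance to the preictal pool
#' strictly exceeds `lam` times its distance to the interictal pool, and
#' *abnormal* otherwise (equality counts as abnormal).  Only normal sets may
#' enter the interictal pool.
#'
#' @param S observed feature matrix (rows = samples).
#' @param pre,inter the preictal and interictal `sample_pool`s.
#' @param lam non-negative threshold multiplier (default 1).
#' @return `TRUE` if abnormal.
#' @export
is_abnormal <- function(S, pre, inter, lam = 1) {
  if (!is_scalar_num(lam) || lam < 0) stop_validation("lam must be >= 0")
  d_pre <- mahal_set(S, pool_stats(pre))
  d_inter <- mahal_set(S, pool_stats(inter))
  !(d_pre > lam * d_inter)
}

# shared sort-and-retain update.  Distances of the pooled candidates are taken
# to the *opposite*-class pool; a stable sort (ties broken by age, older
# first) keeps the first `capacity` samples.
update_pool <- function(pool, obs, ref_pool, order = c("asc", "desc")) {
  order <- match.arg(order)
  obs <- if (is.null(obs)) NULL else as.matrix(obs)
  if (!is.null(obs) && nrow(obs) == 0L) obs <- NULL
  cand <- rbind(pool$features, obs)
  age <- c(pool$age, if (is.null(obs)) NULL else max(pool$age) + seq_len(nrow(obs)))
  st <- pool_stats(ref_pool)
  d <- mahal_points(cand, st)
  idx <- if (order == "asc") base::order(d, age) else base::order(-d, age)
  keep <- sort(idx[seq_len(min(pool$capacity, length(idx)))])
  out <- pool
  out$features <- cand[keep, , drop = FALSE]
  out$age <- age[keep]
  out
}

#' Update the interictal pool with a normal observed set
#'
#' Pools the `N2` current interictal samples with the `N3` observed samples,
#' sorts all `N2 + N3` by Mahalanobis distance to the preictal pool, and
#' retains the first `N2`.  The default ascending order keeps the samples
#' closest to the opposite-class region (the boundary-informative ones, in
#' the spirit of replacing the sample farthest from the support vectors);
#' `order = "desc"` is available because the convention is a design choice.
#'
#' @param inter interictal `sample_pool` (capacity `N2`).
#' @param obs observed feature matrix (`N3` rows); the caller is expected to
#'   have checked [is_abnormal()] first.  `NULL` or 0 rows leaves the pool
#'   unchanged.
#' @param pre preictal `sample_pool` (distance reference).
#' @param order `"asc"` (default) or `"desc"`.
#' @return the updated interictal `sample_pool` (size exactly `N2`).
#' @export
update_pool_inter <- function(inter, obs, pre, order = "asc") {
  if (inter$role != "inter") stop_validation("first pool must have role 'inter'")
  update_pool(inter, obs, pre, order)
}

#' Update the preictal pool with samples preceding a missed seizure
#'
#' Mirror of [update_pool_inter()] with the roles swapped: the `N1 + N3`
#' samples of `S_pre` and the observed set are sorted by distance to the
#' interictal pool and the first `N1` are retained.
#'
#' @param pre preictal `sample_pool` (capacity `N1`).
#' @param obs observed feature matrix.
#' @param inter interictal `sample_pool` (distance reference).
#' @param order `"asc"` (default) or `"desc"`.
#' @return the updated preictal `sample_pool` (size exactly `N1`).
#' @export
update_pool_pre <- function(pre, obs, inter, order = "asc") {
  if (pre$role != "pre") stop_validation("first pool must have role 'pre'")
  update_pool(pre, obs, inter, order)
}

#' Persist / load a sample-pool snapshot as CSV
#'
#' Feature-table layout plus `role`, `age` and `capacity` columns, so a pool
#' can be inspected or restored across sessions.
#'
#' @param pool a `sample_pool`.
#' @param path CSV path.
#' @return `read_pool` returns the `sample_pool`; `write_pool` returns
#'   `path` invisibly.
#' @export
write_pool <- function(pool, path) {
  df <- as.data.frame(pool$features)
  names(df) <- paste0("f", seq_len(ncol(df)))
  out <- cbind(data.frame(role = pool$role, age = pool$age,
                          capacity = pool$capacity), df)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  p <- sample_pool(as.matrix(df[, -(1:3), drop = FALSE]),
                   capacity = df$capacity[1L], role = df$role[1L])
  p$age <- df$age
  p
}
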
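# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Centered moving average with shrinking edge windows
#'
#' Smooths a numeric vector with a centered window of `window` points; at
#' the edges the window shrinks to the available points, so the output has
#' the same length as the input.
#'
#' @param v numeric vector
#' @param window odd positive window width in points
#' @return numeric vector of the same length as `v`
#' @export
moving_average <- function(v, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  n <- length(v)
  if (window > n) stop("window (", window, ") larger than profile length (", n, ")")
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Best one-to-one matching of estimated to reference components
#'
#' Finds the assignment of estimated components to reference components that
#' maximizes the mean Pearson correlation of their spatial profiles
#' (exhaustive over permutations; intended for the small component counts
#' typical of fingerprint models).
#'
#' @param estimated,reference numeric matrices with one column per
#'   component, equal row count (spatial positions); `reference` may have a
#'   different column count, in which case the smaller side is matched.
#' @return list with `pairs` (data.frame `estimated`, `reference`, `r`) and
#'   `mean_r`.
#' @export
match_components <- function(estimated, reference) {
  ke <- ncol(estimated); kr <- ncol(reference)
  k <- min(ke, kr)
  if (max(ke, kr) > 8L) stop("exhaustive matching supported up to 8 components")
  cors <- matrix(NA_real_, ke, kr)
  for (i in seq_len(ke)) for (j in seq_len(kr)) {
    a <- estimated[, i]; b <- reference[, j]
    cors[i, j] <- if (sd(a) == 0 || sd(b) == 0) 0 else stats::cor(a, b)
  }
  # enumerate injections of the smaller index set into the larger
  small_on_rows <- ke <= kr
  perms <- permutations(max(ke, kr))
  best <- NULL; best_mean <- -Inf
  for (p in seq_len(nrow(perms))) {
    sel <- perms[p, seq_len(k)]
    vals <- if (small_on_rows) cors[cbind(seq_len(k), sel)]
            else cors[cbind(sel, seq_len(k))]
    m <- mean(vals)
    if (m > best_mean) {
      best_mean <- m
      best <- if (small_on_rows) data.frame(estimated = seq_len(k), reference = sel, r = vals)
              else data.frame(estimated = sel, reference = seq_len(k), r = vals)
    }
  }
  list(pairs = best[order(best$reference), ], mean_r = best_mean)
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# relative Frobenius reconstruction error ||X - WH||_F / ||X||_F
rel_frobenius_error <- function(X, W, H) {
  nx <- sqrt(sum(X^2))
  if (nx == 0) return(0)
  sqrt(sum((X - W %*% H)^2)) / nx
}
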
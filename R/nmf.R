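#' Zone-average a feature table along the depth axis
#'
#' Averages the (TIC-normalized) intensities of every feature over depth
#' zones of `zone_width` raster units, zeros included in the mean. This is
#' the noise-reduction step ahead of factorization: the zones-by-features
#' matrix replaces the pixels-by-features table.
#'
#' @param table an [msi_features()] table (TIC-normalized for the
#'   fingerprinting workflow)
#' @param zone_width zone width in raster units (default 30)
#' @return list of class `zone_matrix`: `matrix` (zones x features),
#'   `zone_bounds` (data.frame `lo`, `hi` in raster units), `feature_mz`,
#'   `zone_width`, `depth_axis`, `pixel_pitch_um`.
#' @export
zone_average <- function(table, zone_width = 30L) {
  stopifnot(zone_width >= 1)
  d <- depth_coord(table)
  zone <- floor(d / zone_width)
  zlev <- sort(unique(zone))
  m <- matrix(0, length(zlev), ncol(table$matrix))
  for (z in seq_along(zlev)) {
    rows <- zone == zlev[z]
    m[z, ] <- colMeans(table$matrix[rows, , drop = FALSE])
  }
  colnames(m) <- colnames(table$matrix)
  structure(list(matrix = m, feature_mz = table$feature_mz,
                 zone_bounds = data.frame(lo = zlev * zone_width,
                                          hi = (zlev + 1) * zone_width),
                 zone_width = zone_width, depth_axis = table$depth_axis,
                 pixel_pitch_um = table$pixel_pitch_um),
            class = "zone_matrix")
}

#' Scale each feature to [0, 1] by its maximum
#'
#' Divides every feature column of the zone matrix by its maximum absolute
#' value so all features contribute on an equal footing to the
#' factorization. All-zero columns are left unchanged and flagged.
#'
#' @param zm a [zone_average()] zone matrix
#' @return list with `zm` (scaled zone matrix), `scale` (per-feature
#'   divisor; 1 for flagged columns), `zero_features` (logical flag vector).
#' @export
maxabs_scale <- function(zm) {
  m <- zm$matrix
  cmax <- apply(abs(m), 2L, max)
  zero <- cmax == 0
  div <- ifelse(zero, 1, cmax)
  zm$matrix <- sweep(m, 2L, div, "/")
  list(zm = zm, scale = div, zero_features = zero)
}

# --- NMF core -------------------------------------------------------------
# Hierarchical alternating least squares (HALS) with a deterministic
# initialization from the data's leading singular structure (NNDSVD); the
# seed only perturbs exactly-zero initial entries so components never start
# identically degenerate.

nndsvd_init <- function(X, k, seed) {
  s <- svd(X, nu = k, nv = k)
  W <- matrix(0, nrow(X), k); H <- matrix(0, k, ncol(X))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn && nup * nvp > 0) {
      sig <- sqrt(s$d[j] * nup * nvp)
      W[, j] <- sig * up / nup; H[j, ] <- sig * vp / nvp
    } else if (nun * nvn > 0) {
      sig <- sqrt(s$d[j] * nun * nvn)
      W[, j] <- sig * un / nun; H[j, ] <- sig * vn / nvn
    }
  }
  eps0 <- mean(X) * 1e-6
  if (eps0 == 0) eps0 <- 1e-12
  nzW <- W == 0; nzH <- H == 0
  with_seed(seed, {
    W[nzW] <- eps0 * runif(sum(nzW))
    H[nzH] <- eps0 * runif(sum(nzH))
  })
  list(W = W, H = H)
}

hals_sweep <- function(X, W, H) {
  k <- ncol(W)
  A <- crossprod(W, X); B <- crossprod(W)
  for (j in seq_len(k)) {
    if (B[j, j] > .Machine$double.eps) {
      H[j, ] <- pmax(0, H[j, ] + (A[j, ] - B[j, ] %*% H) / B[j, j])
    }
  }
  A2 <- X %*% t(H); B2 <- tcrossprod(H)
  for (j in seq_len(k)) {
    if (B2[j, j] > .Machine$double.eps) {
      W[, j] <- pmax(0, W[, j] + (A2[, j] - W %*% B2[, j]) / B2[j, j])
    }
  }
  list(W = W, H = H)
}

# HALS with momentum extrapolation and restart: each iteration sweeps from
# the extrapolated point; an improving sweep is accepted and the momentum
# grows, a worsening one restarts from the last accepted factors (a plain
# HALS sweep from an accepted point never increases the error, so progress
# cannot stall on rejections). The extrapolation removes the slow linear
# tail of plain alternating updates on near-exact-rank problems.
hals_fit <- function(X, W, H, max_iter = 500L, tol = 1e-9) {
  normX <- sqrt(sum(X^2))
  err <- rel_frobenius_error(X, W, H)
  Wy <- W; Hy <- H; beta <- 0.5
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    s <- hals_sweep(X, Wy, Hy)
    new_err <- if (normX == 0) 0 else
      sqrt(max(0, sum((X - s$W %*% s$H)^2))) / normX
    if (new_err <= err) {
      Wy <- pmax(s$W + beta * (s$W - W), 0)
      Hy <- pmax(s$H + beta * (s$H - H), 0)
      delta <- err - new_err
      W <- s$W; H <- s$H; err <- new_err
      beta <- min(1, beta * 1.05)
      if (delta < tol) { converged <- TRUE; break }
    } else {
      Wy <- W; Hy <- H
      beta <- beta * 0.5
    }
  }
  list(W = W, H = H, error = err, iterations = iter, converged = converged)
}

# Warm-started chain: fit k = 1..k_target, each next fit initialized from
# the previous solution plus one new component seeded from the non-negative
# part of the residual. Guarantees a (numerically) non-increasing error in
# k because the enlarged model starts from a configuration at least as good
# as the k-component optimum found; the plain NNDSVD start is also tried at
# each k and the better final fit kept.
nmf_chain <- function(X, k_target, seed, max_iter = 500L, tol = 1e-9) {
  fits <- vector("list", k_target)
  errs <- numeric(k_target)
  prev <- NULL
  for (k in seq_len(k_target)) {
    cands <- list(nndsvd_init(X, k, seed + k))
    if (!is.null(prev)) {
      R <- pmax(X - prev$W %*% prev$H, 0)
      sr <- svd(R, nu = 1L, nv = 1L)
      wnew <- sqrt(sr$d[1]) * abs(sr$u[, 1])
      hnew <- sqrt(sr$d[1]) * abs(sr$v[, 1])
      # full-strength residual component, and a vanishing one whose start
      # is numerically the k-1 solution itself
      cands <- c(cands,
                 list(list(W = cbind(prev$W, wnew), H = rbind(prev$H, hnew)),
                      list(W = cbind(prev$W, 1e-8 * wnew),
                           H = rbind(prev$H, 1e-8 * hnew))))
    }
    best <- NULL
    for (ini in cands) {
      f <- hals_fit(X, ini$W, ini$H, max_iter = max_iter, tol = tol)
      if (is.null(best) || f$error < best$error) best <- f
    }
    fits[[k]] <- best
    errs[k] <- best$error
    prev <- best
  }
  list(fits = fits, errors = errs)
}

#' Select the number of NMF components
#'
#' Fits the factorization for k = 1, 2, ... under a fixed seed and records
#' the relative Frobenius reconstruction error err(k). Under the default
#' `criterion = "decrement"` the selected k is the smallest one whose error
#' improvement over the next model, err(k) - err(k+1), falls below
#' `delta_tol` — the point where the error trace has stabilised. With
#' `criterion = "absolute"` the smallest k with err(k) < `delta_tol` is
#' selected instead.
#'
#' @param zm_scaled a max-abs-scaled [zone_average()] matrix (the `zm`
#'   element of [maxabs_scale()])
#' @param k_max largest component count to consider; capped at
#'   `min(zones, features)` with a warning
#' @param delta_tol stabilization threshold on the relative Frobenius error
#'   (default 0.0015)
#' @param seed integer seed controlling initialization tie-breaking
#' @param criterion `"decrement"` (plateau of the error trace, default) or
#'   `"absolute"` (error floor)
#' @return list with `k` (selected), `error_trace` (err(k) for all fitted
#'   k), and `stabilized` (FALSE with a warning when the criterion was never
#'   met and k_max was returned).
#' @export
select_n_components <- function(zm_scaled, k_max = 10L, delta_tol = 0.0015,
                                seed = 1L,
                                criterion = c("decrement", "absolute")) {
  criterion <- match.arg(criterion)
  stopifnot(k_max >= 1, delta_tol > 0)
  X <- zm_scaled$matrix
  cap <- min(nrow(X), ncol(X))
  if (k_max > cap) {
    warning("k_max = ", k_max, " exceeds min(zones, features) = ", cap,
            "; capped")
    k_max <- cap
  }
  chain <- nmf_chain(X, k_max, seed)
  errs <- chain$errors
  k <- NA_integer_
  if (criterion == "decrement") {
    if (k_max >= 2L) {
      dec <- errs[-length(errs)] - errs[-1]
      hit <- which(dec < delta_tol)
      if (length(hit)) k <- hit[1]
    }
  } else {
    hit <- which(errs < delta_tol)
    if (length(hit)) k <- hit[1]
  }
  stabilized <- !is.na(k)
  if (!stabilized) {
    warning("reconstruction error never stabilised below ", delta_tol,
            " up to k_max = ", k_max, "; returning k_max")
    k <- k_max
  }
  list(k = k, error_trace = errs, stabilized = stabilized)
}

#' Fit the NMF fingerprint model
#'
#' Decomposes the scaled zones-by-features matrix X into a non-negative
#' spatial matrix W (zones x k; the molecular fingerprints) and a
#' non-negative contribution matrix H (k x features; the pseudo-spectra)
#' minimizing the Frobenius reconstruction error, using hierarchical
#' alternating least squares from a deterministic NNDSVD start (models are
#' fitted for 1..k with warm starts, so the recorded error trace is
#' non-increasing and the returned model is the k-th element of that
#' chain). Convergence: relative error change below `tol` or `max_iter`
#' iterations (a warning flags the iteration cap).
#'
#' @inheritParams select_n_components
#' @param k number of components
#' @param max_iter iteration cap (default 500)
#' @param tol convergence tolerance on the change of the relative error
#'   (default 1e-9)
#' @return list of class `fingerprint_model`: `n_components`, `spatial`
#'   (zones x k), `contributions` (k x features), `error_trace` (relative
#'   Frobenius error for k' = 1..k), `seed`, `iterations`, `converged`,
#'   `feature_mz`, `zone_bounds`, `depth_axis`.
#' @export
fit_nmf <- function(zm_scaled, k, seed = 1L, max_iter = 500L, tol = 1e-9) {
  stopifnot(k >= 1)
  X <- zm_scaled$matrix
  if (k > min(nrow(X), ncol(X))) {
    stop("k = ", k, " exceeds min(zones, features) = ", min(nrow(X), ncol(X)))
  }
  chain <- nmf_chain(X, k, seed, max_iter = max_iter, tol = tol)
  fit <- chain$fits[[k]]
  if (!fit$converged) {
    warning("NMF did not converge within ", max_iter, " iterations")
  }
  structure(list(n_components = as.integer(k), spatial = fit$W,
                 contributions = fit$H, error_trace = chain$errors,
                 seed = seed, iterations = fit$iterations,
                 converged = fit$converged, feature_mz = zm_scaled$feature_mz,
                 zone_bounds = zm_scaled$zone_bounds,
                 depth_axis = zm_scaled$depth_axis),
            class = "fingerprint_model")
}

#' @export
print.fingerprint_model <- function(x, ...) {
  cat("fingerprint_model:", x$n_components, "components,",
      nrow(x$spatial), "zones x", ncol(x$contributions), "features\n")
  cat("  relative reconstruction error:",
      format(x$error_trace[x$n_components], digits = 6),
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  invisible(x)
}

#' Top contributing features of a component
#'
#' Ranks the features of one component by contribution, descending; ties
#' are broken toward the lower m/z.
#'
#' @param model a [fit_nmf()] model
#' @param component component index in `1..k`
#' @param n number of features to return; the full ranking if `n` exceeds
#'   the feature count
#' @return data.frame `rank`, `feature` (column index), `mz`,
#'   `contribution`, sorted by rank.
#' @export
top_features <- function(model, component, n = 10L) {
  if (component < 1 || component > model$n_components) {
    stop("component index out of range: ", component)
  }
  w <- model$contributions[component, ]
  ord <- order(-w, model$feature_mz)
  n <- min(n, length(w))
  sel <- ord[seq_len(n)]
  data.frame(rank = seq_len(n), feature = sel, mz = model$feature_mz[sel],
             contribution = w[sel], row.names = NULL)
}
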
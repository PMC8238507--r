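# internal helpers: Slepian taper, hierarchical seeding, small numerics

.gammacc_cache <- new.env(parent = emptyenv())

#' First discrete prolate spheroidal (Slepian) sequence
#'
#' Computes the leading DPSS taper of length `n` with time-bandwidth product
#' `nw` by solving the standard symmetric tridiagonal eigenproblem
#' (Percival & Walden formulation). The result is cached per `(n, nw)`,
#' normalised to unit energy, and sign-fixed to a positive mean.
#'
#' @param n taper length in samples
#' @param nw time-bandwidth product; the spectral estimators use `nw = 1`
#'   with this single taper (minimal-taper multitaper setting)
#' @return numeric vector of length `n` with `sum(w^2) == 1`
#' @keywords internal
dpss_taper <- function(n, nw = 1) {
  key <- sprintf("dpss_%d_%g", n, nw)
  if (!is.null(.gammacc_cache[[key]])) return(.gammacc_cache[[key]])
  stopifnot(n >= 8, nw > 0)
  w <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  m <- diag(diag_main)
  idx <- cbind(1:(n - 1), 2:n)
  m[idx] <- diag_off
  m[idx[, 2:1]] <- diag_off
  v <- eigen(m, symmetric = TRUE)$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  if (sum(v) < 0) v <- -v
  .gammacc_cache[[key]] <- v
  v
}

#' Derive a child RNG seed from integer components
#'
#' Deterministic integer mixing (multiply-add modulo a Mersenne prime) so a
#' single cohort seed can fan out to per-subject and per-trial streams that
#' regenerate identically for any subset.
#'
#' @param ... integers or strings (strings are hashed by character codes)
#' @return a single integer in `[1, 2^31 - 2]`
#' @keywords internal
mix_seed <- function(...) {
  parts <- list(...)
  s <- 104729
  for (p in parts) {
    if (is.character(p)) p <- utf8ToInt(paste(p, collapse = ""))
    for (x in as.numeric(p)) {
      s <- (s * 69069 + abs(x) + 1) %% 2147483647
    }
  }
  as.integer(s %% 2147483645 + 1)
}

# evaluate expr with a local RNG state seeded by `seed`
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# |FFT|^2 of the columns of a real matrix, rows 1..floor(n/2)+1, computed by
# packing pairs of real columns into complex columns (halves the FFT work)
fft_power_batch <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  nb <- floor(n / 2) + 1
  if (m %% 2 == 1) x <- cbind(x, 0)
  odd <- seq(1, ncol(x), 2)
  z <- x[, odd, drop = FALSE] + 1i * x[, odd + 1, drop = FALSE]
  ft <- stats::mvfft(z)
  a <- ft[seq_len(nb), , drop = FALSE]
  b <- ft[c(1, n:(n - nb + 2)), , drop = FALSE]
  # FFT(odd) = (a + conj(b))/2, FFT(even) = (a - conj(b))/2i; all real ops
  ra <- Re(a); ia <- Im(a); rb <- Re(b); ib <- Im(b)
  p <- matrix(0, nb, ncol(x))
  p[, odd] <- ((ra + rb)^2 + (ia - ib)^2) / 4
  p[, odd + 1] <- ((ra - rb)^2 + (ia + ib)^2) / 4
  p[, seq_len(m), drop = FALSE]
}

# nearest sample index for a time point on a uniform axis
time_index <- function(time, t) which.min(abs(time - t))

# logical index of samples with lo <= t < hi
time_window <- function(time, lo, hi) time >= lo & time < hi
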
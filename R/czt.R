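# Chirp-z (Bluestein) evaluation of uniform-grid Fourier-type sums.
#
# Both the line-broadening function (a sum over a uniform frequency grid
# evaluated on a uniform time grid) and the dissipative potential (a sum over
# a uniform time grid evaluated on a uniform frequency grid) are sums of the
# form
#     S_j = sum_{k=0}^{M-1} a_k exp(-i * theta * k * j),   j = 0 .. K-1
# with theta = (grid spacing product)/hbar.  Bluestein's identity
# k*j = (k^2 + j^2 - (j-k)^2)/2 turns this into a linear convolution with a
# quadratic chirp, evaluated by three FFTs.  The result equals the direct sum
# to floating-point roundoff, so trapezoidal quadrature weights folded into
# a_k are preserved exactly; no frequency- or time-interpolation is involved.
#
# The chirp and its FFT depend only on (theta, M, K, L) and are cached in the
# package environment; repeated calls (one per chromophore pair and disorder
# realization) then cost two length-L FFTs each.

czt_plan <- function(theta, M, K) {
  key <- sprintf("%.17g_%d_%d", theta, M, K)
  plan <- .dissipath_cache[[key]]
  if (!is.null(plan)) return(plan)
  L <- stats::nextn(M + K - 1L, 2L)
  k <- as.numeric(0:(M - 1L))
  j <- as.numeric(0:(K - 1L))
  wk <- exp(-1i * theta * k * k / 2)
  wj <- exp(-1i * theta * j * j / 2)
  b <- complex(length.out = L)
  b[1:K] <- Conj(wj)
  if (M > 1L) {
    m <- as.numeric(1:(M - 1L))
    b[L - m + 1] <- exp(1i * theta * m * m / 2)
  }
  plan <- list(L = L, M = M, K = K, wk = wk, wj = wj, fb = stats::fft(b))
  .dissipath_cache[[key]] <- plan
  plan
}

# a: complex (or numeric) vector of length M.
czt_sum <- function(a, theta, K, plan = NULL) {
  M <- length(a)
  if (is.null(plan)) plan <- czt_plan(theta, M, K)
  pad <- complex(length.out = plan$L)
  pad[1:M] <- a * plan$wk
  conv <- stats::fft(stats::fft(pad) * plan$fb, inverse = TRUE) / plan$L
  plan$wj * conv[1:K]
}

# Is a grid uniformly spaced (to relative tolerance)?
is_uniform_grid <- function(x, tol = 1e-8) {
  if (length(x) < 2L) return(FALSE)
  d <- diff(x)
  max(abs(d - d[1])) <= tol * max(abs(d[1]), .Machine$double.eps)
}

# Trapezoid quadrature weights for a uniform grid.
trapezoid_weights <- function(x) {
  n <- length(x)
  h <- (x[n] - x[1]) / (n - 1)
  w <- rep(h, n)
  w[c(1L, n)] <- h / 2
  w
}
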
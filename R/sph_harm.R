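# Spherical-harmonics decomposition of per-vertex scalar fields on the
# sphere parametrization. Complex orthonormal basis internally (Condon-
# Shortley phase); a real orthonormal basis is available for driving and
# exporting real-valued fields.

sh_n_coeffs <- function(lmax) (lmax + 1L)^2

#' Linear index of harmonic (l, m)
#'
#' Coefficients are stored in order `(0,0), (1,-1), (1,0), (1,1), ...`:
#' index `l^2 + l + m + 1`.
#'
#' @param l Degree(s), `l >= 0`.
#' @param m Order(s), `|m| <= l`.
#' @export
sh_index <- function(l, m) {
  stopifnot(all(l >= 0), all(abs(m) <= l))
  as.integer(l^2 + l + m + 1)
}

#' Degree/order table for a coefficient vector
#' @param lmax Maximum degree.
#' @return Data frame with columns `l` and `m` in storage order.
#' @export
sh_degrees <- function(lmax) {
  l <- unlist(lapply(0:lmax, function(ll) rep(ll, 2 * ll + 1)))
  m <- unlist(lapply(0:lmax, function(ll) seq(-ll, ll)))
  data.frame(l = l, m = m)
}

# normalized associated Legendre P_l^m(x) for m = 0..l, including the
# Condon-Shortley phase, scaled so that Y_lm = Nlm P_l^m e^{i m phi}
normalized_legendre <- function(l, x) {
  if (l == 0) return(matrix(sqrt(1 / (4 * pi)), 1, length(x)))
  P <- pracma::legendre(l, x)  # (l+1) x n, MATLAB convention (with CS phase)
  m <- 0:l
  norm <- sqrt((2 * l + 1) / (4 * pi) *
               exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
  P * norm
}

#' Complex orthonormal spherical-harmonics basis matrix
#'
#' `Y[v, j]` evaluates harmonic `j` (storage order of [sh_index()]) at
#' vertex `v`. Orthonormal on the unit sphere:
#' `integral Y_lm conj(Y_l'm') dA = delta`.
#'
#' @param theta,phi Spherical coordinates per vertex.
#' @param lmax Maximum degree.
#' @return Complex matrix `length(theta) x (lmax+1)^2`.
#' @export
sh_basis <- function(theta, phi, lmax) {
  n <- length(theta)
  Y <- matrix(0 + 0i, n, sh_n_coeffs(lmax))
  x <- cos(theta)
  for (l in 0:lmax) {
    P <- normalized_legendre(l, x)
    for (m in 0:l) {
      col <- P[m + 1, ] * exp(1i * m * phi)
      Y[, sh_index(l, m)] <- col
      if (m > 0)
        Y[, sh_index(l, -m)] <- (-1)^m * Conj(col)
    }
  }
  Y
}

#' Real orthonormal spherical-harmonics basis matrix
#'
#' Real basis (cosine for `m > 0`, sine for `m < 0`), orthonormal on the
#' sphere; used to drive real-valued radial deformation scripts.
#'
#' @inheritParams sh_basis
#' @export
sh_real_basis <- function(theta, phi, lmax) {
  n <- length(theta)
  Y <- matrix(0, n, sh_n_coeffs(lmax))
  x <- cos(theta)
  for (l in 0:lmax) {
    P <- normalized_legendre(l, x)
    Y[, sh_index(l, 0)] <- P[1, ]
    for (m in seq_len(l)) {
      # (-1)^m cancels the Condon-Shortley phase in the real convention
      base <- sqrt(2) * (-1)^m * P[m + 1, ]
      Y[, sh_index(l, m)] <- base * cos(m * phi)
      Y[, sh_index(l, -m)] <- base * sin(m * phi)
    }
  }
  Y
}

#' Forward spherical-harmonics transform by area-weighted quadrature
#'
#' `f_lm = sum_v f(v) conj(Y_lm(v)) w_v`, the discrete counterpart of the
#' surface integral of `f Y*_lm` over the unit sphere, with `w` the
#' sphere-mesh vertex area weights.
#'
#' @param field Numeric vector (one frame, per vertex) or matrix
#'   `[vertex, frame]`.
#' @param basis Complex basis from [sh_basis()] (or a real basis).
#' @param weights Per-vertex quadrature areas, e.g.
#'   [vertex_area_weights()] of the reference sphere.
#' @return Complex matrix `[(lmax+1)^2, n_frames]` (a vector input gives a
#'   one-column matrix).
#' @export
sh_forward <- function(field, basis, weights) {
  f <- if (is.null(dim(field))) matrix(field, ncol = 1) else field
  stopifnot(nrow(f) == nrow(basis), length(weights) == nrow(basis))
  if (ncol(basis) > nrow(basis) / 2)
    warnf("aliasing guard: %d coefficients from %d vertices; increase the subdivision level or lower lmax",
          ncol(basis), nrow(basis))
  t(Conj(basis)) %*% (f * weights)
}

#' Reconstruct a per-vertex field from harmonic coefficients
#'
#' `f(v) = sum_lm f_lm Y_lm(v)`. For conjugate-symmetric coefficients the
#' result is real; an imaginary residue beyond `imag_tol` (relative to the
#' field scale) errors.
#'
#' @param coeffs Complex vector of length `(lmax+1)^2` or matrix
#'   `[(lmax+1)^2, n_frames]`.
#' @param basis Basis matrix evaluated at the sampling points.
#' @param imag_tol Allowed relative imaginary residue.
#' @return Numeric vector or matrix `[vertex, frame]`.
#' @export
sh_reconstruct <- function(coeffs, basis, imag_tol = 1e-8) {
  cc <- if (is.null(dim(coeffs))) matrix(coeffs, ncol = 1) else coeffs
  if (nrow(cc) != ncol(basis))
    stopf("coefficient vector has %d entries; basis expects %d (missing (l,m) entries?)",
          nrow(cc), ncol(basis))
  out <- basis %*% cc
  if (is.complex(out)) {
    scale <- max(Mod(out), 1e-300)
    if (max(abs(Im(out))) > imag_tol * scale)
      warnf("non-negligible imaginary residue (%.3g relative): coefficients not conjugate-symmetric?",
            max(abs(Im(out))) / scale)
    out <- Re(out)
  }
  if (is.null(dim(coeffs))) as.vector(out) else out
}

#' Harmonic coefficient time series of a scalar strain-rate field
#'
#' Projects each frame of the scalar field onto spherical harmonics using
#' the (theta, phi) parametrization and area weights of the reference
#' sphere mesh (the markers' original coordinates), yielding coefficient
#' time series `f_lm(t)`.
#'
#' @param sf A `strain_field`, or a numeric matrix `[frame, vertex]`.
#' @param sphere The reference `sphere_mesh` the markers were seeded from.
#' @param lmax Maximum degree (default 12).
#' @param times Frame times; taken from `sf` when it is a `strain_field`.
#' @param weights Quadrature weights; defaults to the sphere-mesh vertex
#'   areas (unit-sphere parametrization measure). Pass embryo-surface areas
#'   to integrate against the deformed-surface measure instead.
#' @return Object of class `harmonic_series`: `times`, `lmax`, complex
#'   `coeffs` `[(lmax+1)^2, n_frames]`, `degrees` (the (l, m) table),
#'   `basis = "complex_orthonormal"`.
#' @export
harmonic_series <- function(sf, sphere, lmax = 12L, times = NULL,
                            weights = NULL) {
  scalar <- if (inherits(sf, "strain_field")) sf$scalar else sf
  times <- times %||% (if (inherits(sf, "strain_field")) sf$times else
                       seq_len(nrow(scalar)))
  stopifnot(ncol(scalar) == nrow(sphere$vertices))
  basis <- sh_basis(sphere$theta, sphere$phi, lmax)
  weights <- weights %||% vertex_area_weights(sphere)
  coeffs <- sh_forward(t(scalar), basis, weights)
  structure(list(times = times, lmax = as.integer(lmax), coeffs = coeffs,
                 degrees = sh_degrees(lmax), basis = "complex_orthonormal"),
            class = "harmonic_series")
}

#' @export
print.harmonic_series <- function(x, ...) {
  cat(sprintf("<harmonic_series> lmax %d (%d coefficients) x %d frames\n",
              x$lmax, nrow(x$coeffs), ncol(x$coeffs)))
  invisible(x)
}

#' Extract one coefficient time series
#' @param hs A `harmonic_series`.
#' @param l,m Degree and order.
#' @return Complex vector over frames.
#' @export
sh_coefficient <- function(hs, l, m) {
  as.vector(hs$coeffs[sh_index(l, m), ])
}

#' Variance ratios of harmonic modes
#'
#' Per frame, `vr_lm(t) = |f_lm(t)| / sum_l'm' |f_l'm'(t)|` (coefficient-
#' magnitude shares, summing to 1), plus the time average. Frames with all
#' coefficients zero yield `NA` with a log message.
#'
#' @param hs A `harmonic_series`.
#' @return List with `per_frame` (matrix `[(lmax+1)^2, n_frames]`),
#'   `time_averaged` (data frame `l`, `m`, `vr` sorted by decreasing
#'   `vr`).
#' @export
variance_ratios <- function(hs) {
  mag <- Mod(hs$coeffs)
  tot <- colSums(mag)
  zero <- tot == 0
  if (any(zero)) {
    message(sprintf("variance_ratios: %d frame(s) with all-zero coefficients -> NA",
                    sum(zero)))
    tot[zero] <- NA_real_
  }
  vr <- sweep(mag, 2, tot, "/")
  avg <- rowMeans(vr, na.rm = TRUE)
  tab <- cbind(hs$degrees, vr = avg)
  list(per_frame = vr,
       time_averaged = tab[order(-tab$vr), , drop = FALSE])
}
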
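# Numerical helpers: stable log-cosh, Gauss-Legendre nodes, and the
# closed-form depth antiderivatives used on the linear ramp segments.

# log(cosh(x)) without overflow
logcosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch), cached per order
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre01 <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(k, k + 1)] <- b
  Jm[cbind(k + 1, k)] <- b
  e <- eigen(Jm, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  res <- list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
  .gl_cache[[key]] <- res
  res
}

# composite Gauss-Legendre quadrature nodes over [a, b]: panels sized so the
# sharpest tanh transition (width ~ 1 / sigma in depth) is well resolved
gl_nodes_ramp <- function(a, b, n_panel, order = 12) {
  g <- gauss_legendre01(order)
  edges <- seq(a, b, length.out = n_panel + 1)
  wid <- diff(edges)
  x <- as.vector(outer(g$x, wid) + rep(edges[-length(edges)], each = order))
  w <- as.vector(outer(g$w, wid))
  list(x = x, w = w)
}

# antiderivative in depth of the metabolic shape (tanh(-s (u - c)) + 1) / 2
anti_sigmoid_down <- function(u, s, c) (u - logcosh(s * (u - c)) / s) / 2

# antiderivative in depth of the unfavorable-zone mortality A(u)
anti_zone <- function(u, params) {
  params$delta_u * (u - logcosh(params$sigma_u * (u - params$h_u)) / params$sigma_u) +
    params$delta_d * (u + logcosh(params$sigma_d * (u - params$h_d)) / params$sigma_d)
}

# time integral of the diel light factor (1 - cos(2 pi t)) over [ta, tb]
diel_factor_integral <- function(ta, tb) {
  (tb - ta) - (sin(2 * pi * tb) - sin(2 * pi * ta)) / (2 * pi)
}
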
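# fixtures built in code; no data files

# single-vertex (mesh-less) series with axial waveform f(u), u = t/T in [0,1)
single_vertex_series <- function(f, nt = 512L, T = 0.8, pressure = 0) {
  times <- T * (seq_len(nt) - 1L) / nt
  w <- array(0, dim = c(1L, nt, 3L))
  w[1L, , 1L] <- f(times / T)
  wall_field_series(NULL, times, w, matrix(pressure, 1L, nt), T)
}

# multi-vertex mesh-less series from a list of waveforms
multi_vertex_series <- function(fs, nt = 512L, T = 0.8, pressure = 0) {
  times <- T * (seq_len(nt) - 1L) / nt
  w <- array(0, dim = c(length(fs), nt, 3L))
  for (i in seq_along(fs)) w[i, , 1L] <- fs[[i]](times / T)
  wall_field_series(NULL, times, w, matrix(pressure, length(fs), nt), T)
}

# unit right triangle in the z = 0 plane (area 1/2)
unit_triangle_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               rbind(c(0L, 1L, 2L)))
}

# closed-form cycle mean of |A + B sin|
mean_abs_sine <- function(A, B) {
  if (B == 0 || abs(A) >= B) return(abs(A))
  cc <- abs(A) / B
  B * (2 / pi) * (sqrt(1 - cc^2) + cc * asin(cc))
}

# dense independent trapezoid oracle on [0, 1] (closed grid)
dense_mean <- function(f, n = 1e5L) {
  u <- seq(0, 1, length.out = n + 1L)
  y <- f(u)
  sum(diff(u) * (y[-1L] + y[-length(y)]) / 2)
}

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected),
                                              .Machine$double.eps)), tol)
}
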
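# Shared fixtures, built in code.

# standard small scenario for solver-level tests
small_scenario <- function(n = 32, nc = 4) {
  g <- grid2d(n)
  rho <- make_phantom(g)
  coils <- make_coils(g, coil_layout(nc))
  list(g = g, rho = rho, coils = coils,
       full = make_pattern(g, 1, 1, 0))
}

# random complex array helper
rcplx <- function(n) complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))

# pointwise coil-image products c_i * rho as an array
product_array <- function(rho, coils) {
  out <- coils$values
  for (i in seq_len(coils$nc)) out[, , i] <- out[, , i] * rho$values
  out
}

rel_err <- function(a, b) sqrt(sum(abs(a - b)^2) / sum(abs(b)^2))

# multiply a smooth random unit-magnitude phase field onto every coil
# (keeps maps pole-free; used to vary pole-free detection runs)
randomize_coil_phase <- function(coils, seed) {
  g <- coils$grid
  px <- matrix((seq_len(g$nx) - 0.5) / g$nx - 0.5, g$nx, g$ny)
  py <- matrix((seq_len(g$ny) - 0.5) / g$ny - 0.5, g$nx, g$ny, byrow = TRUE)
  vals <- coils$values
  set.seed(seed)
  for (i in seq_len(coils$nc)) {
    cf <- stats::rnorm(5, sd = 1.5)
    ph <- cf[1] * px + cf[2] * py + cf[3] * px^2 + cf[4] * px * py + cf[5] * py^2
    vals[, , i] <- vals[, , i] * exp(1i * ph)
  }
  coil_set(g, vals, "natural")
}

# brute-force winding number by explicit loop over curve points (the
# independent oracle for the vectorized implementation)
brute_winding <- function(field, pts) {
  v <- field[cbind(pts[, 1] + 1L, pts[, 2] + 1L)]
  if (any(v == 0)) return(0L)
  total <- 0
  k <- length(v)
  for (j in seq_len(k)) {
    a <- v[j]; b <- v[if (j == k) 1L else j + 1L]
    total <- total + Arg(b / a)
  }
  as.integer(round(total / (2 * pi)))
}
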
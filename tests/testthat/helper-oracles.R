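# shared test oracles, independent of the implementation paths they check

# central finite-difference gradient of a scalar function
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# a small hand-authored DX fixture: 2 x 2 x 2, values 0.0 .. 0.7 with the
# z index varying fastest
write_dx_fixture <- function(path, n_values = 8L) {
  vals <- sprintf("%.1f", 0.1 * (seq_len(n_values) - 1L))
  writeLines(c(
    "# hand-written fixture",
    "object 1 class gridpositions counts 2 2 2",
    "origin 1.0 2.0 3.0",
    "delta 0.5 0 0",
    "delta 0 0.5 0",
    "delta 0 0 0.5",
    "object 2 class gridconnections counts 2 2 2",
    "object 3 class array type double rank 0 items 8 data follows",
    paste(vals, collapse = " "),
    'object "density" class field'), path)
  path
}

# random rigid motion drawn from the current RNG stream
random_rigid <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3L, 3L, byrow = TRUE)
  list(R = R, t = runif(3, -5, 5))
}
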
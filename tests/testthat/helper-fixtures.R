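# Shared fixtures: hand-built nuclides and small oracle implementations
# kept independent of the package internals they are used to check.

# minimal nuclide with arbitrary emission inventories
make_nuclide <- function(name = "test", half_life_s = log(2),
                         electrons = data.frame(kind = character(),
                                                energy = numeric(),
                                                yield = numeric()),
                         photons = data.frame(energy = numeric(),
                                              yield = numeric())) {
  structure(list(name = name, half_life = half_life_s,
                 electrons = electrons, photons = photons),
            class = "nuclide")
}

one_line_electron_nuclide <- function(energy, yield = 1) {
  make_nuclide(electrons = data.frame(kind = "conversion_or_auger",
                                      energy = energy, yield = yield))
}

# brute-force OLS oracle: explicit normal equations, nothing shared with
# the package fit path
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  sigma2 <- sse / (length(y) - 2)
  list(intercept = beta[1], slope = beta[2],
       cov = sigma2 * xtx_inv, sigma2 = sigma2,
       r_squared = 1 - sse / sst, residuals = as.vector(res))
}

# boundary-distance oracle: bisection on the inside/outside predicate
boundary_oracle <- function(point, direction, geom, t_max = 50) {
  inside <- function(t) {
    p <- point + t * direction
    p[1]^2 + p[2]^2 <= geom$inner_radius^2 & p[3] >= 0 &
      p[3] <= geom$inner_height
  }
  lo <- 0; hi <- t_max
  stopifnot(!inside(hi))
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (inside(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
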
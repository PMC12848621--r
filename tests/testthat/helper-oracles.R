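# Shared oracles and generators, independent of the implementation paths
# they check.

# brute-force matrix-vector product
naive_apply <- function(m, s) {
  out <- numeric(4)
  for (i in 1:4) {
    acc <- 0
    for (j in 1:4) acc <- acc + m[i, j] * s[j]
    out[i] <- acc
  }
  out
}

# naive summation moments (population forms, exactly as printed)
naive_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  s2 <- sum((x - mu)^2) / n
  s <- sqrt(s2)
  c(mean = mu, std = s,
    skewness = sum((x - mu)^3) / (n * s^3),
    kurtosis = sum((x - mu)^4) / (n * s^4))
}

# rotation of the Stokes s1/s2 plane by 2*theta (frame rotation oracle)
stokes_rotation <- function(theta) {
  c2 <- cos(2 * theta); s2 <- sin(2 * theta)
  m <- diag(4)
  m[2:3, 2:3] <- matrix(c(c2, s2, -s2, c2), 2, 2)
  m
}

# random physical Mueller matrix: depolarizer . retarder . diattenuator,
# optionally frame-rotated; physical by construction
random_physical_mueller <- function(max_D = 0.95, min_depol = 0.1) {
  abc <- runif(3, min_depol, 1)
  delta <- runif(1, 0, 2 * pi * 0.999)
  theta <- runif(1, -pi / 2, pi / 2)
  dmag <- runif(1, 0, max_D)
  ddir <- rnorm(3); ddir <- ddir / sqrt(sum(ddir^2))
  rot <- stokes_rotation(runif(1, -pi / 2, pi / 2))
  rot %*% mueller_depolarizer(abc[1], abc[2], abc[3]) %*%
    mueller_retarder(delta, theta) %*% mueller_diattenuator(dmag * ddir) %*%
    t(rot)
}

# random canonical composition with known (Delta, R, D): diagonal
# depolarizer, retarder with random axis/retardance, diattenuator
random_composition <- function(max_D = 0.95) {
  abc <- runif(3, 0.2, 1)
  delta <- runif(1, 0.01, pi * 0.98)
  theta <- runif(1, -pi / 2, pi / 2)
  dmag <- runif(1, 0, max_D)
  ddir <- rnorm(3); ddir <- ddir / sqrt(sum(ddir^2))
  M <- mueller_depolarizer(abc[1], abc[2], abc[3]) %*%
    mueller_retarder(delta, theta) %*% mueller_diattenuator(dmag * ddir)
  list(M = M, Delta = 1 - sum(abc) / 3, R = delta, D = dmag)
}

# synthesize the ideal (noiseless) 36-image stack of a uniform sample
ideal_stack <- function(M, shape = c(2L, 2L), meta = list()) {
  imgs <- list()
  for (g in POL_STATES) for (a in POL_STATES) {
    I <- analyzer_intensity(a, apply_mueller(M, stokes_of_state(g)))
    imgs[[paste0(g, a)]] <- matrix(max(I, 0), shape[1], shape[2])
  }
  intensity_stack(imgs, meta = meta)
}
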
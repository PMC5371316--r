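# Independent oracles, coded from the definitions (not via the package's
# computational paths), plus small fixture builders.

wrap_angle <- function(a) atan2(sin(a), cos(a))

# plain-R bond angle at residue j and dihedral over residues d..d+3
angle_oracle <- function(X, j) {
  u <- X[j - 1, ] - X[j, ]; v <- X[j + 1, ] - X[j, ]
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
}

dihedral_oracle <- function(X, d) {
  b1 <- X[d + 1, ] - X[d, ]; b2 <- X[d + 2, ] - X[d + 1, ]; b3 <- X[d + 3, ] - X[d + 2, ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  atan2(sum(cr(n1, n2) * b2 / sqrt(sum(b2^2))), sum(n1 * n2))
}

# sum-over-terms re-implementation of the surrogate potential (kBT)
energy_oracle <- function(conf, params) {
  X <- conf$coords
  n <- nrow(X)
  h <- params$helix_bias
  e <- 0
  for (j in 2:(n - 1)) e <- e + 0.5 * params$k_angle * (angle_oracle(X, j) - params$theta0)^2
  s2 <- 2 * params$dihedral_width^2
  for (d in 1:(n - 3)) {
    phi <- dihedral_oracle(X, d)
    e <- e - h[d + 1] * exp(-wrap_angle(phi - params$phi_helix)^2 / s2)
    e <- e - params$extended_depth * exp(-wrap_angle(phi - params$phi_extended)^2 / s2)
  }
  for (i in 1:n) for (j in i:n) {
    if (j - i < 4) next
    r <- sqrt(sum((X[i, ] - X[j, ])^2))
    if (r < params$contact_cutoff) e <- e - params$contact_strength
    if (r < params$excluded_radius) e <- e + params$k_repulsion * (1 - r / params$excluded_radius)^2
  }
  e
}

# random valid conformation: perturbed internal coordinates, exact bonds
random_chain <- function(n, seed = 1, spread = 0.5) {
  set.seed(seed)
  helixscan:::chain_from_internal(
    theta = (91 + runif(n - 2, -15, 15)) * pi / 180,
    phi = runif(n - 3, -pi, pi) * spread + 50 * pi / 180 * (1 - spread))
}

rigid_motion <- function(conf, seed = 1) {
  set.seed(seed)
  ang <- runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0), c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  shift <- runif(3, -2, 2)
  X <- conf$coords %*% t(Rx %*% Ry %*% Rz)
  X <- sweep(X, 2, shift, "+")
  chain_conformation(X, conf$segment_id)
}

# exhaustive re-implementation of greedy neighbour-count clustering
daura_oracle <- function(structures, cutoff) {
  N <- length(structures)
  D <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    D[i, j] <- kabsch_rmsd(structures[[i]], structures[[j]])
  }
  remaining <- seq_len(N)
  cl <- integer(N); k <- 0
  while (length(remaining)) {
    k <- k + 1
    counts <- vapply(remaining, function(i) sum(D[i, remaining] <= cutoff), numeric(1))
    center <- remaining[which(counts == max(counts))[1]]   # lowest index on ties
    members <- remaining[D[center, remaining] <= cutoff]
    cl[members] <- k
    remaining <- setdiff(remaining, members)
  }
  cl
}

# small dihedral/angle jitter keeping bonds exact
jitter_conf <- function(conf, sd = 0.01, seed = 1) {
  set.seed(seed)
  th <- vapply(2:(nrow(conf$coords) - 1), function(j) angle_oracle(conf$coords, j),
               numeric(1))
  ph <- vapply(seq_len(nrow(conf$coords) - 3), function(d) dihedral_oracle(conf$coords, d),
               numeric(1))
  helixscan:::chain_from_internal(th + rnorm(length(th), 0, sd),
                                  ph + rnorm(length(ph), 0, sd),
                                  segment_id = conf$segment_id)
}

# masked centred moving average
masked_ma_oracle <- function(v, window) {
  half <- (window - 1) %/% 2
  n <- length(v)
  vapply(seq_len(n), function(j) {
    idx <- max(1, j - half):min(n, j + half)
    if (all(is.na(v[idx]))) NA_real_ else mean(v[idx], na.rm = TRUE)
  }, numeric(1))
}
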
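# shared fixtures and independent oracles

# a small random MB-PIP model over all twelve interaction types
random_toy_model <- function(seed = 42, o2 = 4, o3 = 4, o4 = 3, sd = 1e-3,
                             switch_width = 2) {
  specs <- c(
    lapply(c("CC", "CH", "HH"), interaction_spec, max_degree = o2,
           lambda = 2.2, cutoff = 12, switch_width = switch_width),
    lapply(c("CCC", "CCH", "CHH", "HHH"), interaction_spec, max_degree = o3,
           lambda = 2.0, cutoff = 9, switch_width = switch_width),
    lapply(c("CCCC", "CCCH", "CCHH", "CHHH", "HHHH"), interaction_spec,
           max_degree = o4, lambda = 1.8, cutoff = 7,
           switch_width = switch_width))
  sizes <- vapply(specs, function(s) pip_basis(s$symmetry, s$max_degree,
                                               include = "connected")$n_fun,
                  integer(1))
  coefs <- withr::with_seed(seed, lapply(sizes, function(k) rnorm(k, sd = sd)))
  mbpip_model(specs, coefs)
}

# naive, loop-based orbit-sum evaluation: the independent oracle for the
# compiled basis evaluation path
brute_force_pip_eval <- function(basis, y) {
  out <- numeric(basis$n_fun)
  for (t in seq_len(nrow(basis$expo))) {
    e <- basis$expo[t, ]
    out[basis$fun_id[t]] <- out[basis$fun_id[t]] + prod(y^e)
  }
  out
}

# central finite-difference gradient of any potential
fd_gradient <- function(pot, structure, h = 1e-5) {
  g <- matrix(0, length(structure$elements), 3)
  for (i in seq_len(nrow(g))) {
    for (d in 1:3) {
      xp <- structure; xp$coords[i, d] <- xp$coords[i, d] + h
      xm <- structure; xm$coords[i, d] <- xm$coords[i, d] - h
      g[i, d] <- (pot_energy(pot, xp) - pot_energy(pot, xm)) / (2 * h)
    }
  }
  g
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}
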
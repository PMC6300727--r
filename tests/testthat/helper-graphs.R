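# Small graph constructors and independent brute-force oracles used across
# the suite. Oracles are deliberately naive (triple loops, explicit subgraph
# construction) and share no code with the package implementations.

unit_path <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
  W
}

unit_star <- function(n) {
  W <- matrix(0, n, n)
  W[1, 2:n] <- W[2:n, 1] <- 1
  W
}

unit_complete <- function(n) {
  W <- matrix(1, n, n)
  diag(W) <- 0
  W
}

unit_triangle <- function() unit_complete(3)

# random symmetric weighted graph with edge probability p
rand_graph <- function(n, p = 0.5, wmin = 0.1, wmax = 1) {
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  on <- runif(sum(up)) < p
  w <- ifelse(on, runif(sum(up), wmin, wmax), 0)
  W[up] <- w
  W + t(W)
}

# ring lattice: each node joined to its k nearest neighbours on the ring,
# a fraction p_rewire of edges rewired at random (Watts-Strogatz style)
ring_lattice <- function(n, k = 6, p_rewire = 0, weight = 1) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in seq_len(k / 2)) {
    j <- ((i + d - 1) %% n) + 1
    W[i, j] <- W[j, i] <- weight
  }
  if (p_rewire > 0) {
    idx <- which(upper.tri(W) & W > 0)
    move <- idx[runif(length(idx)) < p_rewire]
    for (e in move) {
      free <- which(upper.tri(W) & W == 0)
      if (length(free) == 0) next
      to <- free[sample.int(length(free), 1)]
      ij <- arrayInd(e, dim(W))
      W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- 0
      ij2 <- arrayInd(to, dim(W))
      W[ij2[1], ij2[2]] <- W[ij2[2], ij2[1]] <- weight
    }
  }
  W
}

# --- oracles ---------------------------------------------------------------

oracle_spl <- function(W) {
  n <- nrow(W)
  d <- ifelse(W > 0, 1 / W, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_eglob <- function(W) {
  d <- oracle_spl(W)
  n <- nrow(W)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_clustering <- function(W) {
  n <- nrow(W)
  A <- (W / max(W))^(1 / 3)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) s <- s + A[i, j] * A[j, h] * A[h, i]
    }
    ci[i] <- s / (k * (k - 1))
  }
  mean(ci)
}

oracle_local_eff <- function(W) {
  n <- nrow(W)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    vals[i] <- oracle_eglob(W[nb, nb, drop = FALSE])
  }
  mean(vals)
}

# --- cohort fixtures -------------------------------------------------------

# a tiny covariate table with balanced groups; optional response effects
toy_cohort_table <- function(n_per_group = 20, groups = c("NCI", "mild", "moderate"),
                             seed = 1) {
  withr::with_seed(seed, {
    n <- n_per_group * length(groups)
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = rep(groups, each = n_per_group),
      age = round(rnorm(n, 70, 5), 1),
      gender = sample(c("F", "M"), n, replace = TRUE),
      handedness = sample(c("R", "L"), n, replace = TRUE, prob = c(0.95, 0.05))
    )
  })
}
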
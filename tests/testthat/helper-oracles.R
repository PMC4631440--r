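# Hand-rolled plain-R oracles, independent of both package code paths and of
# igraph: a literal double loop for degrees, stack DFS for components, and a
# queue BFS for hop distances. Deliberately naive; used on small instances.

oracle_degrees <- function(x, zeta) {
  n <- length(x)
  d <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && abs(x[i] - x[j]) <= zeta) d[i] <- d[i] + 1L
    }
  }
  d
}

oracle_components <- function(x, zeta) {
  n <- length(x)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    stack <- start
    comp[start] <- cid
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- which(abs(x - x[i]) <= zeta & is.na(comp))
      comp[nb] <- cid
      stack <- c(stack, nb)
    }
  }
  # canonical labels: number clusters by their smallest member
  mins <- tapply(x, comp, min)
  as.integer(rank(mins, ties.method = "first")[as.character(comp)])
}

# all-pairs hop distances by queue BFS; Inf across components
oracle_distances <- function(x, zeta) {
  n <- length(x)
  adj <- lapply(seq_len(n), function(i) {
    setdiff(which(abs(x - x[i]) <= zeta), i)
  })
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      i <- queue[1]
      queue <- queue[-1]
      for (j in adj[[i]]) {
        if (is.infinite(d[s, j])) {
          d[s, j] <- d[s, i] + 1
          queue <- c(queue, j)
        }
      }
    }
  }
  d
}

# spread metrics from an oracle distance matrix, mirroring the package's
# definitions: L_avg over connected unordered pairs, D within largest cluster
oracle_spread <- function(x, zeta) {
  d <- oracle_distances(x, zeta)
  comp <- oracle_components(x, zeta)
  ut <- d[upper.tri(d)]
  finite <- ut[is.finite(ut)]
  if (length(finite) == 0) return(list(diameter = NA, avg = NA))
  sizes <- tabulate(comp)
  giant <- which(sizes == max(sizes))[1]
  idx <- which(comp == giant)
  list(diameter = max(d[idx, idx]), avg = mean(finite))
}

# random 1-D instances of assorted shapes for property tests
random_instance <- function(n, seed) {
  set.seed(seed)
  shape <- sample(4, 1)
  x <- switch(shape,
              rnorm(n, 100, 20),
              rlnorm(n, 1, 0.5),
              runif(n, 0, 50),
              c(rnorm(ceiling(n / 2), 0, 1), rnorm(floor(n / 2), 10, 1)))
  # occasional exact duplicates to exercise tie handling
  if (n >= 10) x[1:3] <- x[4]
  zeta <- runif(1, 0.001, 0.3) * diff(range(x))
  list(x = x, zeta = zeta)
}

# the outlier-neutrality claim's domain: a dense unimodal core plus a few
# injected extreme values that stay isolated at the selected zeta
outlier_instance <- function(n, seed) {
  set.seed(seed)
  core <- rnorm(n, 100, 10)
  k <- sample(1:5, 1)
  spikes <- 100 + sample(c(-1, 1), k, replace = TRUE) * runif(k, 100, 300)
  sample(c(core, spikes))
}
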
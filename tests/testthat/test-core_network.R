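test_that("sample ingestion enforces invariants", {
  expect_s3_class(nb_sample(1), "nb_sample")
  expect_error(nb_sample(numeric(0)), class = "netfreq_invalid_input")
  expect_error(nb_sample(c(1, NA)), class = "netfreq_invalid_input")
  expect_error(nb_sample(c(1, Inf)), class = "netfreq_invalid_input")
  expect_error(build_network(nb_sample(1:3), -0.5),
               class = "netfreq_invalid_parameter")
})

test_that("both construction paths reproduce the worked adjacency examples", {
  for (method in c("fast", "reference")) {
    net <- build_network(nb_sample(c(1, 2, 4)), 1, method = method)
    expect_identical(net$degrees, c(1L, 1L, 0L))
    expect_equal(net$edge_count, 1)
    expect_identical(net$cluster_labels, c(1L, 1L, 2L))
    expect_identical(net$giant_size, 2L)

    far <- build_network(nb_sample(c(0, 100)), 1, method = method)
    expect_equal(far$edge_count, 0)
    expect_identical(far$degrees, c(0L, 0L))
    expect_identical(far$cluster_labels, 1:2)

    chain <- build_network(nb_sample(c(0, 0.5, 1.0)), 0.6, method = method)
    expect_identical(chain$degrees, c(1L, 2L, 1L))
  }
})

test_that("zeta >= range gives the complete graph; duplicates stay adjacent at zeta = 0", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  net <- build_network(nb_sample(x), diff(range(x)))
  expect_true(all(net$degrees == length(x) - 1L))
  expect_identical(max(net$cluster_labels), 1L)

  dup <- build_network(nb_sample(c(2, 2, 2, 7)), 0)
  expect_identical(dup$degrees, c(2L, 2L, 2L, 0L))
  expect_equal(dup$edge_count, 3)
})

test_that("fast path equals reference and the hand-rolled double-loop oracle", {
  # seeded lognormal draw at 5% of the median, degrees vs literal Eq-style loop
  set.seed(77)
  x <- rlnorm(200, 1, 0.5)
  zeta <- 0.05 * median(x)
  net <- build_network_fast(nb_sample(x), zeta)
  expect_identical(net$degrees, oracle_degrees(x, zeta))

  for (seed in 1:25) {
    inst <- random_instance(sample(2:120, 1), seed)
    fast <- build_network_fast(nb_sample(inst$x), inst$zeta)
    ref <- build_network_reference(nb_sample(inst$x), inst$zeta)
    expect_identical(fast$degrees, ref$degrees)
    expect_equal(fast$edge_count, ref$edge_count)
    expect_identical(fast$cluster_labels, ref$cluster_labels)
    expect_identical(fast$giant_size, ref$giant_size)
    # third, library-free route
    expect_identical(fast$degrees, oracle_degrees(inst$x, inst$zeta))
    expect_identical(fast$cluster_labels, oracle_components(inst$x, inst$zeta))
  }
})

test_that("handshake, degree bounds and permutation invariance hold", {
  for (seed in 1:20) {
    inst <- random_instance(80, seed + 500)
    net <- build_network_fast(nb_sample(inst$x), inst$zeta)
    expect_equal(sum(net$degrees), 2 * net$edge_count)
    expect_true(all(net$degrees >= 0 & net$degrees <= net$n - 1))

    set.seed(seed)
    perm <- sample(length(inst$x))
    pnet <- build_network_fast(nb_sample(inst$x[perm]), inst$zeta)
    expect_identical(pnet$degrees, net$degrees[perm])
    expect_identical(pnet$cluster_labels, net$cluster_labels[perm])
    expect_equal(pnet$edge_count, net$edge_count)
    expect_identical(pnet$giant_size, net$giant_size)
  }
})

test_that("degrees, edges and p_g are monotone in zeta", {
  for (seed in 1:10) {
    inst <- random_instance(60, seed + 900)
    zetas <- sort(runif(6, 0, 0.4) * diff(range(inst$x)))
    nets <- lapply(zetas, function(z) build_network_fast(nb_sample(inst$x), z))
    degs <- sapply(nets, `[[`, "degrees")
    expect_true(all(apply(degs, 1, function(r) all(diff(r) >= 0))))
    expect_true(all(diff(sapply(nets, `[[`, "edge_count")) >= 0))
    expect_true(all(diff(sapply(nets, giant_cluster_proportion)) >= 0))
  }
})

test_that("giant cluster proportion matches forced partitions", {
  net <- build_network_fast(nb_sample(c(0, 1, 2, 10, 11)), 1.5)
  expect_equal(giant_cluster_proportion(net), 0.6)
  expect_identical(net$cluster_labels, c(1L, 1L, 1L, 2L, 2L))

  two <- build_network_fast(nb_sample(c(0, 1000)), 1)
  expect_equal(giant_cluster_proportion(two), 0.5)
  # tie between equal clusters goes to the one holding the smallest value
  expect_identical(two$giant_cluster, 1L)
})
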
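test_that("mode estimation tie-averages all maximum-degree values", {
  # two-way tie engineered at 13.18 and 13.09 (the bimodal electricity case)
  x <- c(13.00, 13.09, 13.18, 13.27)
  net <- build_network_fast(nb_sample(x), 0.1)
  m <- mode_estimate(net)
  expect_equal(m$max_degree, 2L)
  expect_equal(sort(m$tied_values), c(13.09, 13.18))
  expect_equal(round(m$mode_value, 2), 13.13)

  single <- mode_estimate(build_network_fast(nb_sample(42), 1))
  expect_equal(single$mode_value, 42)
  expect_equal(single$max_degree, 0L)
})

test_that("mode equals the brute-force degree argmax on seeded draws", {
  set.seed(123)
  x <- rnorm(200)
  zeta <- 0.2
  m <- mode_estimate(build_network_fast(nb_sample(x), zeta))
  d <- oracle_degrees(x, zeta)
  expect_equal(m$max_degree, max(d))
  expect_equal(m$mode_value, mean(x[d == max(d)]))
})

test_that("boundary check flags modes within one zeta of the support edge", {
  s <- nb_sample(c(1, 5, 9))
  expect_true(boundary_check(1, s, 0.5))    # mode at the minimum
  expect_true(boundary_check(8.7, s, 0.5))  # within zeta of the maximum
  expect_false(boundary_check(5, s, 0.5))   # mid-range, small zeta
  expect_true(boundary_check(5, s, 4))      # huge zeta swallows the range
})

test_that("exponential pipelines put the mode near the support edge", {
  # a monotone density has no interior mode; the degree-curve argmax should
  # land in the lowest part of the observed range (data-scale closeness --
  # the one-zeta margin itself fires only sporadically at n = 100)
  rel <- sapply(1:10, function(i) {
    s <- simulate_sample(dist_spec("exponential", n = 100, seed = 4000 + i))
    r <- run_pipeline(s, list(with_paths = FALSE))
    (r$report$M - min(s$values)) / diff(range(s$values))
  })
  expect_true(mean(rel < 0.15) >= 0.8)
})

test_that("local modes shortlist true peaks and collapse plateaus", {
  s <- simulate_sample(dist_spec("mixture", n = 400, seed = 11))
  lm <- local_modes(build_network_fast(s, 1.0))
  expect_length(lm, 2)
  locs <- sort(sapply(lm, `[[`, "mode_value"))
  expect_lt(abs(locs[1] - 0), 0.5)
  expect_lt(abs(locs[2] - 10), 0.5)

  # clean unimodal degree curve: a single mode equal to mode_estimate
  tri <- nb_sample(c(0, 1, 1.9, 2.7, 3.4, 4.0, 4.5))  # shrinking gaps
  net <- build_network_fast(tri, 1.0)
  lm2 <- local_modes(net)
  expect_length(lm2, 1)
  expect_equal(lm2[[1]]$mode_value, mode_estimate(net)$mode_value)

  # all degrees equal: one plateau mode averaging everything
  flat <- build_network_fast(nb_sample(c(1, 1, 1)), 0.5)
  lm3 <- local_modes(flat)
  expect_length(lm3, 1)
  expect_equal(lm3[[1]]$mode_value, 1)
})

test_that("shortest paths match on worked chains", {
  for (fn in list(shortest_paths_bfs, shortest_paths_interval)) {
    chain <- fn(build_network_fast(nb_sample(c(0, 1, 2)), 1))
    expect_equal(chain$diameter, 2L)
    expect_equal(chain$avg_path_length, 4 / 3)

    complete <- fn(build_network_fast(nb_sample(c(5, 5.1, 5.2)), 1))
    expect_equal(complete$diameter, 1L)
    expect_equal(complete$avg_path_length, 1)

    hops <- fn(build_network_fast(nb_sample(c(0, 9, 18, 27)), 10))
    expect_equal(hops$diameter, 3L)
    expect_equal(hops$avg_path_length, 10 / 6)

    empty <- fn(build_network_fast(nb_sample(c(0, 100)), 1))
    expect_false(empty$computable)
    expect_true(is.na(empty$avg_path_length))
  }
})

test_that("greedy interval paths equal BFS and the hand-rolled oracle", {
  for (seed in 1:15) {
    inst <- random_instance(sample(5:60, 1), seed + 300)
    net <- build_network_fast(nb_sample(inst$x), inst$zeta)
    a <- shortest_paths_interval(net)
    b <- shortest_paths_bfs(net)
    expect_identical(a$computable, b$computable)
    if (a$computable) {
      expect_equal(a$diameter, b$diameter)
      expect_equal(a$avg_path_length, b$avg_path_length)
      o <- oracle_spread(inst$x, inst$zeta)
      expect_equal(a$diameter, as.integer(o$diameter))
      expect_equal(a$avg_path_length, o$avg)
    }
  }
})

test_that("D and L_avg peak and decay to 1 as zeta fills the graph", {
  set.seed(8)
  x <- rnorm(100, 100, 20)
  grid <- seq(0.01, 1, length.out = 15) * diff(range(x))
  sw <- sweep_zeta(nb_sample(x), grid, with_paths = TRUE)
  expect_equal(sw$d_curve[15], 1)
  expect_equal(sw$l_curve[15], 1)
  expect_gt(max(sw$d_curve, na.rm = TRUE), 1)
  # once past the peak the tail is non-increasing down to 1
  pk <- which.max(sw$d_curve)
  expect_true(all(diff(sw$d_curve[pk:15]) <= 0))
})
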
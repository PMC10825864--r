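test_that("CSR generator matches the Poisson expectation and containment oracle", {
  fp <- circle_footprint(5000)  # area ~78.5 um^2
  expect_equal(nrow(sample_receptors_csr(fp, 0, 1)$positions), 0)
  # mean count over 200 replicates within 3 SE of lambda * area (h = 0)
  lambda <- 50
  counts <- vapply(1:200, function(s)
    nrow(sample_receptors_csr(fp, lambda, s, hardcore = 0)$positions), numeric(1))
  expected <- lambda * fp$area / 1e6
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  f <- sample_receptors_csr(fp, 20, 3)
  expect_true(all(f$cluster_id == -1L))
  expect_true(all(oracle_point_in_polygon(f$positions[, 1], f$positions[, 2],
                                          fp$boundary)))
})

test_that("Thomas generator hits its analytic mean count up to edge/hard-core losses", {
  fp <- circle_footprint(5000)
  expect_equal(nrow(sample_receptors_clustered(
    fp, cluster_params(kappa = 0, mu = 20), 1)$positions), 0)
  params <- cluster_params(kappa = 0.5, mu = 20, sigma = 30, hardcore = 2)
  counts <- vapply(1:200, function(s)
    nrow(sample_receptors_clustered(fp, params, s)$positions), numeric(1))
  expected <- params$kappa * params$mu * fp$area / 1e6  # ~785
  # boundary discard (~sigma * perimeter / area) and hard-core rejection trim
  # a few percent; the realised mean must sit just below the analytic value
  expect_lt(mean(counts), expected + 3 * sd(counts) / sqrt(200))
  expect_gt(mean(counts), 0.92 * expected)
})

test_that("generated fields respect containment, hard-core and determinism", {
  fp <- sample_cell_footprint(5, 4000, 0.3)
  params <- cluster_params(kappa = 0.3, mu = 15, sigma = 30, hardcore = 2)
  for (s in 1:5) {
    f <- sample_receptors_clustered(fp, params, s)
    expect_true(all(oracle_point_in_polygon(f$positions[, 1], f$positions[, 2],
                                            fp$boundary)))
    if (nrow(f$positions) >= 2 && nrow(f$positions) <= 500)
      expect_gte(min(oracle_nn_distances(f$positions)), params$hardcore)
  }
  a <- sample_receptors_clustered(fp, params, 11)
  b <- sample_receptors_clustered(fp, params, 11)
  expect_identical(a$positions, b$positions)
  expect_identical(a$cluster_id, b$cluster_id)
  c1 <- sample_receptors_csr(fp, 10, 11)
  c2 <- sample_receptors_csr(fp, 10, 11)
  expect_identical(c1$positions, c2$positions)
})

test_that("clustered fields have smaller nearest-neighbour distances than matched CSR", {
  fp <- circle_footprint(4000)
  params <- cluster_params(kappa = 0.4, mu = 25, sigma = 30)
  wins <- 0
  for (s in 1:20) {
    cl <- sample_receptors_clustered(fp, params, derive_seed(s, "cl"))
    intensity <- nrow(cl$positions) / (fp$area / 1e6)
    cs <- sample_receptors_csr(fp, intensity, derive_seed(s, "csr"))
    wins <- wins + (median(nearest_neighbor_distances(cl)) <
                      median(nearest_neighbor_distances(cs)))
  }
  expect_lt(stats::binom.test(wins, 20, 0.5, alternative = "greater")$p.value,
            0.01)  # sign test
})

test_that("nearest-neighbour distances match the pairwise oracle and edge cases", {
  f2 <- make_field(rbind(c(10, 10), c(60, 10)))
  expect_equal(nearest_neighbor_distances(f2), c(50, 50))
  set.seed(8)
  pos <- cbind(runif(300, 0, 1000), runif(300, 0, 1000))
  f <- make_field(pos)
  expect_equal(nearest_neighbor_distances(f), oracle_nn_distances(pos))
  fdup <- make_field(rbind(pos, pos[1, , drop = FALSE]))
  expect_equal(nearest_neighbor_distances(fdup)[301], 0)
  expect_error(nearest_neighbor_distances(make_field(pos[1, , drop = FALSE])),
               "fewer than 2")
})

test_that("disruption conserves count, is identity at dose 0, and rejects negatives", {
  fp <- circle_footprint(4000)
  f <- sample_receptors_clustered(fp, cluster_params(), 3)
  dp <- disruption_params(p_max = 0.8, ec50 = 1, hill = 1, tau = 8)
  expect_identical(apply_disruption(f, 0, 24, dp, 1)$positions, f$positions)
  expect_identical(apply_disruption(f, 10, 0, dp, 1)$positions, f$positions)
  for (dose in c(0.01, 1, 100)) for (tm in c(2, 24)) {
    fd <- apply_disruption(f, dose, tm, dp, 7)
    expect_identical(nrow(fd$positions), nrow(f$positions))
  }
  expect_error(apply_disruption(f, -1, 2, dp, 1), "dose")
  expect_error(apply_disruption(f, 1, -2, dp, 1), "time")
})

test_that("saturated disruption is distributionally equivalent to fresh CSR", {
  fp <- circle_footprint(4000)
  dp <- disruption_params(p_max = 1, ec50 = 0.01, hill = 1, tau = 0.1)
  rejections <- 0
  for (s in 1:20) {
    f <- sample_receptors_clustered(fp, cluster_params(hardcore = 0),
                                    derive_seed(s, "f"))
    fd <- apply_disruption(f, 1000, 100, dp, derive_seed(s, "d"))
    expect_true(all(fd$cluster_id == -1L))
    intensity <- nrow(fd$positions) / (fp$area / 1e6)
    fresh <- sample_receptors_csr(fp, intensity, derive_seed(s, "c"), hardcore = 0)
    p <- suppressWarnings(stats::ks.test(nearest_neighbor_distances(fd),
                                         nearest_neighbor_distances(fresh))$p.value)
    rejections <- rejections + (p < 0.01)
  }
  expect_lte(rejections, 2)  # ~0.2 expected under the null at alpha = 0.01
})

test_that("expected surviving-cluster fraction is monotone in dose and time", {
  fp <- circle_footprint(3000)
  dp <- disruption_params(p_max = 0.8, ec50 = 1, hill = 1, tau = 8)
  doses <- c(0, 0.1, 1, 10)
  times <- c(2, 8, 24)
  frac <- matrix(0, length(doses), length(times))
  for (s in 1:50) {
    f <- sample_receptors_clustered(fp, cluster_params(), derive_seed(s, "mono"))
    n <- nrow(f$positions)
    for (i in seq_along(doses)) for (j in seq_along(times)) {
      fd <- apply_disruption(f, doses[i], times[j], dp, derive_seed(s, "d", j))
      frac[i, j] <- frac[i, j] + sum(fd$cluster_id >= 0) / n / 50
    }
  }
  for (j in seq_along(times)) expect_true(all(diff(frac[, j]) <= 0))
  for (i in seq_along(doses)[-1]) expect_true(all(diff(frac[i, ]) <= 0))
})

test_that("receptor fields round-trip through CSV losslessly", {
  fp <- sample_cell_footprint(2, 3000, 0.2)
  f <- sample_receptors_clustered(fp, cluster_params(kappa = 0.3), 9)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_receptor_csv(f, path)
  g <- read_receptor_csv(path, fp)
  expect_equal(g$positions, f$positions)
  expect_identical(g$cluster_id, f$cluster_id)
})
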
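test_that("a lone fluorophore never turns on; a pair in the window always does", {
  f1 <- make_field(matrix(c(100, 100), 1, 2))
  e1 <- aie_emission(f1, labeling_efficiency = 1, rng_seed = 1)
  expect_equal(sum(e1$emissive), 0)
  f2 <- make_field(rbind(c(100, 100), c(105, 100)))  # 5 nm apart
  e2 <- aie_emission(f2, labeling_efficiency = 1, rng_seed = 1)
  expect_true(all(e2$emissive))
  expect_equal(sum(e2$brightness), 2 * aie_params()$unit_brightness)
})

test_that("the AIE distance window is a closed interval at both edges", {
  p <- aie_params()
  at <- function(d) {
    f <- make_field(rbind(c(100, 100), c(100 + d, 100)))
    sum(aie_emission(f, p, labeling_efficiency = 1, rng_seed = 1)$emissive)
  }
  expect_equal(at(p$d_min), 2)
  expect_equal(at(p$d_max), 2)
  expect_equal(at(p$d_min - 1e-6), 0)
  expect_equal(at(p$d_max + 1e-6), 0)
})

test_that("AIE emissive flags match the brute-force pairwise oracle", {
  p <- aie_params()
  for (s in 1:5) {
    set.seed(s)
    pos <- cbind(runif(200, 0, 400), runif(200, 0, 400))
    f <- make_field(pos)
    e <- aie_emission(f, p, labeling_efficiency = 0.8, rng_seed = s)
    expect_identical(e$emissive,
                     oracle_aie_emissive(pos, e$labeled, p$d_min, p$d_max))
  }
})

test_that("the AIE pair relation is symmetric on random fields", {
  for (s in 1:10) {
    set.seed(s)
    pos <- cbind(runif(120, 0, 150), runif(120, 0, 150))
    e <- aie_emission(make_field(pos), labeling_efficiency = 1, rng_seed = s)
    # every emissive point must have an emissive partner inside the window
    idx <- which(e$emissive)
    for (i in idx) {
      d <- sqrt(rowSums(sweep(pos[idx, , drop = FALSE], 2, pos[i, ])^2))
      d <- d[d > 0]
      expect_true(any(d >= aie_params()$d_min & d <= aie_params()$d_max))
    }
  }
})

test_that("clustered fields have a higher emissive fraction than matched CSR", {
  fp <- circle_footprint(4000)
  wins <- 0
  for (s in 1:20) {
    cl <- sample_receptors_clustered(fp, cluster_params(), derive_seed(s, "c"))
    intensity <- nrow(cl$positions) / (fp$area / 1e6)
    cs <- sample_receptors_csr(fp, intensity, derive_seed(s, "r"))
    fr <- function(f) {
      e <- aie_emission(f, rng_seed = derive_seed(s, "lab"))
      mean(e$emissive)
    }
    wins <- wins + (fr(cl) > fr(cs))
  }
  expect_lt(stats::binom.test(wins, 20, 0.5, alternative = "greater")$p.value,
            0.01)
})

test_that("the conventional dye rule ignores geometry and tracks labeled count", {
  set.seed(3)
  pos <- cbind(runif(400, 0, 5000), runif(400, 0, 5000))
  f <- make_field(pos)
  e <- conventional_emission(f, unit_brightness = 120,
                             labeling_efficiency = 0.7, rng_seed = 5)
  expect_identical(e$emissive, e$labeled)
  expect_equal(sum(e$brightness), 120 * sum(e$labeled))
  e1 <- conventional_emission(f, 120, labeling_efficiency = 1, rng_seed = 5)
  expect_equal(sum(e1$emissive), 400)
})

test_that("full disruption leaves expected conventional brightness unchanged", {
  fp <- circle_footprint(3000)
  dp <- disruption_params(p_max = 1, ec50 = 0.01, tau = 0.1)
  diffs <- ns <- numeric(50)
  for (s in 1:50) {
    f <- sample_receptors_clustered(fp, cluster_params(), derive_seed(s, "f"))
    fd <- apply_disruption(f, 1000, 100, dp, derive_seed(s, "d"))
    b0 <- sum(conventional_emission(f, 100, 0.9, derive_seed(s, "l0"))$brightness)
    b1 <- sum(conventional_emission(fd, 100, 0.9, derive_seed(s, "l1"))$brightness)
    diffs[s] <- b1 - b0
    ns[s] <- nrow(f$positions)
  }
  # labeling is Binomial(n, 0.9) per arm; the mean difference over 50 seeds
  # must sit within 3 SE of zero
  se <- sqrt(2 * mean(ns) * 0.9 * 0.1) * 100 / sqrt(50)
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("poisson_dar mode scales brightness with the drawn dye count", {
  f <- make_field(rbind(c(100, 100), c(104, 100)))
  e <- aie_emission(f, labeling_efficiency = 1, rng_seed = 2,
                    dye_mode = "poisson_dar", dar = 1.35)
  expect_true(all(e$brightness[e$emissive] %% aie_params()$unit_brightness == 0))
  # co-located dyes on one antibody must not gate emission by themselves
  f1 <- make_field(matrix(c(100, 100), 1, 2))
  e1 <- aie_emission(f1, labeling_efficiency = 1, rng_seed = 2,
                     dye_mode = "poisson_dar", dar = 10)
  expect_equal(sum(e1$emissive), 0)
})
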
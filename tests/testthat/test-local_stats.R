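chain3 <- function() {
  rs <- region_set(c("A", "B", "C"), cbind(c(0, 1, 2), 0))
  distance_band(rs, 1)
}

test_that("Gi on a 3-chain matches hand enumeration", {
  t <- local_gi(c(A = 1, B = 2, C = 3), chain3(), star = FALSE)
  expect_equal(t$statistic[t$unit_id == "A"], 2 / 5)   # x_B / (x_B + x_C)
  expect_equal(t$statistic[t$unit_id == "B"], 1)       # (x_A + x_C)/(x_A + x_C)
})

test_that("Gi is identically 1 on a complete graph", {
  rs <- region_set(sprintf("u%d", 1:5), cbind(runif(5), runif(5)))
  w <- distance_band(rs, 10)
  set.seed(9)
  t <- local_gi(rlnorm(5), w, star = FALSE)
  expect_equal(t$statistic, rep(1, 5))
})

test_that("local Gi and Gi* match the double-loop oracle on random instances", {
  set.seed(314)
  for (rep in 1:20) {
    inst <- random_instance(sample(8:25, 1))
    for (star in c(FALSE, TRUE)) {
      t <- local_gi(inst$x, inst$w, star = star)
      expect_equal(t$statistic, oracle_local_gi(inst$x, inst$w$w, star),
                   tolerance = 1e-12)
      expect_true(all(t$statistic >= 0 & t$statistic <= 1))
    }
  }
})

test_that("local Moran on the 2x2 checkerboard is -2 everywhere and sums to S0*I", {
  w <- distance_band(grid_rs(2), 1)
  x <- c(1, 0, 0, 1)
  t <- local_moran(x, w)
  expect_equal(t$statistic, rep(-2, 4))
  expect_equal(sum(t$statistic), sum(w$w) * moran_i(x, w))
})

test_that("local Moran matches the double-loop oracle on random instances", {
  set.seed(159)
  for (rep in 1:20) {
    inst <- random_instance(sample(8:36, 1))
    t <- local_moran(inst$x, inst$w)
    expect_equal(t$statistic, oracle_local_moran(inst$x, inst$w$w),
                 tolerance = 1e-10)
    # local-global identity
    expect_equal(sum(t$statistic), sum(inst$w$w) * moran_i(inst$x, inst$w),
                 tolerance = 1e-10)
  }
})

test_that("analytic conditional moments agree with Monte-Carlo permutation moments", {
  set.seed(271)
  inst <- random_instance(25, grid = TRUE)
  x <- inst$x; w <- inst$w
  p_lm <- conditional_permutation(x, w, "local_moran", n_perm = 20000, seed = 1)
  p_gi <- conditional_permutation(x, w, "gi", n_perm = 20000, seed = 2)
  t_gi <- local_gi(x, w, star = FALSE)
  zc <- as.numeric(x) - mean(x); m2 <- mean(zc^2)
  m <- w$w; diag(m) <- 0
  for (i in seq_len(w$n)) {
    mo <- mesospat:::cond_sum_moments(m[i, -i], zc[-i])
    sd_an <- abs(zc[i] / m2) * sqrt(mo$var)
    # means compared on the z scale (units of the null sd), sds relatively
    expect_lt(abs(attr(p_lm, "perm_mean")[[i]] - zc[i] / m2 * mo$mean) / sd_an,
              0.05)
    expect_lt(abs(attr(p_lm, "perm_sd")[[i]] / sd_an - 1), 0.03)
    # Gi z reconstructed from MC reference moments matches the analytic z
    z_mc <- (t_gi$statistic[i] - attr(p_gi, "perm_mean")[[i]]) /
      attr(p_gi, "perm_sd")[[i]]
    expect_lt(abs(t_gi$z[i] - z_mc), 0.1)
  }
})

test_that("a planted high block centers the strongest Gi* z and is detected", {
  rs <- grid_rs(7)
  w <- distance_band(rs, 1)
  x <- rep(1, 49)
  block <- which(rs$centroids[, 1] %in% 2:4 & rs$centroids[, 2] %in% 2:4)
  x[block] <- 8
  center <- unname(which(rs$centroids[, 1] == 3 & rs$centroids[, 2] == 3))
  t <- local_gi(x, w, star = TRUE)
  expect_equal(which.max(t$z), center)
  expect_true(all(t$z[block] > 1.96))
})

test_that("hot/cold bins follow the 90/95/99 thresholds, strongest wins", {
  t <- data.frame(unit_id = letters[1:6], statistic = 1,
                  z = c(2.0, -3.1, 0, 1.7, 2.576, NA),
                  p_normal = NA, p_perm = NA, label = "x")
  out <- hot_cold_classify(t)
  expect_equal(out$label,
               c("hot_95", "cold_99", "not_significant", "hot_90",
                 "hot_99", "not_evaluated"))
})

test_that("conditional permutation p values are seeded and reproducible", {
  inst <- random_instance(16, grid = TRUE)
  p1 <- conditional_permutation(inst$x, inst$w, "gi_star", 199, seed = 5)
  p2 <- conditional_permutation(inst$x, inst$w, "gi_star", 199, seed = 5)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_true(all(p1 > 0 & p1 <= 1))
})

test_that("LISA typing follows the Moran scatterplot quadrants", {
  rs <- grid_rs(5)
  w <- distance_band(rs, 1)
  set.seed(77)
  x <- 5 + runif(25, 0, 0.5)          # moderate heterogeneous background
  x[w$w[13, ] > 0] <- 1               # distinctly low ring of neighbors
  x[13] <- 40                         # extreme high center: a strong outlier
  t <- local_moran(x, w)
  p <- conditional_permutation(x, w, "local_moran", 999, seed = 8)
  out <- lisa_classify(t, x, w, p_perm = p, alpha = 0.05)
  expect_equal(out$label[13], "HL")   # high value among low neighbors
  nb <- which(w$w[13, ] > 0)
  sig_nb <- nb[out$p_perm[nb] <= 0.05]
  expect_true(all(out$label[sig_nb] %in% c("LH", "LL")))
  # degenerate threshold: every unit gets a quadrant label
  out_all <- lisa_classify(t, x, w, p_perm = p, alpha = 1.0)
  expect_true(all(out_all$label %in% c("HH", "LL", "LH", "HL")))
})

test_that("label maps are equivariant under unit reordering", {
  set.seed(63)
  rs <- grid_rs(4)
  x <- rlnorm(16); names(x) <- rs$ids
  perm <- sample(16)
  rs_p <- region_set(rs$ids[perm], rs$centroids[perm, ])
  w <- distance_band(rs, 1); w_p <- distance_band(rs_p, 1)
  t <- hot_cold_classify(local_gi(x, w, star = TRUE))
  t_p <- hot_cold_classify(local_gi(x[perm], w_p, star = TRUE))
  expect_equal(t_p$label, t$label[perm])
  expect_equal(t_p$statistic, t$statistic[perm], tolerance = 1e-12)
})

test_that("BH mask reproduces the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.9), q = 0.05), c(TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 4)), rep(FALSE, 4))
  expect_equal(bh_fdr(c(0.5, 0.99, 1), q = 1), rep(TRUE, 3))
  # monotone in q
  set.seed(5)
  p <- runif(20)
  m1 <- bh_fdr(p, 0.05); m2 <- bh_fdr(p, 0.2)
  expect_true(all(m2[m1]))
})

test_that("islands carry missing local statistics when allowed", {
  rs <- region_set(c("A", "B", "C"), cbind(c(0, 1, 10), 0))
  w <- distance_band(rs, 1.5)        # C is an island
  t <- local_gi(c(A = 1, B = 2, C = 3), w)
  expect_true(is.na(t$statistic[3]))
  expect_equal(t$label[3], "not_evaluated")
})
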
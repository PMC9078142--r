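test_that("global radius matches the brute-force pooled-median oracle", {
  # 101 evenly spaced points on a line: all nearest-neighbor distances are 1
  line <- matrix(0, 101, 7); line[, 1] <- 0:100
  expect_equal(global_radius(line, fraction = 0.01), 1)

  V <- random_points(300, seed = 5)
  expect_equal(global_radius(V, fraction = 0.01),  # k = 2
               oracle_global_radius(V, fraction = 0.01))
  V2 <- random_points(60, seed = 6)
  expect_equal(global_radius(V2), oracle_global_radius(V2))
  expect_error(global_radius(V[1, , drop = FALSE]), "at least 2")
  expect_warning(global_radius(matrix(1, 5, 7)), "Degenerate")
})

test_that("local radius is the median pairwise distance between actives", {
  two <- matrix(c(0, 3), ncol = 1)[, rep(1, 7)] / sqrt(7)
  expect_equal(local_radius(two), 3)
  # collinear actives at 0, 1, 2 -> pairwise {1, 1, 2} -> median 1
  tri <- matrix(0, 3, 7); tri[, 1] <- c(0, 1, 2)
  expect_equal(local_radius(tri), 1)
  A <- random_points(50, seed = 8)
  expect_equal(local_radius(A), oracle_local_radius(A))
  expect_error(local_radius(A[1, , drop = FALSE]), "at least 2")
})

test_that("raw global score equals the brute-force membership fraction", {
  S <- random_points(200, seed = 9)
  V <- random_points(500, seed = 10)
  r <- 1.5
  expect_equal(raw_global_score(S, V, r),
               sum(oracle_members_within(V, S, r)) / 500)
  expect_equal(raw_global_score(S, S, 0), 1)      # full coverage
  expect_equal(raw_global_score(S, V + 100, 0.1), 0)  # empty intersection
})

test_that("raw local score is |A| / |nu_active| with a pseudo-count fallback", {
  A <- matrix(0, 3, 7)
  V <- matrix(0.05, 6, 7)
  rl <- raw_local_score(A, V, r_local = 1)
  expect_equal(as.numeric(rl), 0.5)  # 3 actives / 6 virtual neighbors
  expect_identical(attr(rl, "n_active_neighbors"), 6L)

  far <- matrix(50, 4, 7)
  rl0 <- raw_local_score(A, far, r_local = 1)
  expect_equal(as.numeric(rl0), 6)   # |A| / 0.5 pseudo-count
  expect_true(attr(rl0, "saturation_extreme"))

  A2 <- random_points(10, seed = 11); V2 <- random_points(400, seed = 12)
  rl2 <- raw_local_score(A2, V2, 1.2)
  expect_identical(attr(rl2, "n_active_neighbors"),
                   sum(oracle_members_within(V2, A2, 1.2)))
})

test_that("neighborhood membership uses set semantics and closed balls", {
  # five coincident members: one virtual inside all five neighborhoods
  S <- matrix(0, 5, 7)
  V <- rbind(rep(0.1, 7), rep(10, 7))
  expect_equal(raw_global_score(S, V, r_global = 1), 0.5)
  # boundary point at distance exactly r is inside (closed ball)
  Vb <- matrix(c(1, rep(0, 6)), 1)
  expect_equal(raw_global_score(matrix(0, 1, 7), Vb, r_global = 1), 1)
})

test_that("adding an assayed member never decreases the global score", {
  set.seed(13)
  for (rep in 1:200) {
    n_s <- sample(3:12, 1); n_v <- sample(5:40, 1)
    S <- matrix(rnorm(n_s * 7), n_s)
    V <- matrix(rnorm(n_v * 7), n_v)
    r <- runif(1, 0.5, 3)
    base <- raw_global_score(S, V, r)
    grown <- raw_global_score(rbind(S, rnorm(7)), V, r)
    expect_gte(grown, base)
  }
})

test_that("a virtual compound added inside an active neighborhood strictly lowers the local score", {
  set.seed(14)
  for (rep in 1:200) {
    n_a <- sample(3:8, 1); n_v <- sample(5:30, 1)
    A <- matrix(rnorm(n_a * 7), n_a)
    V <- matrix(rnorm(n_v * 7), n_v)
    r <- runif(1, 0.3, 2)
    base <- raw_local_score(A, V, r)
    inside <- A[sample(n_a, 1), ] + runif(7, -1, 1) * r / 10
    grown <- raw_local_score(A, rbind(V, inside), r)
    expect_lt(as.numeric(grown), as.numeric(base) + 1e-15)
  }
})

test_that("active neighborhoods are nested in assayed neighborhoods when radii allow", {
  set.seed(15)
  for (rep in 1:50) {
    n_a <- sample(2:6, 1); n_i <- sample(2:10, 1); n_v <- sample(10:50, 1)
    A <- matrix(rnorm(n_a * 7), n_a)
    S <- rbind(A, matrix(rnorm(n_i * 7), n_i))
    V <- matrix(rnorm(n_v * 7), n_v)
    r_g <- runif(1, 0.5, 3); r_l <- runif(1, 0, 1) * r_g
    nb <- assign_neighborhoods(S, A, V, r_g, r_l)
    expect_true(all(!nb$in_active | nb$in_assayed))
  }
})

test_that("z-scores are centered, unit-scaled and rank-preserving", {
  set.seed(16)
  rg <- runif(12); rl <- runif(12, 0.05, 20)
  z <- to_z_scores(rg, rl)
  expect_equal(mean(z$z_global), 0, tolerance = 1e-12)
  expect_equal(sd(z$z_global), 1, tolerance = 1e-12)
  expect_equal(mean(z$z_local), 0, tolerance = 1e-12)
  expect_equal(sd(z$z_local), 1, tolerance = 1e-12)
  expect_identical(order(z$z_global), order(rg))
  expect_identical(order(z$z_local), order(rl))
  # two series, ddof = 1: {0.2, 0.4} -> -1/sqrt(2), +1/sqrt(2)
  z2 <- to_z_scores(c(0.2, 0.4), c(1, 1.5))
  expect_equal(z2$z_global, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # scaling all raw locals leaves z-locals unchanged (log + centering)
  z3 <- to_z_scores(rg, rl * 37.5)
  expect_equal(z3$z_local, z$z_local, tolerance = 1e-12)
})

test_that("z-scoring refuses degenerate ensembles without a reference", {
  expect_error(to_z_scores(0.3, 2), "reference")
  expect_error(to_z_scores(c(0.3, 0.3), c(2, 3)), "zero")
  ref <- list(mean_global = 0.4, sd_global = 0.1,
              mean_log_local = 0, sd_log_local = 1)
  z <- to_z_scores(0.5, exp(2), reference = ref)
  expect_equal(z$z_global, 1)
  expect_equal(z$z_local, 2)
})

test_that("score combinations map to the four stages at threshold 1", {
  expect_identical(classify_stage(1.52, 2.39), "high/high")
  expect_identical(classify_stage(1.86, -0.51), "high/low")
  expect_identical(classify_stage(-2.14, 2.97), "low/high")
  expect_identical(classify_stage(-0.96, -1.52), "low/low")
  expect_identical(category_stage(c("high/high", "low/high")),
                   c("saturated", "early"))
  # exactly at the threshold counts as high
  expect_identical(classify_stage(1, 1), "high/high")
  expect_error(classify_stage(NaN, 0), "finite")
})

test_that("lead active-neighbor counts match a brute-force census", {
  A <- random_points(12, seed = 17)
  r <- 2
  got <- count_active_neighbors(A, "p3", r)
  brute <- 0
  for (j in seq_len(12)) {
    if (j != 3 && sqrt(sum((A[3, ] - A[j, ])^2)) <= r) brute <- brute + 1
  }
  expect_identical(got, as.integer(brute))
  # all actives coincident: everyone but the lead is a neighbor
  co <- matrix(1, 5, 7, dimnames = list(paste0("a", 1:5), NULL))
  expect_identical(count_active_neighbors(co, "a2", 0.5), 4L)
  # isolated lead
  iso <- rbind(a1 = rep(0, 7), a2 = rep(30, 7), a3 = rep(-30, 7))
  expect_identical(count_active_neighbors(iso, "a1", 1), 0L)
  expect_error(count_active_neighbors(co, "nope", 1), "not among")
})
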
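test_that("pi_xy evaluates gametic-union heterozygosity on shared sites", {
  # identical fixed populations
  x <- make_profiles(replicate(3, c(10, 0, 0, 0), simplify = FALSE))
  expect_equal(pixy_unigene(x, x)$value, 0)
  # fixed difference
  y <- make_profiles(list(c(0, 10, 0, 0)))
  x1 <- make_profiles(list(c(10, 0, 0, 0)))
  expect_equal(pixy_unigene(x1, y)$value, 1)
  # mixed: (0.5, 0.5) vs fixed A at site 1, both fixed A at site 2
  x2 <- make_profiles(list(c(5, 5, 0, 0), c(10, 0, 0, 0)))
  y2 <- make_profiles(list(c(10, 0, 0, 0), c(10, 0, 0, 0)))
  r <- pixy_unigene(x2, y2)
  expect_equal(r$value, 0.25)
  expect_equal(r$n_sites, 2L)
  # a site failing filters in one population is excluded in both
  x3 <- make_profiles(list(c(5, 5, 0, 0), c(10, 0, 0, 0)))
  y3 <- make_profiles(list(c(3, 0, 0, 0), c(10, 0, 0, 0)))  # site 1 cov 3
  expect_equal(pixy_unigene(x3, y3)$n_sites, 1L)
  # no shared sites -> empty
  y4 <- make_profiles(list(c(2, 0, 0, 0), c(1, 0, 0, 0)))
  expect_equal(nrow(pixy_unigene(x3, y4)), 0L)
})

test_that("pi_xy is symmetric, bounded and consistent with self-union", {
  set.seed(9)
  sim <- simulate_metapopulation(sim_config(n_pops = 2, n_unigenes = 15,
                                            sites_per_unigene = 40,
                                            seg_fraction = 0.5, F = 0.3,
                                            seed = 9))
  p <- split(sim$profiles, by = "pop")
  ab <- pixy_unigene(p[[1]], p[[2]])
  ba <- pixy_unigene(p[[2]], p[[1]])
  expect_equal(ab$value, ba$value)
  expect_true(all(ab$value >= 0 & ab$value <= 1))
  # self-union equals the uncorrected expected heterozygosity of x
  self <- pixy_unigene(p[[1]], p[[1]])
  f <- profile_freqs(filter_sites(p[[1]][, !"pop"]))
  fr <- as.matrix(f[, paste0("f", c("A", "C", "G", "T")), with = FALSE])
  f[, h := 1 - rowSums(fr^2)]
  byug <- f[, .(value = mean(h)), by = unigene]
  expect_equal(self$value, byug$value)
})

test_that("group profiles are unweighted means over member populations", {
  prof <- rbind(make_profiles(list(c(10, 0, 0, 0)), pop = "a"),
                make_profiles(list(c(5, 5, 0, 0)), pop = "b"))
  g <- group_profile(prof, c("a", "b"))
  expect_equal(unlist(g[, c("fA", "fC", "fG", "fT")], use.names = FALSE),
               c(0.75, 0.25, 0, 0))
  # single member is the identity
  g1 <- group_profile(prof, "a")
  expect_equal(g1$fA, 1)
  # equal frequencies at very different coverages give the same answer
  prof2 <- rbind(make_profiles(list(c(5, 5, 0, 0)), pop = "a"),
                 make_profiles(list(c(20, 20, 0, 0)), pop = "b"))
  g2 <- group_profile(prof2, c("a", "b"))
  expect_equal(g2$fA, 0.5)
  # a site missing in any member is excluded
  prof3 <- rbind(make_profiles(list(c(10, 0, 0, 0), c(10, 0, 0, 0)), pop = "a"),
                 make_profiles(list(c(10, 0, 0, 0)), pop = "b"))
  expect_equal(nrow(group_profile(prof3, c("a", "b"))), 1L)
})

test_that("per-unigene F_ST matches hand evaluation and a brute-force oracle", {
  x <- make_profiles(list(c(5, 5, 0, 0)))
  y <- make_profiles(list(c(10, 0, 0, 0)))
  r <- fst_unigene(x, y, corrected = FALSE)
  expect_equal(r$value, 1 / 3, tolerance = 1e-12)
  # identical populations -> 0; fixed difference -> 1
  expect_equal(fst_unigene(x, x, corrected = FALSE)$value, 0)
  fx <- make_profiles(list(c(10, 0, 0, 0)))
  fy <- make_profiles(list(c(0, 10, 0, 0)))
  expect_equal(fst_unigene(fx, fy, corrected = FALSE)$value, 1)
  # monomorphic-everywhere unigene is missing
  expect_true(is.na(fst_unigene(fx, fx, corrected = FALSE)$value))
  # random <= 5-site toys against the independent ratio-of-sums oracle
  set.seed(33)
  for (i in 1:20) {
    ns <- sample(1:5, 1)
    cx <- matrix(sample(0:12, 4 * ns, TRUE), ncol = 4)
    cy <- matrix(sample(0:12, 4 * ns, TRUE), ncol = 4)
    keep <- rowSums(cx) >= 5 & rowSums(cx) <= 40 &
      rowSums(cy) >= 5 & rowSums(cy) <= 40
    if (!any(keep)) next
    cx <- cx[keep, , drop = FALSE]; cy <- cy[keep, , drop = FALSE]
    fc <- filter_config(min_count = 1)
    got <- fst_unigene(make_profiles(asplit(cx, 1)),
                       make_profiles(asplit(cy, 1)), cfg = fc,
                       corrected = FALSE)$value
    oracle <- brute_fst(cx, cy)
    if (is.nan(oracle)) expect_true(is.na(got))
    else expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("pairwise matrices cover all pairs symmetrically", {
  sim <- simulate_metapopulation(sim_config(n_pops = 26, n_unigenes = 5,
                                            sites_per_unigene = 20,
                                            seg_fraction = 0.5, F = 0.1,
                                            seed = 44))
  m <- pairwise_matrix(sim$profiles, "pixy")
  expect_equal(dim(m), c(26L, 26L))
  expect_equal(sum(upper.tri(m)), 325L)  # 26 populations -> 325 pairs
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
  # two populations with identical counts have zero divergence
  prof <- rbind(make_profiles(list(c(5, 5, 0, 0), c(10, 0, 0, 0)), pop = "a"),
                make_profiles(list(c(5, 5, 0, 0), c(10, 0, 0, 0)), pop = "b"))
  expect_equal(unname(pairwise_matrix(prof, "fst", corrected = FALSE)["a", "b"]),
               0)
})

test_that("bootstrap CI matches the binomial closed form on a toy set", {
  # all-identical values collapse the interval
  expect_equal(unname(bootstrap_mean_ci(rep(0.3, 50), reps = 200, seed = 1)),
               c(0.3, 0.3, 0.3))
  set.seed(2)
  v <- rnorm(200)
  ci <- bootstrap_mean_ci(v, reps = 2000, seed = 3)
  expect_lte(ci["lo"], ci["mean"])
  expect_gte(ci["hi"], ci["mean"])
  # toy 0/1 set: the bootstrap mean is Binomial(1000, 1/2)/1000, giving a
  # closed-form percentile interval
  toy <- rep(c(0, 1), each = 500)
  ci2 <- bootstrap_mean_ci(toy, reps = 10000, seed = 4)
  lo_exact <- qbinom(0.025, 1000, 0.5) / 1000
  hi_exact <- qbinom(0.975, 1000, 0.5) / 1000
  expect_equal(unname(ci2["lo"]), lo_exact, tolerance = 0.01)
  expect_equal(unname(ci2["hi"]), hi_exact, tolerance = 0.01)
})
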
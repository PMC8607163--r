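test_that("paired Cohen's d matches hand computation and rejects degenerate input", {
  expect_equal(cohens_d_paired(1:5), 3 / stats::sd(1:5), tolerance = 1e-12)
  expect_equal(cohens_d_paired(1:5), 1.8974, tolerance = 1e-4)
  expect_equal(cohens_d_paired(c(-1, 1)), 0)
  expect_error(cohens_d_paired(c(1, 1, 1, 1)), "undefined")
  expect_error(cohens_d_paired(1), "at least 2")
})

test_that("pointwise paired d equals t / sqrt(n) everywhere", {
  set.seed(31)
  for (k in 1:10) {
    n <- sample(5:40, 1)
    nch <- sample(2:5, 1); nt <- sample(2:6, 1)
    A <- array(stats::rnorm(n * nch * nt), c(n, nch, nt))
    B <- array(stats::rnorm(n * nch * nt), c(n, nch, nt))
    m <- paired_t_map(A, B)
    D <- A - B
    for (c_ in seq_len(nch)) for (t_ in seq_len(nt)) {
      d <- cohens_d_paired(D[, c_, t_])
      expect_equal(d, m$t[c_, t_] / sqrt(n), tolerance = 1e-10)
    }
  }
})

test_that("single-sample clusters reduce all three options to the pointwise d", {
  d <- toy_dataset(n = 12, nch = 3, nt = 4, effect = 3, seed = 8)
  cl <- structure(list(members = cbind(channel = 1L, time = 2L),
                       channels = "a", time_range = rep(d$times[2], 2),
                       mass = 5, polarity = "positive", size = 1L),
                  class = "erp_cluster")
  dpt <- cohens_d_paired(d$data$condA[, 1, 2] - d$data$condB[, 1, 2])
  expect_equal(es_average_over_cluster(d, cl), dpt)
  m2 <- es_max_within_cluster(d, cl)
  expect_equal(m2$d, dpt)
  expect_equal(m2$channel, "a")
  expect_equal(m2$latency, d$times[2])
  r <- es_rectangle(d, cl, "outside")
  expect_equal(r$d, dpt)
})

test_that("the max-within-cluster location is a member and dominates all members", {
  set.seed(77)
  sim <- simulate_erp_dataset(sim_config(n_subjects = 16, n_channels = 10,
                                         sfreq = 100), seed = 4)
  d <- sim$dataset
  g <- neighbors_by_triangulation(sim$layout)
  m <- paired_t_map(d$data$standard, d$data$oddball, channels = d$channels,
                    times = d$times)
  cl <- form_clusters(threshold_map(m, 0.05), g, m)
  expect_gt(length(cl), 0)
  c1 <- cl[[1]]
  res <- es_max_within_cluster(d, c1, conditions = c("standard", "oddball"))
  # identity against the t map at the reported location
  ci <- match(res$channel, d$channels)
  ti <- which(d$times == res$latency)
  expect_equal(res$d, m$t[ci, ti] / sqrt(16), tolerance = 1e-10)
  # it is a member sample and dominates every member's pointwise d
  expect_true(any(c1$members[, "channel"] == ci & c1$members[, "time"] == ti))
  D <- d$data$standard - d$data$oddball
  for (k in seq_len(nrow(c1$members))) {
    dk <- cohens_d_paired(D[, c1$members[k, "channel"], c1$members[k, "time"]])
    expect_lte(abs(dk), abs(res$d) + 1e-12)
  }
})

test_that("rectangle footprints: outside circumscribes, inside fits the L-shape", {
  d <- toy_dataset(n = 10, nch = 3, nt = 4, seed = 14)
  # L-shaped cluster: channel a at t1..t3, channel b at t3 only
  mem <- rbind(cbind(1L, 1L:3L), cbind(2L, 3L))
  colnames(mem) <- c("channel", "time")
  cl <- structure(list(members = mem, channels = c("a", "b"),
                       time_range = range(d$times[1:3]), mass = 10,
                       polarity = "positive", size = nrow(mem)),
                  class = "erp_cluster")
  out <- es_rectangle(d, cl, "outside")
  expect_setequal(out$channels, c("a", "b"))
  expect_equal(out$time_range, d$times[c(1, 3)])
  expect_warning(ins <- es_rectangle(d, cl, "inside"), "single-channel")
  expect_equal(ins$channels, "a")
  expect_equal(ins$time_range, d$times[c(1, 3)])
  # a genuinely rectangular cluster: outside equals the cluster, d = option 1
  mem2 <- cbind(channel = rep(1:2, each = 3), time = rep(1:3, 2))
  cl2 <- structure(list(members = mem2, channels = c("a", "b"),
                        time_range = range(d$times[1:3]), mass = 10,
                        polarity = "positive", size = 6L),
                   class = "erp_cluster")
  out2 <- es_rectangle(d, cl2, "outside")
  expect_equal(out2$d, es_average_over_cluster(d, cl2), tolerance = 1e-12)
  ins2 <- es_rectangle(d, cl2, "inside")
  expect_equal(ins2$d, out2$d, tolerance = 1e-12)
})

test_that("effect sizes are invariant to rescaling and to montage padding", {
  sim <- simulate_erp_dataset(sim_config(n_subjects = 14, n_channels = 8,
                                         sfreq = 100), seed = 12)
  d <- sim$dataset
  g <- neighbors_by_triangulation(sim$layout)
  m <- paired_t_map(d$data$standard, d$data$oddball, channels = d$channels,
                    times = d$times)
  cl <- form_clusters(threshold_map(m, 0.05), g, m)[[1]]
  base <- list(es_average_over_cluster(d, cl), es_max_within_cluster(d, cl)$d,
               es_rectangle(d, cl)$d)
  scaled <- d
  scaled$data <- lapply(d$data, function(a) a * 3.7)
  got <- list(es_average_over_cluster(scaled, cl),
              es_max_within_cluster(scaled, cl)$d,
              es_rectangle(scaled, cl)$d)
  expect_equal(got, base, tolerance = 1e-12)
  # adding unrelated channels does not move the option 2 location
  ext <- erp_dataset(lapply(d$data, function(a) {
    a2 <- array(stats::rnorm(length(a) / dim(a)[2] * (dim(a)[2] + 2)),
                c(dim(a)[1], dim(a)[2] + 2, dim(a)[3]))
    a2[, seq_len(dim(a)[2]), ] <- a
    a2
  }), c(d$channels, "X1", "X2"), d$times)
  m1 <- es_max_within_cluster(d, cl)
  m2 <- es_max_within_cluster(ext, cl)
  expect_equal(m1$channel, m2$channel)
  expect_equal(m1$latency, m2$latency)
  expect_equal(m1$d, m2$d, tolerance = 1e-12)
})

test_that("the report gathers all three options with consistent signs", {
  sim <- simulate_erp_dataset(sim_config(n_subjects = 20, n_channels = 10,
                                         sfreq = 100, effect_d = 1.0), seed = 2)
  g <- neighbors_by_triangulation(sim$layout)
  fit <- suppressWarnings(
    cluster_perm_test(sim$dataset, g, n_randomizations = 600, seed = 8))
  es <- effect_size_report(sim$dataset, fit)
  expect_s3_class(es, "effect_size_report")
  expect_gt(nrow(es), 0)
  for (i in seq_len(nrow(es))) {
    s <- if (es$polarity[i] == "positive") 1 else -1
    expect_equal(sign(es$d_average[i]), s)
    expect_equal(sign(es$d_max[i]), s)
    expect_gte(abs(es$d_max[i]), abs(es$d_average[i]) * 0)  # both present
  }
  # null data produce an empty report
  nullfit <- fit
  nullfit$clusters <- list()
  es0 <- effect_size_report(sim$dataset, nullfit)
  expect_equal(nrow(es0), 0)
})
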
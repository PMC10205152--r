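# Cluster-mass permutation tests, adjacency, and global field power.

line_adj <- function(n) chain_adjacency(n)

test_that("adjacency constructors are symmetric without self-neighbors", {
  coords <- data.frame(channel = paste0("ch", 1:5),
                       x = c(0, 1, 2, 0, 1), y = c(0, 0, 0, 1, 1))
  adj <- montage_adjacency(coords, threshold = 1.01)
  expect_s3_class(adj, "sensor_adjacency")
  for (i in seq_along(adj)) {
    expect_false(i %in% adj[[i]])
    for (j in adj[[i]]) expect_true(i %in% adj[[j]])
  }
  e <- edge_adjacency(cbind(c(1, 2), c(2, 3)), paste0("ch", 1:3))
  expect_equal(e[[2]], c(1L, 3L))
  expect_error(edge_adjacency(cbind("ch1", "chX"), c("ch1", "ch2")),
               "unknown")
})

test_that("a uniform strong effect yields one all-channel cluster at floor p", {
  n_sub <- 10; n_ch <- 6
  set.seed(1)
  vals <- matrix(5 + rnorm(n_sub * n_ch, 0, 0.1), n_sub, n_ch)
  res <- cluster_test_one_sample(vals, line_adj(n_ch))
  expect_length(res$clusters, 1)
  expect_equal(res$clusters[[1]]$members, 1:n_ch)
  # 2^10 = 1024 < 10000: complete enumeration, exact p at the floor
  expect_true(res$complete_enumeration)
  expect_equal(res$n_perm, 1024)
  expect_equal(res$clusters[[1]]$p, 1 / 1024)
  expect_equal(res$clusters[[1]]$t_max, max(abs(res$t)))
  # p values are exact multiples of 1/1024
  expect_equal(res$clusters[[1]]$p * 1024, round(res$clusters[[1]]$p * 1024))
  # enumeration is deterministic and seed-independent
  res2 <- cluster_test_one_sample(vals, line_adj(n_ch), seed = 999)
  expect_equal(cluster_table(res), cluster_table(res2))
})

test_that("null data give empty results, not errors", {
  set.seed(2)
  vals <- matrix(rnorm(8 * 4, 0, 1), 8, 4) - 10 # far below threshold
  res <- cluster_test_one_sample(vals, line_adj(4))
  expect_length(res$clusters, 0)
  expect_equal(nrow(cluster_table(res)), 0)
  expect_error(cluster_test_one_sample(vals[1, , drop = FALSE], line_adj(4)),
               "2 subjects")
})

test_that("cluster membership is invariant to adjacency-preserving relabeling", {
  set.seed(3)
  n_sub <- 9; n_ch <- 7
  vals <- matrix(rnorm(n_sub * n_ch) + rep(c(2, 2, 2, 0, 0, 2, 2),
                                           each = n_sub), n_sub, n_ch)
  res <- cluster_test_one_sample(vals, line_adj(n_ch))
  perm <- c(7:1) # reversing a chain preserves the graph
  res_p <- cluster_test_one_sample(vals[, perm], line_adj(n_ch))
  members <- lapply(res$clusters, `[[`, "members")
  members_back <- lapply(res_p$clusters, function(cl) sort(perm[cl$members]))
  expect_setequal(lapply(members, paste, collapse = ","),
                  lapply(members_back, paste, collapse = ","))
  expect_equal(sort(vapply(res$clusters, `[[`, 0, "p")),
               sort(vapply(res_p$clusters, `[[`, 0, "p")))
})

test_that("paired test recovers an injected temporal effect and is symmetric", {
  set.seed(4)
  n_sub <- 12; n_t <- 60
  a <- matrix(rnorm(n_sub * n_t), n_sub, n_t)
  b <- matrix(rnorm(n_sub * n_t), n_sub, n_t)
  # identical conditions: no clusters
  expect_length(cluster_test_paired(a, a)$clusters, 0)
  a2 <- a
  a2[, 20:30] <- a2[, 20:30] + 3
  res <- cluster_test_paired(a2, b, n_perm = 2000, seed = 5)
  sig <- res$clusters[vapply(res$clusters, `[[`, 0, "p") <= 0.05]
  expect_gte(length(sig), 1)
  hits <- unlist(lapply(sig, `[[`, "members"))
  expect_gt(length(intersect(hits, 20:30)), 0)
  # swapping conditions flips the sign, p unchanged
  res_sw <- cluster_test_paired(b, a2, n_perm = 2000, seed = 5)
  m <- function(r) sort(vapply(r$clusters, `[[`, 0, "mass"))
  expect_equal(m(res_sw), sort(-vapply(res$clusters, `[[`, 0, "mass")))
  expect_equal(sort(vapply(res$clusters, `[[`, 0, "p")),
               sort(vapply(res_sw$clusters, `[[`, 0, "p")))
})

test_that("GFP matches closed forms and the two-pass oracle", {
  L <- 30
  # identical kernels on all channels: zero spatial variance
  K <- matrix(rep(sin(1:L), each = 4), 4, L)
  expect_true(all(gfp(K) == 0))
  # two channels at +a and -a: GFP = a (population SD)
  a <- abs(rnorm(L))
  K2 <- rbind(a, -a)
  expect_equal(unname(gfp(K2)), a)
  # random kernels: equals an independent two-pass computation
  set.seed(6)
  K3 <- matrix(rnorm(8 * L), 8, L)
  expect_equal(gfp(K3), oracle_population_sd(K3))
  # invariant to a common offset
  expect_equal(gfp(K3 + 5), gfp(K3))
  # rms mode and ROI subsetting
  expect_equal(gfp(K3, roi = 1:3, mode = "rms"),
               sqrt(colMeans(K3[1:3, ]^2)))
  expect_error(gfp(K3, roi = integer(0)), "nonempty")
})

test_that("random-permutation p values include the identity and stay positive", {
  set.seed(7)
  vals <- matrix(rnorm(20 * 3) + 3, 20, 3) # 2^20 >> n_perm: random flips
  res <- cluster_test_one_sample(vals, line_adj(3), n_perm = 500, seed = 8)
  expect_false(res$complete_enumeration)
  expect_equal(res$n_perm, 500)
  for (cl in res$clusters) {
    expect_gt(cl$p, 0)
    expect_lte(cl$p, 1)
  }
})
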
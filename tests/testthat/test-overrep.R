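toy_setup <- function() {
  net <- make_network(data.frame(from = c("A", "B", "C"), to = c("B", "C", "D")))
  ann <- toy_annotation(net, list(TB = c("B", "C"), TU = c("A", "B", "C", "D")))
  part <- as_partition(stats::setNames(c(0, 0, 1, 1), c("A", "B", "C", "D")))
  list(net = net, ann = ann, part = part)
}

test_that("count tables are exact set intersections", {
  s <- toy_setup()
  ct <- count_table(s$ann, s$part, 0L, "TB")
  expect_equal(unclass(ct)[c("k", "n", "K", "N")],
               list(k = 1L, n = 2L, K = 2L, N = 4L))
  ctu <- count_table(s$ann, s$part, 0L, "TU")
  expect_equal(ctu$k, ctu$n)                    # term = whole universe
  ann2 <- toy_annotation(s$net, list(TD = "D", TX = c("A", "D")))
  expect_equal(count_table(ann2, s$part, 0L, "TD")$k, 0L)  # empty intersection
  expect_error(count_table(s$ann, s$part, 0L, "nope"), "unknown term")
  expect_error(count_table(s$ann, s$part, 9L, "TB"), "unknown cluster")
})

test_that("hypergeometric tail matches draw enumeration", {
  expect_equal(hypergeom_p(list(k = 5, n = 5, K = 5, N = 10)), 1 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeom_p(list(k = 0, n = 3, K = 4, N = 10)), 1)
  expect_equal(hypergeom_p(list(k = 1, n = 2, K = 2, N = 4)), 5 / 6,
               tolerance = 1e-12)
  # monotone non-increasing in k for fixed (n, K, N)
  ps <- vapply(0:4, function(k) hypergeom_p(list(k = k, n = 4, K = 5, N = 12)), 0)
  expect_true(all(diff(ps) <= 0))
  expect_error(hypergeom_p(list(k = 5, n = 4, K = 5, N = 12)), "invalid")
})

test_that("binomial tail matches outcome enumeration", {
  expect_equal(binomial_p(list(k = 2, n = 2, K = 5, N = 10)), 0.25,
               tolerance = 1e-12)
  expect_equal(binomial_p(list(k = 0, n = 3, K = 2, N = 10)), 1)
  expect_equal(binomial_p(list(k = 2, n = 3, K = 2, N = 6)), 7 / 27,
               tolerance = 1e-12)
  expect_error(binomial_p(list(k = 1, n = 2, K = 0, N = 6)), "impossible")
})

test_that("chi-squared follows the closed form and its symmetries", {
  flat <- chisq_p(list(k = 10, n = 20, K = 20, N = 40))
  expect_equal(flat$stat, 0)
  expect_equal(flat$p, 1)

  enr <- chisq_p(list(k = 20, n = 25, K = 25, N = 50))  # a=20 b=5 c=5 d=20
  expect_equal(enr$stat, 18, tolerance = 1e-12)
  expect_equal(enr$p, stats::pchisq(18, 1, lower.tail = FALSE))
  # cross-check via expected counts sum (O-E)^2/E
  O <- c(20, 5, 5, 20)
  E <- outer(c(25, 25), c(25, 25)) / 50
  expect_equal(enr$stat, sum((O - as.vector(E))^2 / as.vector(E)),
               tolerance = 1e-12)
  # swapping the table's rows (a,b,c,d -> c,d,a,b) leaves the statistic unchanged
  swapped <- chisq_p(list(k = 5, n = 25, K = 25, N = 50))
  expect_equal(swapped$stat, enr$stat)
  # depleted direction reports p = 1 for enrichment
  dep <- chisq_p(list(k = 2, n = 25, K = 25, N = 50))
  expect_equal(dep$p, 1)
  expect_warning(z <- chisq_p(list(k = 0, n = 4, K = 0, N = 8)), "degenerate")
  expect_equal(z$p, 1)
})

test_that("the tests agree on direction for clearly enriched tables", {
  # all three analytic p-values drop below 0.5 once the overlap exceeds its
  # null expectation by at least one null standard deviation (the one-sided
  # chi-squared tail is the full upper tail, so milder positive association
  # legitimately leaves it above 0.5)
  set.seed(42)
  checked <- 0L
  while (checked < 100L) {
    N <- sample(50:200, 1)
    n <- sample(5:(N - 5), 1)
    K <- sample(5:(N - 5), 1)
    mu <- n * K / N
    sd <- sqrt(n * K * (N - K) * (N - n) / (N^2 * (N - 1)))
    lo <- ceiling(mu + sd)
    if (lo > min(n, K)) next
    k <- if (lo == min(n, K)) lo else sample(lo:min(n, K), 1)
    ct <- list(k = k, n = n, K = K, N = N)
    a <- k; b <- n - k; cc <- K - k; d <- N - n - K + k
    if (any(c(a + b, cc + d, a + cc, b + d) == 0)) next
    expect_gt(a * d, b * cc)
    expect_lt(hypergeom_p(ct), 0.5)
    expect_lt(binomial_p(ct), 0.5)
    expect_lt(chisq_p(ct)$p, 0.5)
    checked <- checked + 1L
  }
})

test_that("permutation p is trivially 1 for invariant statistics", {
  s <- toy_setup()
  expect_equal(permutation_p(s$ann, s$part, 0L, "TU", R = 50, seed = 1), 1)
  whole <- as_partition(stats::setNames(rep(0, 4), c("A", "B", "C", "D")))
  expect_equal(permutation_p(s$ann, whole, 0L, "TB", R = 50, seed = 1), 1)
  expect_error(permutation_p(s$ann, s$part, 0L, "TB", R = 0), "R must be")
})

test_that("single-pair permutation equals the corresponding full-table entry", {
  pl <- gen_planted(blocks = 3, size = 8, seed = 21)
  tab <- run_overrep(pl$annotations, pl$truth, "permutation", R = 200,
                     seed = 77, correction = "none")
  for (term in c("signal_block0", "decoy01")) {
    for (cl in 0:2) {
      row <- tab[tab$cluster == cl & tab$term == term, ]
      expect_identical(permutation_p(pl$annotations, pl$truth, cl, term,
                                     R = 200, seed = 77), row$p)
    }
  }
})

test_that("run_overrep flags the planted pair and applies corrections", {
  net <- gen_scale_free(100, 2, seed = 8)
  set.seed(8)
  mapping <- c(list(planted = net$nodes[11:20]),
               lapply(1:9, function(i) sample(net$nodes, 8)))
  names(mapping)[2:10] <- paste0("rnd", 1:9)
  ann <- build_matrix(mapping, net, min_size = 1)
  memb <- rep(0:9, each = 10)
  part <- as_partition(stats::setNames(memb, net$nodes))
  tab <- run_overrep(ann, part, "hypergeom", correction = "none")
  best <- tab[which.min(tab$p), ]
  expect_equal(best$term, "planted")
  expect_equal(best$k, 10L)

  bon <- run_overrep(ann, part, "hypergeom", correction = "bonferroni")
  expect_equal(bon$adj_p, pmin(1, tab$p * nrow(tab)), tolerance = 1e-12)
  expect_true(all(bon$adj_p >= bon$p))
  bh <- run_overrep(ann, part, "hypergeom", correction = "bh")
  expect_equal(bh$adj_p, stats::p.adjust(tab$p, "BH"), tolerance = 1e-12)
  none <- run_overrep(ann, part, "hypergeom", correction = "none")
  expect_identical(none$adj_p, none$p)
  expect_error(run_overrep(ann, part, alpha = 1.5), "alpha")
})

test_that("depletion direction takes the complementary tail", {
  s <- toy_setup()
  dep <- run_overrep(s$ann, s$part, "hypergeom", correction = "none",
                     direction = "depletion")
  enr <- run_overrep(s$ann, s$part, "hypergeom", correction = "none")
  row_d <- dep[dep$cluster == 0 & dep$term == "TB", ]
  expect_equal(row_d$p, stats::phyper(1, 2, 2, 2))
  expect_true(all(dep$p >= 0 & dep$p <= 1) && all(enr$p > 0))
})
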
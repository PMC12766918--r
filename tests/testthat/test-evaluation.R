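coords_of <- function(...) {
  pts <- list(...)
  m <- do.call(rbind, pts)
  rownames(m) <- names(pts)
  colnames(m) <- c("x", "y")
  m
}

test_that("compactness is the mean pairwise distance, singleton = 0", {
  part <- as_partition(stats::setNames(c(0, 0, 1), c("p", "q", "r")))
  xy <- coords_of(p = c(0, 0), q = c(3, 4), r = c(9, 9))
  cc <- compactness(xy, part)
  expect_equal(unname(cc), c(5, 0))

  tri <- as_partition(stats::setNames(c(0, 0, 0, 1), c("a", "b", "c", "z")))
  xy2 <- coords_of(a = c(0, 0), b = c(1, 0), c = c(0.5, sqrt(3) / 2),
                   z = c(5, 5))
  expect_equal(unname(compactness(xy2, tri))[1], 1, tolerance = 1e-12)

  expect_error(compactness(xy[1:2, ], part), "missing coordinates")
})

test_that("separation is the minimum centroid distance and is rigid-motion invariant", {
  part <- as_partition(stats::setNames(c(0, 0, 1, 1), c("a", "b", "c", "d")))
  xy <- coords_of(a = c(-1, 0), b = c(1, 0), c = c(5, 8), d = c(7, 8))
  expect_equal(separation(xy, part), 10)

  part3 <- as_partition(stats::setNames(0:2, c("a", "b", "c")))
  xy3 <- coords_of(a = c(0, 0), b = c(1, 0), c = c(5, 0))
  expect_equal(separation(xy3, part3), 1)

  shift <- xy + matrix(rep(c(13, -7), each = 4), 4)
  expect_equal(separation(shift, part), separation(xy, part))
  theta <- 0.7
  rot <- xy %*% matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  rownames(rot) <- rownames(xy)
  expect_equal(separation(rot, part), separation(xy, part), tolerance = 1e-12)
  expect_equal(separation(xy * 3, part), 3 * separation(xy, part))

  one <- as_partition(stats::setNames(c(0, 0), c("a", "b")))
  expect_error(separation(xy[1:2, ], one), "at least 2")
})

test_that("silhouette matches the hand-computed pair fixture and conventions", {
  part <- as_partition(stats::setNames(c(0, 0, 1, 1), c("a", "b", "c", "d")))
  xy <- coords_of(a = c(0, 0), b = c(0, 1), c = c(10, 0), d = c(10, 1))
  s <- silhouette_score(xy, part)
  b_i <- (10 + sqrt(101)) / 2
  expect_equal(s$mean, (b_i - 1) / b_i, tolerance = 1e-12)
  expect_equal(unname(s$per_node), rep((b_i - 1) / b_i, 4), tolerance = 1e-12)

  coincident <- coords_of(a = c(1, 1), b = c(1, 1), c = c(1, 1), d = c(1, 1))
  expect_equal(silhouette_score(coincident, part)$mean, 0)

  far <- coords_of(a = c(0, 0), b = c(0, 1), c = c(1e5, 0), d = c(1e5, 1))
  expect_gt(silhouette_score(far, part)$mean, 0.9999)
  expect_error(silhouette_score(xy, as_partition(
    stats::setNames(rep(0, 4), c("a", "b", "c", "d")))), "at least 2")
})

test_that("metrics equal their double-loop oracles on a random fixture", {
  set.seed(31)
  nodes <- sprintf("n%02d", 1:40)
  xy <- matrix(rnorm(80), 40, dimnames = list(nodes, c("x", "y")))
  part <- as_partition(stats::setNames(sample(0:4, 40, replace = TRUE), nodes))
  expect_equal(compactness(xy, part), oracle_compactness(xy, part),
               tolerance = 1e-12)
  expect_equal(separation(xy, part), oracle_separation(xy, part),
               tolerance = 1e-12)
  sil <- silhouette_score(xy, part)
  expect_equal(sil$per_node, oracle_silhouette(xy, part), tolerance = 1e-12)
  expect_true(all(sil$per_node >= -1 & sil$per_node <= 1))
  # silhouette is scale invariant
  expect_equal(silhouette_score(xy * 17, part)$per_node, sil$per_node,
               tolerance = 1e-12)
})

test_that("Mann-Whitney U matches enumeration, handles ties and symmetry", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  x <- c(1.2, 3.4, 0.5); y <- c(2.2, 5.1)
  g <- mann_whitney_u(x, y, "greater")
  l <- mann_whitney_u(y, x, "less")
  expect_equal(g$p, l$p, tolerance = 1e-12)

  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")

  # exact p equals the rank-assignment enumeration for all sizes <= 6+6
  set.seed(5)
  for (nx in 1:6) for (ny in 1:6) {
    x <- sample(seq(1, 100, by = 1), nx)
    y <- sample(seq(0.5, 99.5, by = 1), ny)
    expect_equal(mann_whitney_u(x, y)$p, oracle_mwu_enum(x, y),
                 tolerance = 1e-9,
                 label = sprintf("exact MWU nx=%d ny=%d", nx, ny))
  }

  # tie-corrected normal approximation for larger samples tracks wilcox.test
  set.seed(6)
  x <- round(rnorm(20), 1); y <- round(rnorm(25, 0.5), 1)
  ours <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-10)
})

test_that("compare_partitions reports both sides and a null MWU for identity", {
  pl <- gen_planted(seed = 23)
  xy <- layout_coords(pl$network, seed = 1)
  cmp <- compare_partitions(xy, pl$truth, pl$truth)
  expect_equal(cmp$mwu$p, 1)
  expect_length(cmp$report_a$per_cluster_compactness, 4)
  expect_length(cmp$report_b$per_cluster_compactness, 4)
  expect_false(is.na(cmp$report_a$silhouette_mean))

  other <- as_partition(stats::setNames(rep(0:1, 50),
                                        names(pl$truth$assignment)))
  sub <- as_partition(stats::setNames(rep(0:1, 10),
                                      names(pl$truth$assignment)[1:20]))
  expect_error(compare_partitions(xy, pl$truth, sub), "different node sets")
})

test_that("the planted partition beats random relabelings on silhouette", {
  wins <- 0L
  for (s in 1:20) {
    pl <- gen_planted(seed = 100 + s, coherent_terms = FALSE)
    xy <- layout_coords(pl$network, seed = s)
    sil_true <- silhouette_score(xy, pl$truth)$mean
    set.seed(s)
    rand <- as_partition(stats::setNames(sample(pl$truth$assignment),
                                         names(pl$truth$assignment)))
    if (sil_true > silhouette_score(xy, rand)$mean) wins <- wins + 1L
  }
  expect_gte(wins, 17L)
})
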
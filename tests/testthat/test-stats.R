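test_that("bray_curtis matches hand values and the brute-force formula", {
  m <- cbind(a = c(1, 2), b = c(1, 2), c = c(3, 0))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2 / 3)
  disjoint <- cbind(x = c(1, 0), y = c(0, 1))
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)
  set.seed(71)
  r <- matrix(rpois(25, 5), 5, 5, dimnames = list(NULL, letters[1:5]))
  d <- bray_curtis(r)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d[i, j], sum(abs(r[, i] - r[, j])) / sum(r[, i] + r[, j]))
  }
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("bray_curtis agrees with vegan and warns on all-zero pairs", {
  skip_if_not_installed("vegan")
  set.seed(72)
  m <- matrix(rpois(40, 8), 8, 5, dimnames = list(NULL, letters[1:5]))
  ours <- bray_curtis(m)
  ref <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
  zz <- cbind(a = c(0, 0), b = c(0, 0))
  expect_warning(dz <- bray_curtis(zz), "all-zero")
  expect_equal(dz["a", "b"], 0)
})

test_that("pcoa reproduces closed-form geometries", {
  # 3 equidistant points: two equal positive eigenvalues, distances recovered
  d <- matrix(1, 3, 3) - diag(3)
  ord <- pcoa_ordination(d)
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-9]
  expect_equal(length(pos), 2L)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  # 2 points at distance delta -> one axis, coordinates +/- delta/2
  delta <- 0.62
  d2 <- matrix(c(0, delta, delta, 0), 2, 2)
  ord2 <- pcoa_ordination(d2)
  expect_equal(ncol(ord2$coordinates), 1L)
  expect_equal(sort(ord2$coordinates[, 1]), c(-delta / 2, delta / 2),
               tolerance = 1e-12)
  # duplicated sample collapses onto its twin
  d3 <- as.matrix(dist(c(0, 1, 1)))
  ord3 <- pcoa_ordination(d3)
  expect_equal(ord3$coordinates[2, ], ord3$coordinates[3, ], tolerance = 1e-9)
  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("pcoa round-trips Euclidean-embeddable distances to 1e-8", {
  set.seed(73)
  for (i in 1:5) {
    x <- matrix(rnorm(7 * 3), 7, 3)
    d <- as.matrix(dist(x))
    ord <- pcoa_ordination(d)
    rec <- as.matrix(dist(ord$coordinates))
    expect_equal(unname(rec), unname(d), tolerance = 1e-8)
  }
})

test_that("pcoa agrees with the ape reference on eigenvalues", {
  skip_if_not_installed("ape")
  set.seed(74)
  m <- matrix(rpois(60, 6), 10, 6, dimnames = list(NULL, letters[1:6]))
  d <- bray_curtis(m)
  ours <- pcoa_ordination(d)
  ref <- ape::pcoa(as.dist(d))
  k <- sum(ours$eigenvalues > 1e-9)
  expect_equal(ours$eigenvalues[seq_len(k)], ref$values$Eigenvalues[seq_len(k)],
               tolerance = 1e-8)
})

test_that("permanova is relabeling-invariant and floors at 1/(n_perm+1)", {
  set.seed(75)
  # enough samples that a random permutation almost never reproduces the
  # original split, so p can reach the 1/(n_perm + 1) floor
  x <- cbind(matrix(rnorm(40, 0), 4, 10), matrix(rnorm(40, 6), 4, 10))
  colnames(x) <- paste0("s", 1:20)
  d <- as.matrix(dist(t(x)))
  g <- rep(c("a", "b"), each = 10)
  res <- permanova(d, g, n_perm = 999, seed = 1)
  expect_equal(res$p, 0.001)
  # permuting samples and labels jointly leaves pseudo-F unchanged
  perm <- sample(20)
  res2 <- permanova(d[perm, perm], g[perm], n_perm = 9, seed = 1)
  expect_equal(res2$pseudo_F, res$pseudo_F, tolerance = 1e-12)
  expect_error(permanova(d, c("a", rep("b", 19))), "< 2 samples")
  expect_error(permanova(d, rep("a", 20)), ">= 2 groups")
})

test_that("permanova pseudo-F matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(76)
  m <- matrix(rpois(90, 10), 6, 15, dimnames = list(NULL, paste0("s", 1:15)))
  d <- bray_curtis(m)
  g <- rep(c("a", "b", "c"), each = 5)
  ours <- permanova(d, g, n_perm = 99, seed = 2)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
})

test_that("spearman_bh handles perfect monotone and anti-monotone pairs", {
  x <- matrix(seq_len(10), 1, dimnames = list("f1", paste0("s", 1:10)))
  up <- matrix(c(2, 4, 7, 8, 11, 13, 17, 19, 23, 29), 1,
               dimnames = list("o1", paste0("s", 1:10)))
  rec <- spearman_bh(x, up, proportion_transform = FALSE)
  expect_equal(rec$rho, 1)
  expect_equal(rec$p, 0)
  down <- up[, 10:1, drop = FALSE]
  colnames(down) <- paste0("s", 1:10)
  expect_equal(spearman_bh(x, down, proportion_transform = FALSE)$rho, -1)
  expect_error(spearman_bh(x[, 1:3, drop = FALSE], up[, 1:3, drop = FALSE]),
               ">= 4")
})

test_that("spearman rho is invariant under strictly monotone transforms", {
  set.seed(77)
  f <- matrix(rnorm(30), 1, dimnames = list("f", paste0("s", 1:30)))
  o <- matrix(rpois(30, 50) + 1, 1, dimnames = list("o", paste0("s", 1:30)))
  base <- spearman_bh(f, o, proportion_transform = FALSE)$rho
  expect_equal(spearman_bh(exp(f), o, proportion_transform = FALSE)$rho, base)
  expect_equal(spearman_bh(f, o^3, proportion_transform = FALSE)$rho, base)
  # centering/scaling is a no-op for rank correlation
  expect_equal(spearman_bh(center_scale(rbind(f, f * 2))[1, , drop = FALSE],
                           o, proportion_transform = FALSE)$rho, base)
})

test_that("BH q-values dominate p and are monotone in p-rank", {
  set.seed(78)
  f <- matrix(rnorm(10 * 20), 10, 20, dimnames = list(paste0("f", 1:10),
                                                      paste0("s", 1:20)))
  o <- matrix(rpois(5 * 20, 30), 5, 20, dimnames = list(paste0("o", 1:5),
                                                        paste0("s", 1:20)))
  rec <- spearman_bh(f, o)
  expect_true(all(rec$q >= rec$p - 1e-15))
  byp <- rec[order(rec$p), ]
  expect_true(all(diff(byp$q) >= -1e-15))
  expect_equal(nrow(rec), 50L)
})

test_that("top_k_select keeps top-k per sign plus forced records", {
  rec <- data.frame(otu = paste0("o", 1:100), feature = paste0("f", 1:100),
                    rho = seq(-1, 1, length.out = 100),
                    p = seq(0, 0.2, length.out = 100))
  rec$q <- rec$p; rec$significant <- rec$q < 0.05
  rec <- rec[order(rec$q, -abs(rec$rho)), ]
  sel <- top_k_select(rec, k = 5)
  expect_lte(nrow(sel), 10)
  expect_lte(sum(sel$rho > 0), 5)
  expect_lte(sum(sel$rho < 0), 5)
  forced <- top_k_select(rec, k = 5, forced_ids = "o100")
  expect_true("o100" %in% forced$otu)
  expect_true(forced$forced[forced$otu == "o100"])
  only <- top_k_select(rec, k = 0, forced_ids = c("o1", "o2"))
  expect_true(all(only$forced))
  expect_setequal(only$otu, c("o1", "o2"))
})
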
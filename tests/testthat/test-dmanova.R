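# Gower centring, incremental pseudo-F, permutation p-values.

# Direct trace-formula pseudo-F, written independently of the package path.
direct_pseudo_f <- function(G, X0, Xfull) {
  H <- function(X) X %*% solve(crossprod(X)) %*% t(X)
  Hf <- H(Xfull); H0 <- H(X0)
  q <- qr(Xfull)$rank - qr(X0)$rank
  n <- nrow(G); p <- qr(Xfull)$rank
  num <- (sum(diag(Hf %*% G %*% Hf)) - sum(diag(H0 %*% G %*% H0))) / q
  den <- sum(diag((diag(n) - Hf) %*% G %*% (diag(n) - Hf))) / (n - p)
  num / den
}

test_that("Gower centring reproduces the hand-computed two-group matrix", {
  expect_equal(unclass(gower_center(matrix(0, 4, 4))), matrix(0, 4, 4))
  D <- matrix(1, 6, 6); D[1:3, 1:3] <- 0; D[4:6, 4:6] <- 0; diag(D) <- 0
  G <- gower_center(D)
  expect_equal(unclass(G)[1:3, 1:3], matrix(0.25, 3, 3))
  expect_equal(unclass(G)[1:3, 4:6], matrix(-0.25, 3, 3))
  expect_equal(sum(diag(G)), 1.5)
  set.seed(2)
  pts <- matrix(runif(40), 10); Dr <- as.matrix(dist(pts))
  expect_lt(max(abs(rowSums(gower_center(Dr)))), 1e-8)
  expect_error(gower_center(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(gower_center(matrix(c(1, 0, 0, 1), 2)), "zero diagonal")
})

test_that("degenerate designs and distances are rejected", {
  D <- as.matrix(dist(matrix(rnorm(20), 10)))
  G <- gower_center(D)
  x <- rnorm(10)
  expect_error(dmanova_increment(G, cbind(1, x), matrix(x)), "design error")
  expect_error(dmanova_increment(gower_center(matrix(0, 4, 4)),
                                 matrix(1, 4, 1), matrix(rnorm(4))),
               "degenerate-distance")
})

test_that("a saturating group increment reaches pseudo-R2 1 with an infinite F", {
  D <- matrix(1, 6, 6); D[1:3, 1:3] <- 0; D[4:6, 4:6] <- 0; diag(D) <- 0
  G <- gower_center(D)
  r <- dmanova_increment(G, matrix(1, 6, 1), matrix(c(1, 1, 1, 0, 0, 0)),
                         n_perm = 99, seed = 1)
  expect_equal(r$pseudo_r2_full, 1)
  expect_identical(r$F, Inf)
})

test_that("Monte-Carlo p agrees with exhaustive two-group enumeration at n = 6", {
  set.seed(3)
  pts <- matrix(rnorm(12), 6, 2); pts[1:3, ] <- pts[1:3, ] + 2
  G <- gower_center(as.matrix(dist(pts)))
  z <- as.numeric(1:6 %in% 1:3)
  Fs <- apply(combn(6, 3), 2, function(ix) {
    direct_pseudo_f(unclass(G), matrix(1, 6, 1), cbind(1, as.numeric(1:6 %in% ix)))
  })
  F_obs <- direct_pseudo_f(unclass(G), matrix(1, 6, 1), cbind(1, z))
  p_exh <- mean(Fs >= F_obs)
  r <- dmanova_increment(G, matrix(1, 6, 1), matrix(z), n_perm = 4999, seed = 11)
  expect_equal(r$F, F_obs)
  se <- sqrt(p_exh * (1 - p_exh) / 4999)
  expect_lt(abs(r$p - p_exh), 2 * se + 1 / 5000)
})

test_that("pseudo-R2 and F match an independent PERMANOVA implementation", {
  set.seed(9)
  pts <- matrix(abs(rnorm(30 * 6)), 30); pts <- pts / rowSums(pts)
  D <- bray_curtis(pts); G <- gower_center(D)
  z <- rnorm(30)
  r <- dmanova_increment(G, matrix(1, 30, 1), matrix(z), n_perm = 99, seed = 1)
  a <- vegan::adonis2(stats::as.dist(D) ~ z, permutations = 99)
  expect_equal(r$pseudo_r2_full, a$R2[1], tolerance = 1e-10)
  expect_equal(r$F, a$F[1], tolerance = 1e-10)
})

test_that("nested sequences are monotone, deterministic, and validated", {
  set.seed(5)
  n <- 40
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n), g = factor(sample(c("a", "b"), n, TRUE)))
  pts <- matrix(abs(rnorm(n * 5)), n); pts <- pts / rowSums(pts)
  G <- gower_center(bray_curtis(pts))
  specs <- list(base = "x1", plus = c("x1", "g"), full = c("x1", "g", "x2"))
  r1 <- run_dmanova_sequence(G, specs, dat, n_perm = 99, seed = 42)
  r2 <- run_dmanova_sequence(G, specs, dat, n_perm = 99, seed = 42)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$pseudo_r2) >= 0))
  expect_true(all(r1$p_increment[-1] > 0 & r1$p_increment[-1] <= 1))
  expect_error(run_dmanova_sequence(G, list(a = "x1", b = "x2"), dat, 99, 1),
               "nested")
})

test_that("the increment p-value is null-uniform over generator replicates", {
  set.seed(17)
  ps <- vapply(1:200, function(i) {
    n <- 25
    pts <- matrix(abs(rnorm(n * 5)), n); pts <- pts / rowSums(pts)
    G <- gower_center(bray_curtis(pts))
    dmanova_increment(G, matrix(1, n, 1), matrix(rnorm(n)),
                      n_perm = 99, seed = sample.int(1e6, 1))$p
  }, numeric(1))
  # permutation p-values live on a discrete grid; ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
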
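# Ranking metric, running-sum enrichment score, permutation test.

toy_assoc <- function() {
  data.frame(exposure = c("a", "b", "c", "d"),
             beta = c(1.0, 0.5, -0.5, -1.0),
             p = c(0.001, 0.10, 0.20, 0.005))
}

test_that("ranking scores are signed -log10 p with deterministic tie-breaks", {
  rk <- make_ranking(data.frame(exposure = c("up", "dn"),
                                beta = c(2, -2), p = c(0.01, 0.01)))
  expect_equal(unname(unclass(rk)[c("up", "dn")]), c(2, -2))
  # identical (p, |beta|): id order decides
  tie <- make_ranking(data.frame(exposure = c("zz", "aa"),
                                 beta = c(1, 1), p = c(0.05, 0.05)))
  expect_equal(names(tie), c("aa", "zz"))
  capped <- make_ranking(data.frame(exposure = "x0", beta = 1, p = 0))
  expect_true(is.finite(unclass(capped)[["x0"]]))
  expect_error(make_ranking(data.frame(exposure = c("a", "a"),
                                       beta = 1:2, p = c(0.1, 0.2))),
               "one association result per species")
})

test_that("single-member extreme sets reach |ES| = 1, matching brute force", {
  rk <- make_ranking(toy_assoc())
  expect_equal(names(rk), c("a", "b", "c", "d"))
  # brute-force running sum, written out by hand for the 4-item list
  brute <- function(set) {
    w <- abs(unclass(rk)); hit <- names(rk) %in% set
    steps <- ifelse(hit, w / sum(w[hit]), -1 / (4 - length(set)))
    rs <- cumsum(steps)
    rs[which.max(abs(rs))]
  }
  top <- enrichment_score(rk, "a")
  expect_equal(top$es, 1.0)
  expect_equal(top$es, brute("a"))
  expect_equal(top$leading_edge, "a")
  bottom <- enrichment_score(rk, "d")
  expect_equal(bottom$es, -1.0)
  expect_equal(bottom$es, brute("d"))
  mid <- enrichment_score(rk, c("b", "c"))
  expect_equal(mid$es, brute(c("b", "c")))
  expect_error(enrichment_score(rk, c("a", "b", "c", "d")), "degenerate")
  expect_error(enrichment_score(rk, character(0)), "empty")
  expect_error(enrichment_score(rk, "missing"), "absent")
  # a middle member alone cannot reach |ES| = 1
  expect_lt(abs(enrichment_score(rk, "b")$es), 1)
})

test_that("enrichment scores agree with the reference GSEA statistic", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    scores <- rnorm(n) * 3
    assoc <- data.frame(exposure = sprintf("s%02d", 1:n),
                        beta = sign(scores), p = 10^(-abs(scores)))
    rk <- make_ranking(assoc)
    set <- sample(names(rk), sample(2:(n - 2), 1))
    mine <- enrichment_score(rk, set)$es
    ref <- fgsea::calcGseaStat(unclass(rk), which(names(rk) %in% set),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo set-permutation p matches exhaustive enumeration", {
  set.seed(22)
  n <- 8
  assoc <- data.frame(exposure = letters[1:n], beta = rnorm(n),
                      p = runif(n, 1e-4, 0.5))
  rk <- make_ranking(assoc)
  catalog <- structure(list(sets = list(myset = names(rk)[c(1, 2)]),
                            kind = c(myset = "genus"), pruned = character(0)),
                       class = "species_set_catalog")
  obs <- abs(enrichment_score(rk, names(rk)[c(1, 2)])$es)
  all_sets <- combn(names(rk), 2, simplify = FALSE)
  p_exh <- mean(vapply(all_sets, function(s) {
    abs(enrichment_score(rk, s)$es) >= obs
  }, logical(1)))
  r <- enrichment_test(rk, catalog, n_perm = 3999, seed = 5, min_set_size = 2L)
  se <- sqrt(p_exh * (1 - p_exh) / 3999)
  expect_lt(abs(r$p - p_exh), 2 * se + 1 / 4000)
  r2 <- enrichment_test(rk, catalog, n_perm = 999, seed = 5, min_set_size = 2L)
  r3 <- enrichment_test(rk, catalog, n_perm = 999, seed = 5, min_set_size = 2L)
  expect_identical(r2$p, r3$p)
  expect_error(enrichment_test(rk, catalog, n_perm = 10, seed = 1), "config")
})

test_that("undersized sets are skipped and reported", {
  rk <- make_ranking(toy_assoc())
  catalog <- structure(list(sets = list(tiny = "a", pair = c("b", "d")),
                            kind = c(tiny = "gmm", pair = "genus"),
                            pruned = character(0)),
                       class = "species_set_catalog")
  r <- enrichment_test(rk, catalog, n_perm = 99, seed = 1, min_set_size = 2L)
  expect_equal(attr(r, "skipped"), "tiny")
  expect_equal(r$set_id, "pair")
})
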
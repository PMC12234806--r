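# Species filtering, CLR policy, rarefaction, alpha diversity, Bray-Curtis.

test_that("prevalence filter keeps strictly-more-than-threshold species and drops the rest", {
  # species A: 0.02% abundance in 4/10 samples (40% > 30% -> kept)
  # species B: 0.02% in exactly 3/10 (not strictly more than 30% -> dropped)
  # species C: all zero -> dropped; species D: dominant filler
  vals <- matrix(0, 10, 4, dimnames = list(paste0("S", 1:10), c("A", "B", "C", "D")))
  vals[1:4, "A"] <- 2e-4
  vals[1:3, "B"] <- 2e-4
  vals[, "D"] <- 1 - rowSums(vals)
  tab <- abundance_table(vals)
  kept <- colnames(filter_species(tab))
  expect_true("A" %in% kept)
  expect_false("B" %in% kept)
  expect_false("C" %in% kept)
  expect_error(filter_species(tab, min_abund = 0), "config error")
  sparse <- abundance_table(rbind(c(1, 0), c(0, 1)))
  expect_warning(filter_species(sparse, min_prev = 0.6), "no species pass")
})

test_that("CLR matches the direct log-ratio oracle when the pseudo-value is negligible", {
  # second sample pins the global pseudo-value to 1e-12 so the first row's CLR
  # is the pure log-ratio transform of (0.5, 0.25, 0.25)
  tiny <- 1e-12
  vals <- rbind(c(0.5, 0.25, 0.25),
                c(tiny, 0.5, 0.5 - tiny))
  ct <- clr_transform(vals)
  x <- c(0.5, 0.25, 0.25)
  oracle <- log(x) - mean(log(x))   # (0.4621, -0.2310, -0.2310)
  expect_equal(unname(ct$pre_replacement[1, ]), oracle, tolerance = 1e-6)
  expect_equal(unname(oracle), c(0.4621, -0.2310, -0.2310), tolerance = 1e-3)
  # all-equal row -> CLR identically 0
  flat <- clr_transform(rbind(rep(0.25, 4), rep(0.25, 4)))
  expect_equal(max(abs(flat$pre_replacement)), 0, tolerance = 1e-12)
})

test_that("zero cells take each species' minimal non-zero transformed value", {
  vals <- rbind(c(0.6, 0.4, 0),
                c(0.5, 0.3, 0.2),
                c(0.2, 0.3, 0.5))
  ct <- clr_transform(vals)
  # independent hand evaluation of the stated three-step policy
  delta <- 0.2
  lx <- log(vals + delta)
  clr <- lx - rowMeans(lx)
  expect_equal(ct$pre_replacement, clr, ignore_attr = TRUE)
  expect_equal(ct$values[1, 3], min(clr[2:3, 3]))
  expect_true(all(ct$values[!ct$replaced_mask] == ct$pre_replacement[!ct$replaced_mask]))
  # per-species single replacement value
  vals2 <- rbind(c(0.6, 0.4, 0), c(0.7, 0.3, 0), c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5))
  ct2 <- clr_transform(vals2)
  expect_length(unique(ct2$values[ct2$replaced_mask[, 3], 3]), 1L)
  # a fully-zero species is a policy error
  expect_error(clr_transform(rbind(c(1, 0), c(1, 0))), "policy error")
})

test_that("pre-replacement CLR rows sum to zero and closure invariance holds", {
  co <- small_planted_cohort(seed = 4, n = 60)
  ct <- clr_transform(filter_species(co$abundance))
  expect_lt(max(abs(rowSums(ct$pre_replacement))), 1e-8)
  # scaling a raw row by a positive constant before closure changes nothing
  raw <- unclass(co$abundance) * 7.3
  reclosed <- raw / rowSums(raw)
  ct2 <- clr_transform(filter_species(abundance_table(reclosed,
                                                      attr(co$abundance, "genus"))))
  expect_equal(ct$values, ct2$values, tolerance = 1e-9)
})

test_that("rarefaction preserves depth exactly and matches the hypergeometric mean", {
  expect_equal(unname(rarefy_counts(rbind(c(5L, 5L)), depth = 10)[1, ]), c(5L, 5L))
  expect_error(rarefy_counts(rbind(c(5L, 3L)), depth = 10), "below rarefaction depth")
  draws <- vapply(1:2000, function(s) {
    rarefy_counts(rbind(c(900L, 100L)), depth = 100, seed = s)[1, 1]
  }, numeric(1))
  se <- sqrt(100 * 0.9 * 0.1 * (900 / 999) / 2000)
  expect_lt(abs(mean(draws) - 90), 3 * se)
  big <- matrix(rpois(40, 60) + 10L, 4, 10)
  rr <- rarefy_counts(big, depth = min(rowSums(big)), seed = 1)
  expect_true(all(rowSums(rr) == min(rowSums(big))))
})

test_that("alpha diversity closed forms hold", {
  uni <- rbind(rep(25L, 4))
  expect_equal(unname(alpha_diversity(uni, "shannon")), log(4))
  single <- rbind(c(100L, 0L, 0L))
  expect_equal(unname(alpha_diversity(single, "shannon")), 0)
  expect_equal(unname(alpha_diversity(single, "richness")), 1)
  expect_equal(unname(alpha_diversity(single, "inv_simpson")), 1)
  mixed <- rbind(c(0.5, 0.25, 0.25))
  expect_equal(unname(alpha_diversity(mixed, "shannon")),
               -sum(c(0.5, 0.25, 0.25) * log(c(0.5, 0.25, 0.25))))
  expect_equal(unname(alpha_diversity(mixed, "shannon")), 1.0397, tolerance = 1e-4)
  expect_error(alpha_diversity(rbind(c(0, 0))), "domain error")
})

test_that("Bray-Curtis has the hand-computed values and metric properties", {
  expect_equal(bray_curtis(rbind(c(0.6, 0.4), c(0.4, 0.6)))[1, 2], 0.2)
  expect_equal(bray_curtis(rbind(c(0.3, 0.7), c(0.3, 0.7)))[1, 2], 0)
  expect_equal(bray_curtis(rbind(c(1, 0), c(0, 1)))[1, 2], 1)
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 0))), "all-zero")
  co <- small_planted_cohort(seed = 6, n = 40)
  d <- bray_curtis(filter_species(co$abundance))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})
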
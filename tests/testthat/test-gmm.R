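# Module carriage rule and species-set construction.

test_that("carriage applies the two-thirds rule with the short-path tightening", {
  steps <- function(kos) lapply(kos, identity)
  m3 <- gmm_definition("m3", list(steps(list("K1", "K2", "K3"))))
  expect_false(carries_module(c("K1", "K2"), m3))          # 2 of 3 fails
  expect_true(carries_module(c("K1", "K2", "K3"), m3))
  m6 <- gmm_definition("m6", list(steps(list("K1", "K2", "K3", "K4", "K5", "K6"))))
  expect_true(carries_module(c("K1", "K2", "K3", "K4"), m6))   # 4/6 >= 2/3
  expect_false(carries_module(c("K1", "K2", "K3"), m6))        # 3/6 < 2/3
  # any-path rule: path A fails, path B (4 steps, 3 covered) qualifies
  m2p <- gmm_definition("m2p", list(
    steps(list("A1", "A2", "A3")),
    steps(list("B1", "B2", "B3", "B4"))))
  expect_true(carries_module(c("A1", "B1", "B2", "B3"), m2p))
  # a step is covered by ANY of its alternatives
  malt <- gmm_definition("malt", list(list(c("X1", "X2"), c("Y1", "Y2"))))
  expect_true(carries_module(c("X2", "Y1"), malt))
})

test_that("carriage is monotone in the KO repertoire", {
  gen <- generate_gmm_definitions(6, paste0("sp", 1:10), seed = 2)
  all_kos <- unique(unlist(lapply(gen$gmms, function(m) unlist(m$paths))))
  set.seed(7)
  for (i in 1:25) {
    kos <- sample(all_kos, sample(5:25, 1))
    extra <- sample(setdiff(all_kos, kos), 1)
    for (m in gen$gmms) {
      if (carries_module(kos, m)) {
        expect_true(carries_module(c(kos, extra), m))
      }
    }
  }
  # a single-path module with every step covered is carried at any length
  long <- gmm_definition("long", list(lapply(sprintf("K%02d", 1:8), identity)))
  expect_true(carries_module(sprintf("K%02d", 1:8), long))
})

test_that("generated KO profiles reproduce their carriage truth table", {
  sp <- paste0("sp", 1:30)
  gen <- generate_gmm_definitions(8, sp, seed = 5)
  gen2 <- generate_gmm_definitions(8, sp, seed = 5)
  expect_identical(gen$truth, gen2$truth)
  expect_identical(gen$ko_profiles, gen2$ko_profiles)
  decided <- sapply(gen$gmms, function(m) {
    vapply(sp, function(s) carries_module(gen$ko_profiles[[s]], m), logical(1))
  })
  expect_equal(unname(decided), unname(gen$truth))
  expect_error(generate_gmm_definitions(0, sp), "config error")
})

test_that("species sets come from genus map and carriage, with size pruning", {
  vals <- matrix(1 / 8, 4, 8,
                 dimnames = list(paste0("S", 1:4), paste0("sp", 1:8)))
  genus <- setNames(c(rep("gA", 4), rep("gB", 2), rep("gC", 2)), paste0("sp", 1:8))
  ab <- abundance_table(vals, genus)
  m <- gmm_definition("mod1", list(list("K1")))
  ko <- setNames(rep(list(character(0)), 8), paste0("sp", 1:8))
  ko$sp1 <- "K1"; ko$sp3 <- "K1"; ko$sp7 <- "K1"
  cat1 <- build_species_sets(ab, list(m), ko, min_set_size = 3L)
  expect_equal(sort(cat1$sets$mod1), c("sp1", "sp3", "sp7"))
  expect_equal(sort(cat1$sets$gA), paste0("sp", 1:4))
  expect_true(all(c("gB", "gC") %in% cat1$pruned))
  expect_error(build_species_sets(ab, list(m), ko[1:3], min_set_size = 3L),
               "missing species")
  expect_error(build_species_sets(ab, list(), ko, min_set_size = 10L), "empty")
})

test_that("GMM definition and GMT files round-trip", {
  gen <- generate_gmm_definitions(4, paste0("sp", 1:12), seed = 3)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_gmm_definitions(gen$gmms, tmp)
  back <- read_gmm_definitions(tmp)
  expect_equal(length(back), 4L)
  for (m in gen$gmms) {
    expect_equal(unname(lapply(back[[m$module_id]]$paths, unname)),
                 unname(lapply(m$paths, unname)))
  }
  vals <- matrix(1 / 12, 3, 12, dimnames = list(NULL, paste0("sp", 1:12)))
  cat1 <- build_species_sets(abundance_table(vals), gen$gmms, gen$ko_profiles,
                             min_set_size = 1L)
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(cat1, gmt)
  lines <- strsplit(readLines(gmt), "\t")
  expect_equal(length(lines), length(cat1$sets))
  expect_equal(vapply(lines, `[`, "", 1L), names(cat1$sets))
})
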
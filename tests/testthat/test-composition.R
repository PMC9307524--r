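# Count-table operations: rarefaction, relative abundance, succession.

test_that("rarefied samples sum exactly to depth and never exceed input counts", {
  withr::with_seed(30, {
    for (i in 1:10) {
      tab <- generate_count_table(
        prop.table(stats::runif(8)), depths = sample(500:2000, 4), seed = i)
      rar <- rarefy(tab, depth = 400, seed = i)
      expect_true(all(colSums(rar[-1]) == 400))
      expect_true(all(as.matrix(rar[-1]) <= as.matrix(tab[-1])))
    }
  })
})

test_that("a sample at exactly the target depth passes through unchanged", {
  tab <- tibble::tibble(taxon = c("a", "b"), s1 = c(60L, 40L))
  expect_identical(rarefy(tab, 100, seed = 1)$s1, c(60L, 40L))
})

test_that("shallow samples are dropped or raise per policy", {
  tab <- tibble::tibble(taxon = c("a", "b"), deep = c(600L, 400L),
                        shallow = c(5L, 5L))
  expect_warning(rar <- rarefy(tab, 100, seed = 1, policy = "drop"), "shallow")
  expect_equal(names(rar), c("taxon", "deep"))
  expect_error(rarefy(tab, 100, seed = 1, policy = "error"), "shallow")
  expect_error(suppressWarnings(rarefy(tab, 1e6, seed = 1)), "deep enough")
})

test_that("rarefied proportions are unbiased over seeds", {
  tab <- tibble::tibble(taxon = c("a", "b"), s1 = c(1e6L, 1e6L))
  props <- vapply(1:200, function(s) {
    r <- rarefy(tab, 1e4, seed = s)
    r$s1[1] / 1e4
  }, numeric(1))
  se_mean <- sqrt(0.25 / 1e4) / sqrt(200) # binomial SE of the seed average
  expect_lt(abs(mean(props) - 0.5), 3 * se_mean)
})

test_that("relative abundances are per-sample proportions summing to one", {
  expect_equal(
    relative_abundance(tibble::tibble(taxon = "a", s = 17L))$s, 1)
  tab <- tibble::tibble(taxon = c("a", "b"), s = c(3L, 1L))
  expect_equal(relative_abundance(tab)$s, c(0.75, 0.25))
  withr::with_seed(31, {
    for (i in 1:20) {
      rt <- generate_count_table(prop.table(stats::runif(6)),
                                 depths = c(100, 250, 777), seed = i)
      p <- relative_abundance(rt)
      expect_equal(unname(colSums(p[-1])), rep(1, 3), tolerance = 1e-12)
    }
  })
  expect_error(
    relative_abundance(tibble::tibble(taxon = "a", s = 0L)), "All-zero.*s")
})

test_that("replicate means are grouped by metadata", {
  tab <- tibble::tibble(taxon = c("a", "b"),
                        r1 = c(80L, 20L), r2 = c(60L, 40L), r3 = c(10L, 90L))
  meta <- tibble::tibble(sample = c("r1", "r2", "r3"),
                         time_point = c("t1", "t1", "t2"))
  avg <- relative_abundance(tab, metadata = meta, by = "time_point")
  expect_equal(avg$mean_proportion[avg$taxon == "a" & avg$time_point == "t1"],
               0.7)
  expect_equal(avg$n[avg$time_point == "t2"][1], 1L)
})

test_that("succession tracking recovers constructed losses exactly", {
  roster <- paste0("sp", 1:10)
  p1 <- prop.table(c(stats::setNames(rep(1, 10), roster)))
  make_tab <- function(props, seed) {
    generate_count_table(matrix(props, ncol = 3, nrow = 10),
                         depths = rep(2000, 3), taxa = roster, seed = seed)
  }
  # at t3, sp3 / sp7 / sp9 have zero probability everywhere
  p3 <- rep(1 / 7, 10)
  p3[c(3, 7, 9)] <- 0
  tabs <- list(t1 = make_tab(p1, 1), t2 = make_tab(p1, 2),
               t3 = make_tab(p3, 3))
  res <- track_succession(tabs, roster)
  expect_setequal(res$lost_taxa, c("sp3", "sp7", "sp9"))
  expect_equal(res$detected_counts$n_detected[3], 7L)
})

test_that("threshold 0 detects everything; a disjoint roster is all lost", {
  tab <- generate_count_table(c(0.5, 0.5), depths = 100,
                              taxa = c("a", "b"), seed = 1)
  expect_warning(
    all_in <- track_succession(list(t1 = tab), roster = c("a", "b", "ghost"),
                               detection_threshold = 0),
    "absent")
  expect_setequal(all_in$lost_taxa, character(0))
  expect_warning(
    lost <- track_succession(list(t1 = tab), roster = c("x", "y")),
    "absent")
  expect_setequal(lost$lost_taxa, c("x", "y"))
  expect_equal(lost$name_mismatches$t1, c("x", "y"))
})

test_that("raising the detection threshold never shrinks the lost set", {
  withr::with_seed(33, {
    roster <- paste0("sp", 1:8)
    tab <- generate_count_table(prop.table(stats::runif(8, 0, 1)^3),
                                depths = 300, taxa = roster, seed = 3)
    lost_sets <- lapply(c(1, 5, 20, 100), function(th) {
      track_succession(list(t3 = tab), roster, detection_threshold = th)$lost_taxa
    })
    for (i in seq_len(length(lost_sets) - 1)) {
      expect_true(all(lost_sets[[i]] %in% lost_sets[[i + 1]]))
    }
  })
})
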
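tiny_table <- function(vol = c(2, 4, 6), len = NULL, ids = NULL) {
  n <- length(vol)
  tibble::tibble(id = ids %||% sprintf("s%d", seq_len(n)),
                 region = "unknown",
                 Volume = vol,
                 Length = len %||% rev(seq_len(n)))
}

test_that("min-max normalization maps ranges onto [0, 1]", {
  tab <- normalize_features(tiny_table(c(2, 4, 6)), "Volume")
  expect_equal(tab$Volume, c(0, 0.5, 1))
  const <- normalize_features(tiny_table(c(5, 5)), "Volume")
  expect_equal(const$Volume, c(0, 0))
  with_na <- normalize_features(tiny_table(c(2, NA, 6)), "Volume")
  expect_equal(with_na$Volume, c(0, NA, 1))
  expect_error(normalize_features(tiny_table(c(NA, NA)), "Volume"),
               "entirely missing")
  set.seed(1)
  r <- normalize_features(tiny_table(runif(20, 3, 9)), "Volume")$Volume
  expect_equal(range(r), c(0, 1))
})

test_that("cell-distribution scores are rank percentiles with sign inversion", {
  tab <- tiny_table(c(1, 2, 3))
  up <- cell_distribution_query(tab, c(Volume = 1))
  expect_equal(up$score[match(tab$id, up$id)], c(0, 0.5, 1))
  down <- cell_distribution_query(tab, c(Volume = -1))
  expect_equal(down$score[match(tab$id, down$id)], c(1, 0.5, 0))
  expect_equal(up$rank, 1:3)
  # single-spine dataset: percentile defined as 1
  single <- cell_distribution_query(tiny_table(5), c(Volume = 1))
  expect_equal(single$score, 1)
})

test_that("weight validation rejects malformed queries", {
  tab <- tiny_table()
  expect_error(cell_distribution_query(tab, c(Volume = 2)), "\\[-1, 1\\]")
  expect_error(cell_distribution_query(tab, c(Volume = 0)), "nonzero")
  expect_error(cell_distribution_query(tab, c(Nope = 1)), "unknown")
  expect_error(cell_distribution_query(tab, 1), "named")
  expect_error(spine_query(tab, "spine_comparison", c(Volume = 1)),
               "query id")
})

test_that("signatures are normalized centroids, order-invariant", {
  tab <- tiny_table(c(0, 10), ids = c("a", "b"))
  expect_equal(spine_signature(tab, "a", "Volume"), c(Volume = 0))
  expect_equal(spine_signature(tab, c("a", "b"), "Volume"), c(Volume = 0.5))
  expect_equal(spine_signature(tab, c("b", "a"), "Volume"),
               spine_signature(tab, c("a", "b"), "Volume"))
  expect_error(spine_signature(tab, "zz", "Volume"), "absent")
})

test_that("spine comparison rewards similarity and flips under negative weights", {
  tab <- tiny_table(c(1, 2, 3, 4, 8, 6))
  sc <- spine_comparison_query(tab, c(Volume = 1, Length = 1), "s3")
  expect_equal(sc$score[sc$id == "s3"], 1)
  expect_equal(sc$rank[sc$id == "s3"], 1)
  # single negative weight: the farthest spine scores 1
  neg <- spine_comparison_query(tab, c(Volume = -1), "s1")
  far <- tab$id[which.max(abs(tab$Volume - tab$Volume[1]))]
  expect_equal(neg$id[neg$rank == 1], far)
  expect_equal(max(neg$score), 1)
})

test_that("both query modes agree with a brute-force oracle on small tables", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:10, 1)
    tab <- tibble::tibble(
      id = sprintf("sp%02d", seq_len(n)),
      Volume = runif(n, 0.05, 1.5),
      Area = runif(n, 0.5, 6),
      Length = runif(n, 0.3, 5))
    tab$Area[sample(n, 1)] <- NA    # exercise the unscored path
    w <- c(Volume = round(runif(1, 0.1, 1), 2),
           Area = round(runif(1, -1, -0.1), 2),
           Length = round(runif(1, -1, 1), 2))
    if (w[["Length"]] == 0) w[["Length"]] <- 0.5

    got <- cell_distribution_query(tab, w)
    want <- brute_cell_distribution(tab, w)
    expect_equal(got$score[match(names(want), got$id)], unname(want))

    qids <- sample(tab$id[!is.na(tab$Area)], 2)
    got2 <- spine_comparison_query(tab, w, qids)
    want2 <- brute_spine_comparison(tab, w, qids)
    expect_equal(got2$score[match(names(want2), got2$id)], unname(want2))
    expect_setequal(unscored_ids(got2), tab$id[is.na(tab$Area)])
  }
})

test_that("scores are in [0,1], rankings permute scored ids, ties break by id", {
  set.seed(9)
  tab <- tiny_table(runif(30))
  for (sc in list(cell_distribution_query(tab, c(Volume = 1, Length = -0.4)),
                  spine_comparison_query(tab, c(Volume = 0.7), tab$id[4]))) {
    expect_true(all(sc$score >= 0 & sc$score <= 1))
    expect_setequal(sc$id, tab$id)
    expect_equal(sc$rank, seq_len(nrow(sc)))
    expect_true(all(diff(sc$score) <= 0))
  }
  tied <- tiny_table(c(1, 1, 2), ids = c("b", "a", "c"))
  sc <- cell_distribution_query(tied, c(Volume = 1))
  expect_equal(sc$id, c("c", "a", "b"))   # ties by id after score
})

test_that("shuffling dataset order changes no score", {
  set.seed(14)
  tab <- generate_feature_dataset(n_spines = 25, seed = 4, peaks = FALSE)
  shuf <- tab[sample(nrow(tab)), ]
  w <- c(Volume = 0.8, Length = -0.6)
  a <- cell_distribution_query(tab, w)
  b <- cell_distribution_query(shuf, w)
  expect_equal(a$score[match(tab$id, a$id)], b$score[match(tab$id, b$id)])
  qa <- spine_comparison_query(tab, w, tab$id[c(3, 7)])
  qb <- spine_comparison_query(shuf, w, tab$id[c(3, 7)])
  expect_equal(qa$score[match(tab$id, qa$id)], qb$score[match(tab$id, qb$id)])
})

test_that("histograms bin [0,1] conservatively", {
  h <- score_histogram(c(0, 1), n_bins = 2)
  expect_equal(h$count, c(1, 1))
  h2 <- score_histogram(rep(0.5, 7), n_bins = 50)
  expect_equal(sum(h2$count > 0), 1)
  expect_equal(sum(h2$count), 7)
  set.seed(2)
  s <- runif(101)
  expect_equal(sum(score_histogram(s)$count), 101)
})

test_that("range filter and complement partition the scored set", {
  set.seed(5)
  tab <- tiny_table(runif(20))
  sc <- cell_distribution_query(tab, c(Volume = 1))
  inside <- range_filter(sc, 0.25, 0.75)
  outside <- range_filter(sc, 0.25, 0.75, complement = TRUE)
  expect_length(intersect(inside, outside), 0)
  expect_setequal(c(inside, outside), sc$id)
  expect_setequal(range_filter(sc, 0, 1), sc$id)
  degenerate <- cell_distribution_query(tiny_table(c(0.3, 0.9)), c(Volume = 1))
  expect_equal(range_filter(degenerate, 0.5, 0.5), character())
  expect_error(range_filter(sc, 0.9, 0.1), "lo <= hi")
})

test_that("display rescaling remaps and clips", {
  expect_equal(rescale_range(c(0, 0.5, 1), 0, 1), c(0, 0.5, 1))
  expect_equal(rescale_range(c(0.2, 0.6, 0.9), 0.2, 0.6), c(0, 1, 1))
  expect_equal(rescale_range(0.1, 0.2, 0.6), 0)
  expect_error(rescale_range(0.5, 0.7, 0.7), "lo < hi")
  tab <- tiny_table(c(1, 2, 3))
  sc <- rescale_range(cell_distribution_query(tab, c(Volume = 1)), 0.25, 0.75)
  expect_true(all(sc$display_score >= 0 & sc$display_score <= 1))
  expect_true("score" %in% names(sc))
})

test_that("query provenance report captures parameters and histogram", {
  tab <- tiny_table(c(1, 2, 3, 4))
  sc <- spine_comparison_query(tab, c(Volume = 1), "s2")
  p <- withr::local_tempfile(fileext = ".json")
  write_query_report(sc, p, n_bins = 10,
                     filter = list(lo = 0.5, hi = 1, complement = FALSE))
  rep <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(rep$mode, "spine_comparison")
  expect_equal(rep$weights$Volume, 1)
  expect_equal(sum(rep$histogram), 4)
  expect_setequal(rep$filter$ids, range_filter(sc, 0.5, 1))
})
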
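test_that("micro-feature tiles have 18 black pixels, are distinct and pair bijectively", {
  for (seed in c(0, 1, 99)) {
    tiles <- build_tiles(seed)
    expect_length(tiles, 12)
    sums <- vapply(tiles, function(t) sum(t$pattern), numeric(1))
    expect_true(all(sums == 18))
    keys <- vapply(tiles, function(t) paste(t$pattern, collapse = ""), "")
    expect_equal(anyDuplicated(keys), 0)
    ids <- vapply(tiles, function(t) 2L * t$pair_id + t$polarity, integer(1))
    expect_equal(sort(ids), 0:11)
    expect_equal(vapply(tiles, `[[`, integer(1), "tile_id"), ids)
  }
})

test_that("tile generation is deterministic in the seed and varies across seeds", {
  expect_identical(build_tiles(7), build_tiles(7))
  a <- build_tiles(0); b <- build_tiles(1)
  diffs <- mapply(function(x, y) any(x$pattern != y$pattern), a, b)
  expect_true(any(diffs))
})

test_that("schemes pick k covariant pairs deterministically and reject bad k", {
  expect_equal(sort(make_scheme(6, 1)$covariant_pairs), 0:5)
  s3 <- make_scheme(3, 5)
  expect_length(s3$covariant_pairs, 3)
  expect_true(all(s3$covariant_pairs %in% 0:5))
  expect_equal(names(s3$polarity_map), as.character(s3$covariant_pairs))
  expect_identical(make_scheme(3, 5), make_scheme(3, 5))
  s0 <- make_scheme(0, 1)
  expect_length(s0$covariant_pairs, 0)
  expect_error(make_scheme(7, 1), "invalid difficulty")
  expect_error(make_scheme(-1, 1), "invalid difficulty")
})

test_that("textures balance the six selected tiles exactly and fix covariant polarities", {
  sch <- make_scheme(6, 2)
  texK <- make_texture(sch, "K", 11)
  kside <- unname(sch$polarity_map[as.character(0:5)])
  expect_equal(texK$polarity_vector, as.integer(kside))
  texL <- make_texture(sch, "L", 11)
  expect_equal(texL$polarity_vector, 1L - as.integer(kside))
  for (tex in list(texK, texL, make_texture(make_scheme(3, 2), "K", 4))) {
    counts <- tabulate(tex$grid + 1, nbins = 12)
    expect_equal(sort(unique(counts)), c(0L, 150L))
    expect_equal(sum(counts == 150), 6)
    sel <- 2L * 0:5 + tex$polarity_vector
    expect_equal(which(counts == 150) - 1L, sel)
  }
})

test_that("non-covariant polarities are fair coin flips", {
  sch <- make_scheme(4, 3)
  free <- setdiff(0:5, sch$covariant_pairs)
  n <- 600
  pol <- t(vapply(seq_len(n),
                  function(i) make_texture(sch, "K", i)$polarity_vector,
                  integer(6)))
  for (p in free) {
    freq <- mean(pol[, p + 1])
    half_width <- 1.96 * sqrt(0.25 / n)   # binomial 95% band around 0.5
    expect_gt(freq, 0.5 - half_width - 0.04)
    expect_lt(freq, 0.5 + half_width + 0.04)
  }
})

test_that("stimulus sets are balanced with unique ids", {
  sch <- make_scheme(4, 1)
  set <- make_set(sch, 180, 1)
  cats <- vapply(set$stimuli, `[[`, "", "category")
  ids <- vapply(set$stimuli, `[[`, "", "stimulus_id")
  expect_equal(unname(table(cats)[c("K", "L")]), c(90L, 90L),
               ignore_attr = TRUE)
  expect_equal(anyDuplicated(ids), 0)
  tiny <- make_set(sch, 2, 1)
  expect_equal(sort(vapply(tiny$stimuli, `[[`, "", "category")), c("K", "L"))
  expect_error(make_set(sch, 179, 1), "even")
})

test_that("schedules show each stimulus 2-3 times and conserve the trial count", {
  sch <- make_scheme(4, 1)
  set <- make_set(sch, 180, 1)
  schd <- build_schedule(set, 400, 1)
  expect_length(schd$stimulus_id, 400)
  counts <- table(schd$stimulus_id)
  expect_true(all(counts %in% 2:3))
  expect_equal(sum(counts == 3), 40)   # 400 - 2*180
  expect_equal(sum(counts == 2), 140)
  small <- make_set(sch, 2, 1)
  s4 <- build_schedule(small, 4, 1)
  expect_true(all(table(s4$stimulus_id) == 2))
  expect_error(build_schedule(small, 7, 1), "infeasible")
  expect_error(build_schedule(small, 3, 1), "infeasible")
})

test_that("rendered textures conserve tile pixel counts and re-render identically", {
  tiles <- build_tiles(1)
  sch <- make_scheme(4, 1)
  tex <- make_texture(sch, "K", 5)
  raster <- render_raster(tex, tiles)
  expect_equal(dim(raster), c(180, 180))
  # 900 tiles x 18 black pixels, black encoded as 0
  expect_equal(sum(raster == 0), 16200)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  render_png(tex, tiles, f1, final_size = 180)
  render_png(tex, tiles, f2, final_size = 180)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(dim(png::readPNG(f1)), c(180, 180))
  skip_if_not_installed("EBImage")
  f3 <- tempfile(fileext = ".png")
  render_png(tex, tiles, f3)    # default smooth resize
  expect_equal(dim(png::readPNG(f3)), c(275, 275))
})

test_that("rating pairs are 20 within (10 K-K, 10 L-L) plus 20 between, unrepeated, in a fixed order", {
  set <- make_set(make_scheme(4, 1), 20, 1)
  pairs <- sample_rating_pairs(set, 3)
  expect_equal(nrow(pairs), 40)
  expect_equal(sum(pairs$pair_type == "within"), 20)
  expect_equal(sum(pairs$subtype == "KK"), 10)
  expect_equal(sum(pairs$subtype == "LL"), 10)
  expect_equal(sum(pairs$pair_type == "between"), 20)
  cats <- setNames(vapply(set$stimuli, `[[`, "", "category"),
                   vapply(set$stimuli, `[[`, "", "stimulus_id"))
  within <- pairs[pairs$pair_type == "within", ]
  expect_true(all(cats[within$stim1] == cats[within$stim2]))
  between <- pairs[pairs$pair_type == "between", ]
  expect_true(all(cats[between$stim1] != cats[between$stim2]))
  key <- apply(pairs[, c("stim1", "stim2")], 1,
               function(r) paste(sort(r), collapse = "|"))
  expect_equal(anyDuplicated(key), 0)
  expect_identical(pairs, sample_rating_pairs(set, 3))
  expect_error(sample_rating_pairs(make_set(make_scheme(4, 1), 10, 1), 1),
               "at least 10")
})

test_that("covariant polarities make any k >= 1 set perfectly decodable; k = 0 is chance", {
  for (k in c(1, 4, 6)) {
    sch <- make_scheme(k, 8)
    set <- make_set(sch, 40, 8)
    decoded <- vapply(set$stimuli, decode_category, "", scheme = sch)
    expect_equal(decoded, vapply(set$stimuli, `[[`, "", "category"))
  }
  # k = 0: no function of the polarity vector beats 50% in expectation;
  # check the best single-pair rule on a Monte-Carlo sample
  sch0 <- make_scheme(0, 8)
  n <- 400
  cats <- rep(c("K", "L"), each = n / 2)
  pol <- t(mapply(function(cat, i) make_texture(sch0, cat, i)$polarity_vector,
                  cats, seq_len(n)))
  per_pair_acc <- apply(pol, 2, function(col) {
    max(mean((col == 1) == (cats == "K")), mean((col == 0) == (cats == "K")))
  })
  # best of 6 independent coin-flip rules at n = 400: tight around 0.5
  expect_lt(max(per_pair_acc), 0.58)
})
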
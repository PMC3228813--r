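test_that("fragment genomes enumerate every offset at the requested density", {
  el <- c(elt = random_dna(260, seed = 21))
  pool <- c(null = random_dna(6e5, seed = 22))
  fg <- make_fragment_genome(el, sizes = 200, pool, density = 0.10, seed = 23)
  expect_equal(nrow(fg$truth), 260 - 200 + 1)  # 61 offsets
  frag_bp <- sum(fg$truth$size)
  expect_equal(nchar(fg$genome[[1]]), frag_bp * 10)  # exact at density 0.10
  # truth coordinates point at the planted fragment sequences
  i <- 30L
  expect_equal(substr(fg$genome[[1]], fg$truth$start[i] + 1, fg$truth$end[i]),
               substr(el[[1]], fg$truth$offset[i], fg$truth$offset[i] + 199))
  # undersized pool is an informative error
  expect_error(make_fragment_genome(el, 200, c(n = random_dna(1000, seed = 1))),
               "need")
})

test_that("fragment genomes are byte-identical under a fixed seed", {
  el <- c(elt = random_dna(100, seed = 24))
  pool <- c(null = random_dna(2e5, seed = 25))
  a <- make_fragment_genome(el, c(30, 50), pool, seed = 26)
  b <- make_fragment_genome(el, c(30, 50), pool, seed = 26)
  expect_identical(a, b)
})

test_that("detection is any-overlap by default and sensitivities are recounted exactly", {
  truth <- tibble::tibble(chrom = "g", start = c(0L, 100L, 200L),
                          end = c(30L, 150L, 230L),
                          element = "e", size = c(30L, 50L, 30L),
                          offset = c(1L, 1L, 2L))
  regions <- tibble::tibble(chrom = "g", start = c(29L, 300L),
                            end = c(40L, 310L))
  curve <- measure_sensitivity(truth, regions)
  # only the first fragment overlaps (by exactly 1 bp)
  expect_equal(curve$by_size$sensitivity[curve$by_size$size == 30], 0.5)
  expect_equal(curve$by_size$sensitivity[curve$by_size$size == 50], 0)
  # a stricter overlap fraction drops the 1-bp touch
  strict <- measure_sensitivity(truth, regions, overlap_frac = 0.5)
  expect_equal(strict$by_size$sensitivity, c(0, 0))
  # no annotations and full annotations
  none <- measure_sensitivity(truth, regions[0, ])
  expect_true(all(none$by_size$sensitivity == 0))
  all_r <- measure_sensitivity(truth, tibble::tibble(chrom = "g", start = 0L,
                                                     end = 400L))
  expect_true(all(all_r$by_size$sensitivity == 1))
})

test_that("measured sensitivity matches an independent per-fragment recount", {
  set.seed(27)
  sim <- plant_genome(1.5e5, repeat_family(master_length = 200, copies = 40,
                                           divergence = 0.12), seed = 28)
  clouds <- build_esp_clouds(sim$families[[1]], cloud_params(1, 2, 4, 40, 40),
                             k = 12)
  pool <- simulate_null_genome(c(p = random_dna(3e5)), window_bp = 3e5, seed = 29)
  fg <- make_fragment_genome(c(m = sim$masters[[1]]), c(30, 60), pool, seed = 30)
  regions <- annotate_repeats(fg$genome, clouds, window = 10, min_frac = 0.8)
  curve <- measure_sensitivity(fg$truth, regions)
  # recount: brute-force per-fragment any-overlap test
  recount <- vapply(seq_len(nrow(fg$truth)), function(i) {
    any(regions$start < fg$truth$end[i] & regions$end > fg$truth$start[i])
  }, logical(1))
  agg <- tapply(recount, fg$truth$size, mean)
  expect_equal(curve$by_size$sensitivity,
               as.numeric(agg[as.character(curve$by_size$size)]))
  # positional running averages reproduce the per-size means
  for (s in curve$by_size$size) {
    bp <- curve$by_position[curve$by_position$size == s, ]
    expect_equal(length(unique(bp$offset)), sum(fg$truth$size == s))
  }
})

test_that("the sensitivity spline passes through knots, clamps, and degenerates to linear", {
  knots <- tibble::tibble(size = c(30, 50, 80, 100, 150),
                          sensitivity = c(0.2, 0.55, 0.8, 0.9, 0.98))
  fn <- interpolate_sensitivity(knots)
  expect_equal(fn(knots$size), knots$sensitivity, tolerance = 1e-10)
  expect_true(all(fn(seq(10, 400, by = 5)) >= 0 & fn(seq(10, 400, by = 5)) <= 1))
  # constant extrapolation beyond the measured range
  expect_equal(fn(1000), fn(150))
  expect_equal(fn(5), fn(30))

  two <- interpolate_sensitivity(tibble::tibble(size = c(40, 80),
                                                sensitivity = c(0.3, 0.7)))
  expect_equal(two(60), 0.5, tolerance = 1e-10)

  expect_warning(one <- interpolate_sensitivity(
    tibble::tibble(size = 40, sensitivity = 0.4)), "one measured size")
  expect_equal(one(c(10, 100)), c(0.4, 0.4))
})

test_that("the spline tracks a smooth generating curve within 0.05", {
  logistic <- function(x) 1 / (1 + exp(-(x - 80) / 20))
  sizes <- c(30, 60, 90, 120, 200)
  fn <- interpolate_sensitivity(tibble::tibble(size = sizes,
                                               sensitivity = logistic(sizes)))
  grid <- seq(30, 200, by = 1)
  expect_lt(max(abs(fn(grid) - logistic(grid))), 0.05)
})

test_that("missed-bp prediction inverts the sensitivity and reports zero-sensitivity sizes", {
  # sensitivity identically 1: nothing missed
  pred <- predict_missed_bp(tibble::tibble(size = c(30, 50), detected = c(10, 20)),
                            function(len) rep(1, length(len)))
  expect_equal(pred$missed_bp, 0)
  # forced arithmetic: 100 detected at 50% sensitivity -> 100 missed = 5000 bp
  pred <- predict_missed_bp(tibble::tibble(size = 50, detected = 100),
                            function(len) rep(0.5, length(len)))
  expect_equal(pred$per_size$predicted_true, 200)
  expect_equal(pred$missed_bp, 5000)
  # zero sensitivity is excluded loudly, not divided
  expect_warning(
    pred <- predict_missed_bp(tibble::tibble(size = c(30, 50), detected = c(5, 10)),
                              function(len) ifelse(len < 40, 0, 0.5)),
    "sensitivity is 0"
  )
  expect_equal(pred$excluded_sizes, 30)
  expect_equal(nrow(pred$per_size), 1L)
})

test_that("fragment order in the genome does not change measured sensitivity", {
  el <- c(elt = random_dna(120, seed = 31))
  pool <- c(null = random_dna(3e5, seed = 32))
  fg <- make_fragment_genome(el, c(30, 50), pool, seed = 33)
  regions <- tibble::tibble(chrom = "fragment_genome",
                            start = fg$truth$start[c(TRUE, FALSE)],
                            end = fg$truth$end[c(TRUE, FALSE)])
  base <- measure_sensitivity(fg$truth, regions)
  shuf <- measure_sensitivity(fg$truth[sample(nrow(fg$truth)), ], regions)
  expect_equal(dplyr::arrange(shuf$by_size, size), dplyr::arrange(base$by_size, size))
})
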
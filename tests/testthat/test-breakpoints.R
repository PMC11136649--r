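test_that("sampler parameters are validated", {
  expect_s3_class(sampler_params(8, 100, 1), "sampler_params")
  expect_error(sampler_params(-1, 100, 1), "non-negative")
  expect_error(sampler_params(8, 99, 1), "even")
  expect_error(sampler_params(8, 1, 1), ">= 2")
})

test_that("K = 0 yields an empty breakpoint set with lambda 0", {
  gm <- make_toy_map(c(1, 1e6), 1, "constant")
  bs <- sample_breakpoints(gm, sampler_params(0, 100, 7))
  expect_equal(bs$count, 0L)
  expect_equal(bs$lambda, 0)
  expect_length(bs$positions_bp, 0L)
})

test_that("event counts follow the analytic Poisson mean", {
  # chromosome of 62.79 cM, N = 100 haplotypes, K = 8 generations
  gm <- make_toy_map(c(1, 60e6), 62.79, "constant")
  lambda <- 0.6279 * 50 * 8
  bs1 <- sample_breakpoints(gm, sampler_params(8, 100, 1))
  expect_equal(bs1$lambda, lambda, tolerance = 1e-12)
  expect_false(is.unsorted(bs1$positions_bp))
  expect_equal(bs1$count, length(bs1$positions_cM))

  n_seeds <- 1000L
  ms <- vapply(seq_len(n_seeds), function(s) {
    sample_breakpoints(gm, sampler_params(8, 100, s))$count
  }, integer(1))
  expect_lt(abs(mean(ms) - lambda), 3 * sqrt(lambda / n_seeds))
})

test_that("no breakpoint falls strictly inside a zero-rate segment", {
  gm <- genetic_map("20", c(1, 4e5, 6e5, 1e6), c(0, 0.5, 0.5, 1))
  bs <- sample_breakpoints(gm, sampler_params(250, 200, 3))
  expect_gt(bs$count, 100)
  inside <- bs$positions_bp > 4e5 & bs$positions_bp < 6e5
  expect_false(any(inside))
})

test_that("breakpoint sampling is deterministic given the seed", {
  gm <- make_toy_map(c(1, 1e6), 2, "hotspot")
  a <- sample_breakpoints(gm, sampler_params(16, 100, 99))
  b <- sample_breakpoints(gm, sampler_params(16, 100, 99))
  expect_identical(a$positions_bp, b$positions_bp)
  d <- sample_breakpoints(gm, sampler_params(16, 100, 100))
  expect_false(identical(a$positions_bp, d$positions_bp))
})

test_that("recombination probability matches the thinned Poisson closed form", {
  expect_equal(recombination_probability(62.79, 0), 0)
  expect_equal(recombination_probability(0, 8), 0)

  # independent oracle: P(at least one) = 1 - dpois(0, rate)
  oracle <- function(len, k, n) {
    if (is.infinite(n)) return(1 - dpois(0, (len / 100) * k))
    lambda_tot <- (len / 100) * (n / 2) * k   # total event rate
    thin <- 1 - ((n - 1) / n)^2               # P(event involves the haplotype)
    1 - dpois(0, lambda_tot * thin)
  }
  expect_equal(recombination_probability(62.79, 8, Inf),
               oracle(62.79, 8, Inf))
  expect_equal(recombination_probability(286.28, 1, Inf),
               oracle(286.28, 1, Inf))
  expect_equal(recombination_probability(100, 4, 100), oracle(100, 4, 100))

  # frozen closed-form values
  expect_equal(recombination_probability(62.79, 8, Inf), 1 - exp(-5.0232))
  expect_equal(recombination_probability(286.28, 1, Inf), 1 - exp(-2.8628))
  expect_gt(recombination_probability(286.28, 1, Inf), 0.94)

  expect_error(recombination_probability(-1, 8), "non-negative")
  expect_error(recombination_probability(10, -1), "non-negative")
})

test_that("recombination probability is monotone and has the right limits", {
  ks <- c(0, 1, 2, 4, 8, 16, 128)
  p <- recombination_probability(62.79, ks, Inf)
  expect_false(is.unsorted(p))
  expect_equal(p[1], 0)
  expect_gt(recombination_probability(62.79, 1e4, Inf), 1 - 1e-12)
  lens <- c(10, 62.79, 150, 286.28)
  pl <- recombination_probability(lens, 8, Inf)
  expect_false(is.unsorted(pl))
  # finite N slightly lowers the per-haplotype rate
  expect_lt(recombination_probability(62.79, 8, 100),
            recombination_probability(62.79, 8, Inf))
})

test_that("probability_curve tabulates the grid in plotting order", {
  expect_equal(probability_curve(62.79, 0)$probability, 0)
  tab <- probability_curve(c(286.28, 62.79), c(1, 8), N = Inf)
  expect_equal(nrow(tab), 4L)
  expect_false(is.unsorted(tab$length_cM))
  p_small <- tab$probability[tab$length_cM == 62.79 & tab$K == 8]
  p_large <- tab$probability[tab$length_cM == 286.28 & tab$K == 8]
  expect_gte(p_large, p_small)
  expect_gte(p_small, 0.99)
  expect_error(probability_curve(numeric(0), 1), "non-empty")
})

test_that("breakpoints export as a BED-like table", {
  gm <- make_toy_map(c(1, 1e6), 1, "constant")
  bs <- sample_breakpoints(gm, sampler_params(20, 100, 5))
  path <- tempfile(fileext = ".tsv")
  write_breakpoints(bs, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), bs$count)
  expect_equal(tab$position_bp, bs$positions_bp)
  expect_equal(names(tab), c("chrom", "position_bp", "position_cM"))
})
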
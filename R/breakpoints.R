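#' Sampler parameters
#'
#' Bundles the parameters of the recombination process: `K`, the number of
#' simulated generations of meiosis; `N`, the number of haplotypes in the
#' panel (even, since haplotypes come in diploid pairs); and the RNG seed.
#' The expected number of recombination events over a region of genetic
#' length `L` Morgans is `L * (N/2) * K`: each of the `N/2` diploid lineages
#' undergoes `K` meioses, each contributing crossovers at 1 per Morgan.
#'
#' @param K Integer number of simulated generations, `>= 0`.
#' @param N Integer number of haplotypes, even, `>= 2`.
#' @param seed Integer RNG seed.
#' @return An object of class `sampler_params`.
#' @export
sampler_params <- function(K, N, seed) {
  K <- as.integer(K); N <- as.integer(N); seed <- as.integer(seed)
  if (is.na(K) || K < 0L) stop("K must be a non-negative integer")
  if (is.na(N) || N < 2L) stop("N must be an integer >= 2")
  if (N %% 2L != 0L) stop("N must be even (haplotypes come in diploid pairs)")
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(K = K, N = N, seed = seed), class = "sampler_params")
}

#' Sample recombination breakpoints
#'
#' Draws breakpoint positions from a homogeneous Poisson process in
#' genetic-map coordinates over the full map span: the event count
#' `M ~ Poisson(lambda)` with `lambda = total_Morgans * (N/2) * K`, and,
#' conditional on `M`, genetic positions i.i.d. uniform on
#' `[0, total cM]`. Genetic positions are converted to physical positions
#' through the map, so breakpoints concentrate in recombination hotspots and
#' never fall strictly inside zero-rate segments.
#'
#' Draw order under the seed is fixed (event count, then positions) and
#' shared with [forward_transform()], which makes the whole transform
#' replayable from `(map, K, N, seed)`.
#'
#' @param map A [genetic_map()].
#' @param params A [sampler_params()].
#' @return An object of class `breakpoint_set`: list with `count`,
#'   `positions_bp` (sorted, real-valued), `positions_cM` (map-relative),
#'   `lambda`, and `params`.
#' @export
sample_breakpoints <- function(map, params) {
  stopifnot(inherits(map, "genetic_map"), inherits(params, "sampler_params"))
  total <- map_length_cM(map)
  lambda <- (total / 100) * (params$N / 2) * params$K
  g <- with_rng(params$seed, {
    m <- stats::rpois(1L, lambda)
    sort(stats::runif(m, min = 0, max = total))
  })
  new_breakpoint_set(map, g, lambda, params)
}

new_breakpoint_set <- function(map, g, lambda, params) {
  structure(
    list(count = length(g),
         positions_bp = cM_to_bp(map, g),
         positions_cM = g,
         lambda = lambda,
         params = params,
         chromosome = map$chromosome),
    class = "breakpoint_set"
  )
}

#' @export
print.breakpoint_set <- function(x, ...) {
  cat(sprintf(
    "<breakpoint_set> %d events on chromosome %s (lambda = %.3f, K = %d, N = %d, seed = %d)\n",
    x$count, x$chromosome, x$lambda, x$params$K, x$params$N, x$params$seed
  ))
  invisible(x)
}

#' Export breakpoints as a BED-like table
#'
#' Three tab-separated columns: chromosome, physical position (bp) and
#' genetic position (map-relative cM), one row per event, sorted.
#'
#' @param breakpoints A `breakpoint_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breakpoints <- function(breakpoints, path) {
  stopifnot(inherits(breakpoints, "breakpoint_set"))
  df <- data.frame(chrom = breakpoints$chromosome,
                   position_bp = breakpoints$positions_bp,
                   position_cM = breakpoints$positions_cM)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Probability that a haplotype recombines at least once
#'
#' Each recombination event permutes two haplotypes drawn uniformly with
#' replacement, so a given haplotype is involved in an event with
#' probability `1 - ((N-1)/N)^2 = (2N-1)/N^2`. Thinning the process of
#' `total_Morgans * (N/2) * K` expected events accordingly gives a
#' per-haplotype event rate
#' `lambda_h = (length_cM/100) * K * (2N-1)/(2N)`, and the probability of at
#' least one event is `1 - exp(-lambda_h)`. With `N = Inf` the rate is the
#' large-panel limit `(length_cM/100) * K`.
#'
#' @param length_cM Genetic length(s) in centimorgans, `>= 0`.
#' @param K Number of generations, `>= 0`.
#' @param N Number of haplotypes, or `Inf` for the large-panel limit.
#' @return Probability in `[0, 1]`; vectorized over `length_cM` and `K`.
#' @export
recombination_probability <- function(length_cM, K, N = Inf) {
  if (any(length_cM < 0)) stop("length_cM must be non-negative")
  if (any(K < 0)) stop("K must be non-negative")
  if (length(N) != 1L || N < 2) stop("N must be a single value >= 2 (or Inf)")
  thin <- if (is.infinite(N)) 1 else (2 * N - 1) / (2 * N)
  rate <- (length_cM / 100) * K * thin
  1 - exp(-rate)
}

#' Grid of per-haplotype recombination probabilities
#'
#' Tabulates [recombination_probability()] over chromosome genetic lengths
#' and generation counts, in the layout used to plot probability-versus-K
#' curves (one curve per chromosome length).
#'
#' @param lengths_cM Genetic lengths in cM (one per chromosome).
#' @param K_values Generation counts.
#' @param N Number of haplotypes, or `Inf`.
#' @return A data.frame with columns `length_cM`, `K`, `probability`,
#'   ordered by length then K.
#' @export
probability_curve <- function(lengths_cM, K_values, N = Inf) {
  if (length(lengths_cM) == 0L || length(K_values) == 0L) {
    stop("lengths_cM and K_values must be non-empty")
  }
  grid <- expand.grid(K = K_values, length_cM = lengths_cM)
  out <- data.frame(length_cM = grid$length_cM,
                    K = grid$K,
                    probability = recombination_probability(grid$length_cM,
                                                           grid$K, N))
  out[order(out$length_cM, out$K), , drop = FALSE]
}
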
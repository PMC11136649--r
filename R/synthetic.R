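#' Fixture specification for the founder-mosaic panel simulator
#'
#' The simulator builds each haplotype as a Markov mosaic of a small set of
#' founder haplotypes: LD arises because nearby sites tend to be copied from
#' the same founder, and decays with the per-bp switch rate. This gives
#' controllable, realistic block-like LD without a coalescent simulator or
#' any external data.
#'
#' Defaults emulate a dense 1 Mb region: 100 haplotypes (50 diploid
#' samples), 500 biallelic sites, 8 founders, alt-allele probability 0.3
#' per founder per site, and a switch rate of 2e-6 per bp (about two founder
#' switches per haplotype across the region, hence strong long-range LD).
#'
#' @param n_haplotypes Even number of haplotypes.
#' @param n_sites Number of variant sites.
#' @param span_bp Length-2 bp range of the region.
#' @param n_founders Number of founder haplotypes (`<= n_haplotypes`).
#' @param alt_prob Per-site probability that a founder carries the alt
#'   allele.
#' @param switch_rate Per-bp probability rate of switching founders between
#'   adjacent sites (switch probability over a gap `d` is `1 - exp(-rate*d)`).
#' @param chromosome Chromosome label for the fixture.
#' @param seed Integer RNG seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_haplotypes = 100L, n_sites = 500L,
                         span_bp = c(1L, 1000000L), n_founders = 8L,
                         alt_prob = 0.3, switch_rate = 2e-6,
                         chromosome = "20", seed = 1L) {
  n_haplotypes <- as.integer(n_haplotypes)
  n_sites <- as.integer(n_sites)
  n_founders <- as.integer(n_founders)
  if (n_haplotypes < 2L || n_haplotypes %% 2L != 0L) {
    stop("n_haplotypes must be even and >= 2")
  }
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (n_founders < 1L || n_founders > n_haplotypes) {
    stop("n_founders must be in 1..n_haplotypes")
  }
  if (alt_prob < 0 || alt_prob > 1) stop("alt_prob must be in [0, 1]")
  if (switch_rate < 0) stop("switch_rate must be non-negative")
  if (length(span_bp) != 2L || span_bp[2] <= span_bp[1]) {
    stop("span_bp must be an increasing bp range")
  }
  structure(
    list(n_haplotypes = n_haplotypes, n_sites = n_sites,
         span_bp = as.numeric(span_bp), n_founders = n_founders,
         alt_prob = alt_prob, switch_rate = switch_rate,
         chromosome = as.character(chromosome), seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Simulate a phased panel under the founder-mosaic model
#'
#' Draws founder haplotypes with i.i.d. Bernoulli(`alt_prob`) alleles, then
#' copies each panel haplotype from a founder, switching to a uniformly
#' chosen founder between adjacent sites with probability
#' `1 - exp(-switch_rate * gap_bp)`. Positions are drawn uniformly over the
#' span, deduplicated and sorted. Deterministic given the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @return A phased, fully-called [haplotype_panel()].
#' @export
simulate_mosaic_panel <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_rng(spec$seed, {
    pos <- numeric(0)
    while (length(pos) < spec$n_sites) {
      need <- spec$n_sites - length(pos)
      extra <- floor(stats::runif(need + 10L, spec$span_bp[1],
                                  spec$span_bp[2] + 1))
      pos <- sort(unique(c(pos, extra)))
    }
    pos <- pos[seq_len(spec$n_sites)]
    founders <- matrix(
      stats::rbinom(spec$n_founders * spec$n_sites, 1L, spec$alt_prob),
      nrow = spec$n_founders
    )
    p_switch <- 1 - exp(-spec$switch_rate * diff(pos))
    h <- matrix(0L, nrow = spec$n_sites, ncol = spec$n_haplotypes)
    for (j in seq_len(spec$n_haplotypes)) {
      sw <- c(FALSE, stats::runif(spec$n_sites - 1L) < p_switch)
      n_seg <- sum(sw) + 1L
      fid_seg <- sample.int(spec$n_founders, n_seg, replace = TRUE)
      fid <- fid_seg[cumsum(sw) + 1L]
      h[, j] <- founders[cbind(fid, seq_len(spec$n_sites))]
    }
    variants <- data.frame(
      chrom = spec$chromosome, pos = as.integer(pos), id = ".",
      ref = "A", alt = "C", stringsAsFactors = FALSE
    )
    haplotype_panel(variants, h,
                    sprintf("SIM%04d", seq_len(spec$n_haplotypes %/% 2L)))
  })
}

#' Toy genetic maps for testing
#'
#' `shape = "constant"` gives a uniform-rate map (cM linear in bp over the
#' span). `shape = "hotspot"` concentrates 90% of the genetic length in the
#' central 10% of the physical span, mimicking a recombination hotspot
#' flanked by coldspots; the total genetic length is exact by construction.
#'
#' @param span_bp Length-2 bp range.
#' @param total_cM Total genetic length in centimorgans, `>= 0`.
#' @param shape `"constant"` or `"hotspot"`.
#' @param chromosome Chromosome label.
#' @return A [genetic_map()].
#' @export
make_toy_map <- function(span_bp, total_cM, shape = c("constant", "hotspot"),
                         chromosome = "20") {
  shape <- match.arg(shape)
  if (total_cM < 0) stop("total_cM must be non-negative")
  if (length(span_bp) != 2L || span_bp[2] <= span_bp[1]) {
    stop("span_bp must be an increasing bp range")
  }
  a <- span_bp[1]; b <- span_bp[2]
  if (shape == "constant") {
    genetic_map(chromosome, c(a, b), c(0, total_cM))
  } else {
    w <- b - a
    hs_start <- a + 0.45 * w
    hs_end <- a + 0.55 * w
    genetic_map(chromosome,
                c(a, hs_start, hs_end, b),
                c(0, 0.05 * total_cM, 0.95 * total_cM, total_cM))
  }
}

#' Plant an exact duplicate haplotype
#'
#' Replaces the target haplotype with a byte-exact copy of the source.
#' Useful for tracing how long exactly-shared (IBD-like) segments survive
#' the transform: more generations mean more breakpoints and shorter
#' surviving segments.
#'
#' @param panel A [haplotype_panel()].
#' @param source,target Haplotype column indices in `1:N`.
#' @return The modified `haplotype_panel`.
#' @export
plant_duplicate_haplotype <- function(panel, source, target) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- n_haplotypes(panel)
  if (source < 1L || source > n || target < 1L || target > n) {
    stop("haplotype indices must lie in 1..", n)
  }
  panel$haplotypes[, target] <- panel$haplotypes[, source]
  panel
}
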
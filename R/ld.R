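#' Squared correlation between two haplotype columns
#'
#' The usual haplotype-level LD measure: squared Pearson correlation of the
#' two 0/1 allele vectors across haplotypes. Undefined (returns `NA`) when
#' either column is monomorphic, since the correlation has a zero-variance
#' denominator.
#'
#' @param a,b Numeric/integer allele vectors of equal length.
#' @return r-squared in `[0, 1]`, or `NA` for a monomorphic input.
#' @export
pairwise_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("allele vectors must have equal length")
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  min(stats::cor(a, b)^2, 1)
}

#' Per-variant LD scores over a physical window
#'
#' The LD score of a variant is the sum of r-squared between that variant
#' and every other variant within `window_bp` base pairs on either side
#' (inclusive bound, `|delta pos| <= window_bp`). Pairs involving a
#' monomorphic site contribute nothing (r-squared undefined); monomorphic
#' variants are flagged so that cross-panel comparisons can drop them.
#' Multiallelic sites are excluded with a warning.
#'
#' @param panel A [haplotype_panel()] with sorted positions.
#' @param window_bp Half-window in bp (default 100000, i.e. +/-100 kb).
#' @return A data.frame of class `ld_profile` with columns `chrom`, `pos`,
#'   `ld_score`, `n_neighbors` (number of r-squared terms summed) and
#'   `monomorphic`.
#' @export
ld_scores <- function(panel, window_bp = 100000L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (window_bp <= 0) stop("window_bp must be positive")
  v <- panel$variants
  if (is.unsorted(v$pos)) stop("variant positions must be sorted")
  h <- panel$haplotypes
  multi <- grepl(",", v$alt, fixed = TRUE) |
    apply(h, 1L, function(r) any(r > 1L, na.rm = TRUE))
  if (any(multi)) {
    warning(sum(multi), " multiallelic site(s) excluded from LD scores")
    v <- v[!multi, , drop = FALSE]
    h <- h[!multi, , drop = FALSE]
  }
  l <- nrow(h)
  pos <- v$pos
  x <- h - rowMeans(h)
  ss <- rowSums(x * x)
  poly <- ss > 0
  score <- numeric(l)
  nn <- integer(l)
  if (l >= 2L) {
    hi <- findInterval(pos + window_bp, pos)  # last j with pos[j] <= pos[i]+w
    for (i in seq_len(l - 1L)) {
      if (!poly[i] || hi[i] <= i) next
      js <- (i + 1L):hi[i]
      js <- js[poly[js]]
      if (!length(js)) next
      r2 <- as.vector(x[js, , drop = FALSE] %*% x[i, ])^2 / (ss[js] * ss[i])
      r2 <- pmin(r2, 1)
      score[i] <- score[i] + sum(r2)
      score[js] <- score[js] + r2
      nn[i] <- nn[i] + length(js)
      nn[js] <- nn[js] + 1L
    }
  }
  structure(
    data.frame(chrom = v$chrom, pos = pos, ld_score = score,
               n_neighbors = nn, monomorphic = !poly,
               stringsAsFactors = FALSE),
    class = c("ld_profile", "data.frame"),
    window_bp = as.integer(window_bp)
  )
}

check_same_variants <- function(a, b) {
  stopifnot(inherits(a, "ld_profile"), inherits(b, "ld_profile"))
  if (nrow(a) != nrow(b) || !all(a$chrom == b$chrom) || !all(a$pos == b$pos)) {
    stop("LD profiles cover different variant sets")
  }
}

#' Pearson correlation between two LD-score profiles
#'
#' Summarizes how well a synthetic panel preserves the LD landscape of the
#' original: the Pearson correlation of per-variant LD scores across the
#' shared variant set, after dropping variants monomorphic in either panel.
#'
#' @param profile_a,profile_b `ld_profile`s over identical variant sets.
#' @return Pearson's rho.
#' @export
ld_score_correlation <- function(profile_a, profile_b) {
  check_same_variants(profile_a, profile_b)
  keep <- !profile_a$monomorphic & !profile_b$monomorphic
  if (sum(keep) < 3L) stop("too few polymorphic variants shared")
  stats::cor(profile_a$ld_score[keep], profile_b$ld_score[keep])
}

#' Regression slope between two LD-score profiles
#'
#' Ordinary least squares slope (with intercept) of the synthetic LD scores
#' regressed on the original ones. With correlation near 1, a slope below 1
#' reflects a global depletion of LD in the synthetic panel and a slope
#' above 1 a global inflation.
#'
#' @param profile_original,profile_synthetic `ld_profile`s over identical
#'   variant sets.
#' @return The OLS slope beta.
#' @export
ld_score_slope <- function(profile_original, profile_synthetic) {
  check_same_variants(profile_original, profile_synthetic)
  keep <- !profile_original$monomorphic & !profile_synthetic$monomorphic
  xo <- profile_original$ld_score[keep]
  ys <- profile_synthetic$ld_score[keep]
  if (length(xo) < 3L) stop("too few polymorphic variants shared")
  if (stats::var(xo) == 0) stop("original LD scores have zero variance")
  unname(stats::coef(stats::lm(ys ~ xo))[2L])
}

#' Write an LD profile as TSV
#'
#' Columns: chrom, pos, ld_score, n_neighbors (monomorphic variants carry a
#' score of 0 and 0 neighbors).
#'
#' @param profile An `ld_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ld_profile"))
  utils::write.table(
    profile[, c("chrom", "pos", "ld_score", "n_neighbors")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
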
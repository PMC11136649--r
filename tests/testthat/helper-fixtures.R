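# Small builders shared across test files.

toy_panel <- function(n_haplotypes = 20L, n_sites = 60L, seed = 1L,
                      switch_rate = 2e-6, span = c(1, 1e6)) {
  simulate_mosaic_panel(fixture_spec(
    n_haplotypes = n_haplotypes, n_sites = n_sites, span_bp = span,
    switch_rate = switch_rate, seed = seed
  ))
}

# panel built directly from a haplotype matrix (sites x haplotypes)
panel_from_matrix <- function(h, pos, chrom = "20") {
  variants <- data.frame(chrom = chrom, pos = as.integer(pos), id = ".",
                         ref = "A", alt = "C", stringsAsFactors = FALSE)
  haplotype_panel(variants, h, sprintf("S%03d", seq_len(ncol(h) %/% 2L)))
}

# all-pairs LD-score oracle: no windows logic shared with ld_scores()
brute_force_ld_scores <- function(panel, window_bp = 100000L) {
  h <- panel$haplotypes
  pos <- panel$variants$pos
  l <- nrow(h)
  score <- numeric(l)
  for (i in seq_len(l)) {
    for (j in seq_len(l)) {
      if (i == j) next
      if (abs(pos[i] - pos[j]) > window_bp) next
      r2 <- suppressWarnings(stats::cor(h[i, ], h[j, ])^2)
      if (!is.na(r2)) score[i] <- score[i] + r2
    }
  }
  score
}

write_map_file <- function(lines, path = tempfile(fileext = ".map")) {
  writeLines(lines, path)
  path
}
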
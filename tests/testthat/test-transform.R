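test_that("initial shuffle is uniform and deterministic", {
  set.seed(1)
  reps <- 10000L
  ident <- vapply(seq_len(reps), function(i) {
    identical(initial_shuffle(2L), 1:2)
  }, logical(1))
  se <- sqrt(0.25 / reps)
  expect_lt(abs(mean(ident) - 0.5), 3 * se)

  set.seed(42); a <- initial_shuffle(50L)
  set.seed(42); b <- initial_shuffle(50L)
  expect_identical(a, b)
  expect_identical(sort(a), 1:50)
  expect_error(initial_shuffle(1L), ">= 2")
})

test_that("events swap slots, tolerate self-swaps and are involutions", {
  s <- c(1L, 2L, 3L)
  expect_identical(apply_event(s, 1L, 3L), c(3L, 2L, 1L))
  expect_identical(apply_event(s, 2L, 2L), s)
  expect_identical(apply_event(apply_event(s, 1L, 3L), 1L, 3L), s)
  expect_error(apply_event(s, 0L, 2L), "1\\.\\.")
  expect_error(apply_event(s, 1L, 4L), "1\\.\\.")
})

test_that("permutation state stays a bijection through a full schedule", {
  gm <- make_toy_map(c(1, 1e6), 2, "constant")
  plan <- plan_transform(gm, sampler_params(30, 20, 4))
  expect_gt(plan$breakpoints$count, 0)
  perm <- plan$init_order
  for (e in seq_len(nrow(plan$pairs))) {
    perm <- apply_event(perm, plan$pairs[e, 1L], plan$pairs[e, 2L])
    expect_identical(sort(perm), 1:20)
  }
})

test_that("a single event swaps haplotype tails after the breakpoint", {
  # two haplotypes, one crossover between the 2nd and 3rd site
  h <- cbind(c(0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L))
  pos <- c(100, 200, 300, 400)
  plan <- list(breakpoints = list(positions_bp = 250, count = 1L),
               init_order = 1:2,
               pairs = matrix(c(1L, 2L), ncol = 2))
  out <- hapresample:::apply_plan_matrix(h, pos, plan)
  expect_identical(out[, 1], c(0L, 0L, 1L, 1L))
  expect_identical(out[, 2], c(1L, 1L, 0L, 0L))

  # boundary rule: an event exactly at a variant position applies after it
  plan$breakpoints$positions_bp <- 300
  out2 <- hapresample:::apply_plan_matrix(h, pos, plan)
  expect_identical(out2[, 1], c(0L, 0L, 0L, 1L))
})

test_that("K = 0 output is the input under one global relabeling", {
  p <- toy_panel(n_haplotypes = 30L, n_sites = 80L, seed = 5)
  gm <- make_toy_map(c(1, 1e6), 1, "constant")
  fw <- forward_transform(p, gm, K = 0, seed = 17)
  plan <- plan_transform(gm, sampler_params(0, 30, 17))
  expect_identical(fw$panel$haplotypes, p$haplotypes[, plan$init_order])
  expect_identical(fw$metadata$M, 0L)
})

test_that("allele frequencies are conserved exactly at every site and K", {
  p <- toy_panel(n_haplotypes = 40L, n_sites = 120L, seed = 9)
  gm <- make_toy_map(c(1, 1e6), 1.5, "hotspot")
  for (k in c(0, 1, 8, 128)) {
    fw <- forward_transform(p, gm, K = k, seed = 23)
    expect_identical(rowSums(fw$panel$haplotypes), rowSums(p$haplotypes))
    expect_identical(dim(fw$panel$haplotypes), dim(p$haplotypes))
    expect_identical(fw$panel$variants, p$variants)
  }
})

test_that("forward transform is deterministic and seed-sensitive", {
  p <- toy_panel(seed = 2)
  gm <- make_toy_map(c(1, 1e6), 2, "constant")
  a <- forward_transform(p, gm, K = 8, seed = 5)
  b <- forward_transform(p, gm, K = 8, seed = 5)
  expect_identical(a$panel$haplotypes, b$panel$haplotypes)
  d <- forward_transform(p, gm, K = 8, seed = 6)
  expect_false(identical(a$panel$haplotypes, d$panel$haplotypes))
})

test_that("reverse restores the original panel; wrong seed does not", {
  gm <- make_toy_map(c(1, 1e6), 2, "hotspot")
  p <- toy_panel(n_haplotypes = 50L, n_sites = 200L, seed = 31)
  fw <- forward_transform(p, gm, K = 8, seed = 77)
  rv <- reverse_transform(fw$panel, gm, fw$metadata)
  expect_identical(rv$haplotypes, p$haplotypes)
  expect_identical(rv$sample_ids, p$sample_ids)

  bad <- fw$metadata
  bad$seed <- 78L
  bad$M <- NULL   # skip the integrity check to exercise the negative control
  rv_bad <- reverse_transform(fw$panel, gm, bad)
  expect_false(identical(rv_bad$haplotypes, p$haplotypes))
})

test_that("reverse refuses a mismatching map fingerprint or panel width", {
  gm <- make_toy_map(c(1, 1e6), 2, "constant")
  other <- make_toy_map(c(1, 1e6), 2, "hotspot")
  p <- toy_panel(seed = 3)
  fw <- forward_transform(p, gm, K = 4, seed = 9)
  expect_error(reverse_transform(fw$panel, other, fw$metadata),
               class = "hapresample_fingerprint_error")
  wrong_n <- fw$metadata
  wrong_n$N <- 10L
  expect_error(reverse_transform(fw$panel, gm, wrong_n),
               class = "hapresample_fingerprint_error")
})

test_that("validation reports problems and strict mode is fatal", {
  p <- toy_panel(seed = 4)
  rep0 <- validate_panel(p, strict = TRUE)
  expect_true(rep0$ok)
  expect_equal(rep0$n_missing, 0L)
  expect_equal(rep0$n_unphased, 0L)

  pm <- p
  pm$haplotypes[3, 5] <- NA_integer_
  repm <- validate_panel(pm)
  expect_equal(repm$n_missing, 1L)
  expect_false(repm$ok)
  expect_error(validate_panel(pm, strict = TRUE),
               class = "hapresample_validation_error")

  # monomorphic sites are counted, never fatal
  pmono <- p
  pmono$haplotypes[1, ] <- 0L
  expect_gte(validate_panel(pmono, strict = TRUE)$n_monomorphic, 1L)
})

test_that("streaming VCF transform agrees with the in-memory transform", {
  p <- toy_panel(n_haplotypes = 24L, n_sites = 90L, seed = 12)
  gm <- make_toy_map(c(1, 1e6), 2, "hotspot")
  vin <- tempfile(fileext = ".vcf")
  vout <- tempfile(fileext = ".vcf")
  write_haplotype_panel(p, vin)
  suppressMessages(forward_vcf(vin, vout, gm, K = 16, seed = 8))
  fw_file <- read_haplotype_panel(vout)
  fw_mem <- forward_transform(p, gm, K = 16, seed = 8)
  expect_identical(fw_file$haplotypes, fw_mem$panel$haplotypes)
  expect_identical(fw_file$sample_ids, fw_mem$panel$sample_ids)
})

test_that("VCF round trip restores genotypes and original sample names", {
  p <- toy_panel(n_haplotypes = 20L, n_sites = 70L, seed = 21)
  gm <- make_toy_map(c(1, 1e6), 1, "constant")
  vin <- tempfile(fileext = ".vcf")
  vsyn <- tempfile(fileext = ".vcf")
  vres <- tempfile(fileext = ".vcf")
  meta_json <- tempfile(fileext = ".json")
  write_haplotype_panel(p, vin)
  suppressMessages(forward_vcf(vin, vsyn, gm, K = 8, seed = 13,
                               metadata_path = meta_json))

  # metadata travels both in the header and the sidecar
  hdr <- readLines(vsyn, n = 20)
  expect_true(any(startsWith(hdr, "##hapresample_seed=13")))
  meta <- read_metadata_json(meta_json)
  expect_identical(meta$original_samples, p$sample_ids)

  # header-only reversal (no sidecar): genotypes restored, ids anonymous
  suppressMessages(reverse_vcf(vsyn, vres, gm))
  r1 <- read_haplotype_panel(vres)
  expect_identical(r1$haplotypes, p$haplotypes)
  expect_false(identical(r1$sample_ids, p$sample_ids))

  # sidecar reversal: full restoration including sample names
  suppressMessages(reverse_vcf(vsyn, vres, gm, metadata_path = meta_json))
  r2 <- read_haplotype_panel(vres)
  expect_identical(r2$haplotypes, p$haplotypes)
  expect_identical(r2$sample_ids, p$sample_ids)
})

test_that("strict streaming rejects unphased input and leaves no output", {
  p <- toy_panel(seed = 6)
  vin <- tempfile(fileext = ".vcf")
  write_haplotype_panel(p, vin)
  txt <- readLines(vin)
  i <- grep("^[^#]", txt)[1]
  txt[i] <- sub("\\|", "/", txt[i])
  writeLines(txt, vin)
  gm <- make_toy_map(c(1, 1e6), 1, "constant")
  vout <- tempfile(fileext = ".vcf")
  expect_error(suppressMessages(forward_vcf(vin, vout, gm, K = 8, seed = 1)),
               class = "hapresample_validation_error")
  expect_false(file.exists(vout))
  expect_false(file.exists(paste0(vout, ".tmp")))
})

test_that("multi-chromosome and unsorted inputs are rejected", {
  p <- toy_panel(seed = 7)
  vin <- tempfile(fileext = ".vcf")
  write_haplotype_panel(p, vin)
  txt <- readLines(vin)
  data_idx <- grep("^[^#]", txt)
  gm <- make_toy_map(c(1, 1e6), 1, "constant")
  vout <- tempfile(fileext = ".vcf")

  bad <- txt
  bad[data_idx[2]] <- sub("^20\t", "21\t", bad[data_idx[2]])
  f <- tempfile(fileext = ".vcf"); writeLines(bad, f)
  expect_error(suppressMessages(forward_vcf(f, vout, gm, K = 1, seed = 1)),
               "chromosome")

  swapped <- txt
  swapped[data_idx[1:2]] <- swapped[data_idx[2:1]]
  f2 <- tempfile(fileext = ".vcf"); writeLines(swapped, f2)
  expect_error(suppressMessages(forward_vcf(f2, vout, gm, K = 1, seed = 1)),
               "unsorted")
})
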
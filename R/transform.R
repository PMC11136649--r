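#' Initial haplotype shuffle
#'
#' Draws a uniform random permutation of `1:N` from the current RNG stream
#' (callers seed the stream; see [plan_transform()] for the draw order).
#' The permutation maps output haplotype slot to source haplotype index.
#'
#' @param N Number of haplotypes.
#' @return An integer permutation of `1:N`.
#' @export
initial_shuffle <- function(N) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("N must be an integer >= 2")
  sample.int(N)
}

#' Apply one recombination event to a permutation state
#'
#' A recombination event exchanges the source haplotypes carried by output
#' slots `i` and `j`. Events are drawn with replacement, so `i == j` is a
#' legitimate no-op. Applying the same event twice restores the state, which
#' is what makes the whole transform reversible.
#'
#' @param state Integer permutation of `1:N` (output slot -> source index).
#' @param i,j Slot indices in `1:N`.
#' @return The updated permutation.
#' @export
apply_event <- function(state, i, j) {
  n <- length(state)
  if (i < 1L || i > n || j < 1L || j > n) {
    stop("event indices must lie in 1..", n)
  }
  tmp <- state[i]
  state[i] <- state[j]
  state[j] <- tmp
  state
}

#' Replayable transform event schedule
#'
#' Draws, under a single seed, everything stochastic about a transform run:
#' the breakpoint set (event count, then sorted genetic positions), the
#' initial haplotype shuffle, and one `(i, j)` with-replacement haplotype
#' pair per breakpoint in ascending position order. The draw order is fixed,
#' so the identical schedule can be regenerated from `(map, K, N, seed)`
#' alone — the basis of the exact reverse transform.
#'
#' @param map A [genetic_map()].
#' @param params A [sampler_params()].
#' @return A list with `breakpoints` (a `breakpoint_set`), `init_order`
#'   (integer permutation of `1:N`) and `pairs` (`M x 2` integer matrix).
#' @export
plan_transform <- function(map, params) {
  stopifnot(inherits(map, "genetic_map"), inherits(params, "sampler_params"))
  total <- map_length_cM(map)
  lambda <- (total / 100) * (params$N / 2) * params$K
  n <- params$N
  drawn <- with_rng(params$seed, {
    m <- stats::rpois(1L, lambda)
    g <- sort(stats::runif(m, min = 0, max = total))
    init <- sample.int(n)
    # one call drawing i1, j1, i2, j2, ... consumes the stream in the same
    # order as a per-event loop would
    ij <- if (m > 0L) sample.int(n, 2L * m, replace = TRUE) else integer(0)
    list(g = g, init = init, ij = ij)
  })
  pairs <- matrix(drawn$ij, ncol = 2L, byrow = TRUE)
  list(
    breakpoints = new_breakpoint_set(map, drawn$g, lambda, params),
    init_order = drawn$init,
    pairs = pairs
  )
}

# Shared core of the matrix-level forward and reverse transforms. Variants
# are grouped into segments between consecutive breakpoints; within a
# segment the permutation is constant, so whole row blocks are reindexed at
# once. Boundary rule: an event at position r takes effect for the first
# variant with pos > r (a variant exactly at r is emitted under the
# pre-event state).
apply_plan_matrix <- function(h, pos, plan, reverse = FALSE) {
  perm <- plan$init_order
  bp <- plan$breakpoints$positions_bp
  pairs <- plan$pairs
  segs <- findInterval(pos, bp, left.open = TRUE)  # events with bp < pos
  out <- h
  if (nrow(h) == 0L) return(out)
  r <- rle(segs)
  row_end <- cumsum(r$lengths)
  row_start <- c(1L, row_end[-length(row_end)] + 1L)
  done <- 0L
  for (b in seq_along(r$values)) {
    while (done < r$values[b]) {
      done <- done + 1L
      perm <- apply_event(perm, pairs[done, 1L], pairs[done, 2L])
    }
    rows <- row_start[b]:row_end[b]
    cols <- if (reverse) order(perm) else perm
    out[rows, ] <- h[rows, cols, drop = FALSE]
  }
  out
}

#' Transform metadata
#'
#' Everything needed to replay (and therefore reverse) a transform run:
#' the generation count, panel width, seed, event count, a fingerprint of
#' the genetic map and the RNG algorithm identifier. `original_samples` is
#' kept only in the private JSON sidecar, never in the shared VCF header,
#' since stripping sample identities is the point of the transform.
#'
#' @param chromosome Chromosome label.
#' @param K,N,seed Transform parameters (see [sampler_params()]).
#' @param M Breakpoint count, or `NULL` if unknown (it is then recomputed
#'   from the replayed schedule and not cross-checked).
#' @param map_fingerprint Digest from [map_fingerprint()].
#' @param rng RNG algorithm identifier.
#' @param original_samples Optional original sample names for full
#'   restoration on reverse.
#' @return An object of class `transform_metadata`.
#' @export
transform_metadata <- function(chromosome, K, N, seed, M = NULL,
                               map_fingerprint = NULL,
                               rng = RNG_ID,
                               original_samples = NULL) {
  structure(
    list(tool = "hapresample",
         version = as.character(utils::packageVersion("hapresample")),
         chromosome = as.character(chromosome),
         K = as.integer(K),
         N = as.integer(N),
         seed = as.integer(seed),
         M = if (is.null(M)) NULL else as.integer(M),
         map_fingerprint = map_fingerprint,
         rng = rng,
         original_samples = original_samples),
    class = "transform_metadata"
  )
}

#' @export
print.transform_metadata <- function(x, ...) {
  cat(sprintf(
    "<transform_metadata> K=%d N=%d seed=%d M=%s chrom=%s map=%s rng=%s\n",
    x$K, x$N, x$seed,
    if (is.null(x$M)) "?" else as.character(x$M),
    x$chromosome,
    if (is.null(x$map_fingerprint)) "?" else substr(x$map_fingerprint, 1, 8),
    x$rng
  ))
  invisible(x)
}

metadata_header_lines <- function(meta) {
  c(sprintf("##hapresample_version=%s", meta$version),
    sprintf("##hapresample_chromosome=%s", meta$chromosome),
    sprintf("##hapresample_K=%d", meta$K),
    sprintf("##hapresample_N=%d", meta$N),
    sprintf("##hapresample_seed=%d", meta$seed),
    sprintf("##hapresample_M=%d", meta$M),
    sprintf("##hapresample_map_md5=%s", meta$map_fingerprint),
    sprintf("##hapresample_rng=%s", meta$rng))
}

parse_metadata_header <- function(header_lines) {
  grab <- function(key) {
    pat <- paste0("^##hapresample_", key, "=")
    hit <- grep(pat, header_lines, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(pat, "", hit[1])
  }
  k <- grab("K")
  if (is.null(k)) return(NULL)
  transform_metadata(
    chromosome = grab("chromosome"),
    K = as.integer(k),
    N = as.integer(grab("N")),
    seed = as.integer(grab("seed")),
    M = as.integer(grab("M")),
    map_fingerprint = grab("map_md5"),
    rng = grab("rng")
  )
}

#' Write / read transform metadata as a JSON sidecar
#'
#' The sidecar holds the same fields as the `##hapresample_*` VCF header
#' lines plus, optionally, the original sample names. It is intended to stay
#' with the data owner, not to be shared with the synthetic panel.
#'
#' @param meta A `transform_metadata`.
#' @param path JSON path.
#' @return `path` (write) or a `transform_metadata` (read).
#' @export
write_metadata_json <- function(meta, path) {
  stopifnot(inherits(meta, "transform_metadata"))
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_metadata_json
#' @export
read_metadata_json <- function(path) {
  if (!file.exists(path)) stop("metadata sidecar not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform_metadata(
    chromosome = x$chromosome, K = x$K, N = x$N, seed = x$seed,
    M = x$M, map_fingerprint = x$map_fingerprint,
    rng = if (is.null(x$rng)) RNG_ID else x$rng,
    original_samples = x$original_samples
  )
}

#' Forward transform of an in-memory panel
#'
#' Simulates `K` generations of meiotic recombination over the panel:
#' breakpoints are drawn from the Poisson process on the genetic map, the
#' haplotype order is shuffled once, and at each breakpoint (ascending) two
#' haplotype slots drawn with replacement are exchanged. Every emitted site
#' is the input site reindexed by the permutation current at its position,
#' so per-site allele content — and hence every allele frequency — is
#' conserved exactly. Output samples are renamed `SYN0001...`; original
#' identities survive only in the returned metadata.
#'
#' @param panel A [haplotype_panel()] (strictly phased and fully called).
#' @param map A [genetic_map()] for the panel's chromosome.
#' @param K Number of simulated generations, `>= 0`.
#' @param seed Integer RNG seed.
#' @param strict Validate the panel strictly first (recommended; reversal
#'   needs an exactly reproducible matrix).
#' @return A list with `panel` (the synthetic `haplotype_panel`),
#'   `metadata` (a [transform_metadata()]) and `breakpoints`.
#' @export
forward_transform <- function(panel, map, K, seed, strict = TRUE) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(map, "genetic_map"))
  validate_panel(panel, strict = strict)
  n <- n_haplotypes(panel)
  params <- sampler_params(K, n, seed)
  plan <- plan_transform(map, params)
  hout <- apply_plan_matrix(panel$haplotypes, panel$variants$pos, plan)
  syn <- haplotype_panel(panel$variants, hout,
                         sprintf("SYN%04d", seq_len(n %/% 2L)))
  meta <- transform_metadata(
    chromosome = panel$variants$chrom[1],
    K = K, N = n, seed = seed,
    M = plan$breakpoints$count,
    map_fingerprint = map_fingerprint(map),
    original_samples = panel$sample_ids
  )
  list(panel = syn, metadata = meta, breakpoints = plan$breakpoints)
}

#' Reverse transform of an in-memory panel
#'
#' Replays the event schedule from `(map, K, N, seed)` held in the metadata
#' and applies the inverse permutation per segment, restoring the original
#' haplotype matrix exactly. The map fingerprint (and breakpoint count, when
#' recorded) must match the replayed schedule, otherwise the run refuses to
#' proceed rather than silently produce garbage.
#'
#' @param panel A synthetic [haplotype_panel()].
#' @param map The same [genetic_map()] used by the forward run.
#' @param metadata A [transform_metadata()].
#' @return The restored `haplotype_panel`.
#' @export
reverse_transform <- function(panel, map, metadata) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(map, "genetic_map"),
            inherits(metadata, "transform_metadata"))
  if (!is.null(metadata$map_fingerprint) &&
      !identical(map_fingerprint(map), metadata$map_fingerprint)) {
    fingerprint_error("genetic map fingerprint does not match the metadata")
  }
  n <- n_haplotypes(panel)
  if (n != metadata$N) {
    fingerprint_error(sprintf("panel has %d haplotypes but metadata says %d",
                              n, metadata$N))
  }
  plan <- plan_transform(map, sampler_params(metadata$K, metadata$N,
                                             metadata$seed))
  if (!is.null(metadata$M) && plan$breakpoints$count != metadata$M) {
    fingerprint_error(sprintf(
      "replayed %d breakpoints but metadata records %d; map/seed mismatch",
      plan$breakpoints$count, metadata$M))
  }
  horig <- apply_plan_matrix(panel$haplotypes, panel$variants$pos, plan,
                             reverse = TRUE)
  ids <- metadata$original_samples
  if (is.null(ids)) ids <- sprintf("SAMPLE%04d", seq_len(n %/% 2L))
  haplotype_panel(panel$variants, horig, ids)
}

# ---- streaming VCF paths ---------------------------------------------------

read_vcf_header <- function(con) {
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) validation_error("no #CHROM header line found in VCF")
    if (startsWith(ln, "##")) {
      header <- c(header, ln)
    } else if (startsWith(ln, "#CHROM")) {
      return(list(meta = header,
                  columns = strsplit(ln, "\t", fixed = TRUE)[[1]]))
    } else {
      validation_error("malformed VCF: data before #CHROM header line")
    }
  }
}

# Streams data lines through `fun(fields_1_to_9, gt_tokens)` one at a time,
# where gt_tokens is the length-N vector of haplotype allele strings.
# Resident state is one buffer of lines: independent of L.
stream_vcf_rows <- function(cin, cout, ns, out_samples, header_out,
                            row_fun, strict = TRUE, chunk = 512L) {
  writeLines(header_out, cout)
  n <- 2L * ns
  odd <- seq(1L, n, by = 2L)
  even <- odd + 1L
  chrom_seen <- NULL
  prev_pos <- -Inf
  l_count <- 0L
  repeat {
    lines <- readLines(cin, n = chunk)
    if (!length(lines)) break
    out_lines <- character(length(lines))
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) != 9L + ns) {
        validation_error(sprintf("expected %d columns, found %d",
                                 9L + ns, length(f)))
      }
      if (is.null(chrom_seen)) {
        chrom_seen <- f[1]
      } else if (f[1] != chrom_seen) {
        validation_error(paste0("multi-chromosome input (", chrom_seen,
                                " then ", f[1],
                                "); split and run once per chromosome"))
      }
      pos <- as.numeric(f[2])
      if (is.na(pos) || pos < prev_pos) {
        validation_error(paste0("unsorted or invalid POS at line with POS=",
                                f[2]))
      }
      prev_pos <- pos
      if (f[9] != "GT") {
        validation_error("FORMAT must be GT only (haplotype-level streaming)")
      }
      gt <- f[10:(9L + ns)]
      if (strict) {
        bad <- grepl("/", gt, fixed = TRUE) | grepl(".", gt, fixed = TRUE)
        if (any(bad)) {
          validation_error(paste0("unphased or missing genotype at POS=",
                                  f[2]))
        }
      }
      sp <- strsplit(gt, "|", fixed = TRUE)
      if (any(lengths(sp) != 2L)) {
        validation_error(paste0("non-diploid genotype at POS=", f[2]))
      }
      tok <- character(n)
      tok[odd] <- vapply(sp, `[[`, character(1), 1L)
      tok[even] <- vapply(sp, `[[`, character(1), 2L)
      newtok <- row_fun(pos, tok)
      out_lines[i] <- paste(c(f[1:9],
                              paste(newtok[odd], newtok[even], sep = "|")),
                            collapse = "\t")
      l_count <- l_count + 1L
    }
    writeLines(out_lines, cout)
  }
  list(chromosome = chrom_seen, L = l_count)
}

#' Streaming forward transform, VCF to VCF
#'
#' File-level counterpart of [forward_transform()]: reads the input VCF one
#' record at a time, permutes haplotype allele tokens in place and writes
#' the output record, so peak memory does not grow with the number of sites
#' (total cost O(NL)). The output header carries `##hapresample_*` metadata
#' lines; the optional JSON sidecar additionally records the original sample
#' names. Output is written to a temporary file and renamed on success, so a
#' failed run leaves no partial output.
#'
#' @param input Path to a phased, fully-called, single-chromosome VCF
#'   (plain or gzipped).
#' @param output Output VCF path (plain text).
#' @param map A [genetic_map()].
#' @param K Number of simulated generations.
#' @param seed Integer RNG seed.
#' @param strict Fail on unphased/missing genotypes (default `TRUE`).
#' @param metadata_path Optional path for the JSON metadata sidecar.
#' @return The [transform_metadata()], invisibly.
#' @export
forward_vcf <- function(input, output, map, K, seed, strict = TRUE,
                        metadata_path = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  if (!file.exists(input)) validation_error(paste0("input not found: ", input))
  t0 <- proc.time()[["elapsed"]]
  cin <- gzfile(input, "rt")
  on.exit(close(cin), add = TRUE)
  hdr <- read_vcf_header(cin)
  samples <- hdr$columns[-(1:9)]
  ns <- length(samples)
  if (ns < 1L) validation_error("VCF has no sample columns")
  n <- 2L * ns
  params <- sampler_params(K, n, seed)
  plan <- plan_transform(map, params)
  bp <- plan$breakpoints$positions_bp
  pairs <- plan$pairs
  m <- plan$breakpoints$count
  meta <- transform_metadata(
    chromosome = map$chromosome, K = K, N = n, seed = seed, M = m,
    map_fingerprint = map_fingerprint(map), original_samples = samples
  )
  perm <- plan$init_order
  e <- 0L
  tmp <- paste0(output, ".tmp")
  cout <- file(tmp, "wt")
  ok <- FALSE
  on.exit({
    tryCatch(close(cout), error = function(e) NULL)
    if (!ok) unlink(tmp)
  }, add = TRUE)
  header_out <- c(hdr$meta, metadata_header_lines(meta),
                  paste(c(hdr$columns[1:9],
                          sprintf("SYN%04d", seq_len(ns))), collapse = "\t"))
  res <- stream_vcf_rows(cin, cout, ns, NULL, header_out, strict = strict,
                         row_fun = function(pos, tok) {
                           while (e < m && bp[e + 1L] < pos) {
                             e <<- e + 1L
                             perm <<- apply_event(perm, pairs[e, 1L],
                                                  pairs[e, 2L])
                           }
                           tok[perm]
                         })
  close(cout)
  ok <- TRUE
  file.rename(tmp, output)
  meta$chromosome <- if (is.null(res$chromosome)) map$chromosome else
    res$chromosome
  if (!is.null(metadata_path)) write_metadata_json(meta, metadata_path)
  message(sprintf(
    "hapresample forward: N=%d L=%d M=%d lambda=%.4f runtime=%.2fs",
    n, res$L, m, plan$breakpoints$lambda, proc.time()[["elapsed"]] - t0))
  invisible(meta)
}

#' Streaming reverse transform, VCF to VCF
#'
#' Replays the forward event schedule and applies the inverse permutation
#' per segment while streaming, restoring the original genotype matrix
#' exactly. Metadata is taken from, in order of precedence: the `metadata`
#' argument, the JSON sidecar at `metadata_path`, or the `##hapresample_*`
#' lines of the input header. The map fingerprint must match.
#'
#' @param input Path to a transformed VCF.
#' @param output Output VCF path.
#' @param map The [genetic_map()] used by the forward run.
#' @param metadata Optional [transform_metadata()].
#' @param metadata_path Optional JSON sidecar path.
#' @return The metadata used, invisibly.
#' @export
reverse_vcf <- function(input, output, map, metadata = NULL,
                        metadata_path = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  if (!file.exists(input)) validation_error(paste0("input not found: ", input))
  t0 <- proc.time()[["elapsed"]]
  cin <- gzfile(input, "rt")
  on.exit(close(cin), add = TRUE)
  hdr <- read_vcf_header(cin)
  if (is.null(metadata) && !is.null(metadata_path)) {
    metadata <- read_metadata_json(metadata_path)
  }
  if (is.null(metadata)) {
    metadata <- parse_metadata_header(hdr$meta)
  }
  if (is.null(metadata)) {
    validation_error(paste0("no transform metadata: pass `metadata`, a ",
                            "sidecar, or keep the ##hapresample_* header"))
  }
  if (!is.null(metadata$map_fingerprint) &&
      !identical(map_fingerprint(map), metadata$map_fingerprint)) {
    fingerprint_error("genetic map fingerprint does not match the metadata")
  }
  samples <- hdr$columns[-(1:9)]
  ns <- length(samples)
  if (2L * ns != metadata$N) {
    fingerprint_error(sprintf("panel has %d haplotypes but metadata says %d",
                              2L * ns, metadata$N))
  }
  plan <- plan_transform(map, sampler_params(metadata$K, metadata$N,
                                             metadata$seed))
  if (!is.null(metadata$M) && plan$breakpoints$count != metadata$M) {
    fingerprint_error(sprintf(
      "replayed %d breakpoints but metadata records %d; map/seed mismatch",
      plan$breakpoints$count, metadata$M))
  }
  bp <- plan$breakpoints$positions_bp
  pairs <- plan$pairs
  m <- plan$breakpoints$count
  perm <- plan$init_order
  inv <- order(perm)
  e <- 0L
  ids <- metadata$original_samples
  if (is.null(ids)) ids <- sprintf("SAMPLE%04d", seq_len(ns))
  keep <- hdr$meta[!startsWith(hdr$meta, "##hapresample_")]
  header_out <- c(keep, paste(c(hdr$columns[1:9], ids), collapse = "\t"))
  tmp <- paste0(output, ".tmp")
  cout <- file(tmp, "wt")
  ok <- FALSE
  on.exit({
    tryCatch(close(cout), error = function(e) NULL)
    if (!ok) unlink(tmp)
  }, add = TRUE)
  res <- stream_vcf_rows(cin, cout, ns, NULL, header_out, strict = FALSE,
                         row_fun = function(pos, tok) {
                           moved <- FALSE
                           while (e < m && bp[e + 1L] < pos) {
                             e <<- e + 1L
                             perm <<- apply_event(perm, pairs[e, 1L],
                                                  pairs[e, 2L])
                             moved <- TRUE
                           }
                           if (moved) inv <<- order(perm)
                           tok[inv]
                         })
  close(cout)
  ok <- TRUE
  file.rename(tmp, output)
  message(sprintf(
    "hapresample reverse: N=%d L=%d M=%d runtime=%.2fs",
    metadata$N, res$L, m, proc.time()[["elapsed"]] - t0))
  invisible(metadata)
}
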
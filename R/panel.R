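#' Construct a haplotype panel
#'
#' An in-memory phased reference panel: `L` variant sites by `N` haplotypes
#' of allele indices. Columns `2i-1` and `2i` are the two haplotypes of
#' diploid sample `i`. In-memory panels back the evaluation metrics and the
#' simulator; the transform also has a streaming file-to-file path
#' ([forward_vcf()]) whose resident state does not grow with `L`.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp,
#'   non-decreasing), `id`, `ref`, `alt`; one row per site.
#' @param haplotypes Integer matrix, `L` sites x `N` haplotypes, of allele
#'   indices (0 = REF, 1 = first ALT, ...). `NA` marks a missing allele.
#' @param sample_ids Character vector of `N/2` diploid sample names.
#' @param n_unphased Count of unphased genotypes seen when the panel was
#'   parsed from file (0 for panels built in memory; allele order is lost
#'   for unphased genotypes, so strict validation rejects them).
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(variants, haplotypes, sample_ids,
                            n_unphased = 0L) {
  stopifnot(is.data.frame(variants), is.matrix(haplotypes))
  required <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(required %in% names(variants))) {
    stop("variants must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(variants) != nrow(haplotypes)) {
    stop("variants and haplotypes disagree on the number of sites")
  }
  n <- ncol(haplotypes)
  if (n < 2L || n %% 2L != 0L) {
    stop("the panel must contain an even number (>= 2) of haplotypes")
  }
  if (length(sample_ids) != n / 2L) {
    stop("need one sample id per haplotype pair")
  }
  if (is.unsorted(variants$pos)) {
    stop("variant positions must be non-decreasing")
  }
  if (length(unique(variants$chrom)) > 1L) {
    stop("a haplotype_panel holds a single chromosome; split multi-",
         "chromosome input and run once per chromosome")
  }
  structure(
    list(variants = variants,
         haplotypes = haplotypes,
         sample_ids = as.character(sample_ids),
         n_unphased = as.integer(n_unphased)),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "<haplotype_panel> chromosome %s: %d sites x %d haplotypes (%d samples)\n",
    x$variants$chrom[1], nrow(x$haplotypes), ncol(x$haplotypes),
    length(x$sample_ids)
  ))
  invisible(x)
}

#' Number of haplotypes in a panel
#' @param panel A `haplotype_panel`.
#' @return Integer `N`.
#' @export
n_haplotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  ncol(panel$haplotypes)
}

#' Read a phased VCF into a haplotype panel
#'
#' Parses a VCF through vcfR and expands diploid GT fields into the
#' haplotype allele matrix. Unphased ("/") and missing (".") genotypes are
#' tolerated here and counted; [validate_panel()] decides whether they are
#' fatal.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @return A `haplotype_panel`.
#' @export
read_haplotype_panel <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  samples <- colnames(vcf@gt)[-1]
  l <- nrow(gt)
  s <- ncol(gt)
  g <- as.vector(gt)
  g[is.na(g)] <- ".|."
  n_unphased <- sum(grepl("/", g, fixed = TRUE))
  a1 <- sub("[|/].*$", "", g)
  a2 <- sub("^[^|/]*[|/]", "", g)
  a2[!grepl("[|/]", g)] <- "."   # haploid record: second allele missing
  to_int <- function(a) {
    a[a == "."] <- NA
    matrix(as.integer(a), nrow = l, ncol = s)
  }
  m1 <- to_int(a1)
  m2 <- to_int(a2)
  h <- matrix(NA_integer_, nrow = l, ncol = 2L * s)
  h[, seq(1L, 2L * s, by = 2L)] <- m1
  h[, seq(2L, 2L * s, by = 2L)] <- m2
  variants <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), ".", as.character(fix[, "ID"])),
    ref = as.character(fix[, "REF"]),
    alt = ifelse(is.na(fix[, "ALT"]), ".", as.character(fix[, "ALT"])),
    stringsAsFactors = FALSE
  )
  haplotype_panel(variants, h, samples, n_unphased = n_unphased)
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCFv4.2 text file with phased GT-only genotype columns.
#' Extra header lines (e.g. transform metadata) can be injected via
#' `extra_header`.
#'
#' @param panel A `haplotype_panel`.
#' @param path Output path.
#' @param extra_header Character vector of additional `##` header lines.
#' @return `path`, invisibly.
#' @export
write_haplotype_panel <- function(panel, path, extra_header = character()) {
  stopifnot(inherits(panel, "haplotype_panel"))
  v <- panel$variants
  h <- panel$haplotypes
  n <- ncol(h)
  a <- matrix(as.character(h), nrow = nrow(h))
  a[is.na(a)] <- "."
  gtcols <- matrix(paste(a[, seq(1L, n, by = 2L), drop = FALSE],
                         a[, seq(2L, n, by = 2L), drop = FALSE], sep = "|"),
                   nrow = nrow(h))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gtcols, 1L, paste, collapse = "\t"),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", v$chrom[1]),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    extra_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Validate a haplotype panel
#'
#' Reports counts of monomorphic, multiallelic, missing and unphased
#' entries. Monomorphic and multiallelic sites are only reported: the
#' transform permutes allele tokens and is agnostic to what they code.
#' Missing or unphased genotypes are fatal in strict mode because the
#' transform must reproduce the input matrix exactly on reversal and
#' haplotype-level permutation is ill-defined without phase.
#'
#' @param panel A `haplotype_panel`.
#' @param strict If `TRUE`, raise a validation error when any genotype is
#'   missing or unphased.
#' @return A list of class `panel_validation` with fields `n_sites`,
#'   `n_haplotypes`, `n_monomorphic`, `n_multiallelic`, `n_missing`,
#'   `n_unphased`, `ok`.
#' @export
validate_panel <- function(panel, strict = FALSE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  h <- panel$haplotypes
  n_missing <- sum(is.na(h))
  alt_multi <- grepl(",", panel$variants$alt, fixed = TRUE)
  idx_multi <- apply(h, 1L, function(r) any(r > 1L, na.rm = TRUE))
  n_multiallelic <- sum(alt_multi | idx_multi)
  mono <- apply(h, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) == 0L || all(r == r[1])
  })
  rep <- structure(
    list(n_sites = nrow(h),
         n_haplotypes = ncol(h),
         n_monomorphic = sum(mono),
         n_multiallelic = n_multiallelic,
         n_missing = n_missing,
         n_unphased = panel$n_unphased,
         ok = n_missing == 0L && panel$n_unphased == 0L),
    class = "panel_validation"
  )
  if (strict && !rep$ok) {
    validation_error(sprintf(
      "strict validation failed: %d missing allele(s), %d unphased genotype(s)",
      n_missing, panel$n_unphased))
  }
  rep
}

#' @export
print.panel_validation <- function(x, ...) {
  cat(sprintf(
    paste0("<panel_validation> %d sites x %d haplotypes | monomorphic: %d, ",
           "multiallelic: %d, missing: %d, unphased: %d | %s\n"),
    x$n_sites, x$n_haplotypes, x$n_monomorphic, x$n_multiallelic,
    x$n_missing, x$n_unphased, if (x$ok) "OK" else "PROBLEMS"
  ))
  invisible(x)
}
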
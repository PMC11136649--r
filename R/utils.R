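#' @keywords internal
"_PACKAGE"

# All stochastic operations in the package funnel through this helper so that
# the RNG contract is pinned in exactly one place: Mersenne-Twister with
# inversion normals and rejection discrete sampling, seeded once per run.
# The caller's RNG state is saved and restored, so library code never
# perturbs the user's random stream.
RNG_ID <- "Mersenne-Twister/Inversion/Rejection"

with_rng <- function(seed, code) {
  seed <- as.integer(seed)
  if (length(seed) != 1L || is.na(seed)) stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# Error constructors: the CLI maps these condition classes to exit codes.
validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("hapresample_validation_error", "error")))
}

fingerprint_error <- function(msg) {
  stop(errorCondition(msg, class = c("hapresample_fingerprint_error", "error")))
}
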
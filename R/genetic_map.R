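#' Construct a genetic map
#'
#' A genetic map relates physical position (bp, 1-based) to cumulative
#' genetic position (cM) along one chromosome. Physical positions must be
#' strictly increasing and genetic positions non-decreasing (local
#' recombination rates are non-negative). All interpolation between the two
#' coordinate systems is piecewise linear between map knots.
#'
#' @param chromosome Chromosome label (e.g. `"20"`).
#' @param positions_bp Integer-valued physical positions, strictly increasing.
#' @param positions_cM Cumulative genetic positions in centimorgans,
#'   non-decreasing, same length as `positions_bp`.
#' @return An object of class `genetic_map`.
#' @examples
#' gm <- genetic_map("20", c(1000, 2000), c(0, 0.1))
#' bp_to_cM(gm, 1500)
#' @export
genetic_map <- function(chromosome, positions_bp, positions_cM) {
  positions_bp <- as.numeric(positions_bp)
  positions_cM <- as.numeric(positions_cM)
  if (length(positions_bp) != length(positions_cM)) {
    stop("positions_bp and positions_cM must have the same length")
  }
  if (length(positions_bp) < 2L) {
    stop("a genetic map needs at least two entries")
  }
  if (anyNA(positions_bp) || anyNA(positions_cM) ||
      !all(is.finite(positions_bp)) || !all(is.finite(positions_cM))) {
    stop("map coordinates must be finite and non-missing")
  }
  if (any(diff(positions_bp) <= 0)) {
    stop("physical positions must be strictly increasing")
  }
  if (any(diff(positions_cM) < 0)) {
    stop("genetic positions must be non-decreasing (negative cM increment)")
  }
  structure(
    list(chromosome = as.character(chromosome)[1],
         positions_bp = positions_bp,
         positions_cM = positions_cM),
    class = "genetic_map"
  )
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf(
    "<genetic_map> chromosome %s: %d knots, %.0f-%.0f bp, %.4f cM\n",
    x$chromosome, length(x$positions_bp),
    x$positions_bp[1], x$positions_bp[length(x$positions_bp)],
    map_length_cM(x)
  ))
  invisible(x)
}

#' Total genetic length of a map
#'
#' Last minus first cumulative cM position. Internally the package works in
#' genetic coordinates shifted so the map starts at 0 cM.
#'
#' @param map A `genetic_map`.
#' @return Genetic length in centimorgans.
#' @export
map_length_cM <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  g <- map$positions_cM
  g[length(g)] - g[1]
}

#' Read a HapMap-style genetic map file
#'
#' Accepts the common whitespace-delimited map dialects with a one-line
#' header: either 4 columns (chromosome, position bp, rate cM/Mb, cumulative
#' cM) or 3 columns (position bp, rate cM/Mb, cumulative cM). The rate column
#' is ignored; interpolation uses only the cumulative cM column.
#'
#' @param path Path to the map file.
#' @param chromosome Optional chromosome label: with a 4-column file, keep
#'   only rows for this chromosome; with a 3-column file, used as the label
#'   of the returned map.
#' @return A `genetic_map`.
#' @export
read_genetic_map <- function(path, chromosome = NULL) {
  if (!file.exists(path)) stop("genetic map file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) == 4L) {
    if (!is.null(chromosome)) {
      tab <- tab[as.character(tab[[1]]) == as.character(chromosome), ,
                 drop = FALSE]
      if (nrow(tab) == 0L) {
        stop("no map rows for chromosome ", chromosome, " in ", path)
      }
    }
    chrom <- as.character(tab[[1]][1])
    bp <- tab[[2]]
    cm <- tab[[4]]
  } else if (ncol(tab) == 3L) {
    chrom <- if (is.null(chromosome)) "unknown" else as.character(chromosome)
    bp <- tab[[1]]
    cm <- tab[[3]]
  } else {
    stop("unrecognized genetic map format: expected 3 or 4 columns, got ",
         ncol(tab))
  }
  if (nrow(tab) < 2L) stop("genetic map has fewer than 2 usable rows")
  genetic_map(chrom, bp, cm)
}

#' Write a genetic map in HapMap 4-column format
#'
#' Columns: chromosome, physical position (bp), local rate (cM/Mb, derived
#' from finite differences of the cumulative column; 0 on the last row), and
#' cumulative genetic position (cM). Reading the file back reproduces the
#' bp and cM columns exactly.
#'
#' @param map A `genetic_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  n <- length(map$positions_bp)
  rate <- c(diff(map$positions_cM) / (diff(map$positions_bp) / 1e6), 0)
  lines <- c(
    "chr\tposition\tCOMBINED_rate.cM.Mb.\tGenetic_Map.cM.",
    sprintf("%s\t%s\t%s\t%s",
            map$chromosome,
            format(map$positions_bp, digits = 15, scientific = FALSE,
                   trim = TRUE),
            format(rate, digits = 15, trim = TRUE),
            format(map$positions_cM, digits = 15, trim = TRUE))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Physical to genetic coordinates
#'
#' Piecewise-linear interpolation of cumulative cM between map knots; exact
#' at knots and monotone non-decreasing in `pos`. Positions outside the
#' mapped interval are clamped to the first/last knot's cM value, i.e. the
#' recombination rate is taken as zero beyond the map: conservative, since
#' the map states no rate there.
#'
#' @param map A `genetic_map`.
#' @param pos Physical position(s), bp.
#' @return Genetic position(s) in cM, on the map's own cM scale.
#' @export
bp_to_cM <- function(map, pos) {
  stopifnot(inherits(map, "genetic_map"))
  stats::approx(map$positions_bp, map$positions_cM, xout = pos,
                method = "linear", rule = 2, ties = "ordered")$y
}

#' Genetic to physical coordinates
#'
#' Inverse of [bp_to_cM()] on strictly increasing segments. `g` is expressed
#' in map-relative coordinates (0 = first knot, `map_length_cM(map)` = last
#' knot). For a genetic position landing exactly on a flat (zero-rate)
#' segment, the leftmost bp of that segment is returned: a deterministic
#' tie-break for a set of positions that carries zero probability mass under
#' the sampling process.
#'
#' @param map A `genetic_map`.
#' @param g Genetic position(s), cM, in `[0, map_length_cM(map)]`.
#' @return Physical position(s), bp (real-valued).
#' @export
cM_to_bp <- function(map, g) {
  stopifnot(inherits(map, "genetic_map"))
  total <- map_length_cM(map)
  tol <- 1e-9 * max(total, 1)
  if (any(g < -tol | g > total + tol)) {
    stop("genetic position outside [0, ", format(total), "] cM")
  }
  g <- pmin(pmax(g, 0), total)
  cm <- map$positions_cM - map$positions_cM[1]
  bp <- map$positions_bp
  out <- numeric(length(g))
  # findInterval gives the last knot with cm <= g; exact hits take the
  # FIRST knot at that cM (leftmost-bp rule on flat segments).
  idx <- findInterval(g, cm)
  exact <- cm[idx] == g
  if (any(exact)) {
    out[exact] <- bp[match(g[exact], cm)]
  }
  if (any(!exact)) {
    i <- idx[!exact]
    gg <- g[!exact]
    frac <- (gg - cm[i]) / (cm[i + 1L] - cm[i])
    out[!exact] <- bp[i] + frac * (bp[i + 1L] - bp[i])
  }
  out
}

#' Constant-rate null map
#'
#' Returns a map spanning the same physical interval and the same total
#' genetic length as the input but with a uniform recombination rate: cM
#' grows linearly in bp. Used as a null to separate the effect of the
#' recombination landscape (hotspots/coldspots) from the effect of the
#' total amount of recombination.
#'
#' @param map A `genetic_map`.
#' @return A two-knot `genetic_map` with identical total cM.
#' @export
make_constant_rate_map <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  n <- length(map$positions_bp)
  genetic_map(map$chromosome,
              c(map$positions_bp[1], map$positions_bp[n]),
              c(0, map_length_cM(map)))
}

#' Fingerprint of a genetic map table
#'
#' MD5 digest of a canonical serialization of (chromosome, bp, cM). Stored in
#' transform metadata so that a reverse run can verify it is replaying events
#' against the same map that generated them.
#'
#' @param map A `genetic_map`.
#' @return Lower-case hex digest string.
#' @export
map_fingerprint <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  canon <- paste(
    map$chromosome,
    paste(sprintf("%.10g", map$positions_bp), collapse = ","),
    paste(sprintf("%.10g", map$positions_cM), collapse = ","),
    sep = ";"
  )
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canon, tf)
  unname(tools::md5sum(tf))
}
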
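#' Define a genetic map for the simulator
#'
#' A map is a set of chromosomes with physical lengths and marker positions,
#' plus a uniform genetic-to-physical rate used to turn physical distance
#' into recombination fractions through the Haldane map function
#' (no crossover interference): \eqn{r = (1 - e^{-2d})/2} for distance
#' \eqn{d} in Morgans.
#'
#' @param chromosomes Data frame with columns `chrom`, `length_bp` and either
#'   `n_markers` (markers placed on an even grid) or nothing if `markers`
#'   is supplied.
#' @param cm_per_mb Genetic map expansion, centimorgans per megabase (> 0).
#' @param markers Optional data frame `chrom`, `pos` of explicit marker
#'   positions (1-based bp); overrides the even grid for listed chromosomes
#'   and may be combined with grid markers via [add_markers()].
#' @return A `genetic_map` object: list with `chromosomes` (tibble
#'   `chrom`, `length_bp`), `markers` (tibble `chrom`, `pos`, sorted,
#'   strictly increasing within chromosome) and `cm_per_mb`.
#' @examples
#' gm <- genetic_map(data.frame(chrom = "chr1", length_bp = 2e6, n_markers = 5))
#' gm$markers
#' @export
genetic_map <- function(chromosomes, cm_per_mb = 3, markers = NULL) {
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length_bp") %in% names(chromosomes)))
  if (any(chromosomes$length_bp <= 0)) {
    abort("chromosome lengths must be positive")
  }
  if (anyDuplicated(chromosomes$chrom)) {
    abort("duplicated chromosome names in map")
  }
  if (!is.numeric(cm_per_mb) || length(cm_per_mb) != 1L || cm_per_mb <= 0) {
    abort("`cm_per_mb` must be a single positive number")
  }
  if (is.null(markers)) {
    if (!"n_markers" %in% names(chromosomes)) {
      abort("supply either `n_markers` per chromosome or an explicit `markers` table")
    }
    if (any(chromosomes$n_markers < 1)) abort("n_markers must be >= 1")
    markers <- purrr::pmap_dfr(chromosomes, function(chrom, length_bp, n_markers, ...) {
      # even grid, avoiding position 0 and duplicate rounding collisions
      pos <- unique(pmax(1, round(seq_len(n_markers) * as.numeric(length_bp) / (n_markers + 1))))
      tibble(chrom = chrom, pos = pos)
    })
  }
  markers <- as_tibble(markers) %>%
    select("chrom", "pos") %>%
    distinct() %>%
    arrange(.data$chrom, .data$pos)
  validate_map_markers(markers, chromosomes)
  structure(
    list(
      chromosomes = select(chromosomes, "chrom", "length_bp"),
      markers = markers,
      cm_per_mb = cm_per_mb
    ),
    class = "genetic_map"
  )
}

validate_map_markers <- function(markers, chromosomes) {
  bad_chrom <- setdiff(markers$chrom, chromosomes$chrom)
  if (length(bad_chrom)) {
    abort(paste0("markers on unknown chromosome(s): ", paste(bad_chrom, collapse = ", ")))
  }
  joined <- left_join(markers, chromosomes, by = "chrom")
  off <- joined$pos < 1 | joined$pos > joined$length_bp
  if (any(off)) {
    abort(paste0(
      "marker positions outside chromosome on: ",
      paste(unique(joined$chrom[off]), collapse = ", ")
    ))
  }
  non_inc <- markers %>%
    group_by(.data$chrom) %>%
    summarise(ok = all(diff(.data$pos) > 0) || n() == 1L) %>%
    filter(!.data$ok)
  if (nrow(non_inc)) {
    abort(paste0(
      "marker positions not strictly increasing on chromosome ",
      paste(non_inc$chrom, collapse = ", ")
    ))
  }
  invisible(markers)
}

#' Add extra marker positions to a map
#'
#' Used by the fixture generator to guarantee that segregating sites fall
#' inside gene coding sequence.
#'
#' @param map A [genetic_map()].
#' @param extra Data frame with `chrom`, `pos`.
#' @return A new `genetic_map` with the union of marker positions.
#' @export
add_markers <- function(map, extra) {
  stopifnot(inherits(map, "genetic_map"))
  genetic_map(
    map$chromosomes,
    cm_per_mb = map$cm_per_mb,
    markers = bind_rows(map$markers, as_tibble(extra)[, c("chrom", "pos")])
  )
}

#' Default nine-chromosome map
#'
#' A foxtail-millet-scale stand-in genome: nine chromosomes totalling
#' roughly 400 Mb with an even marker grid (about one marker per 200 kb,
#' ~2,000 markers genome-wide) and 3 cM/Mb.
#'
#' @param markers_per_mb Grid density, markers per Mb.
#' @param cm_per_mb Genetic map expansion.
#' @return A [genetic_map()].
#' @export
default_map <- function(markers_per_mb = 5, cm_per_mb = 3) {
  lens <- c(42, 49, 50.5, 40, 47, 36, 36.5, 40.5, 59) * 1e6
  chromosomes <- tibble(
    chrom = paste0("chr", 1:9),
    length_bp = lens,
    n_markers = pmax(1L, round(lens / 1e6 * markers_per_mb))
  )
  genetic_map(chromosomes, cm_per_mb = cm_per_mb)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(
    "<genetic_map> ", nrow(x$chromosomes), " chromosome(s), ",
    nrow(x$markers), " markers, ", x$cm_per_mb, " cM/Mb\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy genetic_map
#' @export
tidy.genetic_map <- function(x, ...) {
  left_join(x$markers, x$chromosomes, by = "chrom")
}

# Recombination fraction between adjacent markers of one chromosome.
haldane_r <- function(pos, cm_per_mb) {
  if (length(pos) < 2L) return(numeric(0))
  d_morgan <- diff(pos) / 1e6 * cm_per_mb / 100
  0.5 * (1 - exp(-2 * d_morgan))
}
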
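# Featurization: fragments -> per-base tracks -> windowed feature tibbles.
# Coordinates are 0-based half-open (BED convention) throughout; per-base
# vectors index base i at element i + 1.

frags_to_iranges <- function(frags, segment_length) {
  abort_if(!all(c("start", "end") %in% names(frags)),
           "`frags` needs `start` and `end` columns")
  abort_if(any(frags$end <= frags$start), "fragments must satisfy end > start")
  outside <- frags$start < 0L | frags$end > segment_length
  if (any(outside)) {
    rlang::warn(sprintf("%d fragment(s) outside the segment were clipped",
                        sum(outside)))
    frags <- dplyr::mutate(frags,
                           start = pmax(.data$start, 0L),
                           end = pmin(.data$end, segment_length))
    frags <- dplyr::filter(frags, .data$end > .data$start)
  }
  IRanges::IRanges(start = frags$start + 1L, end = frags$end)
}

coverage_vector <- function(ir, width) {
  if (length(ir) == 0L) return(numeric(width))
  as.numeric(IRanges::coverage(ir, width = width))
}

# Coverage of [start, end) ranges given in 0-based half-open coordinates,
# clipped to the segment.
interval_cover <- function(start0, end0, width) {
  s <- pmax(start0, 0L) + 1L
  e <- pmin(end0, width)
  keep <- e >= s
  coverage_vector(IRanges::IRanges(s[keep], e[keep]), width)
}

#' Per-base sequencing coverage
#'
#' `coverage[i]` counts the fragments whose half-open span contains base
#' `i` (0-based).
#'
#' @param frags A `fragment_set` (or any tibble with `start`/`end`).
#' @param segment_length Segment length in bp; defaults to the attribute
#'   stored on `frags`.
#' @return Numeric vector of length `segment_length`.
#' @export
compute_coverage <- function(frags, segment_length = attr(frags, "segment_length")) {
  abort_if(is.null(segment_length), "`segment_length` is required")
  coverage_vector(frags_to_iranges(frags, segment_length), segment_length)
}

#' Windowed protection score (WPS)
#'
#' For each base, the number of fragments completely spanning the
#' `w`-wide window centred there minus the number of fragments with at
#' least one endpoint inside that window. Peaks mark protected
#' (nucleosomal) positions; the waveform flattens in open chromatin.
#'
#' @inheritParams compute_coverage
#' @param w Even window width in bp (default 120).
#' @return Numeric vector of length `segment_length`.
#' @export
compute_wps <- function(frags, segment_length = attr(frags, "segment_length"),
                        w = 120L) {
  abort_if(is.null(segment_length), "`segment_length` is required")
  abort_if(w %% 2L != 0L || w <= 0L, "`w` must be a positive even integer")
  abort_if(w > segment_length, "`w` exceeds the segment length")
  ir <- frags_to_iranges(frags, segment_length)  # validates/clips
  L <- as.integer(segment_length)
  if (length(ir) == 0L) return(numeric(L))
  half <- w %/% 2L
  start0 <- IRanges::start(ir) - 1L   # back to 0-based
  last0 <- IRanges::end(ir) - 1L     # last covered base
  len <- last0 - start0 + 1L

  # A fragment spans the window at centre i iff start <= i - half and
  # end >= i + half, i.e. i in [start + half, last + 1 - half].
  spanning <- interval_cover(start0 + half, last0 + 2L - half, L)
  # Endpoint e lies in [i - half, i + half) iff i in [e - half + 1, e + half].
  up <- interval_cover(start0 - half + 1L, start0 + half + 1L, L)
  dn <- interval_cover(last0 - half + 1L, last0 + half + 1L, L)
  # Fragments with both endpoints in the window were counted twice.
  both <- interval_cover(last0 - half + 1L, start0 + half + 1L, L)
  spanning - (up + dn - both)
}

#' Fragment end signals
#'
#' `uend[i]` counts fragments starting (5' end) at base `i`; `dend[i]`
#' counts fragments whose last covered base is `i`. Their peaks flank
#' nucleosomes and vanish in open chromatin.
#'
#' @inheritParams compute_coverage
#' @return A list with numeric vectors `uend` and `dend`.
#' @export
compute_end_signals <- function(frags,
                                segment_length = attr(frags, "segment_length")) {
  abort_if(is.null(segment_length), "`segment_length` is required")
  ir <- frags_to_iranges(frags, segment_length)
  L <- as.integer(segment_length)
  list(uend = as.numeric(tabulate(IRanges::start(ir), nbins = L)),
       dend = as.numeric(tabulate(IRanges::end(ir), nbins = L)))
}

#' All four per-base signal tracks
#'
#' @inheritParams compute_wps
#' @param wps_w WPS window width in bp.
#' @return A tibble of class `signal_tracks` with columns `pos` (0-based),
#'   `wps`, `coverage`, `uend`, `dend`.
#' @export
compute_tracks <- function(frags, segment_length = attr(frags, "segment_length"),
                           wps_w = 120L) {
  abort_if(is.null(segment_length), "`segment_length` is required")
  L <- as.integer(segment_length)
  ends <- compute_end_signals(frags, L)
  out <- tibble::tibble(
    pos = 0:(L - 1L),
    wps = compute_wps(frags, L, w = wps_w),
    coverage = compute_coverage(frags, L),
    uend = ends$uend,
    dend = ends$dend)
  structure(out, class = c("signal_tracks", class(out)),
            segment_length = L, n_fragments = nrow(frags))
}

#' Average signal tracks over non-overlapping windows
#'
#' Tiles the segment with `window_bp`-wide windows (stride = width; a
#' 20-kbp segment at 200 bp gives exactly 100 windows) and averages each
#' track within a window, yielding the windows-by-4 feature representation
#' the control charts monitor. A trailing partial window is dropped with a
#' message.
#'
#' @param tracks A `signal_tracks` tibble.
#' @param window_bp Window width in bp (default 200).
#' @return A tibble of class `feature_windows` with columns `window`
#'   (0-based), `start`, `end`, `wps`, `coverage`, `uend`, `dend`.
#' @export
window_average <- function(tracks, window_bp = 200L) {
  abort_if(window_bp <= 0L, "`window_bp` must be positive")
  L <- nrow(tracks)
  nwin <- L %/% window_bp
  abort_if(nwin == 0L, "segment shorter than one window")
  if (L %% window_bp != 0L) {
    rlang::inform(sprintf("dropping trailing partial window of %d bp",
                          L %% as.integer(window_bp)))
  }
  out <- tracks |>
    dplyr::mutate(window = .data$pos %/% as.integer(window_bp)) |>
    dplyr::filter(.data$window < nwin) |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(dplyr::across(c("wps", "coverage", "uend", "dend"), mean),
                     .groups = "drop") |>
    dplyr::mutate(start = .data$window * as.integer(window_bp),
                  end = .data$start + as.integer(window_bp),
                  .after = "window")
  structure(out, class = c("feature_windows", class(out)),
            window_bp = as.integer(window_bp))
}

#' Extract the windows-by-4 numeric matrix
#'
#' @param fw A `feature_windows` tibble.
#' @return Numeric matrix with columns `wps`, `coverage`, `uend`, `dend`.
#' @export
feature_matrix <- function(fw) {
  as.matrix(fw[, c("wps", "coverage", "uend", "dend")])
}

#' Two-component dispersion summary of a windowed sample
#'
#' The population standard deviations of the windowed WPS and coverage
#' means: the low-dimensional representation monitored by the MEWMA /
#' sensitized charts. Structured (closed) chromatin fluctuates strongly
#' across windows; open chromatin is flat.
#'
#' @param fw A `feature_windows` tibble with at least two rows.
#' @return A named list with `sd_wps` and `sd_coverage` (both >= 0).
#' @export
summarize_std <- function(fw) {
  abort_if(nrow(fw) < 2L, "need at least two windows to summarize dispersion")
  list(sd_wps = sd_pop(fw$wps), sd_coverage = sd_pop(fw$coverage))
}

#' Encode fragments as 2-D count images
#'
#' Primary channel: a genomic-coordinate x fragment-length count matrix
#' (rows are coordinate bins of the fragment start, columns 1-bp length
#' bins over `len_range`). Auxiliary channels hold the coordinate-binned
#' coverage, WPS and fragment head/tail densities. Input for image-based
#' classifiers; entirely deterministic.
#'
#' @inheritParams compute_wps
#' @param len_range Fragment-length range retained, default `c(100, 400)`.
#' @param coord_bin_bp Coordinate bin width in bp, default 200.
#' @param wps_w WPS window for the auxiliary channel.
#' @return A list of class `encoded_image` with elements `lengths`
#'   (count matrix), `coverage`, `wps`, `uend`, `dend` (binned vectors).
#' @export
encode_image <- function(frags, segment_length = attr(frags, "segment_length"),
                         len_range = c(100L, 400L), coord_bin_bp = 200L,
                         wps_w = 120L) {
  abort_if(is.null(segment_length), "`segment_length` is required")
  L <- as.integer(segment_length)
  nbin <- L %/% as.integer(coord_bin_bp)
  lens <- len_range[1]:len_range[2]
  counts <- matrix(0L, nrow = nbin, ncol = length(lens),
                   dimnames = list(NULL, lens))
  if (nrow(frags) > 0L) {
    flen <- frags$end - frags$start
    bin <- frags$start %/% as.integer(coord_bin_bp) + 1L
    keep <- flen >= len_range[1] & flen <= len_range[2] & bin <= nbin & bin >= 1L
    if (any(keep)) {
      tab <- table(factor(bin[keep], levels = seq_len(nbin)),
                   factor(flen[keep], levels = lens))
      counts <- matrix(as.integer(tab), nrow = nbin,
                       dimnames = list(NULL, lens))
    }
  }
  fw <- window_average(compute_tracks(frags, L, wps_w = wps_w),
                       window_bp = coord_bin_bp)
  structure(list(lengths = counts, coverage = fw$coverage, wps = fw$wps,
                 uend = fw$uend, dend = fw$dend),
            class = "encoded_image", coord_bin_bp = as.integer(coord_bin_bp),
            len_range = len_range)
}
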
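#' Simulation parameters for synthetic cfDNA fragments
#'
#' Collects the generative settings of the synthetic cell-free DNA (cfDNA)
#' fragment model. Closed chromatin (CCR) is emulated as a periodic
#' nucleosome lattice: one protected nucleosome per `period_bp` (default
#' 190 bp, the canonical nucleosome repeat length), mono-nucleosomal
#' fragments of about `frag_len_mean_bp` (default 167 bp) centred on the
#' nucleosome dyads with Gaussian placement jitter. Open chromatin (OCR)
#' loses the lattice: fragments are placed uniformly, and per-base coverage
#' is depleted by the multiplicative factor `ocr_depletion`.
#'
#' @param period_bp Nucleosome repeat length in bp. Default 190.
#' @param frag_len_mean_bp Mean fragment length in bp for
#'   nucleosome-protected (closed-state) fragments. Default 167
#'   (mono-nucleosomal cfDNA).
#' @param frag_len_sd_bp Fragment length standard deviation in bp; lengths
#'   are drawn from a normal truncated to `[frag_len_min_bp, frag_len_max_bp]`.
#' @param frag_len_min_bp,frag_len_max_bp Truncation bounds for fragment
#'   length, default 100 and 400 bp.
#' @param depth_ccr Mean number of fragments per nucleosome period in the
#'   closed state. Default 114, giving an expected per-base coverage of
#'   about `depth_ccr * frag_len_mean_bp / period_bp` = 100x, the deep
#'   cfDNA sequencing regime this kind of chart monitoring assumes; at
#'   this depth the per-window signal of an open region clearly exceeds
#'   window-level counting noise.
#' @param ocr_depletion Multiplicative coverage factor in (0, 1) applied in
#'   the open state. Default 0.3: open regions show strongly reduced
#'   coverage and loss of protection-score structure.
#' @param placement_jitter_bp Standard deviation in bp of fragment midpoint
#'   jitter around the nucleosome dyad. Default 20.
#' @param occupancy_sd Coefficient of variation of the smooth nucleosome
#'   occupancy field modulating per-nucleosome depth in the closed state
#'   (default 0.2). Real closed chromatin shows domain-scale coverage
#'   waviness (occupancy domains, GC and accessibility gradients); this
#'   long-range structure is what survives, attenuated, in partially open
#'   mixtures and makes them distinguishable from fully open regions.
#' @param occupancy_phi AR(1) autocorrelation of the log-occupancy field
#'   across adjacent nucleosomes (default 0.9, i.e. a correlation length
#'   of roughly 2 kbp).
#' @param ocr_frag_len_mean_bp,ocr_frag_len_sd_bp Fragment length mean and
#'   standard deviation in the open state (defaults 100 and 20 bp,
#'   truncated at `[ocr_frag_len_min_bp, frag_len_max_bp]`). Open
#'   chromatin is nuclease-hypersensitive and yields shorter,
#'   sub-nucleosomal cfDNA fragments, raising the fragment-end density
#'   relative to coverage and driving the protection score negative.
#' @param ocr_frag_len_min_bp Lower truncation bound for open-state
#'   fragment lengths (default 60 bp).
#'
#' @return A list of class `sim_params`.
#' @export
#' @examples
#' sim_params()
sim_params <- function(period_bp = 190L, frag_len_mean_bp = 167L,
                       frag_len_sd_bp = 15, frag_len_min_bp = 100L,
                       frag_len_max_bp = 400L, depth_ccr = 114,
                       ocr_depletion = 0.3, placement_jitter_bp = 20,
                       occupancy_sd = 0.2, occupancy_phi = 0.9,
                       ocr_frag_len_mean_bp = 100L, ocr_frag_len_sd_bp = 20,
                       ocr_frag_len_min_bp = 60L) {
  check_number(period_bp, "period_bp", lower = 1)
  check_number(frag_len_mean_bp, "frag_len_mean_bp", lower = 1)
  check_number(frag_len_sd_bp, "frag_len_sd_bp", lower = 0)
  check_number(depth_ccr, "depth_ccr", lower = 0)
  check_number(ocr_depletion, "ocr_depletion", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(placement_jitter_bp, "placement_jitter_bp", lower = 0)
  check_number(occupancy_sd, "occupancy_sd", lower = 0)
  check_number(occupancy_phi, "occupancy_phi", lower = 0, upper = 1,
               closed_upper = FALSE)
  abort_if(frag_len_min_bp >= frag_len_max_bp,
           "`frag_len_min_bp` must be below `frag_len_max_bp`.")
  structure(
    list(period_bp = as.integer(period_bp),
         frag_len_mean_bp = as.integer(frag_len_mean_bp),
         frag_len_sd_bp = frag_len_sd_bp,
         frag_len_min_bp = as.integer(frag_len_min_bp),
         frag_len_max_bp = as.integer(frag_len_max_bp),
         depth_ccr = depth_ccr,
         ocr_depletion = ocr_depletion,
         placement_jitter_bp = placement_jitter_bp,
         occupancy_sd = occupancy_sd, occupancy_phi = occupancy_phi,
         ocr_frag_len_mean_bp = as.integer(ocr_frag_len_mean_bp),
         ocr_frag_len_sd_bp = ocr_frag_len_sd_bp,
         ocr_frag_len_min_bp = as.integer(ocr_frag_len_min_bp)),
    class = "sim_params")
}

# Truncated-normal fragment lengths via inverse-CDF sampling; the open
# state draws shorter, sub-nucleosomal fragments.
draw_frag_lengths <- function(n, params, state = "CCR") {
  if (n == 0L) return(integer(0))
  if (state == "OCR") {
    mu <- params$ocr_frag_len_mean_bp; sd <- params$ocr_frag_len_sd_bp
    lb <- params$ocr_frag_len_min_bp
  } else {
    mu <- params$frag_len_mean_bp; sd <- params$frag_len_sd_bp
    lb <- params$frag_len_min_bp
  }
  lo <- stats::pnorm(lb, mu, sd)
  hi <- stats::pnorm(params$frag_len_max_bp, mu, sd)
  u <- stats::runif(n, lo, hi)
  pmax(2L, as.integer(round(stats::qnorm(u, mu, sd))))
}

new_fragment_set <- function(start, end, chrom, segment_length, state) {
  ord <- order(start, end)
  out <- tibble::tibble(chrom = chrom,
                        start = as.integer(start[ord]),
                        end = as.integer(end[ord]))
  structure(out,
            class = c("fragment_set", class(out)),
            segment_length = as.integer(segment_length),
            state = state)
}

#' Simulate cfDNA fragments for one genomic segment
#'
#' Places synthetic cfDNA fragments (0-based half-open intervals) on a
#' segment, in either the closed (`"CCR"`) or open (`"OCR"`) chromatin
#' state. In the closed state, fragment midpoints cluster around a periodic
#' nucleosome lattice so that coverage, the windowed protection score and
#' the fragment-end signals all carry the ~190 bp periodicity whose loss
#' marks open chromatin. In the open state fragments are uniform with
#' expected per-base coverage equal to `ocr_depletion` times the closed
#' state's.
#'
#' @param segment_length_bp Segment length in bp (>= `params$period_bp`).
#' @param state `"CCR"` (closed, in-control) or `"OCR"` (open).
#' @param params A [sim_params()] object.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param chrom Chromosome name used in the output intervals.
#'
#' @return A tibble of class `fragment_set` with columns `chrom`, `start`,
#'   `end` (0-based half-open), carrying the segment length and state as
#'   attributes.
#' @export
#' @examples
#' frags <- simulate_fragments(20000, "CCR", sim_params(), seed = 1)
#' nrow(frags)
simulate_fragments <- function(segment_length_bp, state = c("CCR", "OCR"),
                               params = sim_params(), seed = NULL,
                               chrom = "sim") {
  state <- match.arg(state)
  abort_if(!inherits(params, "sim_params"), "`params` must come from sim_params().")
  check_number(segment_length_bp, "segment_length_bp", lower = params$period_bp)
  L <- as.integer(segment_length_bp)

  with_seed_or_not(seed, {
    if (state == "CCR") {
      centers <- seq(params$period_bp / 2, L - params$period_bp / 2,
                     by = params$period_bp)
      # Smooth multiplicative occupancy field: log-normal AR(1) across
      # nucleosomes, mean 1, CV ~ occupancy_sd.
      sg <- sqrt(log(1 + params$occupancy_sd^2))
      g <- as.numeric(stats::filter(
        stats::rnorm(length(centers), 0,
                     sg * sqrt(1 - params$occupancy_phi^2)),
        params$occupancy_phi, method = "recursive",
        init = stats::rnorm(1, 0, sg)))
      counts <- stats::rpois(length(centers),
                             params$depth_ccr * exp(g - sg^2 / 2))
      mids <- rep(centers, counts) +
        stats::rnorm(sum(counts), 0, params$placement_jitter_bp)
    } else {
      # Fragment count scaled by the length ratio so that the *coverage*
      # ratio OCR/CCR equals ocr_depletion despite shorter fragments.
      n <- stats::rpois(1L, params$ocr_depletion * params$depth_ccr *
                          (L / params$period_bp) *
                          params$frag_len_mean_bp / params$ocr_frag_len_mean_bp)
      mids <- stats::runif(n, 0, L)
    }
    lens <- draw_frag_lengths(length(mids), params, state)
    start <- as.integer(round(mids - lens / 2))
    end <- start + lens
    keep <- start >= 0L & end <= L
    new_fragment_set(start[keep], end[keep], chrom, L, state)
  })
}

#' Mix open and closed feature matrices into a partially open one
#'
#' Generates partially open chromatin (pOCR) features as the element-wise
#' convex combination `tau * OCR + (1 - tau) * CCR` of an open and a closed
#' feature matrix, the standard composite model for intermediate
#' accessibility. `tau` (the composite rate) defaults to 0.7.
#'
#' @param ocr_feat,ccr_feat Windowed feature tibbles from
#'   [window_average()] (or plain numeric matrices) of identical shape.
#' @param tau Composite rate in (0, 1]; `tau = 1` returns `ocr_feat`.
#'
#' @return An object of the same type as the inputs holding the mixture.
#' @export
simulate_pocr_features <- function(ocr_feat, ccr_feat, tau = 0.7) {
  check_number(tau, "tau", lower = 0, upper = 1, closed_lower = FALSE)
  feature_cols <- c("wps", "coverage", "uend", "dend")
  if (is.data.frame(ocr_feat) && all(feature_cols %in% names(ocr_feat))) {
    abort_if(!is.data.frame(ccr_feat) || nrow(ccr_feat) != nrow(ocr_feat),
             "feature tibbles must have identical shapes")
    out <- ocr_feat
    for (cn in feature_cols) {
      out[[cn]] <- tau * ocr_feat[[cn]] + (1 - tau) * ccr_feat[[cn]]
    }
    return(out)
  }
  a <- as_feature_matrix_input(ocr_feat)
  b <- as_feature_matrix_input(ccr_feat)
  abort_if(!all(dim(a) == dim(b)), "feature matrices must have identical shapes")
  tau * a + (1 - tau) * b
}

flip_labels <- function(labels, noise_rate, seed = NULL) {
  check_number(noise_rate, "noise_rate", lower = 0, upper = 0.5,
               closed_upper = FALSE)
  with_seed_or_not(seed, {
    flip <- stats::runif(length(labels)) < noise_rate
    list(labels = ifelse(flip, 1L - labels, labels), flipped = flip)
  })
}

featurize_sample <- function(frags, segment_bp, window_bp, wps_w) {
  tracks <- compute_tracks(frags, segment_length = segment_bp, wps_w = wps_w)
  window_average(tracks, window_bp = window_bp)
}

#' Build a labeled synthetic dataset of open/closed/partially open regions
#'
#' Simulates `n_ocr` open, `n_ccr` closed and `n_pocr` partially open
#' samples, featurizes each 20-kbp segment into a windows-by-4 feature
#' tibble (WPS, coverage, Uend, Dend window means) plus the two-component
#' summary vector (standard deviations of the windowed WPS and coverage
#' means), and attaches observed binary labels. Partially open samples are
#' composite features at rate `tau` and receive a *random* binary observed
#' label (their true state is absent from the binary label vocabulary);
#' a `noise_rate` fraction of the open/closed observed labels is flipped.
#'
#' Defaults (400 open, 1000 closed) mirror a typical out-of-control /
#' in-control training split for the charts.
#'
#' @param n_per_class If given, overrides `n_ocr`, `n_ccr` and `n_pocr`
#'   with a common count.
#' @param tau Composite rate for partially open features.
#' @param noise_rate Fraction of open/closed observed labels flipped,
#'   in `[0, 0.5)`.
#' @param params [sim_params()] generative settings.
#' @param seed Integer seed; the dataset is fully reproducible.
#' @param n_ocr,n_ccr,n_pocr Per-class sample counts.
#' @param segment_bp,window_bp,wps_w Segment, tiling-window and WPS window
#'   sizes in bp (defaults 20000, 200, 120).
#'
#' @return A tibble of class `labeled_dataset`; one row per sample with
#'   columns `sample_id`, `chrom`, `start`, `end`, `true_class` (0 closed,
#'   1 open, 2 partially open), `observed_label` (0/1), `flipped`,
#'   `sd_wps`, `sd_coverage` and the list-column `features`.
#' @export
make_dataset <- function(n_per_class = NULL, tau = 0.7, noise_rate = 0.2,
                         params = sim_params(), seed = 1,
                         n_ocr = 400L, n_ccr = 1000L, n_pocr = 400L,
                         segment_bp = 20000L, window_bp = 200L, wps_w = 120L) {
  if (!is.null(n_per_class)) {
    abort_if(n_per_class < 1, "`n_per_class` must be >= 1")
    n_ocr <- n_ccr <- n_pocr <- as.integer(n_per_class)
  }
  check_number(tau, "tau", lower = 0, upper = 1, closed_lower = FALSE)
  check_number(noise_rate, "noise_rate", lower = 0, upper = 0.5,
               closed_upper = FALSE)

  # pOCR features mix a dedicated fresh OCR/CCR pair, so extra source
  # segments are simulated beyond the n_ocr + n_ccr kept as-is.
  true_class <- c(rep(1L, n_ocr), rep(0L, n_ccr), rep(2L, n_pocr))
  n_total <- length(true_class)

  sim_one <- function(i, state, seed_i) {
    frags <- simulate_fragments(segment_bp, state, params, seed = seed_i)
    featurize_sample(frags, segment_bp, window_bp, wps_w)
  }

  feats <- with_seed_or_not(seed, {
    purrr::map(seq_len(n_total), function(i) {
      if (true_class[i] < 2L) {
        state <- if (true_class[i] == 1L) "OCR" else "CCR"
        sim_one(i, state, derive_seed(seed, i))
      } else {
        fo <- sim_one(i, "OCR", derive_seed(seed, n_total + 2L * i))
        fc <- sim_one(i, "CCR", derive_seed(seed, n_total + 2L * i + 1L))
        simulate_pocr_features(fo, fc, tau = tau)
      }
    })
  })

  observed <- integer(n_total)
  binary <- true_class < 2L
  observed[binary] <- true_class[binary]
  fl <- flip_labels(observed[binary], noise_rate, seed = derive_seed(seed, 900001L))
  observed[binary] <- fl$labels
  observed[!binary] <- with_seed_or_not(derive_seed(seed, 900002L),
                                        sample(0:1, sum(!binary), replace = TRUE))
  flipped <- logical(n_total)
  flipped[binary] <- fl$flipped

  sds <- purrr::map(feats, summarize_std)
  out <- tibble::tibble(
    sample_id = seq_len(n_total),
    chrom = "sim",
    start = (seq_len(n_total) - 1L) * segment_bp,
    end = seq_len(n_total) * segment_bp,
    true_class = true_class,
    observed_label = observed,
    flipped = flipped,
    sd_wps = purrr::map_dbl(sds, "sd_wps"),
    sd_coverage = purrr::map_dbl(sds, "sd_coverage"),
    features = feats)
  structure(out, class = c("labeled_dataset", class(out)),
            noise_rate = noise_rate, tau = tau, params = params,
            segment_bp = as.integer(segment_bp),
            window_bp = as.integer(window_bp), seed = seed)
}

#' Write a fragment set as 3-column BED
#'
#' @param frags A `fragment_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(frags, path) {
  utils::write.table(frags[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
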
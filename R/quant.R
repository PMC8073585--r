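# Chromatographic peak detection, coelution gating, and stable-isotope
# dilution (light-to-heavy) quantification from extracted-ion chromatograms.

#' Read / write extracted-ion-chromatogram tables
#'
#' Long-format TSV with columns `sample_id`, `peptide`, `channel`
#' ("light"/"heavy"), `fragment`, `time_min`, `intensity`, and optionally
#' `replicate`.
#'
#' @param path TSV path.
#' @return Data frame of traces.
#' @export
read_xic <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "peptide", "channel", "fragment", "time_min",
            "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("XIC table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' @rdname read_xic
#' @param xic Data frame of traces.
#' @export
write_xic <- function(xic, path) {
  utils::write.table(xic, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.shared_grid <- function(traces) {
  # fragments usually share the acquisition grid; resample when they don't
  frags <- split(traces, traces$fragment)
  grids <- lapply(frags, function(f) f$time_min[order(f$time_min)])
  if (length(unique(vapply(grids, paste, character(1), collapse = ","))) == 1L) {
    grid <- grids[[1]]
    mat <- vapply(frags, function(f) f$intensity[order(f$time_min)],
                  numeric(length(grid)))
  } else {
    grid <- sort(unique(unlist(grids)))
    mat <- vapply(frags, function(f) {
      f <- f[order(f$time_min), ]
      stats::approx(f$time_min, f$intensity, xout = grid, rule = 2)$y
    }, numeric(length(grid)))
  }
  mat <- matrix(mat, nrow = length(grid),
                dimnames = list(NULL, names(frags)))
  list(time = grid, intensities = mat)
}

.moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  window <- min(window, length(x))
  sm <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]  # edges keep raw values
  sm
}

#' Detect the dominant chromatographic peak of one peptide/channel
#'
#' Sums the fragment traces, smooths the total with a moving average,
#' takes the global maximum as the apex provided it clears a
#' signal-to-noise threshold (noise estimated by the median absolute
#' deviation of the smoothed total), sets boundaries where the smoothed
#' total falls to a fraction of the apex height above baseline, and
#' integrates every fragment by the trapezoid rule over those boundaries.
#'
#' @param traces Data frame with columns `fragment`, `time_min`,
#'   `intensity` for a single peptide/channel (at least 5 points per
#'   fragment).
#' @param smooth_window Moving-average window in points (default 5).
#' @param snr_threshold Minimum (apex - baseline) / noise (default 5).
#' @param boundary_frac Fraction of apex height above baseline at which
#'   boundaries are placed (default 0.02).
#' @return A `peak_group` (list with `apex_time`, `boundaries`, `area`,
#'   `fragment_areas`, `apex_intensity`, `snr`) or `NULL` when no peak
#'   clears the threshold.
#' @export
detect_peak <- function(traces, smooth_window = 5L, snr_threshold = 5,
                        boundary_frac = 0.02) {
  if (nrow(traces) < 5L) stop("need at least 5 trace points", call. = FALSE)
  g <- .shared_grid(traces)
  total <- rowSums(g$intensities)
  if (all(total <= 0)) return(NULL)
  sm <- .moving_average(total, smooth_window)
  baseline <- stats::median(sm)
  noise <- stats::mad(sm)
  apex_idx <- which.max(sm)
  height <- sm[apex_idx] - baseline
  if (height <= 0) return(NULL)
  if (noise > 0 && height / noise < snr_threshold) return(NULL)
  if (noise == 0 && sm[apex_idx] <= 0) return(NULL)
  cutoff <- baseline + boundary_frac * height
  left <- apex_idx
  while (left > 1L && sm[left - 1L] > cutoff) left <- left - 1L
  right <- apex_idx
  n <- length(sm)
  while (right < n && sm[right + 1L] > cutoff) right <- right + 1L
  idx <- left:right
  frag_areas <- apply(g$intensities[idx, , drop = FALSE], 2, function(y)
    pracma::trapz(g$time[idx], y))
  structure(list(
    apex_time = g$time[apex_idx],
    boundaries = c(start = g$time[left], end = g$time[right]),
    area = sum(frag_areas),
    fragment_areas = frag_areas,
    apex_intensity = sm[apex_idx],
    snr = if (noise > 0) height / noise else Inf
  ), class = "peak_group")
}

#' Integrate fragment traces over fixed boundaries
#'
#' Trapezoid integration of each fragment between `boundaries`, used to
#' re-integrate the light channel over the heavy channel's boundaries.
#'
#' @inheritParams detect_peak
#' @param boundaries Length-2 numeric `(start, end)` in minutes.
#' @return Total area (sum over fragments).
#' @export
integrate_trace <- function(traces, boundaries) {
  g <- .shared_grid(traces)
  idx <- which(g$time >= boundaries[1] & g$time <= boundaries[2])
  if (length(idx) < 2L) return(0)
  sum(apply(g$intensities[idx, , drop = FALSE], 2, function(y)
    pracma::trapz(g$time[idx], y)))
}

#' Coelution criterion for a light/heavy peak pair
#'
#' A pair coelutes when the apex times differ by at most `apex_tolerance`
#' (closed boundary: a delta exactly at the tolerance passes) and the
#' boundary intervals overlap by at least `min_overlap` of the shorter
#' interval. A missing peak on either channel fails the criterion.
#'
#' @param light,heavy `peak_group` objects from [detect_peak()], or `NULL`.
#' @param apex_tolerance Maximum apex separation in minutes (default 0.1).
#' @param min_overlap Minimum overlap fraction of the shorter boundary
#'   interval (default 0.5).
#' @return List with `coelutes` (logical) and `apex_delta` (minutes,
#'   `NA` when a peak is missing).
#' @export
coelution_test <- function(light, heavy, apex_tolerance = 0.1,
                           min_overlap = 0.5) {
  if (is.null(light) || is.null(heavy))
    return(list(coelutes = FALSE, apex_delta = NA_real_))
  delta <- abs(light$apex_time - heavy$apex_time)
  ov <- min(light$boundaries[2], heavy$boundaries[2]) -
    max(light$boundaries[1], heavy$boundaries[1])
  shorter <- min(diff(light$boundaries), diff(heavy$boundaries))
  frac <- if (shorter > 0) max(ov, 0) / shorter else 0
  list(coelutes = delta <= apex_tolerance && frac >= min_overlap,
       apex_delta = unname(delta))
}

#' Light-to-heavy area ratio
#'
#' Endogenous (light) over SIL (heavy) peak area; with a fixed SIL spike,
#' higher ratios indicate higher endogenous peptide amounts.
#'
#' @param light,heavy `peak_group` objects.
#' @return Dimensionless ratio.
#' @export
light_heavy_ratio <- function(light, heavy) {
  if (is.null(light) || is.null(heavy))
    stop("both peaks must be present", call. = FALSE)
  if (heavy$area <= 0)
    stop("heavy (SIL) peak area is zero: spike missing, ratio undefined",
         call. = FALSE)
  light$area / heavy$area
}

#' Quantify all sample/peptide pairs of an XIC table
#'
#' For every sample/peptide: detect the heavy (SIL) peak, detect the light
#' peak, apply the coelution criterion, and — when it passes — compute the
#' light-to-heavy ratio with both channels integrated over the heavy
#' channel's boundaries (the SIL spike is uniform across samples, so its
#' boundaries are the more reliable ones). When a `replicate` column is
#' present, replicates are quantified separately and averaged at the ratio
#' level. Undetected peptides yield `NA` ratios, never zeros.
#'
#' @param xic Data frame from [read_xic()] or [simulate_xics()].
#' @inheritParams coelution_test
#' @inheritParams detect_peak
#' @return Data frame with one row per sample/peptide: `sample_id`,
#'   `peptide`, `coelutes`, `detected`, `light_to_heavy_ratio`,
#'   `apex_delta`.
#' @export
quantify_xics <- function(xic, apex_tolerance = 0.1, min_overlap = 0.5,
                          smooth_window = 5L, snr_threshold = 5,
                          boundary_frac = 0.02) {
  has_rep <- "replicate" %in% names(xic)
  rep_id <- if (has_rep) xic$replicate else 0L
  key <- interaction(xic$sample_id, rep_id, xic$peptide, drop = TRUE)
  per_run <- lapply(split(xic, key), function(d) {
    light <- d[d$channel == "light", , drop = FALSE]
    heavy <- d[d$channel == "heavy", , drop = FALSE]
    pk_h <- if (nrow(heavy)) detect_peak(heavy, smooth_window, snr_threshold,
                                         boundary_frac) else NULL
    pk_l <- if (nrow(light)) detect_peak(light, smooth_window, snr_threshold,
                                         boundary_frac) else NULL
    co <- coelution_test(pk_l, pk_h, apex_tolerance, min_overlap)
    detected <- co$coelutes && !is.null(pk_l)
    ratio <- NA_real_
    if (detected && !is.null(pk_h) && pk_h$area > 0) {
      light_area <- integrate_trace(light, pk_h$boundaries)
      ratio <- light_area / pk_h$area
    }
    data.frame(sample_id = d$sample_id[1], peptide = d$peptide[1],
               coelutes = co$coelutes, detected = detected,
               light_to_heavy_ratio = ratio, apex_delta = co$apex_delta,
               stringsAsFactors = FALSE)
  })
  runs <- do.call(rbind, c(per_run, list(make.row.names = FALSE)))
  if (!has_rep) return(runs[order(runs$sample_id, runs$peptide), ,
                            drop = FALSE])
  # average duplicates at the ratio level
  agg <- split(runs, interaction(runs$sample_id, runs$peptide, drop = TRUE))
  out <- do.call(rbind, lapply(agg, function(d) data.frame(
    sample_id = d$sample_id[1], peptide = d$peptide[1],
    coelutes = any(d$coelutes), detected = any(d$detected),
    light_to_heavy_ratio = if (any(d$detected))
      mean(d$light_to_heavy_ratio[d$detected]) else NA_real_,
    apex_delta = if (all(is.na(d$apex_delta))) NA_real_ else
      mean(d$apex_delta, na.rm = TRUE),
    stringsAsFactors = FALSE)))
  out[order(out$sample_id, out$peptide), , drop = FALSE]
}

#' Presence/absence calls per peptide and sample group
#'
#' A peptide is called present ("+") in a group when coelution-gated
#' detection succeeded in at least one sample of that group, absent ("-")
#' otherwise. Panel peptides never quantified still appear as "-" rows.
#'
#' @param results Quantification table from [quantify_xics()].
#' @param manifest Data frame mapping `sample_id` to `group`.
#' @param panel Optional [assay_panel()] (or character vector of peptides)
#'   fixing the row set and order.
#' @return Data frame with `peptide` and one "+"/"-" column per group.
#' @export
call_detection <- function(results, manifest, panel = NULL) {
  results$group <- manifest$group[match(results$sample_id,
                                        manifest$sample_id)]
  if (anyNA(results$group))
    stop("sample(s) missing from manifest: ",
         paste(unique(results$sample_id[is.na(results$group)]),
               collapse = ", "), call. = FALSE)
  peptides <- if (inherits(panel, "assay_panel"))
    vapply(panel$targets, function(t) t$light$sequence, character(1))
  else if (is.character(panel)) panel
  else unique(results$peptide)
  groups <- unique(manifest$group)
  out <- data.frame(peptide = peptides, stringsAsFactors = FALSE)
  for (g in groups)
    out[[g]] <- vapply(peptides, function(p) {
      hit <- results$detected[results$peptide == p & results$group == g]
      if (length(hit) && any(hit)) "+" else "-"
    }, character(1))
  out
}

#' Write a quantification or presence table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
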
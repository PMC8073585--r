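# Synthetic-data generation: proteomes with planted tryptic peptides and
# chromatographic (XIC) traces with known ground truth, so that digestion,
# uniqueness screening, quantification and statistics are all testable
# without external data.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a random proteome with planted tryptic peptides
#'
#' Emits random protein sequences in which the requested peptides are
#' planted with a tryptic context: an arginine is inserted before the
#' peptide and the residue following it is never proline, so that strict
#' tryptic digestion with no missed cleavages is guaranteed to release the
#' planted peptide intact. Planted peptides must end in K or R and must
#' not start with P.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Length-2 integer range of random sequence lengths
#'   (before insertions).
#' @param planted Optional data frame with columns `accession`, `peptide`;
#'   each peptide is inserted once into the named protein. Accessions are
#'   `SYN001`, `SYN002`, ... .
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return Data frame with `accession`, `description`, `sequence`
#'   (the [read_fasta()] layout).
#' @export
generate_proteome <- function(n_proteins, length_range = c(120L, 240L),
                              planted = NULL, seed = 1L) {
  alphabet <- names(aa_mass_table()$residue_mass)
  if (!is.null(planted)) {
    bad <- !grepl("[KR]$", planted$peptide)
    if (any(bad))
      stop("planted peptide(s) must end in K or R: ",
           paste(planted$peptide[bad], collapse = ", "), call. = FALSE)
    if (any(grepl("^P", planted$peptide)))
      stop("planted peptides must not start with proline", call. = FALSE)
  }
  .with_seed(seed, {
    accs <- sprintf("SYN%03d", seq_len(n_proteins))
    seqs <- vapply(seq_len(n_proteins), function(i) {
      len <- sample(length_range[1]:length_range[2], 1L)
      paste0(sample(alphabet, len, replace = TRUE), collapse = "")
    }, character(1))
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        idx <- match(planted$accession[i], accs)
        if (is.na(idx))
          stop("unknown accession in planted table: ", planted$accession[i],
               call. = FALSE)
        s <- seqs[idx]
        pep <- planted$peptide[i]
        if (nchar(pep) + 2L > nchar(s))
          stop(sprintf("planted peptide '%s' longer than protein %s",
                       pep, accs[idx]), call. = FALSE)
        at <- sample(seq_len(nchar(s) - 1L), 1L)
        left <- substr(s, 1L, at)
        right <- substr(s, at + 1L, nchar(s))
        if (substr(right, 1L, 1L) == "P")
          right <- paste0("A", substr(right, 2L, nchar(right)))
        seqs[idx] <- paste0(left, "R", pep, right)
      }
    }
    data.frame(accession = accs,
               description = sprintf("synthetic protein %d", seq_len(n_proteins)),
               sequence = seqs, stringsAsFactors = FALSE)
  })
}

#' Simulation configuration for synthetic XIC traces
#'
#' Bundles the ground-truth design of a multi-group chromatographic
#' simulation: co-eluting light/heavy Gaussian peak groups per
#' sample/peptide, with configurable true light-to-heavy ratio,
#' retention-time jitter, multiplicative lognormal amplitude noise,
#' Poisson baseline, and per-group peptide dropout.
#'
#' @param profile Data frame with columns `peptide`, `group`,
#'   `true_ratio`, `dropout`: the design matrix. A peptide/group pair
#'   absent from the profile is never emitted on the light channel
#'   (dropout 1).
#' @param samples_per_group Samples per group (default 15).
#' @param seed Integer seed.
#' @param peak_width_sec Gaussian peak sigma in seconds (default 4).
#' @param asymmetry Right-tail broadening factor; the right-hand sigma is
#'   `(1 + asymmetry)` times the left (default 0, symmetric).
#' @param noise_baseline Poisson baseline level in counts (default 20).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal amplitude noise per channel/fragment (default 0.05).
#' @param rt_jitter_sd Retention-time jitter standard deviation in
#'   minutes, shared by both channels of a peak group (default 0.02).
#' @param heavy_amplitude Apex amplitude of the SIL spike (default 1e5).
#' @param n_fragments Fragment traces per channel (default 3).
#' @param grid_step_min,window_min Acquisition grid spacing and window
#'   width in minutes.
#' @param rt_range Retention-time span over which peptides are spread.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(profile, samples_per_group = 15L, seed = 1L,
                              peak_width_sec = 4, asymmetry = 0,
                              noise_baseline = 20, noise_cv = 0.05,
                              rt_jitter_sd = 0.02, heavy_amplitude = 1e5,
                              n_fragments = 3L, grid_step_min = 0.012,
                              window_min = 0.72, rt_range = c(10, 45)) {
  stopifnot(all(c("peptide", "group", "true_ratio", "dropout") %in%
                  names(profile)))
  if (any(profile$dropout < 0 | profile$dropout > 1))
    stop("dropout probabilities must lie in [0, 1]", call. = FALSE)
  if (any(profile$true_ratio < 0))
    stop("true ratios must be >= 0", call. = FALSE)
  structure(list(profile = profile, samples_per_group = samples_per_group,
                 seed = seed, peak_width_sec = peak_width_sec,
                 asymmetry = asymmetry, noise_baseline = noise_baseline,
                 noise_cv = noise_cv, rt_jitter_sd = rt_jitter_sd,
                 heavy_amplitude = heavy_amplitude,
                 n_fragments = n_fragments, grid_step_min = grid_step_min,
                 window_min = window_min, rt_range = rt_range),
            class = "simulation_config")
}

.gauss_shape <- function(t, apex, sigma, asymmetry) {
  s <- ifelse(t <= apex, sigma, sigma * (1 + asymmetry))
  exp(-(t - apex)^2 / (2 * s^2))
}

#' Simulate extracted-ion chromatograms with known ground truth
#'
#' For every sample/peptide pair the heavy (SIL) channel is emitted at a
#' fixed spike amplitude and the light channel scaled by the true ratio;
#' both channels share one apex drawn with retention-time jitter. Each
#' fragment trace is a scaled copy of the peak shape with independent
#' multiplicative lognormal noise, on top of a Poisson baseline.
#' Dropped-out peptides emit a baseline-only light trace (the SIL spike
#' is still present).
#'
#' @param config A [simulation_config()].
#' @return List with `xic` (long-format trace table, see [read_xic()]),
#'   `truth` (per sample/peptide: `sample_id`, `group`, `peptide`,
#'   `true_ratio`, `true_apex`, `detectable`), and `manifest`
#'   (`sample_id`, `group`).
#' @export
simulate_xics <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  peptides <- unique(cfg$profile$peptide)
  groups <- unique(cfg$profile$group)
  base_rt <- stats::setNames(
    seq(cfg$rt_range[1], cfg$rt_range[2], length.out = length(peptides)),
    peptides)
  sigma <- cfg$peak_width_sec / 60
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  weights <- rev(seq_len(cfg$n_fragments))
  weights <- weights / sum(weights)
  frag_names <- paste0("y", seq_len(cfg$n_fragments) + 2L)

  .with_seed(cfg$seed, {
    xic <- list()
    truth <- list()
    for (g in groups) {
      for (s in seq_len(cfg$samples_per_group)) {
        sid <- sprintf("%s_%02d", g, s)
        for (pep in peptides) {
          row <- cfg$profile[cfg$profile$peptide == pep &
                               cfg$profile$group == g, , drop = FALSE]
          ratio <- if (nrow(row)) row$true_ratio[1] else 0
          dropout <- if (nrow(row)) row$dropout[1] else 1
          dropped <- ratio <= 0 || stats::runif(1) < dropout
          apex <- base_rt[[pep]] + stats::rnorm(1, 0, cfg$rt_jitter_sd)
          grid <- seq(base_rt[[pep]] - cfg$window_min / 2,
                      base_rt[[pep]] + cfg$window_min / 2,
                      by = cfg$grid_step_min)
          shape <- .gauss_shape(grid, apex, sigma, cfg$asymmetry)
          np <- length(grid)
          emit <- function(channel, amplitude, with_peak) {
            lapply(seq_len(cfg$n_fragments), function(f) {
              base <- if (cfg$noise_baseline > 0)
                stats::rpois(np, cfg$noise_baseline) else numeric(np)
              sig <- if (with_peak)
                amplitude * weights[f] *
                  exp(stats::rnorm(1, 0, sdlog)) * shape
              else numeric(np)
              data.frame(sample_id = sid, peptide = pep, channel = channel,
                         fragment = frag_names[f], time_min = grid,
                         intensity = sig + base, stringsAsFactors = FALSE)
            })
          }
          xic <- c(xic,
                   emit("heavy", cfg$heavy_amplitude, TRUE),
                   emit("light", cfg$heavy_amplitude * ratio, !dropped))
          truth[[length(truth) + 1L]] <- data.frame(
            sample_id = sid, group = g, peptide = pep, true_ratio = ratio,
            true_apex = apex, detectable = !dropped,
            stringsAsFactors = FALSE)
        }
      }
    }
    manifest <- unique(data.frame(
      sample_id = vapply(truth, function(t) t$sample_id, character(1)),
      group = vapply(truth, function(t) t$group, character(1)),
      stringsAsFactors = FALSE))
    list(xic = do.call(rbind, c(xic, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         manifest = manifest[order(manifest$sample_id), , drop = FALSE])
  })
}

#' Bundled reference fixture: panel, detection pattern, region profiles
#'
#' Assembles the package's worked-example fixture: the 18-target assay
#' panel, the reference presence/absence pattern for healthy versus
#' inflamed skin, and two simulation design matrices — a two-group
#' profile reproducing that detection pattern and a three-region profile
#' (GP: gland poor, SGR: sebaceous gland rich, AGR: apocrine gland rich)
#' qualitatively matching the regional biology: S100A8, LCN2, LACRT and
#' LYZ peptides elevated in SGR, dermcidin flat across regions, LACRT/LYZ
#' at the detection limit in AGR and LCN2/LYZ at the detection limit in
#' GP. "At the detection limit" is simulated as a low ratio with high
#' dropout, so rank statistics remain defined in sparsely detected
#' groups.
#'
#' @return List with `panel` ([assay_panel()]), `detection_reference`
#'   (data frame: gene, peptide, healthy, inflamed), `detection_profile`
#'   and `region_profile` (simulation design matrices).
#' @export
make_paper_fixture <- function() {
  panel <- table1_panel()
  ref_path <- system.file("extdata", "detection_reference.tsv",
                          package = "prmassay", mustWork = TRUE)
  detection <- utils::read.delim(ref_path, stringsAsFactors = FALSE,
                                 check.names = FALSE)
  det_profile <- do.call(rbind, lapply(seq_len(nrow(detection)), function(i)
    do.call(rbind, lapply(c("healthy", "inflamed"), function(g) data.frame(
      peptide = detection$peptide[i], group = g,
      true_ratio = if (detection[[g]][i] == "+") 1.5 else 0,
      dropout = if (detection[[g]][i] == "+") 0 else 1,
      stringsAsFactors = FALSE)))))

  hi <- 6.0    # elevated in SGR
  mid <- 1.0   # present
  low <- 0.15  # present in low amounts
  lim <- 0.08  # at the detection limit: low ratio, mostly dropped out
  rp <- function(peptide, gp, agr, sgr)
    data.frame(peptide = peptide,
               group = c("GP", "AGR", "SGR"),
               true_ratio = c(gp[1], agr[1], sgr[1]),
               dropout = c(gp[2], agr[2], sgr[2]),
               stringsAsFactors = FALSE)
  region <- rbind(
    rp("ALNSIIDVYHK",     c(lim, 0.6), c(mid, 0), c(hi, 0)),
    rp("GADVWFK",         c(low, 0.2), c(mid, 0), c(hi, 0)),
    rp("VPLQQNFQDNQFQGK", c(lim, 0.6), c(mid, 0), c(hi, 0)),
    rp("SILLTEQALAK",     c(low, 0.2), c(lim, 0.6), c(hi, 0)),
    rp("WESGYNTR",        c(lim, 0.6), c(lim, 0.6), c(hi, 0)),
    rp("ENAGEDPGLAR",     c(mid, 0),   c(mid, 0),  c(mid, 0))
  )
  list(panel = panel, detection_reference = detection,
       detection_profile = det_profile, region_profile = region)
}

#' Ready-made simulation configurations for the bundled fixture
#'
#' `fixture_detection_config` emulates the two-condition (healthy versus
#' inflamed) method-development experiment; `fixture_region_config`
#' emulates the three-region comparison with 15 samples per region.
#'
#' @param seed Integer seed.
#' @param samples_per_group Samples per group.
#' @return A [simulation_config()].
#' @export
fixture_detection_config <- function(seed = 1L, samples_per_group = 4L) {
  fx <- make_paper_fixture()
  simulation_config(fx$detection_profile,
                    samples_per_group = samples_per_group, seed = seed)
}

#' @rdname fixture_detection_config
#' @export
fixture_region_config <- function(seed = 1L, samples_per_group = 15L) {
  fx <- make_paper_fixture()
  simulation_config(fx$region_profile,
                    samples_per_group = samples_per_group, seed = seed)
}
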
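# Monoisotopic mass and m/z arithmetic for tryptic peptide ions.

.pkg_cache <- new.env(parent = emptyenv())

#' Monoisotopic amino acid mass table
#'
#' Returns the residue monoisotopic masses used throughout the package,
#' together with the mass of water (added once per peptide) and of a proton
#' (added once per charge). Residue masses are loaded from a versioned data
#' file bundled with the package.
#'
#' @return A list with components `residue_mass` (named numeric vector over
#'   the 20 standard one-letter codes, in Da), `water_mass` and `proton_mass`
#'   (both Da).
#' @examples
#' tab <- aa_mass_table()
#' tab$residue_mass[["G"]]
#' @export
aa_mass_table <- function() {
  if (is.null(.pkg_cache$aa_table)) {
    path <- system.file("extdata", "aa_monoisotopic.csv", package = "prmassay",
                        mustWork = TRUE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    masses <- stats::setNames(df$monoisotopic_mass, df$code)
    .pkg_cache$aa_table <- list(
      residue_mass = masses,
      water_mass = 18.010565,
      proton_mass = 1.007276
    )
  }
  .pkg_cache$aa_table
}

# Fixed / label modification deltas (Da)
CARBAMIDOMETHYL_DELTA <- 57.021464
SIL_LYS_DELTA <- 8.014199   # 13C6 15N2 lysine
SIL_ARG_DELTA <- 10.008269  # 13C6 15N4 arginine

#' Peptide modification descriptor
#'
#' @param name Modification name.
#' @param target_rule One-letter residue code the modification attaches to.
#' @param delta_mass Monoisotopic mass shift in Da.
#' @param fixed Logical; `TRUE` for fixed modifications applied to every
#'   matching residue.
#' @return An object of class `modification`.
#' @export
modification <- function(name, target_rule, delta_mass, fixed = FALSE) {
  stopifnot(is.character(name), is.character(target_rule),
            is.numeric(delta_mass))
  structure(list(name = name, target_rule = target_rule,
                 delta_mass = delta_mass, fixed = fixed),
            class = "modification")
}

#' @rdname modification
#' @export
mod_carbamidomethyl <- function() {
  modification("carbamidomethyl", "C", CARBAMIDOMETHYL_DELTA, fixed = TRUE)
}

#' @rdname modification
#' @export
mod_sil_lys <- function() modification("sil_lys", "K", SIL_LYS_DELTA)

#' @rdname modification
#' @export
mod_sil_arg <- function() modification("sil_arg", "R", SIL_ARG_DELTA)

.check_sequence <- function(sequence, table = aa_mass_table()) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("peptide sequence must be a single non-empty string", call. = FALSE)
  residues <- strsplit(sequence, "")[[1]]
  bad <- which(!residues %in% names(table$residue_mass))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d in '%s'",
                 residues[bad[1]], bad[1], sequence), call. = FALSE)
  residues
}

#' Construct a peptide ion
#'
#' A peptide ion is a residue sequence with positioned modifications and a
#' charge state. Under the default fixed-modification policy every cysteine
#' carries carbamidomethyl (+57.021464 Da), matching iodoacetamide
#' alkylation. Heavy (stable-isotope-labelled, SIL) ions carry exactly one
#' label on the C-terminal lysine (+8.014199 Da) or arginine (+10.008269 Da).
#'
#' @param sequence Peptide sequence, uppercase one-letter codes.
#' @param charge Positive integer precursor charge.
#' @param is_heavy Logical; `TRUE` places a SIL label on the C-terminal K/R.
#' @param fixed_cys_cam Apply carbamidomethyl to every cysteine (default).
#' @return An object of class `peptide_ion` with fields `sequence`,
#'   `modifications` (data frame of position/name/delta_mass), `charge`,
#'   `is_heavy`.
#' @examples
#' peptide_ion("GADVWFK", charge = 2)
#' peptide_ion("GADVWFK", charge = 2, is_heavy = TRUE)
#' @export
peptide_ion <- function(sequence, charge = 2L, is_heavy = FALSE,
                        fixed_cys_cam = TRUE) {
  sequence <- unname(sequence)
  residues <- .check_sequence(sequence)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L)
    stop("charge must be a positive integer", call. = FALSE)
  mods <- data.frame(position = integer(0), name = character(0),
                     delta_mass = numeric(0), stringsAsFactors = FALSE)
  if (fixed_cys_cam) {
    cys <- which(residues == "C")
    if (length(cys))
      mods <- rbind(mods, data.frame(position = cys, name = "carbamidomethyl",
                                     delta_mass = CARBAMIDOMETHYL_DELTA))
  }
  n <- length(residues)
  if (is_heavy) {
    term <- residues[n]
    if (term == "K") {
      mods <- rbind(mods, data.frame(position = n, name = "sil_lys",
                                     delta_mass = SIL_LYS_DELTA))
    } else if (term == "R") {
      mods <- rbind(mods, data.frame(position = n, name = "sil_arg",
                                     delta_mass = SIL_ARG_DELTA))
    } else {
      stop(sprintf("non-tryptic terminus '%s': SIL label requires C-terminal K or R",
                   term), call. = FALSE)
    }
  }
  structure(list(sequence = sequence, modifications = mods,
                 charge = charge, is_heavy = is_heavy),
            class = "peptide_ion")
}

#' @export
print.peptide_ion <- function(x, ...) {
  cat(sprintf("<peptide_ion> %s %d+ (%s)\n", modified_sequence(x), x$charge,
              if (x$is_heavy) "heavy" else "light"))
  invisible(x)
}

#' Monoisotopic mass of a peptide ion
#'
#' Sum of residue monoisotopic masses plus one water plus all modification
#' deltas; the charge does not enter the neutral mass.
#'
#' @param ion A [peptide_ion()].
#' @param table An [aa_mass_table()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_monoisotopic_mass(peptide_ion("GADVWFK")) # 821.4072
#' @export
peptide_monoisotopic_mass <- function(ion, table = aa_mass_table()) {
  stopifnot(inherits(ion, "peptide_ion"))
  residues <- .check_sequence(ion$sequence, table)
  sum(table$residue_mass[residues]) + table$water_mass +
    sum(ion$modifications$delta_mass)
}

#' Precursor m/z of a peptide ion
#'
#' `(M + z * proton) / z` with monoisotopic neutral mass M.
#'
#' @inheritParams peptide_monoisotopic_mass
#' @return Precursor m/z in Thomson.
#' @examples
#' precursor_mz(peptide_ion("GADVWFK", charge = 2)) # 411.711
#' @export
precursor_mz <- function(ion, table = aa_mass_table()) {
  stopifnot(inherits(ion, "peptide_ion"))
  if (ion$charge < 1L) stop("charge must be >= 1", call. = FALSE)
  m <- peptide_monoisotopic_mass(ion, table)
  (m + ion$charge * table$proton_mass) / ion$charge
}

#' Stable-isotope-labelled counterpart of a light peptide ion
#'
#' Returns the identical ion flagged heavy, with the SIL label on the
#' C-terminal lysine or arginine. The precursor m/z shift equals the label
#' delta divided by the charge.
#'
#' @param ion A light [peptide_ion()] ending in K or R.
#' @return The heavy `peptide_ion`.
#' @examples
#' precursor_mz(sil_counterpart(peptide_ion("GADVWFK", 2))) # 415.718
#' @export
sil_counterpart <- function(ion) {
  stopifnot(inherits(ion, "peptide_ion"))
  if (ion$is_heavy) stop("ion is already heavy", call. = FALSE)
  has_cam <- any(ion$modifications$name == "carbamidomethyl")
  peptide_ion(ion$sequence, charge = ion$charge, is_heavy = TRUE,
              fixed_cys_cam = has_cam || !grepl("C", ion$sequence, fixed = TRUE))
}

#' Singly charged b/y fragment ion series
#'
#' Computes singly protonated b- and y-ion m/z for fragment lengths 1 to
#' n-1, assigning each modification delta to the fragment containing the
#' modified residue, and drops entries outside the analyzer scan range.
#'
#' @inheritParams peptide_monoisotopic_mass
#' @param scan_min,scan_max Scan range bounds in m/z (default 114-1000,
#'   the targeted-MS2 fragment range).
#' @return Data frame with columns `label` ("b3", "y7" style), `series`,
#'   `index`, `mz`, ordered b1..b(n-1), y1..y(n-1) before range filtering.
#' @examples
#' fragment_mz_series(peptide_ion("GADVWFK", 2))
#' @export
fragment_mz_series <- function(ion, table = aa_mass_table(),
                               scan_min = 114, scan_max = 1000) {
  stopifnot(inherits(ion, "peptide_ion"))
  if (scan_min >= scan_max) stop("scan_min must be < scan_max", call. = FALSE)
  residues <- .check_sequence(ion$sequence, table)
  n <- length(residues)
  res_mass <- unname(table$residue_mass[residues])
  for (i in seq_len(nrow(ion$modifications)))
    res_mass[ion$modifications$position[i]] <-
      res_mass[ion$modifications$position[i]] + ion$modifications$delta_mass[i]
  if (n < 2L)
    return(data.frame(label = character(0), series = character(0),
                      index = integer(0), mz = numeric(0)))
  prefix <- cumsum(res_mass)
  idx <- seq_len(n - 1L)
  # b_i: sum of first i residues + proton; y_i: sum of last i residues + water + proton
  b_mz <- prefix[idx] + table$proton_mass
  y_mz <- (prefix[n] - prefix[n - idx]) + table$water_mass + table$proton_mass
  out <- data.frame(
    label = c(paste0("b", idx), paste0("y", idx)),
    series = rep(c("b", "y"), each = n - 1L),
    index = c(idx, idx),
    mz = c(b_mz, y_mz),
    stringsAsFactors = FALSE
  )
  out[out$mz >= scan_min & out$mz <= scan_max, , drop = FALSE]
}

#' Bracket-notation modified sequence
#'
#' Renders a peptide ion as e.g. `IQGTC[+57.0]YR` or `GADVWFK[+8.0]`,
#' the unambiguous Skyline-ingestible notation used in exported lists.
#'
#' @inheritParams peptide_monoisotopic_mass
#' @return Single string.
#' @export
modified_sequence <- function(ion) {
  stopifnot(inherits(ion, "peptide_ion"))
  residues <- strsplit(ion$sequence, "")[[1]]
  if (nrow(ion$modifications)) {
    mods <- ion$modifications[order(ion$modifications$position), , drop = FALSE]
    agg <- tapply(mods$delta_mass, mods$position, sum)
    for (pos_chr in names(agg)) {
      pos <- as.integer(pos_chr)
      residues[pos] <- sprintf("%s[%+.1f]", residues[pos], agg[[pos_chr]])
    }
  }
  paste0(residues, collapse = "")
}
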
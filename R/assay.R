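# Assembly of the light/heavy PRM target panel and transition-list export.

#' Construct a PRM peptide target
#'
#' A target couples a light peptide ion with its SIL heavy counterpart and
#' the fragment transitions monitored for both channels.
#'
#' @param sequence Peptide sequence.
#' @param charge Precursor charge.
#' @param protein_gene,protein_name,accession Parent protein annotation.
#' @param scan_range Length-2 numeric, fragment m/z window.
#' @param fragment_series Which singly charged series to monitor
#'   (default `"y"`; `c("b", "y")` to monitor both).
#' @return Object of class `peptide_target` with fields `protein_gene`,
#'   `protein_name`, `accession`, `light`, `heavy` (both [peptide_ion()]),
#'   and `transitions` (data frame: channel, label, mz).
#' @export
peptide_target <- function(sequence, charge = 2L, protein_gene = NA_character_,
                           protein_name = NA_character_,
                           accession = NA_character_,
                           scan_range = c(114, 1000),
                           fragment_series = "y") {
  light <- peptide_ion(sequence, charge = charge)
  heavy <- sil_counterpart(light)
  frag <- function(ion, channel) {
    fr <- fragment_mz_series(ion, scan_min = scan_range[1],
                             scan_max = scan_range[2])
    fr <- fr[fr$series %in% fragment_series, , drop = FALSE]
    if (!nrow(fr))
      return(data.frame(channel = character(0), label = character(0),
                        series = character(0), index = integer(0),
                        mz = numeric(0)))
    cbind(channel = channel, fr, row.names = NULL)
  }
  transitions <- rbind(frag(light, "light"), frag(heavy, "heavy"))
  structure(list(protein_gene = protein_gene, protein_name = protein_name,
                 accession = accession, light = light, heavy = heavy,
                 transitions = transitions),
            class = "peptide_target")
}

#' Construct an assay panel
#'
#' @param targets List of [peptide_target()] objects.
#' @param scan_range Fragment m/z window (default `c(114, 1000)`).
#' @param collision_energy Normalized collision energy in percent
#'   (default 30).
#' @param audit Optional data frame recording why each candidate peptide
#'   was kept or dropped during panel building.
#' @return Object of class `assay_panel`.
#' @export
assay_panel <- function(targets, scan_range = c(114, 1000),
                        collision_energy = 30, audit = NULL) {
  keys <- vapply(targets, function(t)
    paste(t$light$sequence, t$light$charge, sep = "/"), character(1))
  if (anyDuplicated(keys))
    stop(sprintf("duplicate target(s) in panel: %s",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")),
         call. = FALSE)
  structure(list(targets = targets, scan_range = scan_range,
                 collision_energy = collision_energy, audit = audit),
            class = "assay_panel")
}

#' @export
print.assay_panel <- function(x, ...) {
  cat(sprintf("<assay_panel> %d targets, scan range %g-%g m/z, NCE %g%%\n",
              length(x$targets), x$scan_range[1], x$scan_range[2],
              x$collision_energy))
  invisible(x)
}

#' Summarise an assay panel as a data frame
#'
#' @param x An [assay_panel()].
#' @param ... Unused.
#' @return One row per target: gene, protein name, accession, peptide,
#'   charge, light and heavy precursor m/z, number of transitions.
#' @export
as.data.frame.assay_panel <- function(x, ...) {
  do.call(rbind, lapply(x$targets, function(t) data.frame(
    gene = t$protein_gene, protein_name = t$protein_name,
    accession = t$accession, peptide = t$light$sequence,
    charge = t$light$charge,
    mz_light = precursor_mz(t$light), mz_heavy = precursor_mz(t$heavy),
    n_transitions = nrow(t$transitions),
    stringsAsFactors = FALSE)))
}

#' Build a PRM panel from protein sequences
#'
#' End-to-end assay design: tryptic digestion, length and cleavage
#' probability filtering, uniqueness screening against a background
#' proteome, SIL pairing and fragment generation. An audit trail records
#' the fate of every candidate. Explicitly requested peptides (overrides)
#' bypass the filters but are still screened and are flagged in the audit
#' when they violate the length window.
#'
#' @param proteins Data frame of target proteins (see [read_fasta()]), or
#'   a FASTA path.
#' @param background Data frame or FASTA path of the background proteome
#'   used for the uniqueness screen; an empty data frame makes the screen
#'   vacuous. Defaults to the target proteins themselves.
#' @param overrides Optional data frame pinning targets explicitly:
#'   columns `peptide`, `charge`, and optionally `gene`, `protein_name`,
#'   `accession`.
#' @param min_len,max_len Peptide length window (defaults 5 and 14).
#' @param max_missed Missed cleavages allowed (default 0).
#' @param rule_model Cleavage model, see [score_cleavage_sites()].
#' @param probability_threshold Minimum cleavage probability (default 1.0).
#' @param equate_ile_leu I/L equivalence in the uniqueness screen.
#' @param default_charge Charge assigned to peptides not listed in
#'   `overrides` (default 2).
#' @param scan_range,collision_energy Panel acquisition settings.
#' @return An [assay_panel()]; its `audit` field lists every candidate
#'   with a `kept` flag and `reason`.
#' @export
build_panel <- function(proteins, background = proteins, overrides = NULL,
                        min_len = 5L, max_len = 14L, max_missed = 0L,
                        rule_model = c("strict", "keil"),
                        probability_threshold = 1.0, equate_ile_leu = TRUE,
                        default_charge = 2L, scan_range = c(114, 1000),
                        collision_energy = 30) {
  rule_model <- match.arg(rule_model)
  if (is.character(proteins)) proteins <- read_fasta(proteins)
  if (is.character(background)) background <- read_fasta(background)

  digests <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i)
    digest_protein(proteins[i, , drop = FALSE], max_missed = max_missed,
                   rule_model = rule_model,
                   probability_threshold = probability_threshold)))
  kept <- filter_peptides(digests, min_len, max_len, probability_threshold)

  audit <- data.frame(peptide = digests$sequence,
                      accession = digests$parent_accession,
                      kept = FALSE, reason = "", stringsAsFactors = FALSE)
  in_len <- nchar(digests$sequence) >= min_len &
    nchar(digests$sequence) <= max_len
  full_prob <- digests$min_boundary_probability >= probability_threshold
  audit$reason[!in_len] <- sprintf("length outside %d-%d", min_len, max_len)
  audit$reason[in_len & !full_prob] <- "boundary cleavage probability below threshold"

  verdicts <- if (nrow(kept))
    screen_uniqueness(kept, background, equate_ile_leu) else NULL
  selected <- character(0)
  if (!is.null(verdicts)) {
    for (i in seq_len(nrow(verdicts))) {
      idx <- which(audit$peptide == verdicts$peptide[i] &
                     audit$accession == verdicts$parent_accession[i])
      if (verdicts$is_unique[i]) {
        audit$kept[idx] <- TRUE
        audit$reason[idx] <- "unique tryptic peptide"
      } else {
        audit$reason[idx] <- sprintf("shared with %s",
                                     verdicts$hit_accessions[i])
      }
    }
    selected <- verdicts$peptide[verdicts$is_unique]
    names(selected) <- verdicts$parent_accession[verdicts$is_unique]
    # a SIL counterpart needs a labelled C-terminal K/R: the protein's
    # C-terminal segment is not pairable and leaves the panel
    tryptic_end <- grepl("[KR]$", selected)
    if (any(!tryptic_end)) {
      for (pep in selected[!tryptic_end]) {
        idx <- which(audit$peptide == pep)
        audit$kept[idx] <- FALSE
        audit$reason[idx] <- "non-tryptic terminus: no SIL counterpart"
      }
      selected <- selected[tryptic_end]
    }
  }

  # explicit overrides: pinned regardless of filters, flagged when unusual
  pinned <- NULL
  if (!is.null(overrides)) {
    pinned <- overrides
    if (is.null(pinned$charge)) pinned$charge <- default_charge
    for (col in c("gene", "protein_name", "accession"))
      if (is.null(pinned[[col]])) pinned[[col]] <- NA_character_
    bad_len <- nchar(pinned$peptide) < min_len | nchar(pinned$peptide) > max_len
    note <- ifelse(bad_len,
                   sprintf("pinned override (length %d violates %d-%d window)",
                           nchar(pinned$peptide), min_len, max_len),
                   "pinned override")
    audit <- rbind(audit, data.frame(peptide = pinned$peptide,
                                     accession = pinned$accession,
                                     kept = TRUE, reason = note))
    selected <- selected[!selected %in% pinned$peptide]
  }

  targets <- list()
  meta <- stats::setNames(proteins$description, proteins$accession)
  for (i in seq_along(selected)) {
    acc <- names(selected)[i]
    targets[[length(targets) + 1L]] <- peptide_target(
      selected[i], charge = default_charge,
      protein_name = if (!is.na(acc) && acc %in% names(meta)) meta[[acc]] else NA_character_,
      accession = acc, scan_range = scan_range)
  }
  if (!is.null(pinned))
    for (i in seq_len(nrow(pinned)))
      targets[[length(targets) + 1L]] <- peptide_target(
        pinned$peptide[i], charge = pinned$charge[i],
        protein_gene = pinned$gene[i], protein_name = pinned$protein_name[i],
        accession = pinned$accession[i], scan_range = scan_range)

  no_pep <- setdiff(proteins$accession,
                    unique(audit$accession[audit$kept]))
  if (length(no_pep))
    warning(sprintf("no surviving peptide for: %s",
                    paste(no_pep, collapse = ", ")))
  assay_panel(targets, scan_range = scan_range,
              collision_energy = collision_energy, audit = audit)
}

#' Reference PRM target table for skin antimicrobial peptides
#'
#' The bundled 18-peptide panel of protein-specific tryptic peptides for
#' 13 skin antimicrobial/immunomodulatory proteins (S100A8, S100A9,
#' cathelicidin, dermcidin, beta-defensins 1-4, lacritin, lipocalin-2,
#' lysozyme, psoriasin, TSLP), with charge states and reference precursor
#' m/z for the light and SIL heavy channel of each target.
#'
#' @return Data frame with columns `gene`, `protein_name`, `accession`,
#'   `peptide`, `charge`, `mz_light`, `mz_heavy`.
#' @export
table1_reference <- function() {
  path <- system.file("extdata", "panel_table1.csv", package = "prmassay",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' The bundled skin-AMP assay panel
#'
#' Builds the full [assay_panel()] for the 18 reference targets of
#' [table1_reference()], recomputing all masses from the sequences.
#'
#' @inheritParams peptide_target
#' @return An [assay_panel()] with 18 targets.
#' @export
table1_panel <- function(scan_range = c(114, 1000), fragment_series = "y") {
  ref <- table1_reference()
  targets <- lapply(seq_len(nrow(ref)), function(i)
    peptide_target(ref$peptide[i], charge = ref$charge[i],
                   protein_gene = ref$gene[i],
                   protein_name = ref$protein_name[i],
                   accession = ref$accession[i], scan_range = scan_range,
                   fragment_series = fragment_series))
  assay_panel(targets, scan_range = scan_range)
}

#' Export a transition list
#'
#' Writes one row per monitored transition with deterministic ordering
#' (protein, peptide, channel, fragment index). The `skyline` dialect uses
#' Skyline import headers; `generic` uses snake_case ones.
#'
#' @param panel An [assay_panel()].
#' @param path Output CSV path.
#' @param dialect `"generic"` or `"skyline"`.
#' @return The exported data frame, invisibly.
#' @export
export_transition_list <- function(panel, path,
                                   dialect = c("generic", "skyline")) {
  dialect <- match.arg(dialect)
  rows <- do.call(rbind, lapply(panel$targets, function(t) {
    tr <- t$transitions
    ion <- list(light = t$light, heavy = t$heavy)
    data.frame(protein = t$protein_gene, accession = t$accession,
               peptide = t$light$sequence,
               modified_sequence = unname(vapply(tr$channel, function(ch)
                 modified_sequence(ion[[ch]]), character(1))),
               precursor_mz = unname(vapply(tr$channel, function(ch)
                 precursor_mz(ion[[ch]]), numeric(1))),
               precursor_charge = t$light$charge,
               channel = tr$channel, fragment = tr$label,
               fragment_mz = tr$mz, stringsAsFactors = FALSE)
  }))
  frag_idx <- as.integer(sub("^[by]", "", rows$fragment))
  rows <- rows[order(rows$protein, rows$peptide, rows$channel, frag_idx), ,
               drop = FALSE]
  if (dialect == "skyline")
    names(rows) <- c("Protein Name", "Accession", "Peptide Sequence",
                     "Peptide Modified Sequence", "Precursor Mz",
                     "Precursor Charge", "Label Type", "Fragment Ion",
                     "Product Mz")
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}

#' Write / read an assay panel as YAML
#'
#' Round-trippable serialization of a panel's targets and settings.
#'
#' @param panel An [assay_panel()].
#' @param path YAML file path.
#' @return `write_panel_yaml` returns `path` invisibly; `read_panel_yaml`
#'   returns the reconstructed [assay_panel()].
#' @export
write_panel_yaml <- function(panel, path) {
  obj <- list(
    scan_range = panel$scan_range,
    collision_energy = panel$collision_energy,
    targets = lapply(panel$targets, function(t) list(
      gene = t$protein_gene, protein_name = t$protein_name,
      accession = t$accession, peptide = t$light$sequence,
      charge = t$light$charge))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_panel_yaml
#' @export
read_panel_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  targets <- lapply(obj$targets, function(t)
    peptide_target(t$peptide, charge = t$charge, protein_gene = t$gene,
                   protein_name = t$protein_name, accession = t$accession,
                   scan_range = unlist(obj$scan_range)))
  assay_panel(targets, scan_range = unlist(obj$scan_range),
              collision_energy = obj$collision_energy)
}
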
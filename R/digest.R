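# In-silico trypsin digestion with per-site cleavage-probability scoring.

#' Read protein records from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] and parses UniProt-style headers
#' (`db|ACCESSION|NAME description`), taking the accession from the second
#' pipe field when present, otherwise the first whitespace-delimited token.
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns `accession`, `description`, `sequence`.
#'   Sequences are uppercased; residues outside the 20-letter alphabet are
#'   flagged with a warning.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  first_tok <- sub("\\s.*$", "", headers)
  accession <- ifelse(grepl("\\|", first_tok),
                      vapply(strsplit(first_tok, "\\|"), function(p)
                        if (length(p) >= 2) p[2] else p[1], character(1)),
                      first_tok)
  description <- sub("^\\S+\\s*", "", headers)
  sequence <- toupper(as.character(set))
  std <- paste(names(aa_mass_table()$residue_mass), collapse = "")
  nonstd <- grepl(sprintf("[^%s]", std), sequence)
  if (any(nonstd))
    warning(sprintf("%d record(s) contain non-standard residues: %s",
                    sum(nonstd), paste(accession[nonstd], collapse = ", ")))
  data.frame(accession = accession, description = description,
             sequence = sequence, stringsAsFactors = FALSE, row.names = NULL)
}

#' Write protein records to a FASTA file
#'
#' @param proteins Data frame as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- ifelse(nzchar(proteins$description),
                       paste(proteins$accession, proteins$description),
                       proteins$accession)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

.keil_rules <- function() {
  if (is.null(.pkg_cache$keil)) {
    path <- system.file("extdata", "trypsin_cleavage_rules.csv",
                        package = "prmassay", mustWork = TRUE)
    .pkg_cache$keil <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .pkg_cache$keil
}

#' Score tryptic cleavage sites
#'
#' Assigns a cleavage probability to every K/R position of a protein.
#' Positions are 1-based indices of the K/R residue; cleavage occurs after
#' that residue. Two rule models are available:
#' \describe{
#'   \item{strict}{probability 1.0 after every K/R not followed by proline,
#'     0.0 when P sits at P1' (the classic no-P convention).}
#'   \item{keil}{probability looked up in a bundled context table keyed on
#'     the residues at P2, P1 and P1', encoding the proline block, its
#'     WKP/MRP rescues and acidic/basic context damping; the first matching
#'     specific rule wins, default 1.0.}
#' }
#'
#' @param sequence Protein sequence string, or a one-row data frame with a
#'   `sequence` column.
#' @param rule_model `"strict"` (default) or `"keil"`.
#' @return Data frame with columns `position` (1-based index of the K/R
#'   after which cleavage occurs) and `probability` in \[0, 1\].
#' @examples
#' score_cleavage_sites("AAKAAR")
#' score_cleavage_sites("AAKPAA")  # proline-blocked site
#' @export
score_cleavage_sites <- function(sequence, rule_model = c("strict", "keil")) {
  rule_model <- match.arg(rule_model)
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  residues <- strsplit(toupper(sequence), "")[[1]]
  n <- length(residues)
  pos <- which(residues %in% c("K", "R"))
  if (!length(pos))
    return(data.frame(position = integer(0), probability = numeric(0)))
  p1 <- residues[pos]
  # a C-terminal K/R is a trivially free site (no P1' context)
  p1prime <- ifelse(pos < n, residues[pmin(pos + 1L, n)], ".")
  p2 <- ifelse(pos > 1L, residues[pmax(pos - 1L, 1L)], ".")
  if (rule_model == "strict") {
    prob <- ifelse(p1prime == "P", 0, 1)
  } else {
    rules <- .keil_rules()
    prob <- vapply(seq_along(pos), function(i) {
      hit <- (rules$p1 == p1[i]) &
        (rules$p2 == "." | rules$p2 == p2[i]) &
        (rules$p1prime == "." | rules$p1prime == p1prime[i])
      rules$probability[which(hit)[1]]
    }, numeric(1))
  }
  data.frame(position = pos, probability = prob)
}

#' Digest a protein in silico with trypsin
#'
#' Cuts after every site whose cleavage probability reaches
#' `probability_threshold` and emits all products with up to `max_missed`
#' retained internal sites. Each peptide records its 1-based inclusive
#' coordinates in the parent, its missed-cleavage count, and the minimum
#' boundary-site probability (1.0 for the protein termini).
#'
#' @param protein One-row data frame with `accession` and `sequence`
#'   columns (see [read_fasta()]), or a plain sequence string.
#' @param max_missed Maximum missed cleavages (default 0).
#' @param rule_model Passed to [score_cleavage_sites()].
#' @param probability_threshold Minimum site probability for a cut
#'   (default 1.0).
#' @return Data frame with columns `sequence`, `parent_accession`, `start`,
#'   `end`, `missed_cleavages`, `min_boundary_probability`.
#' @examples
#' digest_protein("AAKAAR")                 # AAK, AAR
#' digest_protein("AAKAAR", max_missed = 1) # adds AAKAAR
#' @export
digest_protein <- function(protein, max_missed = 0L,
                           rule_model = c("strict", "keil"),
                           probability_threshold = 1.0) {
  rule_model <- match.arg(rule_model)
  if (max_missed < 0L) stop("max_missed must be >= 0", call. = FALSE)
  if (probability_threshold < 0 || probability_threshold > 1)
    stop("probability_threshold must lie in [0, 1]", call. = FALSE)
  if (is.character(protein))
    protein <- data.frame(accession = NA_character_, sequence = protein)
  seq <- toupper(protein$sequence[1])
  acc <- protein$accession[1]
  empty <- data.frame(sequence = character(0), parent_accession = character(0),
                      start = integer(0), end = integer(0),
                      missed_cleavages = integer(0),
                      min_boundary_probability = numeric(0))
  if (!nzchar(seq) || is.na(seq)) return(empty)
  n <- nchar(seq)
  sites <- score_cleavage_sites(seq, rule_model)
  ok <- sites$probability >= probability_threshold & sites$position < n
  cut_after <- sites$position[ok]
  cut_prob <- sites$probability[ok]
  # boundaries: cut points plus the two termini (termini carry probability 1)
  bounds <- c(0L, cut_after, n)
  probs <- c(1, cut_prob, 1)
  k <- length(bounds)
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):min(k, i + 1L + max_missed)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(seq, bounds[i] + 1L, bounds[j]),
        parent_accession = acc,
        start = bounds[i] + 1L,
        end = bounds[j],
        missed_cleavages = j - i - 1L,
        min_boundary_probability = min(probs[i], probs[j])
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Filter digest peptides by length and boundary probability
#'
#' Keeps peptides whose length lies in `[min_len, max_len]` and whose
#' minimum boundary-site probability reaches `probability_threshold`
#' (the fully tryptic, "100 percent cleavage probability" screen).
#' Input order is preserved.
#'
#' @param peptides Data frame from [digest_protein()].
#' @param min_len,max_len Inclusive length bounds (defaults 5 and 14).
#' @param probability_threshold Minimum `min_boundary_probability`.
#' @return Filtered data frame.
#' @export
filter_peptides <- function(peptides, min_len = 5L, max_len = 14L,
                            probability_threshold = 1.0) {
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  len <- nchar(peptides$sequence)
  keep <- len >= min_len & len <= max_len &
    peptides$min_boundary_probability >= probability_threshold
  peptides[keep, , drop = FALSE]
}
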
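# Proteotypic (protein-specific) peptide screening against a background
# proteome by exact substring search, optionally equating Ile and Leu.

#' Screen digest peptides for protein specificity
#'
#' Searches each peptide as an exact substring of every background proteome
#' sequence. A peptide is unique when all of its hits fall on its declared
#' parent accession. Because mass spectrometry cannot distinguish
#' isoleucine from leucine, the two are equated by default before matching.
#'
#' @param peptides Data frame with columns `sequence` and
#'   `parent_accession` (see [digest_protein()]).
#' @param proteome Data frame with columns `accession` and `sequence`
#'   (see [read_fasta()]). May be empty, in which case every peptide is
#'   vacuously unique.
#' @param equate_ile_leu Treat I and L as identical (default `TRUE`).
#' @return Data frame with one row per input peptide: `peptide`,
#'   `parent_accession`, `is_unique`, `hit_accessions` (comma-separated),
#'   `n_hits`, `ile_leu_equivalent`.
#' @examples
#' prot <- data.frame(accession = "P1", sequence = "MAAAGADVWFKR")
#' pep <- data.frame(sequence = "GADVWFK", parent_accession = "P1")
#' screen_uniqueness(pep, prot)
#' @export
screen_uniqueness <- function(peptides, proteome, equate_ile_leu = TRUE) {
  canon <- function(x) if (equate_ile_leu) chartr("I", "L", x) else x
  seqs <- canon(toupper(proteome$sequence))
  out <- lapply(seq_len(nrow(peptides)), function(i) {
    pep <- toupper(peptides$sequence[i])
    parent <- peptides$parent_accession[i]
    hits <- proteome$accession[grepl(canon(pep), seqs, fixed = TRUE)]
    hits <- unique(hits)
    if (!is.na(parent) && nrow(proteome) &&
        parent %in% proteome$accession && !parent %in% hits)
      stop(sprintf("peptide '%s' is absent from its declared parent '%s'",
                   pep, parent), call. = FALSE)
    data.frame(peptide = pep, parent_accession = parent,
               is_unique = all(hits %in% parent),
               hit_accessions = paste(hits, collapse = ","),
               n_hits = length(hits),
               ile_leu_equivalent = equate_ile_leu,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
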
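# Built-in registry of 39 identifier classes.
#
# Templates and generator hints are plausible EMULATIONS of each database's
# accession grammar (literal prefixes plus digit / letter / hex runs), not
# authoritative identifiers.org entries. They are designed so that the 39
# classes are (near-)separable from positional character codes alone, which
# real corpora are not always: e.g. real gene-name-style classes (WikiGene,
# UniProt gene symbols) genuinely overlap; here they are kept apart by letter
# case so that pipeline behaviour can be validated on a learnable corpus.

builtin_spec_table <- function() {
  HEX <- "0123456789ABCDEF"
  lit <- function(s) hint_seg(s, literal = TRUE)
  seg <- hint_seg
  list(
    list("The Consensus CDS", "^CCDS\\d{4,6}$",
      list(lit("CCDS"), seg(DIGITS, 4, 6)), "CCDS ID", 32717),
    list("Conserved Domain Database", "^cd\\d{5}$",
      list(lit("cd"), seg(DIGITS, 5)), "CDD ID", 7204),
    list("ChEMBL", "^CHEMBL\\d+$",
      list(lit("CHEMBL"), seg(DIGITS, 4, 7)), "ChEMBL ID", 4030),
    list("EMBL", "^[A-Z]{1,2}\\d{5,6}$",
      list(seg(UPPER, 1, 2), seg(DIGITS, 5, 6)), "European Nucleotide Archive ID", 199350),
    list("Ensembl exon", "^ENSE\\d{11}$",
      list(lit("ENSE"), seg(DIGITS, 11)), "Exon stable ID", 852763),
    list("Ensembl gene", "^ENSG\\d{11}$",
      list(lit("ENSG"), seg(DIGITS, 11)), "Gene stable ID", 68016),
    list("Entrez Gene Database", "^\\d{5,9}$",
      list(seg(DIGITS, 5, 9)), "NCBI gene (formerly Entrezgene) ID", 22927),
    list("HAMAP", "^MF_\\d{5}$",
      list(lit("MF_"), seg(DIGITS, 5)), "HAMAP ID", 358),
    list("HGNC", "^HGNC:\\d{1,5}$",
      list(lit("HGNC:"), seg(DIGITS, 1, 5)), "HGNC ID", 39780),
    list("HGNC Transcript", "^[A-Z0-9]{2,6}-2\\d{2}$",
      list(seg(ALNUM_UPPER, 2, 6), lit("-2"), seg(DIGITS, 2)), "Transcript name ID", 232496),
    list("PANTHER", "^PTHR\\d{5}$",
      list(lit("PTHR"), seg(DIGITS, 5)), "PANTHER ID", 23775),
    list("Interpro", "^IPR\\d{6}$",
      list(lit("IPR"), seg(DIGITS, 6)), "Interpro ID", 17612),
    list("Merops", "^[A-Z]\\d{2}\\.\\d{3}$",
      list(seg(UPPER, 1), seg(DIGITS, 2), lit("."), seg(DIGITS, 3)),
      "MEROPS - the Peptidase Database ID", 780),
    list("miRBase", "^MI\\d{7}$",
      list(lit("MI"), seg(DIGITS, 7)), "miRBase ID", 1846),
    list("Protein Data Bank", "^[1-9][A-Z0-9]{3}$",
      list(seg("123456789", 1), seg(ALNUM_UPPER, 3)), "PDB ID", 48239),
    list("Pfam", "^PF\\d{5}$",
      list(lit("PF"), seg(DIGITS, 5)), "Pfam ID", 6595),
    list("pfScan", "^PS5\\d{4}$",
      list(lit("PS5"), seg(DIGITS, 4)), "PROSITE profiles ID", 895),
    list("PIRSF", "^PIRSF\\d{6}$",
      list(lit("PIRSF"), seg(DIGITS, 6)), "PIRSF ID", 949),
    list("PRINTS", "^PR\\d{5}$",
      list(lit("PR"), seg(DIGITS, 5)), "Prints ID", 1483),
    list("Protein", "^[A-Z]{3}\\d{5}\\.\\d$",
      list(seg(UPPER, 3), seg(DIGITS, 5), lit("."), seg(DIGITS, 1)),
      "INSDC protein ID", 490333),
    list("Reactome", "^R-HSA-\\d{5,7}$",
      list(lit("R-HSA-"), seg(DIGITS, 5, 7)), "Reactome gene ID", 2495),
    list("Refseq mrna", "^NM_\\d{6,9}$",
      list(lit("NM_"), seg(DIGITS, 6, 9)), "RefSeq mRNA ID", 62046),
    list("Refseq ncrna", "^NR_\\d{6,9}$",
      list(lit("NR_"), seg(DIGITS, 6, 9)), "RefSeq ncRNA ID", 15828),
    list("Refseq peptide", "^NP_\\d{6,9}$",
      list(lit("NP_"), seg(DIGITS, 6, 9)), "RefSeq peptide ID", 57215),
    list("Rfam", "^RF\\d{5}$",
      list(lit("RF"), seg(DIGITS, 5)), "RFAM ID", 58),
    list("Rfam transcript", "^RF\\d{5}\\.\\d$",
      list(lit("RF"), seg(DIGITS, 5), lit("."), seg(DIGITS, 1)),
      "RFAM transcript name ID", 1461),
    list("RNAcentral", "^URS[0-9A-F]{10}$",
      list(lit("URS"), seg(HEX, 10)), "RNAcentral ID", 89729),
    list("ScanProsite", "^PS0\\d{4}$",
      list(lit("PS0"), seg(DIGITS, 4)), "PROSITE patterns ID", 881),
    list("Structure-Function Linkage Database", "^SFLDG\\d{5}$",
      list(lit("SFLDG"), seg(DIGITS, 5)), "SFLD ID", 64),
    list("SMART", "^SM\\d{5}$",
      list(lit("SM"), seg(DIGITS, 5)), "SMART ID", 1020),
    list("SUPERFAMILY", "^SSF\\d{5}$",
      list(lit("SSF"), seg(DIGITS, 5)), "Superfamily ID", 1113),
    list("TIGRFAMs", "^TIGR\\d{5}$",
      list(lit("TIGR"), seg(DIGITS, 5)), "TIGRFAM ID", 594),
    list("UCSC", "^uc\\d{3}[a-z]{3}\\.\\d$",
      list(lit("uc"), seg(DIGITS, 3), seg(LOWER, 3), lit("."), seg(DIGITS, 1)),
      "UCSC Stable ID", 226788),
    list("UniProt Archive", "^UPI[0-9A-F]{10}$",
      list(lit("UPI"), seg(HEX, 10)), "UniParc ID", 90791),
    list("Uniprot gene", "^[A-Z]{2,4}\\d{0,2}$",
      list(seg(UPPER, 2, 4), seg(DIGITS, 0, 2)), "UniProtKB Gene Name symbol", 20438),
    list("Uniprot isoform", "^[OPQ]\\d[A-Z][A-Z0-9]{2}\\d-\\d{1,2}$",
      list(seg("OPQ", 1), seg(DIGITS, 1), seg(UPPER, 1), seg(ALNUM_UPPER, 2),
        seg(DIGITS, 1), lit("-"), seg(DIGITS, 1, 2)),
      "UniProtKB isoform ID", 24825),
    list("Uniprot TrEMBL", "^[A-N]\\d[A-Z][A-Z0-9]{2}\\d$",
      list(seg("ABCDEFGHIJKLMN", 1), seg(DIGITS, 1), seg(UPPER, 1),
        seg(ALNUM_UPPER, 2), seg(DIGITS, 1)),
      "UniProtKB/TrEMBL ID", 61771),
    list("Uniprot Swiss-prot", "^[OPQ]\\d[A-Z][A-Z0-9]{2}\\d$",
      list(seg("OPQ", 1), seg(DIGITS, 1), seg(UPPER, 1), seg(ALNUM_UPPER, 2),
        seg(DIGITS, 1)),
      "UniProtKB/Swiss-Prot ID", 19287),
    list("WikiGene", "^[A-Z][a-z]{2,5}\\d{0,2}$",
      list(seg(UPPER, 1), seg(LOWER, 2, 5), seg(DIGITS, 0, 2)),
      "WikiGene name", 22926)
  )
}

#' Built-in 39-class identifier registry
#'
#' A registry of 39 database identifier classes (Ensembl gene/exon, RefSeq,
#' UniProt, Pfam, Rfam, ChEMBL, PDB, ...) with synthetic, emulated templates:
#' literal prefixes plus digit / letter / hexadecimal runs that mimic each
#' database's accession grammar. These are not authoritative identifiers.org
#' patterns; they exist so that realistic corpora can be generated and the
#' full pipeline exercised offline.
#'
#' @return An [id_registry()] with 39 pattern specs, each carrying a
#'   generator hint.
#' @seealso [reference_profile()] for the per-class corpus sizes emulating
#'   the highly imbalanced source corpus.
#' @export
builtin_registry <- function() {
  reg <- id_registry()
  for (row in builtin_spec_table()) {
    reg <- register_pattern(reg, id_pattern_spec(
      row[[1]], row[[2]],
      generator_hint = row[[3]], description = row[[4]]
    ))
  }
  reg
}

#' Reference class-size profile of the imbalanced study corpus
#'
#' Per-class identifier counts of the corpus the classification pipeline was
#' developed on: 2,751,478 identifiers over 39 classes, ranging from 58 (Rfam)
#' to 852,763 (Ensembl exon) — an imbalance of about 14,702:1. Useful as the
#' profile argument of [generate_dataset()] to emulate that corpus at full
#' scale, and as the arithmetic input of [balance_plan()].
#'
#' @return Named numeric vector of per-class counts, in registry order.
#' @export
reference_profile <- function() {
  rows <- builtin_spec_table()
  counts <- vapply(rows, function(r) as.numeric(r[[5]]), numeric(1))
  names(counts) <- vapply(rows, function(r) r[[1]], character(1))
  counts
}
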
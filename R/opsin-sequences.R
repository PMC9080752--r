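#' @importFrom utils read.delim write.table read.csv write.csv
#' @importFrom stats aggregate approx coef cor deviance logLik model.frame
#'   optim optimize pbinom plogis predict qlogis quantile rbinom rmultinom
#'   rpois runif sd setNames simulate residuals
#' @importFrom graphics abline arrows contour image lines points
NULL

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")

OPSIN_CLASSES <- c("RH1", "SWS1", "SWS2", "RH2", "LWS")

#' Bovine rhodopsin reference sequence
#'
#' The 348-residue amino-acid sequence of bovine rhodopsin, used as the
#' universal coordinate frame for naming opsin residues (e.g. the substitution
#' "S299A" refers to site 299 in this numbering). Landmarks include the
#' retinal-attachment lysine at site 296 and the counterion glutamate at 113.
#'
#' @return A single character string of length-348 amino acids.
#' @export
bovine_rhodopsin <- function() {
  paste0(
    "MNGTEGPNFYVPFSNKTGVVRSPFEAPQYYLAEPWQFSMLAAYMFLLIMLGFPINFLTLY",
    "VTVQHKKLRTPLNYILLNLAVADLFMVFGGFTTTLYTSLHGYFVFGPTGCNLEGFFATLG",
    "GEIALWSLVVLAIERYVVVCKPMSNFRFGENHAIMGVAFTWVMALACAAPPLVGWSRYIP",
    "EGMQCSCGIDYYTPHEETNNESFVIYMFVVHFIIPLIVIFFCYGQLVFTVKEAAAQQQES",
    "ATTQKAEKEVTRMVIIMVIAFLICWLPYAGVAFYIFTHQGSDFGPIFMTIPAFFAKTSAV",
    "YNPVIYIMMNKQFRNCMVTTLCCGKNPLGDDEASTTVSKTETSQVAPA"
  )
}

#' Transmembrane helix ranges of bovine rhodopsin
#'
#' Default residue ranges (bovine numbering) of the seven transmembrane
#' helices, following the bovine rhodopsin crystal structure. The ranges are
#' configuration values: pass an edited data frame to functions that take a
#' `tm` argument to use alternative boundaries.
#'
#' @return A data frame with columns `helix`, `start`, `end`.
#' @export
bovine_tm_ranges <- function() {
  data.frame(
    helix = paste0("TM", 1:7),
    start = c(35L, 71L, 106L, 150L, 200L, 246L, 285L),
    end   = c(64L, 100L, 140L, 173L, 225L, 277L, 309L)
  )
}

#' Is a bovine-numbered site inside a transmembrane helix?
#'
#' @param site Integer vector of bovine rhodopsin sites (1--348).
#' @param tm Data frame of helix ranges as from [bovine_tm_ranges()].
#' @return Logical vector.
#' @export
in_transmembrane <- function(site, tm = bovine_tm_ranges()) {
  site <- as.integer(site)
  if (any(is.na(site)) || any(site < 1L) || any(site > 348L))
    stop("'site' must be within 1..348 (bovine rhodopsin numbering)")
  vapply(site, function(s) any(s >= tm$start & s <= tm$end), logical(1))
}

check_residues <- function(aa, what = "sequence") {
  letters_seen <- unique(strsplit(aa, "")[[1]])
  bad <- setdiff(letters_seen, c(AA_STANDARD, "X"))
  if (length(bad))
    stop(sprintf("non-standard residue letter(s) in %s: %s", what,
                 paste(bad, collapse = ", ")))
  invisible(TRUE)
}

#' Construct an opsin sequence record
#'
#' @param id Sequence identifier.
#' @param opsin_class One of `"RH1"`, `"SWS1"`, `"SWS2"`, `"RH2"`, `"LWS"`.
#' @param amino_acids Amino-acid sequence (20-letter alphabet plus `X`).
#'   May be omitted when `nucleotide_cds` is supplied.
#' @param nucleotide_cds Optional coding nucleotide sequence; when given it is
#'   translated and checked for consistency with `amino_acids`.
#' @return An object of class `opsin_sequence`.
#' @export
opsin_sequence <- function(id, opsin_class, amino_acids = NULL,
                           nucleotide_cds = NULL) {
  opsin_class <- match.arg(opsin_class, OPSIN_CLASSES)
  if (!is.null(nucleotide_cds)) {
    tr <- translate_cds(nucleotide_cds)
    if (is.null(amino_acids)) amino_acids <- tr
    else if (!identical(toupper(amino_acids), tr))
      stop("translation of 'nucleotide_cds' does not equal 'amino_acids'")
  }
  if (is.null(amino_acids) || !nzchar(amino_acids))
    stop("'amino_acids' must be a non-empty string")
  amino_acids <- toupper(amino_acids)
  if (grepl("-", amino_acids, fixed = TRUE))
    stop("gap characters must not be stored in an opsin sequence")
  check_residues(amino_acids, id)
  structure(
    list(id = id, opsin_class = opsin_class, amino_acids = amino_acids,
         nucleotide_cds = nucleotide_cds),
    class = "opsin_sequence"
  )
}

#' @export
print.opsin_sequence <- function(x, ...) {
  cat(sprintf("<opsin_sequence> %s  class=%s  %d aa%s\n", x$id, x$opsin_class,
              nchar(x$amino_acids),
              if (is.null(x$nucleotide_cds)) "" else "  (CDS attached)"))
  invisible(x)
}

as_amino_acids <- function(x) {
  if (inherits(x, "opsin_sequence")) x$amino_acids else toupper(as.character(x))
}

#' Translate a coding sequence with the standard genetic code
#'
#' A trailing stop codon is trimmed silently; an internal stop codon is an
#' error (it indicates a frameshift or misassembly). Codons containing `N`
#' translate to `X`.
#'
#' @param cds Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @return Amino-acid string, one letter per codon.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0)
    stop("coding sequence length is not a multiple of 3")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
  n <- nchar(aa)
  if (n > 1 && substr(aa, n, n) == "*") {
    aa <- substr(aa, 1, n - 1)
    n <- n - 1
  }
  stops <- which(strsplit(aa, "")[[1]] == "*")
  if (length(stops))
    stop(sprintf("internal stop codon at codon index %d", stops[1]))
  aa
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap costs
#' (open 10, extend 1). Deterministic: repeated calls return the identical
#' alignment.
#'
#' @param query,reference Amino-acid strings or `opsin_sequence` objects.
#' @return A `numbered_alignment`: a data frame with one row per alignment
#'   column and columns `query_res`, `ref_res` (residue letters or `"-"`)
#'   and `bovine_site` (all `NA` here; see [assign_bovine_numbering()]).
#' @export
align_pair <- function(query, reference) {
  q <- as_amino_acids(query)
  r <- as_amino_acids(reference)
  if (!nzchar(q) || !nzchar(r)) stop("sequences must be non-empty")
  check_residues(q, "query"); check_residues(r, "reference")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(r),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1
  )
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  out <- data.frame(query_res = qa, ref_res = ra,
                    bovine_site = rep(NA_integer_, length(qa)))
  class(out) <- c("numbered_alignment", "data.frame")
  attr(out, "score") <- Biostrings::score(aln)
  out
}

#' Express a query opsin in bovine rhodopsin site numbering
#'
#' Aligns the query to the 348-residue bovine rhodopsin sequence and labels
#' every alignment column holding a bovine residue with its 1-based bovine
#' position; query residues inherit the site of their column. A query whose
#' alignment covers less than half of bovine is flagged as low coverage
#' (likely not an opsin).
#'
#' @param query Amino-acid string or `opsin_sequence`.
#' @param bovine Bovine rhodopsin sequence (default [bovine_rhodopsin()]).
#' @return A `numbered_alignment` with `bovine_site` filled in and an
#'   attribute `low_coverage` (logical).
#' @export
assign_bovine_numbering <- function(query, bovine = bovine_rhodopsin()) {
  aln <- align_pair(query, bovine)
  is_res <- aln$ref_res != "-"
  aln$bovine_site[is_res] <- cumsum(is_res)[is_res]
  coverage <- mean(aln$query_res[is_res] != "-")
  attr(aln, "low_coverage") <- coverage < 0.5
  if (coverage < 0.5)
    warning(sprintf("alignment covers only %.0f%% of bovine rhodopsin; %s",
                    100 * coverage, "query may not be an opsin"))
  aln
}

#' Map bovine sites to query residue indices
#'
#' @param query Amino-acid string or `opsin_sequence`.
#' @param bovine Bovine rhodopsin sequence.
#' @return Integer vector indexed by bovine site (1..348); `NA` where the
#'   query has a gap at that site.
#' @export
bovine_site_map <- function(query, bovine = bovine_rhodopsin()) {
  aln <- assign_bovine_numbering(query, bovine)
  qidx <- cumsum(aln$query_res != "-")
  qidx[aln$query_res == "-"] <- NA_integer_
  map <- rep(NA_integer_, nchar(bovine))
  keep <- !is.na(aln$bovine_site)
  map[aln$bovine_site[keep]] <- qidx[keep]
  map
}

#' Detect amino-acid substitutions between two opsins in bovine numbering
#'
#' Both sequences are placed in the bovine rhodopsin frame; one substitution
#' is reported for every bovine-numbered site where both sequences carry a
#' residue and the residues differ. Sites where either sequence has a gap or
#' an `X` are excluded.
#'
#' @param query,reference Amino-acid strings or `opsin_sequence` objects.
#' @param bovine Bovine rhodopsin sequence.
#' @return Data frame with columns `bovine_site`, `from` (reference residue),
#'   `to` (query residue), sorted by site.
#' @export
detect_substitutions <- function(query, reference,
                                 bovine = bovine_rhodopsin()) {
  qmap <- bovine_site_map(query, bovine)
  rmap <- bovine_site_map(reference, bovine)
  qaa <- strsplit(as_amino_acids(query), "")[[1]]
  raa <- strsplit(as_amino_acids(reference), "")[[1]]
  sites <- which(!is.na(qmap) & !is.na(rmap))
  from <- raa[rmap[sites]]
  to <- qaa[qmap[sites]]
  keep <- from != to & from != "X" & to != "X"
  out <- data.frame(bovine_site = sites[keep], from = from[keep],
                    to = to[keep])
  out[order(out$bovine_site), , drop = FALSE]
}

#' Percent identity of two aligned sequences
#'
#' Computed over alignment columns where both sequences carry a residue;
#' columns containing `X` are excluded from numerator and denominator.
#'
#' @param a,b Amino-acid strings or `opsin_sequence` objects.
#' @return Fraction in `[0, 1]`.
#' @export
percent_identity <- function(a, b) {
  aln <- align_pair(a, b)
  both <- aln$query_res != "-" & aln$ref_res != "-" &
    aln$query_res != "X" & aln$ref_res != "X"
  if (!any(both)) stop("no comparable columns in alignment")
  mean(aln$query_res[both] == aln$ref_res[both])
}

#' Read opsin sequences from a FASTA file
#'
#' The description line may carry the opsin class as a `class=` key, e.g.
#' `>rh2a_query class=RH2`. Nucleotide FASTA is translated on read when
#' `type = "cds"`.
#'
#' @param path FASTA file.
#' @param type `"aa"` (default) or `"cds"`.
#' @param opsin_class Fallback class for records without a `class=` key.
#' @return List of `opsin_sequence` objects.
#' @export
read_opsin_fasta <- function(path, type = c("aa", "cds"),
                             opsin_class = "RH1") {
  type <- match.arg(type)
  set <- if (type == "aa") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i) {
    desc <- names(set)[i]
    id <- strsplit(desc, "\\s+")[[1]][1]
    cls <- if (grepl("class=", desc)) sub(".*class=(\\S+).*", "\\1", desc)
           else opsin_class
    seqchr <- as.character(set[[i]])
    if (type == "aa") opsin_sequence(id, cls, amino_acids = seqchr)
    else opsin_sequence(id, cls, nucleotide_cds = seqchr)
  })
}

#' Write opsin sequences to a FASTA file
#'
#' @param x List of `opsin_sequence` objects (or a single one).
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_opsin_fasta <- function(x, path, width = 60) {
  if (inherits(x, "opsin_sequence")) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in x) {
    writeLines(sprintf(">%s class=%s", s$id, s$opsin_class), con)
    aa <- s$amino_acids
    starts <- seq(1, nchar(aa), by = width)
    writeLines(substring(aa, starts, pmin(starts + width - 1, nchar(aa))), con)
  }
  invisible(path)
}
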
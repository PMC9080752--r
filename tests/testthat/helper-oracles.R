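# Independent oracles used across tests.

# Standard genetic code as a plain lookup table, independent of any
# translation machinery used by the package.
codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # order: TTT, CTT, ATT, GTT, TCT, ... (first base varies fastest)
  aas <- c(
    "F", "L", "I", "V", "S", "P", "T", "A", "Y", "H", "N", "D",
    "C", "R", "S", "G", "F", "L", "I", "V", "S", "P", "T", "A",
    "Y", "H", "N", "D", "C", "R", "S", "G", "L", "L", "I", "V",
    "S", "P", "T", "A", "*", "Q", "K", "E", "*", "R", "R", "G",
    "L", "L", "M", "V", "S", "P", "T", "A", "*", "Q", "K", "E",
    "W", "R", "R", "G"
  )
  setNames(aas, codons)
}

translate_oracle <- function(cds) {
  tab <- codon_table()
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(tab[codons], collapse = "")
}

# Brute-force global alignment over all monotone alignments, affine gaps
# (a gap of length L costs open + L * ext), BLOSUM62 scores. Only feasible
# for short sequences; returns the maximal score.
brute_force_align_score <- function(a, b, open = 10, ext = 1) {
  sub <- get_blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  # state: (i, j, last move: 0 none/match, 1 gap-in-b, 2 gap-in-a)
  rec <- function(i, j, last, sc) {
    if (i > n && j > m) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= n && j <= m)
      rec(i + 1, j + 1, 0, sc + sub[av[i], bv[j]])
    if (i <= n)  # consume a residue of 'a' against a gap
      rec(i + 1, j, 1, sc - ext - if (last == 1) 0 else open)
    if (j <= m)
      rec(i, j + 1, 2, sc - ext - if (last == 2) 0 else open)
  }
  rec(1, 1, 0, 0)
  best
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

alignment_score <- function(aln, open = 10, ext = 1) {
  sub <- get_blosum62()
  sc <- 0
  gap_q <- FALSE; gap_r <- FALSE
  for (i in seq_len(nrow(aln))) {
    q <- aln$query_res[i]; r <- aln$ref_res[i]
    if (q == "-") {
      sc <- sc - ext - if (gap_q) 0 else open
      gap_q <- TRUE; gap_r <- FALSE
    } else if (r == "-") {
      sc <- sc - ext - if (gap_r) 0 else open
      gap_r <- TRUE; gap_q <- FALSE
    } else {
      sc <- sc + sub[q, r]
      gap_q <- FALSE; gap_r <- FALSE
    }
  }
  sc
}

# Direct evaluation of the systematic-sampling CE used by scheaffer_ce.
ce_oracle <- function(counts, fpc = 1) {
  n <- length(counts)
  m <- mean(counts)
  s2 <- sum((counts - m)^2) / (n - 1)
  sqrt(fpc * s2 / n) / m
}

# Random amino-acid sequence.
random_aa <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}
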
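# Spectral tuning-site prediction of visual pigment lambda-max.
#
# A query opsin's lambda-max is predicted additively: start from the
# lambda-max of an in-vitro characterised reference pigment of the same opsin
# class, and add the documented shift of every substitution between query and
# reference that falls at a known tuning site. A substitution that is not
# itself documented can borrow the shift of a documented substitution at the
# same site when it causes the same polarity transition (polar <-> nonpolar).

POLAR_RESIDUES <- c("S", "T", "C", "Y", "N", "Q", "D", "E", "K", "R", "H", "W")
NONPOLAR_RESIDUES <- c("A", "V", "L", "I", "P", "F", "M", "G")

#' Two-class polarity of an amino acid
#'
#' The default scheme treats residues with hydroxyl, sulfhydryl, amide,
#' charged or indole side chains as polar (S, T, C, Y, N, Q, D, E, K, R, H, W)
#' and the aliphatic/aromatic rest as nonpolar (A, V, L, I, P, F, M, G).
#' Cysteine and tryptophan are borderline in some classifications; they are
#' polar here. Pass a custom `polar` set to override.
#'
#' @param residue Character vector of single residue letters.
#' @param polar Character vector defining the polar class.
#' @return Character vector, `"polar"` or `"nonpolar"`.
#' @export
classify_polarity <- function(residue, polar = POLAR_RESIDUES) {
  residue <- toupper(residue)
  if (any(residue == "X")) stop("cannot classify polarity of residue 'X'")
  bad <- setdiff(unique(residue), AA_STANDARD)
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  ifelse(residue %in% polar, "polar", "nonpolar")
}

#' Load a tuning-site table
#'
#' The shipped table contains every documented effect used by the package
#' (columns `opsin_class`, `bovine_site`, `from`, `to`, `shift_nm`, `source`).
#' Rows with `shift_nm = NA` mark sites known to tune a class whose effect
#' size is not quantified in the shipped table; such rows are used to
#' recognise known sites (and for proximity flagging) but are never applied
#' as shifts. Users may extend or replace the table with their own TSV.
#'
#' @param path Optional path to a user TSV with the same columns.
#' @return Data frame of tuning sites.
#' @export
tuning_sites <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tuning_sites.tsv", package = "ovkit")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("opsin_class", "bovine_site", "from", "to", "shift_nm")
  if (!all(needed %in% names(tab)))
    stop("tuning table must have columns: ", paste(needed, collapse = ", "))
  tab$shift_nm <- suppressWarnings(as.numeric(tab$shift_nm))
  tab
}

#' Construct a reference pigment
#'
#' @param id Identifier, e.g. `"O_latipes_RH1"`.
#' @param opsin_class Opsin class of the pigment.
#' @param lambda_max_nm Peak absorbance in nm (340--580).
#' @param sequence An `opsin_sequence` (or amino-acid string) of the same
#'   class.
#' @return Object of class `reference_pigment`.
#' @export
reference_pigment <- function(id, opsin_class, lambda_max_nm, sequence) {
  opsin_class <- match.arg(opsin_class, OPSIN_CLASSES)
  if (!is.numeric(lambda_max_nm) || lambda_max_nm < 340 || lambda_max_nm > 580)
    stop("'lambda_max_nm' must lie in 340..580 nm")
  if (!inherits(sequence, "opsin_sequence"))
    sequence <- opsin_sequence(id, opsin_class, amino_acids = sequence)
  structure(list(id = id, opsin_class = opsin_class,
                 lambda_max_nm = lambda_max_nm, sequence = sequence),
            class = "reference_pigment")
}

#' @export
print.reference_pigment <- function(x, ...) {
  cat(sprintf("<reference_pigment> %s  class=%s  lambda-max %g nm\n",
              x$id, x$opsin_class, x$lambda_max_nm))
  invisible(x)
}

#' Shifts applicable to a set of substitutions
#'
#' For each substitution (in bovine numbering) the rule is:
#' \describe{
#'   \item{documented}{the exact (site, from, to) triple has a quantified
#'     row in the tuning table for the class;}
#'   \item{polarity_matched}{otherwise, if a quantified row at the same site
#'     has the same polarity transition (e.g. polar to nonpolar) as the
#'     query substitution, that row's shift is borrowed.}
#' }
#' Substitutions at known tuning sites that change no polarity receive no
#' shift. When several quantified rows at one site match the polarity
#' transition with differing shifts, no shift is applied and the substitution
#' is reported as an ambiguous candidate (predictions must stay auditable).
#' At most one shift is applied per substitution.
#'
#' @param subs Data frame of substitutions (`bovine_site`, `from`, `to`) as
#'   from [detect_substitutions()].
#' @param opsin_class Class to filter the table by.
#' @param tuning_table Tuning-site table from [tuning_sites()].
#' @param polar Polar residue set for [classify_polarity()].
#' @return Data frame `bovine_site`, `from`, `to`, `shift_nm`, `rule`; the
#'   attribute `"ambiguous"` holds ambiguous candidates, if any.
#' @export
applicable_shifts <- function(subs, opsin_class,
                              tuning_table = tuning_sites(),
                              polar = POLAR_RESIDUES) {
  tab <- tuning_table[tuning_table$opsin_class == opsin_class, , drop = FALSE]
  empty <- data.frame(bovine_site = integer(), from = character(),
                      to = character(), shift_nm = numeric(),
                      rule = character())
  ambiguous <- empty
  if (!nrow(subs)) {
    attr(empty, "ambiguous") <- ambiguous
    return(empty)
  }
  rows <- lapply(seq_len(nrow(subs)), function(i) {
    s <- subs[i, ]
    at_site <- tab[tab$bovine_site == s$bovine_site, , drop = FALSE]
    if (!nrow(at_site)) return(NULL)
    exact <- at_site[at_site$from == s$from & at_site$to == s$to &
                       !is.na(at_site$shift_nm), , drop = FALSE]
    if (nrow(exact))
      return(data.frame(s, shift_nm = exact$shift_nm[1], rule = "documented"))
    pol <- classify_polarity(c(s$from, s$to), polar)
    if (pol[1] == pol[2]) return(NULL)  # known site, no polarity change
    trans <- paste(pol, collapse = ">")
    quant <- at_site[!is.na(at_site$shift_nm), , drop = FALSE]
    if (!nrow(quant)) return(NULL)
    rtrans <- paste(classify_polarity(quant$from, polar),
                    classify_polarity(quant$to, polar), sep = ">")
    match_rows <- quant[rtrans == trans, , drop = FALSE]
    if (!nrow(match_rows)) return(NULL)
    shifts <- unique(match_rows$shift_nm)
    if (length(shifts) > 1)
      return(data.frame(s, shift_nm = NA_real_, rule = "ambiguous"))
    data.frame(s, shift_nm = shifts, rule = "polarity_matched")
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) rows <- empty
  ambiguous <- rows[rows$rule == "ambiguous", , drop = FALSE]
  rows <- rows[rows$rule != "ambiguous", , drop = FALSE]
  attr(rows, "ambiguous") <- ambiguous
  rows
}

#' Flag undocumented polarity-changing substitutions near tuning sites
#'
#' Substitutions that change polarity, fall inside a transmembrane helix and
#' lie at (or within `proximity` residues of) a known tuning site of the
#' class are returned as candidates that might affect lambda-max even though
#' no documented shift can be applied to them.
#'
#' @param subs Substitution data frame.
#' @param opsin_class Opsin class.
#' @param tuning_table Tuning table; the class's known sites are its
#'   `bovine_site` values (quantified or not).
#' @param tm Transmembrane ranges, see [bovine_tm_ranges()].
#' @param proximity Distance in bovine sites counted as "near" (default 2).
#' @param polar Polar residue set.
#' @return Data frame `bovine_site`, `from`, `to`, `near_site`, `note`.
#' @export
flag_polarity_candidates <- function(subs, opsin_class,
                                     tuning_table = tuning_sites(),
                                     tm = bovine_tm_ranges(), proximity = 2,
                                     polar = POLAR_RESIDUES) {
  stopifnot(proximity >= 0)
  out <- data.frame(bovine_site = integer(), from = character(),
                    to = character(), near_site = integer(),
                    note = character())
  if (!nrow(subs)) return(out)
  known <- sort(unique(
    tuning_table$bovine_site[tuning_table$opsin_class == opsin_class]))
  if (!length(known)) return(out)
  for (i in seq_len(nrow(subs))) {
    s <- subs[i, ]
    if (s$from == "X" || s$to == "X") next
    pol <- classify_polarity(c(s$from, s$to), polar)
    if (pol[1] == pol[2]) next
    if (!in_transmembrane(s$bovine_site, tm)) next
    d <- abs(known - s$bovine_site)
    if (min(d) > proximity) next
    ns <- known[which.min(d)]
    out <- rbind(out, data.frame(
      bovine_site = s$bovine_site, from = s$from, to = s$to, near_site = ns,
      note = sprintf("polarity shift (%s>%s) within %d of known site %d",
                     pol[1], pol[2], min(d), ns)))
  }
  out
}

#' Predict visual pigment lambda-max from tuning-site substitutions
#'
#' Detects substitutions between a query opsin and a characterised reference
#' pigment of the same class (both expressed in bovine rhodopsin numbering),
#' applies every documented or polarity-matched shift additively to the
#' reference lambda-max, and reports polarity-changing transmembrane
#' substitutions that received no shift as candidates.
#'
#' @param query `opsin_sequence` of the query.
#' @param reference A [reference_pigment()] of the same opsin class.
#' @param tuning_table Tuning-site table.
#' @param bovine Bovine rhodopsin sequence.
#' @param tm Transmembrane ranges.
#' @param proximity Proximity window for candidate flagging.
#' @param polar Polar residue set.
#' @return Object of class `lmax_prediction` with elements `query_id`,
#'   `reference_id`, `reference_lambda_max_nm`, `substitutions`, `applied`,
#'   `candidates`, `predicted_lambda_max_nm`.
#' @export
predict_lambda_max <- function(query, reference,
                               tuning_table = tuning_sites(),
                               bovine = bovine_rhodopsin(),
                               tm = bovine_tm_ranges(), proximity = 2,
                               polar = POLAR_RESIDUES) {
  if (!inherits(reference, "reference_pigment"))
    stop("'reference' must be a reference_pigment")
  if (!inherits(query, "opsin_sequence"))
    query <- opsin_sequence("query", reference$opsin_class,
                            amino_acids = query)
  if (query$opsin_class != reference$opsin_class)
    stop(sprintf("opsin class mismatch: query %s vs reference %s",
                 query$opsin_class, reference$opsin_class))
  subs <- detect_substitutions(query, reference$sequence, bovine)
  applied <- applicable_shifts(subs, reference$opsin_class, tuning_table,
                               polar)
  ambiguous <- attr(applied, "ambiguous")
  unshifted <- subs[!(paste(subs$bovine_site, subs$from, subs$to) %in%
                        paste(applied$bovine_site, applied$from, applied$to)),
                    , drop = FALSE]
  candidates <- flag_polarity_candidates(unshifted, reference$opsin_class,
                                         tuning_table, tm, proximity, polar)
  if (nrow(ambiguous)) {
    amb <- data.frame(bovine_site = ambiguous$bovine_site,
                      from = ambiguous$from, to = ambiguous$to,
                      near_site = ambiguous$bovine_site,
                      note = "ambiguous: multiple polarity-matched shifts")
    candidates <- rbind(candidates, amb)
  }
  structure(list(
    query_id = query$id,
    reference_id = reference$id,
    opsin_class = reference$opsin_class,
    reference_lambda_max_nm = reference$lambda_max_nm,
    substitutions = subs,
    applied = applied,
    candidates = candidates,
    predicted_lambda_max_nm = reference$lambda_max_nm + sum(applied$shift_nm)
  ), class = "lmax_prediction")
}

#' @export
print.lmax_prediction <- function(x, ...) {
  cat(sprintf("<lmax_prediction> %s vs %s (%s)\n", x$query_id,
              x$reference_id, x$opsin_class))
  cat(sprintf("  reference lambda-max: %g nm\n", x$reference_lambda_max_nm))
  if (nrow(x$applied)) {
    for (i in seq_len(nrow(x$applied))) {
      a <- x$applied[i, ]
      cat(sprintf("  %s%d%s: %+g nm (%s)\n", a$from, a$bovine_site, a$to,
                  a$shift_nm, a$rule))
    }
  } else cat("  no applicable tuning-site shifts\n")
  cat(sprintf("  predicted lambda-max: %g nm\n", x$predicted_lambda_max_nm))
  if (nrow(x$candidates))
    cat(sprintf("  %d polarity-changing candidate substitution(s) flagged\n",
                nrow(x$candidates)))
  invisible(x)
}

#' Export a lambda-max prediction as a JSON report
#'
#' @param x An `lmax_prediction`.
#' @param path Output file; when `NULL` the JSON string is returned.
#' @return The path, or a JSON string when `path` is `NULL`.
#' @export
export_prediction_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "lmax_prediction"))
  obj <- unclass(x)
  if (is.null(path))
    return(jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                            digits = NA))
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
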
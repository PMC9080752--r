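# Length-normalised proportional opsin expression.
#
# Read counts per opsin gene are normalised by coding-sequence length
# (reads per bp); the rod proportion is RH1's normalised count over the
# total normalised opsin expression, and within-class proportions (single
# cones, double cones) are each gene's normalised count over the class total.

GENE_CLASSES <- c("rod", "single_cone", "double_cone")

check_counts <- function(counts) {
  needed <- c("individual_id", "gene_id", "gene_class", "reads",
              "cds_length_bp")
  miss <- setdiff(needed, names(counts))
  if (length(miss))
    stop("count table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!counts$gene_class %in% GENE_CLASSES))
    stop("gene_class must be one of: ", paste(GENE_CLASSES, collapse = ", "))
  if (any(counts$cds_length_bp <= 0)) stop("cds_length_bp must be positive")
  if (any(counts$reads < 0)) stop("read counts must be nonnegative")
  invisible(counts)
}

#' Read an opsin read-count table
#'
#' Expects a TSV with columns `individual_id`, `gene_id`, `gene_class`
#' (`rod`, `single_cone` or `double_cone`), `reads` and `cds_length_bp`.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_opsin_counts <- function(path) {
  check_counts(read.delim(path, stringsAsFactors = FALSE))
}

#' Length-normalise read counts
#'
#' @param counts Count table (see [read_opsin_counts()]).
#' @return The table with an added `normalised` column, reads per bp of
#'   coding sequence.
#' @export
normalise_counts <- function(counts) {
  check_counts(counts)
  counts$normalised <- counts$reads / counts$cds_length_bp
  counts
}

#' Proportion of rod opsin expression for one individual
#'
#' The rod gene's length-normalised count over the total normalised count of
#' all opsin genes. Genes with zero reads contribute zero but are retained.
#'
#' @param counts Count table rows for a single individual.
#' @return Fraction in `[0, 1]`.
#' @export
rod_proportion <- function(counts) {
  counts <- normalise_counts(counts)
  if (length(unique(counts$individual_id)) != 1)
    stop("'counts' must contain exactly one individual")
  rod <- counts$normalised[counts$gene_class == "rod"]
  if (length(rod) != 1) stop("exactly one rod gene is required")
  total <- sum(counts$normalised)
  if (total == 0) stop("total normalised opsin expression is zero")
  rod / total
}

#' Within-class proportional expression for one individual
#'
#' Each gene's length-normalised count as a fraction of the class total
#' (e.g. double-cone genes out of all double-cone expression).
#'
#' @param counts Count table rows for a single individual.
#' @param gene_class `"single_cone"` or `"double_cone"` (or `"rod"`).
#' @return Named numeric vector of fractions summing to 1.
#' @export
class_proportions <- function(counts, gene_class) {
  gene_class <- match.arg(gene_class, GENE_CLASSES)
  counts <- normalise_counts(counts)
  if (length(unique(counts$individual_id)) != 1)
    stop("'counts' must contain exactly one individual")
  cls <- counts[counts$gene_class == gene_class, , drop = FALSE]
  if (!nrow(cls)) stop("no genes of class ", gene_class)
  total <- sum(cls$normalised)
  if (total == 0) stop("zero total expression for class ", gene_class)
  setNames(cls$normalised / total, cls$gene_id)
}

#' Per-individual expression profile
#'
#' @param counts Count table rows for a single individual.
#' @return Object of class `expression_profile`: the rod proportion plus
#'   per-gene proportions within single cones and double cones.
#' @export
expression_profile <- function(counts) {
  structure(list(
    individual_id = unique(counts$individual_id),
    p_rod = rod_proportion(counts),
    single_cone = class_proportions(counts, "single_cone"),
    double_cone = class_proportions(counts, "double_cone")
  ), class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %s\n", x$individual_id))
  cat(sprintf("  rod (RH1): %.2f%%\n", 100 * x$p_rod))
  cat("  single cones:",
      paste(sprintf("%s %.2f%%", names(x$single_cone),
                    100 * x$single_cone), collapse = ", "), "\n")
  cat("  double cones:",
      paste(sprintf("%s %.2f%%", names(x$double_cone),
                    100 * x$double_cone), collapse = ", "), "\n")
  invisible(x)
}

#' Expression profiles for every individual in a count table
#'
#' @param counts Full count table.
#' @return Named list of [expression_profile()] objects.
#' @export
expression_profiles <- function(counts) {
  check_counts(counts)
  ids <- unique(counts$individual_id)
  setNames(lapply(ids, function(i)
    expression_profile(counts[counts$individual_id == i, , drop = FALSE])),
    ids)
}

#' Group summary of proportional expression
#'
#' Mean and standard error (sd/sqrt(n)) of per-gene proportions, in percent,
#' for each group label (e.g. field-caught vs aquarium-held individuals).
#' For groups of size one the s.e.m. is reported as 0 with `n = 1` flagging
#' that it is undefined.
#'
#' @param profiles List of `expression_profile`s (see
#'   [expression_profiles()]).
#' @param groups Named character vector mapping individual id to group label.
#' @param component `"double_cone"`, `"single_cone"` or `"rod"`.
#' @return Data frame with columns `group`, `gene_id`, `mean_pct`, `sem_pct`,
#'   `n`.
#' @export
group_summary <- function(profiles, groups, component = "double_cone") {
  component <- match.arg(component, c("double_cone", "single_cone", "rod"))
  rows <- do.call(rbind, lapply(profiles, function(p) {
    vals <- if (component == "rod") setNames(p$p_rod, "RH1")
            else p[[component]]
    data.frame(individual_id = p$individual_id, gene_id = names(vals),
               pct = 100 * as.numeric(vals))
  }))
  rows$group <- groups[rows$individual_id]
  if (any(is.na(rows$group))) stop("every individual needs a group label")
  out <- do.call(rbind, lapply(split(rows, list(rows$group, rows$gene_id),
                                     drop = TRUE), function(d) {
    n <- nrow(d)
    data.frame(group = d$group[1], gene_id = d$gene_id[1],
               mean_pct = mean(d$pct),
               sem_pct = if (n > 1) sd(d$pct) / sqrt(n) else 0,
               n = n)
  }))
  rownames(out) <- NULL
  out[order(out$group, out$gene_id), , drop = FALSE]
}
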
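#' Taxon-to-functional-group assignment rules
#'
#' Ordered, case-insensitive exact-name rules mapping taxon labels (phylum,
#' family, genus or species rank) to the nine bacterial groups plus the
#' methanogens. Species- and genus-level rules precede family rules, which
#' precede phylum rules, so e.g. *Ruminococcus bromii* reaches M2 before the
#' Ruminococcaceae family rule would send it to M3. The synonym list includes
#' *Eubacterium hallii* for *Anaerobutyricum hallii*. Taxa matching no rule
#' (e.g. Proteobacteria) are left unassigned.
#'
#' @return Data frame with columns `taxon` (lower-case label) and `mfg`,
#'   in precedence order; class `assignment_rules`.
#' @export
assignment_rules <- function() {
  rule <- function(mfg, ...) data.frame(taxon = tolower(c(...)), mfg = mfg,
                                        stringsAsFactors = FALSE)
  rules <- rbind(
    ## species-level (highest precedence)
    rule("M2", "ruminococcus bromii"),
    rule("M5", "eubacterium rectale", "agathobacter rectalis"),
    rule("M7", "coprococcus catus"),
    rule("M8", "eubacterium hallii", "anaerobutyricum hallii",
         "anaerostipes hadrus"),
    ## genus-level
    rule("M5", "roseburia"),
    rule("M6", "faecalibacterium", "subdoligranulum"),
    rule("M7", "veillonella", "megasphaera", "phascolarctobacterium",
         "dialister", "selenomonas"),
    rule("M8", "anaerostipes", "anaerobutyricum"),
    rule("M9", "blautia"),
    rule("M1", "bacteroides", "prevotella", "alistipes", "parabacteroides",
         "barnesiella", "odoribacter"),
    rule("M4", "bifidobacterium", "collinsella", "lactobacillus",
         "enterococcus", "streptococcus", "lactococcus", "olsenella"),
    rule("M10", "methanobrevibacter", "methanosphaera"),
    ## family-level
    rule("M3", "lachnospiraceae", "ruminococcaceae"),
    rule("M1", "bacteroidaceae", "prevotellaceae", "rikenellaceae",
         "porphyromonadaceae", "marinifilaceae", "tannerellaceae"),
    rule("M4", "bifidobacteriaceae", "coriobacteriaceae", "lactobacillaceae",
         "enterococcaceae", "streptococcaceae", "peptococcaceae"),
    rule("M7", "veillonellaceae", "acidaminococcaceae", "selenomonadaceae"),
    rule("M10", "methanobacteriaceae"),
    ## class/phylum-level (lowest precedence)
    rule("M7", "negativicutes"),
    rule("M1", "bacteroidetes", "bacteroidota"),
    rule("M4", "actinobacteria", "actinobacteriota", "actinomycetota"),
    rule("M10", "euryarchaeota", "methanogenic archaea"))
  if (anyDuplicated(rules$taxon))
    stop("assignment rules are ambiguous: duplicated taxon label", call. = FALSE)
  class(rules) <- c("assignment_rules", class(rules))
  rules
}

#' Read a taxon-abundance table
#'
#' @param path TSV with columns `taxon` and `abundance` (counts or
#'   fractions; counts are normalised downstream).
#' @return Data frame with those two columns.
#' @export
read_taxon_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "abundance") %in% names(tab)))
    stop("taxon table needs columns 'taxon' and 'abundance'", call. = FALSE)
  tab
}

#' Assign taxa to functional groups
#'
#' Each row is matched (case-insensitively, exact label) against the rule
#' list; rule order resolves precedence, so no taxon can land in two groups.
#' Abundances are normalised to the table total first.
#'
#' @param table data frame with `taxon` and `abundance` columns (`>= 0`,
#'   at least one row, positive total).
#' @param rules an [assignment_rules()] table.
#' @return List with `mfg_fractions` (named over M1..M10) and
#'   `unassigned_fraction`.
#' @export
assign_taxa <- function(table, rules = assignment_rules()) {
  if (is.null(table) || nrow(table) == 0L)
    stop("taxon table is empty", call. = FALSE)
  if (any(table$abundance < 0)) stop("abundances must be >= 0", call. = FALSE)
  total <- sum(table$abundance)
  if (total <= 0) stop("taxon table has zero total abundance", call. = FALSE)
  frac <- table$abundance / total
  idx <- match(tolower(trimws(table$taxon)), rules$taxon)
  mfg <- ifelse(is.na(idx), "unassigned", rules$mfg[idx])
  out <- stats::setNames(numeric(10), paste0("M", 1:10))
  agg <- tapply(frac, mfg, sum)
  hit <- intersect(names(agg), names(out))
  out[hit] <- agg[hit]
  list(mfg_fractions = out,
       unassigned_fraction = if ("unassigned" %in% names(agg))
         unname(agg[["unassigned"]]) else 0)
}

#' Redistribute the unassigned fraction
#'
#' Spreads the unassigned share over the nine bacterial groups in proportion
#' to each group's assigned abundance (M10 is untouched, as methanogen
#' abundance comes from qPCR, not 16S data).
#'
#' @param mfg_fractions named fractions over M1..M10.
#' @param unassigned_fraction fraction in `[0, 1)`.
#' @return Rescaled fractions summing (with M10) to 1.
#' @export
redistribute_unassigned <- function(mfg_fractions, unassigned_fraction) {
  stopifnot(unassigned_fraction >= 0, unassigned_fraction < 1)
  f <- mfg_fractions
  bact <- paste0("M", 1:9)
  if (sum(f[bact]) <= 0)
    stop("no bacterial group has assigned abundance; cannot redistribute",
         call. = FALSE)
  f[bact] <- f[bact] / (1 - unassigned_fraction)
  f
}

#' Override the methanogen fraction with a qPCR estimate
#'
#' Sets M10 to the qPCR-derived fraction and rescales the bacterial groups to
#' `1 - m10` so the vector sums exactly to 1.
#'
#' @param mfg_fractions named fractions over M1..M10 (bacterial part summing
#'   to ~1 after redistribution).
#' @param m10_fraction methanogen fraction in `[0, 1)` (0.006 for a D2-like
#'   community, 0.001 for D7-/D19-like).
#' @return Fractions summing exactly to 1.
#' @export
override_methanogens <- function(mfg_fractions, m10_fraction) {
  if (!is.numeric(m10_fraction) || m10_fraction < 0 || m10_fraction >= 1)
    stop("m10_fraction must be in [0, 1)", call. = FALSE)
  f <- mfg_fractions
  bact <- paste0("M", 1:9)
  f[bact] <- f[bact] / sum(f[bact]) * (1 - m10_fraction)
  f["M10"] <- m10_fraction
  f
}

#' Taxon table to donor profile
#'
#' Convenience pipeline: [assign_taxa()], [redistribute_unassigned()],
#' [override_methanogens()], wrapped as a [donor_profile()].
#'
#' @param table taxon-abundance data frame.
#' @param m10_fraction qPCR methanogen fraction.
#' @param rules assignment rules.
#' @param label profile label.
#' @return A [donor_profile()].
#' @export
taxa_to_profile <- function(table, m10_fraction = 0, rules = assignment_rules(),
                            label = "mapped") {
  a <- assign_taxa(table, rules)
  f <- redistribute_unassigned(a$mfg_fractions, a$unassigned_fraction)
  f <- override_methanogens(f, m10_fraction)
  donor_profile(f, label = label)
}
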
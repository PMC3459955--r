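#' Construct a 15-cell triad count table
#'
#' Container for per-SNP trio counts over the 15 Mendelian-compatible
#' (M, P, C) dose cells in the canonical order of [triad_cells()], plus
#' tallies of trios excluded for missing genotypes or Mendelian
#' inconsistency.
#'
#' @param counts integer vector of 15 non-negative cell counts.
#' @param n_excluded_missing number of trios with any missing member
#'   genotype at this SNP.
#' @param n_mendel_errors number of complete but Mendelian-inconsistent
#'   trios.
#' @param snp_id optional SNP label.
#' @return An object of class `cell_table`.
#' @export
cell_table <- function(counts, n_excluded_missing = 0L, n_mendel_errors = 0L,
                       snp_id = NA_character_) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 15, all(counts >= 0),
            n_excluded_missing >= 0, n_mendel_errors >= 0)
  cl <- cells_tab()
  names(counts) <- sprintf("(%d,%d,%d)", cl$M, cl$P, cl$C)
  structure(list(counts = counts,
                 n_excluded_missing = as.integer(n_excluded_missing),
                 n_mendel_errors = as.integer(n_mendel_errors),
                 snp_id = snp_id),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("15-cell triad table%s: %d trios tabulated, %d missing, %d Mendelian errors\n",
              if (!is.na(x$snp_id)) paste0(" [", x$snp_id, "]") else "",
              sum(x$counts), x$n_excluded_missing, x$n_mendel_errors))
  print(x$counts)
  invisible(x)
}

#' Risk-allele doses for each trio at one SNP
#'
#' @param ped a `trio_ped` object.
#' @param trios trio data frame from [build_trios()].
#' @param snp_id SNP to extract.
#' @param risk_allele allele symbol whose copies are counted as the
#'   dose; must be observed at the SNP or declared explicitly.
#' @return Data frame with columns `family_id`, `M`, `P`, `C` (doses in
#'   \{0, 1, 2\} or `NA`).
#' @export
trio_doses <- function(ped, trios, snp_id, risk_allele) {
  stopifnot(inherits(ped, "trio_ped"))
  if (!snp_id %in% ped$map$snp_id) {
    stop(sprintf("unknown snp_id '%s'", snp_id), call. = FALSE)
  }
  j <- match(snp_id, ped$map$snp_id)
  key <- paste(ped$fam$family_id, ped$fam$individual_id)
  dose_of <- function(ids) {
    i <- match(paste(trios$family_id, ids), key)
    (ped$a1[i, j] == risk_allele) + (ped$a2[i, j] == risk_allele)
  }
  data.frame(family_id = trios$family_id,
             M = as.integer(dose_of(trios$mother)),
             P = as.integer(dose_of(trios$father)),
             C = as.integer(dose_of(trios$child)))
}

#' Tabulate trios into the 15-cell triad table
#'
#' Each trio with a complete, Mendelian-consistent (M, P, C) dose triple
#' increments exactly one cell; trios with any missing genotype at the
#' SNP are counted in `n_excluded_missing` and inconsistent trios in
#' `n_mendel_errors`, so that counts + exclusions always add up to the
#' number of input trios.
#'
#' @param ped a `trio_ped` object.
#' @param trios trio data frame from [build_trios()]; defaults to
#'   `build_trios(ped)`.
#' @param snp_id SNP to tabulate.
#' @param risk_allele allele symbol counted as the dose.
#' @return A [cell_table()].
#' @export
tabulate_trios <- function(ped, snp_id, risk_allele, trios = build_trios(ped)) {
  d <- trio_doses(ped, trios, snp_id, risk_allele)
  tabulate_doses(d, snp_id = snp_id)
}

#' Tabulate a dose data frame into a cell table
#'
#' Lower-level interface to [tabulate_trios()] for doses already in
#' hand (e.g. simulator output).
#'
#' @param doses data frame with integer columns `M`, `P`, `C` (`NA` =
#'   missing).
#' @param snp_id optional SNP label.
#' @return A [cell_table()].
#' @export
tabulate_doses <- function(doses, snp_id = NA_character_) {
  status <- mendel_check(doses$M, doses$P, doses$C)
  ok <- status == "consistent"
  counts <- integer(15)
  if (any(ok)) {
    idx <- classify_cell(doses$M[ok], doses$P[ok], doses$C[ok])
    counts <- as.integer(tabulate(idx, nbins = 15))
  }
  cell_table(counts,
             n_excluded_missing = sum(status == "incomplete"),
             n_mendel_errors = sum(status == "inconsistent"),
             snp_id = snp_id)
}

#' Per-trio Mendelian error screen
#'
#' Flags trios whose rate of Mendelian-inconsistent genotypes across all
#' SNPs exceeds `max_error_rate` (computed over complete triples only),
#' a coarse screen for sample swaps and non-biological relationships.
#'
#' @param ped a `trio_ped` object.
#' @param trios trio data frame from [build_trios()].
#' @param max_error_rate maximum tolerated fraction of inconsistent
#'   complete triples (default 0.05).
#' @return Data frame with `family_id`, `n_complete`, `n_errors`,
#'   `error_rate`, `flagged`.
#' @export
mendel_screen <- function(ped, trios = build_trios(ped), max_error_rate = 0.05) {
  stopifnot(inherits(ped, "trio_ped"))
  n_err <- n_cmp <- integer(nrow(trios))
  key <- paste(ped$fam$family_id, ped$fam$individual_id)
  for (j in seq_len(nrow(ped$map))) {
    # dose relative to an arbitrary allele; consistency is allele-neutral
    ref <- stats::na.omit(ped$a1[, j])[1]
    if (is.na(ref)) next
    dj <- (ped$a1[, j] == ref) + (ped$a2[, j] == ref)
    M <- dj[match(paste(trios$family_id, trios$mother), key)]
    P <- dj[match(paste(trios$family_id, trios$father), key)]
    C <- dj[match(paste(trios$family_id, trios$child), key)]
    st <- mendel_check(M, P, C)
    n_cmp <- n_cmp + (st != "incomplete")
    n_err <- n_err + (st == "inconsistent")
  }
  rate <- ifelse(n_cmp > 0, n_err / n_cmp, 0)
  data.frame(family_id = trios$family_id, n_complete = n_cmp,
             n_errors = n_err, error_rate = rate,
             flagged = rate > max_error_rate)
}
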
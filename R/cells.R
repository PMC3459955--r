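#' Triad cell definitions
#'
#' The 15 Mendelian-compatible combinations of (mother, father, child)
#' risk-allele doses, in the canonical ordering used throughout the
#' package. Each cell carries its parental mating-type stratum (the
#' unordered pair of parental doses), child-dose and maternal-dose
#' indicators, and the parental origin of the variant copy in
#' heterozygous children where it is determinate.
#'
#' Origin is `"maternal"` when the child's single risk copy must have
#' come from the mother (cells 3, 6, 11), `"paternal"` when it must have
#' come from the father (cells 5, 7, 13), `"ambiguous"` for the double
#' heterozygote cell 9 (both parents heterozygous, child heterozygous),
#' and `"none"` for homozygous children.
#'
#' @return A 15-row data frame with columns `cell`, `M`, `P`, `C`,
#'   `stratum` (1 = 2x2, 2 = 2x1, 3 = 2x0, 4 = 1x1, 5 = 1x0, 6 = 0x0),
#'   `stratum_label`, `C1`, `C2`, `M1`, `M2` (0/1 indicators) and
#'   `origin`.
#' @examples
#' triad_cells()
#' @export
triad_cells <- function() {
  cells <- data.frame(
    cell = 1:15,
    M = c(2L, 2L, 2L, 1L, 1L, 2L, 0L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L),
    P = c(2L, 1L, 1L, 2L, 2L, 0L, 2L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, 0L),
    C = c(2L, 2L, 1L, 2L, 1L, 1L, 1L, 2L, 1L, 0L, 1L, 0L, 1L, 0L, 0L)
  )
  hi <- pmax(cells$M, cells$P)
  lo <- pmin(cells$M, cells$P)
  lab <- paste0(hi, "x", lo)
  levs <- c("2x2", "2x1", "2x0", "1x1", "1x0", "0x0")
  cells$stratum <- match(lab, levs)
  cells$stratum_label <- lab
  cells$C1 <- as.integer(cells$C == 1L)
  cells$C2 <- as.integer(cells$C == 2L)
  cells$M1 <- as.integer(cells$M == 1L)
  cells$M2 <- as.integer(cells$M == 2L)
  origin <- rep("none", 15)
  origin[cells$C == 1L & cells$P == 0L] <- "maternal"   # father has no copy
  origin[cells$C == 1L & cells$M == 2L] <- "maternal"   # mother must transmit
  origin[cells$C == 1L & cells$M == 0L] <- "paternal"
  origin[cells$C == 1L & cells$P == 2L] <- "paternal"
  origin[cells$M == 1L & cells$P == 1L & cells$C == 1L] <- "ambiguous"
  cells$origin <- origin
  cells
}

# internal cached copy (evaluated once when the package is built)
.cells <- triad_cells()

cells_tab <- function() .cells

#' Mendelian consistency of a trio dose triple
#'
#' Checks whether each (M, P, C) risk-allele dose triple is compatible
#' with Mendelian transmission: the child must receive exactly one
#' allele from each parent, so e.g. a homozygous-risk mother (M = 2)
#' forces the child to carry at least one copy.
#'
#' @param M,P,C integer vectors of maternal, paternal and child doses in
#'   \{0, 1, 2\}; `NA` marks a missing genotype.
#' @return A character vector with values `"consistent"`,
#'   `"inconsistent"` (complete but Mendelian-impossible) or
#'   `"incomplete"` (any member missing).
#' @examples
#' mendel_check(0, 0, 1)  # child carries an allele neither parent has
#' mendel_check(2, 2, 2)
#' @export
mendel_check <- function(M, P, C) {
  n <- max(length(M), length(P), length(C))
  M <- rep_len(as.integer(M), n)
  P <- rep_len(as.integer(P), n)
  C <- rep_len(as.integer(C), n)
  ok_dom <- function(x) all(is.na(x) | (x >= 0L & x <= 2L))
  if (!ok_dom(M) || !ok_dom(P) || !ok_dom(C)) {
    stop("doses must be in {0, 1, 2} or NA", call. = FALSE)
  }
  incomplete <- is.na(M) | is.na(P) | is.na(C)
  # child dose must lie between the minimum and maximum transmissible counts
  cmin <- ifelse(M == 2L, 1L, 0L) + ifelse(P == 2L, 1L, 0L)
  cmax <- ifelse(M >= 1L, 1L, 0L) + ifelse(P >= 1L, 1L, 0L)
  consistent <- !incomplete & C >= cmin & C <= cmax
  out <- ifelse(incomplete, "incomplete",
                ifelse(consistent, "consistent", "inconsistent"))
  out
}

#' Classify trio dose triples into the 15 triad cells
#'
#' Maps each Mendelian-consistent (M, P, C) dose triple to its index in
#' the canonical 15-cell ordering of [triad_cells()].
#'
#' @inheritParams mendel_check
#' @return Integer vector of cell indices in 1..15.
#' @seealso [mendel_check()], [triad_cells()]
#' @examples
#' classify_cell(1, 0, 1)  # cell 11: the variant copy is maternal
#' classify_cell(1, 1, 1)  # cell 9: origin ambiguous
#' @export
classify_cell <- function(M, P, C) {
  status <- mendel_check(M, P, C)
  if (any(status != "consistent")) {
    bad <- which(status != "consistent")[1]
    stop(sprintf("triple %d is %s; classify_cell requires Mendelian-consistent complete triples",
                 bad, status[bad]), call. = FALSE)
  }
  cl <- cells_tab()
  idx <- match(paste(M, P, C), paste(cl$M, cl$P, cl$C))
  idx
}

#' Triad cell probabilities under random mating
#'
#' Closed-form probabilities of the 15 triad cells for a biallelic locus
#' with risk-allele frequency `maf` under Hardy-Weinberg parental
#' genotypes and fair Mendelian transmission, without ascertainment.
#' Cell 9 (both parents heterozygous, child heterozygous) aggregates its
#' two latent transmission paths and therefore carries twice the
#' single-path mass.
#'
#' @param maf risk-allele frequency in [0, 1).
#' @return Numeric vector of 15 probabilities summing to 1.
#' @export
triad_null_probs <- function(maf) {
  stopifnot(is.numeric(maf), length(maf) == 1, maf >= 0, maf < 1)
  cl <- cells_tab()
  hw <- stats::dbinom(0:2, 2, maf)
  # P(transmit risk | parental dose): 0, 1/2, 1
  tr <- c(0, 0.5, 1)
  p <- numeric(15)
  for (i in 1:15) {
    m <- cl$M[i]; f <- cl$P[i]; c <- cl$C[i]
    pm <- tr[m + 1]; pf <- tr[f + 1]
    pc <- switch(as.character(c),
                 "0" = (1 - pm) * (1 - pf),
                 "1" = pm * (1 - pf) + (1 - pm) * pf,
                 "2" = pm * pf)
    p[i] <- hw[m + 1] * hw[f + 1] * pc
  }
  p
}

#' Flip the risk allele of a cell table
#'
#' Relabels doses d -> 2 - d for every trio member, permuting the 15
#' cells accordingly (e.g. cell 1, all homozygous risk, swaps with cell
#' 15, all homozygous wild-type). Applying the flip twice restores the
#' original table.
#'
#' @param x a [cell_table()] object.
#' @return A `cell_table` with permuted counts.
#' @export
flip_risk_allele <- function(x) {
  stopifnot(inherits(x, "cell_table"))
  cl <- cells_tab()
  perm <- match(paste(2L - cl$M, 2L - cl$P, 2L - cl$C),
                paste(cl$M, cl$P, cl$C))
  out <- x
  out$counts <- x$counts[perm]
  names(out$counts) <- names(x$counts)
  out
}
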
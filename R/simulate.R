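#' Simulation configuration for ascertained case-parent trios
#'
#' Describes a single-locus disease-risk model for trios ascertained on
#' an affected child. Parental genotypes are drawn from Hardy-Weinberg
#' proportions at the risk-allele frequency `maf` (mating symmetry holds
#' by construction) and child alleles by fair Mendelian transmission
#' with parental origin tracked. The child's disease probability is
#'
#'   baseline_risk x R1^I(C=1) x R2^I(C=2) x Im^I(C=1 and maternal
#'   origin) x S1^I(M=1) x S2^I(M=2)
#'
#' where R1/R2 are child-dose relative risks, Im the imprinting relative
#' risk of a maternally inherited copy in a heterozygous child, and
#' S1/S2 the maternal-genotype relative risks. The default
#' `baseline_risk` of 0.005 keeps the model in the rare-disease regime
#' where the log-linear model's odds-ratio parameters estimate these
#' relative risks.
#'
#' @param maf risk-allele frequency in [0, 1).
#' @param rr_child_het,rr_child_hom child-dose relative risks R1, R2.
#' @param rr_imprinting imprinting relative risk Im.
#' @param rr_maternal_het,rr_maternal_hom maternal relative risks S1, S2.
#' @param baseline_risk disease probability of the zero-covariate class.
#' @param n_trios number of ascertained trios to generate.
#' @param missing_rate per-genotype dropout probability in [0, 1).
#' @param mendel_error_rate per-trio probability of corrupting one child
#'   allele (chosen uniformly), in [0, 1].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(maf, n_trios,
                       rr_child_het = 1, rr_child_hom = 1,
                       rr_imprinting = 1,
                       rr_maternal_het = 1, rr_maternal_hom = 1,
                       baseline_risk = 0.005,
                       missing_rate = 0, mendel_error_rate = 0) {
  stopifnot(maf >= 0, maf < 1,
            n_trios >= 1,
            rr_child_het >= 0, rr_child_hom >= 0, rr_imprinting >= 0,
            rr_maternal_het >= 0, rr_maternal_hom >= 0,
            baseline_risk > 0, baseline_risk < 1,
            missing_rate >= 0, missing_rate < 1,
            mendel_error_rate >= 0, mendel_error_rate <= 1)
  max_mult <- max(1, rr_child_het * rr_imprinting, rr_child_hom) *
    max(1, rr_maternal_het, rr_maternal_hom)
  if (baseline_risk * max_mult > 1) {
    stop("invalid risk model: baseline_risk x maximum joint relative risk exceeds 1",
         call. = FALSE)
  }
  structure(list(maf = maf, n_trios = as.integer(n_trios),
                 rr_child_het = rr_child_het, rr_child_hom = rr_child_hom,
                 rr_imprinting = rr_imprinting,
                 rr_maternal_het = rr_maternal_het,
                 rr_maternal_hom = rr_maternal_hom,
                 baseline_risk = baseline_risk,
                 missing_rate = missing_rate,
                 mendel_error_rate = mendel_error_rate),
            class = "sim_config")
}

# analytic acceptance probability (expected disease risk of a random child)
acceptance_prob <- function(config) {
  q <- config$maf
  hw <- stats::dbinom(0:2, 2, q)
  tr <- c(0, 0.5, 1)
  p <- 0
  for (m in 0:2) for (f in 0:2) {
    pm <- tr[m + 1]; pf <- tr[f + 1]
    smat <- c(1, config$rr_maternal_het, config$rr_maternal_hom)[m + 1]
    base <- config$baseline_risk * smat
    # (maternal transmitted, paternal transmitted) -> child dose & origin
    probs <- c(pm * pf, pm * (1 - pf), (1 - pm) * pf, (1 - pm) * (1 - pf))
    risks <- base * c(config$rr_child_hom,
                      config$rr_child_het * config$rr_imprinting,
                      config$rr_child_het,
                      1)
    p <- p + hw[m + 1] * hw[f + 1] * sum(probs * pmin(risks, 1))
  }
  p
}

#' Simulate ascertained case-parent trios
#'
#' Draws trios by rejection sampling: candidate trios are generated
#' under Hardy-Weinberg random mating and Mendelian transmission, the
#' child's disease status is drawn from the risk model of
#' [sim_config()], and only trios with an affected child are kept.
#' Parental origin of each child allele is recorded. Uses the current
#' RNG state; call `set.seed()` for reproducibility.
#'
#' @param config a [sim_config()].
#' @return Data frame with one row per accepted trio: `M`, `P`, `C`
#'   doses and logicals `mat_risk`, `pat_risk` (whether the maternally /
#'   paternally inherited allele is the risk allele).
#' @export
simulate_trios <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  acc <- acceptance_prob(config)
  if (acc < 1e-6) {
    stop("acceptance probability below 1e-6; the configured risk model makes ascertainment impractical",
         call. = FALSE)
  }
  n_needed <- config$n_trios
  out <- vector("list", 0)
  got <- 0L
  while (got < n_needed) {
    batch <- max(1000L, ceiling((n_needed - got) / acc * 1.2))
    M <- stats::rbinom(batch, 2, config$maf)
    P <- stats::rbinom(batch, 2, config$maf)
    mat <- (M == 2L) | (M == 1L & stats::runif(batch) < 0.5)
    pat <- (P == 2L) | (P == 1L & stats::runif(batch) < 0.5)
    C <- as.integer(mat) + as.integer(pat)
    risk <- config$baseline_risk *
      ifelse(C == 1L, config$rr_child_het, 1) *
      ifelse(C == 2L, config$rr_child_hom, 1) *
      ifelse(C == 1L & mat, config$rr_imprinting, 1) *
      ifelse(M == 1L, config$rr_maternal_het, 1) *
      ifelse(M == 2L, config$rr_maternal_hom, 1)
    keep <- stats::runif(batch) < risk
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(M = M[keep], P = P[keep],
                                            C = C[keep],
                                            mat_risk = mat[keep],
                                            pat_risk = pat[keep])
      got <- got + sum(keep)
    }
  }
  res <- do.call(rbind, out)[seq_len(n_needed), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Simulate a PED/MAP-compatible trio dataset
#'
#' Generates `n_snps` independent SNPs for `config$n_trios` ascertained
#' trios: SNP `causal_index` follows the full risk model of `config`
#' (trios are ascertained on it), every other SNP is a null locus drawn
#' unconditionally under Hardy-Weinberg and Mendelian transmission at
#' frequency `null_maf`. Genotype dropout (`missing_rate`) and child
#' Mendelian errors (`mendel_error_rate`, corrupting one uniformly
#' chosen child allele) are injected after ascertainment. Alleles are
#' coded `A` (wild-type) and `B` (risk).
#'
#' @param config a [sim_config()].
#' @param n_snps number of SNPs (>= 1).
#' @param causal_index which SNP follows the risk model (default 1).
#' @param null_maf allele frequency of the null SNPs (default
#'   `config$maf`).
#' @param seed optional integer; when given, the RNG is seeded so the
#'   dataset is fully reproducible.
#' @return A `trio_ped` object (families `F0001`..., members `_c`,
#'   `_m`, `_f`).
#' @export
simulate_dataset <- function(config, n_snps = 1, causal_index = 1,
                             null_maf = config$maf, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), n_snps >= 1,
            causal_index >= 1, causal_index <= n_snps)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trios
  causal <- simulate_trios(config)

  dose_mat <- matrix(NA_integer_, 3L * n, n_snps)  # rows: mother, father, child
  mrow <- seq(1L, by = 3L, length.out = n)
  frow <- mrow + 1L
  crow <- mrow + 2L
  for (j in seq_len(n_snps)) {
    if (j == causal_index) {
      dose_mat[mrow, j] <- causal$M
      dose_mat[frow, j] <- causal$P
      dose_mat[crow, j] <- causal$C
    } else {
      M <- stats::rbinom(n, 2, null_maf)
      P <- stats::rbinom(n, 2, null_maf)
      mat <- (M == 2L) | (M == 1L & stats::runif(n) < 0.5)
      pat <- (P == 2L) | (P == 1L & stats::runif(n) < 0.5)
      dose_mat[mrow, j] <- M
      dose_mat[frow, j] <- P
      dose_mat[crow, j] <- mat + pat
    }
  }
  # dose -> allele pair (a1 counts sorted so 1 -> A B)
  a1 <- matrix(ifelse(dose_mat >= 1L, "B", "A"), nrow(dose_mat))
  a2 <- matrix(ifelse(dose_mat == 2L, "B", "A"), nrow(dose_mat))

  # Mendelian errors: corrupt one uniformly chosen child allele
  if (config$mendel_error_rate > 0) {
    for (j in seq_len(n_snps)) {
      hit <- which(stats::runif(n) < config$mendel_error_rate)
      if (length(hit)) {
        which_allele <- stats::runif(length(hit)) < 0.5
        r <- crow[hit]
        flip <- function(x) ifelse(x == "A", "B", "A")
        a1[r[which_allele], j] <- flip(a1[r[which_allele], j])
        a2[r[!which_allele], j] <- flip(a2[r[!which_allele], j])
      }
    }
  }
  # genotype dropout
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(dose_mat)) < config$missing_rate,
                   nrow(dose_mat))
    a1[drop] <- NA_character_
    a2[drop] <- NA_character_
  }

  fam_ids <- sprintf("F%04d", seq_len(n))
  fam <- data.frame(
    family_id = rep(fam_ids, each = 3L),
    individual_id = paste0(rep(fam_ids, each = 3L),
                           rep(c("_m", "_f", "_c"), n)),
    father_id = "0", mother_id = "0",
    sex = rep(c("female", "male", "unknown"), n),
    affected = rep(c("unaffected", "unaffected", "affected"), n),
    stringsAsFactors = FALSE
  )
  fam$father_id[crow] <- fam$individual_id[frow]
  fam$mother_id[crow] <- fam$individual_id[mrow]
  map <- data.frame(snp_id = sprintf("SNP%03d", seq_len(n_snps)),
                    chromosome = "1",
                    position = 1000L * seq_len(n_snps),
                    stringsAsFactors = FALSE)
  dimnames(a1) <- dimnames(a2) <-
    list(paste(fam$family_id, fam$individual_id), map$snp_id)
  structure(list(fam = fam, a1 = a1, a2 = a2, map = map), class = "trio_ped")
}

#' Simulation-based power of a parent-of-origin term test
#'
#' Estimates the power of the likelihood-ratio test of one term by
#' simulating replicate trio datasets under `config`, tabulating each
#' into the 15-cell table and testing the term at `nominal_level`.
#' Replicates in which the term is inestimable are tallied separately
#' and excluded from the denominator (with a warning when they exceed
#' 10%). Per-replicate seeds are derived deterministically from `seed`.
#'
#' @param config a [sim_config()].
#' @param term `"alpha"`, `"beta"` or `"gamma"`.
#' @param nominal_level test level (default 0.05).
#' @param n_replicates number of Monte-Carlo replicates (>= 100).
#' @param seed master seed (integer).
#' @param spec a [model_spec()] used for the fits.
#' @return An object of class `power_result`: list with `power`,
#'   `mc_stderr` (= sqrt(power (1 - power) / n_used)), `n_replicates`,
#'   `n_inestimable`, `term`, `nominal_level` and `config`.
#' @export
estimate_power <- function(config, term = c("alpha", "beta", "gamma"),
                           nominal_level = 0.05, n_replicates = 1000,
                           seed = 1, spec = model_spec()) {
  term <- match.arg(term)
  stopifnot(inherits(config, "sim_config"), n_replicates >= 100)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  hits <- 0L
  inest <- 0L
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    trios <- simulate_trios(config)
    tab <- tabulate_doses(trios)
    tt <- lrt_term(tab, term, spec)
    if (tt$status == "inestimable") {
      inest <- inest + 1L
    } else if (tt$p_value < nominal_level) {
      hits <- hits + 1L
    }
  }
  n_used <- n_replicates - inest
  if (inest > 0.1 * n_replicates) {
    warning(sprintf("term '%s' was inestimable in %d of %d replicates",
                    term, inest, n_replicates), call. = FALSE)
  }
  power <- if (n_used > 0) hits / n_used else NA_real_
  structure(list(power = power,
                 mc_stderr = if (n_used > 0) sqrt(power * (1 - power) / n_used)
                             else NA_real_,
                 n_replicates = n_replicates,
                 n_used = n_used,
                 n_inestimable = inest,
                 term = term,
                 nominal_level = nominal_level,
                 config = config),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "power of %s-term LRT at level %.3g: %.3f (MC se %.4f; %d/%d usable replicates)\n",
    x$term, x$nominal_level, x$power, x$mc_stderr, x$n_used, x$n_replicates))
  invisible(x)
}
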
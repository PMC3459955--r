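#' Read a per-SNP risk-allele configuration
#'
#' Tab-separated file with header columns `snp_id`, `risk_allele` and
#' `analysis_family` (the grouping over which Bonferroni correction is
#' applied), plus an optional `gene` column.
#'
#' @param path TSV file path.
#' @return Data frame with columns `snp_id`, `risk_allele`,
#'   `analysis_family`, `gene`.
#' @export
read_snp_config <- function(path) {
  cfg <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("snp_id", "risk_allele", "analysis_family")
  if (!all(need %in% names(cfg))) {
    stop(sprintf("snp config must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(cfg$gene)) cfg$gene <- NA_character_
  cfg[c("snp_id", "risk_allele", "analysis_family", "gene")]
}

#' Per-SNP parent-of-origin analysis with Bonferroni families
#'
#' For each SNP in `snp_config`, tabulates the trios into the 15-cell
#' triad table, runs the three likelihood-ratio term tests (alpha
#' imprinting, beta and gamma maternal effects) and flags Bonferroni
#' significance within the SNP's analysis family. Raw p-values are
#' always reported; the Bonferroni flag multiplies the raw p-value by
#' the family's test count. By default the family test count is the
#' number of SNPs in the family; set `tests_per_snp = 3` to count every
#' SNP x term combination instead.
#'
#' SNPs absent from the dataset yield a `missing-data` row; SNPs where
#' every term is inestimable (e.g. all trios homozygous wild-type) are
#' flagged `uninformative`. Trios failing the Mendelian-error screen
#' ([mendel_screen()]) are excluded and noted.
#'
#' @param ped a `trio_ped`, normally already passed through
#'   [apply_qc()].
#' @param snp_config data frame from [read_snp_config()].
#' @param spec a [model_spec()].
#' @param level significance level for the Bonferroni flag (default
#'   0.05).
#' @param tests_per_snp tests counted per SNP in the family size
#'   (default 1).
#' @param mendel_max_error_rate per-trio Mendelian error-rate threshold.
#' @return Data frame of class `poo_report`, one row per configured
#'   SNP: `snp_id`, `gene`, `risk_allele`, `analysis_family`,
#'   `n_informative_trios`, `n_trios`, `n_missing`, `n_mendel_errors`,
#'   then for each term `p_<term>`, `or_<term>`, `status_<term>`,
#'   `bonf_sig_<term>`, plus `family_n_tests` and `notes`.
#' @export
run_analysis <- function(ped, snp_config, spec = model_spec(), level = 0.05,
                         tests_per_snp = 1, mendel_max_error_rate = 0.05) {
  stopifnot(inherits(ped, "trio_ped"), level > 0, level <= 1)
  trios <- build_trios(ped)
  screen <- mendel_screen(ped, trios, max_error_rate = mendel_max_error_rate)
  dropped_trios <- screen$family_id[screen$flagged]
  trios_ok <- trios[!trios$family_id %in% dropped_trios, , drop = FALSE]

  rows <- lapply(seq_len(nrow(snp_config)), function(i) {
    sc <- snp_config[i, ]
    base <- data.frame(
      snp_id = sc$snp_id, gene = sc$gene, risk_allele = sc$risk_allele,
      analysis_family = sc$analysis_family,
      n_informative_trios = NA_integer_, n_trios = NA_integer_,
      n_missing = NA_integer_, n_mendel_errors = NA_integer_,
      stringsAsFactors = FALSE
    )
    for (trm in c("alpha", "beta", "gamma")) {
      base[[paste0("p_", trm)]] <- NA_real_
      base[[paste0("or_", trm)]] <- NA_real_
      base[[paste0("status_", trm)]] <- NA_character_
      base[[paste0("bonf_sig_", trm)]] <- NA
    }
    base$notes <- ""
    if (!sc$snp_id %in% ped$map$snp_id) {
      base$status_alpha <- base$status_beta <- base$status_gamma <- "missing-data"
      base$notes <- "SNP absent from dataset"
      return(base)
    }
    tab <- tabulate_trios(ped, sc$snp_id, sc$risk_allele, trios = trios_ok)
    cl <- cells_tab()
    base$n_trios <- sum(tab$counts)
    base$n_missing <- tab$n_excluded_missing
    base$n_mendel_errors <- tab$n_mendel_errors
    # trios in mating types with at least one heterozygous parent carry
    # the model's information
    base$n_informative_trios <- sum(tab$counts[cl$M == 1L | cl$P == 1L])
    if (sum(tab$counts) == 0) {
      base$status_alpha <- base$status_beta <- base$status_gamma <- "missing-data"
      base$notes <- "no complete consistent trios"
      return(base)
    }
    tt <- test_all_terms(tab, spec)
    for (trm in c("alpha", "beta", "gamma")) {
      base[[paste0("p_", trm)]] <- tt[[trm]]$p_value
      base[[paste0("or_", trm)]] <- tt[[trm]]$odds_ratio
      base[[paste0("status_", trm)]] <- tt[[trm]]$status
    }
    if (all(c(tt$alpha$status, tt$beta$status, tt$gamma$status) == "inestimable")) {
      base$notes <- "uninformative"
    }
    base
  })
  out <- do.call(rbind, rows)
  fam_n <- table(snp_config$analysis_family) * tests_per_snp
  out$family_n_tests <- as.integer(fam_n[out$analysis_family])
  for (trm in c("alpha", "beta", "gamma")) {
    p <- out[[paste0("p_", trm)]]
    ok <- !is.na(out[[paste0("status_", trm)]]) &
      out[[paste0("status_", trm)]] == "ok"
    out[[paste0("bonf_sig_", trm)]] <-
      ifelse(ok, !is.na(p) & p * out$family_n_tests <= level, NA)
  }
  if (length(dropped_trios)) {
    attr(out, "mendel_screen_dropped") <- dropped_trios
  }
  attr(out, "level") <- level
  class(out) <- c("poo_report", "data.frame")
  out
}

#' Write an analysis report
#'
#' TSV keeps full numeric precision and every column; the markdown view
#' mirrors the customary per-SNP result table (SNP, gene, risk allele,
#' then p-value and odds ratio for the alpha, beta and gamma terms) with
#' odds ratios rounded to 1 decimal, p-values to 2 significant figures,
#' and inestimable terms rendered as `N/A`.
#'
#' @param rows a `poo_report` from [run_analysis()].
#' @param path output file path.
#' @param format `"tsv"` or `"markdown"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(rows, path, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  stopifnot(nrow(rows) > 0)
  if (format == "tsv") {
    utils::write.table(as.data.frame(rows), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  fmt_p <- function(p, st) ifelse(is.na(p) | st != "ok", "N/A",
                                  vapply(p, function(v) format(signif(v, 2)), ""))
  fmt_or <- function(or, st) ifelse(is.na(or) | st != "ok", "N/A",
                                    sprintf("%.1f", or))
  md <- data.frame(
    SNP = rows$snp_id, Gene = rows$gene, RA = rows$risk_allele,
    `p-alpha` = fmt_p(rows$p_alpha, rows$status_alpha),
    `OR-alpha` = fmt_or(rows$or_alpha, rows$status_alpha),
    `p-beta` = fmt_p(rows$p_beta, rows$status_beta),
    `OR-beta` = fmt_or(rows$or_beta, rows$status_beta),
    `p-gamma` = fmt_p(rows$p_gamma, rows$status_gamma),
    `OR-gamma` = fmt_or(rows$or_gamma, rows$status_gamma),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  md[] <- lapply(md, as.character)
  md[is.na(md)] <- "N/A"
  header <- paste0("| ", paste(names(md), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(md)), collapse = "|"), "|")
  body <- apply(md, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  writeLines(c(header, sep, body), path)
  invisible(path)
}
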
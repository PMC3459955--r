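#' Read PLINK-style PED/MAP trio genotype files
#'
#' Parses whitespace-delimited pedigree (PED) and SNP map (MAP) text
#' files. The PED dialect is: six leading columns (family id, individual
#' id, father id, mother id, sex, affection) followed by two allele
#' tokens per SNP in MAP order. Allele symbol `"0"` encodes a missing
#' allele; a genotype with either allele missing is treated as a missing
#' call. Sex is coded 1 = male, 2 = female, other = unknown; affection
#' 2 = affected, 1 = unaffected, 0 or -9 = unknown. Father/mother id
#' `"0"` means no recorded parent. MAP files may have 3 columns
#' (chromosome, snp id, position) or the standard 4 (chromosome, snp id,
#' genetic distance, position).
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return A `trio_ped` object: a list with
#'   \describe{
#'     \item{fam}{data frame of pedigree columns (`family_id`,
#'       `individual_id`, `father_id`, `mother_id`, `sex`, `affected`).}
#'     \item{a1, a2}{character matrices (individuals x SNPs) of allele
#'       symbols, `NA` for missing.}
#'     \item{map}{data frame with `snp_id`, `chromosome`, `position`.}
#'   }
#'   Individuals referenced as parents but absent from the file are
#'   recorded in `attr(, "unresolved_parents")` and a warning is issued.
#' @export
parse_ped <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  ncol_map <- unique(lengths(map_tok))
  if (length(ncol_map) != 1 || !(ncol_map %in% c(3L, 4L))) {
    stop("MAP file must have 3 or 4 whitespace-delimited columns on every line",
         call. = FALSE)
  }
  mm <- do.call(rbind, map_tok)
  map <- data.frame(
    snp_id = mm[, 2],
    chromosome = mm[, 1],
    position = as.integer(mm[, ncol_map]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(map$snp_id)) {
    stop("duplicate snp_id in MAP file", call. = FALSE)
  }
  n_snp <- nrow(map)

  ped_lines <- readLines(ped_path)
  keep <- nzchar(trimws(ped_lines))
  ped_tok <- strsplit(trimws(ped_lines[keep]), "[ \t]+")
  want <- 6L + 2L * n_snp
  nf <- lengths(ped_tok)
  if (any(nf != want)) {
    bad <- which(keep)[which(nf != want)[1]]
    stop(sprintf("PED parse error at line %d: %d fields, expected %d (6 pedigree columns + 2 alleles x %d SNPs)",
                 bad, nf[which(nf != want)[1]], want, n_snp), call. = FALSE)
  }
  pm <- do.call(rbind, ped_tok)
  fam <- data.frame(
    family_id = pm[, 1],
    individual_id = pm[, 2],
    father_id = pm[, 3],
    mother_id = pm[, 4],
    sex = c("male", "female")[match(pm[, 5], c("1", "2"))],
    affected = c("unaffected", "affected")[match(pm[, 6], c("1", "2"))],
    stringsAsFactors = FALSE
  )
  fam$sex[is.na(fam$sex)] <- "unknown"
  fam$affected[is.na(fam$affected)] <- "unknown"
  key <- paste(fam$family_id, fam$individual_id)
  if (anyDuplicated(key)) {
    stop("individual_id must be unique within family_id", call. = FALSE)
  }

  al <- pm[, -(1:6), drop = FALSE]
  a1 <- al[, seq(1L, 2L * n_snp, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * n_snp, by = 2L), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_
  dimnames(a1) <- dimnames(a2) <- list(key, map$snp_id)

  obj <- structure(list(fam = fam, a1 = a1, a2 = a2, map = map),
                   class = "trio_ped")
  # parents referenced but absent
  refs <- unique(rbind(
    data.frame(family_id = fam$family_id, id = fam$father_id),
    data.frame(family_id = fam$family_id, id = fam$mother_id)
  ))
  refs <- refs[refs$id != "0", , drop = FALSE]
  missing_ref <- !(paste(refs$family_id, refs$id) %in% key)
  if (any(missing_ref)) {
    unresolved <- refs[missing_ref, , drop = FALSE]
    attr(obj, "unresolved_parents") <- unresolved
    warning(sprintf("%d parent reference(s) could not be resolved within their family",
                    nrow(unresolved)), call. = FALSE)
  }
  obj
}

#' @export
print.trio_ped <- function(x, ...) {
  cat(sprintf("trio_ped: %d individuals in %d families, %d SNPs\n",
              nrow(x$fam), length(unique(x$fam$family_id)), nrow(x$map)))
  invisible(x)
}

#' Write a trio_ped object to PED/MAP files
#'
#' Inverse of [parse_ped()] (missing alleles become `"0"`).
#'
#' @param ped a `trio_ped` object.
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_ped <- function(ped, prefix) {
  stopifnot(inherits(ped, "trio_ped"))
  a1 <- ped$a1; a2 <- ped$a2
  a1[is.na(a1)] <- "0"; a2[is.na(a2)] <- "0"
  n_snp <- nrow(ped$map)
  geno <- matrix("", nrow(ped$fam), 2L * n_snp)
  geno[, seq(1L, 2L * n_snp, 2L)] <- a1
  geno[, seq(2L, 2L * n_snp, 2L)] <- a2
  sex <- c(male = "1", female = "2", unknown = "0")[ped$fam$sex]
  aff <- c(unaffected = "1", affected = "2", unknown = "0")[ped$fam$affected]
  lines <- paste(ped$fam$family_id, ped$fam$individual_id, ped$fam$father_id,
                 ped$fam$mother_id, sex, aff,
                 apply(geno, 1, paste, collapse = " "))
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  writeLines(lines, ped_path)
  writeLines(paste(ped$map$chromosome, ped$map$snp_id, 0, ped$map$position,
                   sep = "\t"), map_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Assemble case-parent trios from a pedigree
#'
#' Finds every affected child whose recorded father and mother are both
#' present in the same family. Children with an unresolvable parent are
#' listed in the `incomplete` attribute rather than silently dropped.
#'
#' @param ped a `trio_ped` object.
#' @return A data frame with columns `family_id`, `child`, `mother`,
#'   `father` (individual ids), one row per complete trio, with an
#'   `incomplete` attribute listing affected children lacking a parent.
#'   A recorded mother with male sex (or father with female sex) raises
#'   a pedigree-inconsistency error.
#' @export
build_trios <- function(ped) {
  stopifnot(inherits(ped, "trio_ped"))
  fam <- ped$fam
  key <- paste(fam$family_id, fam$individual_id)
  kids <- fam[fam$affected == "affected" &
                fam$father_id != "0" & fam$mother_id != "0", , drop = FALSE]
  # also report affected children with no recorded parent ids
  norec <- fam[fam$affected == "affected" &
                 (fam$father_id == "0" | fam$mother_id == "0"), , drop = FALSE]
  mi <- match(paste(kids$family_id, kids$mother_id), key)
  fi <- match(paste(kids$family_id, kids$father_id), key)
  have_both <- !is.na(mi) & !is.na(fi)

  msex <- fam$sex[mi[have_both]]
  fsex <- fam$sex[fi[have_both]]
  if (any(msex == "male")) {
    stop("pedigree inconsistency: recorded mother has male sex", call. = FALSE)
  }
  if (any(fsex == "female")) {
    stop("pedigree inconsistency: recorded father has female sex", call. = FALSE)
  }

  trios <- data.frame(
    family_id = kids$family_id[have_both],
    child = kids$individual_id[have_both],
    mother = kids$mother_id[have_both],
    father = kids$father_id[have_both],
    stringsAsFactors = FALSE
  )
  incomplete <- rbind(
    data.frame(family_id = kids$family_id[!have_both],
               child = kids$individual_id[!have_both],
               reason = rep("parent absent from pedigree", sum(!have_both))),
    data.frame(family_id = norec$family_id,
               child = norec$individual_id,
               reason = rep("no recorded parent id", nrow(norec)))
  )
  attr(trios, "incomplete") <- incomplete
  trios
}

#' Genotype call rates
#'
#' `individual_call_rate()` returns, per individual, the fraction of
#' SNPs with a non-missing genotype; `snp_call_rate()` returns, per SNP,
#' the fraction of individuals with a non-missing call.
#'
#' @param ped a `trio_ped` object.
#' @param individual_id,snp_id optional id to look up a single value;
#'   an unknown id is an error.
#' @return Named numeric vector of fractions in [0, 1] (or a single
#'   value when an id is given).
#' @export
individual_call_rate <- function(ped, individual_id = NULL) {
  stopifnot(inherits(ped, "trio_ped"))
  r <- rowMeans(!is.na(ped$a1))
  names(r) <- rownames(ped$a1)
  if (!is.null(individual_id)) {
    hit <- which(ped$fam$individual_id == individual_id)
    if (!length(hit)) stop(sprintf("unknown individual_id '%s'", individual_id),
                           call. = FALSE)
    return(unname(r[hit[1]]))
  }
  r
}

#' @rdname individual_call_rate
#' @export
snp_call_rate <- function(ped, snp_id = NULL) {
  stopifnot(inherits(ped, "trio_ped"))
  r <- colMeans(!is.na(ped$a1))
  names(r) <- ped$map$snp_id
  if (!is.null(snp_id)) {
    if (!snp_id %in% ped$map$snp_id) {
      stop(sprintf("unknown snp_id '%s'", snp_id), call. = FALSE)
    }
    return(unname(r[snp_id]))
  }
  r
}

#' Call-rate quality control
#'
#' Removes individuals with genotype call rate strictly below
#' `individual_threshold`, then recomputes SNP call rates on the
#' surviving individuals and removes SNPs strictly below
#' `snp_threshold`. Because removing SNPs changes individual call rates
#' (and vice versa), the two steps are repeated — individuals first in
#' every round — until no further removal occurs, so the result is a
#' fixed point: applying `apply_qc` to its own output changes nothing.
#' Removing any member of a case-parent trio removes the whole trio.
#' Every removal is listed in the QC report with its call rate and
#' reason.
#'
#' @param ped a `trio_ped` object.
#' @param individual_threshold minimum individual call rate (default
#'   0.95).
#' @param snp_threshold minimum SNP call rate (default 0.98).
#' @return A list of class `trio_qc` with elements `ped` (the filtered
#'   `trio_ped`; may contain zero individuals or SNPs) and `report`
#'   (data frame with columns `entity`, `type`, `call_rate`, `action`,
#'   `reason`).
#' @export
apply_qc <- function(ped, individual_threshold = 0.95, snp_threshold = 0.98) {
  stopifnot(inherits(ped, "trio_ped"),
            individual_threshold > 0, individual_threshold <= 1,
            snp_threshold > 0, snp_threshold <= 1)
  report <- data.frame(entity = character(), type = character(),
                       call_rate = numeric(), action = character(),
                       reason = character(), stringsAsFactors = FALSE)
  out <- ped
  repeat {
    removed_any <- FALSE
    icr <- if (ncol(out$a1)) rowMeans(!is.na(out$a1)) else rep(1, nrow(out$fam))
    fail_ind <- icr < individual_threshold
    key <- paste(out$fam$family_id, out$fam$individual_id)
    if (any(fail_ind)) {
      report <- rbind(report, data.frame(
        entity = key[fail_ind], type = "individual",
        call_rate = icr[fail_ind], action = "removed",
        reason = sprintf("call rate below %.3g", individual_threshold)
      ))
      # drop the remaining members of any trio that lost a member
      trios <- build_trios(out)
      if (nrow(trios)) {
        tkeys <- cbind(paste(trios$family_id, trios$child),
                       paste(trios$family_id, trios$mother),
                       paste(trios$family_id, trios$father))
        broken <- rowSums(matrix(tkeys %in% key[fail_ind], nrow(trios))) > 0
        cascade <- setdiff(as.vector(tkeys[broken, , drop = FALSE]),
                           key[fail_ind])
        if (length(cascade)) {
          report <- rbind(report, data.frame(
            entity = cascade, type = "individual",
            call_rate = icr[match(cascade, key)], action = "removed",
            reason = "trio member failed call-rate QC"
          ))
        }
        fail_ind <- fail_ind | key %in% cascade
      }
      keep <- !fail_ind
      out$fam <- out$fam[keep, , drop = FALSE]
      out$a1 <- out$a1[keep, , drop = FALSE]
      out$a2 <- out$a2[keep, , drop = FALSE]
      removed_any <- TRUE
    }

    scr <- if (nrow(out$fam)) colMeans(!is.na(out$a1)) else rep(1, nrow(out$map))
    fail_snp <- scr < snp_threshold
    if (any(fail_snp)) {
      report <- rbind(report, data.frame(
        entity = out$map$snp_id[fail_snp], type = "snp",
        call_rate = scr[fail_snp], action = "removed",
        reason = sprintf("call rate below %.3g", snp_threshold)
      ))
      out$a1 <- out$a1[, !fail_snp, drop = FALSE]
      out$a2 <- out$a2[, !fail_snp, drop = FALSE]
      out$map <- out$map[!fail_snp, , drop = FALSE]
      removed_any <- TRUE
    }
    if (!removed_any) break
  }
  rownames(report) <- NULL
  structure(list(ped = out, report = report), class = "trio_qc")
}

#' @export
print.trio_qc <- function(x, ...) {
  cat(sprintf("trio QC: %d removal(s); %d individuals and %d SNPs retained\n",
              nrow(x$report), nrow(x$ped$fam), nrow(x$ped$map)))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param qc a `trio_qc` object from [apply_qc()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(qc, path) {
  stopifnot(inherits(qc, "trio_qc"))
  utils::write.table(qc$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Merge PED datasets genotyped on the same map
#'
#' Used to pool cohorts (e.g. pooling two disease cohorts to gain power
#' for shared susceptibility loci). SNP maps must agree exactly;
#' family ids must not collide.
#'
#' @param ... `trio_ped` objects.
#' @return A combined `trio_ped`.
#' @export
merge_ped <- function(...) {
  peds <- list(...)
  stopifnot(length(peds) >= 1, all(vapply(peds, inherits, TRUE, "trio_ped")))
  map0 <- peds[[1]]$map
  for (p in peds[-1]) {
    if (!identical(p$map$snp_id, map0$snp_id)) {
      stop("cannot merge: SNP maps differ", call. = FALSE)
    }
  }
  fam <- do.call(rbind, lapply(peds, `[[`, "fam"))
  if (anyDuplicated(paste(fam$family_id, fam$individual_id))) {
    stop("cannot merge: duplicated family/individual ids across datasets",
         call. = FALSE)
  }
  structure(list(fam = fam,
                 a1 = do.call(rbind, lapply(peds, `[[`, "a1")),
                 a2 = do.call(rbind, lapply(peds, `[[`, "a2")),
                 map = map0),
            class = "trio_ped")
}
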
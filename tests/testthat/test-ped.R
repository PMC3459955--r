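test_that("parse_ped reads a minimal well-formed PED/MAP pair", {
  fx <- write_trio_fixture(M = 1, P = 0, C = 1,
                           extra = list(data.frame(M = 2, P = 1, C = 2)))
  ped <- parse_ped(fx$ped, fx$map)
  expect_s3_class(ped, "trio_ped")
  expect_equal(nrow(ped$fam), 3)
  expect_equal(nrow(ped$map), 2)
  expect_equal(ncol(ped$a1), 2)
  expect_equal(ped$fam$sex, c("female", "male", "unknown"))
  expect_equal(ped$fam$affected, c("unaffected", "unaffected", "affected"))
})

test_that("parse_ped rejects malformed lines with a line number", {
  dir <- tempfile(); dir.create(dir)
  map <- file.path(dir, "x.map")
  writeLines(sprintf("1\tSNP%d\t0\t%d", 1:3, 1:3 * 100), map)
  ped <- file.path(dir, "x.ped")
  # 5 allele columns for a 3-SNP map
  writeLines("F1 kid 0 0 1 2 A A B B A", ped)
  expect_error(parse_ped(ped, map), "line 1")
})

test_that("genotype '0 0' becomes a missing call", {
  fx <- write_trio_fixture(M = NA, P = 0, C = 1)
  ped <- parse_ped(fx$ped, fx$map)
  expect_true(is.na(ped$a1[1, 1]))
  expect_false(is.na(ped$a1[2, 1]))
})

test_that("absent parent references produce a warning, not silence", {
  dir <- tempfile(); dir.create(dir)
  map <- file.path(dir, "x.map"); writeLines("1\tSNP1\t0\t100", map)
  ped <- file.path(dir, "x.ped")
  writeLines(c("F1 kid dad mom 1 2 A B",
               "F1 mom 0 0 2 1 A A"), ped)
  expect_warning(p <- parse_ped(ped, map), "parent reference")
  expect_equal(attr(p, "unresolved_parents")$id, "dad")
})

test_that("build_trios assembles complete affected-child trios", {
  fx <- write_trio_fixture(M = c(1, 0), P = c(1, 1), C = c(1, 0))
  ped <- parse_ped(fx$ped, fx$map)
  trios <- build_trios(ped)
  expect_equal(nrow(trios), 2)
  expect_equal(trios$child, c("kid", "kid"))

  # drop one father: that child is reported, not silently lost
  ped2 <- ped
  keep <- !(ped2$fam$family_id == "F002" & ped2$fam$individual_id == "dad")
  ped2$fam <- ped2$fam[keep, ]; ped2$a1 <- ped2$a1[keep, , drop = FALSE]
  ped2$a2 <- ped2$a2[keep, , drop = FALSE]
  trios2 <- build_trios(ped2)
  expect_equal(nrow(trios2), 1)
  inc <- attr(trios2, "incomplete")
  expect_equal(inc$family_id, "F002")
})

test_that("a recorded mother with male sex is a pedigree error", {
  fx <- write_trio_fixture(M = 1, P = 1, C = 1)
  ped <- parse_ped(fx$ped, fx$map)
  ped$fam$sex[ped$fam$individual_id == "mom"] <- "male"
  expect_error(build_trios(ped), "mother has male sex")
})

test_that("call rates are the fraction of non-missing calls", {
  # one individual with 19 of 20 SNPs called
  set.seed(7)
  n_snp <- 20
  extra <- lapply(seq_len(n_snp - 1),
                  function(i) data.frame(M = 1, P = 1, C = 1))
  fx <- write_trio_fixture(M = NA, P = 1, C = 1, extra = extra)
  ped <- parse_ped(fx$ped, fx$map)
  expect_equal(individual_call_rate(ped, "mom"), 19 / 20)
  expect_equal(individual_call_rate(ped, "dad"), 1.0)
  expect_equal(snp_call_rate(ped, "SNP001"), 2 / 3)
  expect_equal(snp_call_rate(ped, "SNP002"), 1.0)
  expect_error(snp_call_rate(ped, "nope"), "unknown snp_id")
  expect_error(individual_call_rate(ped, "nobody"), "unknown individual_id")
})

test_that("apply_qc removes low-call-rate individuals and their trios", {
  # 3 trios x 10 SNPs; one mother missing 2 of 10 calls (80% < 95%)
  extra <- lapply(1:9, function(i) data.frame(M = c(1, 1, 0), P = c(1, 0, 1),
                                              C = c(1, 1, 1)))
  extra[[1]]$M[2] <- NA
  fx <- write_trio_fixture(M = c(1, NA, 0), P = c(1, 0, 1), C = c(1, 1, 1),
                           extra = extra)
  ped <- parse_ped(fx$ped, fx$map)
  qc <- apply_qc(ped)
  # the failing mother and her whole trio are gone
  expect_false(any(qc$ped$fam$family_id == "F002"))
  expect_equal(nrow(qc$ped$fam), 6)
  expect_true(any(grepl("call rate below", qc$report$reason)))
  expect_true(any(qc$report$reason == "trio member failed call-rate QC"))
  # report lists the failing mother with her call rate
  mom <- qc$report[qc$report$entity == "F002 mom", ]
  expect_equal(mom$call_rate, 0.8)
})

test_that("apply_qc leaves a fully-called dataset unchanged and is idempotent", {
  set.seed(11)
  cfg <- sim_config(maf = 0.3, n_trios = 30)
  ped <- simulate_dataset(cfg, n_snps = 5, seed = 11)
  qc <- apply_qc(ped)
  expect_equal(nrow(qc$report), 0)
  expect_identical(qc$ped$a1, ped$a1)

  # idempotence with some missingness
  cfg2 <- sim_config(maf = 0.3, n_trios = 40, missing_rate = 0.03)
  ped2 <- simulate_dataset(cfg2, n_snps = 20, seed = 12)
  once <- apply_qc(ped2)
  twice <- apply_qc(once$ped)
  expect_identical(twice$ped$fam, once$ped$fam)
  expect_identical(twice$ped$map, once$ped$map)
})

test_that("a 249-trio cohort with 6 failing trios retains 243", {
  # synthetic pooled trio cohort: 249 trios,
  # 20 SNPs, six parents genotyped at 90% (< 95% threshold)
  cfg <- sim_config(maf = 0.3, n_trios = 249)
  ped <- simulate_dataset(cfg, n_snps = 20, seed = 99)
  fail <- sprintf("F%04d_m", c(3, 50, 101, 160, 200, 249))
  i <- match(paste(substr(fail, 1, 5), fail), rownames(ped$a1))
  ped$a1[i, 1:2] <- NA; ped$a2[i, 1:2] <- NA   # 18/20 = 90% call rate
  qc <- apply_qc(ped)
  trios <- build_trios(qc$ped)
  expect_equal(nrow(trios), 243)
  expect_equal(sum(qc$report$type == "individual"), 18)  # 6 trios x 3 members
})

test_that("merge_ped pools cohorts sharing a map", {
  cfg <- sim_config(maf = 0.2, n_trios = 10)
  a <- simulate_dataset(cfg, n_snps = 3, seed = 1)
  b <- simulate_dataset(cfg, n_snps = 3, seed = 2)
  b$fam$family_id <- sub("^F", "G", b$fam$family_id)
  b$fam$individual_id <- sub("^F", "G", b$fam$individual_id)
  b$fam$father_id <- sub("^F", "G", b$fam$father_id)
  b$fam$mother_id <- sub("^F", "G", b$fam$mother_id)
  rownames(b$a1) <- rownames(b$a2) <- paste(b$fam$family_id, b$fam$individual_id)
  m <- merge_ped(a, b)
  expect_equal(nrow(m$fam), 60)
  expect_equal(nrow(build_trios(m)), 20)
})
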
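test_that("dominant segregation verdicts follow the carrier pattern", {
  ped <- example_family()
  aff_ids <- ped$id[ped$affection == "affected"]
  x <- make_vs(1, samples = ped$id[ped$genotyped], gt = "het")
  x$geno[1, "III-9"] <- "hom_ref"
  res <- segregates_dominant(x, ped)
  expect_true(res$verdict)
  expect_true(all(res$detail$status[res$detail$id %in% aff_ids] == "consistent"))
  expect_equal(res$detail$status[res$detail$id == "II-1"], "untyped")

  # one affected individual without the variant breaks segregation
  y <- x; y$geno[1, "III-3"] <- "hom_ref"
  expect_false(segregates_dominant(y, ped)$verdict)

  # an unaffected carrier: fails strict mode, tolerated otherwise
  z <- x; z$geno[1, "III-9"] <- "het"
  expect_false(segregates_dominant(z, ped, strict_unaffected = TRUE)$verdict)
  lax <- segregates_dominant(z, ped, strict_unaffected = FALSE)
  expect_true(lax$verdict)
  expect_equal(sum(lax$detail$status == "nonpenetrant_carrier"), 1)

  none_typed <- pedigree("A", affection = "affected", genotyped = FALSE)
  expect_error(segregates_dominant(make_vs(1, samples = "A"), none_typed),
               "no typed affected")
})

test_that("strict segregation implies the penetrance-tolerant verdict", {
  ped <- example_family()
  set.seed(21)
  violations <- 0
  for (r in 1:60) {
    # bias the draw toward carrier-rich patterns so that strict-true
    # cases actually occur
    x <- make_vs(1, samples = ped$id[ped$genotyped],
                 gt = sample(c("hom_ref", "het", "hom_alt", NA), 9, TRUE,
                             prob = c(0.25, 0.6, 0.1, 0.05)))
    strict <- segregates_dominant(x, ped, strict_unaffected = TRUE)$verdict
    lax <- segregates_dominant(x, ped, strict_unaffected = FALSE)$verdict
    if (strict && !lax) violations <- violations + 1
  }
  expect_equal(violations, 0)
})

test_that("a gene-dropped causal variant always segregates at full penetrance", {
  ped0 <- example_family()
  mk <- default_marker_panel()[1]
  set.seed(31)
  for (r in 1:10) {
    d <- gene_drop(ped0, genetic_model(penetrance = c(1, 1, 0)), mk, 0)
    ped <- ped0
    ped$affection <- unname(d$affection)
    typed <- ped$id[ped$genotyped]
    if (!any(ped$affection[ped$genotyped] == "affected")) next
    gt <- ifelse(d$n_dis[typed] >= 2, "hom_alt",
                 ifelse(d$n_dis[typed] == 1, "het", "hom_ref"))
    x <- make_vs(1, samples = typed, gt = gt)
    expect_true(segregates_dominant(x, ped, strict_unaffected = TRUE)$verdict)
  }
})

test_that("recessive scan reports homozygous and compound-het candidates", {
  ped <- example_family()
  samples <- ped$id[ped$genotyped]
  aff <- samples[ped$affection[match(samples, ped$id)] == "affected"]

  hom <- make_vs(1, samples = samples, gt = "hom_alt", gene = "HOMG")
  res <- recessive_candidates(hom, ped)
  expect_equal(res$type, "homozygous")
  expect_equal(res$gene, "HOMG")

  # two het sites in one gene, carried by every affected
  chet <- make_vs(2, samples = samples, gt = "het", gene = "CHG")
  chet$geno[, "III-9"] <- "hom_ref"   # the unaffected sib is irrelevant
  res2 <- recessive_candidates(chet, ped)
  expect_equal(res2$type, "compound_het")
  expect_false(res2$phased)
  expect_equal(length(strsplit(res2$keys, ";")[[1]]), 2)

  # the nine-candidate pattern: one het site per gene, no recessive fit
  nine <- nine_candidates()
  nine$geno <- matrix("het", 9, length(samples),
                      dimnames = list(NULL, samples))
  nine <- variant_set(nine$variants, nine$pop_af, nine$geno)
  expect_equal(nrow(recessive_candidates(nine, ped)), 0)
})

test_that("recessive scan agrees with a brute-force pair enumeration", {
  ped <- example_family()
  samples <- ped$id[ped$genotyped]
  aff <- samples[ped$affection[match(samples, ped$id)] == "affected"]
  set.seed(77)
  for (r in 1:8) {
    x <- make_vs(30, samples = samples,
                 gt = sample(c("hom_ref", "het", "hom_alt"), 30 * 9, TRUE,
                             prob = c(0.5, 0.35, 0.15)),
                 gene = sample(sprintf("G%02d", 1:8), 30, TRUE))
    got <- recessive_candidates(x, ped)
    # brute force: scan every site and site pair within each gene
    carrier <- (x$geno[, aff, drop = FALSE] != "hom_ref")
    hom_all <- apply(x$geno[, aff, drop = FALSE] == "hom_alt", 1, all)
    expect_setequal(got$keys[got$type == "homozygous"],
                    variant_keys(x)[hom_all])
    for (g in unique(x$variants$gene)) {
      ix <- which(x$variants$gene == g)
      all_carry <- ix[apply(carrier[ix, , drop = FALSE], 1, all)]
      has_het <- all_carry[apply(
        x$geno[all_carry, aff, drop = FALSE] == "het", 1, any)]
      expect_equal(g %in% got$gene[got$type == "compound_het"],
                   length(has_het) >= 2)
    }
  }
})

test_that("control screen counts carriers and applies the retention cut", {
  x <- make_vs(3, pos = c(10, 20, 30))
  keys <- variant_keys(x)
  cohort <- control_cohort(180, setNames(c(0L, 1L, 3L), keys))
  scr <- control_screen(x, cohort)
  expect_equal(scr$carriers, c(0L, 1L, 3L))
  expect_equal(scr$retained, c(TRUE, FALSE, FALSE))
  expect_true(all(control_screen(x, cohort, max_carriers = 3)$retained))

  # a variant missing from the table counts as 0, with a note
  extra <- make_vs(1, pos = 999)
  expect_message(scr2 <- control_screen(extra, cohort), "treated as 0")
  expect_true(scr2$retained)

  expect_error(control_cohort(0), "positive")
  expect_error(control_cohort(10, c(k = 11L)), "n_controls")

  # round trip through the TSV representation
  tmp <- tempfile(fileext = ".tsv")
  write_control_table(cohort, tmp)
  back <- read_control_table(tmp)
  expect_equal(back$n_controls, 180L)
  expect_equal(back$carriers, cohort$carriers)
})
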
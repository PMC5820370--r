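test_that("sharing filter keeps exactly the variants carried by every affected", {
  aff <- c("S1", "S2", "S3", "S4")
  kept <- make_vs(1, gt = "het")
  expect_equal(length(shared_variants(kept, aff)), 1)

  three_of_four <- make_vs(1)
  three_of_four$geno[1, "S4"] <- "hom_ref"
  expect_equal(length(shared_variants(three_of_four, aff)), 0)

  missing_call <- make_vs(1)
  missing_call$geno[1, "S2"] <- NA
  expect_equal(length(shared_variants(missing_call, aff)), 0)

  expect_error(shared_variants(kept, character(0)), "empty")

  # 10 planted shared + 90 private variants in a quartet
  set.seed(5)
  shared10 <- make_vs(10, pos = 1:10 * 17L)
  private <- make_vs(90, pos = 1000L + 1:90 * 13L)
  private$geno[] <- "hom_ref"
  for (i in 1:90)
    private$geno[i, sample(aff, sample(0:3, 1))] <- "het"
  both <- vs_rbind(shared10, private)
  surv <- shared_variants(both, aff)
  expect_equal(length(surv), 10)
  expect_setequal(variant_keys(surv), variant_keys(shared10))
  expect_equal(length(surv), recount_shared(both, aff))
})

test_that("frequency filters exclude on strict max-AF and keep novel variants", {
  below <- make_vs(1, af = 0.004)
  at <- make_vs(1, af = 0.005)
  above <- make_vs(1, af = 0.0051)
  novel <- make_vs(1, af = NA)
  expect_equal(length(filter_frequency(below)), 1)
  expect_equal(length(filter_frequency(at)), 1)       # keep <=, exclude >
  expect_equal(length(filter_frequency(above)), 0)
  expect_equal(length(filter_frequency(novel)), 1)
  expect_error(filter_frequency(below, source_keys = "AF_NOPE"), "unknown")

  # one source above threshold suffices to exclude
  mixed <- make_vs(1)
  mixed$pop_af[1, ] <- c(0.001, 0.9, NA)
  expect_equal(length(filter_frequency(mixed)), 0)
  expect_equal(length(filter_frequency(mixed, source_keys = "AF_DBSNP")), 1)

  # 50 random records: survivor count equals a direct recount
  set.seed(42)
  x <- make_vs(50, af = NA)
  x$pop_af[] <- ifelse(runif(150) < 0.3, NA, runif(150, 0, 0.01))
  expect_equal(length(filter_frequency(x)), recount_af(x, 0.005))

  # in-house arm
  expect_equal(length(filter_inhouse(make_vs(1, inhouse = 0.02))), 0)
  expect_equal(length(filter_inhouse(make_vs(1, inhouse = NA))), 1)
})

test_that("region/consequence filtering keeps nonsynonymous and splice variants", {
  one_each <- make_vs(7, protein_change = NA,
                      consequence = c("nonsynonymous", "synonymous",
                                      "canonical_splice", "utr", "intronic",
                                      "intergenic", "other"))
  both <- filter_region_consequence(one_each)
  expect_equal(length(both), 2)
  expect_setequal(both$variants$consequence,
                  c("nonsynonymous", "canonical_splice"))
  # the two stages count separately: synonymous survives the first pass
  first <- filter_region_consequence(one_each, "exonic_splice")
  expect_equal(length(first), 3)
  expect_true("synonymous" %in% first$variants$consequence)
  expect_equal(length(filter_region_consequence(first, "nonsynonymous")), 2)
})

test_that("score rule is the strict union of the Grantham and phyloP arms", {
  nine <- nine_candidates()
  fl <- candidate_flags(nine)
  expect_equal(sum(fl$phylop_pass), 9)    # all phyloP > 2.7
  expect_equal(sum(fl$grantham_pass), 4)  # scores 155, 112, 180, 89 > 80
  expect_equal(length(score_candidates(nine)), 9)

  # exact boundary values fail both strict arms
  boundary <- make_vs(1, protein_change = "p.Ile2721Thr", phylop = 2.7)
  expect_equal(candidate_flags(boundary)$grantham[1], 89L)
  expect_equal(length(score_candidates(boundary, grantham_min = 89)), 0)
  expect_equal(length(score_candidates(boundary, grantham_min = 88.5)), 1)

  # missing phyloP fails that arm only; missing protein change warns
  no_phylop <- make_vs(1, protein_change = "p.Arg861Cys", phylop = NA)
  expect_equal(length(score_candidates(no_phylop)), 1)
  orphan <- make_vs(1, protein_change = NA, phylop = 5)
  expect_warning(fl2 <- candidate_flags(orphan), "protein change")
  expect_false(fl2$grantham_pass[1])
  expect_true(fl2$phylop_pass[1])

  # union equals the brute-force set definition on a random fixture
  set.seed(7)
  aa <- grantham_properties$residue
  x <- make_vs(60, phylop = runif(60, -2, 7),
               protein_change = format_protein_change(
                 sample(aa, 60, TRUE), 1:60,
                 sample(aa, 60, TRUE)))
  fl3 <- suppressWarnings(candidate_flags(x))
  manual <- union(which(fl3$grantham > 80), which(x$variants$phylop > 2.7))
  expect_setequal(which(fl3$candidate), manual)
})

test_that("the cascade counts stages consistently and monotonically", {
  aff <- c("S1", "S2", "S3", "S4")
  # engineered to lose exactly two records at each sequential stage
  x <- vs_rbind(
    make_vs(2, af = 0.2, pos = 1:2),                        # lost: pop AF
    make_vs(2, inhouse = 0.03, pos = 11:12),                # lost: in-house
    make_vs(2, consequence = "intronic", protein_change = NA,
            pos = 21:22),                                   # lost: region
    make_vs(2, consequence = "synonymous", protein_change = NA,
            pos = 31:32),                                   # lost: synonymous
    make_vs(2, protein_change = c("p.Arg861Cys", "p.Val37Met"),
            phylop = c(1, 5), pos = 41:42),                 # candidates
    make_vs(2, protein_change = "p.Ala48Thr", phylop = 1, pos = 51:52))
  rep <- run_cascade(x, aff)
  expect_equal(unname(rep$counts_shared[1:5]), c(12, 10, 8, 6, 4))
  expect_equal(unname(rep$counts_shared[c("grantham", "phylop")]), c(1, 1))
  expect_equal(length(rep$survivors), 2)
  # every sequential per-sample column is non-increasing
  for (s in aff)
    expect_true(all(diff(rep$counts_per_sample[1:5, s]) <= 0))

  # empty input gives an all-zero report
  empty <- run_cascade(x[0], aff)
  expect_true(all(empty$counts_shared == 0))
  expect_equal(length(empty$survivors), 0)
})

test_that("frequency and region filters commute", {
  set.seed(13)
  for (r in 1:5) {
    x <- make_vs(40, protein_change = NA,
                 consequence = sample(exolink_consequences, 40, TRUE),
                 af = ifelse(runif(40) < 0.4, NA, runif(40, 0, 0.02)))
    a <- filter_region_consequence(filter_frequency(x))
    b <- filter_frequency(filter_region_consequence(x))
    expect_identical(variant_keys(a), variant_keys(b))
  }
})

test_that("cascade and candidate reports are written as readable TSV", {
  aff <- c("S1", "S2", "S3", "S4")
  rep <- run_cascade(nine_candidates(), aff)
  tmp <- tempfile(fileext = ".tsv")
  write_cascade_tsv(rep, tmp)
  tab <- read.delim(tmp)
  expect_equal(tab$stage, rep$stage_names)
  expect_equal(tab$shared, unname(rep$counts_shared))
  write_candidate_tsv(rep$survivors, tmp,
                      segregation = rep(c(TRUE, FALSE), c(2, 7)))
  cand <- read.delim(tmp)
  expect_equal(nrow(cand), 9)
  expect_equal(cand$grantham, nine_candidate_grantham)
  expect_equal(cand$segregation, rep(c("Yes", "No"), c(2, 7)))
})
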
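test_that("marker definitions validate alleles and frequencies", {
  expect_error(marker_def("M", "a"), "at least 2")
  expect_error(marker_def("M", c("a", "b"), c(0.6, 0.5)), "sum to 1")
  mk <- marker_def("M", c("a", "b", "c"))
  expect_equal(mk$freqs, rep(1 / 3, 3))
})

test_that("peeling equals exhaustive enumeration on random pedigrees", {
  set.seed(101)
  done <- 0
  while (done < 12) {
    inst <- random_linkage_instance(three_gen = done %% 3 == 0)
    if (is.null(inst)) next
    done <- done + 1
    for (th in c(0, 0.25, 0.5)) {
      p <- two_locus_likelihood(inst$ped, inst$model, inst$marker,
                                inst$geno, th)
      b <- brute_force_likelihood(inst$ped, inst$model, inst$marker,
                                  inst$geno, th)
      if (is.infinite(p) || is.infinite(b)) {
        expect_identical(p, b)
      } else {
        expect_lt(abs(p - b), 1e-9)
      }
    }
  }
})

test_that("likelihood is invariant to allele relabeling and sib order", {
  set.seed(55)
  ped <- example_family()
  mk <- marker_def("M", c("1", "2", "3", "4"), c(0.4, 0.3, 0.2, 0.1))
  d <- gene_drop(ped, genetic_model(penetrance = c(1, 1, 0)), list(mk), 0.1)
  geno <- d$marker_geno[[1]][ped$id[ped$genotyped]]
  model <- genetic_model()
  ll <- two_locus_likelihood(ped, model, mk, geno, 0.1)

  # permute allele labels (and frequencies accordingly)
  perm <- c(3, 1, 4, 2)
  mk2 <- marker_def("M", as.character(perm), mk$freqs)
  geno2 <- lapply(geno, function(pr) as.character(perm[as.integer(pr)]))
  expect_equal(two_locus_likelihood(ped, model, mk2, geno2, 0.1), ll,
               tolerance = 1e-12)

  # reorder siblings in the pedigree
  ped2 <- ped[c(1, 2, 2 + sample(9)), ]
  ped2 <- pedigree(ped2$id, ped2$father, ped2$mother, ped2$sex,
                   ped2$affection, ped2$genotyped)
  expect_equal(two_locus_likelihood(ped2, model, mk, geno, 0.1), ll,
               tolerance = 1e-12)
})

test_that("LOD curves vanish at theta 0.5 and decay on cosegregating data", {
  ped <- example_family()
  model <- genetic_model()
  im <- max_pedigree_lod(ped, model, grid = c(0, 0.1, 0.4, 0.5))
  expect_identical(im$lod[4], 0)
  expect_gt(im$lod[1], im$lod[3])   # information decays with theta
  expect_equal(im$theta_at_max, 0)

  # impossible data: -Inf likelihood sentinel, no exception
  lethal <- genetic_model(penetrance = c(0, 0, 0))
  trio <- trio_ped()
  mk <- marker_def("M", c("a", "b"))
  expect_identical(
    brute_force_likelihood(trio, lethal, mk, list(), 0.1), -Inf)
  expect_identical(
    two_locus_likelihood(trio, lethal, mk, list(), 0.1), -Inf)
})

test_that("phase-unknown sibship reproduces the (n-1) log10(2) closed form", {
  n <- 5
  ids <- c("F", "M", paste0("C", 1:n))
  ped <- pedigree(ids, c(NA, NA, rep("F", n)), c(NA, NA, rep("M", n)),
                  sex = c("male", "female", rep("male", n)),
                  affection = c("affected", "unaffected",
                                rep("affected", n)))
  mk <- marker_def("M", c("1", "2", "3"))
  geno <- c(list(F = c("1", "2"), M = c("3", "3")),
            setNames(rep(list(c("1", "3")), n), paste0("C", 1:n)))
  # q -> 0 so the affected father is a heterozygous carrier with
  # probability 1; f = 1, no phenocopies
  model <- genetic_model(q = 1e-12, penetrance = c(1, 1, 0))
  l <- lod_curve(ped, model, mk, geno, grid = c(0, 0.5))
  expect_equal(l$lod[1], (n - 1) * log10(2), tolerance = 1e-9)
  # and the enumeration engine agrees
  lb <- lod_curve(ped, model, mk, geno, grid = c(0), engine = "brute")
  expect_equal(lb$lod[1], l$lod[1], tolerance = 1e-10)
})

test_that("enumeration guard refuses oversized problems with an estimate", {
  ped <- example_family()
  im <- exolink:::.informative_marker(ped)
  expect_error(
    brute_force_likelihood(ped, genetic_model(), im$marker, im$geno, 0),
    "configurations")
})

test_that("structural LOD ceiling behaves at its analytic limits", {
  # no meioses: a founder-only pedigree carries no linkage information
  solo <- pedigree("A", affection = "affected")
  expect_equal(max_pedigree_lod(solo)$max_lod, 0)

  # fully penetrant model with a typed affected carrier parent:
  # 9 phase-unknown informative meioses give (9 - 1) * log10(2)
  ped <- example_family()
  ped$genotyped <- rep(TRUE, 11)
  ped$affection[1] <- "affected"
  res <- max_pedigree_lod(ped, genetic_model(q = 1e-12,
                                             penetrance = c(1, 1, 0)),
                          grid = c(0, 0.5), carrier = "II-1")
  expect_equal(res$max_lod, 8 * log10(2), tolerance = 1e-9)
})

test_that("sibship haplotype reconstruction finds the shared disease segment", {
  # family-style fixture: untyped parents, the eight affected sibs all
  # carry the paternal "1" haplotype at every marker, the unaffected
  # sib carries the other paternal allele
  ped <- example_family()
  typed <- ped$id[ped$genotyped]
  mks <- default_marker_panel()
  set.seed(3)
  one_marker <- function() {
    g <- lapply(seq_along(typed), function(i) {
      if (ped$affection[match(typed[i], ped$id)] == "affected")
        c("1", sample(c("3", "4"), 1))
      else c("2", "3")
    })
    setNames(g, typed)
  }
  geno <- replicate(length(mks), one_marker(), simplify = FALSE)
  res <- sibship_shared_haplotype(mks, geno, ped)
  expect_setequal(res$shared_markers, vapply(mks, `[[`, "", "id"))
  expect_equal(res$assignment$shares,
               ped$affection[match(res$assignment$id, ped$id)] == "affected")

  # random unlinked genotypes: shared set empty or nearly so
  set.seed(8)
  hits <- 0
  for (r in 1:5) {
    geno_r <- lapply(mks, function(mk)
      setNames(lapply(typed, function(i) sample(mk$alleles, 2, TRUE)),
               typed))
    res_r <- tryCatch(sibship_shared_haplotype(mks, geno_r, ped),
                      error = function(e) NULL)
    if (!is.null(res_r)) hits <- hits + length(res_r$shared_markers)
  }
  expect_lt(hits, 5 * length(mks) / 2)

  # two sibs, one fully informative marker: phase ambiguity is preserved
  duo <- pedigree(c("F", "M", "A", "B"), c(NA, NA, "F", "F"),
                  c(NA, NA, "M", "M"),
                  sex = c("male", "female", "male", "male"),
                  affection = c("unknown", "unknown", "affected",
                                "unaffected"),
                  genotyped = c(FALSE, FALSE, TRUE, TRUE))
  mk <- marker_def("X", as.character(1:4))
  res2 <- sibship_shared_haplotype(
    list(mk), list(list(A = c("1", "3"), B = c("2", "4"))), duo)
  expect_gte(length(res2$configurations$X), 2)

  # Mendelian-impossible data are flagged as genotyping errors
  tri <- pedigree(c("F", "M", "A", "B", "C"), c(NA, NA, "F", "F", "F"),
                  c(NA, NA, "M", "M", "M"),
                  sex = c("male", "female", rep("male", 3)),
                  affection = c("unknown", "unknown", rep("affected", 3)),
                  genotyped = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  bad <- list(A = c("1", "2"), B = c("3", "4"), C = c("5", "6"))
  expect_error(
    sibship_shared_haplotype(list(marker_def("X", as.character(1:6))),
                             list(bad), tri),
    "genotyping")
})

test_that("marker genotype TSV round-trips", {
  geno <- list(D1 = list(A = c("1", "2"), B = c("2", "2")),
               D2 = list(A = c("3", "1")))
  tmp <- tempfile(fileext = ".tsv")
  write_marker_genotypes(geno, tmp)
  back <- read_marker_genotypes(tmp)
  expect_equal(back, geno)
})

test_that("an unlinked marker rarely yields notable LOD scores", {
  ped <- example_family()
  mk <- marker_def("U", as.character(1:4))
  model <- genetic_model()
  typed <- ped$id[ped$genotyped]
  set.seed(2024)
  max_lods <- vapply(1:200, function(r) {
    d <- gene_drop(ped, genetic_model(penetrance = c(1, 1, 0)), list(mk),
                   theta = 0.5)
    ped$affection <- unname(d$affection)
    lod_curve(ped, model, mk, d$marker_geno[[1]][typed],
              grid = seq(0, 0.5, by = 0.05))$max_lod
  }, numeric(1))
  expect_lt(mean(max_lods), 0.6)
  expect_gte(mean(max_lods < 3), 0.95)
})
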
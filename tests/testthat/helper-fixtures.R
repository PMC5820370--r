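# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# A variant_set with sensible defaults; all arguments recycled to n.
make_vs <- function(n = 1, samples = c("S1", "S2", "S3", "S4"),
                    gt = "het", consequence = "nonsynonymous",
                    protein_change = NA_character_, phylop = NA_real_,
                    af = NA_real_, inhouse = NA_real_, gene = NULL,
                    chrom = "1", pos = NULL) {
  if (is.null(gene)) gene <- sprintf("G%03d", seq_len(n))
  if (is.null(pos)) pos <- seq_len(n) * 100L
  variants <- data.frame(
    chrom = rep_len(chrom, n), pos = rep_len(pos, n),
    ref = "A", alt = "G",
    gene = rep_len(gene, n), transcript = "NM_000001",
    cdna_change = "c.1A>G",
    protein_change = rep_len(protein_change, n),
    consequence = rep_len(consequence, n),
    phylop = rep_len(phylop, n),
    inhouse_freq = rep_len(inhouse, n),
    stringsAsFactors = FALSE)
  pop_af <- matrix(rep_len(af, n), n, 3,
                   dimnames = list(NULL, c("AF_DBSNP", "AF_EVS", "AF_G1K")))
  geno <- matrix(rep_len(gt, n * length(samples)), n, length(samples),
                 dimnames = list(NULL, samples))
  variant_set(variants, pop_af, geno)
}

# Stack variant_sets rowwise (same samples and AF sources).
vs_rbind <- function(...) {
  xs <- list(...)
  variant_set(do.call(rbind, lapply(xs, function(x) x$variants)),
              do.call(rbind, lapply(xs, function(x) x$pop_af)),
              do.call(rbind, lapply(xs, function(x) x$geno)))
}

# The nine prioritized substitutions of the example candidate
# table: protein change and phyloP, one record per gene.
nine_candidates <- function() {
  genes <- c("TP53BP2", "MAPKAPK2", "TGFBI", "ADSSL1", "NCEH1",
             "RNF157", "PHC3", "SLITRK3", "RYR2")
  prot <- c("p.Val37Met", "p.Arg102His", "p.Asp299Asn", "p.Ser193Phe",
            "p.Ala48Thr", "p.Cys638Ser", "p.Glu614Lys", "p.Arg861Cys",
            "p.Ile2721Thr")
  phylop <- c(4.135, 5.691, 5.884, 5.657, 5.305, 5.254, 3.961, 3.886,
              3.683)
  make_vs(9, gene = genes, protein_change = prot, phylop = phylop)
}

# Expected published Grantham scores for the nine substitutions above.
nine_candidate_grantham <- c(21, 29, 23, 155, 58, 112, 56, 180, 89)

# A simple affected trio pedigree (affected father and child).
trio_ped <- function() {
  pedigree(c("F", "M", "C"), c(NA, NA, "F"), c(NA, NA, "M"),
           sex = c("male", "female", "male"),
           affection = c("affected", "unaffected", "affected"))
}

# Random loop-free pedigree + marker + consistent genotypes for the
# peeling-vs-enumeration checks. Sizes are kept small enough that the
# enumeration stays below ~5e5 configurations.
random_linkage_instance <- function(three_gen = FALSE) {
  n_kids <- sample(1:3, 1)
  ids <- c("F", "M", paste0("K", seq_len(n_kids)))
  father <- c(NA, NA, rep("F", n_kids))
  mother <- c(NA, NA, rep("M", n_kids))
  sex <- c("male", "female", sample(c("male", "female"), n_kids, TRUE))
  if (three_gen) {
    sex[3] <- "male"
    n_g <- sample(1:2, 1)
    ids <- c(ids, "S", paste0("G", seq_len(n_g)))
    father <- c(father, NA, rep("K1", n_g))
    mother <- c(mother, NA, rep("S", n_g))
    sex <- c(sex, "female", sample(c("male", "female"), n_g, TRUE))
  }
  affection <- sample(c("affected", "unaffected", "unknown"),
                      length(ids), TRUE)
  ped <- pedigree(ids, father, mother, sex, affection)

  k <- sample(2:4, 1)
  mk <- marker_def("T", as.character(seq_len(k)),
                   freqs = {
                     f <- stats::runif(k, 0.5, 2)
                     f / sum(f)
                   })
  model <- genetic_model(q = stats::runif(1, 1e-4, 0.2),
                         penetrance = sort(stats::runif(3))[c(3, 2, 1)])
  drop <- gene_drop(ped, model, list(mk), theta = stats::runif(1, 0, 0.5))
  geno <- drop$marker_geno[[1]]
  # leave a random subset untyped, but keep the enumeration tractable
  untyped <- sample(ped$id, sample(0:1, 1))
  geno[untyped] <- NULL
  support_size <- vapply(ped$id, function(id) {
    if (id %in% names(geno)) {
      if (geno[[id]][1] == geno[[id]][2]) 4 else 8
    } else (2 * k)^2
  }, numeric(1))
  if (prod(support_size) > 5e5) return(NULL)
  list(ped = ped, marker = mk, model = model, geno = geno)
}

# Independent recount helpers for cascade stages, written against the
# raw matrices rather than the package's filter functions.
recount_shared <- function(x, affected) {
  g <- x$geno[, affected, drop = FALSE]
  sum(apply(g, 1, function(r) all(!is.na(r) & r %in% c("het", "hom_alt"))))
}
recount_af <- function(x, af_max) {
  ok <- apply(x$pop_af, 1, function(r) {
    if (all(is.na(r))) TRUE else max(r, na.rm = TRUE) <= af_max
  })
  sum(ok)
}
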
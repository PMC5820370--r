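#' Gene-drop simulation of a linked disease locus and markers
#'
#' Simulates transmission through a loop-free pedigree of a rare
#' dominant disease allele together with linked multiallelic markers.
#' Founder marker haplotypes are drawn from the marker allele
#' frequencies; one designated founder is forced to be a heterozygous
#' disease-allele carrier (the other founders draw their disease
#' alleles from `model$q`, i.e. are essentially always non-carriers).
#' Each meiosis transmits one of the parent's two haplotypes at the
#' disease locus with probability 1/2; every marker follows the chosen
#' haplotype with probability `1 - theta[m]` and recombines onto the
#' other with probability `theta[m]` (markers conditionally independent
#' given the disease-locus transmission). Affection status is then
#' sampled from the genotype penetrances.
#'
#' @param ped A loop-free [pedigree()].
#' @param model A [genetic_model()]; its penetrances generate the
#'   affection statuses.
#' @param markers List of [marker_def()].
#' @param theta Recombination fraction(s) between the disease locus and
#'   each marker (recycled).
#' @param seed Integer seed; identical seeds give identical output.
#' @param carrier Founder id forced to carry the disease allele
#'   (default: first founder).
#' @param informative If `TRUE`, founder marker haplotypes are assigned
#'   globally unique alleles instead of being drawn from the allele
#'   frequencies, making every marker fully informative (each marker
#'   then needs at least `2 * n_founders` alleles).
#' @return List with `affection` (named character), `carrier` (named
#'   logical, >= 1 disease allele), `n_dis` (named 0/1/2),
#'   `marker_geno` (per marker, named list of allele-label pairs, all
#'   individuals) and `haplotypes` (per individual, 2 x (1 + M) matrix
#'   of disease indicator and marker allele indices — the simulation
#'   truth).
#' @export
gene_drop <- function(ped, model, markers, theta, seed = NULL,
                      carrier = NULL, informative = FALSE) {
  if (!is_loop_free(ped)) stop("gene_drop requires a loop-free pedigree")
  if (!is.null(seed)) set.seed(seed)
  M <- length(markers)
  theta <- rep_len(theta, M)
  if (is.null(carrier)) carrier <- founders(ped)[1]
  if (!carrier %in% founders(ped)) stop("carrier must be a founder id")
  if (informative) {
    too_few <- vapply(markers, function(m)
      length(m$alleles) < 2 * length(founders(ped)), logical(1))
    if (any(too_few))
      stop("informative = TRUE needs >= 2 alleles per founder at every marker")
  }

  haplo <- list()  # id -> 2 x (1+M) matrix: col 1 disease (1=carrier), then markers
  for (j in seq_along(founders(ped))) {
    f <- founders(ped)[j]
    h <- matrix(0L, 2, 1 + M)
    h[, 1] <- stats::rbinom(2, 1, model$q)
    if (f == carrier) h[, 1] <- c(1L, 0L)
    for (m in seq_len(M))
      h[, 1 + m] <- if (informative) c(2L * j - 1L, 2L * j) else
        sample.int(length(markers[[m]]$alleles), 2,
                   replace = TRUE, prob = markers[[m]]$freqs)
    haplo[[f]] <- h
  }
  for (id in attr(ped, "order")) {
    i <- match(id, ped$id)
    if (is.na(ped$father[i])) next
    h <- matrix(0L, 2, 1 + M)
    for (side in 1:2) {
      p <- if (side == 1) ped$father[i] else ped$mother[i]
      ph <- haplo[[p]]
      z <- sample.int(2, 1)                      # disease-locus choice
      h[side, 1] <- ph[z, 1]
      rec <- stats::runif(M) < theta
      h[side, -1] <- ifelse(rec, ph[3 - z, -1], ph[z, -1])
    }
    haplo[[id]] <- h
  }
  n_dis <- vapply(haplo, function(h) sum(h[, 1]), 0L)[ped$id]
  pen <- unname(model$penetrance)
  p_aff <- pen[3 - n_dis]
  affection <- ifelse(stats::runif(nrow(ped)) < p_aff,
                      "affected", "unaffected")
  names(affection) <- ped$id
  marker_geno <- lapply(seq_len(M), function(m) {
    stats::setNames(lapply(ped$id, function(id)
      markers[[m]]$alleles[haplo[[id]][, 1 + m]]), ped$id)
  })
  names(marker_geno) <- vapply(markers, `[[`, "", "id")
  list(affection = affection, carrier = n_dis > 0, n_dis = n_dis,
       marker_geno = marker_geno, haplotypes = haplo[ped$id])
}

# Mendelian drop of one unlinked biallelic variant with population
# allele frequency af; returns genotype strings for all individuals.
.drop_biallelic <- function(ped, af) {
  cnt <- stats::setNames(integer(nrow(ped)), ped$id)
  hap <- list()
  for (f in founders(ped)) hap[[f]] <- stats::rbinom(2, 1, af)
  for (id in attr(ped, "order")) {
    i <- match(id, ped$id)
    if (is.na(ped$father[i])) next
    hap[[id]] <- c(hap[[ped$father[i]]][sample.int(2, 1)],
                   hap[[ped$mother[i]]][sample.int(2, 1)])
  }
  cnt[ped$id] <- vapply(hap[ped$id], sum, 0L)
  c("hom_ref", "het", "hom_alt")[cnt + 1L]
}

#' Default linked-marker panel for simulated studies
#'
#' Four microsatellite-style markers named after the informative
#' markers of a chromosome-1q disease interval, each with six
#' equifrequent alleles (heterozygosity 5/6, comfortably above the 60%
#' informativeness rule of thumb for linkage panels).
#'
#' @return List of [marker_def()].
#' @export
default_marker_panel <- function() {
  lapply(c("D1S2655", "D1S2891", "D1S2629", "D1S229"),
         function(id) marker_def(id, alleles = as.character(1:6)))
}

#' Default annotation profile of the planted causal variant
#'
#' A novel heterozygous missense substitution in an apoptosis-regulator
#' gene on chromosome 1q: `p.Val37Met` (Grantham 21), phyloP 4.135,
#' absent from all population databases, the in-house cohort and the
#' control cohort.
#'
#' @return Named list of annotation fields.
#' @export
default_causal_spec <- function() {
  list(chrom = "1", pos = 223967455L, ref = "G", alt = "A",
       gene = "TP53BP2", transcript = "NM_001031685",
       cdna_change = "c.109G>A", protein_change = "p.Val37Met",
       consequence = "nonsynonymous", phylop = 4.135)
}

#' Simulate a complete family exome study
#'
#' Generates, deterministically per seed, the four inputs of the
#' prioritization pipeline for a multiplex family:
#' \enumerate{
#'   \item a PED file for `ped`;
#'   \item an annotated multi-sample VCF holding `n_background`
#'     Mendelian-dropped background variants plus one causal variant
#'     gene-dropped on a founder haplotype, with genotypes for every
#'     `genotyped` member;
#'   \item marker genotypes for the linked panel, co-dropped with the
#'     causal variant at the given recombination fractions;
#'   \item a control-cohort carrier table (the causal variant has zero
#'     control carriers).
#' }
#' Background allele frequencies follow a two-component spectrum: 70%
#' common (AF ~ U(0.01, 0.5), present in all population sources) and
#' 30% rare (AF ~ U(0, 0.005), half of them novel); background phyloP
#' is U(-2, 7), so both score-filter arms are exercised. With
#' `match_affection = TRUE` (default) the causal gene drop is
#' rejection-sampled until the simulated affection of members with
#' known phenotype reproduces the pedigree's affection pattern, i.e.
#' genotypes are simulated conditional on the observed phenotypes.
#'
#' @param ped A loop-free [pedigree()] (default [example_family()]).
#' @param model A [genetic_model()] generating affections.
#' @param n_background Number of background variants (default 200).
#' @param markers Linked marker panel (default [default_marker_panel()]).
#' @param theta Disease-marker recombination fraction(s) (default 0:
#'   markers inside the disease haplotype block).
#' @param causal Causal-variant annotation (default
#'   [default_causal_spec()]).
#' @param n_controls Control cohort size (default 180).
#' @param seed Integer seed (required for reproducibility).
#' @param dir Output directory (created if needed).
#' @param match_affection Condition the causal drop on the pedigree's
#'   affection pattern (default `TRUE`).
#' @param carrier Carrier founder id (default first founder).
#' @return List with `paths` (vcf, ped, markers, controls), `truth`
#'   (causal key, carrier states, gene-drop result) and `samples`
#'   (typed ids in the VCF).
#' @export
simulate_study <- function(ped = example_family(), model = genetic_model(),
                           n_background = 200,
                           markers = default_marker_panel(), theta = 0,
                           causal = default_causal_spec(),
                           n_controls = 180, seed = 1,
                           dir = tempfile("simstudy"),
                           match_affection = TRUE, carrier = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  known <- ped$affection != "unknown"

  drop <- NULL
  for (try in seq_len(1e5)) {
    cand <- gene_drop(ped, model, markers, theta, seed = NULL,
                      carrier = carrier)
    if (!match_affection ||
        all(cand$affection[known] == ped$affection[known])) {
      drop <- cand
      break
    }
  }
  if (is.null(drop))
    stop("could not match the pedigree affection pattern in 1e5 gene ",
         "drops; is the pattern compatible with the model?")
  if (!match_affection) {
    ped$affection <- unname(drop$affection)
  }

  samples <- ped$id[ped$genotyped]
  af_sources <- c("AF_DBSNP", "AF_EVS", "AF_G1K")

  n_common <- stats::rbinom(1, n_background, 0.7)
  af <- c(stats::runif(n_common, 0.01, 0.5),
          stats::runif(n_background - n_common, 0, 0.005))
  af <- sample(af)
  novel <- af <= 0.005 & stats::runif(n_background) < 0.5
  cons_pool <- c("nonsynonymous", "synonymous", "canonical_splice", "utr",
                 "intronic", "intergenic", "other")
  cons <- sample(cons_pool, n_background, replace = TRUE,
                 prob = c(0.35, 0.20, 0.03, 0.10, 0.20, 0.10, 0.02))
  aa <- grantham_properties$residue
  prot <- ifelse(cons == "nonsynonymous",
                 format_protein_change(sample(aa, n_background, TRUE),
                                       sample.int(800, n_background, TRUE),
                                       sample(aa, n_background, TRUE)),
                 NA_character_)
  prot[cons == "nonsynonymous" &
         substr(prot, 3, 5) == substr(prot, nchar(prot) - 2, nchar(prot))] <-
    NA  # degenerate same-residue draws: drop the annotation
  cons[cons == "nonsynonymous" & is.na(prot)] <- "other"
  inhouse <- ifelse(stats::runif(n_background) < 0.05,
                    stats::runif(n_background, 0.006, 0.05),
                    stats::runif(n_background, 0, 0.004))
  variants <- data.frame(
    chrom = as.character(sample.int(22, n_background, TRUE)),
    pos = sample.int(2e8, n_background),
    ref = sample(c("A", "C", "G", "T"), n_background, TRUE),
    alt = rep(NA_character_, n_background),
    gene = sprintf("GENE%04d", seq_len(n_background)),
    transcript = sprintf("NM_%06d", sample.int(999999, n_background)),
    cdna_change = sprintf("c.%dN>N", sample.int(3000, n_background, TRUE)),
    protein_change = prot,
    consequence = cons,
    phylop = stats::runif(n_background, -2, 7),
    inhouse_freq = inhouse,
    stringsAsFactors = FALSE)
  variants$alt <- vapply(variants$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  pop_af <- matrix(NA_real_, n_background, 3,
                   dimnames = list(NULL, af_sources))
  pop_af[!novel, ] <- af[!novel]
  geno <- t(vapply(seq_len(n_background),
                   function(i) .drop_biallelic(ped, af[i])[match(samples, ped$id)],
                   character(length(samples))))
  colnames(geno) <- samples

  cv <- causal
  causal_row <- data.frame(
    chrom = cv$chrom, pos = cv$pos, ref = cv$ref, alt = cv$alt,
    gene = cv$gene, transcript = cv$transcript,
    cdna_change = cv$cdna_change, protein_change = cv$protein_change,
    consequence = cv$consequence, phylop = cv$phylop,
    inhouse_freq = NA_real_, stringsAsFactors = FALSE)
  causal_geno <- ifelse(drop$n_dis[samples] >= 2, "hom_alt",
                        ifelse(drop$n_dis[samples] == 1, "het", "hom_ref"))
  variants <- rbind(variants, causal_row)
  pop_af <- rbind(pop_af, NA_real_)
  geno <- rbind(geno, causal_geno)
  ord <- order(variants$chrom, variants$pos)
  x <- variant_set(variants[ord, ], pop_af[ord, , drop = FALSE],
                   geno[ord, , drop = FALSE])
  causal_key <- paste(cv$chrom, cv$pos, cv$ref, cv$alt, sep = ":")

  # control cohort: per-variant carrier draws at the true AF; the
  # causal variant is absent from controls
  bg_rows <- which(ord <= n_background)   # x row i came from input row ord[i]
  carriers <- stats::setNames(
    stats::rbinom(length(bg_rows), n_controls,
                  1 - (1 - af[ord[bg_rows]])^2),
    variant_keys(x)[bg_rows])

  paths <- list(vcf = file.path(dir, "study.vcf"),
                ped = file.path(dir, "study.ped"),
                markers = file.path(dir, "markers.tsv"),
                controls = file.path(dir, "controls.tsv"))
  write_annotated_vcf(x, paths$vcf)
  write_ped(ped, paths$ped)
  typed_geno <- lapply(drop$marker_geno, function(g) g[samples])
  write_marker_genotypes(typed_geno, paths$markers)
  write_control_table(control_cohort(n_controls, carriers), paths$controls,
                      extra_zero_keys = causal_key)

  list(paths = paths,
       truth = list(causal_key = causal_key, drop = drop,
                    af_background = af, ped = ped),
       samples = samples)
}

#' Write / read a control-cohort carrier table
#'
#' Plain TSV with a `# n_controls: N` header comment and columns
#' `key`, `carriers`.
#'
#' @param cohort A [control_cohort()].
#' @param path Output path.
#' @param extra_zero_keys Keys to record explicitly with 0 carriers.
#' @return `path` invisibly ([write_control_table()]); a
#'   [control_cohort()] ([read_control_table()]).
#' @export
write_control_table <- function(cohort, path, extra_zero_keys = character(0)) {
  keys <- c(names(cohort$carriers), extra_zero_keys)
  cnt <- c(unname(cohort$carriers), rep(0L, length(extra_zero_keys)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# n_controls: ", cohort$n_controls),
               "key\tcarriers",
               paste(keys, cnt, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_control_table
#' @export
read_control_table <- function(path) {
  lines <- readLines(path)
  hd <- grep("^# n_controls:", lines, value = TRUE)
  if (!length(hd)) stop("control table lacks '# n_controls:' header")
  n_controls <- as.integer(sub("^# n_controls:\\s*", "", hd[1]))
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", colClasses = c("character", "integer"))
  control_cohort(n_controls, stats::setNames(tab$carriers, tab$key))
}

#' Recombination-fraction recovery experiment
#'
#' Replicates the linkage analysis on gene-dropped copies of a
#' pedigree: in each replicate the disease haplotype and a fully
#' informative marker are dropped through the pedigree at the true
#' recombination fraction `true_theta` (conditioning on the pedigree's
#' observed affection pattern, simulated with full penetrance), the
#' two-point LOD curve is computed under `model`, and the
#' maximum-likelihood theta is recorded.
#'
#' @param ped A loop-free [pedigree()] with affection statuses.
#' @param true_theta Simulated disease-marker recombination fraction.
#' @param n_rep Number of replicates.
#' @param model Analysis [genetic_model()] (default q = 1e-4, f = 0.95).
#' @param grid LOD evaluation grid (default steps of 0.05; estimates
#'   are reported at this resolution).
#' @param seed Integer seed.
#' @return Numeric vector of `n_rep` theta estimates.
#' @export
recover_theta <- function(ped, true_theta, n_rep = 100,
                          model = genetic_model(),
                          grid = seq(0, 0.5, by = 0.05), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- marker_def("INF", as.character(seq_len(2 * length(founders(ped)))))
  # simulate under a single-founder origin: a vanishing background
  # allele frequency keeps second, independent disease alleles out of
  # the non-carrier founders, so theta is the only unknown
  sim_model <- genetic_model(q = 1e-12, penetrance = c(1, 1, 0))
  known <- ped$affection != "unknown"
  typed <- ped$id[ped$genotyped]
  vapply(seq_len(n_rep), function(r) {
    for (try in seq_len(1e5)) {
      d <- gene_drop(ped, sim_model, list(mk), true_theta,
                     informative = TRUE)
      if (all(d$affection[known] == ped$affection[known])) break
    }
    lod_curve(ped, model, mk, d$marker_geno[[1]][typed],
              grid = grid)$theta_at_max
  }, numeric(1))
}
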
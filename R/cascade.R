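#' Default filtering thresholds
#'
#' Thresholds of the prioritization cascade. All comparisons are strict:
#' a variant is excluded when its maximum population allele frequency
#' exceeds `af_max` (0.5% default), kept as a candidate when its
#' Grantham score exceeds `grantham_min` OR its phyloP exceeds
#' `phylop_min`.
#'
#' @param af_max Maximum population allele fraction (default 0.005).
#' @param inhouse_max Maximum in-house cohort frequency (default 0.005).
#' @param grantham_min Grantham score threshold (default 80, strict >).
#' @param phylop_min phyloP threshold (default 2.7, strict >).
#' @param af_sources Population-frequency source keys to consult;
#'   `NULL` = all `AF_` columns present.
#' @return A named list of thresholds.
#' @export
cascade_config <- function(af_max = 0.005, inhouse_max = 0.005,
                           grantham_min = 80, phylop_min = 2.7,
                           af_sources = NULL) {
  stopifnot(af_max >= 0, af_max <= 1, inhouse_max >= 0, inhouse_max <= 1,
            is.finite(grantham_min), is.finite(phylop_min))
  list(af_max = af_max, inhouse_max = inhouse_max,
       grantham_min = grantham_min, phylop_min = phylop_min,
       af_sources = af_sources)
}

#' Variants shared by all affected individuals
#'
#' Keeps records in which every listed affected sample carries at least
#' one alternate allele (het or hom_alt). A missing genotype in any
#' affected sample excludes the record: sharing cannot be established.
#'
#' @param x A [variant_set()].
#' @param affected Sample ids of the affected individuals.
#' @return The filtered [variant_set()].
#' @export
shared_variants <- function(x, affected) {
  if (!length(affected)) stop("affected sample list is empty")
  absent <- setdiff(affected, colnames(x$geno))
  if (length(absent))
    stop("affected sample(s) without genotypes: ",
         paste(absent, collapse = ", "))
  g <- x$geno[, affected, drop = FALSE]
  keep <- rowSums(!is.na(g) & (g == "het" | g == "hom_alt")) == length(affected)
  x[keep]
}

# Row-wise max AF across the selected sources; -Inf rows (all NA) mean
# the variant is absent from every database.
.max_pop_af <- function(x, source_keys = NULL) {
  if (is.null(source_keys)) source_keys <- colnames(x$pop_af)
  unknown <- setdiff(source_keys, colnames(x$pop_af))
  if (length(unknown))
    stop("unknown population-frequency source(s): ",
         paste(unknown, collapse = ", "),
         "; available: ", paste(colnames(x$pop_af), collapse = ", "))
  af <- x$pop_af[, source_keys, drop = FALSE]
  if (!nrow(af)) return(numeric(0))
  suppressWarnings(apply(af, 1, max, na.rm = TRUE))
}

#' Exclude variants common in population databases
#'
#' Removes records whose maximum allele frequency across the selected
#' sources strictly exceeds `af_max`. Variants with no frequency
#' annotation in any source (novel variants) are retained.
#'
#' @param x A [variant_set()].
#' @param af_max Frequency threshold as a fraction (default 0.005,
#'   i.e. 0.5%).
#' @param source_keys Source columns to consult; `NULL` = all.
#' @return The filtered [variant_set()].
#' @export
filter_frequency <- function(x, af_max = 0.005, source_keys = NULL) {
  mx <- .max_pop_af(x, source_keys)
  x[!(is.finite(mx) & mx > af_max)]
}

#' Exclude variants frequent in the in-house cohort
#'
#' @param x A [variant_set()].
#' @param inhouse_max Maximum in-house carrier fraction (strict >
#'   excludes). Unannotated records are retained.
#' @return The filtered [variant_set()].
#' @export
filter_inhouse <- function(x, inhouse_max = 0.005) {
  f <- x$variants$inhouse_freq
  x[!(!is.na(f) & f > inhouse_max)]
}

#' Region/consequence filter
#'
#' Two sequential stages mirroring exome prioritization practice:
#' first retain exonic and canonical splice-site variants (dropping
#' intergenic, intronic and UTR records), then drop synonymous
#' substitutions. The survivors have consequence `nonsynonymous` or
#' `canonical_splice`.
#'
#' @param x A [variant_set()].
#' @param stage `"exonic_splice"`, `"nonsynonymous"`, or `"both"`
#'   (default) to apply the two stages in sequence.
#' @return The filtered [variant_set()].
#' @export
filter_region_consequence <- function(x, stage = c("both", "exonic_splice",
                                                   "nonsynonymous")) {
  stage <- match.arg(stage)
  cons <- x$variants$consequence
  if (stage %in% c("both", "exonic_splice"))
    x <- x[cons %in% c("nonsynonymous", "synonymous", "canonical_splice")]
  if (stage %in% c("both", "nonsynonymous"))
    x <- x[x$variants$consequence != "synonymous"]
  x
}

#' Score-based candidate flags (Grantham / phyloP arms)
#'
#' Computes, per record, the Grantham score of its protein change and
#' the pass flags of the two parallel score filters. Records without a
#' phyloP annotation fail the phyloP arm; nonsynonymous records without
#' a parseable protein change raise a warning and fail the Grantham arm.
#'
#' @param x A [variant_set()].
#' @param grantham_min,phylop_min Strict thresholds (see
#'   [cascade_config()]).
#' @return Data frame with columns `grantham` (integer or `NA`),
#'   `grantham_pass`, `phylop_pass`, `candidate` (the union).
#' @export
candidate_flags <- function(x, grantham_min = 80, phylop_min = 2.7) {
  v <- x$variants
  n <- nrow(v)
  grantham <- rep(NA_integer_, n)
  has_prot <- !is.na(v$protein_change) & v$protein_change != ""
  if (any(has_prot)) {
    pc <- parse_protein_change(v$protein_change[has_prot])
    grantham[has_prot] <- grantham_distance(pc$ref_aa, pc$alt_aa)
  }
  orphan <- v$consequence == "nonsynonymous" & !has_prot
  if (any(orphan))
    warning(sum(orphan), " nonsynonymous record(s) lack a protein change; ",
            "Grantham arm fails for: ",
            paste(variant_keys(x)[orphan], collapse = ", "))
  g_pass <- !is.na(grantham) & grantham > grantham_min
  p_pass <- !is.na(v$phylop) & v$phylop > phylop_min
  data.frame(grantham = grantham, grantham_pass = g_pass,
             phylop_pass = p_pass, candidate = g_pass | p_pass)
}

#' Select candidates by the Grantham/phyloP union rule
#'
#' Keeps records with Grantham score strictly above `grantham_min` OR
#' phyloP strictly above `phylop_min`. The two criteria are parallel
#' filters whose union forms the candidate set; a record passing either
#' arm survives.
#'
#' @inheritParams candidate_flags
#' @return The candidate [variant_set()].
#' @export
score_candidates <- function(x, grantham_min = 80, phylop_min = 2.7) {
  fl <- candidate_flags(x, grantham_min, phylop_min)
  x[fl$candidate]
}

#' Run the full variant-filtering cascade
#'
#' Applies, in order: sharing across affected samples, population
#' frequency, in-house frequency, exonic/canonical-splice, removal of
#' synonymous substitutions, then the parallel Grantham/phyloP score
#' filters whose union is the candidate set. Counts are tracked both
#' per affected sample (filters applied to the variants that sample
#' carries) and for the shared intersection.
#'
#' @param x A [variant_set()].
#' @param affected Sample ids of the affected individuals.
#' @param config A [cascade_config()].
#' @return A `cascade_report`: list with `stage_names`,
#'   `counts_per_sample` (stages x samples matrix), `counts_shared`,
#'   `survivors` (candidate [variant_set()]), and `flags`
#'   (the [candidate_flags()] of the nonsynonymous survivors).
#' @export
run_cascade <- function(x, affected, config = cascade_config()) {
  if (!length(affected)) stop("affected sample list is empty")
  absent <- setdiff(affected, colnames(x$geno))
  if (length(absent))
    stop("affected sample(s) without genotypes: ",
         paste(absent, collapse = ", "))
  seq_stages <- c("total", "pop_af", "inhouse", "exonic_splice",
                  "nonsynonymous")
  stages <- c(seq_stages, "grantham", "phylop")

  chain <- function(xs) {
    # returns list of variant_sets after each sequential stage
    out <- vector("list", length(seq_stages))
    out[[1]] <- xs
    out[[2]] <- filter_frequency(out[[1]], config$af_max, config$af_sources)
    out[[3]] <- filter_inhouse(out[[2]], config$inhouse_max)
    out[[4]] <- filter_region_consequence(out[[3]], "exonic_splice")
    out[[5]] <- filter_region_consequence(out[[4]], "nonsynonymous")
    out
  }
  arm_counts <- function(xs) {
    fl <- candidate_flags(xs, config$grantham_min, config$phylop_min)
    c(grantham = sum(fl$grantham_pass), phylop = sum(fl$phylop_pass))
  }

  per_sample <- matrix(0L, length(stages), length(affected),
                       dimnames = list(stages, affected))
  for (s in affected) {
    g <- x$geno[, s]
    carried <- chain(x[!is.na(g) & g %in% c("het", "hom_alt")])
    per_sample[seq_along(seq_stages), s] <- vapply(carried, length, 0L)
    per_sample[c("grantham", "phylop"), s] <- arm_counts(carried[[5]])
  }

  shared_chain <- chain(shared_variants(x, affected))
  counts_shared <- vapply(shared_chain, length, 0L)
  nonsyn <- shared_chain[[5]]
  fl <- candidate_flags(nonsyn, config$grantham_min, config$phylop_min)
  counts_shared <- c(counts_shared, sum(fl$grantham_pass),
                     sum(fl$phylop_pass))
  names(counts_shared) <- stages

  structure(list(stage_names = stages,
                 counts_per_sample = per_sample,
                 counts_shared = counts_shared,
                 survivors = nonsyn[fl$candidate],
                 flags = fl,
                 config = config),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Variant filtering cascade\n")
  tab <- cbind(x$counts_per_sample, shared = x$counts_shared)
  print(tab)
  cat("candidates (Grantham/phyloP union):", length(x$survivors), "\n")
  invisible(x)
}

#' Write a cascade report as TSV (stages x samples + shared)
#'
#' @param report A `cascade_report` from [run_cascade()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cascade_tsv <- function(report, path) {
  tab <- data.frame(stage = report$stage_names,
                    report$counts_per_sample,
                    shared = report$counts_shared,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a candidate table as TSV (gene/transcript/change/scores)
#'
#' One row per candidate with gene, transcript, cDNA and protein change,
#' phyloP, Grantham score and, when supplied, the segregation verdict.
#'
#' @param x Candidate [variant_set()].
#' @param path Output path.
#' @param segregation Optional logical vector (verdict per candidate).
#' @return `path`, invisibly.
#' @export
write_candidate_tsv <- function(x, path, segregation = NULL) {
  fl <- suppressWarnings(candidate_flags(x))
  tab <- data.frame(key = variant_keys(x),
                    gene = x$variants$gene,
                    transcript = x$variants$transcript,
                    cdna_change = x$variants$cdna_change,
                    protein_change = x$variants$protein_change,
                    phylop = x$variants$phylop,
                    grantham = fl$grantham,
                    stringsAsFactors = FALSE)
  if (!is.null(segregation))
    tab$segregation <- ifelse(segregation, "Yes", "No")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
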
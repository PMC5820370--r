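#' Parametric disease model
#'
#' Single-locus disease model used by segregation and linkage analysis:
#' disease allele frequency `q` and penetrances for the three disease
#' genotypes. The default is the autosomal dominant model used for
#' rare monogenic disease mapping: `q = 1e-4`, penetrance 0.95 for
#' carriers (DD and Dd) and phenocopy rate 0 for non-carriers.
#'
#' @param mode `"dominant"` or `"recessive"`.
#' @param q Disease allele frequency, in (0, 1).
#' @param penetrance Length-3 numeric `(f_DD, f_Dd, f_dd)` in \[0, 1\]:
#'   probability of being affected given 2, 1 or 0 copies of the
#'   disease allele. For `mode = "dominant"` the default is
#'   `c(f, f, 0)`; for `"recessive"`, `c(f, 0, 0)`.
#' @param f Shorthand carrier penetrance used to build the default
#'   triple (default 0.95).
#' @return An object of class `genetic_model`.
#' @examples
#' genetic_model()                      # dominant, q = 1e-4, f = 0.95
#' genetic_model(penetrance = c(1, 1, 0))
#' @export
genetic_model <- function(mode = c("dominant", "recessive"), q = 1e-4,
                          penetrance = NULL, f = 0.95) {
  mode <- match.arg(mode)
  if (!(q > 0 && q < 1)) stop("q must lie strictly in (0, 1)")
  if (is.null(penetrance))
    penetrance <- if (mode == "dominant") c(f, f, 0) else c(f, 0, 0)
  if (length(penetrance) != 3 || any(penetrance < 0 | penetrance > 1))
    stop("penetrance must be three probabilities (f_DD, f_Dd, f_dd)")
  structure(list(mode = mode, q = q,
                 penetrance = stats::setNames(penetrance,
                                              c("f_DD", "f_Dd", "f_dd"))),
            class = "genetic_model")
}

#' @export
print.genetic_model <- function(x, ...) {
  cat(sprintf("genetic_model: %s, q = %g, penetrance (DD, Dd, dd) = (%g, %g, %g)\n",
              x$mode, x$q, x$penetrance[1], x$penetrance[2], x$penetrance[3]))
  invisible(x)
}

#' Dominant co-segregation check for one variant
#'
#' A variant segregates dominantly when every typed affected individual
#' carries it (het or hom_alt) and — in strict mode — every typed
#' unaffected individual is hom_ref. Untyped members are ignored.
#' With `strict_unaffected = FALSE` unaffected carriers are tolerated
#' (incomplete penetrance) and reported in the detail table.
#'
#' @param x A [variant_set()] containing the variant.
#' @param i Row index of the variant in `x` (default 1).
#' @param ped A [pedigree()] whose typed members map to `x`'s samples by
#'   id.
#' @param strict_unaffected Require unaffected non-carriers
#'   (default `TRUE`, matching a fully penetrant reading).
#' @return List with `verdict` (logical) and `detail`, a data frame of
#'   per-individual affection, genotype and status (`"consistent"`,
#'   `"inconsistent"`, `"nonpenetrant_carrier"`, `"untyped"`).
#' @export
segregates_dominant <- function(x, ped, i = 1, strict_unaffected = TRUE) {
  g <- x$geno[i, ]
  typed <- ped$id[ped$genotyped & ped$id %in% names(g)]
  aff <- typed[ped$affection[match(typed, ped$id)] == "affected"]
  unaff <- typed[ped$affection[match(typed, ped$id)] == "unaffected"]
  if (!length(aff))
    stop("no typed affected individuals; segregation is undefined")

  carrier <- function(gt) !is.na(gt) & gt %in% c("het", "hom_alt")
  status <- stats::setNames(rep("untyped", nrow(ped)), ped$id)
  status[aff] <- ifelse(carrier(g[aff]), "consistent", "inconsistent")
  status[unaff] <- ifelse(!carrier(g[unaff]), "consistent",
                          if (strict_unaffected) "inconsistent"
                          else "nonpenetrant_carrier")
  verdict <- all(status[c(aff, unaff)] != "inconsistent")
  detail <- data.frame(id = ped$id,
                       affection = ped$affection,
                       genotype = unname(g[match(ped$id, names(g))]),
                       status = unname(status[ped$id]),
                       stringsAsFactors = FALSE)
  list(verdict = verdict, detail = detail)
}

#' Recessive candidate genes (homozygous or compound heterozygous)
#'
#' Scans variants gene by gene for patterns compatible with recessive
#' inheritance among the typed affected individuals: a single site at
#' which all affected are hom_alt, or two or more distinct sites in the
#' same gene at which all affected carry an alternate allele
#' (compound-heterozygous candidate). Phase is not inferred — with
#' unavailable parents, candidate pairs cannot be proven to lie in
#' trans, so compound-het candidates are flagged `phased = FALSE`.
#'
#' @param x A [variant_set()].
#' @param ped A [pedigree()].
#' @return A data frame with columns `gene`, `type`
#'   (`"homozygous"`/`"compound_het"`), `keys` (semicolon-joined variant
#'   keys) and `phased` (always `FALSE` for compound hets). Zero rows
#'   when no gene supports recessive inheritance.
#' @export
recessive_candidates <- function(x, ped) {
  typed <- ped$id[ped$genotyped & ped$id %in% colnames(x$geno)]
  aff <- typed[ped$affection[match(typed, ped$id)] == "affected"]
  if (!length(aff)) stop("no typed affected individuals")
  keys <- variant_keys(x)
  out <- list()
  for (gene in unique(stats::na.omit(x$variants$gene))) {
    ix <- which(!is.na(x$variants$gene) & x$variants$gene == gene)
    g <- x$geno[ix, aff, drop = FALSE]
    hom_all <- apply(g == "hom_alt" & !is.na(g), 1, all)
    for (j in which(hom_all))
      out[[length(out) + 1]] <- data.frame(
        gene = gene, type = "homozygous", keys = keys[ix[j]],
        phased = NA, stringsAsFactors = FALSE)
    carrier <- (g == "het" | g == "hom_alt") & !is.na(g)
    carried_by_all <- which(apply(carrier, 1, all))
    if (length(carried_by_all) >= 2) {
      het_sites <- carried_by_all[apply(
        g[carried_by_all, , drop = FALSE] == "het", 1, any)]
      if (length(het_sites) >= 2)
        out[[length(out) + 1]] <- data.frame(
          gene = gene, type = "compound_het",
          keys = paste(keys[ix[het_sites]], collapse = ";"),
          phased = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), type = character(),
                      keys = character(), phased = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Control cohort of carrier counts
#'
#' @param n_controls Number of population-matched control individuals.
#' @param carriers Named integer vector: variant key
#'   (`chrom:pos:ref:alt`) to carrier count. Variants absent from the
#'   table are treated as 0 carriers (with a note).
#' @return An object of class `control_cohort`.
#' @export
control_cohort <- function(n_controls, carriers = integer(0)) {
  if (n_controls <= 0) stop("n_controls must be positive")
  carriers <- stats::setNames(as.integer(carriers), names(carriers))
  if (any(carriers < 0 | carriers > n_controls))
    stop("carrier counts must lie in [0, n_controls]")
  structure(list(n_controls = as.integer(n_controls),
                 carriers = carriers),
            class = "control_cohort")
}

#' Screen a variant against a control cohort
#'
#' Returns the number of control carriers; the prioritization pipeline
#' retains a variant only when the count does not exceed `max_carriers`
#' (default 0: absent from all controls).
#'
#' @param x A [variant_set()].
#' @param cohort A [control_cohort()].
#' @param i Row index of the variant (default all rows, vectorised).
#' @param max_carriers Maximum tolerated carrier count (default 0).
#' @return Data frame with `key`, `carriers`, `retained`.
#' @export
control_screen <- function(x, cohort, i = seq_len(length(x)),
                           max_carriers = 0) {
  keys <- variant_keys(x)[i]
  cnt <- cohort$carriers[keys]
  unseen <- is.na(cnt)
  if (any(unseen)) {
    message("control cohort has no entry for ",
            paste(keys[unseen], collapse = ", "), "; treated as 0 carriers")
    cnt[unseen] <- 0L
  }
  data.frame(key = keys, carriers = as.integer(cnt),
             retained = as.integer(cnt) <= max_carriers,
             stringsAsFactors = FALSE)
}

#' Write a segregation report as TSV
#'
#' Variant-by-individual genotype matrix with the dominant verdict.
#'
#' @param x A [variant_set()].
#' @param ped A [pedigree()].
#' @param path Output path.
#' @param strict_unaffected Passed to [segregates_dominant()].
#' @return `path`, invisibly.
#' @export
write_segregation_tsv <- function(x, ped, path, strict_unaffected = TRUE) {
  verdicts <- vapply(seq_len(length(x)), function(i)
    segregates_dominant(x, ped, i, strict_unaffected)$verdict, logical(1))
  tab <- data.frame(key = variant_keys(x), x$geno,
                    segregates = ifelse(verdicts, "Yes", "No"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
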
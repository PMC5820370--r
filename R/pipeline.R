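#' End-to-end prioritization and linkage pipeline
#'
#' Orchestrates the full analysis on file inputs: read the pedigree and
#' annotated VCF, run the filtering cascade over the affected samples,
#' check dominant segregation of every cascade survivor across the
#' whole family, screen survivors against the control cohort, and — for
#' the variants that pass all three — compute two-point LOD curves for
#' the supplied markers. Reports are written as plain TSV/JSON for
#' diffability; every row carries the `chrom:pos:ref:alt` key of its
#' input record.
#'
#' @param vcf Path to the annotated multi-sample VCF.
#' @param ped Path to the 6-column PED file.
#' @param markers Path to a marker-genotype TSV
#'   (see [read_marker_genotypes()]), or `NULL` to skip linkage.
#' @param controls Path to a control carrier table
#'   (see [read_control_table()]), or `NULL` to skip the screen.
#' @param out_dir Output directory for report files.
#' @param affected Sample ids forming the sharing intersection;
#'   default: all typed affected pedigree members present in the VCF.
#' @param config Cascade thresholds, a [cascade_config()].
#' @param model Disease model for linkage, a [genetic_model()].
#' @param marker_defs Named list of [marker_def()] for the markers in
#'   the TSV; default: one marker per id with equifrequent alleles as
#'   observed in the data.
#' @param strict_unaffected Passed to [segregates_dominant()].
#' @param theta_grid LOD evaluation grid.
#' @return Invisibly, a list with the report `paths`, the
#'   `cascade` report, `candidates` (final [variant_set()]), the
#'   segregation verdicts and the `lod` results.
#' @export
run_all <- function(vcf, ped, markers = NULL, controls = NULL,
                    out_dir = ".", affected = NULL,
                    config = cascade_config(), model = genetic_model(),
                    marker_defs = NULL, strict_unaffected = TRUE,
                    theta_grid = seq(0, 0.5, by = 0.01)) {
  for (p in c(vcf, ped, markers, controls))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pedigree <- read_ped(ped)
  x <- read_annotated_vcf(vcf)
  if (is.null(affected)) {
    affected <- intersect(
      pedigree$id[pedigree$genotyped & pedigree$affection == "affected"],
      colnames(x$geno))
    if (!length(affected))
      stop("no typed affected pedigree members among the VCF samples")
  }

  message("cascade: ", length(x), " variants, ", length(affected),
          " affected samples")
  report <- run_cascade(x, affected, config)
  write_cascade_tsv(report, file.path(out_dir, "cascade.tsv"))

  surv <- report$survivors
  seg <- vapply(seq_len(length(surv)), function(i)
    segregates_dominant(surv, pedigree, i, strict_unaffected)$verdict,
    logical(1))
  write_segregation_tsv(surv, pedigree, file.path(out_dir, "segregation.tsv"),
                        strict_unaffected)
  message("segregation: ", sum(seg), " of ", length(surv),
          " candidates segregate")

  keep <- seg
  screen <- NULL
  if (!is.null(controls) && length(surv)) {
    cohort <- read_control_table(controls)
    screen <- suppressMessages(control_screen(surv, cohort))
    keep <- keep & screen$retained
    message("control screen: ", sum(screen$retained), " of ",
            length(surv), " absent from ", cohort$n_controls, " controls")
  }
  candidates <- surv[keep]
  write_candidate_tsv(surv, file.path(out_dir, "candidates.tsv"),
                      segregation = seg)

  lod <- list()
  if (!is.null(markers)) {
    geno <- read_marker_genotypes(markers)
    for (mk_id in names(geno)) {
      mk <- if (!is.null(marker_defs) && mk_id %in% names(marker_defs)) {
        marker_defs[[mk_id]]
      } else {
        obs <- sort(unique(unlist(geno[[mk_id]])))
        # a monomorphic typed marker still needs a second allele class
        if (length(obs) < 2) obs <- c(obs, ".other")
        marker_def(mk_id, alleles = obs)
      }
      lod[[mk_id]] <- lod_curve(pedigree, model, mk, geno[[mk_id]],
                                grid = theta_grid)
      message(sprintf("linkage %s: max LOD %.3f at theta = %g", mk_id,
                      lod[[mk_id]]$max_lod, lod[[mk_id]]$theta_at_max))
    }
    ceiling_lod <- max_pedigree_lod(pedigree, model, grid = theta_grid)
    jsonlite::write_json(
      c(lapply(lod, function(l) list(theta = l$theta_grid, lod = l$lod,
                                     max_lod = l$max_lod,
                                     theta_at_max = l$theta_at_max)),
        list(pedigree_ceiling = list(max_lod = ceiling_lod$max_lod,
                                     theta_at_max = ceiling_lod$theta_at_max))),
      file.path(out_dir, "lod.json"), auto_unbox = TRUE, digits = NA)
  }

  paths <- list(cascade = file.path(out_dir, "cascade.tsv"),
                candidates = file.path(out_dir, "candidates.tsv"),
                segregation = file.path(out_dir, "segregation.tsv"),
                lod = if (!is.null(markers)) file.path(out_dir, "lod.json"))
  invisible(list(paths = paths, cascade = report, candidates = candidates,
                 segregation = seg, screen = screen, lod = lod))
}
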
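#' Marker definition
#'
#' A multiallelic (microsatellite-style) marker locus: allele labels and
#' their population frequencies. Equifrequent alleles by default —
#' appropriate when published frequencies are unavailable.
#'
#' @param id Marker label (e.g. `"D1S2655"`).
#' @param alleles Character vector of at least two allele labels.
#' @param freqs Allele frequencies summing to 1 (tolerance 1e-9);
#'   default equifrequent.
#' @return An object of class `marker_def`.
#' @export
marker_def <- function(id, alleles, freqs = NULL) {
  alleles <- as.character(alleles)
  if (length(alleles) < 2) stop("a marker needs at least 2 alleles")
  if (anyDuplicated(alleles)) stop("duplicate allele labels")
  if (is.null(freqs)) freqs <- rep(1 / length(alleles), length(alleles))
  if (length(freqs) != length(alleles))
    stop("freqs must match alleles in length")
  if (abs(sum(freqs) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  if (any(freqs < 0)) stop("allele frequencies must be non-negative")
  structure(list(id = id, alleles = alleles, freqs = freqs),
            class = "marker_def")
}

# ---- two-locus genotype state space -------------------------------------
#
# Haplotype = (disease allele, marker allele); disease alleles are
# 1 = "D" (disease) and 2 = "d" (wild type); marker alleles 1..k.
# Haplotype index h = (d - 1) * k + m, 1..2k.
# Ordered genotype = (paternal haplotype, maternal haplotype);
# index g = (hp - 1) * 2k + hm, 1..(2k)^2.
.two_locus_space <- function(k) {
  twok <- 2L * k
  G <- twok * twok
  g <- seq_len(G)
  hp <- (g - 1L) %/% twok + 1L
  hm <- (g - 1L) %% twok + 1L
  d_of <- function(h) (h - 1L) %/% k + 1L
  m_of <- function(h) (h - 1L) %% k + 1L
  list(k = as.integer(k), twok = twok, G = G, hp = hp, hm = hm,
       dp = d_of(hp), mp = m_of(hp), dm = d_of(hm), mm = m_of(hm),
       nD = (d_of(hp) == 1L) + (d_of(hm) == 1L))
}

.hap_index <- function(d, m, k) (d - 1L) * k + m

# Gamete distribution: Tr[g, h] = P(transmit haplotype h | parent
# ordered genotype g). Parental haplotypes pass intact with prob
# (1-theta)/2 each; the two recombinant disease-marker combinations get
# theta/2 each.
.transmission <- function(sp, theta) {
  Tr <- matrix(0, sp$G, sp$twok)
  combos <- list(
    list(d = sp$dp, m = sp$mp, p = (1 - theta) / 2),
    list(d = sp$dm, m = sp$mm, p = (1 - theta) / 2),
    list(d = sp$dp, m = sp$mm, p = theta / 2),
    list(d = sp$dm, m = sp$mp, p = theta / 2))
  for (cb in combos) {
    idx <- cbind(seq_len(sp$G), .hap_index(cb$d, cb$m, sp$k))
    Tr[idx] <- Tr[idx] + cb$p
  }
  Tr
}

# Genotype states compatible with an observed unordered marker pair
# (allele indices); NULL/NA = untyped -> all states.
.marker_support <- function(sp, pair) {
  if (is.null(pair) || any(is.na(pair))) return(seq_len(sp$G))
  a <- pair[1]; b <- pair[2]
  which((sp$mp == a & sp$mm == b) | (sp$mp == b & sp$mm == a))
}

# Phenotype factor over all G states: penetrance for affected,
# complement for unaffected, 1 for unknown.
.penetrance_vec <- function(sp, affection, pen) {
  f <- pen[3L - sp$nD]                # nD = 2 -> f_DD, 1 -> f_Dd, 0 -> f_dd
  switch(affection,
         affected = f,
         unaffected = 1 - f,
         unknown = rep(1, sp$G))
}

# Founder prior under linkage equilibrium.
.founder_prior <- function(sp, q, mfreq) {
  dis <- c(q, 1 - q)
  ph <- dis[c(rep(1L, sp$k), rep(2L, sp$k))] * rep(mfreq, 2L)
  ph[.hap_index(sp$dp, sp$mp, sp$k)] * ph[.hap_index(sp$dm, sp$mm, sp$k)]
}

# Convert a user genotype list (named by individual, values = character
# or numeric allele pairs) to allele-index pairs.
.index_genotypes <- function(geno, marker, ped) {
  if (is.null(geno)) return(list())
  unknown_ids <- setdiff(names(geno), ped$id)
  if (length(unknown_ids))
    stop("marker genotypes for unknown individual(s): ",
         paste(unknown_ids, collapse = ", "))
  out <- lapply(geno, function(pair) {
    if (is.null(pair) || all(is.na(pair))) return(NULL)
    if (length(pair) != 2) stop("marker genotypes must be allele pairs")
    ix <- match(as.character(pair), marker$alleles)
    if (any(is.na(ix)))
      stop("allele(s) not in marker '", marker$id, "': ",
           paste(pair[is.na(ix)], collapse = ", "))
    ix
  })
  out[!vapply(out, is.null, logical(1))]
}

# ---- factor algebra for peeling -----------------------------------------

# A factor is list(vars, arr) where arr's dims follow vars and each
# variable's extent is the individual's support size.
.factor_join <- function(f1, f2, dims_all) {
  vars <- union(f1$vars, f2$vars)
  u_dims <- unname(dims_all[vars])
  lin_index <- function(f) {
    df <- unname(dims_all[f$vars])
    stride <- cumprod(c(1, df[-length(df)]))
    tmpl <- array(0, dim = u_dims)
    acc <- tmpl
    for (j in seq_along(f$vars)) {
      p <- match(f$vars[j], vars)
      acc <- acc + (slice.index(tmpl, p)) * stride[j] - stride[j]
    }
    acc + 1
  }
  arr <- as.vector(f1$arr)[lin_index(f1)] * as.vector(f2$arr)[lin_index(f2)]
  dim(arr) <- u_dims
  list(vars = vars, arr = arr)
}

.factor_marginalize <- function(f, v, dims_all) {
  p <- match(v, f$vars)
  rest <- setdiff(seq_along(f$vars), p)
  a <- aperm(array(f$arr, unname(dims_all[f$vars])), c(p, rest))
  dv <- dims_all[[v]]
  summed <- colSums(matrix(a, nrow = dv))
  new_vars <- f$vars[rest]
  if (!length(new_vars)) return(list(vars = character(0), arr = sum(summed)))
  dim(summed) <- unname(dims_all[new_vars])
  list(vars = new_vars, arr = summed)
}

# Variable elimination with a greedy smallest-join heuristic. Returns
# the natural-log likelihood (-Inf for an impossible configuration).
.eliminate_all <- function(factors, dims_all) {
  logscale <- 0
  absorb_scalars <- function() {
    is_scalar <- vapply(factors, function(f) length(f$vars) == 0, logical(1))
    for (f in factors[is_scalar]) {
      if (f$arr <= 0) logscale <<- -Inf else logscale <<- logscale + log(f$arr)
    }
    factors <<- factors[!is_scalar]
  }
  absorb_scalars()
  vars_left <- names(dims_all)
  while (length(vars_left) && is.finite(logscale)) {
    cost <- vapply(vars_left, function(v) {
      touching <- Filter(function(f) v %in% f$vars, factors)
      u <- unique(unlist(lapply(touching, `[[`, "vars")))
      prod(dims_all[u])
    }, numeric(1))
    v <- vars_left[which.min(cost)]
    touching <- vapply(factors, function(f) v %in% f$vars, logical(1))
    fs <- factors[touching]
    joined <- fs[[1]]
    for (f in fs[-1]) joined <- .factor_join(joined, f, dims_all)
    marg <- .factor_marginalize(joined, v, dims_all)
    m <- max(marg$arr)
    if (m <= 0 || !is.finite(m)) { logscale <- -Inf; break }
    marg$arr <- marg$arr / m
    logscale <- logscale + log(m)
    factors <- c(factors[!touching], list(marg))
    vars_left <- setdiff(vars_left, v)
    absorb_scalars()
  }
  if (!is.finite(logscale)) return(-Inf)
  absorb_scalars()
  logscale
}

# Shared setup: supports, evidence vectors and factor list for a
# pedigree / model / marker / genotype configuration.
.two_locus_setup <- function(ped, model, marker, geno, theta) {
  if (theta < 0 || theta > 0.5) stop("theta must lie in [0, 0.5]")
  sp <- .two_locus_space(length(marker$alleles))
  gidx <- .index_genotypes(geno, marker, ped)
  supports <- lapply(ped$id, function(id) .marker_support(sp, gidx[[id]]))
  names(supports) <- ped$id
  pen <- unname(model$penetrance)
  evid <- lapply(seq_len(nrow(ped)), function(i) {
    w <- .penetrance_vec(sp, ped$affection[i], pen)
    w[supports[[i]]]
  })
  names(evid) <- ped$id
  prior_full <- .founder_prior(sp, model$q, marker$freqs)
  Tr <- .transmission(sp, theta)
  list(sp = sp, supports = supports, evid = evid, prior = prior_full,
       Tr = Tr)
}

#' Exact two-locus pedigree log-likelihood by peeling
#'
#' Computes the joint likelihood of affection statuses and marker
#' genotypes for a loop-free pedigree under a two-locus model: a
#' biallelic disease locus with parametric penetrances
#' ([genetic_model()]) linked at recombination fraction `theta` to a
#' multiallelic marker. The sum runs over ordered two-locus genotypes
#' (haplotype pairs). Founder haplotype priors assume linkage
#' equilibrium; each meiosis transmits a parental haplotype with
#' probability (1-theta)/2 and each recombinant with theta/2; affected
#' individuals contribute their genotype's penetrance, unaffected its
#' complement, unknown 1; typed individuals constrain the marker part,
#' untyped individuals are summed over. Evaluation is by
#' Elston-Stewart-style variable elimination (peeling), linear in the
#' number of nuclear families for chain-like pedigrees.
#'
#' @param ped A loop-free [pedigree()].
#' @param model A [genetic_model()].
#' @param marker A [marker_def()].
#' @param geno Named list: individual id to unordered allele pair
#'   (labels from `marker$alleles`); omit or `NA` for untyped members.
#' @param theta Recombination fraction in \[0, 0.5\].
#' @return Natural-log likelihood; `-Inf` when the data are impossible
#'   under the model (never an error).
#' @seealso [brute_force_likelihood()] for the enumeration oracle,
#'   [lod_curve()] for LOD scores.
#' @export
two_locus_likelihood <- function(ped, model, marker, geno, theta) {
  if (!is_loop_free(ped))
    stop("pedigree contains loops; peeling unsupported — use ",
         "brute_force_likelihood() on small pedigrees")
  st <- .two_locus_setup(ped, model, marker, geno, theta)
  dims_all <- vapply(st$supports, length, 0L)
  factors <- list()
  fdr <- is_founder(ped)
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (fdr[i]) {
      arr <- st$prior[st$supports[[id]]] * st$evid[[id]]
      dim(arr) <- length(arr)
      factors[[length(factors) + 1]] <- list(vars = id, arr = arr)
    } else {
      fa <- ped$father[i]; mo <- ped$mother[i]
      sc <- st$supports[[id]]; sf <- st$supports[[fa]]; sm <- st$supports[[mo]]
      nc <- length(sc); nf <- length(sf); nm <- length(sm)
      # arr[child, father, mother] =
      #   Tr[gF, pat(gc)] * Tr[gM, mat(gc)] * evidence(gc)
      A <- t(st$Tr[sf, st$sp$hp[sc], drop = FALSE])   # nc x nf
      B <- t(st$Tr[sm, st$sp$hm[sc], drop = FALSE])   # nc x nm
      arr <- array(A * st$evid[[id]], c(nc, nf, nm)) *
        aperm(array(B, c(nc, nm, nf)), c(1, 3, 2))
      factors[[length(factors) + 1]] <- list(vars = c(id, fa, mo), arr = arr)
    }
  }
  .eliminate_all(factors, dims_all)
}

#' Exhaustive two-locus likelihood (testing oracle)
#'
#' Computes the same likelihood as [two_locus_likelihood()] by direct
#' summation over every combination of marker-compatible ordered
#' two-locus genotypes across all individuals — exponential in pedigree
#' size, usable only on small problems, and deliberately independent of
#' the peeling code path.
#'
#' @inheritParams two_locus_likelihood
#' @param max_configs Refuse (with a size estimate) beyond this many
#'   genotype configurations (default 1e7).
#' @return Natural-log likelihood (`-Inf` for impossible data).
#' @export
brute_force_likelihood <- function(ped, model, marker, geno, theta,
                                   max_configs = 1e7) {
  st <- .two_locus_setup(ped, model, marker, geno, theta)
  sizes <- vapply(st$supports, length, 0L)
  n_conf <- prod(sizes)
  if (n_conf > max_configs)
    stop("enumeration would visit ", format(n_conf, big.mark = ","),
         " configurations (> max_configs = ", format(max_configs), ")")
  n <- nrow(ped)
  N <- as.integer(n_conf)
  # column j cycles through the support of individual j
  conf <- matrix(0L, N, n)
  rep_block <- 1L
  for (j in seq_len(n)) {
    conf[, j] <- st$supports[[j]][
      ((seq_len(N) - 1L) %/% rep_block) %% sizes[j] + 1L]
    rep_block <- rep_block * sizes[j]
  }
  colnames(conf) <- ped$id
  terms <- rep(1, N)
  fdr <- is_founder(ped)
  for (j in seq_len(n)) {
    id <- ped$id[j]
    ev <- st$evid[[id]][match(conf[, j], st$supports[[id]])]
    terms <- terms * ev
    if (fdr[j]) {
      terms <- terms * st$prior[conf[, j]]
    } else {
      gf <- conf[, ped$father[j]]; gm <- conf[, ped$mother[j]]
      terms <- terms * st$Tr[cbind(gf, st$sp$hp[conf[, j]])] *
        st$Tr[cbind(gm, st$sp$hm[conf[, j]])]
    }
  }
  L <- sum(terms)
  if (L <= 0) -Inf else log(L)
}

#' LOD-score curve over a recombination-fraction grid
#'
#' LOD(theta) = log10 L(theta) - log10 L(0.5). At theta = 0.5 the
#' disease and marker segregate independently, so LOD(0.5) = 0 exactly.
#' The maximum is reported with ties broken toward smaller theta.
#'
#' @inheritParams two_locus_likelihood
#' @param grid Recombination fractions to evaluate (default 0 to 0.5 in
#'   steps of 0.01).
#' @param engine `"peeling"` (default) or `"brute"` (enumeration; for
#'   small pedigrees and cross-checks).
#' @return An object of class `lod_result`: list with `theta_grid`,
#'   `lod`, `max_lod`, `theta_at_max`.
#' @export
lod_curve <- function(ped, model, marker, geno,
                      grid = seq(0, 0.5, by = 0.01),
                      engine = c("peeling", "brute")) {
  engine <- match.arg(engine)
  llfun <- if (engine == "peeling") two_locus_likelihood
           else brute_force_likelihood
  ll_half <- llfun(ped, model, marker, geno, 0.5)
  lod <- vapply(grid, function(th) {
    if (th == 0.5) return(0)   # identical likelihood cancels exactly
    ll <- llfun(ped, model, marker, geno, th)
    (ll - ll_half) / log(10)
  }, numeric(1))
  max_lod <- max(lod)
  structure(list(theta_grid = grid, lod = lod, max_lod = max_lod,
                 theta_at_max = grid[which.max(lod)]),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("lod_result: max LOD %.4f at theta = %g (%d grid points)\n",
              x$max_lod, x$theta_at_max, length(x$theta_grid)))
  invisible(x)
}

# Build the maximally informative co-segregating marker for a pedigree:
# every founder carries two globally unique equifrequent alleles; the
# disease haplotype is tagged by one allele of the carrier founder and
# transmitted to exactly the affected descendants.
.informative_marker <- function(ped, carrier = NULL) {
  fdr_ids <- founders(ped)
  k <- 2L * length(fdr_ids)
  alleles <- as.character(seq_len(k))
  marker <- marker_def("MAXINF", alleles)
  hap <- list()   # id -> c(paternal allele, maternal allele) indices
  car <- list()   # id -> c(pat is disease hap, mat is disease hap)
  if (is.null(carrier)) {
    # founder whose descendants include the most affected individuals
    n_aff_desc <- vapply(fdr_ids, function(f) {
      desc <- f
      repeat {
        more <- ped$id[ped$father %in% desc | ped$mother %in% desc]
        if (all(more %in% desc)) break
        desc <- union(desc, more)
      }
      sum(ped$affection[match(setdiff(desc, f), ped$id)] == "affected")
    }, 0L)
    carrier <- fdr_ids[which.max(n_aff_desc)]
  }
  for (j in seq_along(fdr_ids)) {
    id <- fdr_ids[j]
    hap[[id]] <- c(2L * j - 1L, 2L * j)
    car[[id]] <- c(id == carrier, FALSE)
  }
  for (id in attr(ped, "order")) {
    i <- match(id, ped$id)
    if (is.na(ped$father[i])) next
    pat <- mat <- NA_integer_; patc <- matc <- FALSE
    for (side in 1:2) {
      p <- if (side == 1) ped$father[i] else ped$mother[i]
      ph <- hap[[p]]; pc <- car[[p]]
      if (any(pc)) {
        want <- ped$affection[i] == "affected"
        pick <- if (want) which(pc)[1] else which(!pc)[1]
      } else pick <- 1L
      if (side == 1) { pat <- ph[pick]; patc <- pc[pick] }
      else { mat <- ph[pick]; matc <- pc[pick] }
    }
    hap[[id]] <- c(pat, mat); car[[id]] <- c(patc, matc)
  }
  geno <- lapply(hap[ped$id[ped$genotyped]],
                 function(h) alleles[h])
  list(marker = marker, geno = geno,
       carrier_states = vapply(car, any, logical(1))[ped$id])
}

#' Structural maximum LOD of a pedigree
#'
#' The ceiling a two-point LOD score can reach given only the pedigree
#' structure and affection pattern: a synthetic fully informative
#' marker (two globally unique equifrequent alleles per founder) is
#' made to co-segregate perfectly with affection under the dominant
#' model, and its LOD curve is evaluated. This is the quantity quoted
#' when an observed suggestive score is said to equal "the maximum LOD
#' attainable for this pedigree".
#'
#' Assumes the affection pattern is compatible with a dominant variant
#' descending from a single founder; marker genotypes are assigned only
#' to `genotyped` members.
#'
#' @inheritParams lod_curve
#' @param carrier Founder id to carry the disease haplotype; default
#'   the founder with the most affected descendants.
#' @return A `lod_result` (see [lod_curve()]).
#' @export
max_pedigree_lod <- function(ped, model = genetic_model(),
                             grid = seq(0, 0.5, by = 0.01),
                             carrier = NULL) {
  im <- .informative_marker(ped, carrier)
  lod_curve(ped, model, im$marker, im$geno, grid)
}

#' Shared parental haplotype in a sibship with untyped parents
#'
#' For a single sibship whose parents are unavailable, enumerates the
#' parental marker-haplotype configurations consistent with Mendelian
#' transmission, marker by marker, and reports the markers at which all
#' affected siblings can have received one same parental haplotype
#' while every unaffected sibling can have avoided it — the
#' disease-associated shared segment.
#'
#' All configurations consistent with the data are retained (for two
#' siblings and a fully informative marker both phase assignments are
#' returned); a marker with no consistent configuration raises an
#' error, which in practice signals a genotyping error.
#'
#' @param markers List of [marker_def()].
#' @param geno List (parallel to `markers`) of named lists: individual
#'   id to allele pair.
#' @param ped A [pedigree()] consisting of one sibship (two founder
#'   parents plus their children).
#' @return List with `shared_markers` (character), `assignment` (data
#'   frame: sibling id, affection, `shares` — carries the shared
#'   haplotype at every shared marker), and `configurations` (per
#'   marker, the list of consistent parental haplotype assignments).
#' @export
sibship_shared_haplotype <- function(markers, geno, ped) {
  fams <- nuclear_families(ped)
  if (length(fams) != 1)
    stop("expected a single sibship (one nuclear family), found ",
         length(fams))
  kids <- fams[[1]]$children
  aff <- kids[ped$affection[match(kids, ped$id)] == "affected"]
  unaff <- kids[ped$affection[match(kids, ped$id)] == "unaffected"]

  per_marker <- lapply(seq_along(markers), function(mi) {
    mk <- markers[[mi]]
    gidx <- .index_genotypes(geno[[mi]], mk, ped)
    typed_kids <- intersect(kids, names(gidx))
    obs <- lapply(gidx[typed_kids], sort)
    alleles_seen <- sort(unique(unlist(obs)))
    # Enumerate parental haplotype assignments (F1, F2, M1, M2) over the
    # alleles observed in the sibship; within-parent order is fixed
    # F1 <= F2, M1 <= M2 (haplotype labels within a parent carry no
    # information).
    dom <- alleles_seen
    grid <- expand.grid(F1 = dom, F2 = dom, M1 = dom, M2 = dom,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[grid$F1 <= grid$F2 & grid$M1 <= grid$M2, , drop = FALSE]
    configs <- list()
    for (r in seq_len(nrow(grid))) {
      pa <- as.integer(grid[r, ])
      # mask positions: (F1,M1), (F1,M2), (F2,M1), (F2,M2)
      masks <- lapply(obs, function(pr) {
        c(all(sort(c(pa[1], pa[3])) == pr),
          all(sort(c(pa[1], pa[4])) == pr),
          all(sort(c(pa[2], pa[3])) == pr),
          all(sort(c(pa[2], pa[4])) == pr))
      })
      if (all(vapply(masks, any, logical(1))))
        configs[[length(configs) + 1]] <- list(
          father = mk$alleles[pa[1:2]], mother = mk$alleles[pa[3:4]],
          masks = masks)
    }
    if (!length(configs))
      stop("no Mendelian-consistent parental configuration for marker '",
           mk$id, "' — check for genotyping errors")
    # does some configuration put one parental haplotype in every
    # affected and allow every unaffected to avoid it?
    slot_of <- list(F1 = c(1, 2), F2 = c(3, 4), M1 = c(1, 3), M2 = c(2, 4))
    supports <- FALSE
    for (cf in configs) {
      for (s in names(slot_of)) {
        uses <- slot_of[[s]]
        aff_ok <- all(vapply(intersect(aff, names(cf$masks)), function(kid)
          any(cf$masks[[kid]][uses]), logical(1)))
        unaff_ok <- all(vapply(intersect(unaff, names(cf$masks)), function(kid)
          any(cf$masks[[kid]][-uses]), logical(1)))
        if (aff_ok && unaff_ok &&
            length(intersect(aff, names(cf$masks))) > 0) {
          supports <- TRUE
        }
      }
    }
    list(id = mk$id, configs = configs, supports = supports)
  })
  shared <- vapply(per_marker, `[[`, logical(1), "supports")
  ids <- vapply(per_marker, `[[`, character(1), "id")
  assignment <- data.frame(
    id = kids,
    affection = ped$affection[match(kids, ped$id)],
    shares = ped$affection[match(kids, ped$id)] == "affected" & any(shared),
    stringsAsFactors = FALSE)
  list(shared_markers = ids[shared],
       assignment = assignment,
       configurations = stats::setNames(lapply(per_marker, `[[`, "configs"),
                                        ids))
}

#' Read marker genotypes from TSV
#'
#' Expects columns `individual`, `marker`, `allele1`, `allele2`.
#'
#' @param path TSV path.
#' @return Named list (by marker id) of named lists (by individual) of
#'   allele pairs, as consumed by [two_locus_likelihood()].
#' @export
read_marker_genotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  req <- c("individual", "marker", "allele1", "allele2")
  if (!all(req %in% names(tab)))
    stop("marker TSV must have columns: ", paste(req, collapse = ", "))
  out <- list()
  for (mk in unique(tab$marker)) {
    sub <- tab[tab$marker == mk, ]
    out[[mk]] <- stats::setNames(
      lapply(seq_len(nrow(sub)), function(i) c(sub$allele1[i], sub$allele2[i])),
      sub$individual)
  }
  out
}

#' Write marker genotypes as TSV
#'
#' @param geno Named list (marker id) of named lists (individual) of
#'   allele pairs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_genotypes <- function(geno, path) {
  rows <- do.call(rbind, lapply(names(geno), function(mk) {
    g <- geno[[mk]]
    data.frame(individual = names(g), marker = mk,
               allele1 = vapply(g, `[`, "", 1),
               allele2 = vapply(g, `[`, "", 2),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
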
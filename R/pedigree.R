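#' Pedigree construction and validation
#'
#' A `pedigree` is a data frame (one row per individual) with columns
#' `id`, `father`, `mother` (`NA` for founders), `sex`
#' (`"male"`, `"female"`, `"unknown"`), `affection` (`"affected"`,
#' `"unaffected"`, `"unknown"`) and the logical `genotyped`, plus a
#' `name` attribute. Construction validates structure: parents must both
#' be present or both absent, referenced parents must exist, the parent
#' graph must be acyclic, and parental sexes must match their role
#' (father male, mother female) unless `check_sex = FALSE`.
#'
#' @param id Character vector of unique individual labels.
#' @param father,mother Parent labels, `NA` for founders.
#' @param sex `"male"`, `"female"` or `"unknown"` (recycled).
#' @param affection `"affected"`, `"unaffected"` or `"unknown"` (recycled).
#' @param genotyped Logical; whether DNA is available for the individual.
#' @param name Family label.
#' @param check_sex Validate father male / mother female. Disable for
#'   incomplete records.
#' @return An object of class `pedigree`.
#' @examples
#' ped <- pedigree(
#'   id = c("F", "M", "C1", "C2"),
#'   father = c(NA, NA, "F", "F"),
#'   mother = c(NA, NA, "M", "M"),
#'   sex = c("male", "female", "male", "female"),
#'   affection = c("affected", "unaffected", "affected", "unaffected")
#' )
#' founders(ped)
#' @export
pedigree <- function(id, father = NA_character_, mother = NA_character_,
                     sex = "unknown", affection = "unknown",
                     genotyped = TRUE, name = "FAM1", check_sex = TRUE) {
  n <- length(id)
  id <- as.character(id)
  father <- rep_len(as.character(father), n)
  mother <- rep_len(as.character(mother), n)
  sex <- match.arg(rep_len(sex, n), c("male", "female", "unknown"),
                   several.ok = TRUE)
  sex <- rep_len(sex, n)
  affection <- match.arg(rep_len(affection, n),
                         c("affected", "unaffected", "unknown"),
                         several.ok = TRUE)
  affection <- rep_len(affection, n)
  genotyped <- rep_len(as.logical(genotyped), n)

  if (anyDuplicated(id))
    stop("duplicate individual ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  one_parent <- xor(is.na(father), is.na(mother))
  if (any(one_parent))
    stop("individuals with exactly one recorded parent (need both or ",
         "neither): ", paste(id[one_parent], collapse = ", "))
  for (p in c(father, mother)) {
    if (!is.na(p) && !p %in% id)
      stop("unknown parent id '", p, "' referenced in pedigree")
  }
  ped <- structure(
    data.frame(id = id, father = father, mother = mother, sex = sex,
               affection = affection, genotyped = genotyped,
               stringsAsFactors = FALSE),
    name = name, class = c("pedigree", "data.frame"))

  ord <- .ped_toposort(ped)  # errors on ancestry cycles
  attr(ped, "order") <- ord
  if (check_sex) {
    fa <- unique(stats::na.omit(father))
    mo <- unique(stats::na.omit(mother))
    bad_fa <- fa[sex[match(fa, id)] == "female"]
    bad_mo <- mo[sex[match(mo, id)] == "male"]
    if (length(bad_fa) || length(bad_mo))
      stop("parental sex inconsistent with role (father must be male, ",
           "mother female): ",
           paste(c(bad_fa, bad_mo), collapse = ", "),
           "; use check_sex = FALSE to relax")
  }
  ped
}

# Topological order of individuals (parents before children); errors if
# anyone is their own ancestor.
.ped_toposort <- function(ped) {
  n <- nrow(ped)
  placed <- character(0)
  remaining <- ped$id
  while (length(remaining)) {
    idx <- match(remaining, ped$id)
    ready <- vapply(idx, function(i) {
      f <- ped$father[i]; m <- ped$mother[i]
      (is.na(f) || f %in% placed) && (is.na(m) || m %in% placed)
    }, logical(1))
    if (!any(ready))
      stop("pedigree contains an ancestry cycle involving: ",
           paste(remaining, collapse = ", "))
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  placed
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree '", attr(x, "name"), "': ", nrow(x), " individuals (",
      sum(is_founder(x)), " founders, ",
      sum(x$affection == "affected"), " affected)\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Founder status
#'
#' @param ped A [pedigree()].
#' @return Logical vector, `TRUE` where the individual has no recorded
#'   parents.
#' @export
is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)

#' Founder ids of a pedigree
#' @param ped A [pedigree()].
#' @return Character vector of founder ids.
#' @export
founders <- function(ped) ped$id[is_founder(ped)]

#' Read a pedigree from a LINKAGE/PLINK PED file
#'
#' Expects the 6 mandatory whitespace-delimited columns: family id,
#' individual id, father id, mother id, sex (1 = male, 2 = female,
#' 0 = unknown), phenotype (1 = unaffected, 2 = affected, 0 = unknown).
#' Parent id `0` means missing; individuals with both parents missing
#' are founders. Lines starting with `#` are ignored. Columns beyond the
#' sixth (genotype columns) are ignored here; see
#' [read_marker_genotypes()] for marker data.
#'
#' @param path PED file path.
#' @param genotyped Ids of individuals with DNA available; default all.
#' @param check_sex Passed to [pedigree()].
#' @return A [pedigree()].
#' @export
read_ped <- function(path, genotyped = NULL, check_sex = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("no pedigree records in ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("malformed PED line ", lineno[which(nf < 6)[1]], " in ", path,
         ": expected >= 6 whitespace-delimited columns, found ",
         nf[which(nf < 6)[1]])
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  sex_code <- c("0" = "unknown", "1" = "male", "2" = "female")
  aff_code <- c("0" = "unknown", "1" = "unaffected", "2" = "affected")
  bad_sex <- !m[, 5] %in% names(sex_code)
  if (any(bad_sex))
    stop("malformed PED line ", lineno[which(bad_sex)[1]],
         ": sex code must be 0/1/2, found '", m[which(bad_sex)[1], 5], "'")
  bad_aff <- !m[, 6] %in% names(aff_code)
  if (any(bad_aff))
    stop("malformed PED line ", lineno[which(bad_aff)[1]],
         ": phenotype code must be 0/1/2, found '", m[which(bad_aff)[1], 6], "'")
  ids <- m[, 2]
  if (is.null(genotyped)) genotyped <- ids
  pedigree(
    id = ids,
    father = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = unname(sex_code[m[, 5]]),
    affection = unname(aff_code[m[, 6]]),
    genotyped = ids %in% genotyped,
    name = m[1, 1],
    check_sex = check_sex
  )
}

#' Write a pedigree to a 6-column PED file
#'
#' Inverse of [read_ped()]: `read_ped(write_ped(ped, f))` round-trips
#' field for field.
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  sex_code <- c(unknown = "0", male = "1", female = "2")
  aff_code <- c(unknown = "0", unaffected = "1", affected = "2")
  lines <- paste(attr(ped, "name"), ped$id,
                 ifelse(is.na(ped$father), "0", ped$father),
                 ifelse(is.na(ped$mother), "0", ped$mother),
                 sex_code[ped$sex], aff_code[ped$affection], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Decompose a pedigree into nuclear families
#'
#' @param ped A [pedigree()].
#' @return A list of lists with elements `father`, `mother` and
#'   `children` (character ids). Every non-founder appears as a child in
#'   exactly one family.
#' @export
nuclear_families <- function(ped) {
  nf <- which(!is_founder(ped))
  if (!length(nf)) return(list())
  key <- paste(ped$father[nf], ped$mother[nf], sep = "\r")
  split_idx <- split(nf, key)
  unname(lapply(split_idx, function(ix) {
    list(father = ped$father[ix[1]], mother = ped$mother[ix[1]],
         children = ped$id[ix])
  }))
}

#' Test whether a pedigree is loop-free
#'
#' A pedigree has a loop when the "marriage graph" (individuals plus one
#' node per nuclear family, each parent and child linked to the family
#' node) contains a cycle — e.g. consanguineous matings or two siblings
#' marrying two siblings. Elston-Stewart peeling requires a loop-free
#' pedigree; [two_locus_likelihood()] checks this before peeling.
#'
#' @param ped A [pedigree()].
#' @return `TRUE` or `FALSE`.
#' @export
is_loop_free <- function(ped) {
  fams <- nuclear_families(ped)
  if (!length(fams)) return(TRUE)
  # Undirected graph: individual nodes + family nodes. Loop-free iff
  # acyclic, i.e. edges == nodes - number of connected components.
  ids <- ped$id
  fam_nodes <- paste0(".fam", seq_along(fams))
  edges <- do.call(rbind, lapply(seq_along(fams), function(k) {
    f <- fams[[k]]
    cbind(c(f$father, f$mother, f$children), fam_nodes[k])
  }))
  nodes <- c(ids, fam_nodes)
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  acyclic <- TRUE
  for (r in seq_len(nrow(edges))) {
    a <- find(match(edges[r, 1], nodes)); b <- find(match(edges[r, 2], nodes))
    if (a == b) { acyclic <- FALSE; break }
    parent[a] <- b
  }
  acyclic
}

#' The package's example multiplex family
#'
#' A loop-free three-generation-style sibship modeled on a large
#' autosomal-dominant-appearing glaucoma family: two deceased, untyped
#' founder parents (affection unknown) and nine typed offspring, eight
#' affected and one unaffected. The founders are retained as untyped
#' members rather than omitted because the pedigree likelihood must sum
#' over their genotypes. The exact attachment of the sibship to earlier
#' generations is not reconstructable from published sources, so this
#' single-sibship form is a documented approximation.
#'
#' @return A [pedigree()] of 11 members.
#' @export
example_family <- function() {
  kids <- paste0("III-", 1:9)
  pedigree(
    id = c("II-1", "II-2", kids),
    father = c(NA, NA, rep("II-1", 9)),
    mother = c(NA, NA, rep("II-2", 9)),
    sex = c("male", "female", rep(c("male", "female"), length.out = 9)),
    affection = c("unknown", "unknown", rep("affected", 8), "unaffected"),
    genotyped = c(FALSE, FALSE, rep(TRUE, 9)),
    name = "POAG1"
  )
}
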
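#' Kinship dyad classes
#'
#' The dyad classes understood by [extract_dyads()], in the conventional
#' reporting order: full siblings first, then the sex-specific sibling
#' classes, parent-child, grandparent-grandchild, avuncular
#' (aunt/uncle-niece/nephew through a full-sibling link), and first cousins
#' (children of full siblings).
#'
#' @export
dyad_classes <- function() {
  c(
    "full_siblings", "full_sisters", "full_brothers", "opposite_sex_siblings",
    "parent_child", "grandparent_grandchild", "avuncular", "first_cousins"
  )
}

#' Extract kinship dyads from a pedigree
#'
#' Enumerates all unordered pairs of a given relationship class, each stored
#' once. Sibling classes require both parents shared (full siblings);
#' avuncular and first-cousin classes are derived through full-sibling links
#' of parents. Individuals of unknown sex are excluded from the sex-specific
#' sibling classes only.
#'
#' @param ped a [pedigree] object.
#' @param dyad_class one of [dyad_classes()].
#' @return a `dyad_set`: data.frame with columns `id_i`, `id_j`,
#'   `family_group` (label of the first member) and attribute `dyad_class`.
#' @export
extract_dyads <- function(ped, dyad_class) {
  stopifnot(inherits(ped, "pedigree"))
  dyad_class <- match.arg(dyad_class, dyad_classes())
  ind <- ped$ind
  n <- nrow(ind)

  pairs <- switch(dyad_class,
    full_siblings = sib_pairs(ind),
    full_sisters = sex_sib_pairs(ind, "female", "female"),
    full_brothers = sex_sib_pairs(ind, "male", "male"),
    opposite_sex_siblings = sex_sib_pairs(ind, "female", "male"),
    parent_child = parent_child_pairs(ind),
    grandparent_grandchild = grandparent_pairs(ind),
    avuncular = avuncular_pairs(ind),
    first_cousins = cousin_pairs(ind)
  )
  pairs <- dedupe_pairs(pairs)
  out <- data.frame(
    id_i = ind$id[pairs[, 1L]],
    id_j = ind$id[pairs[, 2L]],
    family_group = ind$family_group[pairs[, 1L]],
    stringsAsFactors = FALSE
  )
  attr(out, "dyad_class") <- dyad_class
  class(out) <- c("dyad_set", "data.frame")
  out
}

# unordered (min, max) index pairs, unique
dedupe_pairs <- function(pairs) {
  if (!length(pairs)) return(matrix(integer(0), 0, 2))
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  pairs[!duplicated(pairs), , drop = FALSE]
}

# all full-sib index pairs (both parents known and shared)
sib_pairs <- function(ind) {
  known <- which(ind$sire_idx > 0L & ind$dam_idx > 0L)
  key <- paste(ind$sire_idx[known], ind$dam_idx[known])
  out <- list()
  for (g in split(known, key)) {
    if (length(g) < 2L) next
    out[[length(out) + 1L]] <- t(utils::combn(g, 2L))
  }
  if (!length(out)) matrix(integer(0), 0, 2) else do.call(rbind, out)
}

sex_sib_pairs <- function(ind, sex_a, sex_b) {
  p <- sib_pairs(ind)
  if (!nrow(p)) return(p)
  sa <- ind$sex[p[, 1L]]
  sb <- ind$sex[p[, 2L]]
  keep <- (sa == sex_a & sb == sex_b) | (sa == sex_b & sb == sex_a)
  p[keep, , drop = FALSE]
}

parent_child_pairs <- function(ind) {
  i <- seq_len(nrow(ind))
  rbind(
    cbind(ind$sire_idx[ind$sire_idx > 0L], i[ind$sire_idx > 0L]),
    cbind(ind$dam_idx[ind$dam_idx > 0L], i[ind$dam_idx > 0L])
  )
}

grandparent_pairs <- function(ind) {
  out <- list()
  for (i in seq_len(nrow(ind))) {
    for (p in c(ind$sire_idx[i], ind$dam_idx[i])) {
      if (p == 0L) next
      for (gp in c(ind$sire_idx[p], ind$dam_idx[p])) {
        if (gp > 0L) out[[length(out) + 1L]] <- c(gp, i)
      }
    }
  }
  if (!length(out)) matrix(integer(0), 0, 2) else do.call(rbind, out)
}

# map: individual -> indices of its full siblings
full_sib_list <- function(ind) {
  n <- nrow(ind)
  sibs <- vector("list", n)
  known <- which(ind$sire_idx > 0L & ind$dam_idx > 0L)
  key <- paste(ind$sire_idx[known], ind$dam_idx[known])
  for (g in split(known, key)) {
    if (length(g) < 2L) next
    for (i in g) sibs[[i]] <- setdiff(g, i)
  }
  sibs
}

avuncular_pairs <- function(ind) {
  sibs <- full_sib_list(ind)
  out <- list()
  for (i in seq_len(nrow(ind))) {
    for (p in c(ind$sire_idx[i], ind$dam_idx[i])) {
      if (p == 0L || is.null(sibs[[p]])) next
      for (au in sibs[[p]]) out[[length(out) + 1L]] <- c(au, i)
    }
  }
  if (!length(out)) matrix(integer(0), 0, 2) else do.call(rbind, out)
}

cousin_pairs <- function(ind) {
  sibs <- full_sib_list(ind)
  n <- nrow(ind)
  # children index per parent
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(ind$sire_idx[i], ind$dam_idx[i])) {
      if (p > 0L) kids[[p]] <- c(kids[[p]], i)
    }
  }
  out <- list()
  for (p in seq_len(n)) {
    if (is.null(sibs[[p]]) || is.null(kids[[p]])) next
    for (q in sibs[[p]]) {
      if (is.null(kids[[q]])) next
      out[[length(out) + 1L]] <- as.matrix(expand.grid(kids[[p]], kids[[q]]))
    }
  }
  if (!length(out)) return(matrix(integer(0), 0, 2))
  p <- do.call(rbind, out)
  # exclude pairs that are themselves siblings (shared parent)
  same <- (ind$sire_idx[p[, 1L]] > 0L & ind$sire_idx[p[, 1L]] == ind$sire_idx[p[, 2L]]) |
    (ind$dam_idx[p[, 1L]] > 0L & ind$dam_idx[p[, 1L]] == ind$dam_idx[p[, 2L]])
  p[!same, , drop = FALSE]
}

#' Count informative relationships for a pedigree analysis
#'
#' Tabulates, per relationship class, the pairs in which both members have a
#' non-missing phenotype and (under the default rule) at least one member is
#' affected. A pair of relatives is most informative to a variance-component
#' model when at least one member is affected, which is the default counting
#' rule; `rule = "both_nonmissing"` counts every complete-phenotype pair
#' instead. Sibling relationships through the mother (shared dam) and through
#' the father (shared sire) are tabulated separately, alongside full
#' siblings, parent-child split by parental sex, and the four
#' grandparent-grandchild lines.
#'
#' @param ped a [pedigree] object.
#' @param phenotypes data.frame with columns `id` and `status` (0/1/NA).
#' @param rule `"either_affected"` (default) or `"both_nonmissing"`.
#' @return data.frame with columns `relationship` and `n`, including a
#'   `total` row (sum over the listed classes).
#' @export
count_informative_relationships <- function(ped, phenotypes,
                                            rule = c("either_affected", "both_nonmissing")) {
  stopifnot(inherits(ped, "pedigree"))
  rule <- match.arg(rule)
  ind <- ped$ind
  status <- phenotypes$status[match(ind$id, phenotypes$id)]

  informative <- function(pairs) {
    if (!nrow(pairs)) return(0L)
    s1 <- status[pairs[, 1L]]
    s2 <- status[pairs[, 2L]]
    ok <- !is.na(s1) & !is.na(s2)
    if (rule == "either_affected") ok <- ok & (s1 == 1 | s2 == 1)
    sum(ok)
  }

  pc <- parent_child_pairs(ind)
  mother_child <- pc[ind$sex[pc[, 1L]] == "female", , drop = FALSE]
  father_child <- pc[ind$sex[pc[, 1L]] == "male", , drop = FALSE]
  fs <- dedupe_pairs(sib_pairs(ind))
  msib <- dedupe_pairs(shared_parent_pairs(ind, "dam"))
  psib <- dedupe_pairs(shared_parent_pairs(ind, "sire"))
  gp <- grandparent_line_pairs(ind)

  rows <- list(
    `mother-child` = mother_child,
    `father-child` = father_child,
    `full sibling` = fs,
    `sibling via mother` = msib,
    `sibling via father` = psib,
    `maternal grandmother-grandchild` = gp$mat_gm,
    `maternal grandfather-grandchild` = gp$mat_gf,
    `paternal grandmother-grandchild` = gp$pat_gm,
    `paternal grandfather-grandchild` = gp$pat_gf
  )
  n <- vapply(rows, informative, integer(1))
  out <- data.frame(
    relationship = c(names(rows), "total"),
    n = c(n, sum(n)),
    row.names = NULL
  )
  attr(out, "rule") <- rule
  out
}

# sibling pairs sharing the given parent (half or full)
shared_parent_pairs <- function(ind, which_parent) {
  idx <- if (which_parent == "dam") ind$dam_idx else ind$sire_idx
  known <- which(idx > 0L)
  out <- list()
  for (g in split(known, idx[known])) {
    if (length(g) < 2L) next
    out[[length(out) + 1L]] <- t(utils::combn(g, 2L))
  }
  if (!length(out)) matrix(integer(0), 0, 2) else do.call(rbind, out)
}

# grandparent-grandchild pairs split by line (maternal/paternal) and
# grandparent sex
grandparent_line_pairs <- function(ind) {
  res <- list(
    mat_gm = list(), mat_gf = list(),
    pat_gm = list(), pat_gf = list()
  )
  for (i in seq_len(nrow(ind))) {
    m <- ind$dam_idx[i]
    if (m > 0L) {
      if (ind$dam_idx[m] > 0L) res$mat_gm[[length(res$mat_gm) + 1L]] <- c(ind$dam_idx[m], i)
      if (ind$sire_idx[m] > 0L) res$mat_gf[[length(res$mat_gf) + 1L]] <- c(ind$sire_idx[m], i)
    }
    p <- ind$sire_idx[i]
    if (p > 0L) {
      if (ind$dam_idx[p] > 0L) res$pat_gm[[length(res$pat_gm) + 1L]] <- c(ind$dam_idx[p], i)
      if (ind$sire_idx[p] > 0L) res$pat_gf[[length(res$pat_gf) + 1L]] <- c(ind$sire_idx[p], i)
    }
  }
  lapply(res, function(l) {
    if (!length(l)) matrix(integer(0), 0, 2) else do.call(rbind, l)
  })
}
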
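#' Construct a validated pedigree
#'
#' Builds a `pedigree` object from parallel vectors of identifiers. Unknown
#' parents are coded `NA`, `""` or `"0"`. Parents that are referenced but not
#' listed as records are auto-inserted as founders ("phantom parents") with
#' their sex inferred from the parental role; the number inserted is reported
#' via a message and stored in the object.
#'
#' Validation enforces the structural contracts of a parentage graph:
#' no individual is its own parent, the graph is acyclic (so a topological
#' order exists in which every parent precedes its offspring), and parental
#' roles are sex-consistent (an id used as a sire is male, as a dam female;
#' an id used in both roles, or listed with the opposite sex, is an error).
#'
#' @param id character vector of unique individual identifiers.
#' @param sire,dam character vectors of parent identifiers (`NA`/`""`/`"0"` =
#'   unknown).
#' @param sex one of `"female"`, `"male"`, `"unknown"` per individual (also
#'   accepts `F`/`M`/`1`/`2` codings; `1` = male, `2` = female).
#' @param family_group optional self-reported extended-family label per
#'   individual (used for the shared-environment random effect and for
#'   jackknife sampling); defaults to the connected genetic component.
#' @return An object of class `pedigree`: a list with element `ind`, a
#'   data.frame in topological order with columns `id`, `sire`, `dam`, `sex`,
#'   `family_group`, `founder`, and integer parent indices `sire_idx`,
#'   `dam_idx` (0 = unknown), plus `n_phantom`, the count of auto-inserted
#'   founders.
#' @export
pedigree <- function(id, sire = NA, dam = NA, sex = "unknown", family_group = NA) {
  id <- as.character(id)
  n0 <- length(id)
  sire <- normalize_parent(rep_len(as.character(sire), n0))
  dam <- normalize_parent(rep_len(as.character(dam), n0))
  sex <- normalize_sex(rep_len(as.character(sex), n0))
  family_group <- rep_len(as.character(family_group), n0)

  if (anyDuplicated(id)) {
    stop("duplicated individual ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  self_par <- id == sire | id == dam
  self_par[is.na(self_par)] <- FALSE
  if (any(self_par)) {
    stop("individual listed as its own parent: ", paste(id[self_par], collapse = ", "))
  }
  same_par <- !is.na(sire) & !is.na(dam) & sire == dam
  if (any(same_par)) {
    stop("sire and dam identical for: ", paste(id[same_par], collapse = ", "))
  }

  # phantom parents: referenced but not listed
  phantom <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), id)
  if (length(phantom)) {
    message(length(phantom), " parent id(s) not listed as records; inserted as founders")
    ph_sex <- ifelse(phantom %in% sire, "male", "female")
    id <- c(id, phantom)
    sire <- c(sire, rep(NA_character_, length(phantom)))
    dam <- c(dam, rep(NA_character_, length(phantom)))
    sex <- c(sex, ph_sex)
    family_group <- c(family_group, rep(NA_character_, length(phantom)))
  }
  n <- length(id)

  # sex consistency of parental roles
  as_sire <- unique(sire[!is.na(sire)])
  as_dam <- unique(dam[!is.na(dam)])
  both <- intersect(as_sire, as_dam)
  if (length(both)) {
    stop("id(s) used both as sire and dam: ", paste(both, collapse = ", "))
  }
  bad_sire <- as_sire[sex[match(as_sire, id)] == "female"]
  bad_dam <- as_dam[sex[match(as_dam, id)] == "male"]
  if (length(bad_sire) || length(bad_dam)) {
    stop(
      "sex inconsistent with parental role for: ",
      paste(c(bad_sire, bad_dam), collapse = ", ")
    )
  }
  # infer unknown sex from role
  sex[id %in% as_sire & sex == "unknown"] <- "male"
  sex[id %in% as_dam & sex == "unknown"] <- "female"

  sire_idx <- match(sire, id, nomatch = 0L)
  dam_idx <- match(dam, id, nomatch = 0L)

  ord <- topological_order(sire_idx, dam_idx, id)

  ind <- data.frame(
    id = id, sire = sire, dam = dam, sex = sex,
    family_group = family_group,
    stringsAsFactors = FALSE
  )[ord, , drop = FALSE]
  rownames(ind) <- NULL
  ind$sire_idx <- match(ind$sire, ind$id, nomatch = 0L)
  ind$dam_idx <- match(ind$dam, ind$id, nomatch = 0L)
  ind$founder <- ind$sire_idx == 0L & ind$dam_idx == 0L

  if (all(is.na(ind$family_group))) {
    ind$family_group <- as.character(genetic_components(ind))
  } else if (anyNA(ind$family_group)) {
    comp <- genetic_components(ind)
    miss <- is.na(ind$family_group)
    ind$family_group[miss] <- paste0("component_", comp[miss])
  }

  structure(
    list(ind = ind, n_phantom = length(phantom)),
    class = "pedigree"
  )
}

normalize_parent <- function(x) {
  x[x %in% c("0", "", "NA", ".")] <- NA_character_
  x
}

normalize_sex <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("unknown", length(x))
  out[x %in% c("f", "female", "2")] <- "female"
  out[x %in% c("m", "male", "1")] <- "male"
  out
}

# Kahn's algorithm; deterministic tie-break by record order.
# Errors with an individual on a cycle if one exists.
topological_order <- function(sire_idx, dam_idx, id) {
  n <- length(sire_idx)
  # children adjacency
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_idx[i], dam_idx[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  ord <- integer(0)
  avail <- which(indeg == 0L)
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- c(avail, k)
    }
  }
  if (length(ord) < n) {
    on_cycle <- setdiff(seq_len(n), ord)
    stop(
      "parentage graph contains a cycle involving individual ",
      id[on_cycle[1L]]
    )
  }
  ord
}

# Connected components of the genetic (parent-offspring) graph,
# used as a fallback family label when none is supplied.
genetic_components <- function(ind) {
  n <- nrow(ind)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  for (i in seq_len(n)) {
    if (ind$sire_idx[i] > 0L) union2(i, ind$sire_idx[i])
    if (ind$dam_idx[i] > 0L) union2(i, ind$dam_idx[i])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Read a pedigree from a text file
#'
#' Expects at least four columns `id sire dam sex` with an optional fifth
#' `family_group`, separated by whitespace or commas; `0` or an empty field
#' codes an unknown parent; lines starting with `#` are comments. A header
#' line is detected automatically (first field equal to `id`, case
#' insensitive).
#'
#' @param path path to the pedigree file.
#' @return A validated [pedigree] object in topological order.
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no pedigree records in ", path)
  sep <- if (grepl(",", lines[1])) "," else ""
  con <- textConnection(lines)
  on.exit(close(con))
  tab <- utils::read.table(con,
    sep = sep, header = FALSE, colClasses = "character",
    strip.white = TRUE, fill = TRUE
  )
  if (ncol(tab) < 4) stop("pedigree file needs >= 4 columns (id, sire, dam, sex)")
  if (tolower(tab[1, 1]) == "id") tab <- tab[-1, , drop = FALSE]
  fam <- if (ncol(tab) >= 5) tab[[5]] else NA
  pedigree(tab[[1]], tab[[2]], tab[[3]], tab[[4]], fam)
}

#' Write a pedigree to a text file
#'
#' Emits the five-column whitespace format read by [read_pedigree()].
#'
#' @param ped a [pedigree] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  ind <- ped$ind
  out <- data.frame(
    id = ind$id,
    sire = ifelse(is.na(ind$sire), "0", ind$sire),
    dam = ifelse(is.na(ind$dam), "0", ind$dam),
    sex = ind$sex,
    family_group = ind$family_group
  )
  utils::write.table(out, path,
    quote = FALSE, row.names = FALSE,
    col.names = c("id", "sire", "dam", "sex", "family_group")
  )
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  ind <- x$ind
  cat(
    "pedigree:", nrow(ind), "individuals,",
    sum(ind$founder), "founders,",
    length(unique(ind$family_group)), "family groups\n"
  )
  cat(
    "  sex:", sum(ind$sex == "female"), "female /",
    sum(ind$sex == "male"), "male /",
    sum(ind$sex == "unknown"), "unknown\n"
  )
  if (x$n_phantom > 0) cat("  phantom founders inserted:", x$n_phantom, "\n")
  invisible(x)
}

#' Number of individuals in a pedigree
#' @param ped a [pedigree] object.
#' @return integer count.
#' @export
n_individuals <- function(ped) nrow(ped$ind)
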
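#' Inbreeding coefficients from a pedigree
#'
#' Computes F for every individual with the Meuwissen & Luo algorithm
#' (tracing the L matrix of the decomposition A = L D L' one individual at a
#' time), which handles arbitrary inbreeding loops without materialising A.
#'
#' @param ped a [pedigree] object.
#' @return numeric vector of inbreeding coefficients in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ind <- ped$ind
  n <- nrow(ind)
  s <- ind$sire_idx
  d <- ind$dam_idx
  f <- numeric(n)
  dii <- numeric(n) # Mendelian sampling variance scalars
  for (i in seq_len(n)) {
    fs <- if (s[i] > 0L) f[s[i]] else -1
    fd <- if (d[i] > 0L) f[d[i]] else -1
    dii[i] <- 0.5 - 0.25 * (fs + fd)
    if (s[i] == 0L || d[i] == 0L) {
      f[i] <- 0
      next
    }
    # accumulate L-row contributions from the ancestors of i
    w <- numeric(n)
    w[i] <- 1
    fi <- -1 # will collect a_ii - 1 with the self term included
    for (j in i:1) {
      if (w[j] == 0) next
      if (s[j] > 0L) w[s[j]] <- w[s[j]] + 0.5 * w[j]
      if (d[j] > 0L) w[d[j]] <- w[d[j]] + 0.5 * w[j]
      fi <- fi + w[j]^2 * dii[j]
    }
    f[i] <- fi
  }
  f
}

#' Additive (numerator) relationship matrix
#'
#' Builds the A matrix of expected additive genetic relationships by the
#' tabular (recursive) method over the topologically ordered pedigree:
#' founders have `a_ii = 1` and are mutually unrelated; for an individual `k`
#' with parents `s` and `d`, `a_ki = (a_si + a_di)/2` for earlier `i` and
#' `a_kk = 1 + a_sd/2`. The diagonal is `1 + F` with `F` the inbreeding
#' coefficient.
#'
#' The tabular method is quadratic in pedigree size; for model fitting the
#' sparse inverse from [a_inverse()] is used instead and a dense A is never
#' required.
#'
#' @param ped a [pedigree] object.
#' @param sparse return a symmetric sparse `Matrix` (default) rather than a
#'   base dense matrix.
#' @return an n x n symmetric positive semi-definite matrix with dimnames set
#'   to individual ids.
#' @export
additive_relationship_matrix <- function(ped, sparse = TRUE) {
  stopifnot(inherits(ped, "pedigree"))
  ind <- ped$ind
  n <- nrow(ind)
  A <- matrix(0, n, n, dimnames = list(ind$id, ind$id))
  s <- ind$sire_idx
  d <- ind$dam_idx
  for (k in seq_len(n)) {
    if (k > 1L) {
      earlier <- seq_len(k - 1L)
      row <- numeric(k - 1L)
      if (s[k] > 0L) row <- row + 0.5 * A[s[k], earlier]
      if (d[k] > 0L) row <- row + 0.5 * A[d[k], earlier]
      A[k, earlier] <- row
      A[earlier, k] <- row
    }
    asd <- if (s[k] > 0L && d[k] > 0L) A[s[k], d[k]] else 0
    A[k, k] <- 1 + asd / 2
  }
  if (sparse) Matrix::forceSymmetric(Matrix::Matrix(A, sparse = TRUE)) else A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A^-1 directly from pedigree structure by Henderson's rules,
#' with Mendelian-sampling variances adjusted for parental inbreeding
#' (coefficients from [inbreeding()]). The result has O(n) non-zeros and is
#' what the animal-model sampler conditions on; a dense A is never formed.
#'
#' @param ped a [pedigree] object.
#' @return a symmetric sparse `dsCMatrix` with dimnames set to ids.
#' @export
a_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ind <- ped$ind
  n <- nrow(ind)
  s <- ind$sire_idx
  d <- ind$dam_idx
  f <- inbreeding(ped)
  fs <- ifelse(s > 0L, f[pmax(s, 1L)], -1)
  fd <- ifelse(d > 0L, f[pmax(d, 1L)], -1)
  alpha <- 1 / (0.5 - 0.25 * (fs + fd)) # inverse Mendelian sampling variance

  # vectorised triplet assembly: diagonal entries once, off-diagonal entries
  # in both orientations (duplicates are summed by sparseMatrix)
  di <- seq_len(n); dx <- alpha
  oi <- integer(0); oj <- integer(0); ox <- numeric(0)
  has_s <- s > 0L
  has_d <- d > 0L
  k <- which(has_s)
  di <- c(di, s[k]); dx <- c(dx, alpha[k] / 4)
  oi <- c(oi, k); oj <- c(oj, s[k]); ox <- c(ox, -alpha[k] / 2)
  k <- which(has_d)
  di <- c(di, d[k]); dx <- c(dx, alpha[k] / 4)
  oi <- c(oi, k); oj <- c(oj, d[k]); ox <- c(ox, -alpha[k] / 2)
  k <- which(has_s & has_d)
  oi <- c(oi, s[k]); oj <- c(oj, d[k]); ox <- c(ox, alpha[k] / 4)

  M <- Matrix::sparseMatrix(
    i = c(di, oi, oj), j = c(di, oj, oi), x = c(dx, ox, ox),
    dims = c(n, n), dimnames = list(ind$id, ind$id)
  )
  Matrix::forceSymmetric(M)
}

#' Write a relationship matrix as sparse text
#'
#' Emits the non-zero entries of the upper triangle (including the diagonal)
#' as three columns `id_i id_j a_ij`. For pedigrees of at most `dense_limit`
#' individuals a dense CSV can be written instead.
#'
#' @param A relationship matrix from [additive_relationship_matrix()].
#' @param path output path.
#' @param dense write a dense CSV (only allowed for <= `dense_limit` ids).
#' @param dense_limit maximum size for dense output (default 500).
#' @return `path`, invisibly.
#' @export
write_relationship_matrix <- function(A, path, dense = FALSE, dense_limit = 500) {
  if (dense) {
    if (nrow(A) > dense_limit) {
      stop("dense output limited to ", dense_limit, " individuals")
    }
    utils::write.csv(as.matrix(A), path, quote = FALSE)
    return(invisible(path))
  }
  T3 <- methods::as(methods::as(Matrix::triu(A), "generalMatrix"), "TsparseMatrix")
  keep <- T3@x != 0
  out <- data.frame(
    id_i = rownames(A)[T3@i[keep] + 1L],
    id_j = colnames(A)[T3@j[keep] + 1L],
    a_ij = T3@x[keep]
  )
  out <- out[order(match(out$id_i, rownames(A)), match(out$id_j, colnames(A))), ]
  utils::write.table(out, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
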
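#' Read and validate a pedigree
#'
#' Parses a pedigree table (one row per animal with sire and dam links) and
#' returns it topologically sorted so that every parent precedes its
#' offspring. Unknown parents are encoded as `NA`; on input, `"0"`, `""` and
#' `NA` are all accepted as the unknown-parent sentinel. Identifiers are
#' compared as exact strings.
#'
#' @param x A file path to a CSV with columns `animal,sire,dam` (optionally
#'   `birth_year,flock,cohort`), or a data.frame with those columns.
#' @return A data.frame of class `ovi_pedigree`, topologically sorted, with
#'   character columns `animal`, `sire`, `dam` (unknown parents `NA`) and any
#'   further columns carried through.
#' @details Duplicated animal identifiers and pedigree cycles (an animal that
#'   is its own ancestor) are hard errors; the cycle error names the animals
#'   involved.
#' @examples
#' ped <- read_pedigree(data.frame(animal = c("B", "A"),
#'                                 sire = c("A", "0"), dam = c("0", "0")))
#' ped$animal  # "A" "B" -- parents first
#' @export
read_pedigree <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.csv(x, stringsAsFactors = FALSE, colClasses = "character")
  }
  stopifnot(is.data.frame(x))
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(x))) {
    stop("pedigree needs columns 'animal', 'sire', 'dam'")
  }
  ped <- as.data.frame(x, stringsAsFactors = FALSE)
  for (cc in need) {
    v <- trimws(as.character(ped[[cc]]))
    v[v %in% c("", "0", "NA")] <- NA_character_
    ped[[cc]] <- v
  }
  if (anyNA(ped$animal)) stop("missing animal identifier in pedigree")
  if (anyDuplicated(ped$animal)) {
    dup <- unique(ped$animal[duplicated(ped$animal)])
    stop("duplicate animal_id in pedigree: ", paste(dup, collapse = ", "))
  }
  # parents that never appear as animals become implicit founders
  known <- ped$animal
  phantom <- setdiff(stats::na.omit(unique(c(ped$sire, ped$dam))), known)
  if (length(phantom)) {
    pad <- ped[rep(NA_integer_, length(phantom)), , drop = FALSE]
    pad$animal <- phantom
    pad$sire <- NA_character_
    pad$dam <- NA_character_
    ped <- rbind(pad, ped)
    rownames(ped) <- NULL
  }
  ord <- pedigree_toposort(ped$animal, ped$sire, ped$dam)
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("ovi_pedigree", "data.frame")
  ped
}

# Kahn topological sort; errors on cycles, naming the animals left unplaced.
pedigree_toposort <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- unname(idx[sire]); di <- unname(idx[dam])
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    # stable: keep original input order among the available animals
    queue <- sort(queue)
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    stuck <- animal[setdiff(idx, out)]
    stop("pedigree contains a cycle involving: ", paste(stuck, collapse = ", "))
  }
  out
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' @param ped An `ovi_pedigree` from [read_pedigree()] (or a data.frame
#'   accepted by it).
#' @return Named numeric vector of inbreeding coefficients F, in pedigree
#'   order. Founders (and animals with an unknown parent) have F = 0.
#' @export
inbreeding_coef <- function(ped) {
  ped <- as_ovi_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$animal
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  si[is.na(si)] <- 0L; di[is.na(di)] <- 0L
  Fv <- numeric(n)
  Dv <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    Dv[i] <- if (s > 0L && d > 0L) 0.5 - 0.25 * (Fv[s] + Fv[d])
             else if (s > 0L) 0.75 - 0.25 * Fv[s]
             else if (d > 0L) 0.75 - 0.25 * Fv[d]
             else 1
    if (s == 0L || d == 0L) next   # F = 0 with an unknown parent
    L <- numeric(i); L[i] <- 1
    aii <- 0
    for (j in i:1) {
      lj <- L[j]
      if (lj != 0) {
        aii <- aii + lj * lj * Dv[j]
        if (si[j] > 0L) L[si[j]] <- L[si[j]] + 0.5 * lj
        if (di[j] > 0L) L[di[j]] <- L[di[j]] + 0.5 * lj
      }
    }
    Fv[i] <- aii - 1
  }
  names(Fv) <- ped$animal
  Fv
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A for a pedigree using
#' the recursive tabular method: for animal i with parents s and d (in
#' topological order), `a_ii = 1 + 0.5 * a_sd` and, for any earlier animal j,
#' `a_ij = 0.5 * (a_js + a_jd)`, with unknown parents contributing zero.
#'
#' @inheritParams inbreeding_coef
#' @return A dense symmetric matrix with animal identifiers as dimnames.
#'   Diagonals equal `1 + F`.
#' @export
build_A <- function(ped) {
  ped <- as_ovi_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$animal
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- numeric(i - 1L)
      if (!is.na(s)) aij <- aij + 0.5 * A[j, s]
      if (!is.na(d)) aij <- aij + 0.5 * A[j, d]
      A[j, i] <- aij
      A[i, j] <- aij
    }
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly by Henderson's rules with the inbreeding
#' correction: each animal contributes `alpha = 1/d_i` to the inverse, where
#' `d_i` is its Mendelian-sampling variance given parental inbreeding
#' (computed with [inbreeding_coef()]). Unknown parents are treated as
#' unrelated, non-inbred founders.
#'
#' @inheritParams inbreeding_coef
#' @return A sparse symmetric `Matrix::dsCMatrix` with animal identifiers as
#'   dimnames, such that `A %*% A_inverse` is the identity.
#' @export
build_A_inverse <- function(ped) {
  ped <- as_ovi_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$animal
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  Fv <- inbreeding_coef(ped)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  push <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dI <- if (!is.na(s) && !is.na(d)) 0.5 - 0.25 * (Fv[s] + Fv[d])
          else if (!is.na(s)) 0.75 - 0.25 * Fv[s]
          else if (!is.na(d)) 0.75 - 0.25 * Fv[d]
          else 1
    al <- 1 / dI
    push(i, i, al)
    for (p in c(s, d)) {
      if (!is.na(p)) {
        push(i, p, -al / 2); push(p, i, -al / 2)
        push(p, p, al / 4)
      }
    }
    if (!is.na(s) && !is.na(d) && s != d) {
      push(s, d, al / 4); push(d, s, al / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}

as_ovi_pedigree <- function(ped) {
  if (inherits(ped, "ovi_pedigree")) ped else read_pedigree(ped)
}
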
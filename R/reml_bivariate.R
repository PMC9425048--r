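# Bivariate animal-model REML: 2x2 additive and residual covariance
# matrices on animals recorded for both traits, giving genetic and
# phenotypic correlations with delta-method standard errors.

# -2 restricted logL for the bivariate model given natural-scale G0 (additive)
# and R0 (residual) 2x2 covariance matrices. parts: precomputed designs.
neg2_reml_biv <- function(G0, R0, parts) {
  ok <- function(M) all(is.finite(M)) && M[1, 1] > 0 && M[2, 2] > 0 &&
    (M[1, 1] * M[2, 2] - M[1, 2]^2) > 0
  if (!ok(G0) || !ok(R0)) return(1e10)
  n <- parts$n; q <- parts$q
  R0inv <- solve(R0)
  G0inv <- solve(G0)
  Rinv <- kronecker(R0inv, Matrix::Diagonal(n))
  C <- Matrix::crossprod(parts$W, Rinv %*% parts$W)
  # additive penalty: G0inv (x) Ainv laid on the (a1, a2) blocks
  P <- kron_penalty(G0inv, parts$Ainv, parts$off_a, ncol(parts$W))
  C <- Matrix::forceSymmetric(C + P)
  ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE),
                 error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  ldetC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  rhs <- as.numeric(Matrix::crossprod(parts$W, Rinv %*% parts$yv))
  sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  yRy <- as.numeric(Matrix::crossprod(parts$yv, Rinv %*% parts$yv))
  yPy <- yRy - sum(sol * rhs)
  n * log(det(R0)) + q * log(det(G0)) + ldetC + yPy
}

kron_penalty <- function(S, Ainv, off_a, m) {
  At <- methods::as(methods::as(Ainv, "generalMatrix"), "TsparseMatrix")
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (a in 1:2) for (b in 1:2) {
    if (S[a, b] != 0) {
      ii <- c(ii, off_a[[a]][At@i + 1L])
      jj <- c(jj, off_a[[b]][At@j + 1L])
      xx <- c(xx, S[a, b] * At@x)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, m))
}

#' Bivariate animal-model REML: genetic and phenotypic correlations
#'
#' Fits a two-trait animal model by REML on the animals recorded for both
#' traits, estimating 2x2 additive-genetic and residual covariance matrices
#' structured by the pedigree, and reports the genetic correlation
#' `r_g = cov_a / sqrt(va1 * va2)` and the phenotypic correlation computed
#' from the summed covariance components, each with a delta-method standard
#' error from the observed information. Estimates on the correlation
#' boundary (|r| = 1) are projected into the admissible range and flagged.
#'
#' Covariance matrices are optimized through their Cholesky factors, which
#' keeps them positive-definite without explicit constraints. Records are
#' reduced to one per animal per trait (means of repeated records).
#'
#' @param data data.frame with an animal-identifier column and one column
#'   per trait.
#' @param traits Character vector of two trait column names.
#' @param pedigree An `ovi_pedigree` covering the phenotyped animals.
#' @param fixed Fixed-effect formula applied to each trait (default `~ 1`).
#' @param animal Animal-identifier column name.
#' @param se Compute standard errors (default TRUE; the information matrix
#'   requires many extra likelihood evaluations, so recovery sweeps switch
#'   it off).
#' @param Ainv Optional precomputed [build_A_inverse()] result.
#' @return Object of class `ovi_reml_biv`: `G0` (additive covariance), `R0`
#'   (residual covariance), `correlations` data.frame (`r_g`, `r_p`:
#'   estimate, se, significant, boundary), per-trait `h2`, `logLR`,
#'   `converged`, `n`.
#' @export
reml_bivariate <- function(data, traits, pedigree, fixed = ~1,
                           animal = "animal", se = TRUE, Ainv = NULL) {
  stopifnot(length(traits) == 2, all(traits %in% names(data)))
  ped <- as_ovi_pedigree(pedigree)
  d <- data[stats::complete.cases(data[, c(animal, traits)]), , drop = FALSE]
  if (anyDuplicated(d[[animal]])) {
    agg <- stats::aggregate(d[, traits], by = list(d[[animal]]), FUN = mean)
    names(agg)[1] <- animal
    keep <- d[!duplicated(d[[animal]]),
              setdiff(names(d), traits), drop = FALSE]
    d <- merge(keep, agg, by = animal)
  }
  ids <- as.character(d[[animal]])
  if (!all(ids %in% ped$animal)) {
    stop("phenotyped animals missing from pedigree")
  }
  n <- nrow(d)
  if (n < 3) stop("need at least 3 animals recorded for both traits")
  X1 <- stats::model.matrix(fixed, d)
  qrx <- qr(X1)
  if (qrx$rank < ncol(X1)) X1 <- X1[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  if (is.null(Ainv)) Ainv <- build_A_inverse(ped)
  q <- nrow(ped)
  pos <- match(ids, ped$animal)
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = pos, x = 1, dims = c(n, q))
  W1 <- cbind2(methods::as(X1, "CsparseMatrix"), Za)
  zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = dim(W1))
  W <- rbind2(cbind2(W1, zero), cbind2(zero, W1))
  p <- ncol(X1)
  off_a <- list(p + seq_len(q), ncol(W1) + p + seq_len(q))
  y1 <- as.numeric(d[[traits[1]]]); y2 <- as.numeric(d[[traits[2]]])
  parts <- list(W = W, yv = c(y1, y2), Ainv = Ainv, off_a = off_a,
                n = n, q = q)
  v1 <- stats::var(y1); v2 <- stats::var(y2)
  # Cholesky parameterization: par = (log l11, l21, log l22) per matrix
  par2mat <- function(p3) {
    L <- matrix(c(exp(p3[1]), p3[2], 0, exp(p3[3])), 2, 2)
    L %*% t(L)
  }
  fpar <- function(par) neg2_reml_biv(par2mat(par[1:3]), par2mat(par[4:6]),
                                      parts)
  start <- c(0.5 * log(v1 / 2), 0, 0.5 * log(v2 / 2),
             0.5 * log(v1 / 2), 0, 0.5 * log(v2 / 2))
  opt <- stats::nlminb(start, fpar,
                       control = list(eval.max = 1200, iter.max = 600,
                                      rel.tol = 1e-11))
  G0 <- par2mat(opt$par[1:3]); R0 <- par2mat(opt$par[4:6])
  converged <- opt$convergence == 0
  if (!converged) {
    # the optimizer can report "false convergence" at tight tolerances even
    # at a stationary point; accept if the objective is numerically flat
    g <- num_grad_fun(fpar, opt$par, rel_step = 1e-5)
    converged <- max(abs(g)) < 1e-2 * (1 + abs(opt$objective))
  }
  f_nat <- function(th) neg2_reml_biv(matrix(th[c(1, 2, 2, 3)], 2, 2),
                                      matrix(th[c(4, 5, 5, 6)], 2, 2), parts)
  theta <- c(G0[1, 1], G0[1, 2], G0[2, 2], R0[1, 1], R0[1, 2], R0[2, 2])
  vcov <- NULL
  if (se) {
    gh <- num_grad_hess(f_nat, theta, rel_step = 1e-3,
                        abs_floor = 1e-7 * (v1 + v2))
    vcov <- tryCatch(2 * solve(gh$H), error = function(e) NULL)
  }
  corr_line <- function(fun, grad_num) {
    est <- fun(theta)
    bnd <- FALSE
    if (!is.finite(est)) { est <- NA_real_ }
    else if (abs(est) > 1) { est <- sign(est); bnd <- TRUE }
    s <- if (!is.null(vcov)) ratio_se(num_grad_fun(fun, theta), vcov) else NA_real_
    data.frame(estimate = est, se = s,
               significant = significance_flag(est, s), boundary = bnd)
  }
  rg_fun <- function(th) th[2] / sqrt(th[1] * th[3])
  rp_fun <- function(th) (th[2] + th[5]) /
    sqrt((th[1] + th[4]) * (th[3] + th[6]))
  correlations <- rbind(r_g = corr_line(rg_fun), r_p = corr_line(rp_fun))
  h2 <- c(G0[1, 1] / (G0[1, 1] + R0[1, 1]), G0[2, 2] / (G0[2, 2] + R0[2, 2]))
  names(h2) <- traits
  structure(list(G0 = G0, R0 = R0, correlations = correlations, h2 = h2,
                 logLR = -0.5 * opt$objective, converged = converged,
                 n = n, traits = traits, vcov = vcov),
            class = "ovi_reml_biv")
}

# numerical gradient of a scalar function of theta (for delta-method SEs)
num_grad_fun <- function(fun, theta, rel_step = 1e-5) {
  h <- pmax(abs(theta) * rel_step, 1e-10)
  vapply(seq_along(theta), function(i) {
    ei <- replace(numeric(length(theta)), i, h[i])
    (fun(theta + ei) - fun(theta - ei)) / (2 * h[i])
  }, numeric(1))
}

#' @export
print.ovi_reml_biv <- function(x, ...) {
  cat("Bivariate animal-model REML:", paste(x$traits, collapse = " x "), "\n")
  cat(" animals:", x$n, " converged:", x$converged, "\n")
  cat(" additive covariance (G0):\n"); print(round(x$G0, 5))
  cat(" residual covariance (R0):\n"); print(round(x$R0, 5))
  cat(" correlations:\n")
  print(round(as.matrix(x$correlations[, c("estimate", "se")]), 4))
  invisible(x)
}
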
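#' Build the mixed-model equations for an animal model
#'
#' Assembles Henderson's mixed-model equations for given variance components:
#' `C [b; u] = rhs` with `C = W' R^-1 W + diag(0, Kinv_r / sigma2_r)` and
#' `W = [X, Z_1, Z_2, ...]`. Used internally by the REML engine and exposed
#' so the system can be checked against a direct generalized-least-squares
#' solve on small examples.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (aliased columns are dropped).
#' @param ranef Named list of random terms, each a list with `Z` (n x q
#'   incidence, coercible to sparse) and optionally `Kinv` (q x q sparse
#'   precision structure; identity when NULL).
#' @param sigma2 Named numeric vector of variances: one per random term (in
#'   `ranef` order) plus `residual`.
#' @return list: `C` (sparse coefficient matrix), `rhs`, `solution` (named:
#'   fixed effects then random-term blocks), `b`, `u` (list per term), `X`
#'   (full-rank), `p` (fixed-effect rank).
#' @export
build_mme <- function(y, X, ranef, sigma2) {
  pr <- mme_parts(y, X, ranef)
  sige <- sigma2[["residual"]]
  sr <- sigma2[setdiff(names(sigma2), "residual")]
  stopifnot(length(sr) == length(pr$ranef))
  C <- assemble_C(pr, c(sr, residual = sige))
  rhs <- pr$Wty / sige
  sol <- as.numeric(Matrix::solve(C, rhs))
  u <- lapply(seq_along(pr$ranef), function(k) sol[pr$offsets[[k]]])
  names(u) <- names(pr$ranef)
  list(C = C, rhs = rhs, solution = sol, b = sol[seq_len(pr$p)], u = u,
       X = pr$X, p = pr$p)
}

# Shared precomputation: full-rank X, sparse W and its crossproducts.
mme_parts <- function(y, X, ranef) {
  X <- as.matrix(X)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  p <- ncol(X)
  stopifnot(length(y) == nrow(X))
  ranef <- lapply(ranef, function(r) {
    Z <- methods::as(methods::as(r$Z, "CsparseMatrix"), "generalMatrix")
    Kinv <- if (is.null(r$Kinv)) Matrix::Diagonal(ncol(Z)) else
      Matrix::forceSymmetric(methods::as(r$Kinv, "CsparseMatrix"))
    stopifnot(nrow(Z) == length(y), ncol(Kinv) == ncol(Z))
    list(Z = Z, Kinv = Kinv, q = ncol(Z))
  })
  W <- methods::as(X, "CsparseMatrix")
  offsets <- list()
  at <- p
  for (k in seq_along(ranef)) {
    W <- cbind2(W, ranef[[k]]$Z)
    offsets[[k]] <- at + seq_len(ranef[[k]]$q)
    at <- at + ranef[[k]]$q
  }
  # full-dimension penalty blocks: C = WtW/sige + sum_k Pmats[[k]]/sigma2_k
  m <- ncol(W)
  Pmats <- lapply(seq_along(ranef), function(k) {
    Kinv <- methods::as(methods::as(ranef[[k]]$Kinv, "generalMatrix"),
                        "TsparseMatrix")
    Matrix::sparseMatrix(i = offsets[[k]][Kinv@i + 1L],
                         j = offsets[[k]][Kinv@j + 1L],
                         x = Kinv@x, dims = c(m, m), symmetric = FALSE)
  })
  list(X = X, p = p, ranef = ranef, offsets = offsets, W = W, Pmats = Pmats,
       WtW = Matrix::crossprod(W), Wty = as.numeric(Matrix::crossprod(W, y)),
       yty = sum(y^2), n = length(y))
}

assemble_C <- function(pr, theta) {
  sige <- theta[[length(theta)]]
  C <- pr$WtW / sige
  for (k in seq_along(pr$Pmats)) C <- C + pr$Pmats[[k]] / theta[[k]]
  Matrix::forceSymmetric(C)
}

# -2 x restricted log-likelihood (up to a constant not involving the
# variance parameters: the K-structure log-determinants are dropped).
neg2_reml <- function(theta, pr) {
  sige <- theta[length(theta)]
  sr <- theta[-length(theta)]
  if (any(theta <= 0) || any(!is.finite(theta))) return(1e10)
  C <- assemble_C(pr, theta)
  ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE),
                 error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  ldetC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  sol <- as.numeric(Matrix::solve(ch, pr$Wty / sige, system = "A"))
  yPy <- pr$yty / sige - sum(sol * pr$Wty) / sige
  qlog <- sum(vapply(seq_along(pr$ranef),
                     function(k) pr$ranef[[k]]$q * log(sr[k]), numeric(1)))
  pr$n * log(sige) + qlog + ldetC + yPy
}

# Numerical gradient/Hessian of f at theta (central differences).
num_grad_hess <- function(f, theta, rel_step = 1e-4, abs_floor = 1e-9) {
  k <- length(theta)
  h <- pmax(abs(theta) * rel_step, abs_floor)
  g <- numeric(k)
  H <- matrix(0, k, k)
  f0 <- f(theta)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    fp <- f(theta + ei); fm <- f(theta - ei)
    g[i] <- (fp - fm) / (2 * h[i])
    H[i, i] <- (fp - 2 * f0 + fm) / h[i]^2
  }
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      ei <- replace(numeric(k), i, h[i])
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(theta + ei + ej) - f(theta + ei - ej) -
         f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  list(g = g, H = H, f0 = f0)
}

# Quasi-Newton polish of a REML optimum on the natural variance scale;
# sharpens the solution beyond the line-search optimizer's tolerance.
newton_polish <- function(f, theta, lower, maxit = 8) {
  for (it in seq_len(maxit)) {
    gh <- num_grad_hess(f, theta)
    step <- tryCatch(solve(gh$H, gh$g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- pmax(theta - step, lower)
    if (f(cand) <= gh$f0 + 1e-10) theta <- cand else {
      cand <- pmax(theta - 0.5 * step, lower)
      if (f(cand) <= gh$f0) theta <- cand else break
    }
    if (max(abs(step) / pmax(abs(theta), lower)) < 1e-10) break
  }
  theta
}

# Core univariate REML driver over a list of variance components.
reml_fit_core <- function(y, X, ranef, floor_frac = 1e-8, se = TRUE,
                          init = NULL, control = list()) {
  pr <- mme_parts(y, X, ranef)
  vp <- stats::var(y)
  k <- length(pr$ranef) + 1L
  floor_ <- floor_frac * vp
  if (is.null(init)) init <- rep(vp / k, k)
  f_nat <- function(th) neg2_reml(th, pr)
  f_log <- function(lth) neg2_reml(exp(lth), pr)
  opt <- stats::nlminb(log(pmax(init, floor_)), f_log,
                       lower = log(floor_), upper = log(100 * vp),
                       control = utils::modifyList(
                         list(eval.max = 600, iter.max = 400,
                              rel.tol = 1e-12), control))
  theta <- exp(opt$par)
  interior <- theta > 2 * floor_
  # polish only the interior coordinates so boundary zeros stay put
  if (any(interior)) {
    f_sub <- function(sub) {
      full <- theta; full[interior] <- sub; f_nat(full)
    }
    theta[interior] <- newton_polish(f_sub, theta[interior],
                                     lower = rep(floor_, sum(interior)))
  }
  if (length(pr$ranef) == 1L && all(interior)) {
    theta <- profile_refine_single(theta, pr)
  }
  nms <- c(names(pr$ranef), "residual")
  names(theta) <- nms
  converged <- opt$convergence == 0
  if (!converged) {
    # optimizers report failure codes at stationary points under tight
    # tolerances; accept when the likelihood is flat in the free directions
    gfree <- vapply(which(interior), function(i) {
      h <- max(abs(theta[i]) * 1e-4, 1e-9)
      ei <- replace(numeric(length(theta)), i, h)
      (f_nat(theta + ei) - f_nat(theta - ei)) / (2 * h)
    }, numeric(1))
    scale_ <- abs(f_nat(theta)) + 1
    converged <- length(gfree) == 0L ||
      max(abs(gfree * theta[interior])) < 1e-4 * scale_
  }
  out <- list(components = theta, n2ll = f_nat(theta),
              logLR = -0.5 * f_nat(theta),
              converged = converged, boundary = !interior,
              n = pr$n, p = pr$p, neval = opt$evaluations[["function"]])
  if (se) {
    # observed information over the interior components only; components at
    # the floor are treated as fixed at zero (their rows/cols of the
    # covariance are zero and their own SEs are reported as NA)
    idx <- which(interior)
    if (length(idx)) {
      f_sub <- function(sub) {
        full <- theta; full[idx] <- sub; f_nat(full)
      }
      gh <- num_grad_hess(f_sub, theta[idx], rel_step = 1e-3,
                          abs_floor = 1e-5 * max(theta))
      Vsub <- tryCatch(2 * solve(gh$H), error = function(e) NULL)
      if (!is.null(Vsub)) {
        V <- matrix(0, length(theta), length(theta), dimnames = list(nms, nms))
        V[idx, idx] <- Vsub
        out$vcov <- V
        sec <- sqrt(pmax(diag(V), 0))
        sec[!interior] <- NA_real_
        names(sec) <- nms
        out$se_components <- sec
      }
    }
  }
  out
}

# With a single random term the residual variance profiles out analytically
# and the restricted likelihood is one-dimensional in the variance ratio
# gamma = sigma2_u / sigma2_e; a Brent search then locates the optimum to
# near machine precision.
profile_refine_single <- function(theta, pr) {
  q <- pr$ranef[[1]]$q
  np <- pr$n - pr$p
  prof <- function(lgamma) {
    gamma <- exp(lgamma)
    C0 <- Matrix::forceSymmetric(pr$WtW + pr$Pmats[[1]] / gamma)
    ch <- tryCatch(Matrix::Cholesky(C0, LDL = FALSE, perm = TRUE),
                   error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    sol <- as.numeric(Matrix::solve(ch, pr$Wty, system = "A"))
    S0 <- pr$yty - sum(sol * pr$Wty)
    if (S0 <= 0) return(1e10)
    sige <- S0 / np
    np * log(sige) + q * lgamma +
      2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus) + np
  }
  # analytic d prof / d log(gamma): value-based search alone cannot resolve
  # the optimum past the likelihood's rounding noise on flat surfaces
  dprof <- function(lgamma) {
    gamma <- exp(lgamma)
    C0 <- Matrix::forceSymmetric(pr$WtW + pr$Pmats[[1]] / gamma)
    sol <- as.numeric(Matrix::solve(C0, pr$Wty))
    S0 <- pr$yty - sum(sol * pr$Wty)
    uPu <- as.numeric(t(sol) %*% (pr$Pmats[[1]] %*% sol))
    trCP <- sum(Matrix::diag(Matrix::solve(C0, pr$Pmats[[1]])))
    gamma * (-np * (uPu / gamma^2) / S0 + q / gamma - trCP / gamma^2)
  }
  lg0 <- log(theta[1] / theta[2])
  opt <- stats::optimize(prof, interval = c(lg0 - 0.5, lg0 + 0.5),
                         tol = 1e-10)
  lg <- opt$minimum
  root <- tryCatch(
    stats::uniroot(dprof, c(lg - 0.05, lg + 0.05), extendInt = "yes",
                   tol = 1e-13, maxiter = 200),
    error = function(e) NULL)
  if (!is.null(root)) lg <- root$root
  gamma <- exp(lg)
  C0 <- Matrix::forceSymmetric(pr$WtW + pr$Pmats[[1]] / gamma)
  sol <- as.numeric(Matrix::solve(C0, pr$Wty))
  sige <- (pr$yty - sum(sol * pr$Wty)) / np
  cand <- c(gamma * sige, sige)
  if (neg2_reml(cand, pr) <= neg2_reml(theta, pr) + 1e-9) cand else theta
}

# Delta-method SE for a ratio g(theta) given gradient and component vcov.
ratio_se <- function(grad, vcov) {
  if (is.null(vcov)) return(NA_real_)
  v <- as.numeric(t(grad) %*% vcov %*% grad)
  if (v < 0) NA_real_ else sqrt(v)
}

#' Univariate animal-model REML
#'
#' Estimates variance components for one trait by restricted maximum
#' likelihood under a pedigree-based animal model, with optional maternal and
#' permanent-environment random effects, and derives heritabilities and
#' repeatability with delta-method standard errors.
#'
#' The additive effect is structured by the pedigree numerator relationship
#' matrix through its sparse inverse. The maternal effect is a dam-linked
#' random effect: `"genetic"` (default when enabled) ties it to the dam's
#' position in the pedigree with the same A-structure; `"iid"` fits an
#' unstructured dam effect. A permanent-environment effect is added
#' automatically when an animal has repeated records (it can be forced on or
#' off). The direct-maternal genetic covariance is fixed at zero.
#'
#' The restricted likelihood is maximized over positive components (floored
#' at `1e-8` of the phenotypic variance) by a bounded quasi-Newton search on
#' the log scale followed by a Newton polish on the natural scale; standard
#' errors come from the inverse curvature (observed information) of the
#' restricted likelihood at the optimum.
#'
#' @param data data.frame of phenotypic records (one or more rows per
#'   animal).
#' @param trait Name of the response column.
#' @param pedigree An `ovi_pedigree` (see [read_pedigree()]) covering every
#'   phenotyped animal and, for maternal models, their dams.
#' @param fixed Fixed-effect formula (right-hand side), e.g.
#'   `~ cg + cohort_pen + brr + aod + I(aod^2) + bdev`. Default `~ 1`.
#' @param animal Name of the animal-identifier column (default `"animal"`).
#' @param maternal `"none"`, `"genetic"`, or `"iid"`.
#' @param pe `NULL` (auto: on when records are repeated), `TRUE` or `FALSE`.
#' @param se Compute standard errors (default TRUE).
#' @param Ainv Optional precomputed result of [build_A_inverse()] for
#'   `pedigree`.
#' @return Object of class `ovi_reml`: variance `components` (with
#'   `se_components` and `vcov`), `ratios` (data.frame with `h2_direct`,
#'   optionally `h2_maternal` and `repeatability`: estimate, se,
#'   significant), `logLR`, `converged`, `boundary` flags, sizes.
#' @export
reml_univariate <- function(data, trait, pedigree, fixed = ~1,
                            animal = "animal", maternal = c("none", "genetic", "iid"),
                            pe = NULL, se = TRUE, Ainv = NULL) {
  maternal <- match.arg(maternal)
  ped <- as_ovi_pedigree(pedigree)
  stopifnot(trait %in% names(data), animal %in% names(data))
  d <- data[stats::complete.cases(data[, c(trait, animal), drop = FALSE]), ,
            drop = FALSE]
  y <- as.numeric(d[[trait]])
  ids <- as.character(d[[animal]])
  if (!all(ids %in% ped$animal)) {
    stop("phenotyped animals missing from pedigree: ",
         paste(utils::head(setdiff(ids, ped$animal)), collapse = ", "))
  }
  X <- stats::model.matrix(fixed, d)
  if (is.null(Ainv)) Ainv <- build_A_inverse(ped)
  n <- length(y)
  pos <- match(ids, ped$animal)
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = pos, x = 1,
                             dims = c(n, nrow(ped)))
  ranef <- list(additive = list(Z = Za, Kinv = Ainv))
  if (maternal != "none") {
    dam <- ped$dam[pos]
    if (all(is.na(dam))) {
      warning("no known dams; maternal effect dropped")
    } else {
      if (anyNA(dam)) warning(sum(is.na(dam)),
                              " record(s) with unknown dam carry no maternal effect")
      if (maternal == "genetic") {
        dpos <- match(dam, ped$animal)
        keep <- which(!is.na(dpos))
        Zm <- Matrix::sparseMatrix(i = keep, j = dpos[keep], x = 1,
                                   dims = c(n, nrow(ped)))
        ranef$maternal <- list(Z = Zm, Kinv = Ainv)
      } else {
        lev <- sort(unique(stats::na.omit(dam)))
        keep <- which(!is.na(dam))
        Zm <- Matrix::sparseMatrix(i = keep, j = match(dam[keep], lev), x = 1,
                                   dims = c(n, length(lev)))
        ranef$maternal <- list(Z = Zm, Kinv = NULL)
      }
    }
  }
  repeated <- anyDuplicated(ids) > 0
  if (is.null(pe)) pe <- repeated
  if (pe) {
    if (!repeated) warning("permanent-environment effect with single records ",
                           "is confounded with the residual")
    lev <- unique(ids)
    Zp <- Matrix::sparseMatrix(i = seq_len(n), j = match(ids, lev), x = 1,
                               dims = c(n, length(lev)))
    ranef$permanent_env <- list(Z = Zp, Kinv = NULL)
  }
  fit <- reml_fit_core(y, X, ranef, se = se)
  th <- fit$components
  tot <- sum(th)
  nms <- names(th)
  ratios <- list()
  dgrad <- function(which_num) {
    # gradient of sum(theta[num])/sum(theta) wrt theta
    num <- sum(th[which_num])
    (as.numeric(nms %in% which_num) * tot - num) / tot^2
  }
  add_ratio <- function(label, which_num) {
    est <- sum(th[which_num]) / tot
    s <- if (se) ratio_se(dgrad(which_num), fit$vcov) else NA_real_
    ratios[[label]] <<- data.frame(estimate = est, se = s,
                                   significant = significance_flag(est, s))
  }
  add_ratio("h2_direct", "additive")
  if ("maternal" %in% nms) add_ratio("h2_maternal", "maternal")
  if (repeated) {
    add_ratio("repeatability",
              intersect(c("additive", "maternal", "permanent_env"), nms))
  }
  fit$ratios <- do.call(rbind, ratios)
  fit$phenotypic_variance <- tot
  fit$trait <- trait
  fit$maternal <- maternal
  class(fit) <- "ovi_reml"
  fit
}

#' @export
print.ovi_reml <- function(x, ...) {
  cat("Animal-model REML fit for trait '", x$trait, "'\n", sep = "")
  cat(" records:", x$n, " fixed-effect rank:", x$p,
      " converged:", x$converged, "\n")
  cat(" variance components:\n")
  print(round(x$components, 5))
  cat(" ratios:\n")
  print(round(as.matrix(x$ratios[, c("estimate", "se")]), 4))
  invisible(x)
}

#' Flag an estimate as different from zero
#'
#' An estimate is declared different from zero when its absolute value
#' strictly exceeds twice its standard error.
#'
#' @param estimate Numeric estimate(s).
#' @param se Standard error(s), positive.
#' @return Logical vector (`NA` where the SE is missing).
#' @examples
#' significance_flag(-0.41, 0.15)  # TRUE
#' significance_flag(0.06, 0.18)   # FALSE
#' @export
significance_flag <- function(estimate, se) {
  ifelse(is.na(se) | is.na(estimate), NA, abs(estimate) > 2 * se)
}
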
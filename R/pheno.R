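# Phenotype derivation: ADG, ADFI and residual feed intake through a
# pedigree animal model solved by Henderson's mixed-model equations.

#' Average daily gain: OLS slope of weight on days on test
#'
#' @param day,weight_kg numeric vectors of weighing days and weights (kg);
#'   at least two distinct days.
#' @return slope in kg/day.
#' @export
compute_adg <- function(day, weight_kg) {
  stopifnot(length(day) == length(weight_kg))
  ok <- complete.cases(day, weight_kg)
  day <- day[ok]; weight_kg <- weight_kg[ok]
  if (length(unique(day)) < 2L)
    stop("compute_adg needs weights on >= 2 distinct days")
  dx <- day - mean(day)
  sum(dx * weight_kg) / sum(dx * dx)
}

#' Average daily feed intake from a quadratic fit
#'
#' Fits intake = c0 + c1 day + c2 day^2 by least squares and returns the
#' mean of the fitted curve over the integer days spanned by the animal's
#' own on-test to off-test range, so sporadically missing days do not bias
#' the average.
#'
#' @param day,intake_kg numeric vectors; at least three distinct days.
#' @return ADFI in kg/day.
#' @export
compute_adfi <- function(day, intake_kg) {
  stopifnot(length(day) == length(intake_kg))
  ok <- complete.cases(day, intake_kg)
  day <- day[ok]; intake_kg <- intake_kg[ok]
  if (length(unique(day)) < 3L)
    stop("compute_adfi needs intakes on >= 3 distinct days")
  cf <- coef(lm(intake_kg ~ day + I(day^2)))
  grid <- seq(floor(min(day)), ceiling(max(day)))
  mean(cf[1L] + cf[2L] * grid + cf[3L] * grid^2)
}

# pedigree columns as integer indices; parents must precede offspring
.ped_index <- function(pedigree) {
  id <- as.character(pedigree$animal)
  if (anyDuplicated(id)) stop("duplicate animal ids in pedigree")
  s <- match(as.character(pedigree$sire), id, nomatch = 0L)
  d <- match(as.character(pedigree$dam), id, nomatch = 0L)
  n <- length(id)
  if (any(s == seq_len(n)) || any(d == seq_len(n)))
    stop("pedigree cycle: an animal is its own parent")
  if (any(s > seq_len(n)) || any(d > seq_len(n)))
    stop("pedigree not topologically ordered: a parent follows its offspring")
  list(id = id, sire = s, dam = d, n = n)
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes F for each animal by accumulating the within-family variance
#' coefficients along the L-decomposition of the numerator relationship
#' matrix; unknown parents contribute F = -1 to the Mendelian sampling
#' variance term, giving d = 1, 0.75 or 0.5 - 0.25(F_s + F_d).
#'
#' @param pedigree data.frame with columns animal, sire, dam ("0" or NA =
#'   unknown), parents listed before offspring.
#' @return numeric vector of inbreeding coefficients.
#' @export
inbreeding_ml <- function(pedigree) {
  px <- .ped_index(pedigree)
  s <- px$sire; d <- px$dam; n <- px$n
  F <- numeric(n)
  Fpar <- function(p) if (p > 0L) F[p] else -1
  for (i in seq_len(n)) {
    if (s[i] == 0L && d[i] == 0L) { F[i] <- 0; next }
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      dj <- 0.5 - 0.25 * (Fpar(s[j]) + Fpar(d[j]))
      aii <- aii + L[j]^2 * dj
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * L[j]
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * L[j]
    }
    F[i] <- aii - 1
  }
  F
}

#' Sparse inverse numerator relationship matrix
#'
#' Henderson's rules with inbreeding from [inbreeding_ml()]: each animal
#' contributes 1/d_i to its own diagonal and the usual -1/2 and 1/4
#' parent cross terms, where d_i is the Mendelian sampling variance given
#' the parents' inbreeding.
#'
#' @param pedigree data.frame with columns animal, sire, dam, parents
#'   before offspring.
#' @return sparse symmetric matrix (Matrix::dgCMatrix) with dimnames =
#'   animal ids.
#' @export
build_a_inverse <- function(pedigree) {
  px <- .ped_index(pedigree)
  s <- px$sire; d <- px$dam; n <- px$n
  F <- inbreeding_ml(pedigree)
  Fpar <- function(p) if (p > 0L) F[p] else -1
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii[[length(ii) + 1L]] <<- i; jj[[length(jj) + 1L]] <<- j
    xx[[length(xx) + 1L]] <<- v
  }
  for (i in seq_len(n)) {
    di <- 0.5 - 0.25 * (Fpar(s[i]) + Fpar(d[i]))
    al <- 1 / di
    add(i, i, al)
    for (p in c(s[i], d[i])) {
      if (p > 0L) {
        add(i, p, -al / 2); add(p, i, -al / 2)
        add(p, p, al / 4)
      }
    }
    if (s[i] > 0L && d[i] > 0L) {
      add(s[i], d[i], al / 4); add(d[i], s[i], al / 4)
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n), dimnames = list(px$id, px$id))
}

#' Solve Henderson's mixed-model equations
#'
#' Solves
#' \deqn{\begin{pmatrix} X'X & X'Z \\ Z'X & Z'Z + G^{-1}\lambda \end{pmatrix}
#'       \begin{pmatrix} b \\ u \end{pmatrix} =
#'       \begin{pmatrix} X'y \\ Z'y \end{pmatrix}}
#' for one or more independent random effects with variance ratios
#' \eqn{\lambda = \sigma^2_e / \sigma^2_u}.  Rank deficiency in the fixed
#' part is handled by a corner constraint: aliased columns (detected by
#' pivoted QR) are set to zero, so with treatment-style designs the first
#' level of each factor is the reference.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (dense).
#' @param random named list; each element a list with `Z` (incidence
#'   matrix), `ratio` (sigma2_e / sigma2_u), and optionally `Ginv` (sparse
#'   inverse covariance structure, e.g. the A-inverse; identity if
#'   absent).  Elements with ratio `Inf` or `NULL` Z are skipped.
#' @return list with `b` (fixed solutions, aliased = 0), `u` (named list
#'   of random-effect predictions), `residuals` (y - Xb - sum Zu),
#'   `fitted_fixed` (Xb), `kept` (non-aliased fixed columns), and `C`
#'   info for variance estimation.
#' @export
solve_mme <- function(y, X, random = list()) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  random <- Filter(function(r) !is.null(r$Z) && is.finite(r$ratio), random)
  for (r in random) stopifnot(nrow(r$Z) == n, r$ratio >= 0)

  qx <- qr(X)
  kept <- sort(qx$pivot[seq_len(qx$rank)])
  Xk <- X[, kept, drop = FALSE]
  Xs <- Matrix::Matrix(Xk, sparse = TRUE)
  blocks <- list(Xs)
  for (r in random) blocks <- c(blocks, list(Matrix::Matrix(r$Z, sparse = TRUE)))
  W <- do.call(cbind, blocks)
  C <- Matrix::crossprod(W)
  rhs <- Matrix::crossprod(W, y)
  off <- ncol(Xk)
  for (r in random) {
    q <- ncol(r$Z)
    idx <- off + seq_len(q)
    Gi <- if (is.null(r$Ginv)) Matrix::Diagonal(q) else r$Ginv
    C[idx, idx] <- C[idx, idx] + Gi * r$ratio
    off <- off + q
  }
  sol <- as.numeric(Matrix::solve(C, rhs))

  b <- numeric(ncol(X))
  names(b) <- colnames(X)
  b[kept] <- sol[seq_len(ncol(Xk))]
  u <- list()
  off <- ncol(Xk)
  fitted <- as.numeric(Xk %*% sol[seq_len(ncol(Xk))])
  fit_rand <- numeric(n)
  for (nm in names(random)) {
    q <- ncol(random[[nm]]$Z)
    ui <- sol[off + seq_len(q)]
    names(ui) <- colnames(random[[nm]]$Z)
    u[[nm]] <- ui
    fit_rand <- fit_rand + as.numeric(random[[nm]]$Z %*% ui)
    off <- off + q
  }
  list(b = b, u = u, residuals = y - fitted - fit_rand,
       fitted_fixed = fitted, kept = kept, C = C, n_fixed = ncol(Xk))
}

# incidence matrix for a factor (all levels, no reference drop)
.incidence <- function(f) {
  f <- factor(f)
  Z <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

#' Assemble the per-animal phenotype table from raw records
#'
#' Derives onwt/offwt (first and last measured weight), ADG (slope of
#' weight on day), metamidwt (mean on-test weight to the 0.75 power),
#' ADFI (quadratic fit average), and the adjusted covariates adga (ADG
#' linearly corrected to a 90-180 day test window midpoint) and offbfa
#' (BF corrected to 115 kg off-test weight); correction slopes are pooled
#' within-group regressions estimated from the data.
#'
#' @param weights,intakes long data.frames (animal, day, value).
#' @param offtest data.frame (animal, BF, LMA).
#' @param pedigree pedigree/design table with animal, generation, line,
#'   sex, parity, pen, group, age_on_test.
#' @return data.frame keyed by animal with onwt, offwt, age_on_test,
#'   metamidwt, ADG, adga, ADFI, BF, offbfa, LMA plus the design columns.
#' @export
derive_phenotypes <- function(weights, intakes, offtest, pedigree) {
  ids <- pedigree$animal
  w_split <- split(weights[, c("day", "weight_kg")], weights$animal)[ids]
  i_split <- split(intakes[, c("day", "intake_kg")], intakes$animal)[ids]
  onwt <- offwt <- adg <- mmw <- adfi <- midday <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    w <- w_split[[i]]
    if (!is.null(w) && nrow(w) >= 2L) {
      w <- w[order(w$day), ]
      onwt[i] <- w$weight_kg[1L]
      offwt[i] <- w$weight_kg[nrow(w)]
      adg[i] <- compute_adg(w$day, w$weight_kg)
      mmw[i] <- mean(w$weight_kg)^0.75
      midday[i] <- mean(range(w$day))
    }
    fi <- i_split[[i]]
    if (!is.null(fi) && length(unique(fi$day)) >= 3L)
      adfi[i] <- compute_adfi(fi$day, fi$intake_kg)
  }
  out <- data.frame(animal = ids, onwt = onwt, offwt = offwt,
                    age_on_test = pedigree$age_on_test,
                    metamidwt = mmw, ADG = adg, ADFI = adfi,
                    BF = offtest$BF[match(ids, offtest$animal)],
                    LMA = offtest$LMA[match(ids, offtest$animal)],
                    generation = pedigree$generation, line = pedigree$line,
                    sex = pedigree$sex, parity = pedigree$parity,
                    pen = pedigree$pen, group = pedigree$group,
                    stringsAsFactors = FALSE)

  # adga: correct ADG to the midpoint of a 90-180 d test (age 135 d) with a
  # pooled within-group slope of ADG on test-midpoint age
  mid_age <- out$age_on_test + midday
  ok <- complete.cases(out$ADG, mid_age, out$group)
  b_age <- .pooled_slope(out$ADG[ok], mid_age[ok], out$group[ok])
  out$adga <- out$ADG - b_age * (mid_age - 135)
  # offbfa: correct BF to a 115 kg off-test weight
  ok <- complete.cases(out$BF, out$offwt, out$group)
  b_bf <- .pooled_slope(out$BF[ok], out$offwt[ok], out$group[ok])
  out$offbfa <- out$BF - b_bf * (out$offwt - 115)
  out
}

# pooled within-group regression slope of y on x
.pooled_slope <- function(y, x, g) {
  xc <- x - ave(x, g)
  yc <- y - ave(y, g)
  sxx <- sum(xc^2)
  if (sxx <= 0) return(0)
  sum(xc * yc) / sxx
}

#' Build the RFI adjustment model design
#'
#' Fixed effects of line, on-test group and sex (plus generation-by-line
#' cell intercepts when `cell_intercepts`), and a separate slope per
#' generation-by-line cell for each covariate onwt-40, age_on_test-90,
#' offwt-115, metamidwt, adga and offbfa.
#'
#' @keywords internal
.rfi_design <- function(ph, cell_intercepts = TRUE) {
  cell <- factor(paste0("g", ph$generation, "_", ph$line))
  covs <- cbind(onwt = ph$onwt - 40, age = ph$age_on_test - 90,
                offwt = ph$offwt - 115, metamidwt = ph$metamidwt,
                adga = ph$adga, offbfa = ph$offbfa)
  for (cl in levels(cell)) {
    nc <- sum(cell == cl)
    if (nc < ncol(covs))
      stop(sprintf("generation-by-line cell %s has %d animals, fewer than the %d covariates",
                   cl, nc, ncol(covs)))
  }
  X <- cbind(`(Intercept)` = 1,
             .incidence(ph$line)[, -1L, drop = FALSE],
             .incidence(ph$group)[, -1L, drop = FALSE],
             .incidence(ph$sex)[, -1L, drop = FALSE])
  if (cell_intercepts && nlevels(cell) > 1L) {
    Xc <- .incidence(cell)[, -1L, drop = FALSE]
    colnames(Xc) <- paste0("cell_", colnames(Xc))
    X <- cbind(X, Xc)
  }
  Ic <- .incidence(cell)
  for (v in colnames(covs)) {
    B <- Ic * covs[, v]
    colnames(B) <- paste0(v, "_", colnames(Ic))
    X <- cbind(X, B)
  }
  list(X = X, cell = cell)
}

#' Residual feed intake from the ADFI adjustment animal model
#'
#' Fits ADFI with fixed effects of line, on-test group, sex (and
#' generation-by-line intercepts), generation-by-line-specific slopes for
#' onwt-40, age at on-test-90, offwt-115, metamidwt, adga and offbfa, and
#' random animal (pedigree A-inverse), dam and pen-within-group effects at
#' the supplied variance ratios.  RFI is the observed ADFI minus the
#' fixed-effect and covariate prediction: the animal genetic deviation
#' stays inside RFI, which is what makes it a selectable trait.
#'
#' @param phenotypes output of [derive_phenotypes()] (rows with missing
#'   model variables are dropped).
#' @param pedigree full pedigree (may contain more animals than
#'   phenotyped ones).
#' @param ratios named numeric: variance ratios sigma2_e/sigma2_u for
#'   `animal`, `dam`, `pen`; omit or set 0/NA to drop an effect.  NULL
#'   fits the fixed model by OLS.
#' @param cell_intercepts include generation-by-line intercepts (default
#'   TRUE; makes RFI average zero within every cell).
#' @param subtract_random which random-effect predictions to remove from
#'   RFI in addition to the fixed part: "none" (default), "dam_pen", or
#'   "all".
#' @return the phenotype table with an `RFI` column added (NA where model
#'   variables are missing), plus attributes `fit` (the [solve_mme()]
#'   output) and `design`.
#' @export
compute_rfi <- function(phenotypes, pedigree, ratios = NULL,
                        cell_intercepts = TRUE,
                        subtract_random = c("none", "dam_pen", "all")) {
  subtract_random <- match.arg(subtract_random)
  need <- c("ADFI", "onwt", "offwt", "age_on_test", "metamidwt", "adga",
            "offbfa", "generation", "line", "sex", "group")
  ok <- complete.cases(phenotypes[, need])
  ph <- phenotypes[ok, , drop = FALSE]
  des <- .rfi_design(ph, cell_intercepts = cell_intercepts)
  y <- ph$ADFI

  random <- list()
  rat <- function(nm) if (!is.null(ratios) && !is.na(ratios[nm]) &&
                          ratios[nm] > 0) unname(ratios[nm]) else NULL
  if (!is.null(rat("animal"))) {
    Ainv <- build_a_inverse(pedigree)
    Za <- matrix(0, nrow(ph), nrow(Ainv),
                 dimnames = list(NULL, rownames(Ainv)))
    Za[cbind(seq_len(nrow(ph)), match(ph$animal, rownames(Ainv)))] <- 1
    random$animal <- list(Z = Za, Ginv = Ainv, ratio = rat("animal"))
  }
  if (!is.null(rat("dam"))) {
    dam <- pedigree$dam[match(ph$animal, pedigree$animal)]
    dam[dam %in% c("0", NA)] <- "unknown"
    random$dam <- list(Z = .incidence(dam), ratio = rat("dam"))
  }
  if (!is.null(rat("pen"))) {
    random$pen <- list(Z = .incidence(paste(ph$group, ph$pen)),
                       ratio = rat("pen"))
  }

  fit <- solve_mme(y, des$X, random)
  rfi <- y - fit$fitted_fixed
  if (subtract_random != "none") {
    drop_nm <- if (subtract_random == "all") names(random)
               else intersect(c("dam", "pen"), names(random))
    for (nm in drop_nm) {
      Zu <- as.numeric(random[[nm]]$Z %*% fit$u[[nm]])
      rfi <- rfi - Zu
    }
  }
  out <- phenotypes
  out$RFI <- NA_real_
  out$RFI[ok] <- rfi
  attr(out, "fit") <- fit
  attr(out, "design") <- des
  out
}

#' EM-REML variance ratios for the RFI animal model
#'
#' A simple expectation-maximisation REML for independent random effects
#' in the mixed model solved by [solve_mme()]; intended for modest desk
#' scale pedigrees.  Returns ratios sigma2_e/sigma2_u suitable for
#' [compute_rfi()].
#'
#' @param y,X,random as in [solve_mme()], with `random` carrying starting
#'   `ratio` values.
#' @param max_iter,tol iteration control on relative change in variances.
#' @return list with `ratios`, `sigma2` (named, incl. residual) and
#'   `iterations`.
#' @export
em_reml <- function(y, X, random, max_iter = 50, tol = 1e-4) {
  n <- length(y)
  qx <- qr(X)
  rank_x <- qx$rank
  sigma2_e <- var(y) / 2
  sigma2_u <- vapply(random, function(r) sigma2_e / r$ratio, 0)
  for (it in seq_len(max_iter)) {
    for (nm in names(random)) random[[nm]]$ratio <- sigma2_e / sigma2_u[nm]
    fit <- solve_mme(y, X, random)
    Cinv <- Matrix::solve(fit$C)
    off <- fit$n_fixed
    new_u <- sigma2_u
    for (nm in names(random)) {
      q <- ncol(random[[nm]]$Z)
      idx <- off + seq_len(q)
      Gi <- if (is.null(random[[nm]]$Ginv)) Matrix::Diagonal(q)
            else random[[nm]]$Ginv
      u <- fit$u[[nm]]
      tr_term <- sum(Matrix::diag(Gi %*% Cinv[idx, idx, drop = FALSE]))
      new_u[nm] <- (as.numeric(u %*% (Gi %*% u)) + sigma2_e * tr_term) / q
      off <- off + q
    }
    uy <- sum(vapply(names(random), function(nm)
      sum(fit$u[[nm]] * as.numeric(Matrix::crossprod(random[[nm]]$Z, y))), 0))
    new_e <- (sum(y * y) - sum(fit$b * as.numeric(crossprod(X, y))) - uy) /
      (n - rank_x)
    delta <- max(abs(c(new_u - sigma2_u, new_e - sigma2_e)) /
                   (abs(c(sigma2_u, sigma2_e)) + 1e-12))
    sigma2_u <- new_u; sigma2_e <- new_e
    if (delta < tol) break
  }
  list(ratios = sigma2_e / sigma2_u,
       sigma2 = c(sigma2_u, residual = sigma2_e), iterations = it)
}
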
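#' Hellinger transformation of a community matrix
#'
#' `y'_ij = sqrt(y_ij / rowsum_i)`: the square root of relative abundances.
#' Every transformed row has unit sum of squares, which makes Euclidean
#' (RDA) ordination of species counts behave like the Hellinger distance and
#' removes the double-zero problem.
#'
#' @param Y nonnegative abundance matrix (sites x taxa), positive row sums.
#' @return transformed matrix, same shape and dimnames.
#' @export
hellinger <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stopf("negative abundances")
  rs <- rowSums(Y)
  if (any(rs == 0)) {
    nm <- rownames(Y)[rs == 0][1]
    stopf("site %s has zero total abundance", if (is.null(nm)) which(rs == 0)[1] else paste0("'", nm, "'"))
  }
  sqrt(sweep(Y, 1, rs, "/"))
}

# Ezekiel's adjusted R2.
adj_r2 <- function(r2, n, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)

# Column-centre Y; standardize X dropping constant columns; orthonormal
# bases via pivoted QR (tolerance 1e-8) so collinear predictor columns are
# pruned rather than destabilizing the fit.
prep_predictors <- function(X, n, what = "X") {
  X <- as.matrix(X)
  if (nrow(X) != n) stopf("%s has %d rows, response has %d", what, nrow(X), n)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping %d constant column(s) from %s", sum(sds == 0), what)
    X <- X[, sds > 0, drop = FALSE]; sds <- sds[sds > 0]
  }
  if (!ncol(X)) return(list(Q = matrix(0, n, 0), rank = 0L, dropped = character(0)))
  Xs <- scale(X)
  qrx <- qr(Xs, tol = 1e-8)
  r <- qrx$rank
  dropped <- character(0)
  if (r < ncol(Xs)) {
    drop_idx <- qrx$pivot[(r + 1L):ncol(Xs)]
    dropped <- if (is.null(colnames(Xs))) paste0("col", drop_idx)
               else colnames(Xs)[drop_idx]
    warnf("dropping %d collinear column(s) from %s", length(dropped), what)
  }
  list(Q = qr.Q(qrx)[, seq_len(r), drop = FALSE], rank = r, dropped = dropped)
}

#' Redundancy analysis fit
#'
#' Multivariate least squares of a (column-centred) response matrix on
#' standardized predictors: the constrained-ordination engine behind
#' variation partitioning. With a `condition` block, both response and
#' predictors are first residualized on the conditioning variables (partial
#' RDA) and the reported R-squared is the semipartial fraction of the
#' *total* response variance explained by `X` beyond the condition.
#'
#' Collinear predictor columns are dropped (pivoted QR, tolerance 1e-8) with
#' a warning, and the predictor count `m` used in the adjusted R-squared
#' `1 - (1 - R2)(n - 1)/(n - m - 1)` is the post-pruning rank.
#'
#' @param Y response matrix (sites x species), centred internally.
#' @param X predictor matrix, standardized internally.
#' @param condition optional conditioning block (covariables).
#' @param rank_guard when `TRUE`, a predictor set too large for the sample
#'   is truncated to rank `n - q - 2` instead of raising the saturated-model
#'   error (used by the global test in forward selection).
#' @return object of class `rda_fit`: `r2`, `adj_r2`, `rank` (m), `fitted`,
#'   `residuals`, `ss_total`, `ss_explained`, plus the conditioning rank `q`.
#' @export
rda_fit <- function(Y, X, condition = NULL, rank_guard = FALSE) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  ss_tot <- sum(Yc^2)
  if (ss_tot == 0) stopf("response matrix has zero total variance")
  q <- 0L; Qz <- NULL
  if (!is.null(condition)) {
    pz <- prep_predictors(condition, n, "condition")
    Qz <- pz$Q; q <- pz$rank
    if (rank_guard && q > n - 3L) {
      q <- n - 3L
      Qz <- Qz[, seq_len(q), drop = FALSE]
    }
    Yw <- Yc - Qz %*% crossprod(Qz, Yc)
    X <- as.matrix(X) - Qz %*% crossprod(Qz, as.matrix(X))
  } else Yw <- Yc
  px <- prep_predictors(X, n, "X")
  Qx <- px$Q; m <- px$rank
  if (n <= m + q + 1) {
    if (!rank_guard) stopf("saturated model: n = %d with %d predictors (+%d conditioning)", n, m, q)
    m <- max(1L, n - q - 2L)
    Qx <- Qx[, seq_len(m), drop = FALSE]
  }
  fit <- Qx %*% crossprod(Qx, Yw)
  ss_exp <- sum(fit^2)
  r2 <- ss_exp / ss_tot
  a2 <- if (q == 0) adj_r2(r2, n, m)
        else {  # semipartial: difference of Ezekiel-adjusted fractions
          ss_cond <- ss_tot - sum(Yw^2)
          adj_r2((ss_cond + ss_exp) / ss_tot, n, m + q) - adj_r2(ss_cond / ss_tot, n, q)
        }
  structure(list(r2 = r2, adj_r2 = a2, rank = m, q = q, n = n,
                 fitted = fit, residuals = Yw - fit,
                 ss_total = ss_tot, ss_explained = ss_exp,
                 dropped = px$dropped, Qx = Qx, Qz = Qz, Yw = Yw),
            class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf("RDA fit: n = %d, m = %d predictor(s)%s\n", x$n, x$rank,
              if (x$q > 0) sprintf(" | %d conditioning", x$q) else ""))
  cat(sprintf("  R2 = %.4f, adjusted R2 = %.4f\n", x$r2, x$adj_r2))
  invisible(x)
}

#' @export
fitted.rda_fit <- function(object, ...) object$fitted

#' @export
residuals.rda_fit <- function(object, ...) object$residuals

#' Permutation test for a (partial) RDA
#'
#' Pseudo-F `= (SS_explained / m) / (SS_residual / (n - m - q - 1))`. The
#' null distribution permutes raw response rows when there is no
#' conditioning block, and permutes reduced-model residuals (response
#' residualized on the condition) otherwise -- the accepted default for
#' partial canonical tests. `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#' On very small samples where `n! <= n_perm` the full permutation set is
#' enumerated instead (with a warning) and the p-value is exact.
#'
#' @inheritParams rda_fit
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed; same seed gives identical p.
#' @return list of class `perm_test`: `statistic` (pseudo-F), `p_value`,
#'   `n_perm`, `df` and the observed fit.
#' @export
permutation_test <- function(Y, X, condition = NULL, n_perm = 999, seed = NULL,
                             rank_guard = FALSE) {
  fit <- rda_fit(Y, X, condition = condition, rank_guard = rank_guard)
  n <- fit$n; m <- fit$rank; q <- fit$q
  df_res <- n - m - q - 1
  if (df_res <= 0) stopf("no residual degrees of freedom")
  R <- fit$Yw                 # response residualized on condition (or centred Y)
  Qx <- fit$Qx; Qz <- fit$Qz
  ssR <- sum(R^2)
  f_stat <- function(Rp) {
    a <- crossprod(Qx, Rp); ss_exp <- sum(a * a)
    ss_res <- ssR - ss_exp
    if (!is.null(Qz)) { b <- crossprod(Qz, Rp); ss_res <- ss_res - sum(b * b) }
    (ss_exp / m) / (ss_res / df_res)
  }
  F_obs <- f_stat(R)
  exact <- n <= 7 && factorial(n) <= n_perm
  perms <- if (exact) {
    warnf("only %d distinct permutations exist; enumerating exactly", factorial(n))
    all_permutations(n)
  } else NULL
  count <- with_seed(seed, {
    if (exact) {
      sum(vapply(perms, function(ix) f_stat(R[ix, , drop = FALSE]), 0) >= F_obs - 1e-12) - 1L
    } else {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        ix <- sample.int(n)
        if (f_stat(R[ix, , drop = FALSE]) >= F_obs - 1e-12) cnt <- cnt + 1L
      }
      cnt
    }
  })
  np <- if (exact) factorial(n) - 1 else n_perm
  structure(list(statistic = F_obs, p_value = (1 + count) / (1 + np),
                 n_perm = np, df = c(m, df_res), fit = fit, exact = exact),
            class = "perm_test")
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test: pseudo-F = %.4f (df %d, %d), p = %.4g (%d perms%s)\n",
              x$statistic, x$df[1], x$df[2], x$p_value, x$n_perm,
              if (isTRUE(x$exact)) ", exact" else ""))
  invisible(x)
}

#' Forward selection with the double stopping criterion
#'
#' Standard forward selection of predictor columns for RDA, guarded against
#' overfitting in two ways: (1) a global permutation test using all
#' candidates must be significant before any selection starts; (2)
#' selection stops as soon as a candidate's permutation p-value exceeds
#' `alpha` *or* the cumulative adjusted R-squared of the selection would
#' exceed the global model's adjusted R-squared. Each step's test gets a
#' fresh seed derived from the master seed.
#'
#' @param Y response matrix (centred internally).
#' @param candidates matrix of candidate predictors (e.g. an eigenfunction
#'   basis).
#' @param alpha significance level for the global test and each step.
#' @param n_perm permutations per test.
#' @param seed master seed.
#' @return object of class `forward_sel`: data frame `steps` (variable,
#'   added R2, cumulative R2, cumulative adjusted R2, p), `selected` column
#'   names, `global` (the global `perm_test`), `global_adj_r2`.
#' @export
forward_select <- function(Y, candidates, alpha = 0.05, n_perm = 999, seed = NULL) {
  candidates <- as.matrix(candidates)
  if (is.null(colnames(candidates)))
    colnames(candidates) <- paste0("V", seq_len(ncol(candidates)))
  glob_test <- permutation_test(Y, candidates, n_perm = n_perm,
                                seed = derive_seed(seed, 0L), rank_guard = TRUE)
  gfit <- rda_fit(Y, candidates, rank_guard = TRUE)
  empty <- data.frame(variable = character(0), added_r2 = numeric(0),
                      cum_r2 = numeric(0), cum_adj_r2 = numeric(0),
                      p_value = numeric(0))
  res <- structure(list(steps = empty, selected = character(0),
                        global = glob_test, global_adj_r2 = gfit$adj_r2,
                        alpha = alpha), class = "forward_sel")
  if (glob_test$p_value > alpha) return(res)

  Yc <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  ss_tot <- sum(Yc^2)
  n <- nrow(Yc)
  Xs <- scale(candidates)
  keep_cols <- !apply(Xs, 2, function(z) any(!is.finite(z)))
  Xs <- Xs[, keep_cols, drop = FALSE]
  avail <- colnames(Xs)
  Qsel <- matrix(0, n, 0)
  steps <- empty
  cum_ss <- 0
  step <- 0L
  while (length(avail) && ncol(Qsel) < n - 2L) {
    step <- step + 1L
    # residualize remaining candidates on the selection; added SS per candidate
    Xr <- Xs[, avail, drop = FALSE]
    if (ncol(Qsel)) Xr <- Xr - Qsel %*% crossprod(Qsel, Xr)
    norms <- sqrt(colSums(Xr^2))
    usable <- norms > 1e-8 * sqrt(n)
    if (!any(usable)) break
    added <- rep(-Inf, length(avail))
    for (k in which(usable)) {
      u <- Xr[, k] / norms[k]
      added[k] <- sum(crossprod(u, Yc)^2)
    }
    best <- which.max(added)
    cand <- avail[best]
    pt <- permutation_test(Yc, Xs[, cand, drop = FALSE],
                           condition = if (ncol(Qsel)) Qsel else NULL,
                           n_perm = n_perm, seed = derive_seed(seed, step))
    if (pt$p_value > alpha) break
    new_ss <- cum_ss + added[best]
    new_adj <- adj_r2(new_ss / ss_tot, n, ncol(Qsel) + 1L)
    if (new_adj > gfit$adj_r2 && nrow(steps) > 0) break
    cum_ss <- new_ss
    Qsel <- cbind(Qsel, Xr[, best] / norms[best])
    steps <- rbind(steps, data.frame(variable = cand, added_r2 = added[best] / ss_tot,
                                     cum_r2 = cum_ss / ss_tot, cum_adj_r2 = new_adj,
                                     p_value = pt$p_value))
    avail <- avail[-best]
    if (new_adj > gfit$adj_r2) break
  }
  res$steps <- steps
  res$selected <- steps$variable
  res
}

#' @export
print.forward_sel <- function(x, ...) {
  cat(sprintf("Forward selection: global p = %.4g, global adj R2 = %.4f\n",
              x$global$p_value, x$global_adj_r2))
  if (!nrow(x$steps)) cat("  nothing selected\n") else print(x$steps, digits = 4)
  invisible(x)
}

#' Variation partitioning across 2-4 predictor blocks
#'
#' Decomposes the adjusted R-squared of a response matrix into the unique
#' and shared fractions of up to four named explanatory blocks, plus the
#' residual. Every fraction is a difference of Ezekiel-adjusted R-squared
#' values over subset unions of the blocks; the exclusive ("atom")
#' fractions are recovered by Mobius inversion of
#' `B(U) = adjR2(all) - adjR2(all \ U)`, so unique fractions equal the
#' direct difference `adjR2(all) - adjR2(all minus block)` by construction
#' and all atoms plus the residual sum to 1 exactly.
#'
#' Unique fractions are tested by [permutation_test()] with the other
#' blocks as conditioning variables; shared fractions are not testable and
#' are reported untested. Negative fractions are reported as-is and flagged
#' `empty` for display (they indicate less explained variation than chance).
#'
#' @param Y response matrix (e.g. a Hellinger-transformed community).
#' @param blocks named list of 2-4 predictor matrices.
#' @param n_perm permutations for the unique-fraction tests.
#' @param seed master seed (each block's test derives its own stream).
#' @param test run the permutation tests? `FALSE` returns fractions only.
#' @return object of class `varpart_result`: `atoms` (named exclusive
#'   fractions, names like `"A"`, `"A:B"`), `uniques`, `shared_total`,
#'   `residual`, `block_totals` (marginal adjusted R2 per block),
#'   `adj_r2_all`, `tests` data frame (block, F, p, stars), `n`, `n_perm`.
#' @export
variation_partition <- function(Y, blocks, n_perm = 999, seed = NULL, test = TRUE) {
  k <- length(blocks)
  if (k < 1 || k > 4) stopf("variation partitioning supports 1-4 blocks, got %d", k)
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    names(blocks) <- LETTERS[seq_len(k)]
  bn <- names(blocks)
  Y <- as.matrix(Y)
  n <- nrow(Y)

  subsets <- lapply(seq_len(2^k - 1), function(code) which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0))
  code_of <- function(s) sum(2^(s - 1))
  A <- numeric(2^k)  # A[code + 1] = adj R2 of the union; A[1] = 0 for empty set
  for (s in subsets) {
    Xu <- do.call(cbind, lapply(blocks[s], as.matrix))
    A[code_of(s) + 1] <- suppressWarnings(rda_fit(Y, Xu, rank_guard = TRUE)$adj_r2)
  }
  full <- 2^k - 1
  Bfun <- function(s) A[full + 1] - A[full - code_of(s) + 1]  # atoms inside s
  atoms <- numeric(length(subsets))
  names(atoms) <- vapply(subsets, function(s) paste(bn[s], collapse = ":"), "")
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    val <- 0
    for (j in seq_len(2^length(s)) - 1) {    # subsets u of s
      u <- s[bitwAnd(j, 2^(seq_along(s) - 1)) > 0]
      val <- val + (-1)^(length(s) - length(u)) * (if (length(u)) Bfun(u) else 0)
    }
    atoms[i] <- val
  }
  uniques <- atoms[match(bn, names(atoms))]
  names(uniques) <- bn
  residual <- 1 - A[full + 1]
  tests <- NULL
  if (test && k >= 2) {
    tests <- data.frame(block = bn, unique = uniques, statistic = NA_real_,
                        p_value = NA_real_, row.names = NULL)
    for (i in seq_len(k)) {
      other <- do.call(cbind, lapply(blocks[-i], as.matrix))
      pt <- suppressWarnings(
        permutation_test(Y, blocks[[i]], condition = other, n_perm = n_perm,
                         seed = derive_seed(seed, i), rank_guard = TRUE))
      tests$statistic[i] <- pt$statistic
      tests$p_value[i] <- pt$p_value
    }
    tests$stars <- stars_for(tests$p_value)
  }
  block_totals <- vapply(seq_len(k), function(i) A[code_of(i) + 1], 0)
  names(block_totals) <- bn
  structure(list(atoms = atoms, uniques = uniques,
                 shared_total = A[full + 1] - sum(uniques),
                 residual = residual, adj_r2_all = A[full + 1],
                 block_totals = block_totals, subsets_adj_r2 = A[-1],
                 tests = tests, n = n, n_perm = n_perm, empty = atoms < 0),
            class = "varpart_result")
}

stars_for <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

#' @export
print.varpart_result <- function(x, ...) {
  cat(sprintf("Variation partitioning (%d blocks, n = %d)\n",
              length(x$uniques), x$n))
  for (b in names(x$uniques)) {
    st <- if (!is.null(x$tests)) x$tests$stars[x$tests$block == b] else ""
    cat(sprintf("  unique [%s]  %6.1f%% %s%s\n", b, 100 * x$uniques[b], st,
                if (x$uniques[b] < 0) " (empty)" else ""))
  }
  cat(sprintf("  shared (all overlaps) %6.1f%%\n", 100 * x$shared_total))
  cat(sprintf("  residual              %6.1f%%\n", 100 * x$residual))
  invisible(x)
}

#' @export
summary.varpart_result <- function(object, ...) {
  out <- data.frame(fraction = c(names(object$atoms), "residual"),
                    adj_r2 = c(unname(object$atoms), object$residual))
  out$empty <- out$adj_r2 < 0
  if (!is.null(object$tests)) {
    m <- match(out$fraction, object$tests$block)
    out$statistic <- object$tests$statistic[m]
    out$p_value <- object$tests$p_value[m]
  }
  out
}

#' @export
plot.varpart_result <- function(x, main = "Variation partitioning", ...) {
  vals <- c(x$uniques, shared = x$shared_total)
  cols <- c(rep("grey35", length(x$uniques)), "grey75")
  bp <- graphics::barplot(100 * pmax(vals, 0), col = cols, ylab = "% of community variation",
                          main = main, las = 2, ...)
  if (!is.null(x$tests))
    graphics::text(bp[seq_along(x$uniques)], 100 * pmax(x$uniques, 0),
                   labels = x$tests$stars, pos = 3)
  invisible(x)
}

#' First-order jackknife species richness
#'
#' `S_jack = S_obs + f1 (m - 1) / m`, where `f1` is the number of taxa
#' occurring in exactly one of the `m` samples. Estimates the asymptotic
#' richness a finite set of replicate samples (e.g. Surber samples at one
#' site) has not yet detected.
#'
#' @param incidence samples x taxa matrix (abundances or presence);
#'   converted to presence internally. At least 2 samples.
#' @return the jackknife richness estimate (scalar).
#' @export
jackknife1_richness <- function(incidence) {
  incidence <- as.matrix(incidence) > 0
  m <- nrow(incidence)
  if (m < 2) stopf("jackknife needs at least 2 samples")
  occ <- colSums(incidence)
  sum(occ > 0) + sum(occ == 1) * (m - 1) / m
}
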
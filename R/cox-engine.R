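# Stratified Cox partial-likelihood engine.
#
# The partial log-likelihood is the sum of per-stratum contributions; ties
# are handled with the Efron approximation. All derivative sums are built
# from reverse-cumulative risk-set sums over rows sorted by decreasing
# time, so each Newton iteration is O(n * p^2) with vectorized primitives.

# Per-stratum sort order, tie-group boundaries and event groups. These do
# not depend on beta and are computed once per fit.
cox_stratum_prep <- function(X, time, status) {
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]
  ev <- status[ord]
  Xs <- X[ord, , drop = FALSE]

  r <- rle(ts)
  grp_end <- cumsum(r$lengths)                 # last sorted index of each tie group
  grp_id <- rep(seq_along(r$lengths), r$lengths)

  ev_pos <- which(ev == 1)
  groups <- split(ev_pos, grp_id[ev_pos])      # deaths grouped by event time
  d <- lengths(groups)
  B <- grp_end[as.integer(names(groups))]      # risk-set boundary per group

  single <- d == 1L
  list(
    Xs = Xs, ts = ts, ev = ev,
    d1_pos = unlist(groups[single], use.names = FALSE),
    d1_B = B[single],
    tied = unname(groups[!single]),
    tied_B = B[!single],
    group_sizes = unname(d),
    group_times = r$values[as.integer(names(groups))]
  )
}

# Symmetric p x p matrix from its packed upper triangle (column-major pairs).
sym_unflatten <- function(v, jj, kk, p) {
  M <- matrix(0, p, p)
  M[cbind(jj, kk)] <- v
  M[cbind(kk, jj)] <- v
  M
}

# Log-likelihood, score and observed information at beta, summed over strata.
cox_derivatives <- function(beta, preps, pair_j, pair_k) {
  p <- length(beta)
  loglik <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)

  for (pr in preps) {
    Xs <- pr$Xs
    eta <- drop(Xs %*% beta)
    eta <- eta - mean(eta)                     # shift-invariant stabilization
    w <- exp(eta)
    cum0 <- cumsum(w)
    cum1 <- apply(w * Xs, 2, cumsum)
    if (is.null(dim(cum1))) cum1 <- matrix(cum1, nrow = 1)
    XX <- Xs[, pair_j, drop = FALSE] * Xs[, pair_k, drop = FALSE]
    cum2 <- apply(w * XX, 2, cumsum)
    if (is.null(dim(cum2))) cum2 <- matrix(cum2, nrow = 1)

    # Untied event times (fast path).
    if (length(pr$d1_pos)) {
      e <- pr$d1_pos; B <- pr$d1_B
      denom <- cum0[B]
      S1 <- cum1[B, , drop = FALSE]
      S2 <- cum2[B, , drop = FALSE]
      loglik <- loglik + sum(eta[e]) - sum(log(denom))
      Z <- S1 / denom
      grad <- grad + colSums(Xs[e, , drop = FALSE]) - colSums(Z)
      info <- info + sym_unflatten(colSums(S2 / denom), pair_j, pair_k, p) -
        crossprod(Z)
    }

    # Tied event times: Efron's within-tie downweighting.
    if (length(pr$tied)) {
      for (g in seq_along(pr$tied)) {
        D <- pr$tied[[g]]; B <- pr$tied_B[g]; d <- length(D)
        wD <- w[D]
        d0 <- sum(wD)
        d1 <- colSums(wD * Xs[D, , drop = FALSE])
        d2 <- colSums(wD * XX[D, , drop = FALSE])
        s0 <- cum0[B]; s1 <- cum1[B, ]; s2 <- cum2[B, ]
        loglik <- loglik + sum(eta[D])
        grad <- grad + colSums(Xs[D, , drop = FALSE])
        for (k in seq_len(d) - 1L) {
          f <- k / d
          den <- s0 - f * d0
          z <- (s1 - f * d1) / den
          loglik <- loglik - log(den)
          grad <- grad - z
          info <- info + sym_unflatten((s2 - f * d2) / den, pair_j, pair_k, p) -
            tcrossprod(z)
        }
      }
    }
  }
  list(loglik = loglik, grad = grad, info = info)
}

# Newton-Raphson with step-halving. Convergence requires both a small
# score (max |gradient| < grad_tol) and a small relative log-likelihood
# change (< ll_tol).
cox_newton <- function(X, time, status, strata, init = NULL,
                       max_iter = 100L, grad_tol = 1e-7, ll_tol = 1e-9) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (sum(status) == 0L) abort("No events of the target outcome in the data.")

  strata <- as.character(strata)
  idx_by_stratum <- split(seq_along(time), strata)
  preps <- lapply(idx_by_stratum, function(ix) {
    cox_stratum_prep(X[ix, , drop = FALSE], time[ix], status[ix])
  })

  # Covariates with no within-stratum variation carry no information in a
  # stratified partial likelihood: freeze them at 0 and flag infinite
  # variance.
  no_info <- vapply(seq_len(p), function(j) {
    all(vapply(idx_by_stratum, function(ix) var(X[ix, j]) == 0, TRUE))
  }, TRUE)
  active <- which(!no_info)
  if (!length(active)) abort("Every covariate is constant within strata.")

  pair <- which(upper.tri(diag(length(active)), diag = TRUE), arr.ind = TRUE)
  pair_j <- pair[, 1]; pair_k <- pair[, 2]
  preps_a <- lapply(preps, function(pr) {
    pr$Xs <- pr$Xs[, active, drop = FALSE]
    pr
  })

  beta <- if (is.null(init)) numeric(length(active)) else init[active]
  dv <- cox_derivatives(beta, preps_a, pair_j, pair_k)
  ll <- dv$loglik
  converged <- FALSE
  iter <- 0L
  halvings <- 0L
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(dv$info, dv$grad), error = function(e) {
      abort(paste0("Singular information matrix at iteration ", iter,
                   "; possible complete separation or collinearity."))
    })
    beta_new <- beta + step
    dv_new <- cox_derivatives(beta_new, preps_a, pair_j, pair_k)
    h <- 0L
    # tolerate rounding-level decreases so the step is not halved away
    # once the optimum is reached to machine precision
    fuzz <- 1e-12 * (abs(ll) + 1)
    while ((!is.finite(dv_new$loglik) || dv_new$loglik < ll - fuzz) && h < 25L) {
      step <- step / 2
      beta_new <- beta + step
      dv_new <- cox_derivatives(beta_new, preps_a, pair_j, pair_k)
      h <- h + 1L
    }
    halvings <- halvings + h
    rel_change <- abs(dv_new$loglik - ll) / (abs(ll) + 1e-10)
    beta <- beta_new
    dv <- dv_new
    ll <- dv$loglik
    if (max(abs(beta)) > 30) {
      abort("Coefficients diverging (|beta| > 30): complete separation suspected.")
    }
    if (max(abs(dv$grad)) < grad_tol && rel_change < ll_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf(
      "Cox fit did not converge in %d iterations (max |gradient| = %.3g, last relative loglik change = %.3g).",
      max_iter, max(abs(dv$grad)), rel_change))
  }

  vc_a <- solve(dv$info)
  beta_full <- numeric(p)
  se_full <- rep(Inf, p)
  vcov_full <- matrix(NA_real_, p, p)
  beta_full[active] <- beta
  se_full[active] <- sqrt(diag(vc_a))
  vcov_full[active, active] <- vc_a
  names(beta_full) <- names(se_full) <- colnames(X)
  dimnames(vcov_full) <- list(colnames(X), colnames(X))

  list(beta = beta_full, se = se_full, vcov = vcov_full,
       loglik = ll, iterations = iter, max_gradient = max(abs(dv$grad)),
       halvings = halvings, infinite_variance = colnames(X)[no_info],
       converged = converged, preps = preps, idx_by_stratum = idx_by_stratum)
}

# Breslow cumulative baseline hazard at `horizon`, per stratum, evaluated
# at the centered covariate origin (all model-unit covariates 0):
# H0_r(t) = sum over event times t_g <= t of d_g / sum_{risk set} exp(eta).
cox_breslow_s0 <- function(fit_engine, horizon = 10) {
  beta <- fit_engine$beta
  out <- lapply(names(fit_engine$idx_by_stratum), function(s) {
    pr <- fit_engine$preps[[s]]
    eta <- drop(pr$Xs %*% beta)                # unshifted: origin is eta = 0
    cum0 <- cumsum(exp(eta))
    Bs <- c(pr$d1_B, pr$tied_B)
    ds <- c(rep(1L, length(pr$d1_B)), lengths(pr$tied))
    tms <- c(pr$group_times[pr$group_sizes == 1L],
             pr$group_times[pr$group_sizes > 1L])
    sel <- tms <= horizon
    H0 <- if (any(sel)) sum(ds[sel] / cum0[Bs[sel]]) else 0
    events_h <- sum(pr$ev == 1 & pr$ts <= horizon)
    tibble::tibble(region = s, s0_10 = exp(-H0), events_by_horizon = events_h)
  })
  dplyr::bind_rows(out)
}
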
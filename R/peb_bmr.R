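# Group-level Parametric Empirical Bayes over per-participant posteriors,
# and Bayesian Model Reduction for pruning group effects without refitting.

#' Parametric Empirical Bayes over participant posteriors
#'
#' Hierarchical Bayesian linear regression: each participant's posterior
#' mean is treated as an observation of their true parameters with the
#' posterior covariance as (within-subject) observation noise, true
#' parameters vary around group effects `B %*% x_i` with diagonal
#' between-subject covariance `Gamma`, and the group effects carry a
#' Gaussian prior. `Gamma` is optimised by evidence ascent. Because each
#' participant's full posterior covariance enters the model, correlated
#' parameters are handled jointly rather than one at a time.
#'
#' @param posteriors List of `vl_posterior` objects (or any lists with
#'   `mean` and `cov` entries on a common parameter vector).
#' @param design `n x c` matrix of group covariates; defaults to a constant
#'   plus z-scored `ages`. The first column is taken as the group mean.
#' @param ages Optional ages used to build the default design.
#' @param prior_mean,prior_var Prior mean/variance per parameter for the
#'   group-mean column (defaults: the first-level priors stored in the
#'   posteriors, or 0/1). Covariate columns get mean 0 with the same
#'   variances.
#' @param between Either `"optimise"` (default) or a numeric vector of fixed
#'   between-subject variances per parameter.
#' @return A `peb_result`: group effect matrix `Eb` (parameters x
#'   covariates), posterior `b`/`Sb` over `vec(B)`, between-subject
#'   variances `gamma`, free energy `F`, and the priors/design needed by
#'   [bmr_search()].
#' @export
peb_fit <- function(posteriors, design = NULL, ages = NULL,
                    prior_mean = NULL, prior_var = NULL,
                    between = "optimise") {
  n <- length(posteriors)
  if (n < 2) stop("need at least 2 participants")
  mu <- lapply(posteriors, function(p) as.numeric(p$mean))
  Sg <- lapply(posteriors, function(p) as.matrix(p$cov))
  p <- length(mu[[1]])
  pn <- names(posteriors[[1]]$mean)
  if (is.null(pn)) pn <- paste0("p", seq_len(p))
  if (is.null(design)) {
    design <- if (is.null(ages)) matrix(1, n, 1) else
      cbind(mean = 1, age = as.numeric(scale(ages)))
  }
  design <- as.matrix(design)
  if (nrow(design) != n) stop("design rows must match participants")
  if (qr(design)$rank < ncol(design)) stop("group design is rank deficient")
  cc <- ncol(design)
  cn <- colnames(design)
  if (is.null(cn)) cn <- c("mean", paste0("cov", seq_len(cc - 1)))[seq_len(cc)]

  if (is.null(prior_mean)) {
    pr <- posteriors[[1]]$priors
    prior_mean <- if (!is.null(pr)) unname(pr$mean[pn]) else rep(0, p)
    prior_mean[is.na(prior_mean)] <- 0
  }
  if (is.null(prior_var)) {
    pr <- posteriors[[1]]$priors
    prior_var <- if (!is.null(pr)) unname(pr$var[pn]) else rep(1, p)
    prior_var[is.na(prior_var)] <- 1
  }
  b0 <- c(prior_mean, rep(0, p * (cc - 1)))
  Cb <- rep(prior_var, cc)

  evidence <- function(lgam) {
    gam <- exp(lgam)
    iV <- lapply(seq_len(n), function(i) {
      chol2inv(chol(Sg[[i]] + diag(gam, p)))
    })
    P <- diag(1 / Cb, p * cc)
    rhs <- P %*% b0
    for (i in seq_len(n)) {
      xi <- design[i, ]
      P <- P + kronecker(tcrossprod(xi), iV[[i]])
      rhs <- rhs + kronecker(xi, iV[[i]] %*% mu[[i]])
    }
    cP <- tryCatch(chol(P), error = function(e) NULL)
    if (is.null(cP)) return(list(F = -Inf))
    b <- backsolve(cP, forwardsolve(t(cP), rhs))
    Fv <- 0
    for (i in seq_len(n)) {
      pred <- as.numeric(matrix(b, p, cc) %*% design[i, ])
      e <- mu[[i]] - pred
      cV <- chol(Sg[[i]] + diag(gam, p))
      Fv <- Fv - 0.5 * sum(forwardsolve(t(cV), e)^2) -
        sum(log(diag(cV))) - 0.5 * p * log(2 * pi)
    }
    db <- b - b0
    Fv <- Fv - 0.5 * sum(db^2 / Cb) - 0.5 * sum(log(Cb)) -
      0.5 * p * cc * log(2 * pi)
    Fv <- Fv + 0.5 * p * cc * log(2 * pi) - sum(log(diag(cP)))
    list(F = Fv, b = b, P = P, cP = cP)
  }

  if (identical(between, "optimise")) {
    lg0 <- log(pmax(prior_var / 16, 1e-8))
    opt <- optim(lg0, function(lg) -evidence(lg)$F, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-8))
    lgam <- opt$par
  } else {
    lgam <- log(pmax(as.numeric(between), 1e-12))
    if (length(lgam) == 1) lgam <- rep(lgam, p)
  }
  fit <- evidence(lgam)
  Sb <- chol2inv(fit$cP)
  Eb <- matrix(fit$b, p, cc, dimnames = list(pn, cn))
  structure(list(
    Eb = Eb, b = as.numeric(fit$b), Sb = Sb, F = fit$F,
    gamma = setNames(exp(lgam), pn),
    b0 = b0, Cb = Cb, design = design,
    parameters = pn, covariates = cn
  ), class = "peb_result")
}

#' Bayesian model reduction for Gaussian priors and posteriors
#'
#' Given a posterior obtained under a full Gaussian prior, computes the
#' change in log evidence and the posterior that *would* have been obtained
#' under a different (reduced) Gaussian prior, analytically and without
#' refitting. An unchanged prior gives exactly zero change.
#'
#' @param posterior,prior,reduced_prior Lists with `mean` and `cov`.
#' @return List with `dF` (log-evidence change), `mean`, `cov` (reduced
#'   posterior).
#' @export
bmr_evidence <- function(posterior, prior, reduced_prior) {
  m <- as.numeric(posterior$mean); S <- as.matrix(posterior$cov)
  m0 <- as.numeric(prior$mean);    C0 <- as.matrix(prior$cov)
  mr <- as.numeric(reduced_prior$mean); Cr <- as.matrix(reduced_prior$cov)
  if (isTRUE(all.equal(m0, mr, tolerance = 0)) &&
      isTRUE(all.equal(C0, Cr, tolerance = 0))) {
    # identity reduction: nothing changes, exactly
    return(list(dF = 0, mean = m, cov = S))
  }
  ldet <- function(M) {
    c <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(c)) stop("singular precision combination in BMR")
    2 * sum(log(diag(c)))
  }
  P <- chol2inv(chol(S))
  P0 <- chol2inv(chol(C0))
  Pr <- chol2inv(chol(Cr))
  Pn <- P - P0 + Pr
  cn <- tryCatch(chol(Pn), error = function(e) NULL)
  if (is.null(cn)) stop("singular precision combination in BMR")
  Sn <- chol2inv(cn)
  mn <- as.numeric(Sn %*% (P %*% m - P0 %*% m0 + Pr %*% mr))
  dF <- 0.5 * (ldet(Pr) - ldet(P0) + ldet(P) - 2 * sum(log(diag(cn)))) +
    0.5 * (sum(mn * (Pn %*% mn)) - sum(mr * (Pr %*% mr)) -
             sum(m * (P %*% m)) + sum(m0 * (P0 %*% m0)))
  list(dF = dF, mean = mn, cov = Sn)
}

#' Prune group effects by Bayesian model reduction
#'
#' Searches over on/off mixtures of switchable group effects (by default the
#' covariate effects, e.g. the age slopes), scoring each reduced model's
#' evidence analytically with [bmr_evidence()]; a pruned effect has its prior
#' shrunk to (numerically) zero variance around zero. The search is
#' exhaustive for up to `exhaustive_limit` switchable effects and greedy
#' backward beyond that. Ties in evidence are broken toward the sparser
#' model. Retained effects are reported with posterior expectations and 90%
#' credible intervals.
#'
#' @param peb A `peb_result` from [peb_fit()].
#' @param switchable Two-column matrix / data.frame of (parameter, covariate)
#'   index pairs that may be pruned; defaults to every effect of every
#'   covariate except the group mean.
#' @param exhaustive_limit Maximum number of switchable effects searched
#'   exhaustively (default 8).
#' @return A `bmr_result`: `retained` logical matrix (parameters x
#'   covariates), reduced posterior `Eb`/`b`/`Sb`, `dF` of the best model,
#'   and a tidy `table` with expectations, 90% credible intervals and flags.
#' @export
bmr_search <- function(peb, switchable = NULL, exhaustive_limit = 8) {
  p <- length(peb$parameters)
  cc <- length(peb$covariates)
  if (is.null(switchable)) {
    switchable <- if (cc > 1) {
      as.matrix(expand.grid(param = seq_len(p), covariate = 2:cc))
    } else {
      matrix(integer(0), 0, 2)
    }
  }
  switchable <- as.matrix(switchable)
  ns <- nrow(switchable)
  vec_idx <- function(i, j) (j - 1) * p + i
  sw <- if (ns) vec_idx(switchable[, 1], switchable[, 2]) else integer(0)

  post <- list(mean = peb$b, cov = peb$Sb)
  prior <- list(mean = peb$b0, cov = diag(peb$Cb, length(peb$b0)))
  score <- function(off) {
    Cr <- peb$Cb
    mr <- peb$b0
    if (length(off)) {
      Cr[off] <- 1e-10
      mr[off] <- 0
    }
    red <- tryCatch(
      bmr_evidence(post, prior, list(mean = mr, cov = diag(Cr, length(mr)))),
      error = function(e) NULL
    )
    if (is.null(red)) list(dF = -Inf) else red
  }

  best_off <- integer(0)
  best <- score(integer(0))
  if (ns && ns <= exhaustive_limit) {
    for (mset in seq_len(2^ns) - 1L) {
      off <- sw[bitwAnd(mset, 2^(seq_len(ns) - 1)) > 0]
      cand <- score(off)
      if (cand$dF > best$dF + 1e-9 ||
          (abs(cand$dF - best$dF) <= 1e-9 && length(off) > length(best_off))) {
        best <- cand
        best_off <- off
      }
    }
  } else if (ns) {
    repeat {
      improved <- FALSE
      for (s in setdiff(sw, best_off)) {
        cand <- score(sort(c(best_off, s)))
        if (cand$dF > best$dF + 1e-9) {
          best <- cand
          best_off <- sort(c(best_off, s))
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }

  retained <- matrix(TRUE, p, cc, dimnames = list(peb$parameters,
                                                  peb$covariates))
  if (length(best_off)) retained[cbind((best_off - 1) %% p + 1,
                                       (best_off - 1) %/% p + 1)] <- FALSE
  Ebr <- matrix(best$mean, p, cc,
                dimnames = list(peb$parameters, peb$covariates))
  sdv <- sqrt(pmax(diag(as.matrix(best$cov)), 0))
  zc <- qnorm(0.95)
  tab <- data.frame(
    parameter = rep(peb$parameters, cc),
    covariate = rep(peb$covariates, each = p),
    expectation = as.numeric(Ebr),
    ci_lower = as.numeric(Ebr) - zc * sdv,
    ci_upper = as.numeric(Ebr) + zc * sdv,
    retained = as.logical(retained),
    stringsAsFactors = FALSE
  )
  tab$expectation[!tab$retained] <- 0
  structure(list(retained = retained, Eb = Ebr, b = best$mean, Sb = best$cov,
                 dF = best$dF, table = tab, pruned = best_off),
            class = "bmr_result")
}
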
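#' @importFrom stats density quantile sd optim runif qbeta rnorm
#' @importFrom coda mcmc mcmc.list gelman.diag effectiveSize
NULL

#' Create a beta-regression configuration
#'
#' Returns a \linkS4class{BetaModelConfig} with the published defaults:
#' \eqn{\nu \sim \Gamma(2, 0.1)}, \eqn{\sigma \sim Exp(mean = s)} with
#' \eqn{s = sd(FPKM_w)}, \eqn{\beta \sim Beta(2, 2)}, 4 chains of 6000
#' iterations (2000 warm-up).
#'
#' @param nuPriorShape,nuPriorRate Gamma prior on the t degrees of freedom.
#' @param sigmaPriorMean mean of the exponential prior on the error scale;
#'   \code{NA} = compute from the data at fit time.
#' @param betaPriorA,betaPriorB Beta prior on the cytosolic volume fraction.
#' @param chains,iterations,warmup MCMC layout.
#' @param targetAccept,maxTreeDepth sampler tuning knobs (see class docs).
#' @param seed integer RNG seed.
#' @param errorModel \code{"student_t"} or \code{"normal"}.
#' @return a \linkS4class{BetaModelConfig}.
#' @export
betaModelConfig <- function(nuPriorShape = 2, nuPriorRate = 0.1,
                            sigmaPriorMean = NA_real_,
                            betaPriorA = 2, betaPriorB = 2,
                            chains = 4L, iterations = 6000L, warmup = 2000L,
                            targetAccept = 0.9, maxTreeDepth = 10L,
                            seed = 1L, errorModel = "student_t") {
    new("BetaModelConfig",
        nuPriorShape = nuPriorShape, nuPriorRate = nuPriorRate,
        sigmaPriorMean = sigmaPriorMean,
        betaPriorA = betaPriorA, betaPriorB = betaPriorB,
        chains = as.integer(chains), iterations = as.integer(iterations),
        warmup = as.integer(warmup), targetAccept = targetAccept,
        maxTreeDepth = as.integer(maxTreeDepth), seed = as.integer(seed),
        errorModel = errorModel)
}

## resolve the data-dependent sigma prior mean s = sd(FPKM_w)
.sigmaPriorMean <- function(config, fpkm_w) {
    s <- config@sigmaPriorMean
    if (is.na(s)) s <- sd(fpkm_w)
    if (!is.finite(s) || s <= 0) s <- 1  # degenerate constant input
    s
}

## closed-form unnormalized log posterior on the natural scale; vectorized
## over the data, scalar in (beta, nu, sigma).  a0 = w - n, a1 = c - n.
.lpCore <- function(beta, nu, sigma, a0, a1, config, s) {
    r <- a0 - beta * a1
    t <- length(r)
    if (config@errorModel == "student_t") {
        ll <- t * (lgamma((nu + 1) / 2) - lgamma(nu / 2) -
                   0.5 * log(nu * pi) - log(sigma)) -
              (nu + 1) / 2 * sum(log1p(r * r / (nu * sigma * sigma)))
    } else {
        ll <- -t * (0.5 * log(2 * pi) + log(sigma)) -
              sum(r * r) / (2 * sigma * sigma)
    }
    shp <- config@nuPriorShape; rte <- config@nuPriorRate
    lpNu <- shp * log(rte) - lgamma(shp) + (shp - 1) * log(nu) - rte * nu
    lpSigma <- -log(s) - sigma / s
    a <- config@betaPriorA; b <- config@betaPriorB
    lpBeta <- lgamma(a + b) - lgamma(a) - lgamma(b) +
        (a - 1) * log(beta) + (b - 1) * log(1 - beta)
    ll + lpNu + lpSigma + lpBeta
}

#' Log posterior density of the beta regression
#'
#' Unnormalized log posterior of \eqn{(\beta, \nu, \sigma)} under the model
#' \eqn{FPKM_w(i) = (1-\beta) FPKM_n(i) + \beta FPKM_c(i) + \epsilon_i},
#' \eqn{\epsilon_i \sim t(\nu, 0, \sigma)}, with priors
#' \eqn{\nu \sim \Gamma(shape, rate)}, \eqn{\sigma \sim Exp(mean = s)} and
#' \eqn{\beta \sim Beta(a, b)} as set in \code{config}.
#'
#' @param beta cytosolic volume fraction, in (0,1).
#' @param nu Student-t degrees of freedom, > 0.
#' @param sigma error scale, > 0.
#' @param triplet a \linkS4class{MatchedTriplet} with at least 2 transcripts.
#' @param config a \linkS4class{BetaModelConfig}.
#' @return a finite scalar log density (up to an additive constant).
#' @examples
#' tri <- matchedTriplet(c(5, 8, 3), c(4, 10, 1), c(6, 6, 5))
#' logPosterior(0.5, 4, 1, tri)
#' @export
logPosterior <- function(beta, nu, sigma, triplet, config = betaModelConfig()) {
    stopifnot(is(triplet, "MatchedTriplet"))
    if (length(beta) != 1L || beta <= 0 || beta >= 1)
        stop("domain error: beta must lie in (0,1)")
    if (nu <= 0 || sigma <= 0)
        stop("domain error: nu and sigma must be positive")
    w <- fpkmWhole(triplet); n <- fpkmNuclear(triplet); c <- fpkmCytosolic(triplet)
    if (length(w) < 2L)
        stop("triplet must contain at least 2 transcripts")
    s <- .sigmaPriorMean(config, w)
    .lpCore(beta, nu, sigma, w - n, c - n, config, s)
}

## natural <-> unconstrained transforms
.toNatural <- function(z)
    c(beta = 1 / (1 + exp(-z[1])), nu = exp(z[2]), sigma = exp(z[3]))
.logJacobian <- function(z)
    z[1] - 2 * log1p(exp(z[1])) + z[2] + z[3]  # log[b(1-b)] + log nu + log sigma

## one adaptive random-walk Metropolis chain on the unconstrained scale
.runChain <- function(a0, a1, config, s, init, iterations, warmup, chainSeed) {
    set.seed(chainSeed)
    lpost <- function(z) {
        p <- .toNatural(z)
        .lpCore(p[1], p[2], p[3], a0, a1, config, s) + .logJacobian(z)
    }
    z <- init
    lp <- lpost(z)
    if (!is.finite(lp)) return(NULL)
    d <- 3L
    keep <- matrix(NA_real_, iterations - warmup, d)
    ## Welford running moments for covariance adaptation (warm-up only)
    mu <- z; M2 <- diag(1e-4, d); nAdapt <- 1
    logLambda <- 0
    chol0 <- diag(c(0.1, 0.2, 0.2))
    cholP <- chol0
    accTarget <- 0.3  # random-walk optimum; see vignette
    for (it in seq_len(iterations)) {
        zstar <- z + (exp(logLambda) * (rnorm(d) %*% cholP))[1, ]
        lpStar <- lpost(zstar)
        acc <- is.finite(lpStar) && log(runif(1)) < lpStar - lp
        if (acc) { z <- zstar; lp <- lpStar }
        if (it <= warmup) {
            nAdapt <- nAdapt + 1
            delta <- z - mu
            mu <- mu + delta / nAdapt
            M2 <- M2 + outer(delta, z - mu)
            logLambda <- logLambda + (as.numeric(acc) - accTarget) / sqrt(it)
            if (it >= 200L && it %% 100L == 0L) {
                covEmp <- M2 / (nAdapt - 1)
                covProp <- (2.38^2 / d) * covEmp + diag(1e-10, d)
                ch <- tryCatch(chol(covProp), error = function(e) NULL)
                if (!is.null(ch)) cholP <- ch
            }
        } else {
            keep[it - warmup, ] <- z
        }
    }
    keep
}

#' Sample the posterior of the cytosolic volume fraction
#'
#' Runs adaptive random-walk Metropolis MCMC (multiple chains, warm-up
#' covariance adaptation) on the unconstrained scale
#' \eqn{(logit\,\beta, \log\nu, \log\sigma)} with exact Jacobian
#' corrections, targeting the posterior defined by [logPosterior()].
#' Convergence is summarized by the potential scale reduction factor
#' (R-hat) and the effective sample size of the pooled beta draws; a
#' warning (not an error) is emitted when R-hat exceeds 1.01 or the ESS
#' falls below 400.  The run is deterministic given \code{config@seed}.
#'
#' @param triplet a \linkS4class{MatchedTriplet} with at least 2 transcripts.
#' @param config a \linkS4class{BetaModelConfig}.
#' @return a \linkS4class{BetaPosterior}.
#' @seealso [estimateBetaMap()], [optimizeMap()], [qcBeta()]
#' @export
samplePosterior <- function(triplet, config = betaModelConfig()) {
    stopifnot(is(triplet, "MatchedTriplet"))
    w <- fpkmWhole(triplet); nn <- fpkmNuclear(triplet); cc <- fpkmCytosolic(triplet)
    if (length(w) < 2L)
        stop("triplet must contain at least 2 transcripts")
    if (length(w) < 50L)
        warning("only ", length(w), " transcripts; beta may be poorly identified")
    s <- .sigmaPriorMean(config, w)
    config@sigmaPriorMean <- s
    a0 <- w - nn; a1 <- cc - nn
    nChains <- config@chains
    nKeep <- config@iterations - config@warmup
    chains <- vector("list", nChains)
    for (k in seq_len(nChains)) {
        b0 <- qbeta(k / (nChains + 1), config@betaPriorA, config@betaPriorB)
        init <- c(log(b0 / (1 - b0)), log(10), log(s))
        chainSeed <- as.integer((abs(config@seed) + k * 7919L) %% 2147483647L)
        chains[[k]] <- .runChain(a0, a1, config, s, init,
                                 config@iterations, config@warmup, chainSeed)
    }
    ok <- !vapply(chains, is.null, logical(1))
    if (!any(ok))
        stop("inference error: log posterior non-finite at all chain ",
             "initializations (sd(FPKM_w) = ", signif(s, 4), ")")
    chains <- chains[ok]
    natural <- lapply(chains, function(m)
        cbind(beta = 1 / (1 + exp(-m[, 1])), nu = exp(m[, 2]),
              sigma = exp(m[, 3])))
    draws <- do.call(rbind, natural)
    chainIdx <- rep(seq_along(natural), each = nKeep)
    betaChains <- mcmc.list(lapply(natural, function(m) mcmc(m[, "beta"])))
    rhat <- if (length(natural) > 1L)
        unname(gelman.diag(betaChains, autoburnin = FALSE)$psrf[1, 1])
    else NA_real_
    ess <- sum(vapply(natural, function(m)
        unname(effectiveSize(mcmc(m[, "beta"]))), numeric(1)))
    if (is.finite(rhat) && rhat > 1.01)
        warning(sprintf("beta chains may not have converged: Rhat = %.3f", rhat))
    if (is.finite(ess) && ess < 400)
        warning(sprintf("low effective sample size for beta: ESS = %.0f", ess))
    post <- new("BetaPosterior", draws = draws, chain = as.integer(chainIdx),
                betaMap = NA_real_, rhatBeta = rhat, essBeta = ess,
                nTranscripts = length(w), config = config)
    post@betaMap <- estimateBetaMap(post)
    validObject(post)
    post
}

#' MAP estimate of beta from posterior draws
#'
#' The mode of the pooled beta draws, estimated by a Gaussian kernel
#' density on a 512-point grid over (0,1) with the standard reference
#' bandwidth.  A degenerate (constant) sample returns the constant.
#'
#' @param posterior a \linkS4class{BetaPosterior}, or a numeric vector of
#'   beta draws in (0,1).
#' @return the MAP estimate, a scalar in (0,1).
#' @export
estimateBetaMap <- function(posterior) {
    b <- if (is(posterior, "BetaPosterior")) betaDraws(posterior)
         else as.numeric(posterior)
    if (length(b) < 100L)
        stop("data error: at least 100 draws are required (got ",
             length(b), ")")
    if (sd(b) == 0) return(b[1])
    eps <- 1 / 1024
    den <- density(b, n = 512L, from = eps, to = 1 - eps)
    den$x[which.max(den$y)]
}

#' Deterministic MAP by bounded optimization
#'
#' Jointly maximizes [logPosterior()] over \eqn{(\beta, \nu, \sigma)} by
#' L-BFGS-B on the unconstrained scale from a fixed multi-start grid
#' (including a least-squares starting value for beta).  Provides a fast
#' deterministic cross-check of the sampling-based MAP.
#'
#' @param triplet a \linkS4class{MatchedTriplet} with at least 2 transcripts.
#' @param config a \linkS4class{BetaModelConfig}.
#' @return list with elements \code{beta}, \code{nu}, \code{sigma},
#'   \code{logPosterior}.
#' @export
optimizeMap <- function(triplet, config = betaModelConfig()) {
    stopifnot(is(triplet, "MatchedTriplet"))
    w <- fpkmWhole(triplet); nn <- fpkmNuclear(triplet); cc <- fpkmCytosolic(triplet)
    if (length(w) < 2L)
        stop("triplet must contain at least 2 transcripts")
    s <- .sigmaPriorMean(config, w)
    a0 <- w - nn; a1 <- cc - nn
    obj <- function(z) {
        p <- .toNatural(z)
        -.lpCore(p[1], p[2], p[3], a0, a1, config, s)
    }
    ## least-squares start for beta (prior mode when unidentified)
    denom <- sum(a1 * a1)
    bLS <- if (denom > 0) min(max(sum(a0 * a1) / denom, 0.05), 0.95) else 0.5
    rLS <- a0 - bLS * a1
    sLS <- max(sd(rLS), s * 1e-6, 1e-12)
    starts <- list()
    for (b0 in unique(c(bLS, 0.2, 0.5, 0.8)))
        for (nu0 in c(5, 30))
            starts[[length(starts) + 1L]] <-
                c(log(b0 / (1 - b0)), log(nu0), log(sLS))
    lower <- c(-12, log(0.1), log(s) - 25)
    upper <- c(12, log(1e4), log(s) + 25)
    best <- NULL
    for (z0 in starts) {
        fit <- tryCatch(
            optim(z0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                  control = list(maxit = 500L)),
            error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$value < best$value))
            best <- fit
    }
    if (is.null(best))
        stop("inference error: optimizer failed from every start")
    p <- .toNatural(best$par)
    list(beta = unname(p[1]), nu = unname(p[2]), sigma = unname(p[3]),
         logPosterior = -best$value)
}

#' Quality-control check on an estimated beta
#'
#' Samples whose estimated cytosolic volume fraction exceeds the threshold
#' (default 0.95) are flagged for exclusion: such values typically arise
#' from incomplete experimental fractionation or unstable regression
#' rather than biology.  The inequality is strict: exactly 0.95 passes.
#'
#' @param betaMap estimated beta in (0,1).
#' @param threshold exclusion threshold (default 0.95).
#' @return \code{"pass"} or \code{"flag_exclude"}.
#' @export
qcBeta <- function(betaMap, threshold = 0.95) {
    stopifnot(length(betaMap) == 1L, betaMap > 0, betaMap < 1)
    if (betaMap > threshold) "flag_exclude" else "pass"
}
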
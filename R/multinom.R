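# Multinomial (baseline-category) logistic regression by direct
# maximisation of the categorical log-likelihood; written in-package
# because no multinomial regression library is available in the target
# environment. The two-category case reduces exactly to binomial
# logistic regression, which serves as the cross-check in the tests.

#' Multinomial logistic regression
#'
#' Baseline-category logit model: for response categories k = 1..K with
#' reference category 1, `log(P(k)/P(1)) = x' b_k`. Fitted with BFGS on
#' the exact log-likelihood with analytic gradient.
#'
#' @param formula Model formula; the response is coerced to a factor.
#' @param data Data frame.
#' @param ref Reference category (default: first factor level).
#' @param maxit,reltol Optimiser settings passed to [stats::optim()].
#' @return Object of class `multinom_fit`: coefficient matrix (rows =
#'   non-reference categories), `vcov`, `logLik`, `AIC`, `levels`,
#'   `formula`.
#' @export
fit_multinom <- function(formula, data, ref = NULL,
                         maxit = 1000L, reltol = 1e-12) {
  mf <- stats::model.frame(formula, data)
  y <- factor(stats::model.response(mf))
  if (!is.null(ref)) y <- stats::relevel(y, ref = as.character(ref))
  K <- nlevels(y)
  if (K < 2L) stop("SingleCategory: response has fewer than 2 categories",
                   call. = FALSE)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X); p <- ncol(X)
  yi <- as.integer(y)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), yi)] <- 1

  probs_of <- function(b) {
    B <- matrix(b, p, K - 1L)
    eta <- cbind(0, X %*% B)
    eta <- eta - apply(eta, 1L, max)
    e <- exp(eta)
    e / rowSums(e)
  }
  nll <- function(b) {
    P <- probs_of(b)
    -sum(log(pmax(P[cbind(seq_len(n), yi)], 1e-300)))
  }
  grad <- function(b) {
    P <- probs_of(b)
    G <- crossprod(X, P[, -1L, drop = FALSE] - Y[, -1L, drop = FALSE])
    as.numeric(G)
  }
  opt <- stats::optim(rep(0, p * (K - 1L)), nll, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  # Newton polish for glm-grade accuracy
  for (it in 1:25) {
    g <- grad(opt$par)
    if (max(abs(g)) < 1e-8) break
    H <- stats::optimHess(opt$par, nll, grad)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- opt$par - step
    if (!is.finite(nll(cand)) || nll(cand) > opt$value + 1e-8) break
    opt$par <- cand; opt$value <- nll(cand)
  }
  B <- matrix(opt$par, p, K - 1L,
              dimnames = list(colnames(X), levels(y)[-1L]))
  H <- stats::optimHess(opt$par, nll, grad)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(opt$par),
                                                     length(opt$par)))
  npar <- p * (K - 1L)
  structure(
    list(coefficients = t(B), vcov = V, logLik = -opt$value,
         AIC = 2 * opt$value + 2 * npar, npar = npar,
         levels = levels(y), formula = formula, terms = attr(mf, "terms"),
         xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
         convergence = opt$convergence),
    class = "multinom_fit"
  )
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat("<multinom_fit>", deparse(x$formula), "\n")
  cat("AIC:", format(x$AIC), " logLik:", format(x$logLik), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.multinom_fit <- function(object, ...) object$coefficients

#' @export
logLik.multinom_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, class = "logLik")
}

#' @rdname fit_multinom
#' @param object A `multinom_fit`.
#' @param newdata Data frame of covariates.
#' @param ... Unused.
#' @return `predict()` returns a matrix of category probabilities (rows
#'   sum to 1, columns ordered as `object$levels`).
#' @export
predict.multinom_fit <- function(object, newdata, ...) {
  tt <- stats::delete.response(object$terms)
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                  xlev = object$xlevels))
  eta <- cbind(0, X %*% t(object$coefficients))
  eta <- eta - apply(eta, 1L, max)
  e <- exp(eta)
  P <- e / rowSums(e)
  colnames(P) <- object$levels
  P
}

# all sub-models of a full RHS that respect marginality (an interaction
# term requires its main effects); used for exact best-subset AIC search
marginality_subsets <- function(full_terms) {
  tl <- attr(stats::terms(full_terms), "term.labels")
  if (length(tl) == 0L) return(list(stats::reformulate("1")))
  parts <- strsplit(tl, ":", fixed = TRUE)
  subsets <- list()
  for (mask in seq.int(0L, 2L^length(tl) - 1L)) {
    inc <- bitwAnd(mask, 2L^(seq_along(tl) - 1L)) > 0
    ok <- TRUE
    for (i in which(inc)) {
      if (length(parts[[i]]) > 1L) {
        need <- parts[[i]]
        have <- unlist(parts[inc][lengths(parts[inc]) == 1L])
        if (!all(need %in% have)) { ok <- FALSE; break }
      }
    }
    if (ok) {
      subsets[[length(subsets) + 1L]] <-
        if (any(inc)) stats::reformulate(tl[inc]) else stats::reformulate("1")
    }
  }
  subsets
}
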
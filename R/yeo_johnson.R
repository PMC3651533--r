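#' Yeo-Johnson power transformation
#'
#' The Yeo-Johnson family extends the Box-Cox power family to the whole real
#' line and is strictly increasing for every lambda:
#' \deqn{\psi(x;\lambda) = ((x+1)^\lambda - 1)/\lambda \quad (x \ge 0, \lambda \ne 0)}
#' \deqn{\psi(x;\lambda) = \log(x+1) \quad (x \ge 0, \lambda = 0)}
#' \deqn{\psi(x;\lambda) = -((1-x)^{2-\lambda} - 1)/(2-\lambda) \quad (x < 0, \lambda \ne 2)}
#' \deqn{\psi(x;\lambda) = -\log(1-x) \quad (x < 0, \lambda = 2)}
#'
#' @param x numeric vector.
#' @param lambda transformation parameter.
#' @return transformed vector of the same length.
#' @export
yeo_johnson <- function(x, lambda) {
  out <- x
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-10) {
    out[neg] <- -((1 - x[neg])^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[neg] <- -log1p(-x[neg])
  }
  out
}

yj_loglik <- function(x, lambda) {
  psi <- yeo_johnson(x, lambda)
  n <- length(x)
  s2 <- stats::var(psi) * (n - 1) / n
  if (s2 <= 0) return(-Inf)
  # log-Jacobian: d psi/dx = (x+1)^(lambda-1) for x>=0, (1-x)^(1-lambda) for x<0
  jac <- (lambda - 1) * sum(log1p(abs(x)) * sign(x))
  -n / 2 * log(s2) + jac
}

#' Fit a Yeo-Johnson transformation by profile maximum likelihood
#'
#' Maximizes the Gaussian profile log-likelihood of the transformed values
#' over lambda in `[-5, 5]`.
#'
#' @param values numeric vector with at least 3 finite values and nonzero
#'   variance.
#' @param name optional variable name recorded in the result.
#' @return a `transform_spec`: list with `lambda`, `loglik`, `variable`.
#' @export
yeo_johnson_fit <- function(values, name = NULL) {
  x <- values[is.finite(values)]
  if (length(x) < 3L) stop("need at least 3 finite values")
  if (stats::var(x) == 0) stop("constant input: Yeo-Johnson fit is undefined")
  opt <- stats::optimize(function(l) yj_loglik(x, l),
                         interval = c(-5, 5), maximum = TRUE, tol = 1e-6)
  structure(list(lambda = opt$maximum, loglik = opt$objective,
                 variable = name),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat(sprintf("Yeo-Johnson transform%s: lambda = %.4f (loglik %.3f)\n",
              if (is.null(x$variable)) "" else paste0(" [", x$variable, "]"),
              x$lambda, x$loglik))
  invisible(x)
}

#' Apply a fitted transform spec
#' @param spec a `transform_spec` from [yeo_johnson_fit()].
#' @param values numeric vector.
#' @return transformed values.
#' @export
apply_transform <- function(spec, values) {
  stopifnot(inherits(spec, "transform_spec"))
  yeo_johnson(values, spec$lambda)
}
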
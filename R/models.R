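# Reversible amino-acid substitution model (JTT exchangeabilities by default)
# with discrete-gamma rate heterogeneity across sites.

#' Build a reversible amino-acid substitution model
#'
#' Constructs a JTT-type general time-reversible rate matrix
#' \eqn{Q_{ij} = s_{ij}\pi_j} from exchangeabilities \eqn{s_{ij}} and
#' equilibrium frequencies \eqn{\pi}, normalized so that the expected number
#' of substitutions per unit branch length is one
#' (\eqn{-\sum_i \pi_i Q_{ii} = 1}), together with discrete-gamma rate
#' categories of shape `alpha`.
#'
#' @param freqs either the keyword `"jtt-default"` (published JTT
#'   frequencies) or a numeric vector of 20 positive probabilities in
#'   ARNDCQEGHILKMFPSTWYV order summing to one (within 1e-8).
#' @param alpha gamma shape parameter (> 0) for among-site rate variation.
#' @param k number of discrete gamma categories (>= 1, default 4).
#' @param exchangeabilities symmetric 20x20 non-negative matrix; defaults to
#'   the JTT values.
#' @return an object of class `aa_model`: list with elements `pi`, `Q`,
#'   `alpha`, `k`, `rates` (the k category multipliers, mean 1) and a cached
#'   symmetric eigendecomposition used by [transition_matrix()].
#' @examples
#' m <- build_model(alpha = 0.5)
#' range(rowSums(m$Q))          # rows sum to zero
#' -sum(m$pi * diag(m$Q))       # unit expected rate
#' @export
build_model <- function(freqs = "jtt-default", alpha = 1, k = 4,
                        exchangeabilities = jtt_exchangeabilities()) {
  if (identical(freqs, "jtt-default")) freqs <- jtt_frequencies()
  freqs <- as.numeric(freqs)
  if (length(freqs) != 20L || any(freqs <= 0))
    stop("`freqs` must be 20 strictly positive probabilities")
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("`freqs` must sum to 1 (within 1e-8); got ", format(sum(freqs)))
  freqs <- freqs / sum(freqs)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("`alpha` must be a positive scalar")
  if (k < 1) stop("`k` must be >= 1")
  S <- as.matrix(exchangeabilities)
  if (!isTRUE(all.equal(S, t(S))) || any(S < 0))
    stop("exchangeabilities must be symmetric and non-negative")

  Q <- S * rep(freqs, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(AA_ALPHABET, AA_ALPHABET)
  names(freqs) <- AA_ALPHABET

  # eigendecomposition of the symmetrized generator for stable exp(Qt)
  sp <- sqrt(freqs)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)

  structure(list(
    pi = freqs, Q = Q, alpha = alpha, k = as.integer(k),
    rates = discrete_gamma_rates(alpha, k),
    eig_values = eig$values,
    # left/right transforms: P(t) = Linv %*% diag(exp(values*t)) %*% R
    eig_Linv = eig$vectors * rep(1 / sp, times = 20L),
    eig_R = t(eig$vectors * rep(sp, times = 20L))
  ), class = "aa_model")
}

#' @export
print.aa_model <- function(x, ...) {
  cat("Reversible amino-acid model (20 states)\n")
  cat(sprintf("  gamma shape alpha = %g, %d rate categories\n", x$alpha, x$k))
  cat(sprintf("  category rates: %s\n",
              paste(formatC(x$rates, digits = 4, format = "f"),
                    collapse = " ")))
  invisible(x)
}

#' Discrete-gamma rate multipliers (mean-of-category method)
#'
#' Divides the mean-one gamma(alpha, alpha) density into `k` equiprobable
#' categories and returns the mean rate within each category
#' (Yang's mean-based discretization), so that `mean(rates) == 1` exactly.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories (>= 1).
#' @return numeric vector of k increasing rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be > 0")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be an integer >= 1")
  if (k == 1L) return(1)
  cuts <- stats::qgamma((1:(k - 1)) / k, shape = alpha, rate = alpha)
  # E[X | category] via the incomplete-gamma identity with shape alpha + 1
  p1 <- stats::pgamma(c(0, cuts, Inf), shape = alpha + 1, rate = alpha)
  r <- diff(p1) * k
  r / mean(r)   # remove last-digit rounding so the mean is exactly 1
}

#' Transition-probability matrix P(t) = exp(Q t r)
#'
#' @param model an `aa_model` from [build_model()].
#' @param t branch length in expected substitutions/site (>= 0).
#' @param rate optional rate-category multiplier (>= 0, default 1).
#' @return 20x20 row-stochastic matrix.
#' @examples
#' m <- build_model()
#' range(rowSums(transition_matrix(m, 0.3)))
#' @export
transition_matrix <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "aa_model"))
  if (t < 0) stop("branch length `t` must be >= 0")
  if (rate < 0) stop("`rate` must be >= 0")
  P <- model$eig_Linv %*%
    (exp(model$eig_values * (t * rate)) * model$eig_R)
  # clamp tiny negative round-off
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
  P
}

#' Write / read model parameters as a plain-text key=value file
#'
#' Serializes frequencies, alpha and k so a fitted model can be reused
#' across pipeline stages.
#' @param model an `aa_model`.
#' @param path output file.
#' @return `write_model_params`: invisible path; `read_model_params`: an
#'   `aa_model` rebuilt from the stored parameters.
#' @export
write_model_params <- function(model, path) {
  stopifnot(inherits(model, "aa_model"))
  lines <- c(
    sprintf("alpha=%.10g", model$alpha),
    sprintf("k=%d", model$k),
    sprintf("freqs=%s", paste(sprintf("%.10g", model$pi), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  build_model(freqs = as.numeric(strsplit(vals[["freqs"]], ",")[[1]]),
              alpha = as.numeric(vals[["alpha"]]),
              k = as.integer(vals[["k"]]))
}
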
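#' General time-reversible substitution model with invariant sites and
#' discrete-gamma rate heterogeneity (GTR+I+Gamma)
#'
#' @param exch six exchangeabilities in the order AC, AG, AT, CG, CT, GT;
#'   the last (GT) is conventionally fixed to 1.
#' @param freqs stationary base frequencies (A, C, G, T), summing to 1.
#' @param pinv proportion of invariant sites, in `[0, 1)`.
#' @param alpha gamma shape; `Inf` means rate homogeneity.
#' @param ncat number of discrete gamma categories.
#' @return an object of class `rm_model`, kind `"gtr"`.
#' @export
gtr_model <- function(exch = rep(1, 6), freqs = rep(0.25, 4), pinv = 0,
                      alpha = Inf, ncat = 4L) {
  stopifnot(length(exch) == 6, all(exch >= 0), length(freqs) == 4)
  check_model_common(freqs, pinv, alpha, ncat)
  structure(list(kind = "gtr", k = 4L, exch = as.numeric(exch),
                 freqs = as.numeric(freqs / sum(freqs)), pinv = pinv,
                 alpha = alpha, ncat = as.integer(ncat)),
            class = "rm_model")
}

#' Two-state time-reversible model for RY-coded data
#'
#' The binary analogue of GTR applied to purine/pyrimidine characters, with
#' free state frequencies plus invariant sites and discrete-gamma rates.
#'
#' @param freqs stationary frequencies of (R, Y).
#' @param pinv proportion of invariant sites.
#' @param alpha gamma shape (`Inf` = homogeneous).
#' @param ncat gamma categories.
#' @return an object of class `rm_model`, kind `"ry"`.
#' @export
binary_model <- function(freqs = c(0.5, 0.5), pinv = 0, alpha = Inf, ncat = 4L) {
  stopifnot(length(freqs) == 2)
  check_model_common(freqs, pinv, alpha, ncat)
  structure(list(kind = "ry", k = 2L, exch = 1, freqs = as.numeric(freqs / sum(freqs)),
                 pinv = pinv, alpha = alpha, ncat = as.integer(ncat)),
            class = "rm_model")
}

check_model_common <- function(freqs, pinv, alpha, ncat) {
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-6)
    stop("frequencies must be a probability simplex")
  if (pinv < 0 || pinv >= 1) stop("pinv must be in [0, 1)")
  if (alpha <= 0) stop("alpha must be positive")
  if (ncat < 1) stop("ncat must be >= 1")
}

#' @export
print.rm_model <- function(x, ...) {
  cat(sprintf("rm_model [%s]: pinv=%.3f alpha=%s\n", x$kind, x$pinv,
              format(x$alpha, digits = 4)))
  cat("  freqs:", paste(sprintf("%.3f", x$freqs), collapse = " "), "\n")
  if (x$kind == "gtr")
    cat("  exch :", paste(sprintf("%.3f", x$exch), collapse = " "), "\n")
  invisible(x)
}

#' Normalized instantaneous rate matrix of a model
#'
#' Rows sum to zero and the matrix is scaled so that the expected number of
#' substitutions per unit branch length is 1 at stationarity
#' (`-sum(pi_i Q_ii) = 1`).
#'
#' @param model an `rm_model`.
#' @return a k x k rate matrix.
#' @export
build_rate_matrix <- function(model) {
  k <- model$k
  pi <- model$freqs
  Q <- matrix(0, k, k)
  if (k == 4) {
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (e in seq_len(6)) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      Q[i, j] <- model$exch[e] * pi[j]
      Q[j, i] <- model$exch[e] * pi[i]
    }
  } else {
    Q[1, 2] <- pi[2]; Q[2, 1] <- pi[1]
  }
  diag(Q) <- -rowSums(Q)
  sc <- -sum(pi * diag(Q))
  if (sc <= 0) stop("degenerate model: zero overall rate")
  bad <- which(pi == 0 & colSums(Q) != 0)
  if (length(bad)) stop("zero frequency with nonzero exchangeability path")
  dimnames(Q) <- if (k == 4) list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
                 else list(c("R", "Y"), c("R", "Y"))
  Q / sc
}

#' Discrete gamma rate categories
#'
#' Equal-probability bins; category rates are the per-bin means (default) or
#' medians renormalized to mean 1.
#'
#' @param alpha gamma shape (> 0).
#' @param ncat number of categories.
#' @param method `"mean"` or `"median"`.
#' @return list with `rates` (mean 1 under the category weights) and
#'   `weights` (all `1/ncat`).
#' @export
discretize_gamma <- function(alpha, ncat = 4L, method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(alpha > 0, ncat >= 1)
  # beyond this shape the discretized rates differ from 1 by < ~4e-3;
  # treated as the homogeneous limit
  if (!is.finite(alpha) || alpha > 1e5)
    return(list(rates = rep(1, ncat), weights = rep(1 / ncat, ncat)))
  if (method == "median") {
    r <- stats::qgamma((2 * seq_len(ncat) - 1) / (2 * ncat), shape = alpha,
                       rate = alpha)
    r <- r * ncat / sum(r)
  } else {
    bounds <- stats::qgamma(seq_len(ncat - 1) / ncat, shape = alpha, rate = alpha)
    cdf1 <- c(0, stats::pgamma(bounds, shape = alpha + 1, rate = alpha), 1)
    r <- diff(cdf1) * ncat
  }
  list(rates = r, weights = rep(1 / ncat, ncat))
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model an `rm_model` (or a rate matrix via `Q`).
#' @param t branch length in expected substitutions per site.
#' @param Q optional rate matrix overriding `model`.
#' @return k x k row-stochastic matrix.
#' @export
transition_probability <- function(model, t, Q = NULL) {
  if (is.null(Q)) Q <- build_rate_matrix(model)
  pi <- if (is.null(model)) rep(1 / nrow(Q), nrow(Q)) else model$freqs
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  P <- diag(1 / sp) %*% eg$vectors %*% diag(exp(eg$values * t)) %*%
    t(eg$vectors) %*% diag(sp)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

#' Empirical state frequencies of alignment columns
#' @param aln an `rm_alignment`.
#' @param columns columns to use (default all).
#' @param encoding `"nucleotide"` or `"ry"`.
#' @return frequency vector over A,C,G,T or R,Y (ambiguities excluded).
#' @export
empirical_frequencies <- function(aln, columns = NULL,
                                  encoding = c("nucleotide", "ry")) {
  encoding <- match.arg(encoding)
  if (is.null(columns)) columns <- seq_len(ncol(aln$matrix))
  ch <- as.vector(aln$matrix[, columns, drop = FALSE])
  if (encoding == "nucleotide") {
    ch[ch == "U"] <- "T"
    n <- table(factor(ch, levels = c("A", "C", "G", "T")))
  } else {
    ch[ch %in% c("A", "G")] <- "R"
    ch[ch %in% c("C", "T", "U")] <- "Y"
    n <- table(factor(ch, levels = c("R", "Y")))
  }
  n <- as.numeric(n)
  if (sum(n) == 0) return(rep(1 / length(n), length(n)))
  n / sum(n)
}
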
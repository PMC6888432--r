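## Jones-Taylor-Thornton (1992) amino-acid replacement model.
## Lower-triangle exchangeabilities (row order A R N D C Q E G H I L K M F P
## S T W Y V, the PAML convention) and stationary frequencies, as published.

JTT_EXCHANGE_LOWER <- c(
   58,
   54,  45,
   81,  16, 528,
   56, 113,  34,  10,
   57, 310,  86,  49,   9,
  105,  29,  58, 767,   5, 323,
  179, 137,  81, 130,  59,  26, 119,
   27, 328, 391, 112,  69, 597,  26,  23,
   36,  22,  47,  11,  17,   9,  12,   6,  16,
   30,  38,  12,   7,  23,  72,   9,   6,  56, 229,
   35, 646, 263,  26,   7, 292, 181,  27,  45,  21,  14,
   54,  44,  30,  15,  31,  43,  18,  14,  33, 479, 388,  65,
   15,   5,  10,   4,  78,   4,   5,   5,  40,  89, 248,   4,  43,
  194,  74,  15,  15,  14, 164,  18,  24, 115,  10, 102,  21,  16,  17,
  378, 101, 503,  59, 223,  53,  30, 201,  73,  40,  59,  47,  29,  92, 285,
  475,  64, 232,  38,  42,  51,  32,  33,  46, 245,  25, 103, 226,  12, 118, 477,
    9, 126,   8,   4, 115,  18,  10,  55,   8,   9,  52,  10,  24,  53,   6,  35,  12,
   11,  20,  70,  46, 209,  24,   7,   8, 573,  32,  24,   8,  18, 536,  10,  63,  21,  71,
  298,  17,  16,  31,  62,  20,  45,  47,  11, 961, 180,  14, 323,  62,  23,  38, 112,  25,  16)

JTT_FREQUENCIES <- c(
  A = 0.0767479232520768, R = 0.0516909483090517, N = 0.0426449573550427,
  D = 0.0515439484560515, C = 0.0198029801970198, Q = 0.0407519592480408,
  E = 0.0618299381700618, G = 0.0731519268480732, H = 0.0229439770560229,
  I = 0.0537609462390538, L = 0.0919039080960919, K = 0.0586759413240587,
  M = 0.0238259761740238, F = 0.0401259598740401, P = 0.0509009490990509,
  S = 0.0687649312350688, T = 0.0585649414350586, W = 0.0142609857390143,
  Y = 0.0321019678980321, V = 0.0660049339950660)

#' Build a reversible amino-acid substitution model
#'
#' Constructs the rate matrix `Q = S diag(pi)` from the JTT exchangeability
#' matrix `S` and stationary frequencies `pi`, normalized so the expected
#' substitution rate at stationarity is 1 (`-sum(pi_i Q_ii) = 1`), and caches
#' the eigendecomposition of its symmetrized form for fast transition
#' probabilities. With `type = "jtt+f"` the stationary frequencies are
#' replaced by frequencies observed in `alignment` (the "+F" convention); `X`
#' residues and gaps are excluded from the counts.
#'
#' @param type `"jtt"` (published frequencies) or `"jtt+f"` (observed)
#' @param alignment a [MultipleAlignment-class]; required for `"jtt+f"`
#' @return a list with elements `S`, `pi`, `Q`, and eigendecomposition parts
#'   (`values`, `U`, `W` such that `P(t) = U diag(exp(values t)) W`)
#' @export
substitutionModel <- function(type = c("jtt", "jtt+f"), alignment = NULL) {
  type <- match.arg(type)
  S <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  ## the literal above lists the lower triangle row by row (the published
  ## layout); column-major assignment into the upper triangle matches it
  S[upper.tri(S)] <- JTT_EXCHANGE_LOWER
  S <- S + t(S)
  if (type == "jtt") {
    p <- unname(JTT_FREQUENCIES)
  } else {
    if (is.null(alignment))
      stop("alignment is required for the '+F' frequency mode")
    cnt <- observedFrequencies(alignment)
    p <- unname(cnt)
  }
  p <- p / sum(p)
  Q <- S %*% diag(p)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(p * diag(Q))
  Q <- Q / mu
  ## reversible Q: symmetrize with diag(sqrt(pi)), eigendecompose once
  d <- sqrt(p)
  B <- (d %o% (1 / d)) * Q
  B <- (B + t(B)) / 2  # enforce exact symmetry against rounding
  eig <- eigen(B, symmetric = TRUE)
  U <- (1 / d) * eig$vectors          # diag(1/sqrt(pi)) %*% V
  W <- t(eig$vectors * d)             # t(V) %*% diag(sqrt(pi))
  list(type = type, S = S, pi = p, Q = Q,
       values = eig$values, U = U, W = W)
}

#' Observed amino-acid frequencies of an alignment
#'
#' Counts residues over all rows; gaps and `X` are excluded. A pseudocount of
#' 1e-10 guards against absent residues producing zero stationary
#' frequencies.
#'
#' @param alignment a [MultipleAlignment-class]
#' @return named numeric vector of length 20 summing to 1
#' @export
observedFrequencies <- function(alignment) {
  chars <- unlist(strsplit(sequences(alignment), ""), use.names = FALSE)
  cnt <- table(factor(chars, levels = AA_ALPHABET20))
  p <- as.numeric(cnt) + 1e-10
  p <- p / sum(p)
  names(p) <- AA_ALPHABET20
  p
}

#' Transition probability matrix P(t)
#'
#' `exp(Q t)` via the cached eigendecomposition; `t = 0` returns the exact
#' identity. Tiny negative entries from rounding are clamped to zero.
#'
#' @param model a model from [substitutionModel()]
#' @param t evolutionary distance (branch length times rate multiplier), >= 0
#' @return 20 x 20 row-stochastic matrix
#' @export
transitionProbabilities <- function(model, t) {
  if (t < 0) stop("evolutionary distance must be non-negative")
  if (t == 0) return(diag(20))
  P <- model$U %*% (exp(model$values * t) * model$W)
  P[P < 0] <- 0
  P
}

#' Discrete-gamma rate categories
#'
#' Discretizes a gamma prior with shape `alpha` (parameterized shape = rate =
#' `alpha`, so the prior mean is 1) into `K` equal-probability categories,
#' each represented by its bin mean, so the category rates average exactly 1.
#'
#' @param alpha gamma shape parameter, > 0
#' @param K number of categories (default 16)
#' @return list with `alpha`, `K`, `rates` (increasing, mean 1), `weights`
#'   (all `1/K`)
#' @export
gammaCategories <- function(alpha, K = 16L) {
  if (alpha <= 0) stop("alpha must be positive")
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K == 1L) return(list(alpha = alpha, K = 1L, rates = 1, weights = 1))
  b <- stats::qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
  ## mean of a gamma(alpha, alpha) restricted to (b_k, b_{k+1}]:
  ## (shape/rate) * [F_{alpha+1}(b_{k+1}) - F_{alpha+1}(b_k)] / (1/K)
  Fup <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  rates <- K * diff(Fup)
  list(alpha = alpha, K = K, rates = rates, weights = rep(1 / K, K))
}
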
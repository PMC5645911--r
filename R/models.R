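.DNA_STATES <- c("A", "C", "G", "T")
.AA_STATES <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
.RY_STATES <- c("R", "Y")

# rate matrix from symmetric exchangeabilities and stationary frequencies,
# scaled to one expected substitution per unit time
.buildQ <- function(R, freqs) {
  Q <- R %*% diag(freqs)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q / sum(-freqs * diag(Q))
}

.eigQ <- function(Q, freqs) {
  # symmetrize: S = D^(1/2) Q D^(-1/2) with D = diag(freqs)
  d <- sqrt(freqs)
  S <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  V <- diag(1 / d) %*% e$vectors
  Vinv <- t(e$vectors) %*% diag(d)
  list(values = e$values, V = V, Vinv = Vinv)
}

#' Build a substitution model
#'
#' Time-reversible models over DNA (`JC69`, `K2P`, `HKY`, `TN93`, `GTR`),
#' the binary purine/pyrimidine alphabet (`RY`), and amino acids
#' (`PoissonAA` with equal exchangeabilities, or `empiricalAA` with a
#' user-supplied 20x20 exchangeability table such as JTT).  Rate matrices
#' are scaled to one expected substitution per unit branch length.
#' Optional among-site rate variation uses a discrete gamma with
#' `nCat` mean-per-category rates.
#'
#' @param name model name.
#' @param baseFreqs stationary frequencies (defaults: uniform).
#' @param kappa transition/transversion rate ratio (K2P, HKY).
#' @param rates for `GTR`, the six exchangeabilities in order AC, AG, AT,
#'   CG, CT, GT; for `TN93`, `c(alphaR, alphaY)` with transversion rate 1.
#' @param exchangeabilities symmetric 20x20 matrix for `empiricalAA`
#'   (rows/columns in order `ARNDCQEGHILKMFPSTWYV`).
#' @param gammaShape gamma shape (alpha) for among-site rate variation, or
#'   `NULL` for rate homogeneity.
#' @param nCat number of discrete gamma categories (default 4).
#' @return a [SubstitutionModel-class].
#' @examples
#' jc <- substitutionModel("JC69")
#' gtrg <- substitutionModel("GTR", rates = c(1, 2, 1, 1, 2, 1),
#'                           baseFreqs = c(.3, .2, .2, .3), gammaShape = 0.5)
#' @export
substitutionModel <- function(name = c("JC69", "K2P", "HKY", "TN93", "GTR",
                                       "RY", "PoissonAA", "empiricalAA"),
                              baseFreqs = NULL, kappa = 2, rates = NULL,
                              exchangeabilities = NULL, gammaShape = NULL,
                              nCat = 4L) {
  name <- match.arg(name)
  if (name %in% c("JC69", "K2P", "HKY", "TN93", "GTR")) {
    states <- .DNA_STATES
    freqs <- switch(name,
      JC69 = , K2P = rep(0.25, 4),
      if (is.null(baseFreqs)) rep(0.25, 4) else baseFreqs)
    R <- matrix(1, 4, 4, dimnames = list(states, states))
    if (name %in% c("K2P", "HKY")) {
      R["A", "G"] <- R["G", "A"] <- R["C", "T"] <- R["T", "C"] <- kappa
    } else if (name == "TN93") {
      if (is.null(rates) || length(rates) != 2)
        stop("TN93 needs rates = c(alphaR, alphaY)")
      R["A", "G"] <- R["G", "A"] <- rates[1]
      R["C", "T"] <- R["T", "C"] <- rates[2]
    } else if (name == "GTR") {
      if (is.null(rates) || length(rates) != 6)
        stop("GTR needs six rates (AC, AG, AT, CG, CT, GT)")
      R["A", "C"] <- R["C", "A"] <- rates[1]
      R["A", "G"] <- R["G", "A"] <- rates[2]
      R["A", "T"] <- R["T", "A"] <- rates[3]
      R["C", "G"] <- R["G", "C"] <- rates[4]
      R["C", "T"] <- R["T", "C"] <- rates[5]
      R["G", "T"] <- R["T", "G"] <- rates[6]
    }
  } else if (name == "RY") {
    states <- .RY_STATES
    freqs <- if (is.null(baseFreqs)) c(0.5, 0.5) else baseFreqs
    R <- matrix(1, 2, 2, dimnames = list(states, states))
  } else {
    states <- .AA_STATES
    freqs <- if (is.null(baseFreqs)) rep(1 / 20, 20) else baseFreqs
    R <- if (name == "PoissonAA") matrix(1, 20, 20)
    else {
      if (is.null(exchangeabilities))
        stop("empiricalAA needs an exchangeability matrix")
      as.matrix(exchangeabilities)
    }
    dimnames(R) <- list(states, states)
  }
  freqs <- freqs / sum(freqs)
  names(freqs) <- states
  diag(R) <- 0
  Q <- .buildQ(R, freqs)
  dimnames(Q) <- list(states, states)
  new("SubstitutionModel", name = name, states = states, Q = Q,
      freqs = freqs,
      gammaShape = if (is.null(gammaShape)) numeric(0) else gammaShape,
      nCat = as.integer(nCat), eig = .eigQ(Q, freqs))
}

setMethod("show", "SubstitutionModel", function(object) {
  g <- if (length(object@gammaShape))
    sprintf("+G(alpha=%.3g, %d cat)", object@gammaShape, object@nCat) else ""
  cat(sprintf("SubstitutionModel %s%s over {%s}\n", object@name, g,
              paste(object@states, collapse = "")))
})

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [SubstitutionModel-class].
#' @param t branch length (expected substitutions per site); `t = 0`
#'   returns the identity.
#' @return states x states probability matrix.
#' @export
transitionProb <- function(model, t) {
  if (t < 0) stop("negative branch length")
  e <- model@eig
  P <- e$V %*% (exp(e$values * t) * e$Vinv)
  P[P < 0] <- 0
  dimnames(P) <- list(model@states, model@states)
  P
}

#' Mean-per-category discrete gamma rates
#'
#' Standard discretization of a gamma(shape, rate = shape) distribution
#' (mean 1) into `k` equal-probability categories, each represented by its
#' conditional mean.
#'
#' @param shape gamma shape alpha.
#' @param k number of categories.
#' @return numeric vector of k rates with mean 1.
#' @export
discreteGammaRates <- function(shape, k = 4L) {
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = shape,
                     rate = shape)
  p <- stats::pgamma(q, shape = shape + 1, rate = shape)
  r <- k * diff(p)
  r / mean(r) * 1  # exact mean 1 up to numerical error
}

## codon model (GY94-style) used by the simulator and the selection scan
.codonStates <- function() {
  nt <- .DNA_STATES
  cods <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  code <- Biostrings::GENETIC_CODE
  cods[code[cods] != "*"]
}

#' GY94-style codon substitution model
#'
#' 61-state (sense codons) model with HKY nucleotide mutation, codon
#' frequencies from nucleotide frequencies, and nonsynonymous changes
#' scaled by `omega`.  Scaled to one expected substitution per codon per
#' unit branch length.  Used by the simulator's codon mode; neutral
#' evolution corresponds to `omega = 1`.
#'
#' @param kappa transition/transversion ratio.
#' @param omega dN/dS ratio.
#' @param baseFreqs nucleotide frequencies (A, C, G, T).
#' @return a [SubstitutionModel-class] with codon states.
#' @export
codonSubstitutionModel <- function(kappa = 2, omega = 1,
                                   baseFreqs = rep(0.25, 4)) {
  states <- .codonStates()
  code <- Biostrings::GENETIC_CODE
  n <- length(states)
  ntf <- stats::setNames(baseFreqs / sum(baseFreqs), .DNA_STATES)
  freqs <- vapply(states, function(c) prod(ntf[strsplit(c, "")[[1]]]),
                  numeric(1))
  freqs <- freqs / sum(freqs)
  R <- matrix(0, n, n, dimnames = list(states, states))
  isTransition <- function(x, y) paste0(sort(c(x, y)), collapse = "") %in%
    c("AG", "CT")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    a <- strsplit(states[i], "")[[1]]; b <- strsplit(states[j], "")[[1]]
    d <- which(a != b)
    if (length(d) != 1L) next
    r <- if (isTransition(a[d], b[d])) kappa else 1
    if (code[[states[i]]] != code[[states[j]]]) r <- r * omega
    R[i, j] <- R[j, i] <- r
  }
  Q <- .buildQ(R, freqs)
  dimnames(Q) <- list(states, states)
  new("SubstitutionModel", name = "codonGY", states = states, Q = Q,
      freqs = freqs, gammaShape = numeric(0), nCat = 1L,
      eig = .eigQ(Q, freqs))
}
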
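# Substitution models: empirical amino-acid exchangeability matrices read
# from the bundled plain-text data, and parametric nucleotide rate matrices.
# Every model is normalized to one expected substitution per unit distance,
# so branch lengths and distances are in expected substitutions per site.

AA_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
PROT_MODELS <- c("DAYHOFF", "JTT", "MTREV", "LG", "WAG")
NT_MODELS <- c("JC", "K2P", "F81", "F84", "TN93", "PDIST", "RAW")

.model_cache <- new.env(parent = emptyenv())

#' Load a substitution model
#'
#' Protein models are the published empirical matrices (Dayhoff, JTT,
#' mtREV24, LG, WAG) bundled with the package; `"uniform"` is the 20-state
#' Poisson model (equal exchangeabilities and frequencies), useful because
#' its ML distance has the closed form `-(19/20) log(1 - 20 p / 19)`.
#'
#' @param name model name, case-insensitive.
#' @return A list with `name`, `exchangeabilities` (20x20 symmetric, zero
#'   diagonal) and `frequencies` (sums to 1), plus the spectral
#'   decomposition used to compute transition probabilities.
#' @export
prot_model <- function(name) {
  key <- toupper(name)
  if (!key %in% c(PROT_MODELS, "UNIFORM")) {
    stop("unknown protein model: ", name,
         " (available: ", paste(c(PROT_MODELS, "UNIFORM"), collapse = ", "), ")")
  }
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  if (key == "UNIFORM") {
    S <- matrix(1, 20, 20); diag(S) <- 0
    pi <- rep(1 / 20, 20)
  } else {
    path <- system.file("extdata", "models", paste0(tolower(key), ".txt"),
                        package = "phylokit", mustWork = TRUE)
    raw <- as.matrix(utils::read.table(path, comment.char = "#"))
    S <- unname(raw[1:20, ]); pi <- unname(raw[21, ])
    pi <- pi / sum(pi)
  }
  dimnames(S) <- list(AA_ORDER, AA_ORDER)
  names(pi) <- AA_ORDER
  m <- c(list(name = key, exchangeabilities = S, frequencies = pi),
         reversible_decomposition(S, pi))
  .model_cache[[key]] <- m
  m
}

# Q_ij = s_ij pi_j (i != j), diagonal = -rowsum, scaled so the expected
# substitution rate at equilibrium is 1. The similarity transform
# B = D^(1/2) Q D^(-1/2) with D = diag(pi) is symmetric for reversible
# models, so a symmetric eigendecomposition gives stable matrix
# exponentials: P(d) = D^(-1/2) U exp(L d) U' D^(1/2).
reversible_decomposition <- function(S, pi) {
  Q <- S * rep(pi, each = nrow(S))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  beta <- -sum(pi * diag(Q))
  Q <- Q / beta
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2  # clear rounding asymmetry
  eig <- eigen(B, symmetric = TRUE)
  list(rates = Q, eigenvalues = eig$values,
       right = eig$vectors / sq, left = t(eig$vectors * sq))
}

# transition probability matrix P(d) = exp(Q d)
transition_probs <- function(model, d) {
  P <- model$right %*% (exp(model$eigenvalues * d) * model$left)
  P[P < 0] <- 0
  P
}

# Parametric nucleotide models as (exchangeabilities, frequencies), used by
# the sequence-pair simulator. kappa parameters are transition/transversion
# rate ratios; F84's single kappa maps onto the two TN93 transition rates.
nt_model <- function(name, pi = rep(0.25, 4), kappa = 2, kappa1 = kappa,
                     kappa2 = kappa) {
  name <- toupper(name)
  stopifnot(length(pi) == 4, all(pi > 0))
  pi <- pi / sum(pi)
  names(pi) <- NT_UNAMBIG
  S <- matrix(1, 4, 4, dimnames = list(NT_UNAMBIG, NT_UNAMBIG))
  if (name %in% c("JC", "F81")) {
    if (name == "JC") pi <- stats::setNames(rep(0.25, 4), NT_UNAMBIG)
  } else if (name %in% c("K2P", "TN93")) {
    if (name == "K2P") pi <- stats::setNames(rep(0.25, 4), NT_UNAMBIG)
    S["A", "G"] <- S["G", "A"] <- kappa1
    S["C", "T"] <- S["T", "C"] <- kappa2
  } else if (name == "F84") {
    piR <- pi["A"] + pi["G"]; piY <- pi["C"] + pi["T"]
    S["A", "G"] <- S["G", "A"] <- 1 + kappa / piR
    S["C", "T"] <- S["T", "C"] <- 1 + kappa / piY
  } else {
    stop("no transition-probability function for nucleotide model ", name)
  }
  diag(S) <- 0
  c(list(name = name, exchangeabilities = S, frequencies = pi),
    reversible_decomposition(S, pi))
}
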
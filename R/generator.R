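#' Build the transition-frequency (generator) matrix
#'
#' Converts exchange times into the generator `L` of the master equation
#' \eqn{dp(t)/dt = p(t) L}: off-diagonal entries are exchange frequencies
#' \eqn{L_{ij} = 1/\tau^{ij}}, no-exchange pairs get rate 0, and each
#' diagonal entry is minus its row sum, so every row of `L` sums to zero.
#' Because \eqn{\tau} is symmetric, `L` is a symmetric matrix and the
#' chain's equilibrium distributes vibrational energy uniformly over
#' residues.
#'
#' @param tau a [tau_matrix()].
#' @return An object of class `generator_matrix`: list with `labels`,
#'   `L` (rows sum to zero) and `unit` (inverse of the tau unit).
#' @export
build_generator <- function(tau) {
  stopifnot(inherits(tau, "tau_matrix"))
  L <- 1 / tau$times
  L[is.na(L)] <- 0
  diag(L) <- 0
  diag(L) <- -rowSums(L)
  dimnames(L) <- list(tau$labels, tau$labels)
  structure(list(labels = tau$labels, L = L, unit = paste0("1/", tau$unit)),
            class = "generator_matrix")
}

#' @export
print.generator_matrix <- function(x, ...) {
  cat(sprintf("generator_matrix: %d residues, max exchange rate %.4g %s\n",
              length(x$labels), max(x$L - diag(diag(x$L))), x$unit))
  invisible(x)
}

# Connected components of the chain; component id per residue.
generator_components <- function(L) {
  adj <- L$L > 0
  diag(adj) <- FALSE
  graph_components(adj)
}

#' Stationary distribution of the energy-diffusion chain
#'
#' Returns the left null eigenvector \eqn{p^\infty} of the generator
#' (\eqn{p^\infty L = 0}), normalised to sum 1 -- the thermal equilibrium
#' in which every residue holds a fixed fraction of the total vibrational
#' energy. For the symmetric generators arising from symmetric exchange
#' times this is the uniform distribution. A reducible chain (several
#' disconnected residue groups, hence several zero eigenvalues) is an
#' error that reports the disconnected components.
#'
#' @param L a `generator_matrix`.
#' @param zero_tol eigenvalues with \eqn{|\lambda| <} `zero_tol` times the
#'   spectral radius count as zero.
#' @return named numeric vector, non-negative, summing to 1.
#' @export
stationary_distribution <- function(L, zero_tol = 1e-10) {
  stopifnot(inherits(L, "generator_matrix"))
  comp <- generator_components(L)
  if (max(comp) > 1L) {
    groups <- split(L$labels, comp)
    stop("chain is reducible; disconnected components: ",
         paste(vapply(groups, function(g) paste0("{", paste(g, collapse = ","), "}"),
                      character(1)),
               collapse = " "))
  }
  Lm <- L$L
  sym <- isSymmetric(Lm, tol = 1e-12)
  if (sym) {
    # detailed balance w.r.t. uniform: p L = 0 iff L^T p^T = 0 = L p^T
    p <- rep(1 / nrow(Lm), nrow(Lm))
    names(p) <- L$labels
    return(p)
  }
  ee <- eigen(t(Lm))
  lam <- ee$values
  rad <- max(abs(lam))
  zero <- which(abs(lam) < zero_tol * max(rad, 1))
  if (length(zero) != 1L) {
    stop("expected a single zero eigenvalue, found ", length(zero))
  }
  v <- Re(ee$vectors[, zero])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("stationary vector has negative entries")
  v <- pmax(v, 0)
  v <- v / sum(v)
  names(v) <- L$labels
  v
}

#' Propagate an energy distribution under the master equation
#'
#' Evolves a per-residue energy-fraction vector forward in time:
#' \eqn{p(t) = p(0) \exp(tL)}, using a dense matrix exponential. Total
#' mass is conserved exactly by the row-sum-zero structure of `L`;
#' as \eqn{t \to \infty} the result converges to the stationary
#' distribution.
#'
#' @param L a `generator_matrix`.
#' @param p0 named (or positionally matching) non-negative vector summing
#'   to 1: fraction of total vibrational energy per residue at time 0.
#' @param t time, in the tau unit; must be non-negative.
#' @return named numeric vector `p(t)`.
#' @export
propagate <- function(L, p0, t) {
  stopifnot(inherits(L, "generator_matrix"))
  if (t < 0) stop("propagation time must be non-negative")
  p0 <- as.numeric(p0)
  n <- length(L$labels)
  if (length(p0) != n) stop("p0 length does not match residue count")
  if (abs(sum(p0) - 1) > 1e-8) stop("p0 must sum to 1")
  if (any(p0 < 0)) stop("p0 must be non-negative")
  if (t == 0) {
    return(stats::setNames(p0, L$labels))
  }
  Pt <- as.matrix(Matrix::expm(Matrix::Matrix(t * L$L)))
  p <- drop(p0 %*% Pt)
  stats::setNames(p, L$labels)
}
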
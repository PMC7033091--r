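# Transition path theory on the residue energy-exchange chain.
#
# Given two residue clusters A (source) and B (sink), the committors
# classify where a fluctuation of vibrational energy is headed; the
# reactive flux quantifies the stationary current of energy actually in
# transit from A to B. Only relative currents are meaningful: the chain's
# global rate constant multiplies every flux by the same factor.

# Shared boundary-value solver: committor on generator Lm with value 0 on
# `zero_set`, 1 on `one_set`, harmonic (row of Lm annihilates it) elsewhere.
solve_committor <- function(Lm, labels, zero_set, one_set, residual_tol = 1e-10) {
  n <- nrow(Lm)
  i0 <- match_labels(zero_set, labels)
  i1 <- match_labels(one_set, labels)
  if (length(i0) == 0 || length(i1) == 0) stop("A and B must be non-empty")
  if (length(intersect(i0, i1))) stop("A and B must be disjoint")
  iC <- setdiff(seq_len(n), c(i0, i1))
  q <- numeric(n)
  q[i1] <- 1
  if (length(iC)) {
    M <- Lm[iC, iC, drop = FALSE]
    rhs <- -Lm[iC, i1, drop = FALSE] %*% rep(1, length(i1))
    sol <- tryCatch(solve(M, rhs), error = function(e) {
      adj <- Lm > 0
      diag(adj) <- FALSE
      comp <- graph_components(adj)
      core <- unique(comp[c(i0, i1)])
      orphans <- labels[!(comp %in% core)]
      stop("committor system is singular; intermediates not connected to ",
           "A or B: ", paste(orphans, collapse = ", "))
    })
    q[iC] <- drop(sol)
    resid <- max(abs(Lm[iC, , drop = FALSE] %*% q))
    scale <- max(abs(Lm), 1)
    if (resid > residual_tol * scale) {
      stop("committor residual ", format(resid), " exceeds tolerance")
    }
  }
  stats::setNames(q, labels)
}

#' Forward committor
#'
#' Probability, per residue, that the energy-diffusion process started
#' there reaches the sink set `B` before the source set `A`. Solves the
#' discrete harmonic boundary-value problem: `q+` is 0 on `A`, 1 on `B`,
#' and annihilated by the generator rows on all intermediates.
#'
#' @param L a `generator_matrix`.
#' @param A,B disjoint non-empty residue sets (labels or indices).
#' @return named numeric vector in \[0, 1\].
#' @export
forward_committor <- function(L, A, B) {
  stopifnot(inherits(L, "generator_matrix"))
  solve_committor(L$L, L$labels, zero_set = A, one_set = B)
}

#' Backward committor
#'
#' Probability that the process at a residue last visited `A` rather than
#' `B`. Boundary values are 1 on `A` and 0 on `B`; intermediates satisfy
#' the harmonicity condition of the time-reversed generator
#' \eqn{\tilde L_{ij} = p_j^\infty L_{ji} / p_i^\infty}. For the symmetric
#' generators produced from symmetric exchange times this reduces to
#' `1 - forward_committor`.
#'
#' @param L a `generator_matrix`.
#' @param A,B disjoint non-empty residue sets.
#' @param p_inf stationary distribution; computed from `L` when `NULL`.
#' @return named numeric vector in \[0, 1\].
#' @export
backward_committor <- function(L, A, B, p_inf = NULL) {
  stopifnot(inherits(L, "generator_matrix"))
  if (is.null(p_inf)) p_inf <- stationary_distribution(L)
  p <- as.numeric(p_inf)
  Lm <- L$L
  # time-reversed generator: Ltilde[i,j] = p[j] * L[j,i] / p[i]
  Ltilde <- t(Lm * p) / p
  solve_committor(Ltilde, L$labels, zero_set = B, one_set = A)
}

#' Reactive density
#'
#' Stationary probability of finding the system at residue `i` while on a
#' reactive (A-to-B) excursion: \eqn{m_i^R = p_i^\infty q_i^- q_i^+}.
#' Vanishes on both clusters.
#'
#' @param p_inf stationary distribution.
#' @param q_minus,q_plus backward and forward committors on the same
#'   network.
#' @return named numeric vector.
#' @export
reactive_density <- function(p_inf, q_minus, q_plus) {
  as.numeric(p_inf) * as.numeric(q_minus) * as.numeric(q_plus)
}

#' Reactive flux matrix
#'
#' Edgewise stationary current of reactive trajectories. The default
#' (`flux_variant = "source"`) is the standard transition-path-theory
#' expression \eqn{f_{ij} = p_i^\infty q_i^- L_{ij} q_j^+} (for
#' \eqn{i \ne j}), which is divergence-free on intermediates.
#' `flux_variant = "target"` weights each edge by the backward committor
#' of the target residue instead
#' (\eqn{p_i^\infty q_j^- L_{ij} q_j^+}); that variant does not conserve
#' flux and is provided for comparison only (see the package vignette).
#'
#' @param p_inf stationary distribution.
#' @param q_minus,q_plus committors.
#' @param L a `generator_matrix`.
#' @param flux_variant backward-committor index placement: `"source"`
#'   (conservative, default) or `"target"`.
#' @return non-negative matrix with zero diagonal.
#' @export
flux_matrix <- function(p_inf, q_minus, q_plus, L,
                        flux_variant = c("source", "target")) {
  stopifnot(inherits(L, "generator_matrix"))
  flux_variant <- match.arg(flux_variant)
  Lm <- L$L
  p <- as.numeric(p_inf)
  qm <- as.numeric(q_minus)
  qp <- as.numeric(q_plus)
  Loff <- Lm
  diag(Loff) <- 0
  f <- if (flux_variant == "target") {
    (p * Loff) * rep(qm * qp, each = nrow(Lm)) # f_ij = p_i q^-_j L_ij q^+_j
  } else {
    (p * qm * Loff) * rep(qp, each = nrow(Lm)) # f_ij = p_i q^-_i L_ij q^+_j
  }
  f <- pmax(f, 0)
  dimnames(f) <- dimnames(Lm)
  f
}

#' Net (effective) reactive flux
#'
#' Antisymmetrised current \eqn{f^+_{ij} = \max(f_{ij} - f_{ji}, 0)}:
#' removes back-and-forth recrossings so that the flux is divergence-free
#' on intermediates and its total across any A/B-separating cut is the
#' same.
#'
#' @param f a flux matrix (from [flux_matrix()]) or a `flux_field`.
#' @return matrix of the same shape.
#' @export
net_flux <- function(f) {
  if (inherits(f, "flux_field")) f <- f$f
  pmax(f - t(f), 0)
}

#' Total reactive current out of a cluster
#'
#' Sums the flux over all ordered pairs (i in `A`, j outside `A`): the
#' probability current of reactive trajectories leaving the source
#' cluster, equal (for the conservative flux) to the stationary frequency
#' of complete A-to-B transitions per unit time.
#'
#' @param f a flux matrix or a `flux_field` (which supplies its own `A`).
#' @param A source residue set; defaults to the field's `A`.
#' @param labels residue labels when `f` is a bare matrix without
#'   dimnames.
#' @return scalar current (inverse time units of the generator).
#' @export
total_current <- function(f, A = NULL, labels = NULL) {
  if (inherits(f, "flux_field")) {
    if (is.null(A)) A <- f$A
    labels <- f$labels
    f <- f$f
  }
  if (is.null(labels)) labels <- rownames(f)
  if (is.null(A)) stop("A must be given for a bare flux matrix")
  iA <- match_labels(A, labels)
  sum(f[iA, -iA, drop = FALSE])
}

#' Full reactive-flux field between two clusters
#'
#' Convenience constructor running the complete transition-path-theory
#' chain for one liganded state: stationary distribution, both
#' committors, reactive density, gross and net flux matrices, and the
#' total currents.
#'
#' @param L a `generator_matrix`.
#' @param A,B disjoint non-empty residue sets (source and sink clusters).
#' @param p_inf optional precomputed stationary distribution.
#' @param flux_variant passed to [flux_matrix()].
#' @return Object of class `flux_field` with elements `labels`, `A`, `B`,
#'   `p_inf`, `q_plus`, `q_minus`, `m_R`, `f`, `f_net`, `F_gross`,
#'   `F_net`, `flux_variant`, `notes`.
#' @export
flux_field <- function(L, A, B, p_inf = NULL,
                       flux_variant = c("source", "target")) {
  stopifnot(inherits(L, "generator_matrix"))
  flux_variant <- match.arg(flux_variant)
  labels <- L$labels
  iA <- match_labels(A, labels)
  iB <- match_labels(B, labels)
  if (is.null(p_inf)) p_inf <- stationary_distribution(L)
  qp <- forward_committor(L, A = labels[iA], B = labels[iB])
  qm <- backward_committor(L, A = labels[iA], B = labels[iB], p_inf = p_inf)
  mR <- reactive_density(p_inf, qm, qp)
  names(mR) <- labels
  f <- flux_matrix(p_inf, qm, qp, L, flux_variant = flux_variant)
  fn <- net_flux(f)
  notes <- c(
    "backward committor boundary: q- = 1 on A, q- = 0 on B",
    if (flux_variant == "target") {
      "flux formula: target-committor variant f_ij = p_i q-_j L_ij q+_j (not conservative)"
    } else {
      "flux formula: standard TPT f_ij = p_i q-_i L_ij q+_j"
    }
  )
  structure(list(labels = labels, A = labels[iA], B = labels[iB],
                 p_inf = p_inf, q_plus = qp, q_minus = qm, m_R = mR,
                 f = f, f_net = fn,
                 F_gross = sum(f[iA, -iA, drop = FALSE]),
                 F_net = sum(fn[iA, -iA, drop = FALSE]),
                 flux_variant = flux_variant, notes = notes),
            class = "flux_field")
}

#' @export
print.flux_field <- function(x, ...) {
  cat(sprintf("flux_field: |A| = %d, |B| = %d, %d intermediates\n",
              length(x$A), length(x$B),
              length(x$labels) - length(x$A) - length(x$B)))
  cat(sprintf("  F (gross) = %.6g, F (net) = %.6g\n", x$F_gross, x$F_net))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
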
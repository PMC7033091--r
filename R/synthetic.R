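# Synthetic exchange-time matrices with planted metastable structure.
#
# Real exchange times come from long molecular-dynamics simulations; for
# testing and method validation this module plants the essential features
# instead: a small number of residue blocks with fast internal exchange
# and much slower exchange between blocks, lognormal multiplicative noise
# on the rates, an optional pre-masked residue range (emulating exclusion
# of a mobile loop), and a "modulator" perturbation that accelerates
# inter-block exchange at chosen hotspot residues.

#' Generate an exchange-time matrix with planted metastable blocks
#'
#' Exchange rates (not times) are drawn lognormally: the median rate is
#' `k_in` within blocks and `k_in / ratio` between blocks, with `noise`
#' the log-space standard deviation. Times are the reciprocal rates, so
#' the matrix is symmetric, fully connected, and strictly positive.
#' Residue labels are random one-letter amino-acid codes with consecutive
#' author numbers starting at `residue_start`; an `exclude` range removes
#' those residues after generation (subsetting, so retained entries do
#' not depend on whether the exclusion was applied).
#'
#' Defaults (N = 40, two equal blocks, separation ratio 100, noise 0.3)
#' give a network whose metastable split is unambiguous but whose rates
#' vary several-fold, mimicking the heterogeneity of per-residue-pair
#' exchange estimates.
#'
#' @param n number of residues before exclusion (>= 6).
#' @param blocks number of planted blocks (2 to n/3), or use `block_sizes`.
#' @param ratio separation `k_in / k_out` between intra- and inter-block
#'   median rates; must exceed 1.
#' @param k_in median intra-block exchange rate (arbitrary inverse time).
#' @param noise lognormal sigma on rates (0 = deterministic).
#' @param seed integer seed; generation is fully determined by it.
#' @param block_sizes optional explicit block sizes (overrides `blocks`).
#' @param residue_start first author residue number.
#' @param exclude optional ranges passed to [mask_residues()].
#' @return Object of class `planted_system`: `tau` (a `tau_matrix`),
#'   `clusters` (named integer vector of true block ids), `hotspots`
#'   (empty), `params`.
#' @export
generate_block_tau <- function(n = 40, blocks = 2, ratio = 100, k_in = 1,
                               noise = 0.3, seed = 1, block_sizes = NULL,
                               residue_start = 1, exclude = NULL) {
  if (is.null(block_sizes)) {
    if (n < 6) stop("need at least 6 residues")
    if (blocks < 2 || blocks > n / 3) stop("blocks must lie in [2, n/3]")
    block_sizes <- rep(n %/% blocks, blocks)
    extra <- n - sum(block_sizes)
    if (extra > 0) block_sizes[seq_len(extra)] <- block_sizes[seq_len(extra)] + 1L
  } else {
    if (any(block_sizes < 2)) stop("every block needs at least 2 residues")
    n <- sum(block_sizes)
    blocks <- length(block_sizes)
  }
  if (ratio <= 1) stop("separation ratio must exceed 1")
  if (noise < 0) stop("noise must be non-negative")
  k_out <- k_in / ratio

  set.seed(as.integer(seed))
  labels <- paste0(sample(AA_LETTERS, n, replace = TRUE),
                   seq(residue_start, length.out = n))
  block <- rep(seq_len(blocks), block_sizes)

  same <- outer(block, block, "==")
  k_med <- ifelse(same, k_in, k_out)
  z <- matrix(0, n, n)
  z[upper.tri(z)] <- stats::rnorm(n * (n - 1) / 2)
  z <- z + t(z)
  rate <- k_med * exp(noise * z)
  tm <- 1 / rate
  diag(tm) <- NA_real_

  tau <- tau_matrix(tm, labels = labels, unit = "arb")
  clusters <- stats::setNames(block, labels)
  params <- list(n = n, block_sizes = block_sizes, k_in = k_in,
                 k_out = k_out, ratio = ratio, noise = noise, seed = seed,
                 gamma = NA_real_, exclude = exclude)
  if (!is.null(exclude)) {
    tau <- mask_residues(tau, exclude)
    clusters <- clusters[tau$labels]
  }
  structure(list(tau = tau, clusters = clusters, hotspots = character(0),
                 params = params),
            class = "planted_system")
}

#' @export
print.planted_system <- function(x, ...) {
  cat(sprintf(
    "planted_system: %d residues in %d blocks (ratio %.3g, noise %.2g, seed %s)\n",
    length(x$tau$labels), max(x$clusters), x$params$ratio, x$params$noise,
    x$params$seed))
  if (length(x$hotspots)) {
    cat("  hotspots:", paste(x$hotspots, collapse = " "),
        sprintf("(gamma = %.3g)\n", x$params$gamma))
  }
  invisible(x)
}

#' Apply an allosteric-modulator perturbation to a planted system
#'
#' Emulates a modulator that speeds up the energy exchange between the
#' metastable blocks at a small set of hotspot residues: every
#' inter-block exchange time incident to a hotspot is divided by `gamma`
#' (the rate is multiplied by `gamma`); intra-block edges and all other
#' residues are untouched. The operation is deterministic.
#'
#' @param system a `planted_system`.
#' @param hotspots residue labels, all within one block.
#' @param gamma rate acceleration factor (> 0; 1 is the identity).
#' @return a new `planted_system` sharing labels and true clusters, with
#'   `hotspots` and `gamma` recorded.
#' @export
apply_modulator <- function(system, hotspots, gamma) {
  stopifnot(inherits(system, "planted_system"))
  if (gamma <= 0) stop("gamma must be positive")
  labels <- system$tau$labels
  idx <- match_labels(hotspots, labels)
  blk <- system$clusters[idx]
  if (length(unique(blk)) > 1) {
    stop("hotspots must lie within a single block; got blocks ",
         paste(sort(unique(blk)), collapse = ", "))
  }
  tm <- system$tau$times
  other <- which(system$clusters != blk[1])
  for (h in idx) {
    tm[h, other] <- tm[h, other] / gamma
    tm[other, h] <- tm[other, h] / gamma
  }
  out <- system
  out$tau <- tau_matrix(tm, labels = labels, unit = system$tau$unit)
  out$hotspots <- labels[idx]
  out$params$gamma <- gamma
  out
}

# Cumulative jump probabilities of the embedded chain.
embedded_chain <- function(Lm) {
  P <- Lm
  diag(P) <- 0
  rs <- rowSums(P)
  if (any(rs <= 0)) stop("absorbing residue with no outgoing rate")
  P <- P / rs
  t(apply(P, 1, cumsum))
}

#' Monte-Carlo committor estimate via the embedded jump chain
#'
#' Simulates `n_traj` trajectories of the discrete jump chain
#' (next-state probabilities \eqn{L_{ij} / \sum_{k \ne i} L_{ik}}) from a
#' start residue until absorption in A or B, and returns the fraction
#' hitting B first -- an independent stochastic estimate of the forward
#' committor, with its binomial standard error.
#'
#' @param L a `generator_matrix`.
#' @param start start residue (label or index), outside A and B.
#' @param A,B disjoint non-empty residue sets.
#' @param n_traj number of trajectories.
#' @param seed integer seed.
#' @return list with `estimate`, `se`, `n_traj`, `n_hit_B`.
#' @export
simulate_jump_chain <- function(L, start, A, B, n_traj = 1e5, seed = 1) {
  stopifnot(inherits(L, "generator_matrix"))
  if (n_traj < 1) stop("n_traj must be at least 1")
  labels <- L$labels
  iA <- match_labels(A, labels)
  iB <- match_labels(B, labels)
  i0 <- match_labels(start, labels)
  if (length(i0) != 1) stop("start must be a single residue")
  if (i0 %in% c(iA, iB)) stop("start residue lies in A or B")
  cum <- embedded_chain(L$L)
  absorbed_in_B <- logical(n_traj)
  state <- rep.int(i0, n_traj)
  active <- rep.int(TRUE, n_traj)
  set.seed(as.integer(seed))
  while (any(active)) {
    s <- state[active]
    u <- stats::runif(length(s))
    nxt <- integer(length(s))
    for (st in unique(s)) {
      sel <- s == st
      nxt[sel] <- findInterval(u[sel], cum[st, ]) + 1L
    }
    state[active] <- nxt
    hitA <- nxt %in% iA
    hitB <- nxt %in% iB
    done <- hitA | hitB
    ids <- which(active)
    absorbed_in_B[ids[hitB]] <- TRUE
    active[ids[done]] <- FALSE
  }
  p <- mean(absorbed_in_B)
  list(estimate = p, se = sqrt(p * (1 - p) / n_traj),
       n_traj = n_traj, n_hit_B = sum(absorbed_in_B))
}

#' Monte-Carlo estimate of the reactive A-to-B transition rate
#'
#' Simulates one long stationary trajectory of the continuous-time chain
#' (jump chain plus exponential holding times) and counts complete
#' passages from A to B per unit time. For the conservative flux this
#' frequency equals the total reactive current [total_current()], making
#' it an independent oracle for the whole transition-path-theory chain.
#' The returned trajectory summary also holds the per-state fraction of
#' time the last core set visited was A, a stochastic estimate of the
#' backward committor.
#'
#' @param L a `generator_matrix`.
#' @param A,B disjoint non-empty residue sets.
#' @param n_jumps trajectory length in jumps.
#' @param seed integer seed.
#' @return list with `rate`, `se` (Poisson-based), `n_passages`,
#'   `total_time`, `q_minus_mc` (named vector, `NA` where unvisited).
#' @export
simulate_reactive_rate <- function(L, A, B, n_jumps = 2e5, seed = 1) {
  stopifnot(inherits(L, "generator_matrix"))
  labels <- L$labels
  n <- length(labels)
  iA <- match_labels(A, labels)
  iB <- match_labels(B, labels)
  cum <- embedded_chain(L$L)
  exit_rate <- -diag(L$L)
  set.seed(as.integer(seed))
  s <- integer(n_jumps + 1L)
  s[1L] <- iA[1L]
  u <- stats::runif(n_jumps)
  for (k in seq_len(n_jumps)) {
    s[k + 1L] <- findInterval(u[k], cum[s[k], ]) + 1L
  }
  hold <- stats::rexp(n_jumps, rate = exit_rate[s[seq_len(n_jumps)]])
  total_time <- sum(hold)
  # last core set visited at each step: 1 = A, 2 = B, 0 = none yet
  h <- integer(n_jumps + 1L)
  h[s %in% iA] <- 1L
  h[s %in% iB] <- 2L
  pos <- ifelse(h > 0L, seq_along(h), 0L)
  lastpos <- cummax(pos)
  lasth <- ifelse(lastpos > 0L, h[pmax(lastpos, 1L)], 0L)
  n_pass <- sum(lasth[-1L] == 2L & lasth[-length(lasth)] == 1L)
  # time-weighted backward-committor estimate per state
  wA <- tapply(hold * (lasth[seq_len(n_jumps)] == 1L), s[seq_len(n_jumps)], sum)
  wT <- tapply(hold, s[seq_len(n_jumps)], sum)
  qm <- rep(NA_real_, n)
  qm[as.integer(names(wT))] <- as.numeric(wA) / as.numeric(wT)
  names(qm) <- labels
  list(rate = n_pass / total_time,
       se = sqrt(n_pass) / total_time,
       n_passages = n_pass, total_time = total_time,
       q_minus_mc = qm)
}
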
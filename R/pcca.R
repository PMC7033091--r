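# Robust Perron cluster analysis (PCCA+) on the energy-exchange generator.
#
# Metastable residue clusters are groups exchanging energy internally much
# faster than with the rest; they show up as a near-block structure of L
# and as a cluster of eigenvalues near zero. PCCA+ turns the dominant
# eigenvectors into fuzzy grades of membership by expressing every
# residue's spectral coordinates as a combination of q "representative"
# residues (simplex vertices).

#' Dominant spectral decomposition of the generator
#'
#' Computes the `q` eigenvalues of `L` with the largest real part and the
#' corresponding eigenvectors, arranged as per-residue coordinate rows:
#' row `m` of the returned `E` is the vector
#' \eqn{e_m = (e_m^{(1)}, \ldots, e_m^{(q)})}. Eigenvectors are normalised
#' to unit 2-norm with a deterministic sign (largest-magnitude entry
#' positive) and ordered by descending real part, ties broken by index,
#' so results are reproducible across linear-algebra backends.
#'
#' @param L a `generator_matrix`.
#' @param q number of dominant eigenpairs, `2 <= q <= N`.
#' @param imag_tol relative tolerance on imaginary parts of the dominant
#'   eigenvalues; larger imaginary parts (strongly non-reversible input)
#'   are an error.
#' @return Object of class `spectral_decomposition`: `q`, `values`
#'   (length-q eigenvalues), `E` (N x q matrix of residue rows), `labels`.
#' @export
spectral_decomposition <- function(L, q, imag_tol = 1e-8) {
  stopifnot(inherits(L, "generator_matrix"))
  n <- length(L$labels)
  if (q < 2 || q > n) stop("q must satisfy 2 <= q <= N")
  Lm <- L$L
  sym <- isSymmetric(Lm, tol = 1e-12)
  ee <- eigen(Lm, symmetric = sym)
  vals <- ee$values
  vecs <- ee$vectors
  if (is.complex(vals)) {
    rad <- max(abs(vals))
    ord <- order(-Re(vals), seq_along(vals))
    vals <- vals[ord]
    vecs <- vecs[, ord, drop = FALSE]
    if (max(abs(Im(vals[seq_len(q)]))) > imag_tol * max(rad, 1)) {
      stop("dominant eigenvalues have large imaginary parts; ",
           "input is strongly non-reversible")
    }
    vals <- Re(vals)
    vecs <- Re(vecs)
  } else {
    ord <- order(-vals, seq_along(vals))
    vals <- vals[ord]
    vecs <- vecs[, ord, drop = FALSE]
  }
  rad <- max(abs(vals), 1e-300)
  if (q < n && abs(vals[q] - vals[q + 1]) < 1e-12 * rad) {
    warning("eigenvalues ", q, " and ", q + 1, " are numerically degenerate; ",
            "the metastable multiplet is split arbitrarily")
  }
  E <- vecs[, seq_len(q), drop = FALSE]
  for (k in seq_len(q)) {
    v <- E[, k]
    v <- v / sqrt(sum(v^2))
    j <- which.max(abs(v))
    if (v[j] < 0) v <- -v
    E[, k] <- v
  }
  rownames(E) <- L$labels
  structure(list(q = q, values = vals[seq_len(q)], E = E, labels = L$labels),
            class = "spectral_decomposition")
}

#' Select representative residues (simplex vertices)
#'
#' Greedy inner-simplex selection in the q-dimensional spectral
#' coordinates: the first representative is the residue row of maximal
#' norm; each subsequent one maximises the distance to the affine span of
#' those already chosen. For `q = 2` this reduces to picking the pair of
#' residues at maximal mutual distance.
#'
#' @param sd a `spectral_decomposition`.
#' @return integer vector of `q` residue indices.
#' @export
select_representatives <- function(sd) {
  stopifnot(inherits(sd, "spectral_decomposition"))
  E <- sd$E
  q <- sd$q
  idx <- integer(q)
  ortho <- E
  norms <- sqrt(rowSums(ortho^2))
  idx[1] <- which.max(norms)
  ortho <- sweep(ortho, 2, E[idx[1], ], "-")
  for (k in seq_len(q)[-1]) {
    norms <- sqrt(rowSums(ortho^2))
    if (max(norms) < 1e-12) {
      stop("degenerate spectral coordinates: cannot separate ", q, " vertices")
    }
    idx[k] <- which.max(norms)
    v <- ortho[idx[k], ]
    v <- v / sqrt(sum(v^2))
    ortho <- ortho - outer(drop(ortho %*% v), v)
  }
  idx
}

#' Grades of membership from representatives
#'
#' Inverts the vertex expansion \eqn{e_m = \sum_s w_m^{(s)} e_{\pi(s)}}:
#' with `R` the q x q matrix of representative rows, `W = E R^{-1}`.
#' Rows of `W` sum to 1 (the constant dominant eigenvector lies in the
#' column span of `E`). Entries are deliberately NOT clipped to [0, 1]:
#' the cluster-number diagnostic theta is the minimum entry and needs the
#' negative values.
#'
#' @param sd a `spectral_decomposition`.
#' @param reps integer vector of representative indices, typically from
#'   [select_representatives()].
#' @return Object of class `membership_matrix`: `labels`, `W` (N x q),
#'   `representatives`, `theta` (min entry of `W`).
#' @export
compute_memberships <- function(sd, reps) {
  stopifnot(inherits(sd, "spectral_decomposition"))
  if (length(reps) != sd$q) stop("need exactly q representatives")
  R <- sd$E[reps, , drop = FALSE]
  Rinv <- tryCatch(solve(R), error = function(e) {
    stop("representative rows are singular: ", conditionMessage(e))
  })
  W <- sd$E %*% Rinv
  resid <- max(abs(sd$E - W %*% R))
  if (resid > 1e-8) {
    stop("membership inversion residual ", format(resid), " exceeds 1e-8")
  }
  dimnames(W) <- list(sd$labels, paste0("cluster_", seq_len(sd$q)))
  structure(list(labels = sd$labels, W = W, representatives = reps,
                 theta = min(W)),
            class = "membership_matrix")
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat(sprintf("membership_matrix: %d residues x %d clusters, theta = %.4g\n",
              nrow(x$W), ncol(x$W), x$theta))
  cat("representatives:", paste(x$labels[x$representatives], collapse = " "), "\n")
  invisible(x)
}

#' Cluster-number diagnostic theta
#'
#' The minimum grade of membership over all residues and clusters.
#' Memberships approximate transition probabilities into clusters, so
#' they should be non-negative; theta close to 0 means the chosen cluster
#' number is consistent with the spectral structure, while strongly
#' negative theta signals over-clustering.
#'
#' @param W a `membership_matrix` or a bare numeric membership matrix.
#' @return the minimum membership entry.
#' @export
theta <- function(W) {
  if (inherits(W, "membership_matrix")) return(W$theta)
  min(W)
}

#' Scan candidate cluster numbers
#'
#' Runs the full PCCA+ chain (decomposition, representative selection,
#' membership inversion) for each `q` from 2 to `q_max` and tabulates
#' theta together with the spectral gap ratio
#' \eqn{g(q) = |\mathrm{Re}\,\lambda_{q+1}| / |\mathrm{Re}\,\lambda_q|},
#' the timescale separation between the slowest discarded and the slowest
#' retained relaxation mode.
#'
#' A cluster number is admissible when its theta stays above `theta_min`
#' (memberships approximately non-negative, the over-clustering check)
#' and its gap ratio reaches `gap_min` (a q-fold metastable split must
#' come with an actual separation of timescales; without this floor a
#' structureless network, whose memberships are perfectly simplicial at
#' q = 2, would never be flagged). Among admissible values the one with
#' the largest gap is recommended -- metastability is strongest where the
#' spectrum splits. If nothing is admissible the network has no
#' metastable split at this resolution and `recommended` is `NA`.
#'
#' @param L a `generator_matrix`.
#' @param q_max largest cluster number to try (>= 2).
#' @param theta_min floor for theta (default -0.01).
#' @param gap_min minimum spectral gap ratio for a metastable split
#'   (default 3).
#' @return Object of class `cluster_scan`: data frame `table` with
#'   columns `q`, `theta`, `gap`; `recommended` (integer or `NA`);
#'   `theta_min`; `gap_min`.
#' @export
scan_cluster_number <- function(L, q_max = 5, theta_min = -0.01,
                                gap_min = 3) {
  stopifnot(inherits(L, "generator_matrix"))
  if (q_max < 2) stop("q_max must be at least 2")
  n <- length(L$labels)
  q_max <- min(q_max, n - 1L)
  Lm <- L$L
  lam <- sort(Re(eigen(Lm, symmetric = isSymmetric(Lm, tol = 1e-12),
                       only.values = TRUE)$values), decreasing = TRUE)
  rad <- max(abs(lam), 1e-300)
  qs <- 2:q_max
  gap_of <- function(q) {
    a <- abs(lam[q])
    b <- abs(lam[q + 1])
    if (a < 1e-12 * rad && b < 1e-12 * rad) return(1)   # inside a zero multiplet
    if (a < 1e-12 * rad) return(Inf)                    # exact q-fold split
    b / a
  }
  th <- vapply(qs, function(q) {
    tryCatch({
      sd <- suppressWarnings(spectral_decomposition(L, q))
      compute_memberships(sd, select_representatives(sd))$theta
    }, error = function(e) NA_real_)
  }, numeric(1))
  gp <- vapply(qs, gap_of, numeric(1))
  ok <- which(!is.na(th) & th >= theta_min & gp >= gap_min)
  rec <- if (length(ok)) {
    best <- ok[gp[ok] == max(gp[ok])]
    qs[max(best)]
  } else {
    NA_integer_
  }
  structure(list(table = data.frame(q = qs, theta = th, gap = gp),
                 recommended = rec, theta_min = theta_min, gap_min = gap_min),
            class = "cluster_scan")
}

#' @export
print.cluster_scan <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (is.na(x$recommended)) {
    cat(sprintf("no metastable split: no q with theta >= %g and gap >= %g\n",
                x$theta_min, x$gap_min))
  } else {
    cat("recommended number of clusters:", x$recommended, "\n")
  }
  invisible(x)
}

#' Assign residues to clusters at a membership cutoff
#'
#' A residue joins the cluster of its largest membership when that value
#' reaches the cutoff, and stays unassigned (`NA`) otherwise. The default
#' cutoff 0.7 is conservative; on well-separated metastable networks the
#' assignment is insensitive to raising it to 0.8 or 0.9.
#'
#' @param W a `membership_matrix`.
#' @param cutoff membership threshold, in (0.5, 1].
#' @return Object of class `cluster_assignment`: `labels`, `cluster`
#'   (integer or `NA` per residue), `membership` (the max membership),
#'   `cutoff`.
#' @export
assign_clusters <- function(W, cutoff = 0.7) {
  stopifnot(inherits(W, "membership_matrix"))
  if (cutoff <= 0.5 || cutoff > 1) stop("cutoff must lie in (0.5, 1]")
  mx <- apply(W$W, 1, max)
  cl <- max.col(W$W, ties.method = "first")
  cl[mx < cutoff] <- NA_integer_
  structure(list(labels = W$labels, cluster = as.integer(cl),
                 membership = mx, cutoff = cutoff),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  tab <- table(factor(x$cluster))
  cat(sprintf("cluster_assignment (cutoff %.2f): %s; %d unassigned\n",
              x$cutoff,
              paste(sprintf("cluster %s: %d", names(tab), tab), collapse = ", "),
              sum(is.na(x$cluster))))
  invisible(x)
}

#' @export
as.data.frame.cluster_assignment <- function(x, ...) {
  data.frame(label = x$labels, cluster = x$cluster,
             membership = x$membership, stringsAsFactors = FALSE)
}
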
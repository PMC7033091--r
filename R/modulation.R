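# Comparison of two liganded states of the same residue network.
#
# The agonist-only (binary) and agonist+modulator (ternary) complexes give
# two exchange-time matrices over the same residues. Both are run through
# the identical pipeline (generator -> clusters -> reactive flux) and the
# allosteric effect is summarised as the relative change of the
# inter-cluster energy current, overall (delta F) and per residue
# (delta F_X), the latter ranking modulation hotspots.

#' Net reactive current through individual residues
#'
#' For an intermediate residue X this is the total net flux leaving X,
#' \eqn{F_X = \sum_j f^+_{Xj}}; for X in the source cluster A only edges
#' leaving A are counted, and for X in the sink cluster B the incoming
#' net flux is used. Summed over any single cut of intermediates
#' separating A from B, these per-residue currents recover the total net
#' current.
#'
#' @param field a `flux_field`.
#' @param X residue label(s); `NULL` (default) returns all residues.
#' @return named numeric vector of per-residue currents.
#' @export
residue_current <- function(field, X = NULL) {
  stopifnot(inherits(field, "flux_field"))
  labels <- field$labels
  fn <- field$f_net
  iA <- match(field$A, labels)
  iB <- match(field$B, labels)
  out <- rowSums(fn)
  out[iA] <- rowSums(fn[iA, -iA, drop = FALSE])
  out[iB] <- colSums(fn[, iB, drop = FALSE])  # incoming net flux into B
  names(out) <- labels
  if (is.null(X)) return(out)
  idx <- match_labels(X, labels)
  out[idx]
}

#' Relative current change between two states
#'
#' The headline modulation statistic:
#' \eqn{\Delta F = (F_{all} - F_{ag}) / F_{ag} \cdot 100}, the percent
#' change of the inter-cluster energy current on adding the allosteric
#' modulator. Positive values mean the modulator speeds up energy
#' exchange between the clusters.
#'
#' @param F_all current in the modulated (ternary) state.
#' @param F_ag current in the agonist-only (binary) state; must be
#'   positive.
#' @return percent change.
#' @export
delta_F <- function(F_all, F_ag) {
  if (!is.finite(F_ag) || F_ag <= 0) {
    stop("delta_F is undefined for F_ag <= 0")
  }
  (F_all - F_ag) / F_ag * 100
}

#' Compare the binary and ternary states of a receptor network
#'
#' Runs the full pipeline on both exchange-time matrices and reports the
#' modulation statistics. The metastable clusters A and B are determined
#' once, on the designated reference state (default: the binary complex),
#' and reused for both states so the currents compare like with like; the
#' comparison state's own assignment is checked against it and a warning
#' is emitted when they disagree.
#'
#' Per-residue ratios are guarded: residues whose reference-state current
#' is below `eps` times the total current are flagged `low_flux` and get
#' `NA` instead of a spuriously huge percentage.
#'
#' @param tau_binary,tau_ternary `tau_matrix` objects over an identical
#'   residue label set (agonist-only and agonist+modulator states).
#' @param q number of clusters, or `"auto"` to take the
#'   [scan_cluster_number()] recommendation on the reference state.
#' @param cutoff membership cutoff for cluster assignment.
#' @param hotspot_threshold percent change above which a residue counts
#'   as a modulation hotspot (default 70).
#' @param reference which state defines the clusters.
#' @param flux_variant backward-committor index placement in the edge flux:
#'   `"source"` (conservative, default) or `"target"`.
#' @param eps relative guard for per-residue denominators.
#' @return Object of class `modulation_report`: totals `F_ag`, `F_all`
#'   (gross) and `F_ag_net`, `F_all_net`; `delta_F` and `delta_F_net`;
#'   `per_residue` data frame (label, F_X_ag, F_X_all, delta_F_X,
#'   low_flux); `hotspots`; cluster sets `A`, `B`; `settings`.
#' @export
compare_states <- function(tau_binary, tau_ternary, q = 2, cutoff = 0.7,
                           hotspot_threshold = 70,
                           reference = c("binary", "ternary"),
                           flux_variant = c("source", "target"), eps = 1e-12) {
  stopifnot(inherits(tau_binary, "tau_matrix"),
            inherits(tau_ternary, "tau_matrix"))
  reference <- match.arg(reference)
  flux_variant <- match.arg(flux_variant)
  if (!identical(tau_binary$labels, tau_ternary$labels)) {
    stop("the two states must share an identical residue label set ",
         "(after masking)")
  }
  L_bin <- build_generator(tau_binary)
  L_ter <- build_generator(tau_ternary)
  L_ref <- if (reference == "binary") L_bin else L_ter
  L_other <- if (reference == "binary") L_ter else L_bin

  if (identical(q, "auto")) {
    scan <- scan_cluster_number(L_ref)
    if (is.na(scan$recommended)) {
      stop("no metastable split found on the reference state")
    }
    q <- scan$recommended
  }
  sd_ref <- spectral_decomposition(L_ref, q)
  mem_ref <- compute_memberships(sd_ref, select_representatives(sd_ref))
  asg <- assign_clusters(mem_ref, cutoff = cutoff)
  A <- asg$labels[which(asg$cluster == 1L)]
  B <- asg$labels[which(asg$cluster == 2L)]
  if (length(A) == 0 || length(B) == 0) {
    stop("cluster determination on the reference state produced an empty ",
         "cluster at cutoff ", cutoff)
  }

  # consistency: does the other state yield the same assignment?
  asg_other <- tryCatch({
    sd_o <- spectral_decomposition(L_other, q)
    assign_clusters(compute_memberships(sd_o, select_representatives(sd_o)),
                    cutoff = cutoff)
  }, error = function(e) NULL)
  clusters_consistent <- NA
  if (!is.null(asg_other)) {
    clusters_consistent <- same_partition(asg$cluster, asg_other$cluster)
    if (!isTRUE(clusters_consistent)) {
      warning("cluster assignment differs between the two states; ",
              "using the ", reference, "-state clusters for both")
    }
  }

  field_bin <- flux_field(L_bin, A = A, B = B, flux_variant = flux_variant)
  field_ter <- flux_field(L_ter, A = A, B = B, flux_variant = flux_variant)

  F_ag <- field_bin$F_gross
  F_all <- field_ter$F_gross
  dF <- delta_F(F_all, F_ag)
  dF_net <- delta_F(field_ter$F_net, field_bin$F_net)

  rc_ag <- residue_current(field_bin)
  rc_all <- residue_current(field_ter)
  low <- rc_ag < eps * max(field_bin$F_net, .Machine$double.xmin)
  dFX <- ifelse(low, NA_real_, (rc_all - rc_ag) / rc_ag * 100)
  per_residue <- data.frame(label = field_bin$labels,
                            F_X_ag = as.numeric(rc_ag),
                            F_X_all = as.numeric(rc_all),
                            delta_F_X = as.numeric(dFX),
                            low_flux = low,
                            stringsAsFactors = FALSE)
  report <- structure(
    list(F_ag = F_ag, F_all = F_all,
         F_ag_net = field_bin$F_net, F_all_net = field_ter$F_net,
         delta_F = dF, delta_F_net = dF_net,
         per_residue = per_residue,
         hotspots = character(0),
         A = A, B = B,
         unassigned = asg$labels[is.na(asg$cluster)],
         clusters_consistent = clusters_consistent,
         settings = list(q = q, cutoff = cutoff,
                         hotspot_threshold = hotspot_threshold,
                         reference = reference,
                         flux_variant = flux_variant, eps = eps,
                         flux_formula = if (flux_variant == "target")
                           "target-committor" else "standard",
                         residue_current = paste(
                           "net flux leaving X (edges leaving A for X in A;",
                           "incoming net flux for X in B)"))),
    class = "modulation_report")
  report$hotspots <- rank_residues(report, threshold = hotspot_threshold)
  report
}

# Do two integer/NA cluster vectors describe the same partition
# (up to cluster relabeling)?
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(is.na(a), is.na(b))) return(FALSE)
  ok <- !is.na(a)
  key <- paste(a[ok], b[ok])
  map <- unique(cbind(a[ok], b[ok]))
  !any(duplicated(map[, 1])) && !any(duplicated(map[, 2]))
}

#' Rank residues by their current change
#'
#' Filters the per-residue table of a modulation report to residues whose
#' \eqn{\Delta F_X} exceeds the threshold and orders them by decreasing
#' change (ties broken by original label order). Low-flux residues with
#' undefined ratios are never ranked.
#'
#' @param report a `modulation_report`.
#' @param threshold percent threshold (default 70, the conventional
#'   hotspot criterion).
#' @return character vector of residue labels, descending by
#'   \eqn{\Delta F_X}.
#' @export
rank_residues <- function(report, threshold = 70) {
  stopifnot(inherits(report, "modulation_report"))
  pr <- report$per_residue
  sel <- !pr$low_flux & !is.na(pr$delta_F_X) & pr$delta_F_X > threshold
  sub <- pr[sel, , drop = FALSE]
  sub <- sub[order(-sub$delta_F_X, seq_len(nrow(sub))), , drop = FALSE]
  sub$label
}

#' @export
print.modulation_report <- function(x, ...) {
  cat(sprintf("modulation_report: F_ag = %.6g, F_all = %.6g\n",
              x$F_ag, x$F_all))
  cat(sprintf("  delta F = %.2f%% (gross), %.2f%% (net)\n",
              x$delta_F, x$delta_F_net))
  cat(sprintf("  clusters: |A| = %d, |B| = %d, unassigned = %d\n",
              length(x$A), length(x$B), length(x$unassigned)))
  if (length(x$hotspots)) {
    cat("  hotspots (delta F_X >", x$settings$hotspot_threshold, "%):",
        paste(x$hotspots, collapse = " "), "\n")
  } else {
    cat("  no hotspots above", x$settings$hotspot_threshold, "%\n")
  }
  invisible(x)
}
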
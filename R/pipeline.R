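# Pipeline front end: configuration, staged execution, TSV/JSON output.
# All tabular outputs are TSV with '#'-prefixed metadata header lines;
# summaries are JSON. Reruns with identical config and inputs are
# byte-identical (deterministic solvers, fixed seeds).

pkg_version <- function() as.character(utils::packageVersion("evibnet"))

# Small deterministic rolling hash of the resolved configuration, carried
# in every output header so files can be matched to the run that made them.
config_hash <- function(config) {
  config <- config[setdiff(names(config), "out_dir")]  # analysis fingerprint only
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

header_lines <- function(config, extra = character(0)) {
  c(sprintf("# evibnet %s  config %s", pkg_version(), config_hash(config)),
    paste0("# ", extra))
}

default_config <- function() {
  list(tau = NULL, tau_binary = NULL, tau_ternary = NULL,
       symmetrize = "off", excluded_ranges = NULL,
       q = 2, q_max = 5, theta_min = -0.01, cutoff = 0.7,
       hotspot_threshold = 70, flux_variant = "source",
       current = "gross", seed = 1, out_dir = ".")
}

#' Write a membership table
#'
#' TSV with one row per residue: label, the grade of membership in each
#' cluster, and the assigned cluster id (`NA` below the cutoff). Theta,
#' q and the cutoff go in `#` header lines.
#'
#' @param mem a `membership_matrix`.
#' @param assignment the matching `cluster_assignment`.
#' @param path output path.
#' @param config resolved configuration list (for the header); optional.
#' @export
write_membership <- function(mem, assignment, path, config = list()) {
  stopifnot(inherits(mem, "membership_matrix"),
            inherits(assignment, "cluster_assignment"))
  hdr <- header_lines(config, c(
    sprintf("q = %d  theta = %.10g  cutoff = %.3g",
            ncol(mem$W), mem$theta, assignment$cutoff),
    sprintf("representatives = %s",
            paste(mem$labels[mem$representatives], collapse = ","))))
  df <- data.frame(residue_label = mem$labels,
                   round(mem$W, 10),
                   assigned_cluster = assignment$cluster,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[2:(1 + ncol(mem$W))] <- paste0("w_", seq_len(ncol(mem$W)))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Write a reactive-flux edge list
#'
#' TSV of all edges with positive gross flux: residue_i, residue_j,
#' f_ij (gross) and f_plus_ij (net), with a summary header (total gross
#' and net currents, cluster sizes, unassigned count).
#'
#' @param field a `flux_field`.
#' @param path output path.
#' @param n_unassigned residues outside both clusters (for the header).
#' @param config resolved configuration list; optional.
#' @export
write_flux <- function(field, path, n_unassigned = NA, config = list()) {
  stopifnot(inherits(field, "flux_field"))
  hdr <- header_lines(config, c(
    sprintf("F_gross = %.10g  F_net = %.10g", field$F_gross, field$F_net),
    sprintf("A_size = %d  B_size = %d  unassigned = %s",
            length(field$A), length(field$B), n_unassigned),
    field$notes))
  ij <- which(field$f > 0, arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  df <- data.frame(residue_i = field$labels[ij[, 1]],
                   residue_j = field$labels[ij[, 2]],
                   f_ij = field$f[ij],
                   f_plus_ij = field$f_net[ij],
                   stringsAsFactors = FALSE)
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Write a modulation report
#'
#' The per-residue table goes to `<stem>.tsv`, the summary (totals,
#' delta F, hotspots, settings in effect) to `<stem>.json`.
#'
#' @param report a `modulation_report`.
#' @param stem output path without extension.
#' @param config resolved configuration list; optional.
#' @export
write_report <- function(report, stem, config = list()) {
  stopifnot(inherits(report, "modulation_report"))
  tsv <- paste0(stem, ".tsv")
  hdr <- header_lines(config, c(
    sprintf("F_ag = %.10g  F_all = %.10g  delta_F = %.6g",
            report$F_ag, report$F_all, report$delta_F),
    sprintf("residue current definition: %s",
            report$settings$residue_current)))
  writeLines(hdr, tsv)
  suppressWarnings(utils::write.table(report$per_residue, tsv, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  summary <- list(
    version = pkg_version(),
    config_hash = config_hash(config),
    F_ag = report$F_ag, F_all = report$F_all,
    F_ag_net = report$F_ag_net, F_all_net = report$F_all_net,
    delta_F = report$delta_F, delta_F_net = report$delta_F_net,
    hotspots = report$hotspots,
    A = report$A, B = report$B, unassigned = report$unassigned,
    settings = report$settings)
  jsonlite::write_json(summary, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}

#' Write a planted system (tau TSV plus ground-truth JSON)
#'
#' @param system a `planted_system`.
#' @param stem output path without extension.
#' @export
write_planted_system <- function(system, stem) {
  stopifnot(inherits(system, "planted_system"))
  write_tau(system$tau, paste0(stem, ".tsv"))
  truth <- list(clusters = as.list(system$clusters),
                hotspots = system$hotspots,
                params = system$params)
  jsonlite::write_json(truth, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}

load_state <- function(path, config) {
  tau <- read_tau(path, symmetrize = config$symmetrize)
  if (!is.null(config$excluded_ranges) && length(config$excluded_ranges)) {
    tau <- mask_residues(tau, config$excluded_ranges)
  }
  tau
}

#' Run the full analysis pipeline from a configuration
#'
#' Configuration may be a YAML file path or a named list; unset fields
#' take documented defaults. With a single `tau` input the pipeline runs
#' mask -> generator -> PCCA+ -> flux and writes `membership.tsv` and
#' `flux.tsv`. With `tau_binary` and `tau_ternary` it additionally runs
#' the two-state comparison and writes `report.tsv` / `report.json`.
#' The resolved configuration is always written next to the outputs as
#' `config_resolved.yaml`. All computation happens before any file is
#' written, so a failing stage leaves no partial outputs.
#'
#' @param config YAML path or named list; see Details for fields.
#' @return invisibly, a list with the computed objects (`tau`, `scan`,
#'   `membership`, `assignment`, `field`, and `report` for two-state
#'   runs) and the output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  two_state <- !is.null(cfg$tau_binary) && !is.null(cfg$tau_ternary)
  if (!two_state && is.null(cfg$tau)) {
    stop("config needs either 'tau' or both 'tau_binary' and 'tau_ternary'")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list(config = cfg)
  if (two_state) {
    tau_bin <- load_state(cfg$tau_binary, cfg)
    tau_ter <- load_state(cfg$tau_ternary, cfg)
    report <- compare_states(tau_bin, tau_ter, q = cfg$q,
                             cutoff = cfg$cutoff,
                             hotspot_threshold = cfg$hotspot_threshold,
                             flux_variant = cfg$flux_variant)
    L_bin <- build_generator(tau_bin)
    sd <- spectral_decomposition(L_bin, report$settings$q)
    mem <- compute_memberships(sd, select_representatives(sd))
    asg <- assign_clusters(mem, cutoff = cfg$cutoff)
    field <- flux_field(L_bin, A = report$A, B = report$B,
                        flux_variant = cfg$flux_variant)
    results$report <- report
    results$tau <- tau_bin
  } else {
    tau <- load_state(cfg$tau, cfg)
    L <- build_generator(tau)
    q <- cfg$q
    if (identical(q, "auto")) {
      scan <- scan_cluster_number(L, q_max = cfg$q_max,
                                  theta_min = cfg$theta_min)
      if (is.na(scan$recommended)) stop("no metastable split found")
      q <- scan$recommended
      results$scan <- scan
    }
    sd <- spectral_decomposition(L, q)
    mem <- compute_memberships(sd, select_representatives(sd))
    asg <- assign_clusters(mem, cutoff = cfg$cutoff)
    A <- tau$labels[which(asg$cluster == 1L)]
    B <- tau$labels[which(asg$cluster == 2L)]
    if (!length(A) || !length(B)) stop("empty cluster at cutoff ", cfg$cutoff)
    field <- flux_field(L, A = A, B = B,
                        flux_variant = cfg$flux_variant)
    results$tau <- tau
  }
  results$membership <- mem
  results$assignment <- asg
  results$field <- field

  paths <- list(
    membership = file.path(cfg$out_dir, "membership.tsv"),
    flux = file.path(cfg$out_dir, "flux.tsv"),
    config = file.path(cfg$out_dir, "config_resolved.yaml"))
  write_membership(mem, asg, paths$membership, config = cfg)
  write_flux(field, paths$flux,
             n_unassigned = sum(is.na(asg$cluster)), config = cfg)
  if (two_state) {
    paths$report <- file.path(cfg$out_dir, "report")
    write_report(results$report, paths$report, config = cfg)
  }
  yaml::write_yaml(c(cfg, list(version = pkg_version(),
                               config_hash = config_hash(cfg))),
                   paths$config)
  results$paths <- paths
  invisible(results)
}
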
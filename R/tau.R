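#' Pairwise energy-exchange time matrix
#'
#' Construct the basic input object of the pipeline: a symmetric square
#' matrix of characteristic times \eqn{\tau^{ij}} for exchanging vibrational
#' energy between residues \eqn{i} and \eqn{j}. Residue labels follow the
#' convention `<one-letter code><author residue number>`, e.g. `"Y80"`.
#' Missing, blank or infinite entries mean "no exchange observed" and are
#' stored as `NA`; they become rate-0 (absent) edges in the generator.
#' The diagonal is undefined and ignored.
#'
#' Only ratios of exchange times matter downstream (committors are invariant
#' under a global rescaling of all rates, and currents scale linearly), so
#' the time unit is carried as metadata only.
#'
#' @param times square numeric matrix of exchange times; off-diagonal
#'   entries must be positive, `NA`/`Inf` meaning no exchange.
#' @param labels character vector of unique residue labels; defaults to
#'   `rownames(times)`.
#' @param symmetrize `"off"` (default) raises an error on asymmetric input;
#'   `"mean"` replaces each pair by its arithmetic mean.
#' @param unit time unit of the entries, metadata only (default `"ps"`).
#' @return An object of class `tau_matrix`: list with `labels`, `times`
#'   (symmetric, `NA` diagonal) and `unit`.
#' @seealso [read_tau()], [mask_residues()], [build_generator()]
#' @export
tau_matrix <- function(times, labels = rownames(times),
                       symmetrize = c("off", "mean"), unit = "ps") {
  symmetrize <- match.arg(symmetrize)
  times <- as.matrix(times)
  storage.mode(times) <- "double"
  if (nrow(times) != ncol(times)) {
    stop("tau matrix must be square, got ", nrow(times), "x", ncol(times))
  }
  n <- nrow(times)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("label count does not match matrix dimension")
  if (anyDuplicated(labels)) {
    stop("duplicate residue labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  diag(times) <- NA_real_
  times[!is.finite(times)] <- NA_real_  # no-exchange pairs
  off <- times[upper.tri(times) | lower.tri(times)]
  if (any(off <= 0, na.rm = TRUE)) {
    stop("non-positive exchange time encountered; tau entries must be > 0")
  }
  # symmetry (NA pattern must match in either mode)
  tt <- t(times)
  na_mismatch <- xor(is.na(times), is.na(tt))
  if (any(na_mismatch)) {
    stop("asymmetric no-exchange pattern: tau[i,j] defined but tau[j,i] missing")
  }
  dev <- abs(times - tt)
  scale <- pmax(abs(times), abs(tt), 1)
  asym <- any(dev / scale > 1e-8, na.rm = TRUE)
  if (asym) {
    if (symmetrize == "off") {
      stop("tau matrix is not symmetric; pass symmetrize = \"mean\" to average")
    }
    times <- (times + tt) / 2
  }
  dimnames(times) <- list(labels, labels)
  structure(list(labels = labels, times = times, unit = unit),
            class = "tau_matrix")
}

#' @export
print.tau_matrix <- function(x, ...) {
  n <- length(x$labels)
  n_edge <- sum(!is.na(x$times[upper.tri(x$times)]))
  cat(sprintf("tau_matrix: %d residues, %d exchange pairs (unit: %s)\n",
              n, n_edge, x$unit))
  cat("labels:", paste(utils::head(x$labels, 6), collapse = " "),
      if (n > 6) "..." else "", "\n")
  invisible(x)
}

#' Read an exchange-time matrix from a delimited file
#'
#' Expects a square table whose first row and first column carry matching
#' residue labels; cell (i, j) is \eqn{\tau^{ij}}. Blank cells and `Inf`
#' are read as "no exchange".
#'
#' @param path path to a TSV (default) or CSV file.
#' @param sep field separator; guessed from the extension (`.csv` gives
#'   `","`, anything else tab) when `NULL`.
#' @param symmetrize,unit passed to [tau_matrix()].
#' @return a `tau_matrix`.
#' @export
read_tau <- function(path, sep = NULL, symmetrize = c("off", "mean"),
                     unit = "ps") {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    stop("file is not a square matrix: ", nrow(m), " rows vs ",
         ncol(m), " columns")
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row labels do not match column labels in ", path)
  }
  tau_matrix(m, symmetrize = symmetrize, unit = unit)
}

#' Write an exchange-time matrix to a TSV file
#'
#' @param tau a `tau_matrix`.
#' @param path output path.
#' @export
write_tau <- function(tau, path) {
  stopifnot(inherits(tau, "tau_matrix"))
  df <- data.frame(label = tau$labels, tau$times, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Parse exclusion ranges given as "start-end" strings, numeric length-2
# vectors, or a list thereof, into a two-column matrix.
parse_ranges <- function(excluded) {
  if (is.null(excluded) || length(excluded) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  if (!is.list(excluded)) {
    excluded <- if (is.numeric(excluded) && length(excluded) == 2) {
      list(excluded)
    } else {
      as.list(excluded)
    }
  }
  rng <- lapply(excluded, function(r) {
    if (is.character(r)) {
      parts <- suppressWarnings(as.integer(strsplit(r, "[-:]")[[1]]))
      if (length(parts) != 2 || anyNA(parts)) {
        stop("cannot parse residue range: ", r)
      }
      parts
    } else {
      if (length(r) != 2) stop("numeric range must have two elements")
      as.integer(r)
    }
  })
  out <- do.call(rbind, rng)
  if (any(out[, 1] > out[, 2])) stop("range start exceeds end")
  out
}

#' Restrict a tau matrix to residues outside excluded number ranges
#'
#' Drops every residue whose author number falls in one of the given
#' ranges, preserving the order of the retained labels. The canonical use
#' is excluding a highly mobile loop (e.g. the M2 receptor's third
#' intracellular loop, residues 212-383) for which the exchange-time
#' approximation is unreliable.
#'
#' @param tau a `tau_matrix`.
#' @param excluded ranges as `"start-end"` strings, numeric `c(start, end)`
#'   pairs, or a list of either; an empty list is the identity.
#' @return a `tau_matrix` over the retained residues.
#' @export
mask_residues <- function(tau, excluded) {
  stopifnot(inherits(tau, "tau_matrix"))
  rng <- parse_ranges(excluded)
  if (nrow(rng) == 0) return(tau)
  num <- residue_number(tau$labels)
  drop <- rep(FALSE, length(num))
  for (k in seq_len(nrow(rng))) {
    hit <- num >= rng[k, 1] & num <= rng[k, 2]
    if (!any(hit)) {
      stop("exclusion range ", rng[k, 1], "-", rng[k, 2],
           " matches no residue label")
    }
    drop <- drop | hit
  }
  keep <- which(!drop)
  if (length(keep) == 0) stop("exclusion removes every residue")
  tau_matrix(tau$times[keep, keep, drop = FALSE],
             labels = tau$labels[keep], unit = tau$unit)
}
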
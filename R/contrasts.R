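#' Quantile specification
#'
#' Defines the ordered probabilities \eqn{0 < p_1 < \dots < p_m < 1} whose
#' group quantiles are the inferential targets.
#'
#' @param probabilities numeric vector, strictly increasing, all in (0, 1).
#' @param labels optional character labels, one per probability.
#' @return An object of class `quantile_spec` with elements `p` and `labels`.
#' @examples
#' quantile_spec(0.5)
#' quantile_spec(c(0.25, 0.5, 0.75))
#' @export
quantile_spec <- function(probabilities, labels = NULL) {
  p <- as.numeric(probabilities)
  if (length(p) < 1L || anyNA(p)) {
    stop("'probabilities' must be a non-empty numeric vector without NA")
  }
  if (any(p <= 0) || any(p >= 1)) {
    stop("all probabilities must lie in the open interval (0, 1)")
  }
  if (is.unsorted(p, strictly = TRUE)) {
    stop("probabilities must be strictly increasing")
  }
  if (is.null(labels)) {
    labels <- paste0("p", format(p, trim = TRUE))
  }
  if (length(labels) != length(p)) {
    stop("'labels' must have one entry per probability")
  }
  structure(list(p = p, labels = as.character(labels)),
            class = "quantile_spec")
}

#' @export
print.quantile_spec <- function(x, ...) {
  cat("Quantile specification: m =", length(x$p), "\n")
  cat("  p =", paste(format(x$p), collapse = ", "), "\n")
  invisible(x)
}

.new_contrast_family <- function(H, margins, row_labels, tag, k, m) {
  H <- as.matrix(H)
  storage.mode(H) <- "double"
  r <- nrow(H)
  if (length(margins) == 1L) margins <- rep(as.numeric(margins), r)
  if (length(margins) != r) stop("'margins' must have length 1 or r")
  if (is.null(row_labels)) row_labels <- paste0("c", seq_len(r))
  rownames(H) <- row_labels
  structure(list(H = H, margins = as.numeric(margins),
                 row_labels = as.character(row_labels),
                 family_tag = tag, k = as.integer(k), m = as.integer(m)),
            class = "contrast_family")
}

#' Dunnett-type (many-to-one) contrast family
#'
#' Each non-base group is compared against the base group: row for group
#' \eqn{\ell \neq b} has +1 at \eqn{\ell} and -1 at the base \eqn{b}, so
#' \eqn{h_\ell' q = q_\ell - q_b}. Rows are ordered by ascending group index.
#' For `base = k` the matrix equals `[diag(k-1), -1]` (each earlier group
#' minus the last), the layout used for many-to-one comparisons against a
#' reference year or treatment.
#'
#' @param k number of groups (>= 2).
#' @param base index of the base (reference) group.
#' @param margins per-row margins \eqn{\varepsilon_\ell}; scalar is recycled.
#' @return A `contrast_family` with `k - 1` rows.
#' @examples
#' contrast_dunnett(3)
#' contrast_dunnett(17, base = 17)
#' @export
contrast_dunnett <- function(k, base = 1L, margins = 0) {
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be at least 2")
  if (base < 1L || base > k) stop("'base' must be a group index in 1..k")
  others <- setdiff(seq_len(k), as.integer(base))
  H <- matrix(0, nrow = k - 1L, ncol = k)
  for (row in seq_along(others)) {
    H[row, others[row]] <- 1
    H[row, base] <- -1
  }
  .new_contrast_family(H, margins,
                       paste0("g", others, " - g", base),
                       "dunnett", k, 1L)
}

#' Tukey-type (all-pairs) contrast family
#'
#' All pairwise comparisons: row for pair \eqn{(\ell_1, \ell_2)} with
#' \eqn{\ell_1 > \ell_2} has +1 at \eqn{\ell_1} and -1 at \eqn{\ell_2}
#' (later group minus earlier group). Rows are ordered lexicographically in
#' \eqn{(\ell_2, \ell_1)}.
#'
#' @inheritParams contrast_dunnett
#' @return A `contrast_family` with `k * (k - 1) / 2` rows.
#' @examples
#' contrast_tukey(4)
#' @export
contrast_tukey <- function(k, margins = 0) {
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be at least 2")
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)     # col > row
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  H <- matrix(0, nrow = nrow(pairs), ncol = k)
  for (row in seq_len(nrow(pairs))) {
    H[row, pairs[row, "col"]] <- 1                       # later group
    H[row, pairs[row, "row"]] <- -1                      # earlier group
  }
  .new_contrast_family(H, margins,
                       paste0("g", pairs[, "col"], " - g", pairs[, "row"]),
                       "tukey", k, 1L)
}

#' Grand-mean-type contrast family
#'
#' Each group is compared against the unweighted mean of all groupwise
#' effects: the contrast matrix is the centering matrix
#' \eqn{I_k - k^{-1} J_k}, so row \eqn{\ell} estimates
#' \eqn{q_\ell - \bar q} with \eqn{\bar q = k^{-1}\sum_i q_i}.
#'
#' @inheritParams contrast_dunnett
#' @return A `contrast_family` with `k` rows (rank `k - 1`).
#' @examples
#' contrast_grandmean(4)
#' @export
contrast_grandmean <- function(k, margins = 0) {
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be at least 2")
  H <- diag(k) - matrix(1 / k, k, k)
  .new_contrast_family(H, margins, paste0("g", seq_len(k), " - mean"),
                       "grandmean", k, 1L)
}

#' User-supplied contrast family
#'
#' Wraps an arbitrary contrast matrix. Every row must satisfy the contrast
#' property: within each probability block the coefficients sum to zero.
#' Columns are group-major: column \eqn{(i-1) m + j} belongs to group
#' \eqn{i}, probability \eqn{p_j}.
#'
#' @param H numeric matrix with `k * m` columns.
#' @param k number of groups.
#' @param m number of probabilities per group (default 1).
#' @param margins per-row margins; scalar recycled.
#' @param row_labels optional row names.
#' @return A `contrast_family`.
#' @export
contrast_custom <- function(H, k, m = 1L, margins = 0, row_labels = NULL) {
  H <- as.matrix(H)
  k <- as.integer(k); m <- as.integer(m)
  if (ncol(H) != k * m) stop("'H' must have k * m columns")
  if (nrow(H) < 1L) stop("'H' must have at least one row")
  fam <- .new_contrast_family(H, margins, row_labels, "custom", k, m)
  rep_ok <- validate_contrasts(fam, k, m = m)
  if (!rep_ok$ok) stop(rep_ok$message)
  fam
}

#' Joint median and IQR contrast family
#'
#' Expands a single-quantile (m = 1) contrast family over k groups into a
#' joint family on medians and interquartile ranges via the Kronecker
#' product with the selector matrix
#' \deqn{S = \begin{pmatrix} 0 & 1 & 0 \\ -1 & 0 & 1 \end{pmatrix}}
#' acting on the per-group quantile triple at p = (0.25, 0.5, 0.75): the
#' first selector row extracts the median, the second the IQR
#' \eqn{q(0.75) - q(0.25)}. The row count doubles; rows come in
#' (median, IQR) pairs per base row. Use together with
#' `quantile_spec(c(0.25, 0.5, 0.75))`.
#'
#' @param base a validated `contrast_family` with `m = 1`.
#' @param margins margins for the expanded family (length `2 * r_base` or
#'   scalar); defaults to 0.
#' @return A `contrast_family` with `m = 3` and twice the rows of `base`.
#' @examples
#' contrast_med_iqr(contrast_tukey(3))
#' @export
contrast_med_iqr <- function(base, margins = 0) {
  if (!inherits(base, "contrast_family")) stop("'base' must be a contrast_family")
  if (base$m != 1L) stop("'base' must be a single-quantile (m = 1) family")
  S <- rbind(c(0, 1, 0), c(-1, 0, 1))
  H <- base$H %x% S
  labels <- as.vector(rbind(paste0(base$row_labels, " (median)"),
                            paste0(base$row_labels, " (IQR)")))
  .new_contrast_family(H, margins, labels,
                       paste0("kron-", base$family_tag), base$k, 3L)
}

#' Validate a contrast family
#'
#' Checks matrix shape and the contrast property: for every row \eqn{\ell}
#' and probability index \eqn{j}, \eqn{\sum_{i=1}^k h_{\ell i j} = 0}
#' (absolute tolerance 1e-10). Also flags all-zero rows.
#'
#' @param family a `contrast_family` (or plain matrix).
#' @param k number of groups to validate against.
#' @param spec optional `quantile_spec` supplying `m`.
#' @param m number of probabilities per group if `spec` is missing.
#' @param tol absolute tolerance for the blockwise zero-sum check.
#' @return A list with `ok` (logical), `bad_rows` (integer vector of
#'   offending rows) and `message`.
#' @examples
#' validate_contrasts(contrast_dunnett(4), k = 4)
#' @export
validate_contrasts <- function(family, k, spec = NULL, m = NULL, tol = 1e-10) {
  H <- if (inherits(family, "contrast_family")) family$H else as.matrix(family)
  if (is.null(m)) {
    m <- if (!is.null(spec)) length(spec$p)
         else if (inherits(family, "contrast_family")) family$m
         else 1L
  }
  k <- as.integer(k); m <- as.integer(m)
  if (ncol(H) != k * m) {
    return(list(ok = FALSE, bad_rows = integer(0),
                message = sprintf("matrix has %d columns, expected k*m = %d",
                                  ncol(H), k * m)))
  }
  bad <- integer(0)
  for (row in seq_len(nrow(H))) {
    sums <- vapply(seq_len(m), function(j) {
      sum(H[row, (seq_len(k) - 1L) * m + j])
    }, numeric(1))
    if (any(abs(sums) > tol) || all(H[row, ] == 0)) bad <- c(bad, row)
  }
  ok <- length(bad) == 0L
  msg <- if (ok) "all rows satisfy the contrast property"
         else sprintf("rows violating the contrast property (or all-zero): %s",
                      paste(bad, collapse = ", "))
  list(ok = ok, bad_rows = bad, message = msg)
}

#' Replace the margins of a contrast family
#'
#' @param family a `contrast_family`.
#' @param margins numeric vector of length `r` (or scalar).
#' @return The family with updated margins.
#' @export
set_margins <- function(family, margins) {
  r <- nrow(family$H)
  if (length(margins) == 1L) margins <- rep(as.numeric(margins), r)
  if (length(margins) != r) stop("'margins' must have length 1 or r")
  family$margins <- as.numeric(margins)
  family
}

#' @export
print.contrast_family <- function(x, ...) {
  cat(sprintf("Contrast family '%s': r = %d rows, k = %d groups, m = %d\n",
              x$family_tag, nrow(x$H), x$k, x$m))
  print(x$H)
  if (any(x$margins != 0)) cat("margins:", paste(format(x$margins), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a contrast family to JSON
#'
#' @param family a `contrast_family`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
contrast_to_json <- function(family, path = NULL) {
  obj <- list(matrix = unclass(unname(family$H)), margins = family$margins,
              row_labels = family$row_labels, family_tag = family$family_tag,
              k = family$k, m = family$m)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a contrast family from JSON
#'
#' @param x JSON string or path to a JSON file produced by
#'   [contrast_to_json()].
#' @return A `contrast_family`.
#' @export
contrast_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  fam <- .new_contrast_family(obj$matrix, obj$margins, obj$row_labels,
                              obj$family_tag, obj$k, obj$m)
  rep_ok <- validate_contrasts(fam, fam$k, m = fam$m)
  if (!rep_ok$ok) stop(rep_ok$message)
  fam
}
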
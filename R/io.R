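#' Read a long-format CSV into a grouped sample
#'
#' Expects one row per observation with a group label column and a numeric
#' value column. Groups are ordered by first appearance. Rows with missing
#' or non-finite values are dropped with a message reporting the count.
#'
#' @param path CSV file path (header row required).
#' @param group_col,value_col column names (defaults `"group"`,
#'   `"value"`).
#' @param sep field separator.
#' @return A `grouped_sample`.
#' @export
read_group_data <- function(path, group_col = "group", value_col = "value",
                            sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c(group_col, value_col) %in% names(df))) {
    stop(sprintf("columns '%s' and '%s' are required", group_col, value_col))
  }
  val <- suppressWarnings(as.numeric(df[[value_col]]))
  keep <- is.finite(val)
  if (any(!keep)) {
    message(sprintf("dropped %d row(s) with missing/non-numeric values",
                    sum(!keep)))
  }
  if (!any(keep)) stop("no usable rows in ", path)
  g <- as.character(df[[group_col]])[keep]
  if (length(unique(g)) < 2L) stop("at least two groups required")
  grouped_sample(val[keep], g)
}

#' Coerce a test result to a data.frame
#'
#' @param x a `qmctp` result.
#' @param ... unused.
#' @return The per-contrast result table.
#' @export
as.data.frame.qmctp <- function(x, ...) x$table

#' Write a test result table as TSV
#'
#' Writes the per-contrast table preceded by provenance header comments
#' (method, covariance estimator, alternative, alpha, resampling size,
#' seed, group sizes, global decision).
#'
#' @param x a `qmctp` result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  stopifnot(inherits(x, "qmctp"))
  hdr <- c(
    sprintf("# qmctp result | method=%s cov=%s alternative=%s direction=%s",
            x$method, x$cov_method, x$alternative, x$direction),
    sprintf("# alpha=%g B=%s M=%s seed=%s", x$alpha,
            if (is.null(x$B)) "NA" else x$B,
            if (is.null(x$M)) "NA" else x$M,
            if (is.null(x$seed)) "NA" else x$seed),
    sprintf("# sizes=%s", paste(x$sizes, collapse = ",")),
    sprintf("# global_rejected=%s", x$global_rejected)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Re-read a result TSV written by [write_result_tsv()]
#'
#' @param path TSV path.
#' @return A data.frame with the per-contrast table.
#' @export
read_result_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run a multiple test from a configuration file
#'
#' The configuration (YAML or JSON) mirrors the arguments of [qmctp()]:
#' `input` (CSV path), `group_col`, `value_col`, `probs`, `contrast`
#' (tag or path to a contrast-family JSON), `base`, `margins`,
#' `alternative`, `direction`, `method`, `cov_method`, `alpha`, `B`, `M`,
#' `seed`, `output` (optional TSV path). A seed is required whenever a
#' resampling method is chosen.
#'
#' @param config path to a YAML/JSON configuration file, or an equivalent
#'   named list.
#' @return The `qmctp` result, invisibly when an output path is written.
#' @export
run_qmctp_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(config)
    } else {
      yaml::read_yaml(config)
    }
  } else {
    config
  }
  get_or <- function(name, default) if (is.null(cfg[[name]])) default else cfg[[name]]
  method <- get_or("method", "bonf-permutation")
  if (method %in% c("bonf-permutation", "mctp-bootstrap") &&
      is.null(cfg$seed)) {
    stop("a seed is required for resampling methods")
  }
  gs <- read_group_data(cfg$input, get_or("group_col", "group"),
                        get_or("value_col", "value"))
  contrast <- get_or("contrast", "dunnett")
  if (is.character(contrast) && file.exists(contrast)) {
    contrast <- contrast_from_json(contrast)
  }
  res <- qmctp(gs,
               probs = get_or("probs", 0.5),
               contrast = contrast,
               base = get_or("base", 1L),
               margins = cfg$margins,
               alternative = get_or("alternative", "two_sided"),
               direction = get_or("direction", "greater"),
               method = method,
               cov_method = get_or("cov_method", "kernel"),
               alpha = get_or("alpha", 0.05),
               B = get_or("B", 1999L),
               M = get_or("M", 1e5),
               B_cov = get_or("B_cov", 2000L),
               gamma = get_or("gamma", 0.05),
               seed = cfg$seed)
  if (!is.null(cfg$output)) {
    write_result_tsv(res, cfg$output)
    return(invisible(res))
  }
  res
}
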
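# Serialization: JSON for parameter sets and estimation/recovery results,
# TSV (tab-delimited, '.' decimal, Unix newlines) for trajectories and
# perturbation reports, and a flat key=value run configuration.

#' Write a trajectory as TSV
#'
#' Tab-delimited, header \code{tau m_R m_M m_C p_R p_M p_C}, 8 significant
#' digits, Unix newlines.
#'
#' @param traj A \code{trajectory} data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectoryTsv <- function(traj, path) {
  out <- traj
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(signif(x, 8), format = "g",
                                                  digits = 8))
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Read a trajectory written by \code{\link{writeTrajectoryTsv}}
#' @param path File path.
#' @return A \code{trajectory} data frame.
#' @export
readTrajectoryTsv <- function(path) {
  traj <- read.table(path, header = TRUE, sep = "\t")
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Write perturbation reports as TSV
#' @param reports Data frame of perturbation rows.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeReportsTsv <- function(reports, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(reports, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Write an estimation result as JSON
#'
#' Keys: \code{f}, \code{g}, \code{alpha_tilde}, \code{beta},
#' \code{p_c_eq}, \code{residual_norm}.
#'
#' @param result An \code{estimation_result}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeEstimationJson <- function(result, path) {
  jsonlite::write_json(
    list(f = result$params$f, g = result$params$g,
         alpha_tilde = result$params$alpha_tilde, beta = result$params$beta,
         p_c_eq = result$p_c_eq, residual_norm = result$residual_norm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a thermodynamic parameter set from JSON
#'
#' Accepts the schema written by \code{\link{writeEstimationJson}} /
#' \code{\link{writeParamsJson}}: keys \code{f}, \code{g},
#' \code{alpha_tilde}, \code{beta} (others ignored).
#'
#' @param path JSON file path.
#' @return A \code{\link{thermoParams}} object.
#' @export
readParamsJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("f", "g", "alpha_tilde", "beta")
  if (!all(need %in% names(x)))
    stop("parameter JSON must contain keys ",
         paste(need, collapse = ", "), call. = FALSE)
  thermoParams(x$f, x$g, x$alpha_tilde, x$beta)
}

#' Write a thermodynamic parameter set as JSON
#' @param params A \code{\link{thermoParams}} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeParamsJson <- function(params, path) {
  .check_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read observed ratios from JSON or flat key=value config
#'
#' JSON files (extension \code{.json}) must carry keys \code{r_M},
#' \code{r_C}, \code{r_block}; any other file is parsed as flat
#' \code{key=value} lines (\code{#} comments and blank lines ignored).
#'
#' @param path File path.
#' @return An \code{\link{observedRatios}} object.
#' @export
readRatios <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    readKeyValue(path)
  }
  need <- c("r_M", "r_C", "r_block")
  if (!all(need %in% names(x)))
    stop("ratios file must define ", paste(need, collapse = ", "),
         call. = FALSE)
  observedRatios(as.numeric(x$r_M), as.numeric(x$r_C),
                 as.numeric(x$r_block))
}

#' Parse a flat key=value configuration file
#'
#' Lines of the form \code{key = value}; blank lines and lines starting
#' with \code{#} are ignored; values that parse as numbers become numeric,
#' comma-separated values become vectors.
#'
#' @param path File path.
#' @return Named list.
#' @export
readKeyValue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key=value): ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (any(is.na(num))) val else num
  }
  out
}
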
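# Screen summary assembly and disk output.

#' Assemble the machine-readable screen summary
#'
#' Merges the per-drug ATE rows, the path-specific decompositions and the
#' adjusted log-rank results into one record per drug x endpoint, adding
#' volcano-plot coordinates (log-HR, -log10 p). Drugs that failed the gate
#' carry their gate status and no effect estimates.
#'
#' @param ate_results results table from [run_screen()] (one row per drug x
#'   endpoint).
#' @param decompositions named list of `pse_decomposition` objects, keyed
#'   `"<drug>.<ENDPOINT>"`.
#' @param logrank named list of `logrank_result` objects with the same keys.
#' @return data.frame, one row per drug x endpoint.
#' @export
assemble_screen_report <- function(ate_results, decompositions = list(),
                                   logrank = list()) {
  out <- ate_results
  keys <- c(names(decompositions), names(logrank))
  if (length(keys)) {
    known <- paste(out$drug, out$endpoint, sep = ".")
    bad <- setdiff(keys, known)
    if (length(bad))
      stop_pharmscreen("keys not present in the ATE table: ",
                       paste(bad, collapse = ", "))
  }
  if (nrow(out) == 0) {
    out$pct_direct <- numeric(0); out$pct_node <- numeric(0)
    out$pct_subtype <- numeric(0); out$logrank_p <- numeric(0)
    out$volcano_x <- numeric(0); out$volcano_y <- numeric(0)
    return(out)
  }
  key <- paste(out$drug, out$endpoint, sep = ".")
  pick <- function(lst, field) {
    vapply(key, function(k) {
      if (!is.null(lst[[k]])) lst[[k]][[field]] else NA_real_
    }, numeric(1), USE.NAMES = FALSE)
  }
  out$pct_direct <- pick(decompositions, "pct_direct")
  out$pct_node <- pick(decompositions, "pct_node")
  out$pct_subtype <- pick(decompositions, "pct_subtype")
  out$logrank_p <- pick(logrank, "p_value")
  has_hr <- "log_hr" %in% names(out)
  out$volcano_x <- if (has_hr) out$log_hr else NA_real_
  out$volcano_y <- if ("p_value" %in% names(out)) -log10(out$p_value)
                   else NA_real_
  out
}

#' Write the screen outputs to disk
#'
#' Writes the summary table (`screen_results.csv`), the per-drug balance
#' reports (`balance.csv`), the decompositions and log-rank results embedded
#' in the summary, the per-drug KM curve tables (`km_curves.csv`), a JSON
#' mirror of the summary, and a run manifest (configuration echo).
#'
#' @param screen a `screen_result`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_screen_report <- function(screen, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- assemble_screen_report(screen$results, screen$pse,
                                    screen$logrank)
  paths <- character(0)
  p <- file.path(out_dir, "screen_results.csv")
  utils::write.csv(summary, p, row.names = FALSE)
  paths <- c(paths, p)
  if (length(screen$balance)) {
    bal <- do.call(rbind, lapply(names(screen$balance), function(d) {
      cbind(drug = d, as.data.frame(screen$balance[[d]]))
    }))
    p <- file.path(out_dir, "balance.csv")
    utils::write.csv(bal, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (length(screen$km)) {
    kmtab <- do.call(rbind, lapply(names(screen$km), function(k) {
      cbind(key = k, as.data.frame(screen$km[[k]]))
    }))
    p <- file.path(out_dir, "km_curves.csv")
    utils::write.csv(kmtab, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "screen_results.json")
  jsonlite::write_json(summary, p, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  manifest <- screen$config
  manifest$rules <- unclass(manifest$rules)
  p <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(.manifest_safe(unclass(manifest)), p)
  paths <- c(paths, p)
  invisible(paths)
}

# yaml cannot serialize functions/formulas; keep plain values only.
.manifest_safe <- function(x) {
  if (is.list(x)) return(lapply(x, .manifest_safe))
  if (is.function(x)) return("<function>")
  x
}
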
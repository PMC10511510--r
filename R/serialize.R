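## Standardized report serialization: .json (canonical nested form),
## .csv (flattened key/value table), .txt (human-readable).

report_payload <- function(report) {
  x <- unclass(report)
  if (!is.null(x$foci)) x$foci <- as.data.frame(x$foci)
  x
}

#' Serialize a standardized report
#'
#' Writes the requested formats next to each other:
#' \code{<basename>.json} is the canonical nested form and round-trips
#' losslessly through [read_report_json()]; \code{<basename>.csv} is a
#' flattened two-column key/value table; \code{<basename>.txt} is a
#' human-readable rendering. Percentages are printed with two decimals
#' in the txt form; json/csv keep full precision.
#'
#' @param report a \code{standardized_report}.
#' @param out_dir output directory (created).
#' @param formats subset of \code{c("json", "csv", "txt")}.
#' @param basename file stem, default \code{report_<phase>}.
#' @return Character vector of written paths (empty, with a warning, for
#'   an empty format set).
#' @export
serialize_report <- function(report, out_dir,
                             formats = c("json", "csv", "txt"),
                             basename = NULL) {
  if (!inherits(report, "standardized_report"))
    stop("'report' must be a standardized_report", call. = FALSE)
  if (length(formats) == 0L) {
    warning("empty format set: nothing written")
    return(invisible(character()))
  }
  stopifnot(all(formats %in% c("json", "csv", "txt")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(basename)) basename <- paste0("report_", report$phase)
  paths <- character()
  if ("json" %in% formats) {
    p <- file.path(out_dir, paste0(basename, ".json"))
    jsonlite::write_json(report_payload(report), p, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", na = "null")
    paths <- c(paths, p)
  }
  if ("csv" %in% formats) {
    p <- file.path(out_dir, paste0(basename, ".csv"))
    utils::write.csv(flatten_report(report), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if ("txt" %in% formats) {
    p <- file.path(out_dir, paste0(basename, ".txt"))
    writeLines(format_report_text(report), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname serialize_report
#' @param path a \code{.json} report file.
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$foci)) x$foci <- as.data.frame(x$foci)
  if (!is.null(x$profiles))
    x$profiles <- lapply(x$profiles, function(p) lapply(p, as.numeric))
  structure(x, class = "standardized_report")
}

#' Flatten a report to a key/value table
#'
#' Recursive dotted-path flattening: nested fields become keys like
#' \code{volumes.patient_space_ml}; focus rows become
#' \code{foci.1.volume_ml}.
#'
#' @param report a \code{standardized_report}.
#' @return data.frame with columns \code{key}, \code{value}.
#' @export
flatten_report <- function(report) {
  out <- list()
  rec <- function(x, prefix) {
    if (is.data.frame(x)) {
      for (r in seq_len(nrow(x))) rec(as.list(x[r, ]), paste0(prefix, ".", r))
    } else if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
        rec(x[[i]], if (nzchar(prefix)) paste0(prefix, ".", nm) else nm)
      }
    } else if (length(x) > 1L) {
      for (i in seq_along(x)) rec(x[[i]], paste0(prefix, ".", i))
    } else {
      out[[length(out) + 1L]] <<- data.frame(key = prefix,
                                             value = as.character(x))
    }
  }
  rec(report_payload(report), "")
  do.call(rbind, out)
}

format_report_text <- function(report) {
  pct <- function(x) sprintf("%.2f", x)
  lines <- c(sprintf("Standardized %s report", report$phase),
             strrep("-", 40))
  if (report$phase == "preoperative") {
    lines <- c(lines,
      sprintf("Tumor volume (patient space):   %.3f ml",
              report$volumes$patient_space_ml),
      sprintf("Tumor volume (reference space): %.3f ml",
              report$volumes$reference_space_ml),
      sprintf("Laterality: left %s%% / right %s%% (dominant: %s%s)",
              pct(report$laterality$left_pct), pct(report$laterality$right_pct),
              report$laterality$dominant,
              if (isTRUE(report$laterality$midline_crossing))
                ", crosses midline" else ""),
      sprintf("Multifocal: %s (%d focus/foci)",
              if (isTRUE(report$multifocal)) "yes" else "no",
              nrow(report$foci)))
    for (i in seq_len(nrow(report$foci)))
      lines <- c(lines, sprintf("  focus %d: %.3f ml at (%.1f, %.1f, %.1f) mm",
                                report$foci$focus_id[i],
                                report$foci$volume_ml[i],
                                report$foci$centroid_x_mm[i],
                                report$foci$centroid_y_mm[i],
                                report$foci$centroid_z_mm[i]))
    for (nm in names(report$profiles)) {
      lines <- c(lines, sprintf("Location profile [%s]:", nm))
      prof <- report$profiles[[nm]]
      for (rn in names(prof))
        lines <- c(lines, sprintf("  %-24s %s%%", rn, pct(prof[[rn]])))
    }
  } else {
    lines <- c(lines,
      sprintf("Preoperative volume:  %.3f ml", report$volumes$preop_ml),
      sprintf("Postoperative volume: %.3f ml", report$volumes$postop_ml),
      sprintf("Extent of resection:  %s%%%s", pct(report$eor_pct),
              if (isTRUE(report$growth_flag)) " (interval growth)" else ""),
      sprintf("Resection class:      %s", report$resection_class))
  }
  if (length(report$provenance)) {
    lines <- c(lines, "Provenance:")
    for (nm in names(report$provenance))
      lines <- c(lines, sprintf("  %s: %s", nm,
                                paste(report$provenance[[nm]], collapse = ", ")))
  }
  lines
}
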
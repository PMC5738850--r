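# Table serialization (CSV / JSON) and curve / surface rendering.
#
# CSV dialect (the on-disk contract):
#   header  formula,x_param,x_value[,y_param,y_value],accuracy,fixed_json
#   newline \n, floats in shortest round-trip decimal form, the fixed_json
#   column quoted (it contains commas).

# Shortest decimal representation that round-trips to the identical double.
fmt_shortest <- function(x) {
  vapply(as.numeric(x), function(v) {
    if (!is.finite(v)) return(as.character(v))
    if (v == round(v) && abs(v) < 1e15) {
      s <- sprintf("%.0f", v)
      if (as.numeric(s) == v) return(s)
    }
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

csv_quote <- function(s) paste0('"', gsub('"', '""', s, fixed = TRUE), '"')

# Minimal CSV field splitter honouring double-quote escaping.
split_csv_line <- function(line) {
  out <- character(0)
  field <- character(0)
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  in_quotes <- FALSE
  i <- 1L
  buf <- c()
  while (i <= length(chars)) {
    ch <- chars[i]
    if (in_quotes) {
      if (ch == '"') {
        if (i < length(chars) && chars[i + 1L] == '"') {
          buf <- c(buf, '"'); i <- i + 1L
        } else in_quotes <- FALSE
      } else buf <- c(buf, ch)
    } else if (ch == '"') {
      in_quotes <- TRUE
    } else if (ch == ",") {
      out <- c(out, paste(buf, collapse = "")); buf <- c()
    } else buf <- c(buf, ch)
    i <- i + 1L
  }
  if (in_quotes) return(NULL)
  c(out, paste(buf, collapse = ""))
}

is_surface_table <- function(table) "y_param" %in% names(table)

check_sweep_table <- function(table) {
  if (!is.data.frame(table)) stop_validation("table must be a sweep_table data frame")
  base_cols <- if (is_surface_table(table)) {
    c("formula", "x_param", "x_value", "y_param", "y_value", "accuracy", "fixed_json")
  } else {
    c("formula", "x_param", "x_value", "accuracy", "fixed_json")
  }
  missing <- setdiff(base_cols, names(table))
  if (length(missing)) {
    stop_validation(sprintf("table lacks required columns: %s",
                            paste(missing, collapse = ", ")))
  }
  if (nrow(table) < 2L) {
    stop_validation("sweep tables have at least 2 records by construction")
  }
  if (any(table$accuracy < 0 | table$accuracy > 1)) {
    stop_validation("accuracy values must lie in [0, 1]")
  }
  invisible(table[base_cols])
}

#' Write a sweep table to CSV or JSON
#'
#' CSV uses the fixed dialect above: `\n` newlines and shortest round-trip
#' float formatting, so `read_sweep_table(write_sweep_table(t))` reproduces
#' every accuracy bit-for-bit.  JSON writes an array of records with the
#' same keys.
#'
#' @param table A `sweep_table` from [run_sweep()] or [run_surface()].
#' @param path Output file path.
#' @param format `"csv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  table <- check_sweep_table(table)
  if (format == "json") {
    # digits = I(17): 17 significant digits always round-trip to the same double
    jsonlite::write_json(table, path, dataframe = "rows", digits = I(17))
    return(invisible(path))
  }
  surface <- is_surface_table(table)
  header <- if (surface) "formula,x_param,x_value,y_param,y_value,accuracy,fixed_json"
            else "formula,x_param,x_value,accuracy,fixed_json"
  rows <- vapply(seq_len(nrow(table)), function(i) {
    fields <- c(table$formula[i], table$x_param[i], fmt_shortest(table$x_value[i]))
    if (surface) fields <- c(fields, table$y_param[i], fmt_shortest(table$y_value[i]))
    fields <- c(fields, fmt_shortest(table$accuracy[i]), csv_quote(table$fixed_json[i]))
    paste(fields, collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

#' Read a sweep table from CSV or JSON
#'
#' Accepts the dialect written by [write_sweep_table()]; the header decides
#' between curve and surface layout, and malformed rows are rejected with
#' their line numbers.
#'
#' @param path Input file path.
#' @param format `"csv"` (default) or `"json"`.
#' @return A validated `sweep_table` data frame.
#' @export
read_sweep_table <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    df <- jsonlite::fromJSON(path)
    tab <- check_sweep_table(df)
    class(tab) <- c("sweep_table", "data.frame")
    return(tab)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop_format(sprintf("'%s': empty file", path))
  curve_header <- "formula,x_param,x_value,accuracy,fixed_json"
  surface_header <- "formula,x_param,x_value,y_param,y_value,accuracy,fixed_json"
  surface <- identical(lines[1], surface_header)
  if (!surface && !identical(lines[1], curve_header)) {
    stop_format(sprintf("'%s': unrecognized header '%s'", path, lines[1]))
  }
  if (length(lines) < 2L) {
    stop_format(sprintf("'%s': no records after the header", path))
  }
  nfields <- if (surface) 7L else 5L
  rows <- lapply(seq.int(2L, length(lines)), function(ln) {
    fields <- split_csv_line(lines[ln])
    if (is.null(fields) || length(fields) != nfields) {
      stop_format(sprintf("'%s' line %d: expected %d fields", path, ln, nfields))
    }
    num_idx <- if (surface) c(3L, 5L, 6L) else c(3L, 4L)
    nums <- suppressWarnings(as.numeric(fields[num_idx]))
    if (anyNA(nums)) {
      stop_format(sprintf("'%s' line %d: non-numeric value in a numeric column", path, ln))
    }
    fields
  })
  m <- do.call(rbind, rows)
  tab <- if (surface) {
    data.frame(formula = m[, 1], x_param = m[, 2], x_value = as.numeric(m[, 3]),
               y_param = m[, 4], y_value = as.numeric(m[, 5]),
               accuracy = as.numeric(m[, 6]), fixed_json = m[, 7])
  } else {
    data.frame(formula = m[, 1], x_param = m[, 2], x_value = as.numeric(m[, 3]),
               accuracy = as.numeric(m[, 4]), fixed_json = m[, 5])
  }
  tab <- check_sweep_table(tab)
  class(tab) <- c("sweep_table", "data.frame")
  tab
}

## ---- rendering -----------------------------------------------------------

draw_curve <- function(table) {
  ord <- order(table$x_value)
  graphics::plot(table$x_value[ord], table$accuracy[ord], type = "b",
                 pch = 16, cex = 0.6, ylim = c(0, 1),
                 xlab = table$x_param[1], ylab = "prediction accuracy r",
                 main = sprintf("%s accuracy curve", table$formula[1]))
  graphics::grid()
}

draw_surface <- function(table) {
  xv <- sort(unique(table$x_value))
  yv <- sort(unique(table$y_value))
  z <- matrix(NA_real_, length(xv), length(yv))
  xi <- match(table$x_value, xv)
  yi <- match(table$y_value, yv)
  z[cbind(xi, yi)] <- table$accuracy
  graphics::filled.contour(
    xv, yv, z, zlim = c(0, 1),
    color.palette = function(n) grDevices::hcl.colors(n, "viridis"),
    xlab = table$x_param[1], ylab = table$y_param[1],
    main = sprintf("%s accuracy surface (r)", table$formula[1]))
}

#' Render a sweep table as a curve or surface plot
#'
#' Curves connect points in x order with the y-axis fixed to \[0, 1\];
#' surfaces render the long-format table as a filled contour grid with the
#' accuracy color scale fixed to \[0, 1\].  The `html` format embeds an SVG
#' in a single self-contained document (no external references).
#'
#' @param table A `sweep_table`.
#' @param path Output file path.
#' @param format `"png"`, `"svg"` or `"html"`.
#' @param kind `"auto"` (default: infer from the table's columns),
#'   `"curve"` or `"surface"`; a mismatch with the table's dimensionality
#'   is an error.
#' @param width,height Device size in pixels (png) or inches (svg/html).
#' @return `path`, invisibly.
#' @export
render_sweep <- function(table, path, format = c("png", "svg", "html"),
                         kind = c("auto", "curve", "surface"),
                         width = NULL, height = NULL) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  table <- check_sweep_table(table)
  surface <- is_surface_table(table)
  if (kind == "curve" && surface) {
    stop_validation("kind 'curve' requested but the table is two-dimensional")
  }
  if (kind == "surface" && !surface) {
    stop_validation("kind 'surface' requested but the table is one-dimensional")
  }
  draw <- if (surface) draw_surface else draw_curve

  if (format == "png") {
    w <- if (is.null(width)) 800 else width
    h <- if (is.null(height)) 600 else height
    grDevices::png(path, width = w, height = h, res = 96, type = "cairo")
    on.exit(grDevices::dev.off())
    draw(table)
    return(invisible(path))
  }

  w <- if (is.null(width)) 8 else width
  h <- if (is.null(height)) 6 else height
  svg_path <- if (format == "svg") path else tempfile(fileext = ".svg")
  grDevices::svg(svg_path, width = w, height = h)
  ok <- FALSE
  tryCatch({ draw(table); ok <- TRUE }, finally = grDevices::dev.off())
  if (!ok) stop_gpasim("rendering failed", "gpasim_error")
  if (format == "svg") return(invisible(path))

  svg_body <- paste(readLines(svg_path, warn = FALSE), collapse = "\n")
  unlink(svg_path)
  html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
            sprintf("<title>%s accuracy</title>", table$formula[1]),
            "</head><body>", svg_body, "</body></html>")
  writeLines(html, path, sep = "\n")
  invisible(path)
}
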
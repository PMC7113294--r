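# Replicate-level statistics for flow-cell experiments: Grubbs outlier
# testing (iterative), per-day summaries after outlier removal, and
# heat-map tables of every structural parameter across flow cells x days.

#' Grubbs critical value
#'
#' Two-sided critical value for the Grubbs single-outlier statistic at
#' significance `alpha` and sample size `n`, from the closed-form
#' t-quantile expression
#' G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2)) with
#' t = t_{1 - alpha/(2n), n-2}.
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level.
#' @return Critical value of G.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3) stop("Grubbs test requires n >= 3")
  t <- qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs test: G = max |x_i - mean(x)| / sd(x) compared with
#' the critical value from [grubbs_critical()]. Samples with zero standard
#' deviation contain no outlier by definition.
#'
#' @param x Numeric vector, `NA`s ignored; at least 3 non-missing values.
#' @param alpha Significance level (default 0.05).
#' @return List with `index` (index into `x` of the flagged value, or
#'   `NA_integer_` when none), `G`, `G_crit`, `n`.
#' @examples
#' grubbs_test(c(8.0, 8.1, 7.9, 8.0, 20.0))$index  # 5
#' @export
grubbs_test <- function(x, alpha = 0.05) {
  ok <- which(!is.na(x))
  n <- length(ok)
  if (n < 3) stop("Grubbs test requires at least 3 non-missing values")
  v <- x[ok]
  s <- sd(v)
  if (s == 0)
    return(list(index = NA_integer_, G = 0, G_crit = grubbs_critical(n, alpha),
                n = n))
  dev <- abs(v - mean(v))
  G <- max(dev) / s
  crit <- grubbs_critical(n, alpha)
  idx <- if (G > crit) ok[which.max(dev)] else NA_integer_
  list(index = idx, G = G, G_crit = crit, n = n)
}

#' Iterative Grubbs outlier removal
#'
#' Applies [grubbs_test()] repeatedly, masking the flagged value each
#' round, until no further outlier is found or the removal cap
#' `ceiling(n/4)` is reached (guards against stripping a small sample to
#' nothing).
#'
#' @inheritParams grubbs_test
#' @param max_remove Maximum number of removals; default `ceiling(n/4)`
#'   of the non-missing count.
#' @return Integer vector of outlier indices into `x`, in removal order
#'   (possibly empty).
#' @export
grubbs_outliers <- function(x, alpha = 0.05, max_remove = NULL) {
  n0 <- sum(!is.na(x))
  if (is.null(max_remove)) max_remove <- ceiling(n0 / 4)
  found <- integer(0)
  work <- x
  while (length(found) < max_remove && sum(!is.na(work)) >= 3) {
    res <- grubbs_test(work, alpha)
    if (is.na(res$index)) break
    found <- c(found, res$index)
    work[res$index] <- NA
  }
  found
}

#' Replicate table of one structural parameter
#'
#' Matrix of parameter values, flow cells in rows and cultivation days in
#' columns, with the parameter name and units attached. Missing cells
#' (e.g. imaging artifacts) are `NA`.
#'
#' @param values Numeric matrix, rows = flow cells, columns = days.
#' @param parameter Parameter name (e.g. `"sc_percent"`).
#' @param units Unit string (e.g. `"%"`, `"um"`, `"nats"`).
#' @param flow_cells,days Optional dimnames; defaults 1..nrow and
#'   0..ncol-1.
#' @return An object of class `replicate_table`.
#' @export
replicate_table <- function(values, parameter, units = "",
                            flow_cells = NULL, days = NULL) {
  values <- as.matrix(values)
  if (is.null(flow_cells)) flow_cells <- seq_len(nrow(values))
  if (is.null(days)) days <- seq_len(ncol(values)) - 1L
  stopifnot(length(flow_cells) == nrow(values), length(days) == ncol(values))
  dimnames(values) <- list(flow_cell = as.character(flow_cells),
                           day = as.character(days))
  structure(list(values = values, parameter = as.character(parameter),
                 units = as.character(units)),
            class = "replicate_table")
}

#' @export
print.replicate_table <- function(x, ...) {
  cat(sprintf("<replicate_table> %s [%s]: %d flow cells x %d days (%d missing)\n",
              x$parameter, x$units, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' Per-day replicate summary after outlier removal
#'
#' For each day (column) of a replicate table: identify outliers among the
#' non-missing flow-cell values by iterative Grubbs testing, then report
#' mean, median (even counts: mean of the two central order statistics)
#' and sample standard deviation (n-1 denominator) of the surviving
#' values. Days with fewer than 3 non-missing values cannot be outlier
#' tested; they are still summarized but flagged unreliable.
#'
#' @param table A [replicate_table()].
#' @param alpha Grubbs significance level.
#' @return List with `summary` (data.frame: day, n_total, n_missing,
#'   n_outliers, n_used, mean, median, sd, reliable) and `outlier_mask`
#'   (logical matrix aligned with the table).
#' @export
replicate_summary <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "replicate_table"))
  vals <- table$values
  n_days <- ncol(vals)
  mask <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  rows <- vector("list", n_days)
  for (j in seq_len(n_days)) {
    col <- vals[, j]
    n_missing <- sum(is.na(col))
    n_avail <- sum(!is.na(col))
    reliable <- n_avail >= 3
    out_idx <- if (reliable) grubbs_outliers(col, alpha) else integer(0)
    mask[out_idx, j] <- TRUE
    used <- col
    used[out_idx] <- NA
    used <- used[!is.na(used)]
    rows[[j]] <- data.frame(
      day = colnames(vals)[j],
      n_total = nrow(vals), n_missing = n_missing,
      n_outliers = length(out_idx), n_used = length(used),
      mean = if (length(used)) mean(used) else NA_real_,
      median = if (length(used)) median(used) else NA_real_,
      sd = if (length(used) >= 2) sd(used) else NA_real_,
      reliable = reliable)
  }
  list(summary = do.call(rbind, rows), outlier_mask = mask)
}

format_cell <- function(v, outlier) {
  if (is.na(v)) return("")
  s <- sprintf("%.17g", v)
  if (outlier) paste(s, "o") else s
}

#' Export replicate tables as heat-map CSVs and figures
#'
#' Writes, per parameter, a CSV (rows = flow cells, columns = days;
#' missing cells blank; Grubbs outliers annotated with a trailing `"o"`)
#' and a color-mapped PNG heat map with a calibration bar — the standard
#' at-a-glance view of how a structural parameter develops across all
#' replicates. The CSV value matrix round-trips exactly through
#' [read_replicate_csv()].
#'
#' @param tables A [replicate_table()] or list of them; all tables must
#'   share the flow-cell and day axes.
#' @param dir Output directory (created if needed).
#' @param alpha Grubbs significance level for the outlier annotation.
#' @param render Also write PNG heat maps (default TRUE).
#' @return Invisibly, a data.frame of written file paths per parameter.
#' @export
heatmap_table <- function(tables, dir, alpha = 0.05, render = TRUE) {
  if (inherits(tables, "replicate_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  ref <- dimnames(tables[[1]]$values)
  for (t in tables) {
    if (!identical(dimnames(t$values), ref))
      stop("replicate table axes mismatch for parameter `", t$parameter,
           "`: all tables must share flow-cell and day axes")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- lapply(tables, function(t) {
    res <- replicate_summary(t, alpha)
    vals <- t$values
    mask <- res$outlier_mask
    cells <- matrix(mapply(format_cell, vals, mask), nrow(vals), ncol(vals))
    df <- data.frame(flow_cell = rownames(vals), cells,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("flow_cell", paste0("day_", colnames(vals)))
    csv <- file.path(dir, paste0(t$parameter, ".csv"))
    write.csv(df, csv, row.names = FALSE, quote = TRUE)
    png_file <- NA_character_
    if (render) {
      png_file <- file.path(dir, paste0(t$parameter, ".png"))
      render_heatmap(t, mask, png_file)
    }
    data.frame(parameter = t$parameter, csv = csv, png = png_file)
  })
  invisible(do.call(rbind, files))
}

# ggplot2 tile heat map with calibration bar; outliers marked "o"
render_heatmap <- function(table, outlier_mask, path) {
  vals <- table$values
  df <- expand.grid(flow_cell = rownames(vals), day = colnames(vals),
                    stringsAsFactors = FALSE)
  df$value <- as.vector(vals)
  df$outlier <- as.vector(outlier_mask)
  df$flow_cell <- factor(df$flow_cell, levels = rev(rownames(vals)))
  df$day <- factor(df$day, levels = colnames(vals))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$flow_cell,
                                        fill = .data$value)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(data = df[!is.na(df$value) & df$outlier, , drop = FALSE],
                       label = "o", size = 3) +
    ggplot2::scale_fill_viridis_c(
      na.value = "grey80",
      name = paste0(table$parameter,
                    if (nzchar(table$units)) paste0(" [", table$units, "]"))) +
    ggplot2::labs(x = "day", y = "flow cell") +
    ggplot2::theme_minimal()
  grDevices::png(path, width = 1200, height = 800, res = 150,
                 type = "cairo")
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' Read a heat-map CSV back into a replicate table
#'
#' Inverse of the CSV side of [heatmap_table()]: blank cells become `NA`,
#' the `"o"` outlier annotation is stripped (and returned as a mask), and
#' the value matrix is recovered exactly.
#'
#' @param path CSV path written by [heatmap_table()].
#' @param parameter,units Metadata for the reconstructed table; the
#'   parameter defaults to the file name.
#' @return A [replicate_table()] with the outlier mask in
#'   `attr(, "outlier_mask")`.
#' @export
read_replicate_csv <- function(path, parameter = NULL, units = "") {
  if (is.null(parameter))
    parameter <- tools::file_path_sans_ext(basename(path))
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "flow_cell")
    stop("not a replicate CSV (first column must be flow_cell): ", path)
  cells <- as.matrix(df[, -1, drop = FALSE])
  outlier <- grepl(" o$", cells)
  raw <- sub(" o$", "", cells)
  vals <- matrix(ifelse(raw == "", NA, raw), nrow(cells), ncol(cells))
  storage.mode(vals) <- "double"
  days <- sub("^day_", "", colnames(cells))
  tab <- replicate_table(vals, parameter, units,
                         flow_cells = df$flow_cell, days = days)
  dim(outlier) <- dim(vals)
  dimnames(outlier) <- dimnames(tab$values)
  attr(tab, "outlier_mask") <- outlier
  tab
}
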
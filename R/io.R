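#' Read a two-group data table
#'
#' Parses a delimited text file with a header row and one row per unit into a
#' [two_group_sample()]. The file must contain exactly two distinct group
#' labels with equal counts; group 1 is the label encountered first
#' top-to-bottom and row order within group is preserved. Decimal points only
#' (no locale-dependent parsing).
#'
#' @param path Path to the file.
#' @param delimiter Field separator (default comma).
#' @param group_col,x_col,y_col Column names for the group label, covariate
#'   and outcome (defaults `"group"`, `"x"`, `"y"`).
#' @return A [two_group_sample()]; the group labels are kept in `$labels`.
#' @export
read_two_group_table <- function(path, delimiter = ",",
                                 group_col = "group", x_col = "x", y_col = "y") {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", strip.white = TRUE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(group_col, x_col, y_col), names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0)
    stop("no data rows in ", path, call. = FALSE)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop(sprintf("non-numeric or missing '%s' value(s) at data row(s) %s",
                   col, paste(bad, collapse = ", ")), call. = FALSE)
    v
  }
  x <- num(x_col)
  y <- num(y_col)
  g <- df[[group_col]]
  labels <- unique(g)
  if (length(labels) != 2L)
    stop(sprintf("expected exactly 2 group labels, found %d (%s)",
                 length(labels), paste(labels, collapse = ", ")), call. = FALSE)
  i1 <- g == labels[1]
  if (sum(i1) != sum(!i1))
    stop(sprintf("unequal group sizes: %d ('%s') vs %d ('%s')",
                 sum(i1), labels[1], sum(!i1), labels[2]), call. = FALSE)
  two_group_sample(x[i1], y[i1], x[!i1], y[!i1], labels = labels)
}

#' Write a two-group sample as a delimited table
#'
#' Inverse of [read_two_group_table()]: writes columns group, x, y with a
#' header, full precision, group 1 first.
#'
#' @param sample A [two_group_sample()].
#' @param path Output path.
#' @param delimiter Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_two_group_table <- function(sample, path, delimiter = ",") {
  if (!inherits(sample, "two_group_sample"))
    stop("'sample' must be a 'two_group_sample' object", call. = FALSE)
  df <- data.frame(
    group = rep(sample$labels, each = sample$n),
    x = format(c(sample$x1, sample$x2), digits = 17, trim = TRUE),
    y = format(c(sample$y1, sample$y2), digits = 17, trim = TRUE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Reads a flat `key: value` config (one pair per line, `#` comments allowed)
#' as used by the power and simulation commands. Values that parse as numbers
#' become numeric (comma-separated values become numeric vectors, e.g. for
#' fixed covariate lists); `true`/`false` become logical; anything else stays
#' a string. Keys are taken verbatim, so short names like `n` are safe.
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    sep <- regexpr(":", ln, fixed = TRUE)
    key <- if (sep > 0) trimws(substr(ln, 1, sep - 1)) else ""
    val <- if (sep > 0) trimws(substr(ln, sep + 1, nchar(ln))) else ""
    if (!nzchar(key) || !nzchar(val))
      stop("malformed config line (expected 'key: value'): ", ln, call. = FALSE)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num
      else if (length(parts) == 1L && tolower(val) %in% c("true", "false"))
        as.logical(toupper(val))
      else val
  }
  out
}

fmt_full <- function(x) format(x, digits = 17, trim = TRUE)

#' Run the full ANCOVA report on a data file
#'
#' Reads the file, computes the sample statistics, the ANCOVA adjusted-mean
#' test, the gain-score ANOVA, the ANOVA of the outcome alone, and the
#' covariate-imbalance advisory, and renders a report. `format = "text"`
#' gives a human-readable report with values rounded to 3 decimals;
#' `format = "keyvalue"` gives machine-readable `key=value` lines at full
#' precision.
#'
#' @param path Data file path (see [read_two_group_table()]).
#' @param alpha Level in (0,1) for test and confidence interval.
#' @param format `"text"` or `"keyvalue"`.
#' @param delimiter,group_col,x_col,y_col Passed to [read_two_group_table()].
#' @param quiet If `TRUE`, do not print the report.
#' @return Invisibly, a list with `sample`, `stats`, `ancova`, `gain`,
#'   `anova_y`, `imbalance`, `report` (character vector of report lines).
#' @export
run_test_command <- function(path, alpha = 0.05,
                             format = c("text", "keyvalue"),
                             delimiter = ",", group_col = "group",
                             x_col = "x", y_col = "y", quiet = FALSE) {
  format <- match.arg(format)
  check_alpha(alpha)
  sample <- read_two_group_table(path, delimiter, group_col, x_col, y_col)
  fit <- ancova_test(sample, alpha)
  st <- fit$stats
  gain <- gain_score_test(sample)
  ay <- anova_y_test(sample)
  imb <- imbalance_warning(st)
  if (format == "text") {
    r3 <- function(x) formatC(x, digits = 3, format = "f")
    report <- c(
      sprintf("Two-group ANCOVA report (n = %d per group; groups %s, %s)",
              st$n, sample$labels[1], sample$labels[2]),
      sprintf("Sample statistics: s_xx = %s, s_yy = %s, s_xy = %s",
              r3(st$s_xx), r3(st$s_yy), r3(st$s_xy)),
      sprintf("  dx = %s, dy = %s, b = %s, r^2 = %s, f = %s",
              r3(st$delta_x_bar), r3(st$delta_y_bar), r3(st$b), r3(st$r2), r3(st$f)),
      sprintf("ANCOVA: adjusted difference = %s (se %s), %s%% CI [%s, %s]",
              r3(fit$adjusted_diff), r3(fit$se), format(100 * (1 - alpha)),
              r3(fit$ci[1]), r3(fit$ci[2])),
      sprintf("  F(%d, %d) = %s, p = %s",
              fit$df[1], fit$df[2], r3(fit$f_stat), r3(fit$p)),
      sprintf("Gain-score ANOVA: F(%d, %d) = %s, p = %s",
              gain$df[1], gain$df[2], r3(gain$f_stat), r3(gain$p)),
      sprintf("ANOVA of y only:  F(%d, %d) = %s, p = %s",
              ay$df[1], ay$df[2], r3(ay$f_stat), r3(ay$p)),
      sprintf("Covariate imbalance advisory (n > 5 and f > 5): %s",
              if (imb) "imbalance suspected" else "no warning")
    )
  } else {
    kv <- c(n = st$n,
            mean_x1 = st$mean_x1, mean_x2 = st$mean_x2,
            mean_y1 = st$mean_y1, mean_y2 = st$mean_y2,
            delta_x_bar = st$delta_x_bar, delta_y_bar = st$delta_y_bar,
            s_xx = st$s_xx, s_yy = st$s_yy, s_xy = st$s_xy,
            b = st$b, r2 = st$r2, f = st$f, d_p = st$d_p,
            adjusted_diff = fit$adjusted_diff, se = fit$se,
            mst = fit$mst, mse = fit$mse,
            ancova_f = fit$f_stat, ancova_t = fit$t_stat,
            ancova_df2 = fit$df[2], ancova_p = fit$p,
            ci_lower = fit$ci[1], ci_upper = fit$ci[2], alpha = alpha,
            gain_f = gain$f_stat, gain_df2 = gain$df[2], gain_p = gain$p,
            anova_y_f = ay$f_stat, anova_y_df2 = ay$df[2], anova_y_p = ay$p,
            imbalance_warning = as.numeric(imb))
    report <- paste0(names(kv), "=", vapply(kv, fmt_full, character(1)))
  }
  if (imb)
    message("note: covariate imbalance f = ", signif(st$f, 4),
            " > 5 with n > 5; the covariate means may differ by more than chance")
  if (!quiet) cat(report, sep = "\n")
  invisible(list(sample = sample, stats = st, ancova = fit, gain = gain,
                 anova_y = ay, imbalance = imb, report = report))
}

model_from_args <- function(args) {
  need <- c("rho")
  for (nm in need) if (is.null(args[[nm]]))
    stop("missing model parameter: ", nm, call. = FALSE)
  grab <- function(nm, default) if (is.null(args[[nm]])) default else as.numeric(args[[nm]])
  ancova_model(
    mu_x1 = grab("mu_x1", grab("delta_mu_x", 0)),
    mu_x2 = grab("mu_x2", 0),
    mu_y1 = grab("mu_y1", grab("delta_mu_y", 0)),
    mu_y2 = grab("mu_y2", 0),
    sigma_x = grab("sigma_x", 1),
    sigma_y = grab("sigma_y", 1),
    rho = as.numeric(args$rho)
  )
}

#' Run a power computation from flags and/or a config file
#'
#' Resolves a complete power request from a flat key-value config file and/or
#' direct arguments (arguments override config values), then either computes
#' a single power value or, when `sweep` and `grid` are given, a power curve
#' table. Model parameters may be given as full means (`mu_x1`, `mu_x2`, ...)
#' or as standardized differences (`delta_mu_x`, `delta_mu_y` with group-2
#' means at 0); `sigma_x`, `sigma_y` default to 1.
#'
#' @param config_path Optional path to a key-value config file.
#' @param ... Named overrides: model parameters, `n`, `alpha`, `design`,
#'   `fixed_f`, `analysis`, `sweep`, `grid` (numeric vector), `out` (path to
#'   write a curve table as delimited text).
#' @param quiet If `TRUE`, do not print.
#' @return Invisibly: a single power value, or the curve data frame.
#' @export
run_power_command <- function(config_path = NULL, ..., quiet = FALSE) {
  args <- list(...)
  if (!is.null(config_path)) {
    cfg <- read_config(config_path)
    for (nm in names(cfg)) if (is.null(args[[nm]])) args[[nm]] <- cfg[[nm]]
  }
  model <- model_from_args(args)
  if (is.null(args$n)) stop("missing 'n'", call. = FALSE)
  req <- power_request(
    model, n = as.integer(args$n),
    alpha = if (is.null(args$alpha)) 0.05 else as.numeric(args$alpha),
    design = if (is.null(args$design)) "randomized" else args$design,
    fixed_f = if (is.null(args$fixed_f)) NULL else as.numeric(args$fixed_f),
    analysis = if (is.null(args$analysis)) "ancova" else args$analysis
  )
  if (!is.null(args$sweep)) {
    if (is.null(args$grid)) stop("'sweep' requires 'grid'", call. = FALSE)
    tab <- power_curve(req, args$sweep, as.numeric(args$grid))
    if (!is.null(args$out)) {
      utils::write.table(tab, args$out, sep = ",", quote = FALSE, row.names = FALSE)
      if (!quiet) cat("wrote", nrow(tab), "rows to", args$out, "\n")
    } else if (!quiet) {
      print(tab)
    }
    return(invisible(tab))
  }
  pw <- compute_power(req)
  if (!quiet) cat(fmt_full(pw), "\n")
  invisible(pw)
}

#' Run a Monte Carlo simulation from a config file
#'
#' Builds a [simulation_config()] from a flat key-value config file (and/or
#' direct overrides) and reports the empirical rejection rate with its Monte
#' Carlo standard error; the seed is echoed for reproducibility. Fixed
#' covariate values can be supplied in the config as `fixed_x1` / `fixed_x2`
#' lists or read from a data file via `x_file` (same format as
#' [read_two_group_table()], the y column is ignored).
#'
#' @param config_path Path to the config file (optional if all fields are
#'   given in `...`).
#' @param ... Named overrides for any config field.
#' @param quiet If `TRUE`, do not print the summary.
#' @return Invisibly, the `"ancova_mc"` result.
#' @export
run_simulate_command <- function(config_path = NULL, ..., quiet = FALSE) {
  args <- list(...)
  if (!is.null(config_path)) {
    cfg <- read_config(config_path)
    for (nm in names(cfg)) if (is.null(args[[nm]])) args[[nm]] <- cfg[[nm]]
  }
  model <- model_from_args(args)
  for (nm in c("n", "replications", "seed"))
    if (is.null(args[[nm]])) stop("missing '", nm, "'", call. = FALSE)
  design <- if (is.null(args$design)) "random" else args$design
  fixed_x_values <- NULL
  if (design == "fixed_x") {
    if (!is.null(args$x_file)) {
      s <- read_two_group_table(args$x_file)
      fixed_x_values <- list(s$x1, s$x2)
    } else if (!is.null(args$fixed_x1) && !is.null(args$fixed_x2)) {
      fixed_x_values <- list(as.numeric(args$fixed_x1), as.numeric(args$fixed_x2))
    } else {
      stop("design 'fixed_x' requires 'x_file' or 'fixed_x1'/'fixed_x2'", call. = FALSE)
    }
  }
  config <- simulation_config(
    model, n = as.integer(args$n),
    replications = as.integer(args$replications),
    seed = as.integer(args$seed),
    design = design, fixed_x_values = fixed_x_values,
    analysis = if (is.null(args$analysis)) "ancova" else args$analysis,
    alpha = if (is.null(args$alpha)) 0.05 else as.numeric(args$alpha)
  )
  t0 <- proc.time()[["elapsed"]]
  res <- empirical_power(config)
  message(sprintf("simulation: analysis = %s, design = %s, n = %d, R = %d, seed = %d, %.2fs",
                  res$analysis, res$design, res$n, res$replications, res$seed,
                  proc.time()[["elapsed"]] - t0))
  if (!quiet) print(res)
  invisible(res)
}

#' Path to the bundled worked-example data set
#'
#' A small fictitious pre/post-style data set of two groups of five units
#' each (columns group, x, y), bundled for the worked example in the README
#' and the tests.
#'
#' @return Path to the CSV file.
#' @export
example_data_path <- function() {
  system.file("extdata", "two_group_example.csv", package = "ancovapower",
              mustWork = TRUE)
}
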
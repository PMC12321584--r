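#' Group comparisons with the pipeline's standard tests
#'
#' Two-sided tests on per-unit values: Student's t, Mann-Whitney U
#' (Wilcoxon rank sum) or Kruskal-Wallis followed by Dunn's multiple
#' comparisons restricted to prespecified pairs. Dunn's z statistics use the
#' standard large-sample approximation with rank-tie correction and
#' Bonferroni adjustment over the requested pairs only.
#'
#' @param table data frame with columns `unit`, `group`, `value` (one metric
#'   at a time).
#' @param test `"t"`, `"mann-whitney"` or `"kruskal-dunn"`.
#' @param pairs list of 2-vectors of group labels to compare; default all
#'   pairs for two-group tests, required for `"kruskal-dunn"` to restrict
#'   comparisons (NULL means all pairs).
#' @return data frame of class `test_results`: `test`, `group1`, `group2`,
#'   `statistic`, `p_value`, `adjust`.
#' @export
compare_groups <- function(table, test = c("t", "mann-whitney", "kruskal-dunn"),
                           pairs = NULL) {
  test <- match.arg(test)
  if (!all(c("group", "value") %in% names(table)))
    vz_stop("'table' needs columns 'group' and 'value'")
  table$group <- as.character(table$group)
  gl <- unique(table$group)
  if (length(gl) < 2) vz_stop("need at least 2 groups")
  sizes <- table(table$group)
  if (any(sizes < 2)) vz_stop("every group needs at least 2 units")
  if (is.null(pairs)) pairs <- utils::combn(gl, 2, simplify = FALSE)
  for (p in pairs) if (!all(p %in% gl)) vz_stop("unknown group label in pairs: %s", paste(p, collapse = ", "))

  if (test %in% c("t", "mann-whitney")) {
    rows <- lapply(pairs, function(p) {
      x <- table$value[table$group == p[1]]
      y <- table$value[table$group == p[2]]
      if (test == "t") {
        ht <- stats::t.test(x, y)
        data.frame(test = "t", group1 = p[1], group2 = p[2],
                   statistic = unname(ht$statistic), p_value = ht$p.value,
                   adjust = "none")
      } else {
        ht <- suppressWarnings(stats::wilcox.test(x, y))
        data.frame(test = "mann-whitney", group1 = p[1], group2 = p[2],
                   statistic = unname(ht$statistic), p_value = ht$p.value,
                   adjust = "none")
      }
    })
    out <- do.call(rbind, rows)
  } else {
    kw <- stats::kruskal.test(table$value, factor(table$group))
    dn <- vz_dunn(table$value, table$group, pairs)
    out <- rbind(
      data.frame(test = "kruskal-wallis", group1 = "all", group2 = "all",
                 statistic = unname(kw$statistic), p_value = kw$p.value,
                 adjust = "none"),
      dn)
  }
  class(out) <- c("test_results", "data.frame")
  out
}

# Dunn's post hoc: z based on mean ranks with tie correction; Bonferroni
# over the requested pairs.
vz_dunn <- function(value, group, pairs) {
  rk <- rank(value)
  N <- length(value)
  ties <- table(value)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rows <- lapply(pairs, function(p) {
    r1 <- rk[group == p[1]]; r2 <- rk[group == p[2]]
    n1 <- length(r1); n2 <- length(r2)
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n1 + 1 / n2))
    z <- (mean(r1) - mean(r2)) / se
    data.frame(test = "dunn", group1 = p[1], group2 = p[2],
               statistic = z,
               p_value = min(1, 2 * stats::pnorm(-abs(z)) * length(pairs)),
               adjust = "bonferroni")
  })
  do.call(rbind, rows)
}

#' Write a deterministic CSV + SVG report bundle
#'
#' Writes one CSV per metric (per-group mean, SEM, n) and, when requested,
#' a matching mean +/- SEM bar panel as SVG. Histogram panels reuse the
#' exact 2-nm bin edges of [distance_histogram()] results. Empty metrics are
#' skipped with a log entry. Given identical inputs the CSVs are
#' byte-identical.
#'
#' @param metrics named list; each element is either a data frame with
#'   columns `group`, `value` (bar panel) or a `distance_histogram`
#'   (histogram panel).
#' @param dir output directory (created if needed).
#' @param svg also write SVG panels (default FALSE).
#' @return invisible character vector of files written; skipped panels are
#'   reported via `message()`.
#' @export
render_report <- function(metrics, dir, svg = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(metrics)) {
    m <- metrics[[nm]]
    if (inherits(m, "distance_histogram")) {
      df <- data.frame(bin_lo_nm = m$bin_edges_nm[-25],
                       bin_hi_nm = m$bin_edges_nm[-1],
                       count = m$counts, rel_freq = m$rel_freq)
      path <- file.path(dir, paste0(nm, "_histogram.csv"))
      utils::write.csv(df, path, row.names = FALSE)
      written <- c(written, path)
      if (svg) written <- c(written, vz_svg_panel(
        file.path(dir, paste0(nm, "_histogram.svg")),
        function() graphics::barplot(m$rel_freq,
                                     names.arg = m$bin_edges_nm[-25],
                                     xlab = "edge distance (nm)",
                                     ylab = "relative frequency", main = nm)))
      next
    }
    if (is.null(m) || nrow(m) == 0) {
      message(sprintf("render_report: metric '%s' is empty; panel skipped", nm))
      next
    }
    agg <- do.call(rbind, lapply(split(m$value, m$group), function(v)
      data.frame(mean = mean(v), sem = vz_sem(v), n = length(v))))
    agg <- data.frame(group = rownames(agg), agg, row.names = NULL)
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(agg, path, row.names = FALSE)
    written <- c(written, path)
    if (svg) written <- c(written, vz_svg_panel(
      file.path(dir, paste0(nm, ".svg")),
      function() {
        b <- graphics::barplot(agg$mean, names.arg = agg$group,
                               ylab = nm,
                               ylim = c(0, max(agg$mean + agg$sem) * 1.2))
        graphics::arrows(b, agg$mean - agg$sem, b, agg$mean + agg$sem,
                         angle = 90, code = 3, length = 0.05)
      }))
  }
  invisible(written)
}

vz_svg_panel <- function(path, draw) {
  grDevices::svg(path, width = 5, height = 4)
  on.exit(grDevices::dev.off())
  draw()
  path
}
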
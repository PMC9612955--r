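#' Filter trials and derive analysis columns
#'
#' Applies the trial-validity and rescaling rules: trials whose rating was
#' given faster than 150 ms are removed (a rating at exactly 150 ms is
#' kept), high-temperature trials judged "not painful" have their rating
#' converted to 0 on the pain scale (`pain0`), ratings are rescaled to a
#' 0--1 scale (`rating01`, from `pain0` on high-temperature rows), and the
#' trial-number covariates `t` and `log_t` are added.  The fractions of
#' trials removed — over all trials and over high-temperature trials only —
#' are attached as the `filter_report` attribute.
#'
#' The operation is idempotent: re-filtering an already clean table changes
#' nothing.
#'
#' @param table long trial table with columns `participant_id`, `trial`,
#'   `task`, `reward`, `temperature`, `performance`, `pain_binary`,
#'   `rating`, `rating_rt_ms` (as produced by [simulate_trials()]).
#' @return the filtered table (class `clean_trials`) with derived columns
#'   `pain0`, `rating01`, `t`, `log_t` and attribute `filter_report`.
#' @export
preprocess_trials <- function(table) {
  req <- c("participant_id", "trial", "task", "reward", "temperature",
           "performance", "pain_binary", "rating", "rating_rt_ms")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  n_in <- nrow(table)
  high_in <- table$temperature == "high"
  keep <- table$rating_rt_ms >= 150
  out <- table[keep, , drop = FALSE]
  high <- out$temperature == "high"
  out$pain0 <- ifelse(high & out$pain_binary == "not painful", 0, out$rating)
  out$rating01 <- ifelse(high, out$pain0, out$rating) / 100
  out$t <- out$trial
  out$log_t <- log(out$trial)
  rownames(out) <- NULL
  rep_ <- list(
    n_input = n_in, n_removed = n_in - nrow(out),
    frac_removed_all = if (n_in > 0) (n_in - nrow(out)) / n_in else 0,
    n_high_input = sum(high_in),
    n_high_removed = sum(high_in) - sum(high),
    frac_removed_high = if (sum(high_in) > 0)
      (sum(high_in) - sum(high)) / sum(high_in) else 0)
  attr(out, "filter_report") <- rep_
  class(out) <- c("clean_trials", "data.frame")
  out
}

#' Restrict a clean table to one analysis set
#'
#' The pain analyses use only trials on which the high, painful temperature
#' was presented; the performance analyses use only trials on which the
#' 2-back task was performed.
#'
#' @param table a [preprocess_trials()] table.
#' @param analysis `"pain"` (high-temperature rows) or `"performance"`
#'   (2-back rows).
#' @return the subset, keeping the `clean_trials` class.
#' @export
select_analysis_set <- function(table, analysis = c("pain", "performance")) {
  analysis <- match.arg(analysis)
  keep <- if (analysis == "pain") table$temperature == "high"
  else table$task == "2back"
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L && nrow(table) > 0L)
    warning("the ", analysis, " analysis set is empty", call. = FALSE)
  if (!inherits(out, "clean_trials"))
    class(out) <- c("clean_trials", class(out))
  out
}

#' Per-participant condition-cell means
#'
#' Averages a trial-level value within each participant x condition cell
#' and returns the participants x cells matrix that the repeated-measures
#' ANOVA and contrast functions consume.  Participants missing any
#' requested cell are dropped listwise with a warning.
#'
#' @param table a (clean) trial table.
#' @param value name of the column to average (e.g. `"pain0"` or
#'   `"performance"`).
#' @param factors character vector of two condition columns (e.g.
#'   `c("task", "reward")`).
#' @param id name of the participant identifier column.
#' @return a numeric matrix of class `cell_means` (participants x cells)
#'   with attributes `factors` (named list of level vectors) and `cells`
#'   (data frame mapping columns to factor levels).
#' @export
cell_means <- function(table, value, factors, id = "participant_id") {
  miss <- setdiff(c(value, factors, id), names(table))
  if (length(miss))
    stop("table is missing column(s): ", paste(miss, collapse = ", "))
  levs <- lapply(table[factors], function(x) sort(unique(as.character(x))))
  names(levs) <- factors
  cells <- expand.grid(levs, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  cell_of <- interaction(lapply(table[factors], as.character),
                         sep = ":", lex.order = FALSE)
  want <- interaction(cells, sep = ":")
  agg <- aggregate(table[[value]],
                   by = list(id = table[[id]], cell = as.character(cell_of)),
                   FUN = mean)
  ids <- sort(unique(table[[id]]))
  m <- matrix(NA_real_, length(ids), nrow(cells),
              dimnames = list(ids, as.character(want)))
  m[cbind(match(agg$id, ids), match(agg$cell, colnames(m)))] <- agg$x
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    warning("dropping participant(s) with empty cells: ",
            paste(ids[!complete], collapse = ", "), call. = FALSE)
    m <- m[complete, , drop = FALSE]
  }
  structure(m, factors = levs, cells = cells, value = value,
            class = c("cell_means", "matrix", "array"))
}

#' @export
print.cell_means <- function(x, ...) {
  cat(sprintf("per-participant cell means of %s (%d participants x %d cells)\n",
              attr(x, "value"), nrow(x), ncol(x)))
  print(round(colMeans(unclass(x)), 3))
  invisible(x)
}

#' Plot condition-cell means with within-subject error bars
#'
#' @param x a [cell_means()] matrix.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the data frame of per-cell means and within-subject
#'   SEs.
#' @export
plot.cell_means <- function(x, ...) {
  s <- cell_summary(x)
  k <- nrow(s)
  graphics::plot(seq_len(k), s$mean,
                 ylim = range(c(s$mean - 2 * s$se, s$mean + 2 * s$se)),
                 xaxt = "n", xlab = "", pch = 19,
                 ylab = attr(x, "value"), xlim = c(0.5, k + 0.5), ...)
  graphics::axis(1, at = seq_len(k), labels = s$cell, las = 2, cex.axis = 0.8)
  graphics::arrows(seq_len(k), s$mean - s$se, seq_len(k), s$mean + s$se,
                   angle = 90, code = 3, length = 0.05)
  invisible(s)
}
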
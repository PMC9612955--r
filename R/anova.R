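#' 2 x 2 repeated-measures ANOVA on condition-cell means
#'
#' Runs the within-subject analysis of variance for a 2 x 2 factorial on
#' per-participant cell means: two main effects and the interaction, each
#' with 1 numerator df and `n - 1` denominator df, with the effect size
#' partial eta squared computed as `SS_effect / (SS_effect + SS_error)`
#' from the effect's own error stratum.  Each F equals the square of the
#' paired t statistic of the corresponding difference score, which is the
#' oracle the test suite checks against.  If an effect's sums of squares
#' are both zero (identical cells), its F is reported as 0 with a note.
#'
#' @param cells a [cell_means()] matrix with exactly four columns from two
#'   two-level factors.
#' @return a data frame of class `rm_anova` with columns `effect`, `F`,
#'   `df_num`, `df_den`, `p`, `partial_eta_sq`, `note`.
#' @export
rm_anova_2x2 <- function(cells) {
  levs <- attr(cells, "factors")
  if (is.null(levs) || length(levs) != 2L ||
      any(lengths(levs) != 2L) || ncol(cells) != 4L)
    stop("`cells` must be a cell_means matrix of a 2x2 within design")
  if (anyNA(cells)) stop("incomplete cells; drop participants first")
  n <- nrow(cells)
  if (n < 3L) stop("need at least 3 participants")
  f1 <- names(levs)[1]; f2 <- names(levs)[2]
  map <- attr(cells, "cells")
  long <- data.frame(
    y = as.vector(cells),
    id = factor(rep(rownames(cells), times = 4L)),
    A = factor(rep(map[[f1]], each = n)),
    B = factor(rep(map[[f2]], each = n)))
  fit <- aov(y ~ A * B + Error(id / (A * B)), data = long)
  sm <- summary(fit)
  # sums of squares at rounding-noise scale count as exact zeros
  ss_tol <- (1e-10 * (1 + max(abs(long$y))))^2 * nrow(long)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    eff <- tab[match(term, rn), ]
    err <- tab[match("Residuals", rn), ]
    ss_e <- eff[["Sum Sq"]]; ss_r <- err[["Sum Sq"]]
    note <- ""
    Fv <- eff[["F value"]]; p <- eff[["Pr(>F)"]]
    if (ss_e < ss_tol && ss_r < ss_tol) {
      Fv <- 0; p <- 1; ss_e <- ss_r <- 0
      note <- "0/0 sums of squares reported as F = 0"
    } else if (!is.finite(Fv)) {
      Fv <- Inf; p <- 0; note <- "zero error stratum"
    }
    data.frame(F = Fv, df_num = eff[["Df"]], df_den = err[["Df"]], p = p,
               partial_eta_sq = if (ss_e + ss_r > 0) ss_e / (ss_e + ss_r)
               else 0,
               note = note)
  }
  out <- rbind(
    cbind(effect = f1, pull("Error: id:A", "A")),
    cbind(effect = f2, pull("Error: id:B", "B")),
    cbind(effect = paste0(f1, ":", f2), pull("Error: id:A:B", "A:B")))
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' @export
print.rm_anova <- function(x, digits = 3, ...) {
  cat("2x2 repeated-measures ANOVA\n")
  y <- x
  y$F <- round(y$F, digits); y$p <- signif(y$p, digits)
  y$partial_eta_sq <- round(y$partial_eta_sq, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

# the four planned simple-effect contrasts of a 2x2 design: the first
# factor's effect within each level of the second and vice versa
default_contrast_family <- function(cells) {
  levs <- attr(cells, "factors")
  map <- attr(cells, "cells")
  f1 <- names(levs)[1]; f2 <- names(levs)[2]
  fam <- list()
  for (l2 in levs[[f2]]) {
    w <- ifelse(map[[f2]] == l2,
                ifelse(map[[f1]] == levs[[f1]][2], 1, -1), 0)
    fam[[sprintf("%s-%s | %s=%s", levs[[f1]][2], levs[[f1]][1], f2, l2)]] <- w
  }
  for (l1 in levs[[f1]]) {
    w <- ifelse(map[[f1]] == l1,
                ifelse(map[[f2]] == levs[[f2]][2], 1, -1), 0)
    fam[[sprintf("%s-%s | %s=%s", levs[[f2]][2], levs[[f2]][1], f1, l1)]] <- w
  }
  fam
}

#' Planned contrasts with Holm step-down adjustment
#'
#' Paired t tests of a family of contrasts over per-participant cell means,
#' with two-sided p values adjusted by the Holm--Bonferroni step-down
#' procedure over the family.  The default family for a 2 x 2 design is the
#' four simple effects: the first factor's effect within each level of the
#' second, and the second factor's effect within each level of the first.
#' Each contrast's standard error is its own paired-difference SD (no
#' pooled error term).
#'
#' @param cells a [cell_means()] matrix.
#' @param family named list of contrast weight vectors (one weight per cell
#'   column); `NULL` uses the default simple-effect family.
#' @return a data frame of class `contrast_result` with columns `label`,
#'   `estimate`, `t`, `df`, `p_raw`, `p_holm`.
#' @export
planned_contrasts <- function(cells, family = NULL) {
  if (is.null(family)) family <- default_contrast_family(cells)
  if (length(family) == 0L) stop("contrast family is empty")
  if (anyNA(cells)) stop("incomplete cells; drop participants first")
  n <- nrow(cells)
  res <- lapply(names(family), function(lab) {
    w <- family[[lab]]
    stopifnot(length(w) == ncol(cells))
    d <- drop(unclass(cells) %*% w)
    s <- sd(d)
    tval <- if (s == 0) 0 else mean(d) / (s / sqrt(n))
    data.frame(label = lab, estimate = mean(d), t = tval, df = n - 1L,
               p_raw = if (s == 0 && mean(d) != 0) 0
               else 2 * pt(-abs(tval), n - 1L))
  })
  out <- do.call(rbind, res)
  out$p_holm <- p.adjust(out$p_raw, method = "holm")
  rownames(out) <- NULL
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' @export
print.contrast_result <- function(x, digits = 3, ...) {
  cat("planned contrasts (Holm-adjusted)\n")
  y <- x
  for (cl in c("estimate", "t")) y[[cl]] <- round(y[[cl]], digits)
  for (cl in c("p_raw", "p_holm")) y[[cl]] <- signif(y[[cl]], digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Within-subject standard errors of condition-cell means
#'
#' Removes between-participant offsets before computing error bars: each
#' participant's cell values are centred at their own mean and re-centred
#' on the grand mean, and the per-cell SD of these normalized values is
#' inflated by `sqrt(C/(C-1))` (C = number of cells) to correct the
#' downward bias of the centring, then divided by `sqrt(n)`.
#'
#' @param cells a [cell_means()] matrix with at least 2 participants.
#' @return named numeric vector of one SE per cell.
#' @export
within_subject_se <- function(cells) {
  m <- unclass(cells)
  n <- nrow(m)
  if (n < 2L) stop("within-subject SE undefined for a single participant")
  C <- ncol(m)
  norm <- m - rowMeans(m) + mean(m)
  apply(norm, 2, sd) * sqrt(C / (C - 1)) / sqrt(n)
}

#' Figure-ready cell summary
#'
#' @param cells a [cell_means()] matrix.
#' @return data frame with one row per cell: `cell`, `mean`, `se`
#'   (within-subject), `n`.
#' @export
cell_summary <- function(cells) {
  data.frame(cell = colnames(cells), mean = colMeans(unclass(cells)),
             se = within_subject_se(cells), n = nrow(cells),
             row.names = NULL)
}
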
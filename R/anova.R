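# Repeated-measures statistics for the colour differences.  Each of the 19
# medications is the within-subjects unit, measured in all 12 cells of the
# background x flash x EV factorial.  The engine is stats::aov with an
# Error(subject/...) stratification; the Greenhouse-Geisser epsilon is
# computed from orthonormal within-subject contrasts when requested.

#' Per-condition colour-difference summary
#'
#' Mean and sample standard deviation (n - 1 denominator) of Delta E over
#' medications, per condition.  A single-record condition reports `NA` for
#' the SD.
#'
#' @param records data frame with columns `condition` and `delta_e` (e.g.
#'   from [condition_delta_e()]).
#' @return Data frame `condition`, `mean_delta_e`, `sd_delta_e`, `n`.
#' @export
delta_e_summary <- function(records) {
  stopifnot(all(c("condition", "delta_e") %in% names(records)))
  if (nrow(records) == 0) {
    pc_stop("pillchroma_domain_error", "no colour-difference records")
  }
  m <- aggregate(records$delta_e, list(condition = records$condition), mean)
  s <- aggregate(records$delta_e, list(condition = records$condition),
                 function(v) if (length(v) > 1) sd(v) else NA_real_)
  n <- aggregate(records$delta_e, list(condition = records$condition), length)
  out <- data.frame(condition = m$condition, mean_delta_e = m$x,
                    sd_delta_e = s$x, n = n$x, stringsAsFactors = FALSE)
  out[order(out$condition, method = "radix"), , drop = FALSE]
}

# Coerce a long Delta-E table into factors and verify the complete
# within-subject crossing; errors name the first missing cell.
check_crossing <- function(table, factors) {
  need <- c("label", factors, "delta_e")
  stopifnot(all(need %in% names(table)))
  cells <- do.call(interaction, c(table[factors], drop = FALSE, sep = ":"))
  tab <- table(table$label, cells)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    pc_stop("pillchroma_design_error",
            "incomplete repeated-measures crossing: subject %s has %d record(s) in cell %s",
            rownames(tab)[bad[1]], tab[bad[1], bad[2]], colnames(tab)[bad[2]])
  }
  invisible(table)
}

# Orthonormal contrast columns for a factor with L levels (or the
# normalised unit column when the factor is not part of the effect).
orth_contrasts <- function(L) {
  C <- stats::contr.helmert(L)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Subjects x cells response matrix, cells ordered background, flash, ev
# (slowest to fastest).
cell_matrix <- function(table) {
  tb <- table
  tb$background <- factor(tb$background, c("black", "white"))
  tb$flash <- factor(tb$flash, c("on", "off"))
  tb$ev <- factor(tb$ev, sort(unique(tb$ev)))
  cells <- interaction(tb$ev, tb$flash, tb$background, sep = ":")
  labs <- sort(unique(tb$label))
  Y <- matrix(NA_real_, length(labs), nlevels(cells),
              dimnames = list(labs, levels(cells)))
  Y[cbind(match(tb$label, labs), as.integer(cells))] <- tb$delta_e
  Y
}

# Univariate RM-ANOVA statistics for one within-subject effect, from the
# response matrix and an orthonormal contrast matrix (cells x d).  Used for
# the Greenhouse-Geisser epsilon and as an independent cross-check of aov.
rm_effect_stats <- function(Y, M) {
  Z <- Y %*% M
  n <- nrow(Z); d <- ncol(Z)
  zbar <- colMeans(Z)
  ss_eff <- n * sum(zbar^2)
  ss_err <- sum(sweep(Z, 2, zbar)^2)
  Fv <- (ss_eff / d) / (ss_err / (d * (n - 1)))
  S <- cov(Z)
  eps <- sum(diag(S))^2 / (d * sum(S^2))
  eps <- min(max(eps, 1 / d), 1)
  list(F = Fv, df1 = d, df2 = d * (n - 1), eps = eps,
       p = stats::pf(Fv, d, d * (n - 1), lower.tail = FALSE))
}

# Contrast matrix for an effect named by the subset of factors it involves,
# matching the cell ordering of cell_matrix().
effect_contrast <- function(effect, n_ev) {
  part <- function(L, active) {
    if (active) orth_contrasts(L) else matrix(1 / sqrt(L), L, 1)
  }
  kronecker(part(2, "background" %in% effect),
            kronecker(part(2, "flash" %in% effect),
                      part(n_ev, "ev" %in% effect)))
}

#' Three-way repeated-measures ANOVA of colour differences
#'
#' Within-subjects F tests for the main effects of background, flash and EV
#' and all their interactions, with each medication as the repeated-measures
#' subject.  The uncorrected univariate F is reported by default; with
#' `gg = TRUE` the Greenhouse-Geisser epsilon (from the covariance of the
#' orthonormal within-subject contrasts) additionally adjusts the degrees of
#' freedom and p-values of the multi-df effects.
#'
#' @param table long-format data frame with columns `label` (medication),
#'   `background`, `flash`, `ev`, `delta_e`; every medication must appear
#'   exactly once in each of the 12 cells.
#' @param gg apply the Greenhouse-Geisser correction (default `FALSE`).
#' @return A data frame of class `pill_anova` with one row per effect:
#'   `effect`, `df1`, `df2`, `F`, `p` (plus `eps`, `df1_gg`, `df2_gg`,
#'   `p_gg` when `gg = TRUE`).
#' @export
delta_e_rm_anova <- function(table, gg = FALSE) {
  check_crossing(table, c("background", "flash", "ev"))
  tb <- table
  tb$label <- factor(tb$label)
  tb$background <- factor(tb$background, c("black", "white"))
  tb$flash <- factor(tb$flash, c("on", "off"))
  tb$ev <- factor(tb$ev, sort(unique(tb$ev)))
  fit <- aov(delta_e ~ background * flash * ev +
               Error(label / (background * flash * ev)), data = tb)
  sm <- summary(fit)
  # a numerically zero effect + residual (constant response) is F = 0, p = 1
  ss_floor <- 1e-10 * (sum(tb$delta_e^2) + 1)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    for (i in seq_along(eff)) {
      if (eff[i] == "Residuals") next
      Fv <- tab[i, "F value"]
      pv <- tab[i, "Pr(>F)"]
      if (tab[i, "Sum Sq"] < ss_floor && tab[nrow(tab), "Sum Sq"] < ss_floor) {
        Fv <- 0; pv <- 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        effect = eff[i],
        df1 = tab[i, "Df"],
        df2 = tab[nrow(tab), "Df"],
        F = Fv,
        p = pv,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (gg) {
    Y <- cell_matrix(tb)
    n_ev <- nlevels(tb$ev)
    out$eps <- NA_real_
    out$p_gg <- NA_real_
    for (i in seq_len(nrow(out))) {
      effs <- strsplit(out$effect[i], ":", fixed = TRUE)[[1]]
      st <- rm_effect_stats(Y, effect_contrast(effs, n_ev))
      out$eps[i] <- st$eps
      out$p_gg[i] <- stats::pf(out$F[i], st$eps * out$df1[i],
                               st$eps * out$df2[i], lower.tail = FALSE)
    }
    out$df1_gg <- out$eps * out$df1
    out$df2_gg <- out$eps * out$df2
  }
  class(out) <- c("pill_anova", "data.frame")
  out
}

#' @export
print.pill_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (within-subjects effects)\n")
  y <- x
  class(y) <- "data.frame"
  y$F <- round(y$F, 3)
  y$p <- signif(y$p, 3)
  if ("p_gg" %in% names(y)) {
    y$eps <- round(y$eps, 3)
    y$p_gg <- signif(y$p_gg, 3)
  }
  print(y, row.names = FALSE)
  invisible(x)
}

#' Stratified one-way RM-ANOVA over EV with Bonferroni pairwise contrasts
#'
#' Within each of the four background x flash strata, a one-way
#' repeated-measures ANOVA tests the EV effect across medications, followed
#' by paired t tests for every EV pair with Bonferroni adjustment
#' (`adjusted_p = min(1, raw_p * number of pairs)`).
#'
#' @param table long-format table as in [delta_e_rm_anova()].
#' @return A list with `anova` (one row per stratum: `background`, `flash`,
#'   `df1`, `df2`, `F`, `p`) and `pairwise` (one row per stratum and EV
#'   pair: `background`, `flash`, `ev1`, `ev2`, `raw_p`, `adjusted_p`).
#' @export
ev_strata_anova <- function(table) {
  check_crossing(table, c("background", "flash", "ev"))
  strata <- unique(table[, c("background", "flash")])
  strata <- strata[order(strata$background, strata$flash, method = "radix"), ]
  a_rows <- list(); p_rows <- list()
  for (i in seq_len(nrow(strata))) {
    sub <- table[table$background == strata$background[i] &
                   table$flash == strata$flash[i], ]
    evs <- sort(unique(sub$ev))
    if (length(evs) < 2) {
      pc_stop("pillchroma_design_error",
              "stratum %s/%s has fewer than 2 EV levels",
              strata$background[i], strata$flash[i])
    }
    sub$label <- factor(sub$label)
    sub$ev <- factor(sub$ev, evs)
    fit <- aov(delta_e ~ ev + Error(label / ev), data = sub)
    tab <- summary(fit)[["Error: label:ev"]][[1]]
    a_rows[[i]] <- data.frame(
      background = strata$background[i], flash = strata$flash[i],
      df1 = tab["ev", "Df"], df2 = tab["Residuals", "Df"],
      F = tab["ev", "F value"], p = tab["ev", "Pr(>F)"],
      stringsAsFactors = FALSE
    )
    pairs <- utils::combn(evs, 2)
    n_pairs <- ncol(pairs)
    for (j in seq_len(n_pairs)) {
      x1 <- sub$delta_e[sub$ev == pairs[1, j]][order(sub$label[sub$ev == pairs[1, j]])]
      x2 <- sub$delta_e[sub$ev == pairs[2, j]][order(sub$label[sub$ev == pairs[2, j]])]
      raw <- t.test(x1, x2, paired = TRUE)$p.value
      p_rows[[length(p_rows) + 1L]] <- data.frame(
        background = strata$background[i], flash = strata$flash[i],
        ev1 = pairs[1, j], ev2 = pairs[2, j],
        raw_p = raw, adjusted_p = min(1, raw * n_pairs),
        stringsAsFactors = FALSE
      )
    }
  }
  list(anova = do.call(rbind, a_rows), pairwise = do.call(rbind, p_rows))
}

#' Association between condition-level accuracy and colour difference
#'
#' Spearman rank correlation between per-condition mean Delta E and top-k
#' accuracy, with a per-condition concordance diagnostic that flags
#' conditions behaving against the overall monotone trend (a condition is
#' flagged when, against a majority of the other conditions, larger colour
#' difference goes with *higher* accuracy).
#'
#' @param accuracy data frame `condition`, `k`, `accuracy` (from
#'   [topk_accuracy()]).
#' @param summaries data frame `condition`, `mean_delta_e` (from
#'   [delta_e_summary()]).
#' @return A list with `correlations` (`k`, `spearman`, `n`), `flagged`
#'   (`condition`, `k`, `violation_score` for flagged conditions) and
#'   `table` (the merged per-condition data).  With constant accuracies the
#'   correlation is reported as `NA`.
#' @export
accuracy_delta_e_association <- function(accuracy, summaries) {
  stopifnot(all(c("condition", "k", "accuracy") %in% names(accuracy)),
            all(c("condition", "mean_delta_e") %in% names(summaries)))
  if (!setequal(unique(accuracy$condition), summaries$condition)) {
    pc_stop("pillchroma_pairing_error",
            "accuracy and colour-difference tables cover different conditions")
  }
  merged <- merge(accuracy, summaries[, c("condition", "mean_delta_e")],
                  by = "condition")
  cors <- list(); flags <- list()
  for (kk in sort(unique(merged$k))) {
    sub <- merged[merged$k == kk, ]
    rho <- if (sd(sub$accuracy) == 0 || sd(sub$mean_delta_e) == 0) {
      NA_real_
    } else {
      suppressWarnings(cor(sub$mean_delta_e, sub$accuracy, method = "spearman"))
    }
    cors[[length(cors) + 1L]] <- data.frame(k = kk, spearman = rho,
                                            n = nrow(sub))
    for (i in seq_len(nrow(sub))) {
      dd <- sub$mean_delta_e[i] - sub$mean_delta_e[-i]
      da <- sub$accuracy[i] - sub$accuracy[-i]
      informative <- dd != 0 & da != 0
      if (!any(informative)) next
      score <- mean(sign(dd[informative]) == sign(da[informative]))
      if (score > 0.5) {
        flags[[length(flags) + 1L]] <- data.frame(
          condition = sub$condition[i], k = kk, violation_score = score,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  list(
    correlations = do.call(rbind, cors),
    flagged = if (length(flags)) do.call(rbind, flags) else
      data.frame(condition = character(), k = numeric(),
                 violation_score = numeric()),
    table = merged
  )
}
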
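# Treatment-level reporting: means +/- SD, percent contrasts against a
# reference treatment, letter-coded significance (one-way ANOVA + Tukey HSD
# + compact letter display), and 2^-ddCt relative expression.

#' Per-treatment mean, SD and n
#'
#' @param values Numeric trait values.
#' @param treatment Grouping factor/character of the same length.
#' @return Data frame with columns \code{treatment}, \code{mean}, \code{sd}
#'   (sample SD, n-1 denominator), \code{n}.
#' @export
summarize_treatments <- function(values, treatment) {
  stopifnot(length(values) == length(treatment))
  treatment <- as.character(treatment)
  groups <- unique(treatment)
  n <- vapply(groups, function(g) sum(treatment == g), integer(1))
  if (length(groups) < 2) stop("need at least 2 treatment groups")
  if (any(n == 0)) stop("empty treatment group")
  data.frame(treatment = groups,
             mean = vapply(groups, function(g) mean(values[treatment == g]),
                           numeric(1)),
             sd = vapply(groups, function(g) stats::sd(values[treatment == g]),
                         numeric(1)),
             n = n, row.names = NULL)
}

#' Percent difference relative to a reference value
#'
#' \deqn{100 \times (reference - value) / reference}
#' i.e. positive when \code{value} is lower than the reference ("x percent
#' lower than the reference treatment").
#'
#' @param value Trait value(s).
#' @param reference Reference value.
#' @return Percent difference, vectorised over \code{value}.
#' @export
percent_vs_reference <- function(value, reference) {
  if (any(reference == 0)) stop("division error: reference must be non-zero")
  (reference - value) / reference * 100
}

# Compact letter display by insert-absorb from a pairwise significance
# matrix (rows/cols in the order of `groups`, TRUE = significantly
# different).  Groups sharing a letter are not significantly different.
cld_insert_absorb <- function(groups, signif) {
  k <- length(groups)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (!signif[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] <= cols[[b]]) && any(cols[[b]] & !cols[[a]]))
        keep[a] <- FALSE
      if (a != b && keep[a] && keep[b] && identical(cols[[a]], cols[[b]]) &&
          a > b)
        keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  # order columns by the first group they contain, assign letters
  first <- vapply(cols, function(c) which(c)[1], integer(1))
  cols <- cols[order(first)]
  letters_out <- rep("", k)
  for (ci in seq_along(cols))
    letters_out[cols[[ci]]] <- paste0(letters_out[cols[[ci]]], letters[ci])
  stats::setNames(letters_out, groups)
}

#' Letter-coded significance groups
#'
#' One-way ANOVA followed by Tukey's HSD; treatments sharing a letter are
#' not significantly different at level \code{alpha}.  Letters are assigned
#' with groups ordered by decreasing mean, so "a" marks the highest group.
#' Degenerate inputs with zero variance everywhere and equal means collapse
#' to a single shared letter.
#'
#' @param values Numeric trait values.
#' @param treatment Grouping factor/character.
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letters, one per treatment, in order
#'   of decreasing group mean.
#' @export
letter_groups <- function(values, treatment, alpha = 0.05) {
  treatment <- as.character(treatment)
  stopifnot(length(values) == length(treatment))
  groups <- unique(treatment)
  if (length(groups) < 2) stop("need at least 2 groups")
  n <- table(treatment)
  if (any(n < 2)) stop("each group needs n >= 2")
  means <- vapply(groups, function(g) mean(values[treatment == g]), numeric(1))
  ord <- order(means, decreasing = TRUE)
  groups <- groups[ord]; means <- means[ord]
  k <- length(groups)

  if (stats::var(values) < 1e-24)
    return(stats::setNames(rep("a", k), groups))

  d <- data.frame(y = values, g = factor(treatment, levels = groups))
  fit <- stats::aov(y ~ g, data = d)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  p <- tk[, "p adj"]
  diffs <- tk[, "diff"]
  # zero residual variance makes p NaN: equal means are then "same",
  # different means "different"
  p[is.nan(p)] <- ifelse(abs(diffs[is.nan(p)]) < 1e-12, 1, 0)

  signif <- matrix(FALSE, k, k)
  pair_names <- rownames(tk)
  for (r in seq_along(pair_names)) {
    gg <- strsplit(pair_names[r], "-", fixed = TRUE)[[1]]
    i <- match(gg[1], groups); j <- match(gg[2], groups)
    signif[i, j] <- signif[j, i] <- p[r] <= alpha
  }
  cld_insert_absorb(groups, signif)
}

#' Relative expression by the 2^-ddCt method
#'
#' \deqn{2^{-[(Ct_{target,sample} - Ct_{ref,sample}) -
#'           (Ct_{target,control} - Ct_{ref,control})]}}
#'
#' @param ct_target_sample,ct_ref_sample Target and reference-gene Ct in
#'   the sample of interest.
#' @param ct_target_control,ct_ref_control Same in the control/calibrator.
#' @return Fold change, vectorised.
#' @export
relative_expression_ddct <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_control, ct_ref_control) {
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  if (any(!is.finite(ddct))) stop("all Ct values must be finite")
  2^(-ddct)
}
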
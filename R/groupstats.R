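#' Kolmogorov-Smirnov normality check
#'
#' Two-sided KS test of a sample against a normal distribution with the
#' sample's own mean and standard deviation.
#'
#' @param x Numeric vector, `n >= 5`, non-constant.
#' @return The two-sided p-value.
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 5L) abort("Normality check needs at least 5 values.")
  s <- sd(x)
  if (s == 0) abort("Sample is constant; normality is undefined.")
  suppressWarnings(ks.test(x, "pnorm", mean(x), s))$p.value
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Compares replicate values between groups (cultivars) by one-way analysis
#' of variance assuming equal variances, follows up with Tukey's honestly
#' significant difference test on all pairs, and summarises the pairwise
#' outcomes as a compact letter display: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param data Tibble with a grouping column and a value column.
#' @param group,value Column names (strings) of the group labels and the
#'   replicate values.
#' @param alpha Significance level for the letter display.
#' @return An `anova_cld` object: list with `anova` (one-row tibble:
#'   `f_statistic`, `p_value`, `df_between`, `df_within`), `tukey` (tibble:
#'   `group1`, `group2`, `diff`, `p_adj`), `letters` (tibble: `group`,
#'   `mean`, `sem`, `n`, `letters`), `alpha`.
#' @examples
#' d <- tibble::tibble(
#'   g = rep(c("a", "b", "c"), each = 5),
#'   y = c(rnorm(5, 0), rnorm(5, 0.5), rnorm(5, 5))
#' )
#' anova_tukey_cld(d, "g", "y")
#' @export
anova_tukey_cld <- function(data, group = "group", value = "value",
                            alpha = 0.05) {
  stopifnot(group %in% names(data), value %in% names(data))
  g <- factor(data[[group]])
  y <- data[[value]]
  keep <- !is.na(y) & !is.na(g)
  g <- droplevels(g[keep])
  y <- y[keep]
  if (nlevels(g) < 2L) abort("Need at least 2 groups.")
  if (any(table(g) < 2L)) abort("Every group needs at least 2 replicates.")
  if (sd(y) == 0) abort("All values identical; group comparison is degenerate.")

  fit <- aov(y ~ g)
  an <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$g
  pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- tibble(
    group1 = vapply(pair_names, `[`, "", 1L),
    group2 = vapply(pair_names, `[`, "", 2L),
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"]
  )

  levels_g <- levels(g)
  sig <- matrix(FALSE, nlevels(g), nlevels(g),
                dimnames = list(levels_g, levels_g))
  for (k in seq_len(nrow(tukey))) {
    if (tukey$p_adj[k] < alpha) {
      sig[tukey$group1[k], tukey$group2[k]] <- TRUE
      sig[tukey$group2[k], tukey$group1[k]] <- TRUE
    }
  }
  letters_vec <- cld_letters(sig)

  summ <- tibble(group = g, value = y) %>%
    group_by(.data$group) %>%
    summarise(
      mean = mean(.data$value),
      sem = sd(.data$value) / sqrt(n()),
      n = n(), .groups = "drop"
    ) %>%
    mutate(group = as.character(.data$group),
           letters = letters_vec[.data$group])

  structure(
    list(
      anova = tibble(
        f_statistic = an[["F value"]][1L], p_value = an[["Pr(>F)"]][1L],
        df_between = an[["Df"]][1L], df_within = an[["Df"]][2L]
      ),
      tukey = tukey, letters = summ, alpha = alpha
    ),
    class = "anova_cld"
  )
}

#' Compact letter display from a pairwise significance matrix
#'
#' Implements the insert-and-absorb algorithm: start with one letter holding
#' all groups; for each significantly different pair, split every letter set
#' containing both members into two sets (each missing one member of the
#' pair), then absorb sets contained in others; finally drop sets that are
#' redundant for both group coverage and non-significance coverage. Letters
#' are assigned in order of each set's first group.
#'
#' @param sig Square logical matrix with group dimnames; `TRUE` where the
#'   pair differs significantly. Must be symmetric with a `FALSE` diagonal.
#' @return Named character vector of letter strings, one per group; groups
#'   share a letter exactly when their pair is not significant.
#' @export
cld_letters <- function(sig) {
  stopifnot(is.matrix(sig), nrow(sig) == ncol(sig),
            !is.null(rownames(sig)), identical(sig, t(sig)))
  groups <- rownames(sig)
  ng <- length(groups)
  sets <- list(seq_len(ng))

  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]
    j <- pairs[k, 2L]
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    sets <- absorb_sets(new_sets)
  }
  sets <- drop_redundant_sets(sets, sig)

  # order by first (smallest-index) member for stable letter assignment
  sets <- sets[order(vapply(sets, min, 0L))]
  letters_pool <- c(letters, paste0(rep(letters, each = 26L), letters))
  out <- rep("", ng)
  for (k in seq_along(sets)) {
    out[sets[[k]]] <- paste0(out[sets[[k]]], letters_pool[k])
  }
  setNames(out, groups)
}

# Remove sets that are subsets of another set.
absorb_sets <- function(sets) {
  sets <- unique(lapply(sets, sort))
  keep <- rep(TRUE, length(sets))
  for (a in seq_along(sets)) {
    for (b in seq_along(sets)) {
      if (a != b && keep[b] && all(sets[[a]] %in% sets[[b]]) &&
          length(sets[[a]]) < length(sets[[b]])) {
        keep[a] <- FALSE
        break
      }
    }
  }
  sets[keep]
}

# Drop sets whose vertices and non-significant pairs are all covered by the
# remaining sets (keeps the display minimal in common cases).
drop_redundant_sets <- function(sets, sig) {
  covered_pairs <- function(s) {
    if (length(s) < 2L) return(matrix(integer(), ncol = 2L))
    t(utils::combn(s, 2L))
  }
  k <- 1L
  while (k <= length(sets) && length(sets) > 1L) {
    others <- sets[-k]
    verts_ok <- all(sets[[k]] %in% unlist(others))
    pairs_k <- covered_pairs(sets[[k]])
    pair_in <- function(p, ss) any(vapply(ss, function(s)
      p[1L] %in% s && p[2L] %in% s, TRUE))
    pairs_ok <- nrow(pairs_k) == 0L ||
      all(apply(pairs_k, 1L, pair_in, ss = others))
    if (verts_ok && pairs_ok) {
      sets <- others
    } else {
      k <- k + 1L
    }
  }
  sets
}

#' @export
print.anova_cld <- function(x, ...) {
  cat(sprintf("<anova_cld> F(%d, %d) = %.3f, p = %.3g, alpha = %g\n",
              x$anova$df_between, x$anova$df_within,
              x$anova$f_statistic, x$anova$p_value, x$alpha))
  print(x$letters)
  invisible(x)
}
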
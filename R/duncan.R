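#' Duncan's multiple range test
#'
#' Stepwise post-hoc comparison of group means after a one-way layout,
#' as used for the between-species concentration comparisons. The
#' pooled error variance (MSE) and residual degrees of freedom come
#' from the one-way ANOVA decomposition; means are sorted ascending and
#' a span of p ordered means is declared different when its range
#' exceeds the least significant range
#' \deqn{R_p = q_{1-\alpha_p}(p, df)\sqrt{MSE/n_h},\quad
#'       \alpha_p = 1-(1-\alpha)^{p-1},}
#' the studentized-range quantile at Duncan's protection level, with
#' \eqn{n_h} the harmonic mean of the group sizes. Critical values are
#' computed from the studentized-range distribution (`qtukey`), not
#' from printed tables, so any error degrees of freedom are supported.
#' Homogeneous subsets are lettered by the standard sweep: a subspan of
#' a span already declared homogeneous is never tested.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @param alpha nominal significance level in (0, 1); default 0.05.
#' @return list of class `duncan_result`: `group_means` (named, input
#'   order), `letters` (named; groups sharing any letter do not differ
#'   at `alpha`), `mse`, `df` (residual), `n_harmonic`,
#'   `critical_ranges` (indexed by span size p = 2..k), `alpha`.
#' @examples
#' set.seed(1)
#' g <- list(a = rnorm(5, 0, 0.1), b = rnorm(5, 10, 0.1),
#'           c = rnorm(5, 20, 0.1))
#' duncan_mrt(g)$letters
#' @export
duncan_mrt <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_fr("need at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop_fr("groups must be named")
  ni <- lengths(groups)
  if (any(ni < 2L))
    stop_fr("insufficient replication: every group needs >= 2 values")
  if (!(alpha > 0 && alpha < 1))
    stop_fr("alpha must be in (0, 1)")

  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, stats::var, numeric(1))
  df <- sum(ni) - k
  mse <- sum((ni - 1) * vars) / df
  nh <- k / sum(1 / ni)

  # least significant range for spans of p ordered means
  p_seq <- 2:k
  crit <- vapply(p_seq, function(p) {
    stats::qtukey((1 - alpha)^(p - 1), nmeans = p, df = df) * sqrt(mse / nh)
  }, numeric(1))
  names(crit) <- p_seq

  ord <- order(means)
  sorted <- means[ord]
  letters_sorted <- duncan_letters(sorted, crit)
  letters <- stats::setNames(character(k), names(groups))
  letters[names(sorted)] <- letters_sorted

  structure(list(group_means = means, letters = letters, mse = mse,
                 df = df, n_harmonic = nh, critical_ranges = crit,
                 alpha = alpha),
            class = "duncan_result")
}

# Shortest-significant-range sweep over sorted means. nonsig[i, j] is
# set for every span contained in a span whose range fell below its
# critical value; subspans of homogeneous spans are shielded from
# further testing, per Duncan's procedure.
duncan_nonsig <- function(sorted_means, crit) {
  k <- length(sorted_means)
  nonsig <- matrix(FALSE, k, k)
  declare <- function(i, j) {
    if (j <= i) return(invisible(NULL))
    if (nonsig[i, j]) return(invisible(NULL))
    p <- j - i + 1L
    if (sorted_means[j] - sorted_means[i] <= crit[[as.character(p)]]) {
      for (a in i:j) for (b in a:j) nonsig[a, b] <<- TRUE
    } else {
      declare(i, j - 1L)
      declare(i + 1L, j)
    }
    invisible(NULL)
  }
  declare(1L, k)
  nonsig
}

duncan_letters <- function(sorted_means, crit) {
  k <- length(sorted_means)
  nonsig <- duncan_nonsig(sorted_means, crit)
  # maximal homogeneous runs over the sorted means
  runs <- list()
  for (i in 1:k) {
    j <- i
    while (j < k && nonsig[i, j + 1L]) j <- j + 1L
    runs[[length(runs) + 1L]] <- c(i, j)
  }
  # drop runs contained in an earlier (longer) run
  keep <- rep(TRUE, length(runs))
  for (a in seq_along(runs)) for (b in seq_along(runs)) {
    if (a != b && keep[a] &&
        runs[[b]][1] <= runs[[a]][1] && runs[[a]][2] <= runs[[b]][2] &&
        !identical(runs[[a]], runs[[b]]))
      keep[a] <- FALSE
  }
  runs <- unique(runs[keep])
  out <- character(k)
  for (r in seq_along(runs)) {
    idx <- runs[[r]][1]:runs[[r]][2]
    out[idx] <- paste0(out[idx], letters[((r - 1L) %% 26L) + 1L])
  }
  names(out) <- names(sorted_means)
  out
}

#' @export
print.duncan_result <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, df = %d, MSE = %.4g)\n",
              x$alpha, x$df, x$mse))
  ord <- order(x$group_means)
  print(data.frame(mean = x$group_means[ord], letters = x$letters[ord]))
  invisible(x)
}

#' Duncan's test across species for every analyte
#'
#' Runs [duncan_mrt()] per analyte on substituted per-sample values,
#' grouping by species. Analytes for which fewer than two species have
#' at least two observations are skipped.
#'
#' @inheritParams summarize_measurements
#' @param alpha significance level, default 0.05.
#' @return data.frame `analyte_id`, `species`, `mean`, `letters`,
#'   `mse`, `df`.
#' @export
duncan_by_analyte <- function(ms, policy = censoring_policy(), alpha = 0.05) {
  stopifnot(inherits(ms, "measurement_set"))
  rec <- ms$records
  rec$subst <- substitute_censored(rec, ms$panel, policy)
  rows <- list()
  for (a in sort(unique(rec$analyte_id))) {
    sub <- rec[rec$analyte_id == a, , drop = FALSE]
    groups <- split(sub$subst, sub$species)
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) < 2L) next
    res <- duncan_mrt(groups, alpha = alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      analyte_id = a, species = names(res$group_means),
      mean = unname(res$group_means),
      letters = unname(res$letters[names(res$group_means)]),
      mse = res$mse, df = res$df, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(analyte_id = character(), species = character(),
                      mean = numeric(), letters = character(),
                      mse = numeric(), df = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
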
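# Shared builders and independent oracles for the test suite.

make_records <- function(species, analyte_id, values,
                         batch_id = "B01", prefix = "S") {
  n <- length(values)
  data.frame(
    sample_id = sprintf("%s_%s%03d", species, prefix, seq_len(n)),
    batch_id = batch_id, species = species, analyte_id = analyte_id,
    value = values, censored = is.na(values), stringsAsFactors = FALSE)
}

tiny_ms <- function(records) {
  measurement_set(records, panel = default_panel())
}

# Independent Duncan oracle: iterative shortest-significant-range
# procedure. Spans are visited in decreasing size; a span contained in
# one already declared homogeneous is shielded from testing. Letters
# come straight from the maximal homogeneous spans over the sorted
# means (uncovered means get their own letter).
duncan_oracle <- function(groups, alpha = 0.05) {
  k <- length(groups)
  ni <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  df <- sum(ni) - k
  mse <- sum((ni - 1) * vapply(groups, var, numeric(1))) / df
  nh <- k / sum(1 / ni)
  ord <- order(means)
  sorted <- means[ord]

  homogeneous <- list()
  contained <- function(i, j) {
    any(vapply(homogeneous,
               function(h) h[1] <= i && j <= h[2], logical(1)))
  }
  for (p in k:2) {
    crit <- qtukey((1 - alpha)^(p - 1), nmeans = p, df = df) * sqrt(mse / nh)
    for (i in seq_len(k - p + 1L)) {
      j <- i + p - 1L
      if (contained(i, j)) next
      if (sorted[j] - sorted[i] <= crit)
        homogeneous[[length(homogeneous) + 1L]] <- c(i, j)
    }
  }
  lett <- character(k)
  nxt <- 1L
  if (length(homogeneous)) {
    homogeneous <- homogeneous[order(vapply(homogeneous, `[`, 0, 1))]
    for (h in homogeneous) {
      idx <- h[1]:h[2]
      lett[idx] <- paste0(lett[idx], letters[nxt])
      nxt <- nxt + 1L
    }
  }
  for (i in seq_len(k)) {
    if (!nzchar(lett[i])) {
      lett[i] <- letters[nxt]
      nxt <- nxt + 1L
    }
  }
  names(lett) <- names(sorted)
  lett
}

# Two lettered partitions encode the same grouping when every pair of
# groups agrees on "shares a letter or not".
same_letter_partition <- function(a, b) {
  stopifnot(setequal(names(a), names(b)))
  nm <- names(a)
  shares <- function(x, i, j) {
    length(intersect(strsplit(x[[i]], "")[[1]],
                     strsplit(x[[j]], "")[[1]])) > 0
  }
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i < j &&
          shares(a, nm[i], nm[j]) != shares(b, nm[i], nm[j]))
        return(FALSE)
    }
  }
  TRUE
}
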
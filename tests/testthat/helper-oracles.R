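# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# 4-connected component count of a logical matrix (breadth-first flood fill)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] && lab[i, j] == 0L) {
        nxt <- nxt + 1L
        queue <- list(c(i, j))
        lab[i, j] <- nxt
        while (length(queue) > 0) {
          p <- queue[[1]]
          queue <- queue[-1]
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            q <- p + d
            if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
                q[2] <= ncol(mask) && mask[q[1], q[2]] &&
                lab[q[1], q[2]] == 0L) {
              lab[q[1], q[2]] <- nxt
              queue[[length(queue) + 1]] <- q
            }
          }
        }
      }
    }
  }
  nxt
}

# one-way ANOVA F from explicit sums of squares
anova_f_brute <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  ss_within <- sum(unlist(tapply(values, groups, function(v) {
    (v - mean(v))^2
  })))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  (ss_between / df1) / (ss_within / df2)
}

# minimal pattern_image for images built directly in tests
as_pattern_image <- function(pixels, mm_per_pixel, label = "test") {
  structure(list(pixels = pixels, mm_per_pixel = mm_per_pixel,
                 species_label = label, provenance = "generated",
                 spec = NULL),
            class = "pattern_image")
}

# strict local maxima count of a numeric vector above a floor
count_local_maxima <- function(v, floor = 1e-9) {
  n <- length(v)
  sum(vapply(2:(n - 1), function(i) {
    v[i] > floor && v[i] > v[i - 1] && v[i] > v[i + 1]
  }, logical(1)))
}
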